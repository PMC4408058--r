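# A compact Levenberg-Marquardt nonlinear least-squares solver with a
# central-difference Jacobian. Written in-package because no LM library is
# available in the build environment; behaves like the classic damped
# Gauss-Newton: lambda shrinks on accepted steps, grows on rejected ones.
# Steps are clamped (callers optimise on log scales, where a step of 10 is
# already a factor e^10) and non-finite candidates are rejected outright.

marquardt <- function(resid_fn, par, max_iter = 200, tol = 1e-12,
                      lambda0 = 1e-3, max_step = 5) {
  par <- as.numeric(p0 <- par)
  names(par) <- names(p0)
  r <- resid_fn(par)
  if (!all(is.finite(r))) abort("non-finite residuals at the start values")
  rss <- sum(r^2)
  lambda <- lambda0
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    J <- num_jacobian(resid_fn, par)
    if (!all(is.finite(J))) break
    g <- crossprod(J, r)                  # gradient of rss / 2
    A <- crossprod(J)
    if (!all(is.finite(g)) || sqrt(sum(g^2)) < 1e-12 * (1 + sqrt(rss))) {
      converged <- all(is.finite(g))
      break
    }
    improved <- FALSE
    for (k in 1:40) {
      damp <- A + lambda * diag(pmax(diag(A), 1e-12), nrow(A))
      step <- tryCatch(drop(solve(damp, g)), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        smax <- max(abs(step))
        if (smax > max_step) step <- step * (max_step / smax)
        cand <- par - step
        rc <- resid_fn(cand)
        if (all(is.finite(rc))) {
          rss_c <- sum(rc^2)
          if (rss_c <= rss) {
            rel <- (rss - rss_c) / max(rss, 1e-300)
            par <- cand; r <- rc; rss <- rss_c
            lambda <- max(lambda / 10, 1e-12)
            improved <- TRUE
            if (rel < tol || rss < 1e-300) converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!improved) {
      # no downhill step found: we are at (or numerically on) a minimum
      converged <- TRUE
      break
    }
    if (converged) break
  }
  list(par = par, rss = rss, converged = converged, iterations = iter)
}

num_jacobian <- function(f, x, h = NULL) {
  f0 <- f(x)
  if (is.null(h)) h <- pmax(1e-7, abs(x) * 1e-7)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h[i]
    J[, i] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  J
}
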