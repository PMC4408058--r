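# Holling functional-response models for per-cell kill counts versus
# expected abundance, fitted by unweighted Gaussian least squares:
#   type I   y = a + b * N            (linear, opportunistic predation)
#   type II  y = k * N / (x + N)      (hyperbolic, specialist; saturating)
#   type III y = k * N^r / (x^r + N^r) (sigmoidal, generalist)
# where k is the asymptotic kill rate, x the abundance at which killing
# reaches k/2 and r a "learning" exponent (type III reduces to type II at
# r = 1). Model support is judged by small-sample corrected AIC, with
# models within 2 AICc units regarded as equally supported.

fr_forms <- c("I", "II", "III")

#' Construct a functional-response model
#'
#' @param form "I", "II" or "III".
#' @param ... Named parameters: `a`, `b` for type I; `k`, `x` for type II;
#'   `k`, `x`, `r` for type III.
#' @return An `fr_model`.
#' @export
fr_model <- function(form, ...) {
  form <- match.arg(form, fr_forms)
  params <- c(...)
  need <- switch(form, I = c("a", "b"), II = c("k", "x"), III = c("k", "x", "r"))
  if (!setequal(names(params), need)) {
    abort(sprintf("type %s needs parameters %s", form, paste(need, collapse = ", ")))
  }
  params <- params[need]
  if (form %in% c("II", "III") && (params["k"] <= 0 || params["x"] <= 0)) {
    abort("type II/III require k > 0 and x > 0")
  }
  if (form == "III" && params["r"] <= 0) abort("type III requires r > 0")
  structure(list(form = form, params = params), class = "fr_model")
}

#' Predicted kills at a given abundance
#'
#' Evaluates the response curve literally; a type I line may predict
#' negative kills at low abundance and is reported as-is.
#'
#' @param model An [fr_model()].
#' @param abundance Abundance per full cell (vector, >= 0).
#' @return Expected kills per full cell.
#' @export
fr_predict <- function(model, abundance) {
  if (any(abundance < 0)) abort("abundance must be >= 0")
  p <- model$params
  switch(model$form,
    I = p["a"] + p["b"] * abundance,
    II = p["k"] * abundance / (p["x"] + abundance),
    III = {
      nr <- abundance^p["r"]
      p["k"] * nr / (p["x"]^p["r"] + nr)
    }
  ) |> unname()
}

#' Small-sample corrected AIC for a least-squares fit
#'
#' `AICc = n log(rss / n) + 2 p + 2 p (p + 1) / (n - p - 1)` with
#' `p = p_curve + 1`: the Gaussian error variance counts as a parameter,
#' the standard least-squares convention.
#'
#' @param rss Residual sum of squares (> 0; a perfect fit has no defined
#'   AICc and is an error — the caller should report a perfect fit).
#' @param n Number of data points.
#' @param p_curve Number of curve parameters (2 for I and II, 3 for III).
#' @return AICc value.
#' @export
fr_aicc <- function(rss, n, p_curve) {
  p <- p_curve + 1
  if (rss <= 0) abort("AICc is undefined at rss = 0 (perfect fit)")
  if (n <= p + 1) abort(sprintf("AICc needs n > p + 1 (n = %d, p = %d)", n, p))
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

default_starts <- function(form, abundance, kills) {
  k0 <- max(2 * max(kills), 1e-3)
  x0 <- max(median(abundance), 1e-3)
  switch(form,
    I = {
      b <- stats::coef(stats::lm(kills ~ abundance))
      list(c(a = unname(b[1]), b = unname(b[2])))
    },
    II = list(c(k = k0, x = x0)),
    # the high r start matters: sigmoid responses near a step need it
    III = lapply(c(1, 2, 8), function(r0) c(k = k0, x = x0, r = r0))
  )
}

#' Fit one functional-response form by Levenberg-Marquardt least squares
#'
#' Type I is solved in closed form (ordinary least squares). Types II and
#' III are fitted by a damped Gauss-Newton (Levenberg-Marquardt) search on
#' the log scale of `k`, `x` (and `r`), from multiple default starts;
#' the best residual sum of squares wins. Standard errors come from the
#' Jacobian at the optimum.
#'
#' @param form "I", "II" or "III".
#' @param data Tibble/data frame with columns `abundance` and `kills`
#'   (full-cell scaled values; kills may be fractional).
#' @param starts Optional list of named start vectors overriding the
#'   defaults.
#' @return An `fr_fit` with elements `model`, `se`, `rss`, `n`, `aicc`,
#'   `converged`, `perfect_fit`, `fitted`, `residuals`.
#' @export
fit_model <- function(form, data, starts = NULL) {
  form <- match.arg(form, fr_forms)
  abundance <- data$abundance
  kills <- data$kills
  n <- length(kills)
  p_curve <- if (form == "III") 3L else 2L
  if (n < p_curve + 2) abort(sprintf("type %s needs at least %d points", form, p_curve + 2))

  if (form == "I") {
    fit <- stats::lm(kills ~ abundance)
    cf <- stats::coef(fit)
    params <- c(a = unname(cf[1]), b = unname(cf[2]))
    rss <- sum(stats::residuals(fit)^2)
    # vcov warns on an exact-interpolation fit; SEs are ~0 there anyway
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    names(se) <- c("a", "b")
    converged <- TRUE
  } else {
    to_nat <- function(th) exp(th)
    resid_fn <- function(th) {
      pr <- to_nat(th)
      m <- list(form = form, params = pr)
      class(m) <- "fr_model"
      kills - fr_predict(m, abundance)
    }
    starts <- starts %||% default_starts(form, abundance, kills)
    best <- NULL
    for (st in starts) {
      res <- tryCatch(marquardt(resid_fn, log(pmax(st, 1e-8))),
                      error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
    }
    if (is.null(best)) {
      abort(sprintf("type %s fit failed from every start", form))
    }
    params <- to_nat(best$par)
    names(params) <- if (form == "II") c("k", "x") else c("k", "x", "r")
    rss <- best$rss
    converged <- best$converged
    # SEs on the natural scale from the Jacobian of predictions
    se <- tryCatch({
      pred_fn <- function(pr) {
        m <- list(form = form, params = setNames(pr, names(params)))
        class(m) <- "fr_model"
        fr_predict(m, abundance)
      }
      J <- num_jacobian(pred_fn, params)
      s2 <- rss / (n - p_curve)
      V <- s2 * solve(crossprod(J))
      sqrt(pmax(diag(V), 0))
    }, error = function(e) rep(NA_real_, length(params)))
    names(se) <- names(params)
  }

  perfect <- rss <= .Machine$double.eps * max(1, sum(kills^2))
  aicc <- if (perfect) -Inf else fr_aicc(rss, n, p_curve)
  model <- structure(list(form = form, params = params), class = "fr_model")
  structure(list(
    model = model, se = se, rss = rss, n = n, p_curve = p_curve,
    aicc = aicc, converged = converged, perfect_fit = perfect,
    fitted = fr_predict(model, abundance),
    residuals = kills - fr_predict(model, abundance),
    data = tibble::tibble(abundance = abundance, kills = kills)
  ), class = "fr_fit")
}

#' @export
print.fr_fit <- function(x, ...) {
  cat(sprintf("<fr_fit> type %s: %s | rss = %.4g, AICc = %.4g%s\n",
              x$model$form,
              paste(sprintf("%s = %.4g", names(x$model$params), x$model$params),
                    collapse = ", "),
              x$rss, x$aicc,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
tidy.fr_fit <- function(x, ...) {
  tibble::tibble(form = x$model$form, term = names(x$model$params),
                 estimate = unname(x$model$params),
                 std.error = unname(x$se[names(x$model$params)]))
}

#' @export
glance.fr_fit <- function(x, ...) {
  tibble::tibble(form = x$model$form, rss = x$rss, n = x$n,
                 AICc = x$aicc, converged = x$converged)
}

#' Compare functional-response fits by AICc
#'
#' Computes delta AICc against the best model and the equal-support set
#' (all forms within `threshold` AICc units of the best). Unconverged fits
#' are excluded with a warning. Also accepts a bare named vector of AICc
#' values (e.g. published table values) in place of fitted objects.
#'
#' @param fits List of `fr_fit` objects, or a named numeric vector of AICc
#'   values (names = forms).
#' @param threshold Equal-support threshold in AICc units (default 2).
#' @return An `fr_comparison` tibble: `form`, `aicc`, `delta_aicc`,
#'   `equal_support`; the fits (when given) ride along as an attribute.
#' @export
compare_models <- function(fits, threshold = 2) {
  if (is.numeric(fits)) {
    tbl <- tibble::tibble(form = names(fits), aicc = unname(fits))
    kept <- NULL
  } else {
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (any(!conv)) {
      warn(sprintf("excluding unconverged fit(s): %s",
                   paste(vapply(fits[!conv], function(f) f$model$form, ""),
                         collapse = ", ")))
    }
    kept <- fits[conv]
    if (length(kept) == 0) abort("no converged fits to compare")
    tbl <- tibble::tibble(
      form = vapply(kept, function(f) f$model$form, ""),
      aicc = vapply(kept, function(f) f$aicc, numeric(1))
    )
  }
  tbl$delta_aicc <- tbl$aicc - min(tbl$aicc)
  tbl$equal_support <- tbl$delta_aicc <= threshold
  out <- dplyr::arrange(tbl, .data$delta_aicc)
  attr(out, "fits") <- kept
  attr(out, "threshold") <- threshold
  class(out) <- c("fr_comparison", class(out))
  out
}

#' Equal-support set of a comparison
#' @param comparison An `fr_comparison`.
#' @return Character vector of forms with delta AICc below the threshold.
#' @export
equal_support <- function(comparison) {
  comparison$form[comparison$equal_support]
}

#' Residual diagnostics for a functional-response fit
#'
#' Standardised residuals (residual / sqrt(rss / (n - p))), outlier flags
#' at |z| > 3 and a Shapiro-Wilk normality summary. Reports only; no
#' points are ever dropped automatically.
#'
#' @param fit A converged `fr_fit`.
#' @return Tibble with `abundance`, `kills`, `residual`, `std_residual`,
#'   `outlier`; Shapiro-Wilk statistic and p-value as attributes.
#' @export
fr_diagnostics <- function(fit) {
  if (!isTRUE(fit$converged)) abort("diagnostics need a converged fit")
  s <- sqrt(max(fit$rss / (fit$n - fit$p_curve), 0))
  z <- if (s > 0) fit$residuals / s else rep(0, fit$n)
  out <- dplyr::mutate(fit$data, residual = fit$residuals,
                       std_residual = z, outlier = abs(z) > 3)
  sw <- if (fit$n >= 3 && s > 0) shapiro.test(fit$residuals) else NULL
  attr(out, "shapiro_W") <- if (is.null(sw)) NA_real_ else unname(sw$statistic)
  attr(out, "shapiro_p") <- if (is.null(sw)) NA_real_ else sw$p.value
  out
}

#' Plot data and fitted functional-response curves
#'
#' @param object An `fr_comparison` built from fitted objects.
#' @param ... Unused.
#' @return A ggplot object: per-cell points plus one curve per fitted form.
#' @export
autoplot.fr_comparison <- function(object, ...) {
  fits <- attr(object, "fits")
  if (is.null(fits) || length(fits) == 0) {
    abort("this comparison carries no fitted objects to plot")
  }
  dat <- fits[[1]]$data
  grid <- tibble::tibble(abundance = seq(0, max(dat$abundance), length.out = 200))
  curves <- purrr::map_dfr(fits, function(f) {
    dplyr::mutate(grid, kills = fr_predict(f$model, grid$abundance),
                  form = f$model$form)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$abundance, y = .data$kills)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$form), linewidth = 0.7) +
    ggplot2::labs(x = "Expected abundance per full cell",
                  y = "Animals killed per full cell", colour = "Response type") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
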