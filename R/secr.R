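# Maximum-likelihood spatially explicit capture-recapture (SECR) with a
# half-normal detection function. Detections are modelled as independent
# Bernoulli trials per (occasion, detector) — binary proximity detectors —
# with probability declining with distance between the detector and the
# animal's latent activity centre. The likelihood is conditional on
# capture, with g0 and sigma free to differ by sex; density follows from a
# Horvitz-Thompson sum of inverse effective sampling areas.

#' Half-normal detection function
#'
#' Detection probability at distance `d` from an activity centre:
#' `g0 * exp(-d^2 / (2 * sigma^2))`.
#'
#' @param d Distance(s), km, `>= 0`.
#' @param g0 Detection probability at the centre, in (0, 1).
#' @param sigma Spatial scale of the decline, km, `> 0`.
#' @return Detection probabilities, same length as `d`.
#' @export
halfnormal <- function(d, g0, sigma) {
  if (any(d < 0)) abort("distances must be >= 0")
  if (g0 <= 0 || g0 >= 1) abort("g0 must lie strictly in (0, 1)")
  if (sigma <= 0) abort("sigma must be > 0")
  g0 * exp(-d^2 / (2 * sigma^2))
}

#' Build a habitat mask for likelihood integration
#'
#' A regular lattice of candidate activity-centre locations covering the
#' detector bounding box expanded by `buffer` on every side.
#'
#' @param detectors A [detector_array].
#' @param buffer Buffer width, km (> 0). A buffer of ~4 sigma is ample.
#' @param spacing Lattice spacing, km (> 0); each point represents a cell
#'   of `spacing^2` km^2.
#' @return Tibble of mask points `x`, `y` with attributes `cell_area`,
#'   `spacing`, `buffer`; class `secr_mask`.
#' @export
build_mask <- function(detectors, buffer, spacing = buffer / 16) {
  stopifnot(inherits(detectors, "detector_array"))
  if (buffer <= 0 || spacing <= 0) abort("buffer and spacing must be > 0")
  if (spacing > buffer) {
    warn("mask spacing exceeds buffer: the integration lattice is very coarse")
  }
  xy <- detector_coords(detectors)
  xs <- seq(min(xy[, 1]) - buffer, max(xy[, 1]) + buffer, by = spacing)
  ys <- seq(min(xy[, 2]) - buffer, max(xy[, 2]) + buffer, by = spacing)
  mask <- tibble::tibble(x = rep(xs, times = length(ys)),
                         y = rep(ys, each = length(xs)))
  attr(mask, "cell_area") <- spacing^2
  attr(mask, "spacing") <- spacing
  attr(mask, "buffer") <- buffer
  class(mask) <- c("secr_mask", class(mask))
  mask
}

# distances: detectors x points
dist_matrix <- function(det_xy, pts_xy) {
  dx <- outer(det_xy[, 1], pts_xy[, 1], "-")
  dy <- outer(det_xy[, 2], pts_xy[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Probability of one individual's capture history at a given centre
#'
#' Product of independent Bernoulli terms over every active (occasion,
#' detector) pair: detected cells contribute `p_kd`, undetected active
#' cells `1 - p_kd`, with `p_kd = halfnormal(distance, g0, sigma)`.
#'
#' @param history Binary occasions x detectors matrix for one individual.
#' @param centre Numeric `(x, y)`, km.
#' @param detectors A [detector_array].
#' @param g0,sigma Detection parameters for this individual's sex.
#' @return Probability in \[0, 1\].
#' @export
history_prob <- function(history, centre, detectors, g0, sigma) {
  usage <- detectors$usage
  history <- as.matrix(history)
  if (!all(dim(history) == dim(usage))) {
    abort("history must be an occasions x detectors matrix matching usage")
  }
  if (any(history == 1 & usage == 0)) {
    abort("detection recorded on an occasion where the detector's usage is 0")
  }
  d <- sqrt(colSums((t(detector_coords(detectors)) - centre)^2))
  p <- halfnormal(d, g0, sigma)
  # occasions are exchangeable given usage: aggregate per detector
  y_d <- colSums(history)
  k_d <- colSums(usage)
  # avoid 0 * log(0) at detectors far beyond detection range
  exp(sum(ifelse(y_d > 0, y_d * log(p), 0) + (k_d - y_d) * log1p(-p)))
}

#' Probability of detecting an animal at least once
#'
#' `1 - prod(1 - p_kd)` over all active (occasion, detector) pairs for an
#' activity centre at `centre`.
#'
#' @inheritParams history_prob
#' @return Probability in \[0, 1\].
#' @export
p_dot <- function(centre, detectors, g0, sigma) {
  d <- sqrt(colSums((t(detector_coords(detectors)) - centre)^2))
  p <- halfnormal(d, g0, sigma)
  k_d <- colSums(detectors$usage)
  -expm1(sum(k_d * log1p(-p)))
}

# vectorised log(p.) over all mask points for one sex
log_pdot_mask <- function(detectors, mask, g0, sigma) {
  D <- dist_matrix(detector_coords(detectors), cbind(mask$x, mask$y))
  P <- halfnormal(D, g0, sigma)
  k_d <- colSums(detectors$usage)
  log_surv <- colSums(k_d * log1p(-P))     # log prod (1-p)^k over detectors
  log1p(-exp(log_surv))                    # log p_dot
}

#' Effective sampling area for one sex
#'
#' The mask integral of the probability of at least one detection,
#' `a = sum p_dot(s) * cell_area` — the divisor of the Horvitz-Thompson
#' density estimator.
#'
#' @param detectors A [detector_array].
#' @param mask A mask from [build_mask()].
#' @param g0,sigma Detection parameters.
#' @return Area in km^2.
#' @export
effective_area <- function(detectors, mask, g0, sigma) {
  a <- sum(exp(log_pdot_mask(detectors, mask, g0, sigma))) * attr(mask, "cell_area")
  if (a <= 0) abort("degenerate fit: effective sampling area is zero")
  a
}

# per-individual detection count matrices, split by sex:
# list(sex -> list(Y = individuals x detectors counts, ids))
capture_tallies <- function(cd) {
  dets <- cd$detectors$detectors$detector
  out <- list()
  for (sx in intersect(c("M", "F"), unique(cd$captures$sex))) {
    sub <- cd$captures[cd$captures$sex == sx, ]
    ids <- sort(unique(sub$individual))
    Y <- matrix(0L, length(ids), length(dets), dimnames = list(ids, dets))
    tab <- table(factor(sub$individual, ids), factor(sub$detector, dets))
    Y[] <- as.integer(tab)
    out[[sx]] <- list(ids = ids, Y = Y)
  }
  out
}

# conditional log-likelihood contribution of one sex group, vectorised
# over mask points. params = c(g0, sigma).
loglik_sex <- function(Y, detectors, mask, g0, sigma) {
  D <- dist_matrix(detector_coords(detectors), cbind(mask$x, mask$y))
  P <- halfnormal(D, g0, sigma)
  k_d <- colSums(detectors$usage)
  logP <- log(pmax(P, 1e-300))  # floor keeps 0 * -Inf out of the matrix product
  log1mP <- log1p(-P)
  # log Pr(history_i | centre s): individuals x mask
  LH <- Y %*% logP + (matrix(k_d, nrow(Y), length(k_d), byrow = TRUE) - Y) %*% log1mP
  log_surv <- colSums(k_d * log1mP)
  log_pdot <- log1p(-exp(log_surv))
  cell <- attr(mask, "cell_area")
  log_a <- log(sum(exp(log_pdot))) + log(cell)
  # log sum_s exp(LH_i(s)) * cell, stabilised per individual
  mx <- apply(LH, 1, max)
  log_num <- mx + log(rowSums(exp(LH - mx))) + log(cell)
  sum(log_num - log_a)
}

#' Conditional SECR log-likelihood
#'
#' Sum over captured individuals of the log probability of their capture
#' history given capture at least once, integrating activity centres over
#' the habitat mask. `g0` and `sigma` may differ by sex.
#'
#' @param cd A [capture_data] (every individual sexed).
#' @param params List with numeric `g0` and `sigma`; either scalars
#'   (shared across sexes) or named vectors `c(M = , F = )`.
#' @param mask A mask from [build_mask()].
#' @return Log-likelihood (finite for valid parameters).
#' @export
conditional_loglik <- function(cd, params, mask) {
  stopifnot(inherits(cd, "capture_data"))
  if (nrow(cd$captures) == 0) abort("no captured individuals")
  tallies <- capture_tallies(cd)
  ll <- 0
  for (sx in names(tallies)) {
    g0 <- if (length(params$g0) > 1) params$g0[[sx]] else params$g0
    sigma <- if (length(params$sigma) > 1) params$sigma[[sx]] else params$sigma
    ll <- ll + loglik_sex(tallies[[sx]]$Y, cd$detectors, mask, g0, sigma)
  }
  if (!is.finite(ll)) {
    abort(sprintf("non-finite conditional log-likelihood at g0=%s sigma=%s",
                  paste(signif(params$g0, 4), collapse = "/"),
                  paste(signif(params$sigma, 4), collapse = "/")))
  }
  ll
}

#' Data-driven initial sigma guess
#'
#' Half the maximum distance between detectors at which the same individual
#' was recorded; falls back to half the median inter-detector spacing when
#' no individual moved between detectors.
#'
#' @param cd A [capture_data].
#' @return Sigma guess, km.
#' @export
init_sigma <- function(cd) {
  xy <- detector_coords(cd$detectors)
  rownames(xy) <- cd$detectors$detectors$detector
  dmax <- 0
  for (id in unique(cd$captures$individual)) {
    dets <- unique(cd$captures$detector[cd$captures$individual == id])
    if (length(dets) > 1) {
      dd <- stats::dist(xy[dets, , drop = FALSE])
      dmax <- max(dmax, max(dd))
    }
  }
  if (dmax > 0) return(dmax / 2)
  d <- stats::dist(xy)
  max(stats::median(d) / 2, 1e-3)
}

#' Fit the SECR model by maximising the conditional likelihood
#'
#' Optimises on the transformed scale (logit g0, log sigma) with a
#' quasi-Newton method, then derives density via Horvitz-Thompson: each
#' captured individual contributes the inverse of its sex's effective
#' sampling area. The reported SE of density combines Horvitz-Thompson
#' variation with parameter uncertainty (inverse-Hessian delta method).
#'
#' @param cd A [capture_data].
#' @param mask Optional mask; defaults to [build_mask()] with buffer
#'   `4 * init_sigma(cd)` and spacing `buffer/16`.
#' @param init Optional list `list(g0 = , sigma = )` of starting values
#'   (scalars, recycled across sexes).
#' @param sex_specific Fit separate (g0, sigma) per sex (default TRUE;
#'   needs >= 2 individuals of each observed sex).
#' @param reltol Convergence tolerance on the log-likelihood (default 1e-8).
#' @return A `secr_fit`: parameter tibble, log-likelihood, density with SE,
#'   per-sex sample sizes and a convergence flag.
#' @export
fit_secr <- function(cd, mask = NULL, init = NULL, sex_specific = TRUE,
                     reltol = 1e-8) {
  stopifnot(inherits(cd, "capture_data"))
  if (is.null(mask)) {
    buffer <- 4 * init_sigma(cd)
    mask <- build_mask(cd$detectors, buffer = buffer, spacing = buffer / 16)
  }
  tallies <- capture_tallies(cd)
  sexes <- names(tallies)
  n_by_sex <- vapply(tallies, function(t) length(t$ids), integer(1))
  if (sex_specific && any(n_by_sex < 2)) {
    abort("sex-specific fit needs >= 2 individuals per observed sex; use sex_specific = FALSE")
  }

  s0 <- if (!is.null(init)) init$sigma else init_sigma(cd)
  g0_0 <- if (!is.null(init)) init$g0 else {
    # crude moment start: detections per active detector-occasion, floored
    min(0.5, max(0.01, nrow(cd$captures) /
                   (sum(cd$detectors$usage) * max(1, sum(n_by_sex)))) * 5)
  }

  # degenerate design: no spatial information at all
  spatial_recap <- any(vapply(unique(cd$captures$individual), function(id) {
    length(unique(cd$captures$detector[cd$captures$individual == id])) > 1
  }, logical(1)))
  n_det_used <- length(unique(cd$captures$detector))
  degenerate <- !spatial_recap && n_det_used < 2

  theta0 <- if (sex_specific) {
    c(rep(stats::qlogis(g0_0), length(sexes)), rep(log(s0), length(sexes)))
  } else {
    c(stats::qlogis(g0_0), log(s0))
  }

  unpack <- function(theta) {
    if (sex_specific) {
      k <- length(sexes)
      list(g0 = setNames(stats::plogis(theta[seq_len(k)]), sexes),
           sigma = setNames(exp(theta[k + seq_len(k)]), sexes))
    } else {
      list(g0 = stats::plogis(theta[1]), sigma = exp(theta[2]))
    }
  }
  negll <- function(theta) {
    p <- unpack(theta)
    tryCatch(-conditional_loglik(cd, p, mask), error = function(e) 1e10)
  }

  opt <- tryCatch(
    optim(theta0, negll, method = "BFGS",
          control = list(reltol = reltol, maxit = 500), hessian = TRUE),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    opt <- optim(theta0, negll, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = 2000), hessian = TRUE)
  }
  params <- unpack(opt$par)
  vcov_theta <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  converged <- opt$convergence == 0 && !degenerate && !is.null(vcov_theta) &&
    all(is.finite(vcov_theta)) && all(diag(vcov_theta) >= 0)

  # per-sex effective areas and Horvitz-Thompson density
  area_of <- function(p, sx) {
    g0 <- if (length(p$g0) > 1) p$g0[[sx]] else p$g0
    sg <- if (length(p$sigma) > 1) p$sigma[[sx]] else p$sigma
    effective_area(cd$detectors, mask, g0, sg)
  }
  a_sex <- vapply(sexes, function(sx) area_of(params, sx), numeric(1))
  a_i <- rep(a_sex, times = n_by_sex)
  dens <- density_estimate(a_i)

  # parameter-uncertainty part of Var(D), delta method on transformed scale
  se_d <- dens$se
  if (!is.null(vcov_theta) && all(is.finite(vcov_theta))) {
    dfun <- function(theta) {
      p <- unpack(theta)
      a <- vapply(sexes, function(sx) area_of(p, sx), numeric(1))
      sum(n_by_sex / a) * 100
    }
    g <- num_grad(dfun, opt$par)
    v_par <- drop(t(g) %*% vcov_theta %*% g)
    if (is.finite(v_par) && v_par >= 0) se_d <- sqrt(dens$se^2 + v_par)
  }

  # parameter SEs back-transformed
  par_se <- rep(NA_real_, length(opt$par))
  if (!is.null(vcov_theta)) {
    vd <- diag(vcov_theta)
    vd[vd < 0] <- NA
    par_se <- sqrt(vd)
  }
  k <- if (sex_specific) length(sexes) else 1
  par_tbl <- tibble::tibble(
    sex = if (sex_specific) sexes else "pooled",
    g0 = as.numeric(if (sex_specific) params$g0 else params$g0[1]),
    g0_se = par_se[seq_len(k)] * params$g0 * (1 - params$g0),  # logit delta
    sigma = as.numeric(if (sex_specific) params$sigma else params$sigma[1]),
    sigma_se = par_se[k + seq_len(k)] * params$sigma            # log delta
  )

  structure(list(
    params = par_tbl,
    loglik = -opt$value,
    density = dens$estimate,
    density_se = se_d,
    n_individuals = n_by_sex,
    effective_areas = a_sex,
    converged = converged,
    degenerate = degenerate,
    sex_specific = sex_specific,
    mask = mask,
    vcov = vcov_theta,
    theta = opt$par
  ), class = "secr_fit")
}

# central-difference gradient
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Horvitz-Thompson density from per-individual effective areas
#'
#' `D = sum(1 / a_i) * 100` animals per 100 km^2; the reported SE here is
#' the Horvitz-Thompson (sampling) component `100 * sqrt(sum(1 / a_i^2))`;
#' [fit_secr()] adds the parameter-uncertainty component.
#'
#' @param areas Per-individual effective sampling areas, km^2, all > 0.
#' @return List with `estimate` and `se` (per 100 km^2).
#' @export
density_estimate <- function(areas) {
  if (any(areas <= 0)) abort("all effective areas must be > 0")
  list(estimate = sum(1 / areas) * 100, se = 100 * sqrt(sum(1 / areas^2)))
}

#' @export
print.secr_fit <- function(x, ...) {
  cat(sprintf("<secr_fit> D = %.3f per 100 km^2 (SE %.3f), logLik %.3f, %s\n",
              x$density, x$density_se, x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED"))
  print(x$params)
  invisible(x)
}

#' @export
tidy.secr_fit <- function(x, ...) {
  tidyr::pivot_longer(x$params, cols = c("g0", "sigma"),
                      names_to = "term", values_to = "estimate") |>
    dplyr::mutate(std.error = ifelse(.data$term == "g0", .data$g0_se, .data$sigma_se)) |>
    dplyr::select("sex", "term", "estimate", "std.error")
}

#' @export
glance.secr_fit <- function(x, ...) {
  tibble::tibble(
    density = x$density, density_se = x$density_se, logLik = x$loglik,
    n_individuals = sum(x$n_individuals), converged = x$converged
  )
}
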