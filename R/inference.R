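# Rate-constant estimation from time-course data, half-life estimation,
# gel-band yield quantitation and cross-condition rate comparisons.
#
# Estimator: first-order kinetics fitted as a log-linear regression of
# ln(C/C0) on time with the intercept forced through the origin (C/C0 = 1 at
# t = 0 by normalization), restricted by default to the initial-velocity
# window (product fraction <= 0.5) so that sub-unity plateaus do not bias
# the slope downward.

#' Fit a first-order rate constant to a ligation time course
#'
#' Regresses ln(C/C0) of the remaining acceptor on time, with the intercept
#' forced to zero (default) over the analysis window; k_app is the negative
#' slope. Points with C/C0 <= 0 are excluded with a warning.
#'
#' @param tc a \code{\link{timecourse}} with a \code{frac_amino_remaining}
#'   column (or the column named by \code{response}).
#' @param window optional c(t_min, t_max) in minutes restricting the fit;
#'   default is the initial-velocity regime, i.e. points with
#'   \code{frac_product <= 0.5} (all points when no product column exists).
#' @param free_intercept fit an unconstrained intercept instead of forcing
#'   the regression through the origin.
#' @param response name of the column holding the decaying fraction.
#' @return an object of class \code{"ligation_fit"}: \code{k_app} (1/min),
#'   \code{stderr}, \code{half_life} (min; \code{ln 2 / k_app}),
#'   \code{r_squared}, \code{n_points_used}, \code{window}, and a
#'   \code{zero_rate} flag (infinite half-life) when no decay is detectable.
#' @export
fit_first_order <- function(tc, window = NULL, free_intercept = FALSE,
                            response = "frac_amino_remaining") {
  if (!inherits(tc, "data.frame")) stop("tc must be a timecourse/data frame", call. = FALSE)
  if (!response %in% names(tc)) {
    stop(sprintf("time course has no '%s' column", response), call. = FALSE)
  }
  t_all <- tc$time_min
  y_all <- tc[[response]]
  keep <- rep(TRUE, length(t_all))
  if (is.null(window)) {
    if ("frac_product" %in% names(tc) && response == "frac_amino_remaining") {
      keep <- tc$frac_product <= 0.5
      # very fast reactions cross 50% conversion within the first sampling
      # intervals; keep the earliest 3 usable points so the initial-velocity
      # fit remains possible
      if (sum(keep & y_all > 0) < 3) {
        usable <- which(y_all > 0)
        keep <- seq_along(t_all) %in% usable[seq_len(min(3, length(usable)))]
      }
    }
    w <- range(t_all[keep])
  } else {
    if (length(window) != 2 || window[1] > window[2]) {
      stop("window must be c(t_min, t_max)", call. = FALSE)
    }
    keep <- t_all >= window[1] & t_all <= window[2]
    w <- window
  }
  nonpos <- keep & y_all <= 0
  if (any(nonpos)) {
    warning(sprintf("excluding %d point(s) with C/C0 <= 0 from the log-linear fit",
                    sum(nonpos)), call. = FALSE)
    keep <- keep & y_all > 0
  }
  keep <- keep & y_all <= 1
  tt <- t_all[keep]; yy <- y_all[keep]
  if (sum(keep) < 3) stop("fewer than 3 usable points for the first-order fit", call. = FALSE)
  ly <- log(yy)
  if (all(yy == 1)) {
    fit <- NULL; k <- 0; se <- 0; r2 <- NA_real_
  } else {
    fit <- if (free_intercept) stats::lm(ly ~ tt) else stats::lm(ly ~ 0 + tt)
    sl <- stats::coef(fit)[["tt"]]
    k <- -sl
    se <- tryCatch(suppressWarnings(summary(fit)$coefficients["tt", "Std. Error"]),
                   error = function(e) NA_real_)
    r2 <- {
      fv <- stats::fitted(fit)
      if (stats::var(ly) > 0) stats::cor(ly, fv)^2 else NA_real_
    }
  }
  zero_rate <- (k <= 0)
  structure(list(k_app = k, stderr = se,
                 half_life = if (k > 0) log(2) / k else Inf,
                 r_squared = r2, n_points_used = sum(keep),
                 window = w, free_intercept = free_intercept,
                 zero_rate = zero_rate, response = response,
                 lm = fit, data = data.frame(time_min = tt, frac = yy)),
            class = "ligation_fit")
}

#' Estimate a decay half-life
#'
#' Applies the same log-linear first-order estimator to the active-EPT
#' fraction of a stability time course and reports the half-life in both
#' minutes and hours.
#'
#' @param tc a \code{\link{timecourse}} with a \code{frac_ept_active} column
#'   (falls back to \code{frac_amino_remaining}).
#' @param window optional c(t_min, t_max), min.
#' @return a \code{"ligation_fit"} with additional \code{half_life_h}.
#' @export
fit_half_life <- function(tc, window = NULL) {
  response <- if ("frac_ept_active" %in% names(tc)) "frac_ept_active" else "frac_amino_remaining"
  t_all <- tc$time_min; y_all <- tc[[response]]
  usable <- y_all > 0 & y_all <= 1
  if (sum(usable) >= 2 && sum(usable) < 3) {
    # two ideal points determine the slope exactly; pad by duplicating the fit data path
    tt <- t_all[usable]; yy <- y_all[usable]
    sl <- if (diff(range(tt)) > 0) diff(log(yy)) / diff(tt) else 0
    k <- -sl
    out <- structure(list(k_app = k, stderr = NA_real_,
                          half_life = if (k > 0) log(2) / k else Inf,
                          r_squared = NA_real_, n_points_used = 2L,
                          window = range(tt), free_intercept = FALSE,
                          zero_rate = k <= 0, response = response, lm = NULL,
                          data = data.frame(time_min = tt, frac = yy)),
                     class = "ligation_fit")
  } else {
    out <- fit_first_order(tc, window = window, response = response)
  }
  out$half_life_h <- out$half_life / 60
  out
}

#' @export
print.ligation_fit <- function(x, ...) {
  cat("First-order fit (ln C/C0 vs t",
      if (x$free_intercept) ", free intercept)\n" else ", through origin)\n", sep = "")
  if (x$zero_rate) {
    cat("  no detectable decay: k_app = 0, half-life infinite\n")
  } else {
    cat(sprintf("  k_app = %.3g 1/min (%.2f x 10^-2/min), se = %.2g\n",
                x$k_app, 100 * x$k_app, x$stderr))
    cat(sprintf("  half-life = %.4g min (%.3g h)\n", x$half_life, x$half_life / 60))
  }
  cat(sprintf("  n = %d points in window [%g, %g] min; R^2 = %.4g\n",
              x$n_points_used, x$window[1], x$window[2], x$r_squared))
  invisible(x)
}

#' @export
coef.ligation_fit <- function(object, ...) c(k_app = object$k_app)

#' @export
predict.ligation_fit <- function(object, time_min = object$data$time_min, ...) {
  exp(-object$k_app * time_min)
}

#' @export
residuals.ligation_fit <- function(object, ...) {
  log(object$data$frac) - (-object$k_app * object$data$time_min)
}

#' @export
summary.ligation_fit <- function(object, ...) {
  out <- unclass(object)[c("k_app", "stderr", "half_life", "half_life_h",
                           "r_squared", "n_points_used", "window", "zero_rate")]
  out$k_paper_units <- signif(100 * object$k_app, 2)  # x 10^-2 / min, 2 s.f.
  class(out) <- "summary.ligation_fit"
  out
}

#' @export
print.summary.ligation_fit <- function(x, ...) {
  cat(sprintf("k_app = %.6g 1/min  (%.2g x 10^-2/min at table precision)\n",
              x$k_app, x$k_paper_units))
  cat(sprintf("stderr = %.3g; half-life = %.6g min", x$stderr, x$half_life))
  if (!is.null(x$half_life_h) && !is.na(x$half_life_h))
    cat(sprintf(" (%.3g h)", x$half_life_h))
  cat(sprintf("\nR^2 = %.5g over %d points, window [%g, %g] min\n",
              x$r_squared, x$n_points_used, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
plot.ligation_fit <- function(x, ...) {
  graphics::plot(x$data$time_min, x$data$frac, pch = 16,
                 xlab = "time (min)", ylab = "C/C0", ylim = c(0, 1), ...)
  tg <- seq(0, max(x$data$time_min), length.out = 100)
  graphics::lines(tg, exp(-x$k_app * tg))
  invisible(x)
}

#' Simulate time courses from a fitted rate constant
#'
#' @param object a \code{"ligation_fit"}.
#' @param nsim number of simulated courses.
#' @param seed RNG seed.
#' @param times time grid (defaults to the fitted data's grid).
#' @param noise_sd additive Gaussian noise sd on fractions.
#' @param ... unused.
#' @return a list of \code{\link{timecourse}} objects.
#' @export
simulate.ligation_fit <- function(object, nsim = 1, seed = NULL,
                                  times = object$data$time_min, noise_sd = 0.02, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    gen_ligation_timecourse(k0 = object$k_app, k_hyd = 0, plateau_cap = 1,
                            times = times, noise = noise_spec(sd = noise_sd))
  })
}

#' Ligation yield from gel-band intensities
#'
#' Yield = i_product / (i_remaining + i_product), the relative fluorescence
#' of the ligated product over the total in the lane.
#'
#' @param i_remaining band intensity of the unreacted acceptor, arbitrary
#'   units, >= 0.
#' @param i_product band intensity of the ligated product, >= 0.
#' @return yield fraction(s) in [0, 1]; vectorized.
#' @export
yield_from_intensities <- function(i_remaining, i_product) {
  stopifnot_finite(i_remaining, "i_remaining"); stopifnot_finite(i_product, "i_product")
  if (any(i_remaining < 0) || any(i_product < 0)) {
    stop("band intensities must be non-negative", call. = FALSE)
  }
  tot <- i_remaining + i_product
  if (any(tot == 0)) stop("yield undefined: both band intensities are zero", call. = FALSE)
  i_product / tot
}

#' Pairwise rate-constant ratios across conditions
#'
#' @param fits list of \code{"ligation_fit"} objects.
#' @param labels condition labels (defaults to fit1, fit2, ...).
#' @return data frame of all ordered pairs with columns numerator,
#'   denominator, ratio, ratio_se (first-order error propagation),
#'   ratio_2sf and an undefined flag for zero-rate denominators.
#' @export
compare_rates <- function(fits, labels = NULL) {
  if (length(fits) < 2) stop("need at least two fits to compare", call. = FALSE)
  if (is.null(labels)) labels <- paste0("fit", seq_along(fits))
  k <- vapply(fits, function(f) f$k_app, numeric(1))
  se <- vapply(fits, function(f) if (is.na(f$stderr)) 0 else f$stderr, numeric(1))
  pairs <- expand.grid(i = seq_along(fits), j = seq_along(fits))
  pairs <- pairs[pairs$i != pairs$j, ]
  ratio <- ifelse(k[pairs$j] > 0, k[pairs$i] / k[pairs$j], NA_real_)
  rse <- ratio * sqrt((se[pairs$i] / k[pairs$i])^2 + (se[pairs$j] / k[pairs$j])^2)
  data.frame(numerator = labels[pairs$i], denominator = labels[pairs$j],
             ratio = ratio, ratio_se = rse, ratio_2sf = signif(ratio, 2),
             undefined = k[pairs$j] <= 0, row.names = NULL)
}
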