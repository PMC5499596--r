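# Two-state melting curves and their least-squares analysis: the package's
# route from a UV-melt-style theta(T) profile to (dH, dS), hence K(T).

#' Melting curve container
#'
#' @param temp_C temperature grid, degrees Celsius, strictly increasing.
#' @param theta fraction duplex at each temperature, each in [0, 1].
#' @param total_conc per-strand total concentration, M.
#' @return an object of class \code{"melting_curve"}.
#' @export
melting_curve <- function(temp_C, theta, total_conc) {
  stopifnot_finite(temp_C, "temp_C"); stopifnot_finite(theta, "theta")
  if (length(temp_C) != length(theta)) stop("temp_C and theta lengths differ", call. = FALSE)
  if (any(diff(temp_C) <= 0)) stop("temperatures must be strictly increasing", call. = FALSE)
  if (any(theta < 0 | theta > 1)) stop("theta values must lie in [0, 1]", call. = FALSE)
  if (total_conc <= 0) stop("total_conc must be positive", call. = FALSE)
  structure(list(temp_C = temp_C, theta = theta, total_conc = total_conc),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("Melting curve: %d points, %.0f-%.0f C, C = %.3g M per strand\n",
              length(x$temp_C), min(x$temp_C), max(x$temp_C), x$total_conc))
  invisible(x)
}

#' Fit the two-state melting model
#'
#' Least-squares estimation of (dH, dS) from a theta(T) melting profile under
#' the non-self-complementary two-state model K(T) = theta/((1-theta)^2 C).
#' Starting values come from a linearized van't Hoff regression of ln K on
#' 1/T restricted to the transition region (theta in [0.15, 0.85]); the
#' refinement is bounded Levenberg-Marquardt least squares on theta residuals.
#'
#' @param curve a \code{\link{melting_curve}}.
#' @return an object of class \code{c("melt_fit", "duplex_thermo")} carrying
#'   dH, dS, the residual norm, fitted values and the input curve.
#' @export
fit_two_state_melt <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  th <- curve$theta; TC <- curve$temp_C; C <- curve$total_conc
  if (length(th) < 6) stop("need at least 6 points to fit a melting curve", call. = FALSE)
  if (all(th > 0.99) || all(th < 0.01)) {
    stop("curve is entirely duplexed or entirely melted: (dH, dS) not identifiable",
         call. = FALSE)
  }
  if (min(th) > 0.2 || max(th) < 0.8) {
    stop("theta must span at least [0.2, 0.8] for a reliable two-state fit", call. = FALSE)
  }
  TK <- TC + C_TO_K
  sel <- th >= 0.15 & th <= 0.85
  K_obs <- th[sel] / ((1 - th[sel])^2 * C)
  vh <- stats::lm(log(K_obs) ~ I(1 / TK[sel]))
  # ln K = -dH/R * (1/T) + dS/R  (dS here in kcal units, converted below)
  dH0 <- -stats::coef(vh)[[2]] * R_KCAL
  dS0 <- stats::coef(vh)[[1]] * R_KCAL * 1000
  resid_fun <- function(p) {
    theta_two_state(list(dH = p[1], dS = p[2]), TC, C) - th
  }
  fit <- minpack.lm::nls.lm(
    par = c(dH0, dS0), fn = resid_fun,
    lower = c(-500, -1500), upper = c(-1e-6, -1e-6),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-10, maxiter = 500))
  est <- fit$par
  fitted <- theta_two_state(list(dH = est[1], dS = est[2]), TC, C)
  structure(list(dH = est[1], dS = est[2], source = "melt_fit",
                 residual_norm = sqrt(sum((fitted - th)^2)),
                 fitted = fitted, curve = curve,
                 start = c(dH = dH0, dS = dS0), info = fit$info),
            class = c("melt_fit", "duplex_thermo"))
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Two-state melting-curve fit\n")
  cat(sprintf("  dH = %.2f kcal/mol, dS = %.1f cal/(mol K)\n", x$dH, x$dS))
  cat(sprintf("  K(25 C) = %.3g 1/M, Tm = %.1f C at C = %.3g M\n",
              vant_hoff_K(x, 25 + C_TO_K),
              melting_temperature(x, x$curve$total_conc), x$curve$total_conc))
  cat(sprintf("  residual norm = %.3g over %d points\n",
              x$residual_norm, length(x$curve$temp_C)))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) c(dH = object$dH, dS = object$dS)

#' @export
residuals.melt_fit <- function(object, ...) object$curve$theta - object$fitted

#' @export
predict.melt_fit <- function(object, temp_C = object$curve$temp_C, ...) {
  theta_two_state(object, temp_C, object$curve$total_conc)
}

#' @export
summary.melt_fit <- function(object, ...) {
  out <- list(coef = coef(object),
              K25 = vant_hoff_K(object, 25 + C_TO_K),
              Tm = melting_temperature(object, object$curve$total_conc),
              residual_norm = object$residual_norm,
              n = length(object$curve$temp_C))
  class(out) <- "summary.melt_fit"
  out
}

#' @export
print.summary.melt_fit <- function(x, ...) {
  cat("Two-state melt fit summary\n")
  cat(sprintf("  dH = %.3f kcal/mol, dS = %.2f cal/(mol K)\n", x$coef[1], x$coef[2]))
  cat(sprintf("  K(25 C) = %.4g 1/M, Tm = %.2f C\n", x$K25, x$Tm))
  cat(sprintf("  residual norm = %.3g (n = %d)\n", x$residual_norm, x$n))
  invisible(x)
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$curve$temp_C, x$curve$theta, xlab = "temperature (C)",
                 ylab = "fraction duplex", pch = 16, ...)
  tg <- seq(min(x$curve$temp_C), max(x$curve$temp_C), length.out = 200)
  graphics::lines(tg, predict(x, tg))
  invisible(x)
}
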