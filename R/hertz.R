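## Elasticity: Hertz theory with the Sneddon extension for four-sided
## pyramidal indenters. F = E/(1 - nu^2) * tan(alpha)/sqrt(2) * delta^2,
## E the only free parameter, fitted over a fixed indentation depth.

#' Hertz-Sneddon force for a pyramidal indenter
#'
#' @param E Young's modulus in kPa.
#' @param delta Indentation in nm (vectorised, >= 0).
#' @param geometry An [indenter_geometry()].
#' @return Force in pN.
#' @examples
#' hertz_sneddon_force(2, 500, indenter_geometry(face_angle = 20)) # ~171.6 pN
#' @export
hertz_sneddon_force <- function(E, delta, geometry = indenter_geometry()) {
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  hertz_prefactor(E, geometry) * delta^2
}

#' Fit the Young's modulus to a processed indentation curve
#'
#' Least-squares fit of the Hertz-Sneddon law over indentations in
#' `[0, fit_depth]`, with E the only free parameter and the contact point
#' fixed from preprocessing. Because the model is linear in E, the fit is the
#' closed-form regression of force on indentation squared through the origin.
#' The indentation at a target force (1 nN by default) is computed alongside
#' when the curve reaches it.
#'
#' @param processed A `processed_curve` from [preprocess_curve()] /
#'   [compute_indentation()].
#' @param geometry An [indenter_geometry()].
#' @param fit_depth Fit depth in nm (the curve must reach it).
#' @param target_force Force (pN) for the indentation-at-force readout;
#'   `NULL` to skip.
#' @return An object of class `hertz_fit`: `E` (kPa), `prefactor` (pN/nm^2),
#'   `contact_point`, `fit_depth`, `rss`, `n_points`,
#'   `indentation_at_target` (nm or NA), `target_force`, plus the fitted
#'   `(delta, force)` samples. Errors: `afm_shallow_curve` if the curve does
#'   not reach `fit_depth` or has fewer than 20 samples in range.
#' @examples
#' cfg <- indentation_sim_config(noise_sd = 0, baseline_tilt_range = c(0, 0))
#' cur <- simulate_indentation_curve(2, cfg, seed = 1)
#' fit <- fit_hertz(preprocess_curve(cur), cfg$geometry)
#' coef(fit)
#' @export
fit_hertz <- function(processed, geometry = indenter_geometry(),
                      fit_depth = 500, target_force = 1000) {
  stopifnot(inherits(processed, "processed_curve"))
  delta <- processed$indentation
  f <- processed$force
  in_range <- delta <= fit_depth
  if (sum(in_range) < 20L || !length(delta) || max(delta) < fit_depth)
    stop(structure(class = c("afm_shallow_curve", "error", "condition"),
                   list(message = sprintf(
                     "curve too shallow: max indentation %.0f nm < fit depth %.0f nm",
                     if (length(delta)) max(delta) else 0, fit_depth),
                     call = NULL)))
  d2 <- delta[in_range]^2
  b <- sum(f[in_range] * d2) / sum(d2 * d2)
  rss <- sum((f[in_range] - b * d2)^2)
  E <- b * (1 - geometry$poisson_ratio^2) * sqrt(2) /
    tan(geometry$face_angle * pi / 180) * 1e3
  d_at <- NA_real_
  if (!is.null(target_force))
    d_at <- tryCatch(indentation_at_force(processed, target_force),
                     afm_max_force_not_reached = function(e) NA_real_)
  structure(
    list(E = E, prefactor = b, contact_point = processed$contact_point,
         fit_depth = fit_depth, rss = rss, n_points = sum(in_range),
         indentation_at_target = d_at,
         target_force = if (is.null(target_force)) NA_real_ else target_force,
         delta = delta[in_range], force = f[in_range],
         geometry = geometry),
    class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.3f kPa (alpha = %g deg, nu = %g, depth %g nm, n = %d)\n",
              x$E, x$geometry$face_angle, x$geometry$poisson_ratio,
              x$fit_depth, x$n_points))
  if (is.finite(x$indentation_at_target))
    cat(sprintf("  indentation at %g pN: %.1f nm\n", x$target_force,
                x$indentation_at_target))
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(E_kPa = object$E, prefactor_pN_per_nm2 = object$prefactor)
}

#' @export
predict.hertz_fit <- function(object, delta = object$delta, ...) {
  object$prefactor * delta^2
}

#' @export
residuals.hertz_fit <- function(object, ...) object$force - predict(object)

#' @export
summary.hertz_fit <- function(object, ...) {
  cat(sprintf("Hertz-Sneddon fit over 0-%g nm\n", object$fit_depth))
  cat(sprintf("  E = %.4f kPa, RSS = %.4g pN^2 over %d points (residual SD %.2f pN)\n",
              object$E, object$rss, object$n_points,
              sqrt(object$rss / object$n_points)))
  invisible(object)
}

#' @export
plot.hertz_fit <- function(x, ...) {
  graphics::plot(x$delta, x$force, pch = 16, cex = 0.4,
                 xlab = "indentation (nm)", ylab = "force (pN)", ...)
  dd <- seq(0, max(x$delta), length.out = 200)
  graphics::lines(dd, predict(x, dd), col = 2, lwd = 2)
  invisible(x)
}

#' Indentation at a target force
#'
#' Indentation at the first crossing of the target force along the approach,
#' linearly interpolated between the bracketing samples.
#'
#' @param processed A `processed_curve`.
#' @param target_force Target force in pN (default 1 nN).
#' @return Indentation in nm. Error of class `afm_max_force_not_reached` if
#'   the corrected force never reaches the target.
#' @export
indentation_at_force <- function(processed, target_force = 1000) {
  delta <- processed$indentation
  f <- processed$force
  ord <- order(delta)
  delta <- delta[ord]; f <- f[ord]
  i <- which(f >= target_force)[1L]
  if (is.na(i))
    stop(structure(class = c("afm_max_force_not_reached", "error", "condition"),
                   list(message = sprintf("force never reaches %g pN", target_force),
                        call = NULL)))
  if (i == 1L) return(delta[1L])
  frac <- (target_force - f[i - 1L]) / (f[i] - f[i - 1L])
  delta[i - 1L] + frac * (delta[i] - delta[i - 1L])
}
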