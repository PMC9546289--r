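## Adhesion analysis: detachment-point detection and work-of-adhesion
## integration of the retract curve. W = integral of the adhesive force over
## piezo distance between the retract zero-force point and the detachment
## point, reported in fJ (1 pN nm = 1e-6 fJ).

#' Find the detachment point of a baseline-corrected retract curve
#'
#' The detachment point is the last position at which the force is still
#' adhesive (below `-threshold * noise_sd`), refined by linear interpolation
#' of the force's return to the baseline band -- the same
#' threshold-plus-refinement idea as the contact-point detector, mirrored.
#'
#' @param height Retract piezo z in nm (increasing).
#' @param force Baseline-corrected force in pN (adhesion negative).
#' @param noise_sd Noise SD in pN.
#' @param threshold Threshold in noise SDs (with a small absolute floor).
#' @return Detachment position in nm, or `NA` if the force is never
#'   adhesive (work 0 downstream).
#' @export
find_detachment_point <- function(height, force, noise_sd, threshold = 3) {
  thr <- max(threshold * noise_sd, 0.5)
  adh <- which(force < -thr)
  if (!length(adh)) return(NA_real_)
  i <- adh[length(adh)]
  if (i == length(force)) return(height[i])
  ## interpolate where the force comes back to the -thr band
  f1 <- force[i]; f2 <- force[i + 1L]
  frac <- if (f2 > f1) (-thr - f1) / (f2 - f1) else 0
  height[i] + frac * (height[i + 1L] - height[i])
}

#' Work of adhesion over a retract interval
#'
#' Trapezoidal integral of the adhesive force over piezo distance between
#' the zero-force point and the detachment point. By default only the
#' negative-force (adhesive) part contributes; positive excursions between
#' ruptures count as zero rather than negative work (`signed = TRUE`
#' integrates the signed force instead).
#'
#' @param height Retract piezo z in nm (increasing).
#' @param force Baseline-corrected force in pN.
#' @param zero_force_point,detachment_point Integration bounds in nm
#'   (`zero_force_point < detachment_point`, both inside the segment).
#' @param signed Integrate the signed force instead of the adhesive part.
#' @return Work of adhesion in fJ (>= 0 for the default adhesive-only mode).
#' @export
work_of_adhesion <- function(height, force, zero_force_point,
                             detachment_point, signed = FALSE) {
  if (!is.finite(zero_force_point) || !is.finite(detachment_point) ||
      zero_force_point > detachment_point)
    stop("integration bounds must be ordered and finite", call. = FALSE)
  if (zero_force_point < min(height) - 1e-9 ||
      detachment_point > max(height) + 1e-9)
    stop("integration bounds outside the retract segment", call. = FALSE)
  sel <- height >= zero_force_point & height <= detachment_point
  if (sum(sel) < 2L) return(0)
  z <- height[sel]
  f <- force[sel]
  g <- if (signed) -f else pmax(-f, 0)
  sum(diff(z) * (g[-1L] + g[-length(g)]) / 2) * 1e-6
}

#' Analyze one adhesion retract curve
#'
#' Baseline and noise are estimated from the post-detachment tail (the
#' farthest fraction of the retract, the only region guaranteed force-free),
#' the zero-force point is the first downward zero crossing after contact,
#' the detachment point comes from [find_detachment_point()], and the work
#' of adhesion is integrated between them. Discrete ruptures are counted as
#' upward force steps larger than `step_threshold` inside the adhesive
#' region. The constant-height pause segment is ignored.
#'
#' @param curve A [force_curve()] with `mode = "adhesion"` and a retract
#'   segment.
#' @param tail_fraction Fraction of the retract (farthest part) used for the
#'   baseline.
#' @param threshold Detachment threshold in noise SDs.
#' @param step_threshold Minimum upward force step (pN) counted as a
#'   rupture; default `max(20, 5 * noise_sd)`.
#' @param signed Passed to [work_of_adhesion()].
#' @return An object of class `adhesion_result`: `work_fJ`,
#'   `zero_force_point`, `detachment_point`, `max_adhesion_force` (pN, > 0),
#'   `rupture_count`, `noise_sd`, `qc`.
#' @export
analyze_adhesion <- function(curve, tail_fraction = 0.2, threshold = 3,
                             step_threshold = NULL, signed = FALSE) {
  stopifnot(inherits(curve, "force_curve"))
  if (curve$mode != "adhesion")
    warning("curve mode is not 'adhesion'")
  seg <- get_segment(curve, "retract")
  if (is.null(seg)) stop("adhesion analysis needs a retract segment", call. = FALSE)
  z <- seg$height - seg$height[1L]
  n <- length(z)
  tail_idx <- seq.int(max(1L, floor(n * (1 - tail_fraction))), n)
  offset <- stats::median(seg$force[tail_idx])
  noise_sd <- stats::sd(seg$force[tail_idx])
  if (!is.finite(noise_sd)) noise_sd <- 0
  f <- seg$force - offset
  thr <- max(threshold * noise_sd, 0.5)
  ## zero-force point: first sample at/below zero after the initial
  ## compressive part (or the first sample if never compressive)
  pos <- f > thr
  zf_idx <- if (pos[1L]) {
    i <- which(!pos)[1L]
    if (is.na(i)) n else i
  } else 1L
  zero_force_point <- z[zf_idx]
  detachment_point <- find_detachment_point(z, f, noise_sd, threshold)
  qc <- structure(list(passed = TRUE, reasons = character(0)), class = "qc_record")
  if (is.na(detachment_point)) {
    res <- list(work_fJ = 0, zero_force_point = zero_force_point,
                detachment_point = zero_force_point,
                max_adhesion_force = 0, rupture_count = 0L,
                noise_sd = noise_sd, qc = qc, curve_id = curve$curve_id,
                group_label = curve$group_label)
    return(structure(res, class = "adhesion_result"))
  }
  work <- work_of_adhesion(z, f, zero_force_point, detachment_point,
                           signed = signed)
  if (is.null(step_threshold)) step_threshold <- max(20, 5 * noise_sd)
  reg <- z >= zero_force_point & z <= detachment_point + 2 * (z[2L] - z[1L])
  steps <- diff(f[reg])
  rupture_count <- sum(steps > step_threshold)
  structure(
    list(work_fJ = work, zero_force_point = zero_force_point,
         detachment_point = detachment_point,
         max_adhesion_force = max(0, -min(f[reg])),
         rupture_count = as.integer(rupture_count),
         noise_sd = noise_sd, qc = qc, curve_id = curve$curve_id,
         group_label = curve$group_label),
    class = "adhesion_result")
}

#' @export
print.adhesion_result <- function(x, ...) {
  cat(sprintf("<adhesion_result> %s: W = %.3f fJ, detachment at %.0f nm, %d rupture(s), max adhesion %.0f pN\n",
              x$curve_id, x$work_fJ, x$detachment_point, x$rupture_count,
              x$max_adhesion_force))
  invisible(x)
}
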