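## Raw-curve preprocessing for indentation analysis: baseline and tilt
## correction, contact-point detection (threshold candidate + piecewise
## refinement), indentation-axis construction and automated QC.

#' Estimate baseline offset, tilt and noise of an approach curve
#'
#' Robust linear fit of force against piezo height over the designated
#' non-contact fraction of the approach (the part farthest from the sample).
#' The fit is iteratively re-weighted: ordinary least squares, then samples
#' with residuals beyond 3 MAD are dropped and the fit repeated, which makes
#' the estimate tolerant of a contact region accidentally inside the window.
#'
#' @param curve A [force_curve()] with an approach segment.
#' @param fraction Fraction of the approach (from its start) treated as
#'   non-contact; in (0, 1).
#' @return List with `offset` (pN, at the start of the approach), `tilt`
#'   (pN/nm, slope against travelled distance), `noise_sd` (pN, residual SD)
#'   and `n` (samples used).
#' @export
estimate_baseline <- function(curve, fraction = 0.5) {
  stopifnot(inherits(curve, "force_curve"), fraction > 0, fraction < 1)
  seg <- get_segment(curve, "approach")
  if (is.null(seg)) stop("no approach segment", call. = FALSE)
  n <- length(seg$height)
  m <- floor(n * fraction)
  if (m < 10L) stop("fewer than 10 samples in the baseline region", call. = FALSE)
  idx <- seq_len(m)
  x <- seg$height[1L] - seg$height[idx]   # travelled distance, >= 0
  y <- seg$force[idx]
  use <- rep(TRUE, m)
  fit <- NULL
  for (it in 1:3) {
    fit <- stats::lm.fit(cbind(1, x[use]), y[use])
    r <- y - (fit$coefficients[1] + fit$coefficients[2] * x)
    s <- stats::mad(r[use])
    if (s == 0) break
    new_use <- abs(r) <= 3 * s
    if (all(new_use == use)) break
    use <- new_use
    if (sum(use) < 10L) break
  }
  resid <- y[use] - (fit$coefficients[1] + fit$coefficients[2] * x[use])
  list(offset = unname(fit$coefficients[1]),
       tilt = unname(fit$coefficients[2]),
       noise_sd = stats::sd(resid),
       n = sum(use))
}

## baseline-corrected approach force (vector aligned with the approach segment)
corrected_approach_force <- function(curve, baseline) {
  seg <- get_segment(curve, "approach")
  x <- seg$height[1L] - seg$height
  seg$force - baseline$offset - baseline$tilt * x
}

#' Detect the contact point of an approach curve
#'
#' Two-stage detector. Candidate: the start of the last run of samples whose
#' baseline-corrected force exceeds `threshold * noise_sd` (with a small
#' absolute floor for noise-free curves) and stays above it to the end of the
#' approach. Refinement: over a window of candidate positions around it, the
#' summed squared residuals of a piecewise model -- zero force before z0, a
#' quadratic Hertz-type rise after -- are minimised, with parabolic
#' sub-sample interpolation of the optimum.
#'
#' @param curve A [force_curve()] with an approach segment.
#' @param baseline Result of [estimate_baseline()].
#' @param threshold Crossing threshold in units of noise SD.
#' @param window_back_nm,window_fwd_nm Extent (nm) of the candidate window
#'   behind / ahead of the threshold crossing. The window reaches much
#'   further back than forward because on soft samples the noise threshold
#'   is crossed well past true contact.
#' @param post_nm Extra post-contact depth (nm) beyond the window used by
#'   the piecewise fit.
#' @return Contact point z0 in piezo coordinates (nm), or an error of class
#'   `afm_no_contact` if the force never crosses the threshold.
#' @export
find_contact_point <- function(curve, baseline = estimate_baseline(curve),
                               threshold = 3, window_back_nm = 500,
                               window_fwd_nm = 150, post_nm = 300) {
  seg <- get_segment(curve, "approach")
  f <- corrected_approach_force(curve, baseline)
  z <- seg$height
  thr <- max(threshold * baseline$noise_sd, 0.5)
  above <- f > thr
  below <- which(!above)
  cand <- if (length(below)) {
    if (max(below) == length(f)) length(f) else max(below) + 1L
  } else 1L
  ## "stays above": the force must remain above threshold for a sustained
  ## run to the end of the approach, or isolated noise spikes fake a contact
  if (!any(above) || (length(f) - cand + 1L) < 10L)
    stop(structure(class = c("afm_no_contact", "error", "condition"),
                   list(message = "no contact: force never stays above the threshold",
                        call = NULL)))
  spacing <- abs(z[1L] - z[2L])
  wb <- max(3L, round(window_back_nm / spacing))
  wf <- max(3L, round(window_fwd_nm / spacing))
  post <- max(10L, round(post_nm / spacing))
  lo <- max(2L, cand - wb)
  hi <- min(length(f) - 5L, cand + wf)
  if (lo >= hi) return(z[cand])
  cand_idx <- lo:hi
  k <- curve$spring_constant
  ## fixed evaluation set so RSS values are comparable across candidates
  ev_lo <- max(1L, lo - post)
  ev_hi <- min(length(f), hi + post)
  rss <- vapply(cand_idx, function(i) {
    r_pre <- if (i > ev_lo) sum(f[ev_lo:(i - 1L)]^2) else 0
    post_idx <- i:ev_hi
    ## deflection-corrected indentation so the quadratic model is exact
    u <- pmax(z[i] - z[post_idx] - f[post_idx] / k, 0)
    b <- sum(f[post_idx] * u^2) / sum(u^4)
    b <- max(b, 0)
    r_post <- sum((f[post_idx] - b * u^2)^2)
    r_pre + r_post
  }, numeric(1))
  j <- which.min(rss)
  z0 <- z[cand_idx[j]]
  ## parabolic sub-sample interpolation on the RSS profile
  if (j > 1L && j < length(cand_idx)) {
    r1 <- rss[j - 1L]; r2 <- rss[j]; r3 <- rss[j + 1L]
    den <- r1 - 2 * r2 + r3
    if (den > 0) {
      shift <- 0.5 * (r1 - r3) / den
      shift <- max(-1, min(1, shift))
      z0 <- z0 - shift * spacing   # z decreases with index on approach
    }
  }
  z0
}

#' Build the indentation axis of an approach curve
#'
#' Indentation is piezo travel past contact minus cantilever deflection:
#' `delta = (z0 - z) - F/k` for post-contact approach samples (piezo height
#' decreases on approach).
#'
#' @param curve A [force_curve()] with an approach segment.
#' @param z0 Contact point (nm), e.g. from [find_contact_point()].
#' @param baseline Result of [estimate_baseline()]; used to correct the
#'   force before the deflection term.
#' @param spring_constant Cantilever stiffness k in pN/nm; defaults to the
#'   curve's.
#' @return An object of class `processed_curve`: list with `source`,
#'   `corrected_force` (full approach), `contact_point`, `indentation` and
#'   `force` (post-contact samples, delta clipped at >= 0), `tilt_slope`,
#'   `offset`, `noise_sd_estimate`, `qc` (filled by [qc_curve()]).
#' @export
compute_indentation <- function(curve, z0, baseline = estimate_baseline(curve),
                                spring_constant = curve$spring_constant) {
  if (spring_constant <= 0) stop("spring constant must be positive", call. = FALSE)
  seg <- get_segment(curve, "approach")
  f <- corrected_approach_force(curve, baseline)
  post <- which(seg$height < z0)
  delta <- (z0 - seg$height[post]) - f[post] / spring_constant
  keep <- delta >= 0
  structure(
    list(source = curve,
         corrected_force = f,
         contact_point = z0,
         indentation = delta[keep],
         force = f[post][keep],
         tilt_slope = baseline$tilt,
         offset = baseline$offset,
         noise_sd_estimate = baseline$noise_sd,
         qc = NULL),
    class = "processed_curve")
}

#' @export
print.processed_curve <- function(x, ...) {
  cat(sprintf("<processed_curve> %s: contact at %.1f nm, %d post-contact samples, noise %.2f pN\n",
              x$source$curve_id, x$contact_point, length(x$indentation),
              x$noise_sd_estimate))
  if (!is.null(x$qc))
    cat(sprintf("  QC: %s\n", if (x$qc$passed) "passed"
                else paste(x$qc$reasons, collapse = ", ")))
  invisible(x)
}

#' Default QC thresholds
#'
#' Automated surrogate for manual outlier screening; every threshold is
#' explicit and configurable.
#'
#' @param max_noise_sd Maximum tolerated noise SD in pN.
#' @param max_tilt Maximum tolerated baseline tilt magnitude in pN/nm
#'   (`drift` flag).
#' @param min_monotone_fraction Minimum fraction of increasing steps in the
#'   smoothed post-contact force (`non_monotone` flag).
#' @param saturation_samples Number of samples pinned at the maximum force
#'   that flags `saturated`.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(max_noise_sd = 15, max_tilt = 0.1,
                          min_monotone_fraction = 0.8,
                          saturation_samples = 25L) {
  list(max_noise_sd = max_noise_sd, max_tilt = max_tilt,
       min_monotone_fraction = min_monotone_fraction,
       saturation_samples = saturation_samples)
}

#' Quality-control a processed curve
#'
#' Deterministic flags given the thresholds: `excessive_noise`, `no_contact`,
#' `non_monotone` (post-contact force not rising), `saturated` (force pinned
#' at its maximum) and `drift` (baseline tilt too large). A curve passes iff
#' no reason is flagged.
#'
#' @param processed A `processed_curve` from [compute_indentation()], or
#'   `NULL`/an `afm_no_contact` error for curves without contact.
#' @param thresholds See [qc_thresholds()].
#' @return List of class `qc_record` with `passed` and `reasons`.
#' @export
qc_curve <- function(processed, thresholds = qc_thresholds()) {
  reasons <- character(0)
  if (is.null(processed) || inherits(processed, "afm_no_contact")) {
    reasons <- "no_contact"
  } else {
    if (processed$noise_sd_estimate > thresholds$max_noise_sd)
      reasons <- c(reasons, "excessive_noise")
    if (length(processed$indentation) < 20L)
      reasons <- c(reasons, "no_contact")
    if (abs(processed$tilt_slope) > thresholds$max_tilt)
      reasons <- c(reasons, "drift")
    f <- processed$force[order(processed$indentation)]
    if (length(f) >= 30L) {
      w <- max(5L, length(f) %/% 50L)
      fs <- as.numeric(stats::filter(f, rep(1 / w, w), sides = 2))
      fs <- fs[!is.na(fs)]
      mono <- mean(diff(fs) > 0)
      if (mono < thresholds$min_monotone_fraction)
        reasons <- c(reasons, "non_monotone")
      n_sat <- sum(f >= max(f) - max(1e-9, processed$noise_sd_estimate / 4))
      if (n_sat > thresholds$saturation_samples)
        reasons <- c(reasons, "saturated")
    }
  }
  structure(list(passed = length(reasons) == 0L, reasons = reasons),
            class = "qc_record")
}

#' @export
print.qc_record <- function(x, ...) {
  cat(if (x$passed) "QC passed\n"
      else sprintf("QC failed: %s\n", paste(x$reasons, collapse = ", ")))
  invisible(x)
}

#' Preprocess a raw indentation curve end to end
#'
#' Baseline estimation, contact-point detection, indentation-axis
#' construction and QC in one call. Curves whose contact point cannot be
#' found are returned as a `processed_curve` with a failed QC record
#' (`no_contact`) rather than an error, so that batch runs keep going.
#'
#' @param curve A [force_curve()] with an approach segment.
#' @param baseline_fraction Non-contact fraction for [estimate_baseline()].
#' @param contact_threshold Threshold (noise SDs) for [find_contact_point()].
#' @param thresholds QC thresholds, see [qc_thresholds()].
#' @return A `processed_curve` with its `qc` field filled in.
#' @export
preprocess_curve <- function(curve, baseline_fraction = 0.5,
                             contact_threshold = 3,
                             thresholds = qc_thresholds()) {
  baseline <- estimate_baseline(curve, baseline_fraction)
  z0 <- tryCatch(find_contact_point(curve, baseline, contact_threshold),
                 afm_no_contact = function(e) NULL)
  if (is.null(z0)) {
    out <- structure(
      list(source = curve, corrected_force = corrected_approach_force(curve, baseline),
           contact_point = NA_real_, indentation = numeric(0),
           force = numeric(0), tilt_slope = baseline$tilt,
           offset = baseline$offset, noise_sd_estimate = baseline$noise_sd,
           qc = NULL),
      class = "processed_curve")
    out$qc <- structure(list(passed = FALSE, reasons = "no_contact"),
                        class = "qc_record")
    return(out)
  }
  processed <- compute_indentation(curve, z0, baseline)
  processed$qc <- qc_curve(processed, thresholds)
  processed
}
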