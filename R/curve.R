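## Force-curve data model: segments, curves, validation.

SEGMENT_KINDS <- c("approach", "pause", "retract")
CURVE_MODES <- c("indentation", "adhesion", "unfolding")

#' Create one segment of a force-distance curve
#'
#' A segment is one phase of the piezo trajectory (approach, pause or retract)
#' with paired piezo height and vertical force samples. The package convention
#' is that piezo height decreases while approaching the sample and increases
#' while retracting, so that `contact_point - height` is travel past contact.
#'
#' @param kind One of `"approach"`, `"pause"`, `"retract"`.
#' @param height Piezo z positions in nm; strictly monotone for approach
#'   (decreasing) and retract (increasing) segments.
#' @param force Vertical force in pN, same length as `height`.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `afm_segment`.
#' @export
segment <- function(kind, height, force, sampling_rate) {
  kind <- match.arg(kind, SEGMENT_KINDS)
  height <- as.numeric(height)
  force <- as.numeric(force)
  if (length(height) != length(force))
    stop("height and force must have equal length", call. = FALSE)
  if (length(height) < 2L)
    stop("a segment needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(height)) || !all(is.finite(force)))
    stop("segment values must all be finite", call. = FALSE)
  if (kind == "approach" && any(diff(height) >= 0))
    stop("approach height must be strictly decreasing", call. = FALSE)
  if (kind == "retract" && any(diff(height) <= 0))
    stop("retract height must be strictly increasing", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number", call. = FALSE)
  structure(
    list(kind = kind, height = height, force = force,
         sampling_rate = as.numeric(sampling_rate)),
    class = "afm_segment"
  )
}

#' Create a force-distance curve
#'
#' Container for one AFM force-distance record: an ordered list of segments
#' plus the cantilever and experiment metadata needed by the analysis
#' (spring constant, speed, temperature, measurement mode and identifiers).
#'
#' @param segments List of [segment()] objects, in acquisition order. At least
#'   one approach or retract segment must be present.
#' @param spring_constant Cantilever stiffness k in pN/nm (1 N/m = 1000 pN/nm
#'   is NOT the convention here; 0.12 N/m = 120 pN/nm).
#' @param velocity Approach/retract speed in nm/s.
#' @param temperature Temperature in K.
#' @param mode One of `"indentation"`, `"adhesion"`, `"unfolding"`.
#' @param curve_id,cell_id,group_label Identifiers (character scalars).
#' @param annotations Named list of free-form annotations (ground truth from
#'   the simulator, provenance notes, unknown file keys). Values must be
#'   length-1 atomic.
#' @return An object of class `force_curve`.
#' @examples
#' seg <- segment("approach", height = c(10, 5), force = c(0, 1),
#'                sampling_rate = 4096)
#' fc <- force_curve(list(seg), spring_constant = 120, velocity = 5000,
#'                   temperature = 310, mode = "indentation", curve_id = "c1")
#' print(fc)
#' @export
force_curve <- function(segments, spring_constant, velocity, temperature,
                        mode, curve_id, cell_id = "", group_label = "",
                        annotations = list()) {
  mode <- match.arg(mode, CURVE_MODES)
  if (!is.list(segments) || length(segments) == 0L)
    stop("segments must be a non-empty list", call. = FALSE)
  ok <- vapply(segments, inherits, logical(1), what = "afm_segment")
  if (!all(ok)) stop("all segments must be afm_segment objects", call. = FALSE)
  kinds <- vapply(segments, `[[`, character(1), "kind")
  if (!any(kinds %in% c("approach", "retract")))
    stop("at least one approach or retract segment is required", call. = FALSE)
  for (nm in c("spring_constant", "velocity", "temperature")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a positive number", nm), call. = FALSE)
  }
  if (!is.character(curve_id) || length(curve_id) != 1L || !nzchar(curve_id))
    stop("curve_id must be a non-empty string", call. = FALSE)
  if (length(annotations) &&
      (is.null(names(annotations)) || any(!nzchar(names(annotations)))))
    stop("annotations must be a named list", call. = FALSE)
  structure(
    list(segments = segments,
         spring_constant = as.numeric(spring_constant),
         velocity = as.numeric(velocity),
         temperature = as.numeric(temperature),
         mode = mode,
         curve_id = curve_id,
         cell_id = as.character(cell_id),
         group_label = as.character(group_label),
         annotations = annotations),
    class = "force_curve"
  )
}

#' Extract the first segment of a given kind
#'
#' @param curve A [force_curve()].
#' @param kind Segment kind to extract.
#' @return The segment, or `NULL` if absent.
#' @export
get_segment <- function(curve, kind = SEGMENT_KINDS) {
  kind <- match.arg(kind)
  for (s in curve$segments) if (s$kind == kind) return(s)
  NULL
}

#' @export
print.afm_segment <- function(x, ...) {
  cat(sprintf("<afm_segment> %s: %d samples, height [%.6g, %.6g] nm, force [%.6g, %.6g] pN\n",
              x$kind, length(x$height), min(x$height), max(x$height),
              min(x$force), max(x$force)))
  invisible(x)
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %s (%s)\n", x$curve_id, x$mode))
  cat(sprintf("  k = %g pN/nm, v = %g nm/s, T = %g K", x$spring_constant,
              x$velocity, x$temperature))
  if (nzchar(x$group_label)) cat(sprintf(", group = %s", x$group_label))
  cat("\n")
  for (s in x$segments)
    cat(sprintf("  %-8s %6d samples @ %g Hz\n", s$kind, length(s$height),
                s$sampling_rate))
  if (length(x$annotations))
    cat(sprintf("  annotations: %s\n", paste(names(x$annotations), collapse = ", ")))
  invisible(x)
}
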