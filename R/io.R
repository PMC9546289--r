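## Plain-text curve container (FDC-TSV) and manifest I/O.
##
## FDC-TSV: UTF-8 text; header lines "# key = value" with required keys
## curve_id, mode, spring_constant_pN_per_nm, velocity_nm_per_s,
## temperature_K, sampling_rate_Hz; then a column header
## "segment\theight_nm\tforce_pN" and tab-separated data rows with
## segment in {approach, pause, retract}. Unknown header keys are preserved
## as curve annotations. Numbers are stored with %.17g so that a
## write -> read round trip is bit-exact on doubles.

REQUIRED_FDC_KEYS <- c("curve_id", "mode", "spring_constant_pN_per_nm",
                       "velocity_nm_per_s", "temperature_K",
                       "sampling_rate_Hz")

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a force curve to an FDC-TSV file
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_curve()]
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  rates <- vapply(curve$segments, `[[`, numeric(1), "sampling_rate")
  hdr <- c(
    sprintf("# curve_id = %s", curve$curve_id),
    sprintf("# mode = %s", curve$mode),
    sprintf("# spring_constant_pN_per_nm = %s", fmt_num(curve$spring_constant)),
    sprintf("# velocity_nm_per_s = %s", fmt_num(curve$velocity)),
    sprintf("# temperature_K = %s", fmt_num(curve$temperature)),
    sprintf("# sampling_rate_Hz = %s", fmt_num(rates[1L]))
  )
  if (nzchar(curve$cell_id))
    hdr <- c(hdr, sprintf("# cell_id = %s", curve$cell_id))
  if (nzchar(curve$group_label))
    hdr <- c(hdr, sprintf("# group_label = %s", curve$group_label))
  ## per-segment rates only when they differ from the header rate
  for (i in seq_along(rates))
    if (rates[i] != rates[1L])
      hdr <- c(hdr, sprintf("# segment%d_sampling_rate_Hz = %s", i, fmt_num(rates[i])))
  for (nm in names(curve$annotations)) {
    v <- curve$annotations[[nm]]
    v <- if (is.numeric(v)) fmt_num(v) else as.character(v)
    hdr <- c(hdr, sprintf("# %s = %s", nm, v))
  }
  rows <- unlist(lapply(curve$segments, function(s) {
    paste(s$kind, fmt_num(s$height), fmt_num(s$force), sep = "\t")
  }), use.names = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(hdr, "segment\theight_nm\tforce_pN", rows), con)
  invisible(path)
}

parse_error <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Read a force curve from an FDC-TSV file
#'
#' Parses the documented plain-text container and returns a validated
#' [force_curve()]. Header keys beyond the required set are preserved in the
#' curve's annotation list (numeric-looking values are converted to numbers).
#' Malformed headers, ragged columns and non-finite values raise an error
#' naming the offending line.
#'
#' @param path File path.
#' @return A [force_curve()].
#' @export
read_curve <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop(sprintf("%s: empty file", path), call. = FALSE)
  i <- 1L
  meta <- list()
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    m <- regmatches(lines[i], regexec("^#\\s*([^=\\s]+)\\s*=\\s*(.*)$",
                                      lines[i], perl = TRUE))[[1]]
    if (length(m) != 3L) parse_error(path, i, "malformed header line")
    meta[[m[2]]] <- trimws(m[3])
    i <- i + 1L
  }
  missing <- setdiff(REQUIRED_FDC_KEYS, names(meta))
  if (length(missing))
    stop(sprintf("%s: missing required header key(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (i > length(lines) || lines[i] != "segment\theight_nm\tforce_pN")
    parse_error(path, i, "expected column header 'segment\\theight_nm\\tforce_pN'")
  first_row <- i + 1L
  data_lines <- lines[seq.int(first_row, length(lines))]
  data_lines <- data_lines[nzchar(data_lines)]
  if (!length(data_lines))
    parse_error(path, first_row, "no data rows")
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3L))
    parse_error(path, first_row + which(nfield != 3L)[1] - 1L,
                "expected 3 tab-separated fields")
  kind <- vapply(parts, `[[`, character(1), 1L)
  bad <- which(!(kind %in% SEGMENT_KINDS))
  if (length(bad))
    parse_error(path, first_row + bad[1] - 1L,
                sprintf("unknown segment kind '%s'", kind[bad[1]]))
  height <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  force <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(!is.finite(height) | !is.finite(force))
  if (length(bad))
    parse_error(path, first_row + bad[1] - 1L, "non-finite or non-numeric value")

  num_or <- function(key, default = NA_real_) {
    v <- meta[[key]]
    if (is.null(v)) return(default)
    x <- suppressWarnings(as.numeric(v))
    if (!is.finite(x))
      stop(sprintf("%s: header key %s is not numeric", path, key), call. = FALSE)
    x
  }
  base_rate <- num_or("sampling_rate_Hz")
  ## split data rows into contiguous segment blocks
  brk <- c(0L, which(kind[-1L] != kind[-length(kind)]), length(kind))
  segs <- vector("list", length(brk) - 1L)
  seg_rate_keys <- character(0)
  for (s in seq_len(length(brk) - 1L)) {
    idx <- seq.int(brk[s] + 1L, brk[s + 1L])
    key <- sprintf("segment%d_sampling_rate_Hz", s)
    rate <- num_or(key, base_rate)
    if (!is.null(meta[[key]])) seg_rate_keys <- c(seg_rate_keys, key)
    segs[[s]] <- tryCatch(
      segment(kind[idx[1]], height[idx], force[idx], rate),
      error = function(e) stop(sprintf("%s: segment %d: %s", path, s,
                                       conditionMessage(e)), call. = FALSE))
  }
  known <- c(REQUIRED_FDC_KEYS, "cell_id", "group_label", seg_rate_keys)
  ann_keys <- setdiff(names(meta), known)
  annotations <- lapply(meta[ann_keys], function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.finite(x) && grepl("^[-+0-9.eE]+$", v)) x else v
  })
  force_curve(segs,
              spring_constant = num_or("spring_constant_pN_per_nm"),
              velocity = num_or("velocity_nm_per_s"),
              temperature = num_or("temperature_K"),
              mode = meta$mode,
              curve_id = meta$curve_id,
              cell_id = if (is.null(meta$cell_id)) "" else meta$cell_id,
              group_label = if (is.null(meta$group_label)) "" else meta$group_label,
              annotations = annotations)
}

#' Read a study manifest
#'
#' A manifest is a CSV with columns `path`, `group_label`, `cell_id`, `mode`
#' listing the curve files of a study. Duplicate paths and empty manifests are
#' errors; missing files are NOT an error here -- they are reported per entry
#' when the curves are actually loaded with [load_manifest_curves()].
#'
#' @param path Manifest CSV path.
#' @return A data.frame of class `afm_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "group_label", "cell_id", "mode")
  if (!all(need %in% names(df)))
    stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (nrow(df) == 0L) stop("manifest has no entries", call. = FALSE)
  if (anyDuplicated(df$path))
    stop("manifest contains duplicate paths", call. = FALSE)
  bad <- setdiff(unique(df$mode), CURVE_MODES)
  if (length(bad))
    stop(sprintf("unknown mode(s) in manifest: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  class(df) <- c("afm_manifest", "data.frame")
  df
}

#' Load the curves referenced by a manifest
#'
#' @param manifest An `afm_manifest` from [read_manifest()], or a path to one.
#' @param base_dir Directory against which relative manifest paths are
#'   resolved; defaults to the current directory.
#' @return A list with `curves` (the successfully loaded [force_curve()]s) and
#'   `errors` (a data.frame of per-entry failures: path, message). Duplicate
#'   curve ids across loaded files are an error.
#' @export
load_manifest_curves <- function(manifest, base_dir = ".") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  curves <- list()
  errs <- data.frame(path = character(0), message = character(0),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    full <- if (file.exists(p)) p else file.path(base_dir, p)
    res <- tryCatch(suppressWarnings(read_curve(full)), error = function(e) e)
    if (inherits(res, "error")) {
      errs <- rbind(errs, data.frame(path = p,
                                     message = conditionMessage(res),
                                     stringsAsFactors = FALSE))
    } else {
      res$group_label <- manifest$group_label[i]
      res$cell_id <- as.character(manifest$cell_id[i])
      curves[[length(curves) + 1L]] <- res
    }
  }
  ids <- vapply(curves, `[[`, character(1), "curve_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate curve_id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  list(curves = curves, errors = errs)
}
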