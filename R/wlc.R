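## Worm-like chain model and sawtooth-trace analysis:
## peak detection, per-edge WLC fits at fixed persistence length,
## contour-length-increment classification, trace acceptance rules
## and rate-dependence summaries.

#' Worm-like chain parameters
#'
#' Persistence length is fixed at 0.4 nm by default, the effective value for a
#' stretched polypeptide backbone; it is never fitted in the standard
#' pipeline (a free-p mode exists only as a diagnostic in [fit_wlc_edge()]).
#'
#' @param persistence_length Persistence length p in nm.
#' @param temperature Temperature in K (sets kB*T).
#' @return An object of class `wlc_params` with fields `p`, `temperature`,
#'   `kBT`.
#' @export
wlc_params <- function(persistence_length = 0.4, temperature = 298) {
  stopifnot(persistence_length > 0, temperature > 0)
  structure(list(p = persistence_length, temperature = temperature,
                 kBT = kBT(temperature)),
            class = "wlc_params")
}

#' Worm-like chain interpolation force
#'
#' Entropic restoring force of a worm-like chain at extension `x` and contour
#' length `Lc`:
#' `F(x) = (kBT/p) * (0.25*(1 - x/Lc)^-2 - 0.25 + x/Lc)`.
#'
#' @param x Extension in nm, `0 <= x < Lc` (vectorised).
#' @param Lc Contour length in nm.
#' @param params A [wlc_params()].
#' @return Force in pN.
#' @examples
#' wlc_force(44.1, 88.2) # half extension, about 12.86 pN
#' @export
wlc_force <- function(x, Lc, params = wlc_params()) {
  if (any(x < 0) || any(x >= Lc))
    stop("wlc_force requires 0 <= x < Lc", call. = FALSE)
  phi <- x / Lc
  (params$kBT / params$p) * (0.25 * (1 - phi)^-2 - 0.25 + phi)
}

#' Worm-like chain stiffness dF/dx
#'
#' @inheritParams wlc_force
#' @return Stiffness in pN/nm.
#' @export
wlc_stiffness <- function(x, Lc, params = wlc_params()) {
  if (any(x < 0) || any(x >= Lc))
    stop("wlc_stiffness requires 0 <= x < Lc", call. = FALSE)
  phi <- x / Lc
  (params$kBT / params$p) * (0.5 * (1 - phi)^-3 + 1) / Lc
}

## Vectorised force balance of a WLC in series with a Hookean cantilever:
## find extension x such that k*(D - x) = wlc_force(x, Lc) for piezo
## displacement D. Bisection: monotone, bracketed, robust near x -> Lc.
solve_wlc_balance <- function(D, Lc, spring_constant, params) {
  lo <- rep(0, length(D))
  hi <- pmin(D, Lc * (1 - 1e-9))
  for (i in seq_len(64L)) {
    mid <- (lo + hi) / 2
    g <- spring_constant * (D - mid) - wlc_force(mid, Lc, params)
    up <- g > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Deterministic loading rate of a WLC pulled through a cantilever
#'
#' Local force ramp rate dF/dt when a chain of contour length `Lc` is pulled
#' at constant piezo velocity through a spring: the series stiffness of the
#' cantilever and the chain times the velocity, evaluated at force `F`.
#'
#' @param F Force in pN at which to evaluate the rate.
#' @param Lc Contour length in nm.
#' @param spring_constant Cantilever stiffness in pN/nm.
#' @param velocity Pulling speed in nm/s.
#' @param params A [wlc_params()].
#' @return Loading rate in pN/s.
#' @export
unfolding_loading_rate <- function(F, Lc, spring_constant, velocity,
                                   params = wlc_params()) {
  ## invert F = wlc(x) for x, then series stiffness
  x <- vapply(F, function(f) {
    stats::uniroot(function(x) wlc_force(x, Lc, params) - f,
                   c(0, Lc * (1 - 1e-9)), tol = 1e-10)$root
  }, numeric(1))
  kw <- wlc_stiffness(x, Lc, params)
  velocity * spring_constant * kw / (spring_constant + kw)
}

#' Detect sawtooth peaks in a baseline-corrected retract trace
#'
#' Peaks are local maxima of a lightly smoothed force signal that exceed
#' `max(min_force, threshold * noise_sd)`; neighbouring maxima not separated
#' by a force drop of at least `drop_fraction` of the lower peak are merged
#' (the higher one is kept). Each retained peak is paired with its rising
#' edge: the samples from the preceding valley up to the peak.
#'
#' @param height Piezo z in nm (increasing along the retract).
#' @param force Corrected force in pN (tension positive).
#' @param noise_sd Noise standard deviation in pN.
#' @param min_force Absolute floor for peak height in pN.
#' @param min_spacing Minimum peak separation in nm.
#' @param threshold Peak threshold in noise SD units.
#' @param drop_fraction Required fractional force drop between peaks.
#' @param smooth_width Running-mean window in samples.
#' @return A data.frame with one row per peak: `index`, `z`, `peak_force`
#'   (raw maximum near the smoothed peak), `edge_start` (index of the
#'   preceding valley). Empty data.frame if no peaks.
#' @export
detect_sawtooth_peaks <- function(height, force, noise_sd, min_force = 30,
                                  min_spacing = 5, threshold = 5,
                                  drop_fraction = 0.25, smooth_width = 5L) {
  n <- length(force)
  empty <- data.frame(index = integer(0), z = numeric(0),
                      peak_force = numeric(0), edge_start = integer(0))
  if (n < 3L) return(empty)
  fs <- if (smooth_width > 1L && n > smooth_width)
    stats::filter(force, rep(1 / smooth_width, smooth_width), sides = 2)
  else force
  fs <- as.numeric(fs)
  fs[is.na(fs)] <- force[is.na(fs)]
  thr <- max(min_force, threshold * noise_sd)
  spacing_idx <- max(1L, as.integer(round(min_spacing / max(diff(height[1:2]), 1e-9))))
  ## local maxima over +-spacing_idx
  cand <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - spacing_idx); hi <- min(n, i + spacing_idx)
    if (fs[i] >= thr && fs[i] == max(fs[lo:hi])) cand <- c(cand, i)
  }
  if (!length(cand)) return(empty)
  ## collapse plateaus of equal smoothed value
  cand <- cand[c(TRUE, diff(cand) > spacing_idx | diff(fs[cand]) != 0)]
  ## prominence pruning: require a drop between consecutive kept peaks
  kept <- cand[1L]
  for (c2 in cand[-1L]) {
    prev <- kept[length(kept)]
    valley <- min(fs[prev:c2])
    if (valley <= (1 - drop_fraction) * min(fs[prev], fs[c2])) {
      kept <- c(kept, c2)
    } else if (fs[c2] > fs[prev]) {
      kept[length(kept)] <- c2
    }
  }
  ## valleys / edge starts and raw peak forces
  edge_start <- integer(length(kept))
  peak_force <- numeric(length(kept))
  for (j in seq_along(kept)) {
    from <- if (j == 1L) 1L else kept[j - 1L]
    seg <- from:kept[j]
    edge_start[j] <- seg[which.min(fs[seg])]
    win <- max(1L, kept[j] - 2L):min(n, kept[j] + 2L)
    peak_force[j] <- max(force[win])
  }
  data.frame(index = kept, z = height[kept], peak_force = peak_force,
             edge_start = edge_start)
}

#' Fit the WLC contour length to one rising edge
#'
#' Least-squares fit of the worm-like chain force law to the (extension,
#' force) samples of a rising edge, with the contour length `Lc` as the only
#' free parameter (persistence length fixed). The fit is a bracketed 1-D
#' golden-section/parabolic minimisation of the residual sum of squares over
#' `Lc` in `(max(x), 10 * max(x))`.
#'
#' @param x Extension in nm (tip-sample separation, deflection-corrected).
#' @param force Force in pN.
#' @param params A [wlc_params()].
#' @param free_p Diagnostic mode: additionally fit the persistence length.
#' @return An object of class `wlc_fit`: list with `Lc`, `rss`, `n`, `p`,
#'   `x`, `force`.
#' @export
fit_wlc_edge <- function(x, force, params = wlc_params(), free_p = FALSE) {
  if (length(x) != length(force)) stop("x and force lengths differ", call. = FALSE)
  ## compressive / zero-extension samples carry no WLC information
  keep <- x > 0
  x <- x[keep]; force <- force[keep]
  if (length(x) < 8L)
    stop("edge has fewer than 8 samples", call. = FALSE)
  xm <- max(x)
  if (xm <= 0) stop("edge has non-positive extension", call. = FALSE)
  rss_fun <- function(Lc, p_) {
    pr <- if (p_ == params$p) params else wlc_params(p_, params$temperature)
    sum((force - wlc_force(x, Lc, pr))^2)
  }
  if (!free_p) {
    opt <- stats::optimize(rss_fun, c(xm * (1 + 1e-8), 10 * xm), p_ = params$p,
                           tol = 1e-8 * xm)
    fit <- list(Lc = opt$minimum, rss = opt$objective, n = length(x),
                p = params$p, x = x, force = force)
  } else {
    obj <- function(par) rss_fun(exp(par[1]) + xm, exp(par[2]))
    o <- stats::optim(c(log(0.2 * xm), log(params$p)), obj)
    fit <- list(Lc = exp(o$par[1]) + xm, rss = o$value, n = length(x),
                p = exp(o$par[2]), x = x, force = force)
  }
  structure(fit, class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("<wlc_fit> Lc = %.2f nm (p = %.2f nm fixed), n = %d, rss = %.3g pN^2\n",
              x$Lc, x$p, x$n, x$rss))
  invisible(x)
}

#' @export
coef.wlc_fit <- function(object, ...) c(Lc = object$Lc, p = object$p)

#' @export
predict.wlc_fit <- function(object, x = object$x, ...) {
  wlc_force(x, object$Lc, wlc_params(object$p))
}

#' @export
residuals.wlc_fit <- function(object, ...) {
  object$force - predict(object)
}

#' @export
plot.wlc_fit <- function(x, ...) {
  graphics::plot(x$x, x$force, xlab = "extension (nm)", ylab = "force (pN)",
                 pch = 16, cex = 0.5, ...)
  xx <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xx, predict(x, xx), col = 2, lwd = 2)
  invisible(x)
}

#' Default contour-length classification windows
#'
#' FLNA repeat 22 releases about 30.4 nm of contour length per unfolding,
#' titin I27 about 27.3 nm; events are classified by which window their
#' increment falls into. Windows must not overlap.
#'
#' @param flna_center,i27_center Window centres in nm.
#' @param half_width Half-width w in nm (same for both windows).
#' @return Named list of `c(center, half_width)` pairs.
#' @export
classification_windows <- function(flna_center = 30.4, i27_center = 27.3,
                                   half_width = 1.5) {
  w <- list(FLNA = c(center = flna_center, half_width = half_width),
            I27 = c(center = i27_center, half_width = half_width))
  if (abs(flna_center - i27_center) < 2 * half_width)
    stop("classification windows overlap", call. = FALSE)
  w
}

#' Classify an unfolding event by its contour-length increment
#'
#' @param increment Contour-length increment in nm.
#' @param windows Windows from [classification_windows()].
#' @return `"FLNA"`, `"I27"` or `"unclassified"` (vectorised).
#' @examples
#' classify_event(c(30.4, 27.3, 28.85))
#' @export
classify_event <- function(increment, windows = classification_windows()) {
  out <- rep("unclassified", length(increment))
  for (lab in names(windows)) {
    wc <- windows[[lab]]
    out[abs(increment - wc[["center"]]) <= wc[["half_width"]]] <- lab
  }
  out
}

#' Default trace acceptance rules
#'
#' @param min_i27 Minimum number of I27-classified events.
#' @param max_flna Maximum number of FLNA-classified events.
#' @param require_flna_first Require the FLNA event (if present) to precede
#'   every I27 event of higher force (weak-before-strong ordering).
#' @return Named list of rules.
#' @export
acceptance_rules <- function(min_i27 = 4L, max_flna = 1L,
                             require_flna_first = TRUE) {
  list(min_i27 = min_i27, max_flna = max_flna,
       require_flna_first = require_flna_first)
}

#' Apply acceptance rules to the events of one trace
#'
#' The final detachment peak must already be excluded from `events` (the
#' trace analyzer does this: the last peak carries no contour increment and
#' only provides the edge of the preceding domain event).
#'
#' @param events data.frame with columns `label`, `peak_force`, `Lc`,
#'   `increment`, `order_index`.
#' @param rules Rules from [acceptance_rules()].
#' @param pulling_speed Pulling speed in nm/s (carried into the result).
#' @return An object of class `trace_result`: list with `events`, `accepted`,
#'   `rejection_reason`, `pulling_speed`.
#' @export
accept_trace <- function(events, rules = acceptance_rules(),
                         pulling_speed = NA_real_) {
  reason <- NULL
  n_i27 <- sum(events$label == "I27")
  n_flna <- sum(events$label == "FLNA")
  if (n_i27 < rules$min_i27) {
    reason <- "too_few_events"
  } else if (n_flna > rules$max_flna) {
    reason <- "multiple_flna"
  } else if (rules$require_flna_first && n_flna >= 1L) {
    fl <- which(events$label == "FLNA")[1L]
    i27_stronger <- events$label == "I27" &
      events$peak_force > events$peak_force[fl]
    if (any(which(i27_stronger) < fl)) reason <- "ordering_violation"
  }
  structure(list(events = events, accepted = is.null(reason),
                 rejection_reason = if (is.null(reason)) NA_character_ else reason,
                 pulling_speed = pulling_speed),
            class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  cat(sprintf("<trace_result> %s (%d events%s)\n",
              if (x$accepted) "accepted" else paste0("rejected: ", x$rejection_reason),
              nrow(x$events),
              if (is.na(x$pulling_speed)) "" else sprintf(", %g nm/s", x$pulling_speed)))
  if (nrow(x$events)) print(x$events, digits = 4)
  invisible(x)
}

#' Analyze one sawtooth unfolding trace
#'
#' Full per-trace pipeline: baseline/noise estimation from the post-detachment
#' tail, sawtooth peak detection, per-edge WLC fits at fixed persistence
#' length on the deflection-corrected extension axis
#' (`x = z - F/k`), forward contour-length increments (the length released by
#' the domain unfolding at peak i appears in the edge of peak i+1), increment
#' classification and acceptance rules. The last detected peak is treated as
#' the final detachment: it contributes the closing edge but is excluded from
#' domain counting.
#'
#' @param curve A [force_curve()] with `mode = "unfolding"` and a retract
#'   segment.
#' @param params A [wlc_params()].
#' @param windows Classification windows, see [classification_windows()].
#' @param rules Acceptance rules, see [acceptance_rules()].
#' @param noise_sd Optional known noise SD (pN); estimated from the trace
#'   tail when `NULL`.
#' @param tail_fraction Fraction of the retract (farthest part) used for
#'   baseline and noise estimation.
#' @param ... Passed to [detect_sawtooth_peaks()].
#' @return A `trace_result` whose `events` data.frame has columns
#'   `order_index`, `label`, `peak_force`, `Lc`, `increment`, `rss`, `z`.
#' @export
analyze_unfolding_trace <- function(curve, params = wlc_params(),
                                    windows = classification_windows(),
                                    rules = acceptance_rules(),
                                    noise_sd = NULL, tail_fraction = 0.1,
                                    ...) {
  stopifnot(inherits(curve, "force_curve"))
  seg <- get_segment(curve, "retract")
  if (is.null(seg)) stop("unfolding analysis needs a retract segment", call. = FALSE)
  z <- seg$height - seg$height[1L]
  f <- seg$force
  n <- length(f)
  tail_idx <- seq.int(max(1L, floor(n * (1 - tail_fraction))), n)
  offset <- stats::median(f[tail_idx])
  if (is.null(noise_sd)) noise_sd <- stats::sd(f[tail_idx])
  if (!is.finite(noise_sd)) noise_sd <- 0
  f <- f - offset
  pk <- detect_sawtooth_peaks(z, f, noise_sd = noise_sd, ...)
  mk_result <- function(ev) accept_trace(ev, rules, pulling_speed = curve$velocity)
  empty <- data.frame(order_index = integer(0), label = character(0),
                      peak_force = numeric(0), Lc = numeric(0),
                      increment = numeric(0), rss = numeric(0), z = numeric(0))
  if (nrow(pk) < 2L) return(mk_result(empty))
  k <- curve$spring_constant
  fits <- vector("list", nrow(pk))
  for (j in seq_len(nrow(pk))) {
    idx <- pk$edge_start[j]:pk$index[j]
    xj <- z[idx] - f[idx] / k
    fits[[j]] <- tryCatch(fit_wlc_edge(xj, f[idx], params),
                          error = function(e) NULL)
  }
  keep <- !vapply(fits, is.null, logical(1))
  pk <- pk[keep, , drop = FALSE]
  fits <- fits[keep]
  if (nrow(pk) < 2L) return(mk_result(empty))
  Lc <- vapply(fits, `[[`, numeric(1), "Lc")
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  ## forward attribution: increment of event j is Lc[j+1] - Lc[j];
  ## the last peak (detachment) closes the series and is dropped.
  m <- length(Lc) - 1L
  ev <- data.frame(order_index = seq_len(m) - 1L,
                   label = classify_event(diff(Lc), windows),
                   peak_force = pk$peak_force[seq_len(m)],
                   Lc = Lc[seq_len(m)],
                   increment = diff(Lc),
                   rss = rss[seq_len(m)],
                   z = pk$z[seq_len(m)],
                   stringsAsFactors = FALSE)
  mk_result(ev)
}

#' Summarize unfolding events by domain label and pulling speed
#'
#' @param traces List of `trace_result` objects (from
#'   [analyze_unfolding_trace()]).
#' @param accepted_only Use accepted traces only (`TRUE`, default) or all
#'   traces. Both views are part of the standard report.
#' @return A list with `events` (pooled event table with a `speed` column)
#'   and `by_group` (per label x speed: n, mean, sd, se force, mean Lc and
#'   mean increment, plus lognormal mode of force where n >= 3).
#' @export
summarize_unfolding <- function(traces, accepted_only = TRUE) {
  use <- traces
  if (accepted_only) use <- Filter(function(t) isTRUE(t$accepted), traces)
  if (!length(use))
    return(list(events = NULL, by_group = NULL))
  evs <- do.call(rbind, lapply(use, function(t) {
    if (!nrow(t$events)) return(NULL)
    cbind(t$events, speed = t$pulling_speed)
  }))
  if (is.null(evs) || !nrow(evs))
    return(list(events = NULL, by_group = NULL))
  key <- interaction(evs$label, evs$speed, drop = TRUE)
  rows <- lapply(split(evs, key), function(d) {
    fo <- d$peak_force
    mode <- if (length(fo) >= 3 && all(fo > 0)) {
      mu <- mean(log(fo)); sig <- sqrt(mean((log(fo) - mu)^2))
      exp(mu - sig^2)
    } else NA_real_
    data.frame(label = d$label[1], speed = d$speed[1], n = nrow(d),
               mean_force = mean(fo), sd_force = stats::sd(fo),
               se_force = stats::sd(fo) / sqrt(nrow(d)),
               lognormal_mode_force = mode,
               mean_Lc = mean(d$Lc), mean_increment = mean(d$increment),
               stringsAsFactors = FALSE)
  })
  by_group <- do.call(rbind, rows)
  rownames(by_group) <- NULL
  list(events = evs, by_group = by_group[order(by_group$label, by_group$speed), ])
}
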