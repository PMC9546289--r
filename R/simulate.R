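## Synthetic force-curve generator: the stand-in for instrument data and the
## source of every parameter-recovery test. Three curve classes:
## indentation (Hertz-Sneddon forward model), adhesion (piecewise-linear
## rupture profiles with exact work), unfolding (serial WLC + cantilever
## force balance with kinetic Monte Carlo Bell-Evans unfolding).

#' Indenter geometry
#'
#' @param shape Only `"four_sided_pyramid"` is supported.
#' @param face_angle Pyramid face angle alpha in degrees (prefactor
#'   `tan(alpha)/sqrt(2)`).
#' @param poisson_ratio Poisson ratio nu; 0.5 treats the cell as
#'   incompressible.
#' @return An object of class `indenter_geometry`.
#' @export
indenter_geometry <- function(shape = "four_sided_pyramid", face_angle = 18,
                              poisson_ratio = 0.5) {
  shape <- match.arg(shape)
  stopifnot(face_angle > 0, face_angle < 90,
            poisson_ratio >= 0, poisson_ratio <= 0.5)
  structure(list(shape = shape, face_angle = face_angle,
                 poisson_ratio = poisson_ratio),
            class = "indenter_geometry")
}

## Hertz-Sneddon prefactor A in pN/nm^2 so that F = A * delta^2.
## E in kPa; 1 kPa = 1e-3 pN/nm^2.
hertz_prefactor <- function(E, geometry) {
  (E * 1e-3) / (1 - geometry$poisson_ratio^2) *
    tan(geometry$face_angle * pi / 180) / sqrt(2)
}

#' Configuration for simulated indentation experiments
#'
#' Defaults reproduce the study conditions of a live-cell stiffness mapping
#' experiment: cell populations with lognormally distributed Young's moduli
#' (parameterised by mode and shape sigma, location `mu = log(mode) + sigma^2`),
#' 50 cells measured 10 times each, 7.5 um curves at 5 um/s and 4096 Hz,
#' 1 nN force setpoint, a 0.12 N/m (120 pN/nm) cantilever and 37 C (310 K).
#'
#' @param modulus_mode Lognormal mode of the cell population in kPa.
#' @param modulus_sigma Lognormal shape parameter.
#' @param n_cells Number of cells.
#' @param curves_per_cell Curves measured per cell (same true E, fresh noise
#'   and contact offset).
#' @param geometry An [indenter_geometry()].
#' @param contact_offset_range Range (nm) of the pre-contact span drawn per
#'   curve.
#' @param baseline_tilt_range Range (pN/nm) of the baseline tilt drawn per
#'   curve.
#' @param noise_sd Additive white Gaussian force noise in pN.
#' @param max_force Force setpoint in pN; the approach is truncated there.
#' @param spring_constant Cantilever stiffness in pN/nm.
#' @param velocity Approach speed in nm/s.
#' @param sampling_rate Sampling rate in Hz.
#' @param curve_length Total approach length in nm.
#' @param temperature Temperature in K.
#' @param group_label Group label stamped on the curves.
#' @param seed Optional integer seed for [simulate_indentation_population()].
#' @return An object of class `indentation_sim_config`.
#' @export
indentation_sim_config <- function(modulus_mode = 1.88, modulus_sigma = 0.5,
                                   n_cells = 50L, curves_per_cell = 10L,
                                   geometry = indenter_geometry(),
                                   contact_offset_range = c(4000, 6000),
                                   baseline_tilt_range = c(-0.02, 0.02),
                                   noise_sd = 5, max_force = 1000,
                                   spring_constant = 120, velocity = 5000,
                                   sampling_rate = 4096, curve_length = 7500,
                                   temperature = 310, group_label = "groupA",
                                   seed = NULL) {
  stopifnot(modulus_mode > 0, modulus_sigma >= 0, n_cells >= 1,
            curves_per_cell >= 1, noise_sd >= 0, max_force > 0,
            spring_constant > 0, velocity > 0, sampling_rate > 0,
            curve_length > 0, temperature > 0,
            length(contact_offset_range) == 2,
            all(contact_offset_range > 0),
            contact_offset_range[2] < curve_length)
  structure(as.list(environment()), class = "indentation_sim_config")
}

#' Simulate one indentation force curve
#'
#' Approach segment with a flat (optionally tilted) pre-contact region, a
#' contact point at a drawn pre-contact offset, and post-contact force
#' following the Hertz-Sneddon law in true indentation (the force balance
#' `A * delta^2 = k * (travel - delta)` is solved in closed form so the
#' finite cantilever deflection F/k is part of the forward model). Gaussian
#' noise is added and the curve is truncated at the force setpoint. Ground
#' truth is recorded in the curve annotations (`true_E_kPa`,
#' `true_contact_nm`, `true_tilt_pN_per_nm`).
#'
#' @param E True Young's modulus in kPa.
#' @param config An [indentation_sim_config()].
#' @param cell_id,curve_id Identifiers.
#' @param seed Optional seed (for single-curve reproducibility).
#' @return A [force_curve()] with one approach segment.
#' @export
simulate_indentation_curve <- function(E, config = indentation_sim_config(),
                                       cell_id = "cell1", curve_id = NULL,
                                       seed = NULL) {
  stopifnot(E > 0)
  if (!is.null(seed)) set.seed(seed)
  spacing <- config$velocity / config$sampling_rate
  z <- seq(config$curve_length, 0, by = -spacing)
  offset <- stats::runif(1, config$contact_offset_range[1],
                         config$contact_offset_range[2])
  z0 <- config$curve_length - offset
  tilt <- stats::runif(1, config$baseline_tilt_range[1],
                       config$baseline_tilt_range[2])
  A <- hertz_prefactor(E, config$geometry)
  k <- config$spring_constant
  s <- pmax(0, z0 - z)                       # piezo travel past contact
  delta <- (-k + sqrt(k^2 + 4 * A * k * s)) / (2 * A)
  f_el <- A * delta^2
  cross <- which(f_el >= config$max_force)
  if (length(cross)) {
    keep <- seq_len(cross[1L])
    z <- z[keep]; f_el <- f_el[keep]
  }
  f <- f_el + tilt * (config$curve_length - z)
  if (config$noise_sd > 0) f <- f + stats::rnorm(length(f), 0, config$noise_sd)
  if (is.null(curve_id))
    curve_id <- sprintf("%s_%s_%06d", config$group_label, cell_id,
                        sample.int(1e6, 1))
  force_curve(
    list(segment("approach", z, f, config$sampling_rate)),
    spring_constant = k, velocity = config$velocity,
    temperature = config$temperature, mode = "indentation",
    curve_id = curve_id, cell_id = cell_id, group_label = config$group_label,
    annotations = list(true_E_kPa = E, true_contact_nm = z0,
                       true_tilt_pN_per_nm = tilt,
                       noise_sd_pN = config$noise_sd,
                       face_angle_deg = config$geometry$face_angle,
                       poisson_ratio = config$geometry$poisson_ratio))
}

#' Simulate an indentation population (cells x repeat curves)
#'
#' Draws one true modulus per cell from a lognormal distribution with the
#' configured mode and sigma (location `mu = log(mode) + sigma^2`, so that
#' `exp(mu - sigma^2)` equals the configured mode), then simulates
#' `curves_per_cell` curves per cell.
#'
#' @param config An [indentation_sim_config()].
#' @param seed Integer seed; overrides `config$seed`.
#' @return A list with `curves` (list of [force_curve()]), `truth`
#'   (data.frame cell_id, E_true_kPa) and `config`.
#' @export
simulate_indentation_population <- function(config = indentation_sim_config(),
                                            seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  mu <- log(config$modulus_mode) + config$modulus_sigma^2
  E_cells <- stats::rlnorm(config$n_cells, meanlog = mu,
                           sdlog = config$modulus_sigma)
  curves <- vector("list", config$n_cells * config$curves_per_cell)
  cell_ids <- sprintf("%s_cell%03d", config$group_label,
                      seq_len(config$n_cells))
  n <- 0L
  for (i in seq_len(config$n_cells)) {
    for (j in seq_len(config$curves_per_cell)) {
      n <- n + 1L
      curves[[n]] <- simulate_indentation_curve(
        E_cells[i], config, cell_id = cell_ids[i],
        curve_id = sprintf("%s_c%02d", cell_ids[i], j))
    }
  }
  list(curves = curves,
       truth = data.frame(cell_id = cell_ids, E_true_kPa = E_cells,
                          stringsAsFactors = FALSE),
       config = config)
}

#' Mode of the lognormal distribution used by the generators
#'
#' @param mode Target mode.
#' @param sigma Shape parameter.
#' @return The location parameter `mu = log(mode) + sigma^2`.
#' @export
lognormal_mu_for_mode <- function(mode, sigma) log(mode) + sigma^2

#' Configuration for simulated adhesion experiments
#'
#' Retract curves of a single-cell adhesion experiment: after a compressive
#' unloading ramp the force crosses zero, an adhesive (negative-force)
#' profile follows whose noise-free integral equals `work_target` exactly,
#' and the curve detaches by a sharp rupture back to the baseline. Profiles:
#' `"triangular"` (single ramp + final rupture) or `"multi_rupture"`
#' (`rupture_count` equal sub-events, each ending in a sign-restoring force
#' step).
#'
#' @param profile `"triangular"` or `"multi_rupture"`.
#' @param work_target Work of adhesion in fJ (1 fJ = 1e6 pN nm).
#' @param rupture_count Number of ruptures for `multi_rupture`.
#' @param detachment_range Range (nm) for the drawn detachment position.
#' @param zero_force_range Range (nm) for the drawn zero-force point.
#' @param noise_sd Force noise SD in pN.
#' @param max_force Contact force in pN at the start of the retract.
#' @param spring_constant Cantilever stiffness in pN/nm.
#' @param velocity Retract speed in nm/s.
#' @param sampling_rate Sampling rate in Hz.
#' @param temperature Temperature in K.
#' @param group_label Group label.
#' @param seed Optional seed.
#' @return An object of class `adhesion_sim_config`.
#' @export
adhesion_sim_config <- function(profile = c("triangular", "multi_rupture"),
                                work_target = 2, rupture_count = 3L,
                                detachment_range = c(5000, 15000),
                                zero_force_range = c(150, 400),
                                noise_sd = 5, max_force = 2000,
                                spring_constant = 120, velocity = 5000,
                                sampling_rate = 2048, temperature = 310,
                                group_label = "groupA", seed = NULL) {
  profile <- match.arg(profile)
  stopifnot(work_target >= 0, rupture_count >= 1,
            length(detachment_range) == 2, all(detachment_range > 0),
            zero_force_range[1] > 0,
            zero_force_range[2] < detachment_range[1],
            noise_sd >= 0, spring_constant > 0, velocity > 0,
            sampling_rate > 0)
  structure(as.list(environment()), class = "adhesion_sim_config")
}

#' Simulate one adhesion retract curve
#'
#' The adhesive profile is piecewise linear on the sampling grid, so its
#' trapezoidal integral equals `work_target` to floating-point accuracy.
#' Ground truth (`true_work_fJ`, `true_detachment_nm`, `true_zero_force_nm`,
#' `true_ruptures`) is recorded in the annotations.
#'
#' @param config An [adhesion_sim_config()].
#' @param curve_id,cell_id Identifiers.
#' @param work_target Optional per-curve override of `config$work_target`.
#' @param seed Optional seed.
#' @return A [force_curve()] with a token pause segment and the retract.
#' @export
simulate_adhesion_curve <- function(config = adhesion_sim_config(),
                                    curve_id = NULL, cell_id = "cell1",
                                    work_target = config$work_target,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacing <- config$velocity / config$sampling_rate
  z_zero <- stats::runif(1, config$zero_force_range[1], config$zero_force_range[2])
  z_d <- stats::runif(1, config$detachment_range[1], config$detachment_range[2])
  i_zero <- max(2L, round(z_zero / spacing))
  i_d <- round(z_d / spacing)
  n <- ceiling(i_d * 1.4) + round(2000 / spacing)
  z <- spacing * (0:(n - 1L))
  f <- numeric(n)
  W_pNnm <- work_target * 1e6
  ruptures <- 0L
  if (work_target > 0) {
    ## compressive unloading ramp: +max_force at z=0 down to 0 at z_zero
    pre <- 1:(i_zero + 1L)
    f[pre] <- config$max_force * (1 - (pre - 1L) / i_zero)
    nev <- if (config$profile == "triangular") 1L else as.integer(config$rupture_count)
    bounds <- round(seq(i_zero, i_d, length.out = nev + 1L))
    base_nm <- z[i_d + 1L] - z[i_zero + 1L]  # indices are 0-based on grid
    depth <- 2 * W_pNnm / base_nm            # equal depth per sub-event
    for (e in seq_len(nev)) {
      a <- bounds[e]; b <- bounds[e + 1L]
      ## ramp 0 -> -depth over [a, b-1], sharp rupture to the next level at b
      idx <- a:(b - 1L)
      f[idx + 1L] <- -depth * (idx - a) / (b - 1L - a)
    }
    ruptures <- nev
  }
  if (config$noise_sd > 0) f <- f + stats::rnorm(n, 0, config$noise_sd)
  if (is.null(curve_id))
    curve_id <- sprintf("%s_adh_%06d", config$group_label, sample.int(1e6, 1))
  pause_len <- 8L
  pause <- segment("pause", rep(0, pause_len),
                   rep(config$max_force, pause_len), config$sampling_rate)
  force_curve(
    list(pause, segment("retract", z, f, config$sampling_rate)),
    spring_constant = config$spring_constant, velocity = config$velocity,
    temperature = config$temperature, mode = "adhesion",
    curve_id = curve_id, cell_id = cell_id, group_label = config$group_label,
    annotations = list(true_work_fJ = work_target,
                       true_detachment_nm = z[i_d + 1L],
                       true_zero_force_nm = z[i_zero + 1L],
                       true_ruptures = ruptures,
                       noise_sd_pN = config$noise_sd))
}

#' Simulate an adhesion study group
#'
#' Per-curve work targets are drawn from a lognormal with the given median
#' (`exp(mu)`) and shape, so a 2.5x ratio of group medians is exact in truth.
#'
#' @param n_curves Number of curves.
#' @param work_median Median work of adhesion in fJ.
#' @param work_sigma Lognormal shape of the work distribution.
#' @param config An [adhesion_sim_config()].
#' @param seed Integer seed.
#' @return A list with `curves`, `truth` (curve_id, work_fJ) and `config`.
#' @export
simulate_adhesion_population <- function(n_curves = 90L, work_median = 2,
                                         work_sigma = 0.6,
                                         config = adhesion_sim_config(),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rlnorm(n_curves, meanlog = log(work_median), sdlog = work_sigma)
  curves <- vector("list", n_curves)
  for (i in seq_len(n_curves)) {
    curves[[i]] <- simulate_adhesion_curve(
      config, curve_id = sprintf("%s_adh%04d", config$group_label, i),
      cell_id = sprintf("%s_cell%03d", config$group_label, i),
      work_target = w[i])
  }
  list(curves = curves,
       truth = data.frame(curve_id = vapply(curves, `[[`, character(1), "curve_id"),
                          work_fJ = w, stringsAsFactors = FALSE),
       config = config)
}

#' Bell-Evans parameters of one unfoldable domain
#'
#' @param k0 Intrinsic (zero-force) unfolding rate in 1/s.
#' @param delta_x Distance to the transition state in nm.
#' @return An object of class `bell_evans_params`.
#' @export
bell_evans_params <- function(k0, delta_x) {
  stopifnot(k0 > 0, delta_x > 0)
  structure(list(k0 = k0, delta_x = delta_x), class = "bell_evans_params")
}

#' Most probable unfolding force under the Bell-Evans model
#'
#' `F* = (kBT/dx) * log(r * dx / (k0 * kBT))` for loading rate `r`. If the
#' logarithm's argument is <= 1 the most probable force is 0 (returned with a
#' warning).
#'
#' @param params A [bell_evans_params()].
#' @param loading_rate Loading rate in pN/s.
#' @param temperature Temperature in K.
#' @return Most probable force in pN.
#' @examples
#' bell_evans_force(bell_evans_params(1e-4, 0.25), 1e4, 298) # about 257 pN
#' @export
bell_evans_force <- function(params, loading_rate, temperature = 298) {
  kT <- kBT(temperature)
  arg <- loading_rate * params$delta_x / (params$k0 * kT)
  if (any(arg <= 1)) {
    warning("loading rate too low for a positive most-probable force; returning 0")
    return(ifelse(arg <= 1, 0, (kT / params$delta_x) * log(arg)))
  }
  (kT / params$delta_x) * log(arg)
}

#' Default polyprotein layout: 3x I27 + FLNA repeat 22 + 4x I27
#'
#' Contour-length increments are 27.3 nm (I27) and 30.4 nm (FLNA repeat 22).
#' The Bell-Evans parameters are calibration defaults chosen so that the
#' simulated most-probable unfolding forces land near published ranges for
#' these domains (I27 roughly 215/250 pN and FLNA repeat 22 tens of pN at
#' 400/1600 nm/s); they are not measured constants.
#'
#' @param variant `"Q"` (unedited, weaker) or `"R"` (edited, stronger) FLNA
#'   repeat 22.
#' @return data.frame with columns `label`, `dLc`, `k0`, `delta_x`, one row
#'   per domain in N- to C-terminal order.
#' @export
default_polyprotein_layout <- function(variant = c("Q", "R")) {
  variant <- match.arg(variant)
  i27 <- data.frame(label = "I27", dLc = 27.3, k0 = 3.5e-4, delta_x = 0.25,
                    stringsAsFactors = FALSE)
  flna <- if (variant == "Q")
    data.frame(label = "FLNA", dLc = 30.4, k0 = 8, delta_x = 0.22,
               stringsAsFactors = FALSE)
  else
    data.frame(label = "FLNA", dLc = 30.4, k0 = 2.5, delta_x = 0.15,
               stringsAsFactors = FALSE)
  rbind(i27, i27, i27, flna, i27, i27, i27, i27)
}

#' Configuration for simulated unfolding experiments
#'
#' @param domain_layout data.frame with columns `label`, `dLc` (nm), `k0`
#'   (1/s), `delta_x` (nm); see [default_polyprotein_layout()].
#' @param persistence_length WLC persistence length in nm.
#' @param pulling_speed Retract speed in nm/s.
#' @param spring_constant Cantilever stiffness in pN/nm (0.01 N/m probe).
#' @param temperature Temperature in K.
#' @param noise_sd Force noise SD in pN.
#' @param n_traces Number of traces for population runs.
#' @param initial_contour Contour length (nm) of the folded construct before
#'   any unfolding (linkers + folded domains).
#' @param detach_force Force (pN) at which the tip-surface attachment breaks
#'   after (or before) the domains unfold; `Inf` disables detachment.
#' @param trace_length Retract length in nm.
#' @param sampling_rate Output sampling rate in Hz; default gives about
#'   0.39 nm point spacing at any speed.
#' @param internal_step Internal force-balance grid step in nm (kept small so
#'   force increments per KMC step stay near 1 pN).
#' @param seed Optional seed.
#' @return An object of class `unfolding_sim_config`.
#' @export
unfolding_sim_config <- function(domain_layout = default_polyprotein_layout("Q"),
                                 persistence_length = 0.4,
                                 pulling_speed = 1600, spring_constant = 10,
                                 temperature = 298, noise_sd = 5,
                                 n_traces = 100L, initial_contour = 35,
                                 detach_force = 400, trace_length = 800,
                                 sampling_rate = NULL, internal_step = 0.1,
                                 seed = NULL) {
  stopifnot(nrow(domain_layout) >= 1,
            all(c("label", "dLc", "k0", "delta_x") %in% names(domain_layout)),
            all(domain_layout$dLc > 0), all(domain_layout$k0 > 0),
            all(domain_layout$delta_x > 0),
            persistence_length > 0, pulling_speed > 0, spring_constant > 0,
            temperature > 0, noise_sd >= 0, initial_contour > 0,
            trace_length > 0, internal_step > 0)
  if (is.null(sampling_rate)) sampling_rate <- pulling_speed / 0.390625
  structure(as.list(environment()), class = "unfolding_sim_config")
}

## extension at which the WLC reaches force F (scalar Lc)
wlc_extension_at <- function(F, Lc, params) {
  stats::uniroot(function(x) wlc_force(x, Lc, params) - F,
                 c(0, Lc * (1 - 1e-9)), tol = 1e-9)$root
}

#' Simulate one sawtooth unfolding trace (kinetic Monte Carlo)
#'
#' Constant-velocity pulling; at every piezo position the force solves the
#' serial WLC + cantilever force balance at the currently released contour
#' length. Each folded domain unfolds stochastically with Bell-Evans rate
#' `k(F) = k0 * exp(F * dx / kBT)`, integrated over time on a fine internal
#' grid (force steps of order 1 pN); on unfolding its contour increment is
#' added. After the last unfolding the trace ends with a final detachment at
#' `detach_force`. The ground-truth event list (domain, force, piezo
#' position, time) is recorded in the annotations as JSON and is also
#' retrievable with [true_events()].
#'
#' @param config An [unfolding_sim_config()].
#' @param curve_id Identifier.
#' @param seed Optional seed.
#' @return A [force_curve()] with one retract segment.
#' @export
simulate_unfolding_trace <- function(config = unfolding_sim_config(),
                                     curve_id = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- wlc_params(config$persistence_length, config$temperature)
  kT <- params$kBT
  k <- config$spring_constant
  v <- config$pulling_speed
  dz <- config$internal_step
  dt <- dz / v
  layout <- config$domain_layout
  folded <- rep(TRUE, nrow(layout))
  Lc <- config$initial_contour
  D_cur <- dz
  t_cur <- 0
  F_stop <- if (is.finite(config$detach_force)) config$detach_force else 600
  D_path <- numeric(0); F_path <- numeric(0)
  events <- list()
  detached <- FALSE
  repeat {
    x_cap <- wlc_extension_at(F_stop * 1.05, Lc, params)
    D_max <- min(x_cap + F_stop * 1.05 / k, config$trace_length)
    if (D_cur >= D_max) break
    grid <- seq(D_cur, D_max, by = dz)
    if (length(grid) < 2L) break
    x <- solve_wlc_balance(grid, Lc, k, params)
    Fg <- k * (grid - x)
    j_det <- if (is.finite(config$detach_force))
      which(Fg >= config$detach_force)[1L] else NA_integer_
    if (any(folded)) {
      rates <- sapply(which(folded), function(d)
        layout$k0[d] * exp(Fg * layout$delta_x[d] / kT))
      rates <- if (is.matrix(rates)) rates else matrix(rates, ncol = 1)
      tot <- rowSums(rates)
      H <- cumsum(c(0, (tot[-1] + tot[-length(tot)]) / 2 * dt))
      thresh <- -log(stats::runif(1))
      j_unf <- which(H >= thresh)[1L]
    } else {
      j_unf <- NA_integer_
    }
    j <- suppressWarnings(min(j_unf, j_det, na.rm = TRUE))
    if (!is.finite(j)) {                     # nothing happens within this grid
      D_path <- c(D_path, grid); F_path <- c(F_path, Fg)
      break
    }
    D_path <- c(D_path, grid[seq_len(j)])
    F_path <- c(F_path, Fg[seq_len(j)])
    t_event <- t_cur + (j - 1L) * dt
    if (!is.na(j_det) && j == j_det && (is.na(j_unf) || j_det <= j_unf)) {
      events[[length(events) + 1L]] <- data.frame(
        label = "detach", force = Fg[j], z = grid[j], time = t_event,
        stringsAsFactors = FALSE)
      detached <- TRUE
      break
    }
    ## pick which folded domain unfolded, proportional to its rate at the event
    fi <- which(folded)
    w <- layout$k0[fi] * exp(Fg[j] * layout$delta_x[fi] / kT)
    d <- fi[sample.int(length(fi), 1L, prob = w)]
    events[[length(events) + 1L]] <- data.frame(
      label = layout$label[d], force = Fg[j], z = grid[j], time = t_event,
      stringsAsFactors = FALSE)
    folded[d] <- FALSE
    Lc <- Lc + layout$dLc[d]
    D_cur <- grid[j] + dz
    t_cur <- t_event + dt
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(label = character(0), force = numeric(0), z = numeric(0),
               time = numeric(0))
  ## resample to the output grid, add a baseline tail after detachment
  end_z <- min(config$trace_length,
               max(D_path) + if (detached) 150 else 0)
  spacing_out <- v / config$sampling_rate
  z_out <- seq(dz, end_z, by = spacing_out)
  f_out <- stats::approx(D_path, F_path, xout = pmin(z_out, max(D_path)),
                         rule = 2)$y
  if (detached) f_out[z_out > max(D_path)] <- 0
  if (config$noise_sd > 0)
    f_out <- f_out + stats::rnorm(length(f_out), 0, config$noise_sd)
  if (is.null(curve_id))
    curve_id <- sprintf("unfold_%06d", sample.int(1e6, 1))
  force_curve(
    list(segment("retract", z_out, f_out, config$sampling_rate)),
    spring_constant = k, velocity = v, temperature = config$temperature,
    mode = "unfolding", curve_id = curve_id,
    annotations = list(
      true_events = as.character(jsonlite::toJSON(ev, digits = NA)),
      n_domains = nrow(layout),
      initial_contour_nm = config$initial_contour,
      persistence_nm = config$persistence_length,
      noise_sd_pN = config$noise_sd))
}

#' Ground-truth unfolding events of a simulated trace
#'
#' @param curve A [force_curve()] produced by [simulate_unfolding_trace()].
#' @return data.frame with columns `label`, `force`, `z`, `time`.
#' @export
true_events <- function(curve) {
  js <- curve$annotations$true_events
  if (is.null(js)) stop("curve has no true_events annotation", call. = FALSE)
  jsonlite::fromJSON(js)
}
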