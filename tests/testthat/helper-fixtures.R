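# Shared fixtures: everything is generated in code at test time.

# noise- and tilt-free indentation config (optionally higher setpoint so
# stiff curves still reach the 500 nm fit depth)
clean_indent_cfg <- function(max_force = 1000, ...) {
  indentation_sim_config(noise_sd = 0, baseline_tilt_range = c(0, 0),
                         max_force = max_force, ...)
}

# a hand-built approach curve: flat baseline then linear force rise,
# useful when a test needs exact control over z and F
linear_contact_curve <- function(z0 = 5000, slope = 1, k = 120,
                                 curve_length = 7500, spacing = 2,
                                 mode = "indentation") {
  z <- seq(curve_length, 0, by = -spacing)
  f <- ifelse(z < z0, slope * (z0 - z), 0)
  force_curve(list(segment("approach", z, f, 2048)),
              spring_constant = k, velocity = 5000, temperature = 310,
              mode = mode, curve_id = "linear1")
}

# analytic triangular adhesion retract built directly on arrays:
# force 0 at z_zero, linear to -depth just before z_d, rupture to 0
triangle_retract <- function(depth = 1000, z_zero = 0, z_d = 2000,
                             spacing = 2, z_end = z_d * 1.5 + 500) {
  z <- seq(0, z_end, by = spacing)
  f <- numeric(length(z))
  ramp <- z > z_zero & z < z_d
  f[ramp] <- -depth * (z[ramp] - z_zero) / (z_d - spacing - z_zero)
  list(z = z, f = f)
}

# random small curve for round-trip tests
random_curve <- function(id) {
  n <- sample(5:40, 1)
  segs <- list(
    segment("approach", sort(runif(n, 0, 1000), decreasing = TRUE),
            rnorm(n), 4096),
    segment("retract", sort(runif(n, 0, 1000)), rnorm(n), 2048)
  )
  force_curve(segs, spring_constant = runif(1, 10, 200),
              velocity = runif(1, 100, 10000),
              temperature = runif(1, 270, 330),
              mode = sample(c("indentation", "adhesion", "unfolding"), 1),
              curve_id = id, cell_id = "cellX", group_label = "G",
              annotations = list(true_E_kPa = runif(1), note = "free text"))
}
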