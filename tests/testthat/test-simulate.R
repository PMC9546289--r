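test_that("indentation forward model matches the closed form and is clean pre-contact", {
  geo <- indenter_geometry(face_angle = 20, poisson_ratio = 0.5)
  # direct evaluation: E = 2 kPa, alpha = 20 deg, nu = 0.5, delta = 500 nm
  expect_equal(hertz_sneddon_force(2, 500, geo),
               2e-3 / (1 - 0.25) * tan(20 * pi / 180) / sqrt(2) * 500^2)
  expect_equal(hertz_sneddon_force(2, 500, geo), 171.58, tolerance = 1e-4)

  cfg <- clean_indent_cfg(geometry = geo)
  cur <- simulate_indentation_curve(2, cfg, seed = 5)
  seg <- get_segment(cur, "approach")
  z0 <- cur$annotations$true_contact_nm
  pre <- seg$height >= z0
  expect_true(all(seg$force[pre] == 0))
  # post-contact force satisfies the Hertz law in TRUE indentation
  post <- which(seg$height < z0)
  delta <- (z0 - seg$height[post]) - seg$force[post] / cur$spring_constant
  expect_equal(seg$force[post], hertz_sneddon_force(2, delta, geo),
               tolerance = 1e-9)
})

test_that("simulated curves are deterministic given a seed", {
  cfg <- indentation_sim_config(noise_sd = 5)
  a <- simulate_indentation_curve(2, cfg, seed = 99)
  b <- simulate_indentation_curve(2, cfg, seed = 99)
  expect_identical(a$segments[[1]]$force, b$segments[[1]]$force)
  p1 <- simulate_indentation_population(indentation_sim_config(n_cells = 3L,
                                                               curves_per_cell = 2L),
                                        seed = 7)
  p2 <- simulate_indentation_population(indentation_sim_config(n_cells = 3L,
                                                               curves_per_cell = 2L),
                                        seed = 7)
  expect_identical(p1$truth$E_true_kPa, p2$truth$E_true_kPa)
  expect_identical(p1$curves[[4]]$segments[[1]]$force,
                   p2$curves[[4]]$segments[[1]]$force)
  # and byte-identical files
  dir <- withr::local_tempdir()
  write_curve(a, file.path(dir, "a"))
  write_curve(b, file.path(dir, "b"))
  expect_identical(readLines(file.path(dir, "a")),
                   readLines(file.path(dir, "b")))
})

test_that("population generator honours counts, degenerate sigma and the lognormal mode", {
  pop <- simulate_indentation_population(
    indentation_sim_config(n_cells = 50L, curves_per_cell = 10L), seed = 3)
  expect_length(pop$curves, 500L)
  expect_equal(nrow(pop$truth), 50L)

  degen <- simulate_indentation_population(
    indentation_sim_config(modulus_mode = 1.88, modulus_sigma = 0,
                           n_cells = 5L, curves_per_cell = 1L), seed = 4)
  expect_equal(degen$truth$E_true_kPa, rep(1.88, 5))

  # Monte Carlo vs closed-form mode: draws from mu = log(mode) + sigma^2
  set.seed(12)
  draws <- rlnorm(1e5, lognormal_mu_for_mode(1.88, 0.5), 0.5)
  lv <- log(draws)
  emp_mode <- exp(mean(lv) - mean((lv - mean(lv))^2))
  expect_equal(emp_mode, 1.88, tolerance = 0.03)
})

test_that("adhesion generator integrates exactly to its work target", {
  # noise-free trapezoid of the generated profile equals work_target to <0.1%
  for (prof in c("triangular", "multi_rupture")) {
    cfg <- adhesion_sim_config(profile = prof, work_target = 1,
                               rupture_count = 3L, noise_sd = 0)
    cur <- simulate_adhesion_curve(cfg, seed = 21)
    seg <- get_segment(cur, "retract")
    w <- sum(diff(seg$height) *
               (pmax(-seg$force, 0)[-1] + pmax(-seg$force, 0)[-length(seg$force)]) / 2) * 1e-6
    expect_equal(w, 1, tolerance = 1e-3)
  }
  # work 0 -> flat retract at zero force
  flat <- simulate_adhesion_curve(adhesion_sim_config(work_target = 0,
                                                      noise_sd = 0), seed = 22)
  expect_true(all(get_segment(flat, "retract")$force == 0))
  # 3 ruptures -> 3 sign-restoring steps in the noise-free profile
  cfg3 <- adhesion_sim_config(profile = "multi_rupture", work_target = 2,
                              rupture_count = 3L, noise_sd = 0)
  cur3 <- simulate_adhesion_curve(cfg3, seed = 23)
  seg3 <- get_segment(cur3, "retract")
  steps <- diff(seg3$force)
  expect_equal(sum(steps > 50), 3L)
  expect_equal(cur3$annotations$true_ruptures, 3L)
})

test_that("Bell-Evans most probable force follows its closed form", {
  be <- bell_evans_params(1e-4, 0.25)
  f1 <- bell_evans_force(be, 1e4, 298)
  kT <- kBT(298)
  expect_equal(f1, (kT / 0.25) * log(1e4 * 0.25 / (1e-4 * kT)))
  expect_equal(f1, 257.06, tolerance = 1e-4)
  # rate scaled by e raises F* by exactly kBT/dx
  expect_equal(bell_evans_force(be, exp(1) * 1e4, 298) - f1, kT / 0.25)
  # strictly monotone in the rate
  rates <- 10^seq(2, 6, by = 0.5)
  expect_true(all(diff(bell_evans_force(be, rates, 298)) > 0))
  # too-low rate: most probable force 0, with a warning
  expect_warning(f0 <- bell_evans_force(bell_evans_params(1e6, 0.25), 1, 298))
  expect_equal(f0, 0)
})

test_that("KMC unfolding respects limits: frozen domains never unfold, speed raises forces", {
  # k0 -> 0 keeps the domain folded for the whole trace
  lay <- data.frame(label = "I27", dLc = 27.3, k0 = 1e-30, delta_x = 0.25)
  cfg <- unfolding_sim_config(domain_layout = lay, noise_sd = 0,
                              initial_contour = 60, detach_force = 400,
                              trace_length = 300)
  ev <- true_events(simulate_unfolding_trace(cfg, seed = 31))
  expect_false("I27" %in% ev$label)
  expect_true("detach" %in% ev$label)

  # doubling the pulling speed raises the mean true unfolding force of
  # every domain type (Bell-Evans monotonicity through the simulator)
  set.seed(32)
  mean_force <- function(speed, n = 25) {
    cfg <- unfolding_sim_config(pulling_speed = speed, noise_sd = 0)
    f <- vapply(seq_len(n), function(i) {
      ev <- true_events(simulate_unfolding_trace(cfg))
      c(mean(ev$force[ev$label == "FLNA"]), mean(ev$force[ev$label == "I27"]))
    }, numeric(2))
    rowMeans(f, na.rm = TRUE)
  }
  lo <- mean_force(400)
  hi <- mean_force(800)
  expect_gt(hi[1], lo[1])   # FLNA
  expect_gt(hi[2], lo[2])   # I27
})

test_that("the weak FLNA domain unfolds first in nearly all traces", {
  set.seed(33)
  cfg <- unfolding_sim_config(noise_sd = 0)
  firsts <- vapply(1:40, function(i)
    true_events(simulate_unfolding_trace(cfg))$label[1], character(1))
  expect_gte(mean(firsts == "FLNA"), 0.95)
})
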