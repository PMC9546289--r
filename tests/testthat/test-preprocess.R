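test_that("baseline estimation recovers injected offset, tilt and noise", {
  # flat zero curve -> (0, 0, 0)
  z <- seq(7500, 0, by = -2)
  flat <- force_curve(list(segment("approach", z, rep(0, length(z)), 4096)),
                      120, 5000, 310, "indentation", "flat")
  b <- estimate_baseline(flat)
  expect_equal(b$offset, 0)
  expect_equal(b$tilt, 0)
  expect_equal(b$noise_sd, 0)

  # injected tilt, no noise: slope recovered to 1e-9
  cfg <- indentation_sim_config(noise_sd = 0,
                                baseline_tilt_range = c(0.05, 0.05))
  cur <- simulate_indentation_curve(2, cfg, seed = 41)
  b <- estimate_baseline(cur)
  expect_equal(b$tilt, 0.05, tolerance = 1e-9)

  # injected 5 pN noise: estimate within 15%
  cfgn <- indentation_sim_config(noise_sd = 5, baseline_tilt_range = c(0, 0))
  curn <- simulate_indentation_curve(2, cfgn, seed = 42)
  bn <- estimate_baseline(curn)
  expect_equal(bn$noise_sd, 5, tolerance = 0.15)

  short <- force_curve(list(segment("approach", seq(100, 0, by = -10),
                                    rep(0, 11), 4096)),
                       120, 5000, 310, "indentation", "short")
  expect_error(estimate_baseline(short, fraction = 0.5), "10 samples")
})

test_that("contact point is recovered to within a sample spacing without noise", {
  spacing <- 5000 / 4096
  for (E in c(0.5, 2, 10)) {
    cur <- simulate_indentation_curve(E, clean_indent_cfg(max_force = 2000),
                                      seed = 50 + E)
    z0 <- find_contact_point(cur)
    expect_lt(abs(z0 - cur$annotations$true_contact_nm), spacing)
  }
  # all-zero curve: no contact
  z <- seq(7500, 0, by = -2)
  flat <- force_curve(list(segment("approach", z, rep(0, length(z)), 4096)),
                      120, 5000, 310, "indentation", "flat")
  expect_error(find_contact_point(flat), class = "afm_no_contact")
})

test_that("contact recovery under 5 pN noise stays within 20 nm for >=95% of curves", {
  set.seed(52)
  cfg <- indentation_sim_config(noise_sd = 5)
  err <- replicate(100, {
    cur <- simulate_indentation_curve(2, cfg)
    pr <- preprocess_curve(cur)
    pr$contact_point - cur$annotations$true_contact_nm
  })
  expect_gte(mean(abs(err) <= 20), 0.95)
})

test_that("indentation axis follows delta = (z0 - z) - F/k", {
  # arithmetic of the stated formula: F = 100 pN at z0 - z = 600, k = 120
  z <- seq(1000, 0, by = -100)
  z0 <- 700
  f <- ifelse(z < z0, 100 * (z0 - z) / 600, 0)
  cur <- force_curve(list(segment("approach", z, f, 100)),
                     120, 5000, 310, "indentation", "arith")
  pr <- compute_indentation(cur, z0,
                            baseline = list(offset = 0, tilt = 0, noise_sd = 0))
  i600 <- which.min(abs((z0 - z[z < z0]) - 600))
  expect_equal(pr$indentation[i600], 600 - 100 / 120, tolerance = 1e-9)

  # rigid substrate: force rises with slope k against z, so delta == 0
  rigid <- linear_contact_curve(z0 = 5000, slope = 120, k = 120)
  pr <- compute_indentation(rigid, 5000,
                            baseline = list(offset = 0, tilt = 0, noise_sd = 0))
  expect_true(all(abs(pr$indentation) < 1e-9))

  expect_error(compute_indentation(rigid, 5000,
                                   baseline = list(offset = 0, tilt = 0,
                                                   noise_sd = 0),
                                   spring_constant = 0),
               "positive")

  # noiseless Hertz curve: (delta, F) pairs satisfy the law with true E
  cfg <- clean_indent_cfg()
  cur <- simulate_indentation_curve(2, cfg, seed = 53)
  pr <- preprocess_curve(cur)
  keep <- pr$indentation > 50   # away from the contact singularity
  pred <- hertz_sneddon_force(2, pr$indentation[keep], cfg$geometry)
  expect_lt(max(abs(pr$force[keep] - pred) / pred), 1e-3)
})

test_that("QC flags noisy, contactless and drifting curves deterministically", {
  cfg <- indentation_sim_config(noise_sd = 5)
  pr <- preprocess_curve(simulate_indentation_curve(2, cfg, seed = 61))
  expect_true(pr$qc$passed)

  # noise far beyond threshold
  cfgn <- indentation_sim_config(noise_sd = 150)
  prn <- preprocess_curve(simulate_indentation_curve(2, cfgn, seed = 62))
  expect_false(prn$qc$passed)
  expect_true("excessive_noise" %in% prn$qc$reasons)

  # flat curve: no contact
  z <- seq(7500, 0, by = -2)
  flat <- force_curve(list(segment("approach", z, rnorm(length(z), 0, 1), 4096)),
                      120, 5000, 310, "indentation", "flat")
  prf <- preprocess_curve(flat)
  expect_false(prf$qc$passed)
  expect_true("no_contact" %in% prf$qc$reasons)

  # strong baseline drift
  cfgd <- indentation_sim_config(noise_sd = 0,
                                 baseline_tilt_range = c(0.2, 0.2))
  prd <- preprocess_curve(simulate_indentation_curve(2, cfgd, seed = 63))
  expect_true("drift" %in% prd$qc$reasons)
})

test_that("corrected pre-contact force is statistically indistinguishable from zero", {
  set.seed(64)
  cfg <- indentation_sim_config(noise_sd = 5)
  zmeans <- replicate(20, {
    cur <- simulate_indentation_curve(2, cfg)
    pr <- preprocess_curve(cur)
    seg <- get_segment(cur, "approach")
    pre <- seg$height > pr$contact_point + 20
    mean(pr$corrected_force[pre]) / (5 / sqrt(sum(pre)))
  })
  # standardized means ~ N(0,1): all within +-4, mean within +-2/sqrt(20)
  expect_true(all(abs(zmeans) < 4))
  expect_lt(abs(mean(zmeans)), 2 / sqrt(20) * 3)
})

test_that("preprocessing an already-corrected curve is a near no-op", {
  cfg <- indentation_sim_config(noise_sd = 2)
  cur <- simulate_indentation_curve(2, cfg, seed = 65)
  pr1 <- preprocess_curve(cur)
  seg <- get_segment(cur, "approach")
  cur2 <- force_curve(list(segment("approach", seg$height,
                                   pr1$corrected_force, 4096)),
                      cur$spring_constant, cur$velocity, cur$temperature,
                      "indentation", "again")
  pr2 <- preprocess_curve(cur2)
  expect_lt(max(abs(pr2$corrected_force - pr1$corrected_force)), 2)
  expect_lt(abs(pr2$contact_point - pr1$contact_point), 10)
})
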