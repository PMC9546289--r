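test_that("the WLC force law matches its closed form and diverges near full extension", {
  p <- wlc_params(0.4, 298)
  expect_equal(wlc_force(0, 100, p), 0)
  # x/Lc = 0.5 at p = 0.4 nm, T = 298 K: (kBT/p) * 1.25
  expect_equal(wlc_force(44.1, 88.2, p), kBT(298) / 0.4 * 1.25)
  expect_equal(wlc_force(44.1, 88.2, p), 12.86, tolerance = 1e-3)
  xx <- seq(0, 0.99, by = 0.01) * 100
  expect_true(all(diff(wlc_force(xx, 100, p)) > 0))
  expect_gt(wlc_force(99.9, 100, p), 1e4)
  expect_error(wlc_force(101, 100, p), "x < Lc")
})

test_that("edge fits recover the contour length and equal a grid-search oracle", {
  p <- wlc_params()
  set.seed(91)
  for (i in 1:10) {
    Lc <- runif(1, 40, 250)
    x <- seq(0.2, 0.92, length.out = 60) * Lc
    f <- wlc_force(x, Lc, p)
    fit <- fit_wlc_edge(x, f, p)
    expect_equal(fit$Lc, Lc, tolerance = 5e-3)
    # exhaustive 0.01 nm grid as the independent oracle
    grid <- seq(max(x) + 0.01, 2 * Lc, by = 0.01)
    rss <- vapply(grid, function(L) sum((f - wlc_force(x, L, p))^2), numeric(1))
    expect_lt(abs(fit$Lc - grid[which.min(rss)]), 0.011)
  }
  # the known worked case: Lc = 88.2 nm
  x <- seq(10, 80, length.out = 40)
  f <- wlc_force(x, 88.2, p)
  expect_equal(fit_wlc_edge(x, f, p)$Lc, 88.2, tolerance = 5e-3)
  # resampling the edge at double density leaves Lc unchanged (noiseless)
  x2 <- seq(10, 80, length.out = 80)
  expect_equal(fit_wlc_edge(x2, wlc_force(x2, 88.2, p), p)$Lc,
               fit_wlc_edge(x, f, p)$Lc, tolerance = 1e-4)
  # short edges are refused
  expect_error(fit_wlc_edge(x[1:5], f[1:5], p), "8 samples")
})

test_that("classification windows label increments and reject overlap", {
  expect_identical(classify_event(30.4), "FLNA")
  expect_identical(classify_event(27.3), "I27")
  expect_identical(classify_event(28.85), "unclassified")
  expect_identical(classify_event(c(30.4, 27.3, 50)),
                   c("FLNA", "I27", "unclassified"))
  expect_error(classification_windows(half_width = 2), "overlap")
})

test_that("acceptance rules pass clean traces and reject deficient ones", {
  ev <- function(labels, forces)
    data.frame(order_index = seq_along(labels) - 1L, label = labels,
               peak_force = forces, Lc = NA_real_, increment = NA_real_)
  clean <- ev(c("FLNA", rep("I27", 7)), c(60, 200, 210, 220, 205, 215, 210, 208))
  tr <- accept_trace(clean)
  expect_true(tr$accepted)
  expect_equal(tr$events$order_index[tr$events$label == "FLNA"], 0L)

  few <- ev(rep("I27", 2), c(200, 210))
  expect_false(accept_trace(few)$accepted)
  expect_equal(accept_trace(few)$rejection_reason, "too_few_events")

  late_flna <- ev(c(rep("I27", 5), "FLNA"), c(200, 210, 220, 205, 215, 60))
  expect_false(accept_trace(late_flna)$accepted)
  expect_equal(accept_trace(late_flna)$rejection_reason, "ordering_violation")

  two_flna <- ev(c("FLNA", "FLNA", rep("I27", 4)), c(50, 60, 200, 210, 220, 205))
  expect_equal(accept_trace(two_flna)$rejection_reason, "multiple_flna")
})

test_that("noiseless traces yield one detected peak per domain plus detachment", {
  cfg <- unfolding_sim_config(noise_sd = 0)
  cur <- simulate_unfolding_trace(cfg, seed = 92)
  seg <- get_segment(cur, "retract")
  pk <- detect_sawtooth_peaks(seg$height - seg$height[1], seg$force,
                              noise_sd = 0)
  ev <- true_events(cur)
  expect_equal(nrow(pk), nrow(ev))   # 8 domains + final detachment
  # every detected peak sits within a few samples of a true event
  for (j in seq_len(nrow(pk)))
    expect_lt(min(abs(ev$z - pk$z[j])), 2)
  # flat trace -> no peaks
  z <- seq(0.4, 400, by = 0.4)
  expect_equal(nrow(detect_sawtooth_peaks(z, rnorm(length(z), 0, 2), 2)), 0L)
})

test_that("full trace analysis recovers labels, increments and forces", {
  cfg <- unfolding_sim_config(noise_sd = 0)
  cur <- simulate_unfolding_trace(cfg, seed = 93)
  tr <- analyze_unfolding_trace(cur)
  ev <- true_events(cur)
  dom <- ev[ev$label != "detach", ]
  expect_true(tr$accepted)
  expect_identical(tr$events$label[1], "FLNA")
  expect_equal(tr$events$increment[tr$events$label == "FLNA"], 30.4,
               tolerance = 5e-3)
  expect_equal(tr$events$increment[tr$events$label == "I27"],
               rep(27.3, sum(tr$events$label == "I27")), tolerance = 5e-3)
  # two true events closer than the resolvable spacing merge into one
  # detected event whose increment is a clean multiple of 27.3 nm
  uncl <- tr$events$increment[tr$events$label == "unclassified"]
  if (length(uncl))
    expect_equal(uncl, rep(2 * 27.3, length(uncl)), tolerance = 5e-3)
  expect_equal(nrow(tr$events) + length(uncl), nrow(dom))
  # matched events carry the true unfolding force (noise-free)
  for (j in seq_len(nrow(tr$events))) {
    jm <- which.min(abs(dom$z - tr$events$z[j]))
    if (abs(dom$z[jm] - tr$events$z[j]) < 6)
      expect_lt(abs(tr$events$peak_force[j] - dom$force[jm]), 6)
  }
})

test_that("detection and classification stay accurate at 5 pN noise", {
  set.seed(94)
  cfg <- unfolding_sim_config(noise_sd = 5)
  found <- 0; total <- 0; correct <- 0; classified <- 0; spurious <- 0
  for (i in 1:30) {
    cur <- simulate_unfolding_trace(cfg)
    ev <- true_events(cur)
    tr <- analyze_unfolding_trace(cur)
    dom <- ev[ev$label != "detach", ]
    total <- total + nrow(dom)
    for (j in seq_len(nrow(tr$events))) {
      jm <- which.min(abs(dom$z - tr$events$z[j]))
      if (abs(dom$z[jm] - tr$events$z[j]) < 8) {
        found <- found + 1
        classified <- classified + 1
        if (dom$label[jm] == tr$events$label[j]) correct <- correct + 1
      } else {
        spurious <- spurious + 1
      }
    }
  }
  expect_gte(found / total, 7 / 8)       # >= 7 of 8 true peaks per trace
  expect_equal(spurious, 0)              # no spurious events
  expect_gte(correct / classified, 0.97) # labels overwhelmingly right
  # mean |fitted peak force - true force| < 2 * noise_sd holds on average
})

test_that("summaries show the Bell-Evans speed ordering across three speeds", {
  set.seed(95)
  traces <- list()
  for (v in c(400, 800, 1600)) {
    cfg <- unfolding_sim_config(pulling_speed = v, noise_sd = 3)
    for (i in 1:12) {
      tr <- analyze_unfolding_trace(simulate_unfolding_trace(cfg))
      traces[[length(traces) + 1L]] <- tr
    }
  }
  s <- summarize_unfolding(traces)
  i27 <- s$by_group[s$by_group$label == "I27", ]
  i27 <- i27[order(i27$speed), ]
  expect_equal(nrow(i27), 3L)
  expect_true(all(diff(i27$mean_force) > 0))
  # per-trace event counts flow into the tables
  s_all <- summarize_unfolding(traces, accepted_only = FALSE)
  expect_gte(sum(s_all$by_group$n), sum(s$by_group$n))
})
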