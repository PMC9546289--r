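## Study runners: simulate -> preprocess -> modality analysis -> statistics,
## deterministic given a seed, with CSV/JSON result writing.

#' Run a two-group cell-stiffness study on simulated populations
#'
#' Simulates two cell populations with lognormally distributed Young's
#' moduli (defaults: modes 1.88 and 2.72 kPa, sigma 0.5, 50 cells x 10
#' curves per group), preprocesses every curve, fits the Hertz-Sneddon model
#' at 500 nm depth, reads the indentation at 1 nN where reached, and
#' compares the groups (lognormal modes, medians, Mann-Whitney).
#'
#' @param seed Integer seed (controls everything random).
#' @param modes Named numeric vector of length 2: lognormal modes (kPa) per
#'   group; names are the group labels.
#' @param sigma Lognormal shape parameter.
#' @param n_cells,curves_per_cell Population size per group.
#' @param noise_sd Force noise in pN.
#' @param geometry An [indenter_geometry()].
#' @param fit_depth Hertz fit depth in nm.
#' @return An object of class `stiffness_study`: `per_curve` (data.frame),
#'   `comparison_E` (group comparison of E), `comparison_delta` (comparison
#'   of the 1 nN indentation where available), `truth`, `seed`.
#' @export
run_stiffness_study <- function(seed = 1L,
                                modes = c(FLNAQ = 1.88, FLNAR = 2.72),
                                sigma = 0.5, n_cells = 50L,
                                curves_per_cell = 10L, noise_sd = 5,
                                geometry = indenter_geometry(),
                                fit_depth = 500) {
  stopifnot(length(modes) == 2L, !is.null(names(modes)))
  set.seed(seed)
  rows <- list()
  truth <- list()
  for (g in names(modes)) {
    cfg <- indentation_sim_config(modulus_mode = modes[[g]],
                                  modulus_sigma = sigma, n_cells = n_cells,
                                  curves_per_cell = curves_per_cell,
                                  noise_sd = noise_sd, geometry = geometry,
                                  group_label = g)
    pop <- simulate_indentation_population(cfg, seed = NULL)
    truth[[g]] <- cbind(pop$truth, group = g)
    for (cur in pop$curves) {
      pr <- preprocess_curve(cur)
      E <- d1 <- NA_real_
      qc_pass <- pr$qc$passed
      if (qc_pass) {
        fit <- tryCatch(fit_hertz(pr, geometry, fit_depth),
                        afm_shallow_curve = function(e) NULL)
        if (is.null(fit)) {
          qc_pass <- FALSE
        } else {
          E <- fit$E
          d1 <- fit$indentation_at_target
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        curve_id = cur$curve_id, cell_id = cur$cell_id, group = g,
        E_kPa = E, delta_at_1nN_nm = d1,
        true_E_kPa = cur$annotations$true_E_kPa,
        qc = if (qc_pass) "pass" else paste(pr$qc$reasons, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  per_curve <- do.call(rbind, rows)
  ok <- per_curve[per_curve$qc == "pass" & is.finite(per_curve$E_kPa), ]
  labs <- names(modes)
  comparison_E <- compare_groups(
    stats::setNames(split(ok$E_kPa, factor(ok$group, levels = labs)), labs),
    metric_name = "youngs_modulus_kPa")
  del <- ok[is.finite(ok$delta_at_1nN_nm), ]
  comparison_delta <- if (all(table(factor(del$group, levels = labs)) >= 3))
    compare_groups(
      stats::setNames(split(del$delta_at_1nN_nm, factor(del$group, levels = labs)), labs),
      metric_name = "indentation_at_1nN_nm")
  else NULL
  structure(list(per_curve = per_curve, comparison_E = comparison_E,
                 comparison_delta = comparison_delta,
                 truth = do.call(rbind, truth), seed = seed),
            class = "stiffness_study")
}

#' @export
print.stiffness_study <- function(x, ...) {
  cat(sprintf("<stiffness_study> seed %d, %d curves (%d passing QC)\n",
              x$seed, nrow(x$per_curve), sum(x$per_curve$qc == "pass")))
  print(x$comparison_E)
  invisible(x)
}

#' Run a two-group adhesion study on simulated retract curves
#'
#' Simulates two groups of single-cell adhesion curves with lognormally
#' distributed work of adhesion (defaults: medians 2 and 5 fJ, a true 2.5x
#' group ratio), analyzes every retract and compares the groups.
#'
#' @param seed Integer seed.
#' @param medians Named numeric vector of length 2: median work (fJ) per
#'   group.
#' @param sigma Lognormal shape of the per-curve work distribution.
#' @param n_per_group Curves per group.
#' @param noise_sd Force noise in pN.
#' @param profile Adhesion profile, see [adhesion_sim_config()].
#' @return An object of class `adhesion_study`: `per_curve`, `comparison`,
#'   `truth`, `seed`.
#' @export
run_adhesion_study <- function(seed = 1L, medians = c(FLNAQ = 2, FLNAR = 5),
                               sigma = 0.6, n_per_group = 90L, noise_sd = 5,
                               profile = "triangular") {
  stopifnot(length(medians) == 2L, !is.null(names(medians)))
  set.seed(seed)
  rows <- list()
  truth <- list()
  for (g in names(medians)) {
    cfg <- adhesion_sim_config(profile = profile, noise_sd = noise_sd,
                               group_label = g)
    pop <- simulate_adhesion_population(n_per_group, medians[[g]], sigma,
                                        cfg, seed = NULL)
    truth[[g]] <- cbind(pop$truth, group = g)
    for (cur in pop$curves) {
      res <- analyze_adhesion(cur)
      rows[[length(rows) + 1L]] <- data.frame(
        curve_id = cur$curve_id, group = g, work_fJ = res$work_fJ,
        max_adhesion_pN = res$max_adhesion_force,
        rupture_count = res$rupture_count,
        detachment_nm = res$detachment_point,
        true_work_fJ = cur$annotations$true_work_fJ,
        qc = if (res$qc$passed) "pass" else paste(res$qc$reasons, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  per_curve <- do.call(rbind, rows)
  labs <- names(medians)
  comparison <- compare_groups(
    stats::setNames(split(per_curve$work_fJ,
                          factor(per_curve$group, levels = labs)), labs),
    metric_name = "work_of_adhesion_fJ")
  structure(list(per_curve = per_curve, comparison = comparison,
                 truth = do.call(rbind, truth), seed = seed),
            class = "adhesion_study")
}

#' @export
print.adhesion_study <- function(x, ...) {
  cat(sprintf("<adhesion_study> seed %d, %d curves\n", x$seed, nrow(x$per_curve)))
  print(x$comparison)
  invisible(x)
}

#' Run a two-speed unfolding study on simulated sawtooth traces
#'
#' Simulates polyprotein unfolding traces at each pulling speed, analyzes
#' every trace (peak detection, WLC fits, classification, acceptance) and
#' summarizes unfolding forces and contour-length increments per domain
#' label and speed, both for accepted traces only and for all traces.
#'
#' @param seed Integer seed.
#' @param speeds Pulling speeds in nm/s.
#' @param n_traces Traces per speed.
#' @param variant FLNA variant for [default_polyprotein_layout()].
#' @param noise_sd Force noise in pN.
#' @return An object of class `unfolding_study`: `traces` (list of
#'   `trace_result`), `summary_accepted`, `summary_all`, `events_csv`
#'   (pooled per-event table), `seed`.
#' @export
run_unfolding_study <- function(seed = 1L, speeds = c(400, 1600),
                                n_traces = 60L, variant = "Q", noise_sd = 5) {
  set.seed(seed)
  traces <- list()
  for (v in speeds) {
    cfg <- unfolding_sim_config(domain_layout = default_polyprotein_layout(variant),
                                pulling_speed = v, noise_sd = noise_sd)
    for (i in seq_len(n_traces)) {
      cur <- simulate_unfolding_trace(cfg,
                                      curve_id = sprintf("unf_%s_v%04d_%03d", variant, v, i))
      tr <- analyze_unfolding_trace(cur)
      tr$curve_id <- cur$curve_id
      traces[[length(traces) + 1L]] <- tr
    }
  }
  summ_acc <- summarize_unfolding(traces, accepted_only = TRUE)
  summ_all <- summarize_unfolding(traces, accepted_only = FALSE)
  ev <- do.call(rbind, lapply(traces, function(t) {
    if (!nrow(t$events)) return(NULL)
    data.frame(curve_id = t$curve_id, order_index = t$events$order_index,
               label = t$events$label, peak_force_pN = t$events$peak_force,
               Lc_nm = t$events$Lc, dLc_nm = t$events$increment,
               rss = t$events$rss, speed_nm_s = t$pulling_speed,
               accepted = t$accepted, stringsAsFactors = FALSE)
  }))
  structure(list(traces = traces, summary_accepted = summ_acc,
                 summary_all = summ_all, events_csv = ev, seed = seed),
            class = "unfolding_study")
}

#' @export
print.unfolding_study <- function(x, ...) {
  n_acc <- sum(vapply(x$traces, `[[`, logical(1), "accepted"))
  cat(sprintf("<unfolding_study> seed %d, %d traces (%d accepted)\n",
              x$seed, length(x$traces), n_acc))
  if (!is.null(x$summary_accepted$by_group))
    print(x$summary_accepted$by_group, digits = 4)
  invisible(x)
}

#' Write the result bundle of a study to disk
#'
#' Per-curve/per-event CSV tables plus a JSON comparison report and a small
#' run log (seed, package version, curve counts). Output is deterministic
#' for a given study object.
#'
#' @param study A `stiffness_study`, `adhesion_study` or `unfolding_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("afmforce %s", as.character(utils::packageVersion("afmforce"))),
                 sprintf("seed = %d", study$seed),
                 sprintf("class = %s", class(study)[1]))
  if (inherits(study, "stiffness_study")) {
    utils::write.csv(study$per_curve, file.path(dir, "per_curve.csv"),
                     row.names = FALSE)
    comparison_json(study$comparison_E, file.path(dir, "comparison_E.json"))
    if (!is.null(study$comparison_delta))
      comparison_json(study$comparison_delta,
                      file.path(dir, "comparison_delta.json"))
    log_lines <- c(log_lines, sprintf("curves = %d, qc_pass = %d",
                                      nrow(study$per_curve),
                                      sum(study$per_curve$qc == "pass")))
  } else if (inherits(study, "adhesion_study")) {
    utils::write.csv(study$per_curve, file.path(dir, "per_curve.csv"),
                     row.names = FALSE)
    comparison_json(study$comparison, file.path(dir, "comparison_work.json"))
    log_lines <- c(log_lines, sprintf("curves = %d", nrow(study$per_curve)))
  } else if (inherits(study, "unfolding_study")) {
    utils::write.csv(study$events_csv, file.path(dir, "events.csv"),
                     row.names = FALSE)
    if (!is.null(study$summary_accepted$by_group))
      utils::write.csv(study$summary_accepted$by_group,
                       file.path(dir, "summary_accepted.csv"), row.names = FALSE)
    if (!is.null(study$summary_all$by_group))
      utils::write.csv(study$summary_all$by_group,
                       file.path(dir, "summary_all.csv"), row.names = FALSE)
    log_lines <- c(log_lines, sprintf("traces = %d", length(study$traces)))
  } else {
    stop("unknown study class", call. = FALSE)
  }
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
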