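## End-to-end orchestration: simulate (or load) every data type, run each
## analysis stage with the study's thresholds, and collect all counts and
## fractions into one machine-readable summary.

#' Pipeline configuration
#'
#' @param seed master seed; each simulator derives its own stream from it.
#' @param sim a \code{\link{sim_config}} (rebuilt with \code{seed} if omitted).
#' @param alpha_phospho raw p threshold for phosphosite regulation and
#'   dependency calls (default 0.01).
#' @param alpha_interactome p threshold for interactor calls (default 0.05).
#' @param localization_cutoff minimum site localization probability (0.75).
#' @param windows a \code{\link{window_spec}} for the PRR stage.
#' @param out_dir optional directory; when set, per-stage TSVs and
#'   \code{summary.json} are written there.
#' @return validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL,
                            alpha_phospho = 0.01,
                            alpha_interactome = 0.05,
                            localization_cutoff = 0.75,
                            windows = window_spec(),
                            out_dir = NULL) {
  for (a in c(alpha_phospho, alpha_interactome, localization_cutoff))
    if (!is_prob(a) || a <= 0 || a >= 1)
      stopf("thresholds must lie strictly in (0,1); got %s", format(a))
  if (is.null(sim)) sim <- sim_config(seed = seed)
  stopifnot(inherits(sim, "sim_config"), inherits(windows, "window_spec"))
  structure(list(seed = seed, sim = sim, alpha_phospho = alpha_phospho,
                 alpha_interactome = alpha_interactome,
                 localization_cutoff = localization_cutoff,
                 windows = windows, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' Simulates all four data types under the configured seed, then runs:
#' UV-regulation and p38/MK dependency calling; iceLogo motif enrichment of
#' UV-up p38-dependent sites against all quantified sites; 14-3-3 pulldown
#' interactor calling; occupancy recovery; PRR computation, per-gene
#' differential release, the global Wilcoxon, and the NELF-target overlap.
#' The returned summary holds every count/fraction with the thresholds used;
#' with \code{out_dir} set it is also written as \code{summary.json} beside
#' per-stage TSVs.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return list of class \code{"uvphos_summary"}; the per-stage objects are
#'   attached in \code{$stages}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- cfg$sim

  ph <- simulate_phospho_experiment(sim)
  calls <- call_uv_regulation(ph$table, alpha = cfg$alpha_phospho,
                              localization_cutoff = cfg$localization_cutoff)
  calls <- call_dependency(ph$table, calls, "p38i+UV/mock",
                           alpha = cfg$alpha_phospho, level = "p38")
  if (sim$include_mk)
    calls <- call_dependency(ph$table, calls, "MKi+UV/mock",
                             alpha = cfg$alpha_phospho, level = "mk")
  frac <- summarize_fractions(calls)

  fg_sel <- !is.na(calls$uv_direction) & calls$uv_direction == "up" &
    !is.na(calls$dependency) & calls$dependency == "p38_dependent"
  win <- ph$table$features$sequence_window
  logo <- icelogo_enrichment(count_position_frequencies(win[fg_sel]),
                             count_position_frequencies(win))

  pd <- simulate_pulldown(sim)
  inter <- call_interactors(pd$table, "14-3-3/control", "p38i+UV/UV",
                            alpha = cfg$alpha_interactome)
  n_int <- sum(inter$interactor)
  n_dep_int <- sum(inter$p38_dependent)

  oc <- simulate_occupancy(sim)
  occ <- compute_site_occupancy(oc$table)
  occ_err <- mean(abs(occ$occupancy_pct[occ$valid] -
                        oc$truth$occupancy_pct[occ$valid]))

  pc <- simulate_polii_coverage(sim)
  prr <- compute_prr(pc$tracks, pc$genes, cfg$windows,
                     untreated_condition = "mock")
  dprr <- differential_prr(prr, "mock", "UV")
  up_genes <- dprr$gene_id[dprr$call == "up"]
  nelfe <- pc$truth$gene_id[pc$truth$nelfe_bound]
  nelfe_overlap <- if (length(up_genes))
    set_overlap_fraction(up_genes, nelfe) else NA_real_

  get_frac <- function(nm, col) {
    i <- match(nm, frac$name)
    if (is.na(i)) NA_real_ else frac[[col]][i]
  }
  summary <- list(
    parameters = list(seed = cfg$seed, alpha_phospho = cfg$alpha_phospho,
                      alpha_interactome = cfg$alpha_interactome,
                      localization_cutoff = cfg$localization_cutoff,
                      epsilon = cfg$windows$epsilon,
                      n_sites = sim$n_sites, n_genes = sim$n_genes),
    phospho = list(
      n_tested = frac$n[frac$name == "up_of_total"],
      n_up = frac$k[frac$name == "up_of_total"],
      n_down = frac$k[frac$name == "down_of_total"],
      up_pct = get_frac("up_of_total", "pct"),
      down_pct = get_frac("down_of_total", "pct"),
      p38_dep_of_up_pct = get_frac("dep_of_up", "pct"),
      stq_of_up_pct = get_frac("stq_of_up", "pct"),
      mk_dep_of_dep_pct = get_frac("mk_dep_of_dep", "pct")),
    interactome = list(
      n_interactors = n_int, n_p38_dependent = n_dep_int,
      p38_dep_pct = if (n_int) 100 * n_dep_int / n_int else NA_real_),
    occupancy = list(mean_abs_error_pct = occ_err,
                     n_invalid = sum(!occ$valid)),
    prr = list(
      n_eligible = sum(prr$eligible),
      n_up = sum(dprr$call == "up"), n_down = sum(dprr$call == "down"),
      mean_delta_released = mean(dprr$delta_prr[
        dprr$gene_id %in% pc$truth$gene_id[pc$truth$released]]),
      global_wilcoxon_p = attr(dprr, "global_test")$p_value,
      nelfe_overlap_pct = 100 * nelfe_overlap))

  out <- structure(list(summary = summary, fractions = frac,
                        stages = list(calls = calls, logo = logo,
                                      interactors = inter, occupancy = occ,
                                      prr = prr, differential_prr = dprr,
                                      truth = list(phospho = ph$truth,
                                                   pulldown = pd$truth,
                                                   polii = pc$truth,
                                                   occupancy = oc$truth))),
                   class = "uvphos_summary")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(calls, file.path(cfg$out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dprr, file.path(cfg$out_dir, "prr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.uvphos_summary <- function(x, ...) {
  s <- x$summary
  cat("uvphos pipeline summary\n")
  cat(sprintf("  phospho: %d tested, %d up (%.1f%%), %d down; p38-dep %.1f%% of up; S/TQ %.1f%% of up\n",
              s$phospho$n_tested, s$phospho$n_up, s$phospho$up_pct,
              s$phospho$n_down, s$phospho$p38_dep_of_up_pct,
              s$phospho$stq_of_up_pct))
  cat(sprintf("  interactome: %d interactors, %d p38-dependent (%.0f%%)\n",
              s$interactome$n_interactors, s$interactome$n_p38_dependent,
              s$interactome$p38_dep_pct))
  cat(sprintf("  occupancy: mean |error| %.2f points\n",
              s$occupancy$mean_abs_error_pct))
  cat(sprintf("  PRR: %d eligible genes, %d up vs %d down, global Wilcoxon p = %.3g, NELF overlap %.0f%%\n",
              s$prr$n_eligible, s$prr$n_up, s$prr$n_down,
              s$prr$global_wilcoxon_p, s$prr$nelfe_overlap_pct))
  invisible(x)
}
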