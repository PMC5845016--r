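## Seeded synthetic-data generators. Each emulates one experimental design of
## the study — SILAC phosphoproteomics with planted UV/p38/MK strata,
## 14-3-3 pulldown enrichment, paused-polymerase coverage with planted
## release shifts, and phosphatase-reference occupancy — and returns the
## dataset together with a truth table sufficient to score every downstream
## caller. Log2-ratio noise is Normal, coverage noise Poisson; all draws go
## through one Mersenne-Twister stream per call, so a fixed seed gives
## byte-identical output.

#' Simulation configuration
#'
#' Defaults plant the fractions the study reports: ~4\% of sites UV-induced,
#' ~26\% of those p38-dependent, ~60\% of those MK2/3/5-dependent, ~17\% of
#' UV-induced sites S/TQ (ATR-type), and 28\% of pulldown interactors
#' p38-dependent.
#'
#' @param seed integer RNG seed.
#' @param n_sites number of phosphosites.
#' @param frac_uv_up probability a site is UV-upregulated (default 0.04).
#' @param frac_p38_dep_given_up P(p38-dependent | UV-up) (default 0.26).
#' @param frac_mk_dep_given_p38 P(MK-dependent | p38-dependent) (default 0.60).
#' @param frac_stq_given_up P(ATR-type S/TQ site | UV-up) (default 0.17);
#'   drawn from the p38-independent stratum so motif strata stay disjoint.
#' @param effect_log2 mean planted UV effect in log2 units (default 1.5).
#' @param sigma_rep replicate noise SD in log2 units (default 0.35).
#' @param n_replicates replicates per contrast (default 2).
#' @param motif_injection plant LXRQXS/T into MK-dependent windows and S/TQ
#'   into the ATR stratum (default TRUE).
#' @param include_mk also simulate the MKi+UV/mock contrast (default TRUE).
#' @param n_proteins,frac_interactor,frac_p38_dep_given_interactor,effect_pulldown
#'   pulldown simulator: proteins quantified, interactor fraction, dependent
#'   fraction among interactors (default 0.28), mean bait enrichment (log2).
#' @param n_genes,gene_length_range,gene_gap,frac_released,delta_prr_planted,tss_height,body_rate,background_rate,frac_nelfe_of_released,frac_nelfe_of_other
#'   pol II coverage simulator: gene count, length range (bp), intergenic
#'   gap, fraction of genes with planted release, planted PRR shift (log2),
#'   TSS bump amplitude, gene-body and background Poisson rates, and the
#'   NELF-target labelling fractions.
#' @param n_occ_sites,occ_range,occ_cv occupancy simulator: sites, planted
#'   occupancy range, multiplicative noise CV.
#' @return validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 13091L,
                       frac_uv_up = 0.04,
                       frac_p38_dep_given_up = 0.26,
                       frac_mk_dep_given_p38 = 0.60,
                       frac_stq_given_up = 0.17,
                       effect_log2 = 1.5,
                       sigma_rep = 0.35,
                       n_replicates = 2L,
                       motif_injection = TRUE,
                       include_mk = TRUE,
                       n_proteins = 2000L,
                       frac_interactor = 0.19,
                       frac_p38_dep_given_interactor = 0.28,
                       effect_pulldown = 2,
                       n_genes = 300L,
                       gene_length_range = c(1000L, 30000L),
                       gene_gap = 5000L,
                       frac_released = 0.30,
                       delta_prr_planted = 1,
                       tss_height = 30,
                       body_rate = 1,
                       background_rate = 0.05,
                       frac_nelfe_of_released = 0.70,
                       frac_nelfe_of_other = 0.20,
                       n_occ_sites = 500L,
                       occ_range = c(0.1, 0.9),
                       occ_cv = 0.05) {
  cfg <- as.list(environment())
  probs <- c("frac_uv_up", "frac_p38_dep_given_up", "frac_mk_dep_given_p38",
             "frac_stq_given_up", "frac_interactor",
             "frac_p38_dep_given_interactor", "frac_released",
             "frac_nelfe_of_released", "frac_nelfe_of_other")
  for (p in probs) if (!is_prob(cfg[[p]])) stopf("%s must be a probability in [0,1]", p)
  if (!(sigma_rep > 0)) stopf("sigma_rep must be > 0")
  if (n_replicates < 2L) stopf("n_replicates must be >= 2")
  if (occ_cv < 0) stopf("occ_cv must be >= 0")
  structure(cfg, class = "sim_config")
}

## Random window with given center residue; other positions uniform over the
## 20 amino acids. half = flank on each side.
random_windows <- function(n, half = 15L) {
  ctr <- sample(c("S", "T", "Y"), n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  mat <- matrix(sample(AA20, n * (2L * half + 1L), replace = TRUE),
                nrow = n)
  mat[, half + 1L] <- ctr
  list(windows = apply(mat, 1L, paste, collapse = ""), center = ctr, mat = mat)
}

inject_at <- function(mat, rows, offsets, residues, half = 15L) {
  for (j in seq_along(offsets))
    mat[rows, half + 1L + offsets[j]] <- residues[j]
  mat
}

#' Simulate a SILAC phosphoproteomics experiment
#'
#' Plants the hierarchical strata of the UV/p38/MK design into a
#' \code{\link{silac_site_table}}: UV/mock log2 ratios are
#' Normal(effect * uv_up, sigma) per replicate; the inhibitor contrasts
#' carry the same effect except for sites dependent on the inhibited kinase,
#' whose effect is removed. MK-dependent windows receive the LXRQXS/T
#' consensus and ATR-type windows S/TQ when motif injection is on.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{table} (\code{silac_site_table}) and \code{truth}
#'   (data.frame: \code{site_id}, \code{uv_up}, \code{p38_dep},
#'   \code{mk_dep}, \code{atr_substrate}, \code{effect}).
#' @export
simulate_phospho_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_sites
    uv_up <- stats::runif(n) < cfg$frac_uv_up
    p38_dep <- uv_up & stats::runif(n) < cfg$frac_p38_dep_given_up
    mk_dep <- p38_dep & stats::runif(n) < cfg$frac_mk_dep_given_p38
    # ATR-type S/TQ stratum: disjoint from the p38-dependent stratum
    atr <- uv_up & !p38_dep &
      stats::runif(n) < (cfg$frac_stq_given_up / max(1 - cfg$frac_p38_dep_given_up, 1e-9))
    effect <- ifelse(uv_up, cfg$effect_log2, 0)

    half <- 15L
    rw <- random_windows(n, half)
    mat <- rw$mat
    if (cfg$motif_injection) {
      if (any(mk_dep)) {
        mat[mk_dep, half + 1L] <- sample(c("S", "T"), sum(mk_dep),
                                         replace = TRUE, prob = c(0.8, 0.2))
        mat <- inject_at(mat, mk_dep, c(-5L, -3L, -2L), c("L", "R", "Q"), half)
      }
      if (any(atr)) {
        mat[atr, half + 1L] <- sample(c("S", "T"), sum(atr),
                                      replace = TRUE, prob = c(0.8, 0.2))
        mat <- inject_at(mat, atr, 1L, "Q", half)
      }
    }
    windows <- apply(mat, 1L, paste, collapse = "")
    residue <- substr(windows, half + 1L, half + 1L)

    conds <- c("UV/mock", "p38i+UV/mock", if (cfg$include_mk) "MKi+UV/mock")
    design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                          condition = conds, stringsAsFactors = FALSE)
    design$column <- sprintf("ratio.%s.r%d", design$condition, design$replicate)
    design <- design[, c("column", "condition", "replicate")]
    mu <- cbind("UV/mock" = effect,
                "p38i+UV/mock" = ifelse(p38_dep, 0, effect),
                "MKi+UV/mock" = ifelse(mk_dep, 0, effect))
    ratios <- sapply(seq_len(nrow(design)), function(j)
      stats::rnorm(n, mean = mu[, design$condition[j]], sd = cfg$sigma_rep))
    colnames(ratios) <- design$column

    sites <- data.frame(site_id = sprintf("site%05d", seq_len(n)),
                        protein_id = sprintf("P%05d", 1L + (seq_len(n) - 1L) %/% 3L),
                        gene_name = sprintf("GENE%05d", 1L + (seq_len(n) - 1L) %/% 3L),
                        position = sample(10:800, n, replace = TRUE),
                        residue = residue,
                        localization_prob = 1 - stats::runif(n, 0, 0.2),
                        sequence_window = windows,
                        stringsAsFactors = FALSE)
    truth <- data.frame(site_id = sites$site_id, uv_up = uv_up,
                        p38_dep = p38_dep, mk_dep = mk_dep,
                        atr_substrate = atr, effect = effect,
                        stringsAsFactors = FALSE)
    list(table = silac_site_table(sites, ratios, design), truth = truth)
  })
}

#' Simulate a 14-3-3 pulldown experiment
#'
#' Protein-level log2 enrichment: interactors get bait-vs-control ratios
#' Normal(effect, sigma), non-interactors Normal(0, sigma); p38-dependent
#' interactors additionally lose binding in the inhibitor-vs-UV contrast
#' (mean \code{-0.75 * effect}).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{table} (\code{\link{pulldown_table}}) and
#'   \code{truth} (\code{protein_id}, \code{interactor}, \code{p38_dep}).
#' @export
simulate_pulldown <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 101L, {
    n <- cfg$n_proteins
    interactor <- stats::runif(n) < cfg$frac_interactor
    p38_dep <- interactor & stats::runif(n) < cfg$frac_p38_dep_given_interactor
    conds <- c("14-3-3/control", "p38i+UV/UV")
    design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                          condition = conds, stringsAsFactors = FALSE)
    design$column <- sprintf("ratio.%s.r%d", design$condition, design$replicate)
    design <- design[, c("column", "condition", "replicate")]
    mu <- cbind("14-3-3/control" = ifelse(interactor, cfg$effect_pulldown, 0),
                "p38i+UV/UV" = ifelse(p38_dep, -0.75 * cfg$effect_pulldown, 0))
    ratios <- sapply(seq_len(nrow(design)), function(j)
      stats::rnorm(n, mean = mu[, design$condition[j]], sd = cfg$sigma_rep))
    colnames(ratios) <- design$column
    proteins <- data.frame(protein_id = sprintf("P%05d", seq_len(n)),
                           gene_name = sprintf("GENE%05d", seq_len(n)),
                           stringsAsFactors = FALSE)
    truth <- data.frame(protein_id = proteins$protein_id,
                        interactor = interactor, p38_dep = p38_dep,
                        stringsAsFactors = FALSE)
    list(table = pulldown_table(proteins, ratios, design), truth = truth)
  })
}

#' Simulate paused-polymerase coverage with planted release
#'
#' Genes are placed non-overlapping on one synthetic chromosome, strands
#' alternating. Per track, the Poisson rate is a low uniform background plus,
#' per gene, a Gaussian TSS-proximal bump and a uniform gene-body rate; in
#' the UV condition the gene body beyond +1000 bp is multiplied by
#' \code{2^delta_prr} for the released subset, so the planted PRR shift is
#' exact up to the pseudocount. Genes at or below the length filter are
#' flagged PRR-ineligible in the truth table. NELF-target labels cover
#' \code{frac_nelfe_of_released} of released genes and
#' \code{frac_nelfe_of_other} of the rest.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{genes} (gene-model data.frame), \code{tracks}
#'   (list of \code{\link{coverage_track}}: mock/UV x replicates) and
#'   \code{truth} (\code{gene_id}, \code{released}, \code{delta_prr},
#'   \code{length_eligible}, \code{nelfe_bound}).
#' @export
simulate_polii_coverage <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 202L, {
    n <- cfg$n_genes
    len <- round(stats::runif(n, cfg$gene_length_range[1], cfg$gene_length_range[2]))
    gap <- cfg$gene_gap
    start <- cumsum(c(gap, utils::head(len, -1) + gap))
    end <- start + len
    chromlen <- end[n] + gap
    if (chromlen > 5e8) stopf("synthetic chromosome too large; reduce n_genes")
    strand <- rep(c("+", "-"), length.out = n)
    genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                        chrom = "chrS", strand = strand,
                        start = start, end = end,
                        tss = ifelse(strand == "+", start, end - 1L),
                        tes = ifelse(strand == "+", end, start - 1L),
                        length = len, stringsAsFactors = FALSE)
    released <- stats::runif(n) < cfg$frac_released
    delta <- ifelse(released, cfg$delta_prr_planted, 0)
    nelfe <- ifelse(released, stats::runif(n) < cfg$frac_nelfe_of_released,
                    stats::runif(n) < cfg$frac_nelfe_of_other)

    base_lambda <- function(uv) {
      lam <- rep(cfg$background_rate, chromlen)
      for (i in seq_len(n)) {
        d <- seq.int(-500L, len[i] - 1L)          # transcription-direction offsets
        bump <- cfg$tss_height * exp(-(d - 100)^2 / (2 * 250^2))
        body <- ifelse(d >= 0, cfg$body_rate, 0)
        if (uv && released[i])
          body <- ifelse(d >= 1000, body * 2^cfg$delta_prr_planted, body)
        gpos <- if (strand[i] == "+") genes$tss[i] + d else genes$tss[i] - d
        inb <- gpos >= 0 & gpos < chromlen
        lam[gpos[inb] + 1L] <- lam[gpos[inb] + 1L] + (bump + body)[inb]
      }
      lam
    }
    lam_mock <- base_lambda(FALSE)
    lam_uv <- base_lambda(TRUE)
    tracks <- list()
    for (r in seq_len(cfg$n_replicates)) {
      tracks[[length(tracks) + 1L]] <-
        coverage_track(list(chrS = as.numeric(stats::rpois(chromlen, lam_mock))),
                       "mock", r)
      tracks[[length(tracks) + 1L]] <-
        coverage_track(list(chrS = as.numeric(stats::rpois(chromlen, lam_uv))), "UV", r)
    }
    truth <- data.frame(gene_id = genes$gene_id, released = released,
                        delta_prr = delta,
                        length_eligible = len > 3000,
                        nelfe_bound = nelfe, stringsAsFactors = FALSE)
    list(genes = genes, tracks = tracks, truth = truth)
  })
}

#' Simulate a phosphatase-reference occupancy experiment
#'
#' For each site and condition a true occupancy o is drawn uniformly from
#' \code{occ_range}; the observed unmodified-peptide ratio is
#' \code{1/(1-o)} with multiplicative log-normal noise of the configured CV.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{table} (data.frame \code{site_id},
#'   \code{condition}, \code{ratio}) and \code{truth} (planted
#'   \code{occupancy_pct} per row).
#' @export
simulate_occupancy <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 303L, {
    n <- cfg$n_occ_sites
    tab <- expand.grid(site_id = sprintf("occ%04d", seq_len(n)),
                       condition = c("mock", "UV"),
                       stringsAsFactors = FALSE)
    o <- stats::runif(nrow(tab), cfg$occ_range[1], cfg$occ_range[2])
    sdlog <- sqrt(log(1 + cfg$occ_cv^2))
    noise <- if (cfg$occ_cv > 0)
      exp(stats::rnorm(nrow(tab), -sdlog^2 / 2, sdlog)) else 1
    tab$ratio <- noise / (1 - o)
    truth <- data.frame(site_id = tab$site_id, condition = tab$condition,
                        occupancy_pct = 100 * o, stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}
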