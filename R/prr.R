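## RNA polymerase II promoter-release analysis from coverage tracks.
##
## The polymerase release ratio (PRR) of a gene is the log2 ratio of the
## normalized pol II signal in an early gene-body window over the signal in
## the TSS window, both expressed in transcription direction:
##   TSS window        [-300, +1000) bp around the TSS
##   downstream window [+1000, +3000) bp (2 kb)
##   PRR = log2((e_down + eps) / (e_tss + eps))
## Only genes longer than 3 kb whose untreated TSS signal passes a minimum
## RPKM are eligible. Higher PRR = more paused polymerase released into
## elongation.

#' Window and filter specification for the PRR analysis
#'
#' @param tss_window TSS window relative to the TSS, half-open, in
#'   transcription direction (default \code{c(-300, 1000)}).
#' @param downstream_window early gene-body window (default
#'   \code{c(1000, 3000)}).
#' @param min_gene_length genes must be strictly longer than this (default
#'   3000 bp).
#' @param tss_min_signal minimum untreated TSS-window signal, RPKM units
#'   (default 1).
#' @param epsilon pseudocount added to both window signals before the log2
#'   ratio (default 0.1 RPKM), keeping silent windows finite.
#' @return list of class \code{"window_spec"}.
#' @export
window_spec <- function(tss_window = c(-300, 1000),
                        downstream_window = c(1000, 3000),
                        min_gene_length = 3000,
                        tss_min_signal = 1,
                        epsilon = 0.1) {
  stopifnot(tss_window[2] > tss_window[1],
            downstream_window[2] > downstream_window[1],
            epsilon > 0)
  structure(list(tss_window = tss_window,
                 downstream_window = downstream_window,
                 min_gene_length = min_gene_length,
                 tss_min_signal = tss_min_signal,
                 epsilon = epsilon),
            class = "window_spec")
}

#' Mean normalized signal of a track over a TSS-relative window
#'
#' The window \code{[w1, w2)} is expressed relative to the TSS with positive
#' offsets in transcription direction; it is projected onto genomic
#' coordinates (mirrored for minus-strand genes), truncated at chromosome
#' ends with a warning, and the coverage mass is converted to RPKM-scale
#' units: \code{sum * 1e9 / (width * library_size)}.
#'
#' @param track a \code{\link{coverage_track}}.
#' @param gene one row of a gene-model data.frame
#'   (\code{\link{read_gene_models}}).
#' @param window numeric length-2 half-open interval relative to the TSS.
#' @return RPKM-scale signal, or \code{NA} if the window is entirely off the
#'   chromosome.
#' @export
compute_window_signal <- function(track, gene, window) {
  cov <- track$cov[[gene$chrom]]
  if (is.null(cov)) return(NA_real_)
  if (gene$strand == "+") {
    g1 <- gene$tss + window[1]; g2 <- gene$tss + window[2]
  } else {
    g1 <- gene$tss - window[2] + 1; g2 <- gene$tss - window[1] + 1
  }
  lo <- max(g1, 0); hi <- min(g2, length(cov))
  if (hi <= lo) {
    warnf("window [%d,%d) for gene %s lies off chromosome %s",
          g1, g2, gene$gene_id, gene$chrom)
    return(NA_real_)
  }
  if (lo > g1 || hi < g2)
    warnf("window truncated at chromosome end for gene %s", gene$gene_id)
  width <- hi - lo
  sum(cov[(lo + 1):hi]) * 1e9 / (width * track$library_size)
}

#' Per-gene polymerase release ratios across conditions
#'
#' Computes the PRR per gene per track (condition x replicate), then averages
#' replicate PRRs within each condition. Eligibility requires gene length
#' strictly above \code{spec$min_gene_length} and mean untreated TSS signal
#' at or above \code{spec$tss_min_signal}.
#'
#' @param tracks list of \code{\link{coverage_track}} objects covering all
#'   conditions and replicates.
#' @param genes gene-model data.frame.
#' @param spec a \code{\link{window_spec}}.
#' @param untreated_condition condition used for the TSS-signal filter
#'   (default the first track's condition).
#' @return list of class \code{"prr_table"}: \code{per_rep} (long data.frame
#'   gene x condition x replicate with \code{e_tss}, \code{e_down},
#'   \code{prr}), \code{summary} (gene x condition mean PRR, wide),
#'   \code{eligible} (named logical), \code{genes}, \code{spec}.
#' @export
compute_prr <- function(tracks, genes, spec = window_spec(),
                        untreated_condition = tracks[[1]]$condition) {
  per <- do.call(rbind, lapply(tracks, function(tr) {
    e_tss <- numeric(nrow(genes)); e_down <- numeric(nrow(genes))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      e_tss[i] <- compute_window_signal(tr, g, spec$tss_window)
      e_down[i] <- compute_window_signal(tr, g, spec$downstream_window)
    }
    data.frame(gene_id = genes$gene_id, condition = tr$condition,
               replicate = tr$replicate, e_tss = e_tss, e_down = e_down,
               prr = log2((e_down + spec$epsilon) / (e_tss + spec$epsilon)),
               stringsAsFactors = FALSE)
  }))
  tss_ref <- per[per$condition == untreated_condition, ]
  mean_tss <- tapply(tss_ref$e_tss, tss_ref$gene_id, mean, na.rm = TRUE)
  eligible <- genes$length > spec$min_gene_length &
    !is.na(mean_tss[genes$gene_id]) &
    mean_tss[genes$gene_id] >= spec$tss_min_signal
  eligible <- stats::setNames(as.logical(eligible), genes$gene_id)
  if (!any(eligible)) stopf("no gene passes the PRR eligibility filters")
  keep <- per[eligible[per$gene_id], ]
  agg <- stats::aggregate(prr ~ gene_id + condition, keep, mean)
  summary <- stats::reshape(agg, idvar = "gene_id", timevar = "condition",
                            direction = "wide")
  names(summary) <- sub("^prr\\.", "", names(summary))
  structure(list(per_rep = per, summary = summary, eligible = eligible,
                 genes = genes, spec = spec),
            class = "prr_table")
}

#' @export
print.prr_table <- function(x, ...) {
  cat(sprintf("<prr_table> %d genes (%d eligible), conditions: %s\n",
              nrow(x$genes), sum(x$eligible),
              paste(unique(x$per_rep$condition), collapse = ", ")))
  invisible(x)
}

#' Differential polymerase release between two conditions
#'
#' Per eligible gene, the replicate-paired difference of PRRs
#' (\code{uv - mock}, replicate-matched) is tested over genes with the
#' moderated t (BH-adjusted); a gene is called \code{up}/\code{down} at
#' \code{q < alpha} with the matching sign. Alongside, the global mock-vs-UV
#' Wilcoxon rank-sum test (with continuity correction) compares the per-gene
#' mean PRR distributions.
#'
#' @param prr a \code{\link{compute_prr}} result.
#' @param cond_mock,cond_uv condition labels.
#' @param alpha BH q threshold for per-gene calls (default 0.05).
#' @return data.frame per eligible gene: \code{delta_prr}, \code{t_mod},
#'   \code{p}, \code{q}, \code{call}; the global test is attached as
#'   attribute \code{"global_test"}.
#' @export
differential_prr <- function(prr, cond_mock, cond_uv, alpha = 0.05) {
  per <- prr$per_rep[prr$eligible[prr$per_rep$gene_id], ]
  pm <- per[per$condition == cond_mock, ]
  pu <- per[per$condition == cond_uv, ]
  reps <- sort(unique(pm$replicate))
  if (!identical(reps, sort(unique(pu$replicate))))
    stopf("replicate structure differs between '%s' and '%s'", cond_mock, cond_uv)
  ids <- unique(pm$gene_id)
  dm <- sapply(reps, function(r) {
    m <- pm$prr[pm$replicate == r][match(ids, pm$gene_id[pm$replicate == r])]
    u <- pu$prr[pu$replicate == r][match(ids, pu$gene_id[pu$replicate == r])]
    u - m
  })
  dm <- matrix(dm, nrow = length(ids),
               dimnames = list(ids, paste0("r", reps)))
  fit <- fit_ebayes(dm)
  q <- rep(NA_real_, length(ids))
  ok <- !is.na(fit$p_two)
  q[ok] <- bh_adjust(fit$p_two[ok])
  call <- rep("ns", length(ids))
  call[!is.na(q) & q < alpha & fit$mean_log2 > 0] <- "up"
  call[!is.na(q) & q < alpha & fit$mean_log2 < 0] <- "down"
  mean_mock <- tapply(pm$prr, pm$gene_id, mean)[ids]
  mean_uv <- tapply(pu$prr, pu$gene_id, mean)[ids]
  glob <- wilcoxon_rank_sum(as.numeric(mean_mock), as.numeric(mean_uv),
                            continuity = TRUE)
  out <- data.frame(gene_id = ids, prr_mock = as.numeric(mean_mock),
                    prr_uv = as.numeric(mean_uv),
                    delta_prr = fit$mean_log2, t_mod = fit$t_mod,
                    p = fit$p_two, q = q, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "global_test") <- glob
  out
}

#' Strand-oriented metagene profile around TSSs
#'
#' Average normalized coverage as a function of signed distance to the TSS
#' (negative = upstream in transcription direction), binned, averaged over
#' genes and then over tracks. Positions falling off a chromosome are
#' dropped from the average.
#'
#' @param tracks a \code{\link{coverage_track}} or list of tracks (averaged,
#'   e.g. replicates of one condition).
#' @param genes gene-model data.frame.
#' @param span half-width in bp around the TSS (default 2000).
#' @param bins number of bins (default 100; must divide \code{2*span}
#'   evenly for equal bins).
#' @return data.frame with bin \code{center} (bp, relative to TSS) and
#'   \code{signal} (mean per-base RPKM-scale coverage).
#' @export
metagene_profile <- function(tracks, genes, span = 2000L, bins = 100L) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  offsets <- seq.int(-span, span - 1L)
  acc <- matrix(0, nrow = length(tracks), ncol = length(offsets))
  cnt <- matrix(0, nrow = length(tracks), ncol = length(offsets))
  for (ti in seq_along(tracks)) {
    tr <- tracks[[ti]]
    scale <- 1e9 / tr$library_size
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      cov <- tr$cov[[g$chrom]]
      if (is.null(cov)) next
      gpos <- if (g$strand == "+") g$tss + offsets else g$tss - offsets
      inb <- gpos >= 0 & gpos < length(cov)
      acc[ti, inb] <- acc[ti, inb] + cov[gpos[inb] + 1L] * scale
      cnt[ti, inb] <- cnt[ti, inb] + 1
    }
  }
  per_track <- acc / pmax(cnt, 1)
  sig <- colMeans(per_track)
  bin <- cut(offsets, breaks = seq.int(-span, span, length.out = bins + 1L),
             include.lowest = TRUE, right = FALSE, labels = FALSE)
  data.frame(center = tapply(offsets + 0.5, bin, mean),
             signal = tapply(sig, bin, mean))
}
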