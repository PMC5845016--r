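## Pulldown interactome calling and flat gene-set over-representation
## testing (hypergeometric tail / one-sided Fisher, BH-corrected), plus
## simple set-overlap summaries.

#' Call pulldown interactors and their kinase dependency
#'
#' A protein is an interactor if its bait-vs-control enrichment is
#' significant by the moderated one-sample t-test (\code{p < alpha}, positive
#' mean). If an inhibitor contrast is given, an interactor is additionally
#' p38-dependent when that contrast is significantly negative (one-sided
#' moderated t at the same \code{alpha}), i.e. binding is lost under kinase
#' inhibition.
#'
#' @param x a \code{\link{pulldown_table}}.
#' @param bait_contrast condition label of the bait-vs-control ratios.
#' @param inhibitor_contrast optional label of the inhibitor-vs-UV ratios.
#' @param alpha p threshold (default 0.05).
#' @return data.frame per protein: \code{interactor}, \code{p_bait},
#'   \code{mean_bait}, and if tested \code{p38_dependent}, \code{p_inhibitor}.
#' @export
call_interactors <- function(x, bait_contrast = "14-3-3/control",
                             inhibitor_contrast = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "pulldown_table"))
  bait <- moderated_one_sample_test(x, bait_contrast)
  out <- data.frame(protein_id = bait$protein_id,
                    gene_name = x$features$gene_name,
                    mean_bait = bait$mean_log2, p_bait = bait$p,
                    interactor = !is.na(bait$p) & bait$p < alpha & bait$mean_log2 > 0,
                    stringsAsFactors = FALSE)
  if (!is.null(inhibitor_contrast)) {
    inh <- moderated_one_sample_test(x, inhibitor_contrast, alternative = "less")
    out$p_inhibitor <- inh$p
    out$p38_dependent <- out$interactor & !is.na(inh$p) & inh$p < alpha
  }
  out
}

#' Gene-set over-representation test
#'
#' One-sided enrichment of a query gene set against a universe, per set of a
#' collection, using the hypergeometric upper tail
#' \code{P(X >= k)} with \code{k} = overlap, \code{K} = set size in universe,
#' \code{n} = query size, \code{N} = universe size — identical to one-sided
#' Fisher's exact test, both exposed for transparency. BH correction across
#' retained sets.
#'
#' @param query character vector of gene identifiers (must be a subset of
#'   \code{universe}).
#' @param universe character vector of background gene identifiers.
#' @param sets a \code{\link{read_gmt}} collection or named list of character
#'   vectors.
#' @param test \code{"hypergeom"} or \code{"fisher"}.
#' @param min_size,max_size retain only sets whose universe-restricted size
#'   is within \code{[min_size, max_size]} (defaults 3 and 1000).
#' @return data.frame per retained set: \code{set}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{q}.
#' @export
gene_set_enrichment <- function(query, universe, sets,
                                test = c("hypergeom", "fisher"),
                                min_size = 3L, max_size = 1000L) {
  test <- match.arg(test)
  query <- unique(toupper(query))
  universe <- unique(toupper(universe))
  bad <- setdiff(query, universe)
  if (length(bad))
    stopf("query gene(s) not in universe: %s%s",
          paste(utils::head(bad, 5), collapse = ", "),
          if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5L) else "")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(toupper(sets[[nm]])), universe)
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(members, query))
    p <- if (test == "hypergeom") {
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    } else {
      tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), nrow = 2L)
      stats::fisher.test(tab, alternative = "greater")$p.value
    }
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stopf("no gene set passed the size filter")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Fraction of set a covered by set b
#'
#' \code{|a intersect b| / |a|}, after uppercasing and deduplication.
#'
#' @param a,b character vectors of gene identifiers.
#' @return a probability.
#' @export
set_overlap_fraction <- function(a, b) {
  a <- unique(toupper(a)); b <- unique(toupper(b))
  if (!length(a)) stopf("empty reference set")
  length(intersect(a, b)) / length(a)
}
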