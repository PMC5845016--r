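## Hierarchical dependency calling on SILAC phosphosite tables:
## UV-regulation (up/down/ns at p < alpha, moderated t), then p38-dependence
## among UV-up sites, then MK2/3/5-dependence among p38-dependent sites.

#' Call UV-regulated phosphorylation sites
#'
#' Sites passing the localization-probability filter are tested with the
#' moderated one-sample t-test on the UV/mock contrast; a site is called
#' \code{up} if \code{p < alpha} with positive mean log2 ratio, \code{down}
#' if negative, \code{ns} otherwise. An optional absolute fold-change
#' threshold can be added on top of the p-value rule.
#'
#' @param x a \code{\link{silac_site_table}}.
#' @param contrast UV contrast label (default \code{"UV/mock"}).
#' @param alpha raw p-value threshold (default 0.01).
#' @param localization_cutoff minimum localization probability (default
#'   0.75); sites below it are excluded from testing.
#' @param fc_cutoff minimum \code{|mean log2|} required for a call (default
#'   0, i.e. p-value only).
#' @return data.frame of class \code{"regulation_calls"}: per site
#'   \code{uv_direction} in \{up, down, ns\} (\code{NA} if untested),
#'   \code{p_uv}, \code{q_uv}, \code{mean_uv}, \code{is_stq}, plus
#'   \code{dependency}/\code{mk_dependency} columns initialized to
#'   \code{"na"}.
#' @export
call_uv_regulation <- function(x, contrast = "UV/mock", alpha = 0.01,
                               localization_cutoff = 0.75, fc_cutoff = 0) {
  stopifnot(inherits(x, "silac_site_table"))
  if (!is_prob(alpha) || alpha <= 0) stopf("alpha must lie in (0,1)")
  res <- moderated_one_sample_test(x, contrast)
  tested <- !is.na(res$p) &
    (!is.na(x$features$localization_prob) &
       x$features$localization_prob >= localization_cutoff)
  dir <- rep(NA_character_, nrow(res))
  dir[tested] <- "ns"
  sig <- tested & !is.na(res$p) & res$p < alpha & abs(res$mean_log2) >= fc_cutoff
  dir[sig & res$mean_log2 > 0] <- "up"
  dir[sig & res$mean_log2 < 0] <- "down"
  calls <- data.frame(site_id = res$site_id,
                      uv_direction = dir,
                      p_uv = res$p, q_uv = res$q, mean_uv = res$mean_log2,
                      n_obs_uv = res$n_obs,
                      is_stq = flag_stq(x),
                      dependency = "na",
                      mk_dependency = "na",
                      stringsAsFactors = FALSE)
  calls$dependency[is.na(dir)] <- NA_character_
  calls$mk_dependency[is.na(dir)] <- NA_character_
  structure(calls, class = c("regulation_calls", "data.frame"),
            contrast_uv = contrast, alpha = alpha,
            localization_cutoff = localization_cutoff)
}

#' Call kinase dependency of UV-induced phosphorylation
#'
#' Among previously called sites, a site is inhibitor-dependent if its
#' phosphorylation significantly decreases under kinase inhibition: the
#' per-replicate difference of log2 ratios, inhibitor contrast minus UV
#' contrast (H/L - M/L = log2 H/M), is tested one-sided negative with the
#' moderated t at \code{alpha}. With \code{level = "p38"} the test scope is
#' UV-up sites and fills \code{dependency}; with \code{level = "mk"} the
#' scope is p38-dependent sites and fills \code{mk_dependency}. Variance
#' moderation uses all sites with complete difference replicates, not just
#' the scoped ones.
#'
#' @param x a \code{\link{silac_site_table}} containing both contrasts.
#' @param calls a \code{"regulation_calls"} object from
#'   \code{\link{call_uv_regulation}}.
#' @param inhibitor_contrast e.g. \code{"p38i+UV/mock"} or
#'   \code{"MKi+UV/mock"}.
#' @param uv_contrast the reference UV contrast (default from \code{calls}).
#' @param alpha one-sided p threshold (default 0.01).
#' @param level \code{"p38"} or \code{"mk"}.
#' @return the updated \code{"regulation_calls"} with
#'   \code{p_<level>} and the dependency label filled for scoped sites
#'   (\code{*_dependent} / \code{*_independent}), \code{"na"} elsewhere.
#' @export
call_dependency <- function(x, calls, inhibitor_contrast,
                            uv_contrast = attr(calls, "contrast_uv"),
                            alpha = 0.01, level = c("p38", "mk")) {
  level <- match.arg(level)
  stopifnot(inherits(calls, "regulation_calls"))
  m_uv <- ratio_matrix(x, uv_contrast)
  m_in <- ratio_matrix(x, inhibitor_contrast)
  if (!identical(dim(m_uv), dim(m_in)))
    stopf("contrasts '%s' and '%s' have different replicate structure",
          uv_contrast, inhibitor_contrast)
  d <- m_in - m_uv  # per-replicate log2 (inhibitor+UV / UV)
  fit <- fit_ebayes(d)
  p_one <- stats::pt(fit$t_mod, df = fit$df_total)  # H_1: decrease
  scope <- if (level == "p38") {
    !is.na(calls$uv_direction) & calls$uv_direction == "up"
  } else {
    !is.na(calls$dependency) & calls$dependency == "p38_dependent"
  }
  dep_col <- if (level == "p38") "dependency" else "mk_dependency"
  lab <- rep("na", nrow(calls))
  lab[is.na(calls$uv_direction)] <- NA_character_
  dep <- scope & !is.na(p_one) & p_one < alpha
  lab[scope] <- ifelse(dep[scope], paste0(level, "_dependent"),
                       paste0(level, "_independent"))
  lab[scope & is.na(p_one)] <- "na"
  calls[[dep_col]] <- lab
  calls[[paste0("p_", level)]] <- p_one
  calls[[paste0("mean_", level)]] <- fit$mean_log2
  attr(calls, paste0("contrast_", level)) <- inhibitor_contrast
  calls
}

#' Flag S/TQ (ATM/ATR/DNA-PKcs consensus) sites
#'
#' TRUE iff the window center is S or T and the +1 residue is Q.
#'
#' @param x a \code{silac_site_table} or a character vector of odd-length
#'   sequence windows.
#' @return logical vector.
#' @export
flag_stq <- function(x) {
  w <- if (inherits(x, "silac_site_table")) x$features$sequence_window else x
  nc <- nchar(w)
  ctr <- (nc + 1L) %/% 2L
  substr(w, ctr, ctr) %in% c("S", "T") & substr(w, ctr + 1L, ctr + 1L) == "Q"
}

#' Summarize regulation-call counts and fractions
#'
#' Accepts either a \code{"regulation_calls"} object or a named list of raw
#' counts (\code{total}, \code{up}, \code{down}, and optionally \code{dep},
#' \code{mk_dep}, \code{stq_up}). Each fraction is reported with all three
#' percentage display forms (see \code{\link{percent_forms}}).
#'
#' @param x calls object or named count list.
#' @return data.frame with one row per summary fraction: \code{name},
#'   \code{k}, \code{n}, \code{pct}, \code{pct_trunc1}, \code{pct_round1},
#'   \code{pct_int}.
#' @export
summarize_fractions <- function(x) {
  if (inherits(x, "regulation_calls")) {
    tested <- !is.na(x$uv_direction)
    up <- tested & x$uv_direction == "up"
    counts <- list(
      total = sum(tested),
      up = sum(up),
      down = sum(tested & x$uv_direction == "down"),
      dep = sum(up & !is.na(x$dependency) & x$dependency == "p38_dependent"),
      stq_up = sum(up & x$is_stq),
      mk_dep = sum(!is.na(x$mk_dependency) & x$mk_dependency == "mk_dependent"))
  } else counts <- x
  rows <- list(
    c("up_of_total", "up", "total"),
    c("down_of_total", "down", "total"),
    c("dep_of_up", "dep", "up"),
    c("stq_of_up", "stq_up", "up"),
    c("mk_dep_of_dep", "mk_dep", "dep"),
    c("interactor_dep", "dep_interactors", "interactors"))
  out <- do.call(rbind, lapply(rows, function(r) {
    k <- counts[[r[2L]]]; n <- counts[[r[3L]]]
    if (is.null(k) || is.null(n) || !length(k) || !length(n) || n == 0) return(NULL)
    pf <- percent_forms(k, n)
    data.frame(name = r[1L], k = k, n = n, pct = pf$pct,
               pct_trunc1 = pf$trunc1, pct_round1 = pf$round1,
               pct_int = pf$int, stringsAsFactors = FALSE)
  }))
  out
}
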