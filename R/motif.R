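## Position-specific sequence analysis around phosphorylation sites:
## position x residue count matrices, iceLogo-style enrichment of a
## foreground window set against a background set, fixed-consensus motif
## matchers, and a rule-based 14-3-3 binding-motif scorer.

#' Count per-position residue frequencies in phosphosite windows
#'
#' Builds the 20-residue x position count matrix over a frame of
#' \code{2*flank + 1} positions centered on the phosphoacceptor. Terminal
#' padding (\code{_}) is tallied separately and never counted as a residue.
#'
#' @param windows character vector of odd-length amino-acid windows with the
#'   phosphorylated residue at the center.
#' @param flank number of flanking positions on each side (default 6).
#' @return object of class \code{"motif_counts"}: \code{counts} (20 x
#'   positions matrix, positions labelled \code{-flank..+flank}),
#'   \code{padding} (per-position padding counts), \code{n_windows}.
#' @export
count_position_frequencies <- function(windows, flank = 6L) {
  nc <- nchar(windows)
  if (any(nc %% 2L == 0L))
    stopf("windows must have odd length; offending index %d", which(nc %% 2L == 0L)[1L])
  if (any(nc < 2L * flank + 1L))
    stopf("window shorter than the %d-position frame", 2L * flank + 1L)
  pos <- seq.int(-flank, flank)
  counts <- matrix(0L, nrow = length(AA20), ncol = length(pos),
                   dimnames = list(AA20, as.character(pos)))
  padding <- stats::setNames(integer(length(pos)), as.character(pos))
  ctr <- (nc + 1L) %/% 2L
  for (j in seq_along(pos)) {
    ch <- substr(windows, ctr + pos[j], ctr + pos[j])
    tab <- table(factor(ch, levels = c(AA20, "_")))
    counts[, j] <- tab[AA20]
    padding[j] <- tab["_"]
  }
  structure(list(counts = counts, padding = padding,
                 n_windows = length(windows), flank = flank),
            class = "motif_counts")
}

#' iceLogo-style position-specific enrichment
#'
#' For each (position, residue) cell, compares the foreground frequency with
#' the background frequency under the binomial sampling model of the
#' reference set: \code{z = (f_fg - f_bg) / sqrt(f_bg (1 - f_bg) / n_fg)},
#' with a two-sided normal p-value. Frequencies are taken over non-padding
#' observations at each position. Following iceLogo's default, no
#' multiple-testing correction is applied unless \code{adjust = "BH"}.
#'
#' @param fg,bg \code{"motif_counts"} objects on the same frame; \code{bg}
#'   is typically all quantified sites.
#' @param alpha per-cell significance level (default 0.05).
#' @param adjust \code{"none"} (iceLogo default) or \code{"BH"}.
#' @return data.frame with \code{position}, \code{residue}, \code{freq_fg},
#'   \code{freq_bg}, \code{diff}, \code{z}, \code{p}, \code{significant}.
#' @export
icelogo_enrichment <- function(fg, bg, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fg, "motif_counts"), inherits(bg, "motif_counts"))
  if (fg$n_windows == 0L) stopf("empty foreground set")
  if (fg$flank != bg$flank) stopf("foreground and background frames differ")
  n_fg <- fg$n_windows - fg$padding          # non-padding windows per position
  n_bg <- bg$n_windows - bg$padding
  f_fg <- sweep(fg$counts, 2L, pmax(n_fg, 1L), "/")
  f_bg <- sweep(bg$counts, 2L, pmax(n_bg, 1L), "/")
  pos <- rep(as.integer(colnames(fg$counts)), each = nrow(fg$counts))
  res <- rep(rownames(fg$counts), times = ncol(fg$counts))
  ffg <- as.vector(f_fg); fbg <- as.vector(f_bg)
  nn <- rep(pmax(n_fg, 1L), each = nrow(fg$counts))
  se <- sqrt(fbg * (1 - fbg) / nn)
  z <- ifelse(se > 0, (ffg - fbg) / se,
              ifelse(ffg == fbg, 0, Inf * sign(ffg - fbg)))
  p <- 2 * stats::pnorm(-abs(z))
  padj <- if (adjust == "BH") bh_adjust(p) else p
  data.frame(position = pos, residue = res, freq_fg = ffg, freq_bg = fbg,
             diff = ffg - fbg, z = z, p = p,
             significant = padj < alpha, stringsAsFactors = FALSE)
}

#' Define a fixed phosphosite motif
#'
#' @param name motif label.
#' @param center allowed phosphoacceptor residues (subset of S/T/Y).
#' @param fixed named list: offset (as character, e.g. \code{"-3"}) ->
#'   allowed residues at that offset.
#' @return object of class \code{"motif_spec"}.
#' @export
motif_spec <- function(name, center, fixed = list()) {
  offs <- as.integer(names(fixed))
  if (length(offs) && any(abs(offs) > 6L)) stopf("motif offsets must lie within +/-6")
  if (!all(center %in% c("S", "T", "Y"))) stopf("center residues must be S/T/Y")
  structure(list(name = name, center = center, fixed = fixed),
            class = "motif_spec")
}

#' @rdname motif_spec
#' @details \code{motif_stq}: the ATM/ATR/DNA-PKcs consensus S/T-Q (Q at +1).
#' @export
motif_stq <- function() motif_spec("S/TQ", c("S", "T"), list(`1` = "Q"))

#' @rdname motif_spec
#' @details \code{motif_lxrqxst}: the MK2/3/5 substrate consensus LXRQXS/T
#'   (L at -5, R at -3, Q at -2).
#' @export
motif_lxrqxst <- function()
  motif_spec("LXRQXS/T", c("S", "T"), list(`-5` = "L", `-3` = "R", `-2` = "Q"))

#' @rdname motif_spec
#' @details \code{motif_rxxstxdxdi}: the p38-dependent, MK-independent
#'   consensus RXXS/TXDXDI (R at -3, D at +2 and +4, I at +5).
#' @export
motif_rxxstxdxdi <- function()
  motif_spec("RXXS/TXDXDI", c("S", "T"),
             list(`-3` = "R", `2` = "D", `4` = "D", `5` = "I"))

#' Match windows against a fixed motif
#'
#' TRUE iff the center residue is in the motif's center set and every
#' required offset carries one of its allowed residues.
#'
#' @param windows character vector of odd-length windows.
#' @param spec a \code{\link{motif_spec}}.
#' @return logical vector.
#' @export
match_motif <- function(windows, spec) {
  stopifnot(inherits(spec, "motif_spec"))
  nc <- nchar(windows)
  ctr <- (nc + 1L) %/% 2L
  ok <- substr(windows, ctr, ctr) %in% spec$center
  for (off in names(spec$fixed)) {
    i <- ctr + as.integer(off)
    ok <- ok & substr(windows, i, i) %in% spec$fixed[[off]]
  }
  ok
}

#' Rule-based 14-3-3 binding-motif prediction
#'
#' A transparent surrogate for consensus-based 14-3-3 site predictors. Three
#' rules are scored against the window (center must be S or T):
#' mode I (R at -3, S/T/F/W/Y at -2, P at +2; score 3), mode II (R at -4 or
#' -3 and P at +2; score 2), and a relaxed arginine-anchor rule (R at -3
#' with S at -2, no +2 constraint; score 1). The score is the best matching
#' rule; a window is positive when the score reaches \code{cutoff}.
#'
#' @param windows character vector of odd-length windows, center S or T.
#' @param cutoff minimum score to call positive (default 1, i.e. any rule).
#' @return data.frame with \code{score}, \code{mode} (best matching rule or
#'   \code{NA}) and \code{positive}.
#' @export
predict_14_3_3 <- function(windows, cutoff = 1) {
  nc <- nchar(windows)
  ctr <- (nc + 1L) %/% 2L
  at <- function(off) substr(windows, ctr + off, ctr + off)
  if (!all(at(0L) %in% c("S", "T")))
    stopf("14-3-3 prediction requires a phospho-S/T center")
  m1 <- at(-3L) == "R" & at(-2L) %in% c("S", "T", "F", "W", "Y") & at(2L) == "P"
  m2 <- (at(-4L) == "R" | at(-3L) == "R") & at(2L) == "P"
  m3 <- at(-3L) == "R" & at(-2L) == "S"
  score <- pmax(ifelse(m1, 3L, 0L), ifelse(m2, 2L, 0L), ifelse(m3, 1L, 0L))
  mode <- rep(NA_character_, length(windows))
  mode[m3] <- "relaxed-anchor"
  mode[m2] <- "mode-II"
  mode[m1] <- "mode-I"
  data.frame(score = score, mode = mode, positive = score >= cutoff,
             stringsAsFactors = FALSE)
}
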