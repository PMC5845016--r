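## Ratio-table containers: a SILAC phosphosite table and a protein-level
## pulldown table share the same (feature x design-column) log2-ratio matrix
## contract; both inherit from "ratio_table" so the moderated statistics and
## dependency callers can treat them uniformly.

#' Construct a SILAC phosphosite table
#'
#' The central phosphoproteomics container: one row per phosphorylation site
#' with its sequence context, plus a site x column matrix of log2 SILAC
#' ratios whose columns are described by a design table mapping each column
#' to a (condition, replicate) pair. Ratios are stored in log2 space; missing
#' quantifications stay \code{NA}, never zero.
#'
#' @param sites data.frame with columns \code{site_id}, \code{protein_id},
#'   \code{gene_name}, \code{position} (1-based residue index), \code{residue}
#'   (one of S/T/Y), \code{localization_prob} in [0,1], and
#'   \code{sequence_window} (odd-length amino-acid string, phosphoacceptor at
#'   the center, \code{_} padding at protein termini).
#' @param ratios numeric matrix, \code{nrow(sites)} rows, one column per
#'   design entry, log2 scale.
#' @param design data.frame with columns \code{column} (colnames of
#'   \code{ratios}), \code{condition} (label such as \code{"UV/mock"}) and
#'   \code{replicate} (integer index).
#' @return an object of class \code{c("silac_site_table", "ratio_table")}.
#' @export
silac_site_table <- function(sites, ratios, design) {
  need <- c("site_id", "protein_id", "gene_name", "position", "residue",
            "localization_prob", "sequence_window")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stopf("site table is missing mandatory column(s): %s", paste(miss, collapse = ", "))
  w <- as.character(sites$sequence_window)
  nc <- nchar(w)
  if (any(nc %% 2L == 0L))
    stopf("sequence_window must have odd length (phospho residue at center); offending site(s): %s",
          paste(utils::head(sites$site_id[nc %% 2L == 0L], 3), collapse = ", "))
  if (!all(sites$residue %in% c("S", "T", "Y")))
    stopf("residue must be one of S, T, Y")
  ctr <- substr(w, (nc + 1L) %/% 2L, (nc + 1L) %/% 2L)
  bad <- ctr != as.character(sites$residue)
  if (any(bad))
    stopf("sequence_window center does not match residue for site(s): %s",
          paste(utils::head(sites$site_id[bad], 3), collapse = ", "))
  lp <- sites$localization_prob
  if (any(!is.na(lp) & (lp < 0 | lp > 1)))
    stopf("localization_prob must lie in [0,1]")
  x <- ratio_table(sites, ratios, design, id_col = "site_id")
  class(x) <- c("silac_site_table", class(x))
  x
}

#' Construct a protein-level pulldown table
#'
#' Same ratio-matrix contract as \code{\link{silac_site_table}} but one row
#' per protein (bait-vs-control and inhibitor-vs-UV SILAC enrichment ratios).
#'
#' @param proteins data.frame with columns \code{protein_id}, \code{gene_name}.
#' @param ratios numeric matrix of log2 enrichment ratios.
#' @param design design data.frame as for \code{\link{silac_site_table}}.
#' @return an object of class \code{c("pulldown_table", "ratio_table")}.
#' @export
pulldown_table <- function(proteins, ratios, design) {
  miss <- setdiff(c("protein_id", "gene_name"), names(proteins))
  if (length(miss))
    stopf("pulldown table is missing mandatory column(s): %s", paste(miss, collapse = ", "))
  x <- ratio_table(proteins, ratios, design, id_col = "protein_id")
  class(x) <- c("pulldown_table", class(x))
  x
}

ratio_table <- function(features, ratios, design, id_col) {
  ratios <- as.matrix(ratios)
  storage.mode(ratios) <- "double"
  if (nrow(ratios) != nrow(features))
    stopf("ratio matrix has %d rows but the feature table has %d", nrow(ratios), nrow(features))
  miss <- setdiff(c("column", "condition", "replicate"), names(design))
  if (length(miss))
    stopf("design is missing column(s): %s", paste(miss, collapse = ", "))
  if (ncol(ratios) != nrow(design))
    stopf("ratio matrix has %d columns but the design describes %d", ncol(ratios), nrow(design))
  colnames(ratios) <- design$column
  if (anyDuplicated(design$column))
    stopf("duplicate design columns")
  structure(list(features = as.data.frame(features, stringsAsFactors = FALSE),
                 ratios = ratios,
                 design = as.data.frame(design, stringsAsFactors = FALSE)),
            id_col = id_col, class = "ratio_table")
}

#' Conditions present in a ratio table
#' @param x a \code{ratio_table}.
#' @return character vector of condition labels.
#' @export
conditions <- function(x) unique(x$design$condition)

#' Extract the feature x replicate log2-ratio matrix for one condition
#'
#' @param x a \code{ratio_table} (\code{silac_site_table} or
#'   \code{pulldown_table}).
#' @param condition condition label present in the design.
#' @return numeric matrix, rows = features (named by id), columns = replicates
#'   in increasing replicate order.
#' @export
ratio_matrix <- function(x, condition) {
  sel <- x$design$condition == condition
  if (!any(sel))
    stopf("condition '%s' is absent from the design (have: %s)",
          condition, paste(conditions(x), collapse = ", "))
  d <- x$design[sel, , drop = FALSE]
  d <- d[order(d$replicate), , drop = FALSE]
  m <- x$ratios[, d$column, drop = FALSE]
  rownames(m) <- x$features[[attr(x, "id_col")]]
  colnames(m) <- paste0("r", d$replicate)
  m
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("<%s> %d features, %d ratio columns (%s)\n",
              class(x)[1L], nrow(x$features), ncol(x$ratios),
              paste(conditions(x), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ratio_table <- function(x) dim(x$ratios)
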