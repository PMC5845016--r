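## Readers and writers for the tabular and genomic formats the pipeline
## consumes: TSV site/pulldown tables (MaxQuant-like, configurable dialect),
## BED/GTF gene models, bedGraph coverage, GMT gene sets. Internal
## coordinates are 0-based half-open everywhere; conversion happens only at
## the parse/serialize boundary.

#' Site-table dialect
#'
#' Describes how a TSV phosphosite table maps onto the internal container:
#' which header pattern marks a ratio column (two capture groups: condition
#' label, replicate index) and whether ratios are stored linear (to be
#' log2-transformed on read) or already in log2 space.
#'
#' @param ratio_pattern regex with exactly two capture groups.
#' @param linear logical; \code{TRUE} if the file stores linear ratios.
#' @param columns named character vector mapping internal field names to file
#'   header names (defaults to identity).
#' @return a list of class \code{"site_dialect"}.
#' @export
site_dialect <- function(ratio_pattern = "^ratio\\.(.+)\\.r([0-9]+)$",
                         linear = FALSE,
                         columns = NULL) {
  std <- c("site_id", "protein_id", "gene_name", "position", "residue",
           "localization_prob", "sequence_window")
  cols <- stats::setNames(std, std)
  if (!is.null(columns)) cols[names(columns)] <- columns
  structure(list(ratio_pattern = ratio_pattern, linear = linear, columns = cols),
            class = "site_dialect")
}

#' MaxQuant-like dialect for "Phospho (STY)Sites"-style exports
#'
#' Matches headers such as \code{"Ratio M/L normalized Exp1"}; such files
#' carry linear SILAC ratios, so \code{linear = TRUE}.
#' @return a \code{site_dialect}.
#' @export
maxquant_dialect <- function() {
  site_dialect(
    ratio_pattern = "^Ratio ([A-Za-z0-9+/]+) normalized Exp([0-9]+)$",
    linear = TRUE,
    columns = c(site_id = "id", protein_id = "Protein", gene_name = "Gene names",
                position = "Position", residue = "Amino acid",
                localization_prob = "Localization prob",
                sequence_window = "Sequence window"))
}

#' Read a SILAC phosphosite table from TSV
#'
#' @param path TSV file with a header row.
#' @param dialect a \code{\link{site_dialect}}.
#' @return a \code{\link{silac_site_table}}; linear-dialect ratios are
#'   log2-transformed, missing cells stay \code{NA}, non-numeric ratio cells
#'   become \code{NA} with a warning.
#' @export
read_site_table <- function(path, dialect = site_dialect()) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "NaN", ""))
  cols <- dialect$columns
  miss <- cols[!(cols %in% names(df))]
  if (length(miss))
    stopf("site table '%s' is missing mandatory column(s): %s",
          path, paste(miss, collapse = ", "))
  sites <- stats::setNames(df[, cols, drop = FALSE], names(cols))
  sites$position <- as.integer(sites$position)
  sites$localization_prob <- as.numeric(sites$localization_prob)

  m <- regexec(dialect$ratio_pattern, names(df))
  hit <- vapply(m, function(g) g[1L] != -1L, logical(1))
  if (!any(hit))
    stopf("no ratio columns in '%s' match pattern '%s'", path, dialect$ratio_pattern)
  caps <- regmatches(names(df), m)[hit]
  design <- data.frame(column = names(df)[hit],
                       condition = vapply(caps, `[`, "", 2L),
                       replicate = as.integer(vapply(caps, `[`, "", 3L)),
                       stringsAsFactors = FALSE)
  ratios <- sapply(design$column, function(cn) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad))
        warnf("column '%s': %d non-numeric ratio value(s) set to missing (first at row %d)",
              cn, length(bad), bad[1L])
      v <- vn
    }
    v
  })
  ratios <- matrix(ratios, nrow = nrow(df),
                   dimnames = list(NULL, design$column))
  if (dialect$linear) {
    if (any(ratios <= 0, na.rm = TRUE))
      warnf("non-positive linear ratios set to missing")
    ratios[!is.na(ratios) & ratios <= 0] <- NA_real_
    ratios <- log2(ratios)
  }
  silac_site_table(sites, ratios, design)
}

#' Write a SILAC phosphosite table to TSV
#'
#' Inverse of \code{\link{read_site_table}} under the same dialect: ratio
#' headers are reconstructed from the design, values are written in log2
#' space (or back-transformed for a linear dialect) at full double precision
#' so a write/read round trip preserves finite values exactly.
#'
#' @param x a \code{silac_site_table}.
#' @param path output file.
#' @param dialect a \code{\link{site_dialect}}; only the default template
#'   headers are supported for writing.
#' @export
write_site_table <- function(x, path, dialect = site_dialect()) {
  out <- x$features
  r <- x$ratios
  if (dialect$linear) r <- 2^r
  hdr <- sprintf("ratio.%s.r%d", x$design$condition, x$design$replicate)
  rt <- as.data.frame(apply(r, 2, function(v) sprintf("%.17g", v)),
                      stringsAsFactors = FALSE)
  rt[is.na(r[seq_len(nrow(r)), , drop = FALSE])] <- NA
  if (nrow(r) == 1L) rt <- as.data.frame(t(rt), stringsAsFactors = FALSE)
  names(rt) <- hdr
  utils::write.table(cbind(out, rt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene models from BED or GTF
#'
#' Coordinates are normalized to 0-based half-open; the TSS is assigned
#' strand-aware (for minus-strand genes the TSS is \code{end - 1} in genomic
#' coordinates, so \code{tss > tes}).
#'
#' @param path BED (6+ columns) or GTF file.
#' @param format \code{"bed"} or \code{"gtf"} (guessed from the extension by
#'   default).
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end} (0-based half-open),
#'   \code{tss}, \code{tes}, \code{length}.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(gtf|gff[0-9]?)$", path, ignore.case = TRUE)) "gtf" else "bed"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GTF")
  if (format == "gtf") {
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    ids <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) gr$gene_id else gr$ID
  } else {
    ids <- if ("name" %in% names(S4Vectors::mcols(gr))) gr$name
           else paste0("gene", seq_along(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stopf("gene model(s) with unknown strand: %s",
          paste(utils::head(ids[strand == "*"], 3), collapse = ", "))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  zero <- end0 <= start0
  if (any(zero)) {
    warnf("skipping %d zero-length gene model(s)", sum(zero))
    keep <- !zero
    gr <- gr[keep]; ids <- ids[keep]; strand <- strand[keep]
    start0 <- start0[keep]; end0 <- end0[keep]
  }
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand,
             start = start0, end = end0,
             tss = ifelse(strand == "+", start0, end0 - 1L),
             tes = ifelse(strand == "+", end0, start0 - 1L),
             length = end0 - start0,
             stringsAsFactors = FALSE)
}

#' Write gene models as BED6
#' @param genes data.frame as returned by \code{\link{read_gene_models}}.
#' @param path output file.
#' @export
write_gene_models_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
                    genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a coverage track
#'
#' @param cov named list: one non-negative numeric vector of per-base
#'   coverage per chromosome.
#' @param condition,replicate track labels.
#' @param library_size total mapped read mass in read-bases; defaults to the
#'   sum of all coverage.
#' @return object of class \code{"coverage_track"}.
#' @export
coverage_track <- function(cov, condition, replicate, library_size = NULL) {
  if (any(vapply(cov, function(v) any(v < 0), logical(1))))
    stopf("coverage must be non-negative")
  if (is.null(library_size))
    library_size <- sum(vapply(cov, sum, 0))
  structure(list(condition = condition, replicate = as.integer(replicate),
                 cov = cov, library_size = library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s r%d: %d chrom(s), library mass %.3g\n",
              x$condition, x$replicate, length(x$cov), x$library_size))
  invisible(x)
}

#' Read a bedGraph coverage file into a dense per-base track
#'
#' @param path bedGraph file (0-based half-open, non-overlapping intervals).
#' @param condition,replicate labels attached to the track.
#' @return a \code{\link{coverage_track}} with per-base coverage and
#'   \code{library_size} equal to the total coverage mass.
#' @export
read_coverage <- function(path, condition, replicate) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L)
    return(coverage_track(list(), condition, replicate, library_size = 0))
  if (any(gr$score < 0))
    stopf("negative coverage value in '%s'", path)
  byc <- GenomicRanges::split(GenomicRanges::ranges(gr), GenomicRanges::seqnames(gr))
  if (!all(IRanges::isDisjoint(byc)))
    stopf("overlapping bedGraph intervals in '%s'", path)
  covrle <- GenomicRanges::coverage(gr, weight = gr$score)
  cov <- lapply(covrle, as.numeric)
  cov <- cov[vapply(cov, length, 0L) > 0L]
  coverage_track(cov, condition, replicate)
}

#' Write a coverage track as bedGraph (run-length encoded)
#' @param track a \code{\link{coverage_track}}.
#' @param path output file.
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$cov)) {
    r <- rle(track$cov[[chrom]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, start[keep], end[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, \code{name<TAB>description<TAB>member...}.
#' Member identifiers are uppercased and deduplicated.
#'
#' @param path GMT file.
#' @return a named list of character vectors (class
#'   \code{"gene_set_collection"}) with a \code{description} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3L
  if (any(short))
    stopf("GMT line %d has fewer than 3 tab-separated fields", which(short)[1L])
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm))
    stopf("duplicate gene-set name '%s' in '%s'", nm[duplicated(nm)][1L], path)
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- nm
  structure(sets, description = stats::setNames(vapply(fields, `[`, "", 2L), nm),
            class = "gene_set_collection")
}
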