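#' @keywords internal
"_PACKAGE"

## Amino-acid alphabet used throughout (20 proteinogenic residues; '_' marks
## window padding beyond protein termini).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Evaluate an expression under a fixed RNG state
#'
#' Runs \code{expr} with the Mersenne-Twister generator seeded at \code{seed}
#' and restores the caller's RNG state afterwards, so simulators are
#' deterministic without clobbering the session seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

#' Percentage display forms for a count fraction
#'
#' Published summary labels round percentages inconsistently: some one-decimal
#' values are truncated (25.65\% printed as 25.6), others conventionally
#' rounded (1.169\% printed as 1.2), and whole-number labels are half-up
#' rounded. All three forms are therefore reported side by side rather than
#' privileging one convention.
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @return a list with the raw percentage \code{pct} and the display forms
#'   \code{trunc1} (one decimal, truncated), \code{round1} (one decimal,
#'   half-up rounded) and \code{int} (integer, half-up rounded).
#' @examples
#' percent_forms(538, 13091)$trunc1   # 4.1
#' percent_forms(153, 13091)$round1   # 1.2
#' percent_forms(89, 538)$int         # 17
#' @export
percent_forms <- function(k, n) {
  if (!is.numeric(k) || !is.numeric(n) || n <= 0 || k < 0)
    stopf("percent_forms() needs counts k >= 0 and n > 0")
  pct <- 100 * k / n
  list(pct    = pct,
       trunc1 = floor(pct * 10) / 10,
       round1 = floor(pct * 10 + 0.5) / 10,
       int    = floor(pct + 0.5))
}
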