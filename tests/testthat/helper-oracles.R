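# Independent oracles and small fixture builders shared across tests.

# Bisection solver for the two log-variance moment equations: finds d0 with
# trigamma(d0/2) = excess and the matched s02. Independent of the package's
# Newton-based implementation.
oracle_ebayes <- function(mat) {
  s2 <- apply(mat, 1, function(v) var(v[!is.na(v)]))
  df <- rowSums(!is.na(mat)) - 1
  keep <- df >= 1 & !is.na(s2)
  s2 <- pmax(s2[keep], 1e-8); df <- df[keep]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  excess <- var(e) - mean(trigamma(df / 2))
  if (excess <= 0) return(list(d0 = Inf, s02 = exp(mean(e))))
  lo <- 1e-8; hi <- 1e8
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) - excess > 0) lo <- mid else hi <- mid
  }
  x <- sqrt(lo * hi)
  list(d0 = 2 * x, s02 = exp(mean(e) + digamma(x) - log(x)))
}

# Exact rank-sum tail by enumeration: P over all equally likely assignments
# of the pooled scores to group sizes (nx, ny) that the x-group score sum is
# as or more extreme than observed.
enum_ranksum_p <- function(x, y, alternative = "less") {
  pooled <- c(x, y)
  nx <- length(x)
  obs <- sum(x)
  sums <- combn(pooled, nx, sum)
  switch(alternative,
         less = mean(sums <= obs),
         greater = mean(sums >= obs),
         two.sided = min(1, 2 * min(mean(sums <= obs), mean(sums >= obs))))
}

# Hypergeometric upper tail by direct summation.
enum_hyper_p <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-sided exact Spearman p by full permutation enumeration (n <= 6).
enum_spearman_p <- function(x, y) {
  n <- length(x)
  obs <- abs(cor(x, y, method = "spearman"))
  perms <- gtools_permutations(n)
  rhos <- apply(perms, 1, function(idx) cor(x, y[idx], method = "spearman"))
  mean(abs(rhos) >= obs - 1e-12)
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Minimal site table: one condition block per named matrix in ratios_list.
make_site_table <- function(ratios_list, windows = NULL, loc = 1) {
  n <- nrow(ratios_list[[1]])
  if (is.null(windows)) windows <- rep("AAAAAASAAAAAA", n)
  sites <- data.frame(site_id = sprintf("s%03d", seq_len(n)),
                      protein_id = sprintf("P%03d", seq_len(n)),
                      gene_name = sprintf("G%03d", seq_len(n)),
                      position = seq_len(n) + 10L,
                      residue = substr(windows, (nchar(windows) + 1) %/% 2,
                                       (nchar(windows) + 1) %/% 2),
                      localization_prob = rep(loc, n),
                      sequence_window = windows,
                      stringsAsFactors = FALSE)
  design <- do.call(rbind, lapply(names(ratios_list), function(cond) {
    reps <- seq_len(ncol(ratios_list[[cond]]))
    data.frame(column = sprintf("ratio.%s.r%d", cond, reps),
               condition = cond, replicate = reps, stringsAsFactors = FALSE)
  }))
  silac_site_table(sites, do.call(cbind, ratios_list), design)
}

AA20_test <- function() c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Random 13-mer windows with S/T/Y centers and uniform flanks.
random_aa_windows <- function(n) {
  ctr <- sample(c("S", "T", "Y"), n, TRUE)
  vapply(seq_len(n), function(i)
    paste(c(sample(AA20_test(), 6, TRUE), ctr[i],
            sample(AA20_test(), 6, TRUE)), collapse = ""), "")
}

# Uniform-coverage track over one chromosome.
flat_track <- function(value, len, condition, replicate) {
  coverage_track(list(chrS = rep(value, len)), condition, replicate)
}
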