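# Independent brute-force oracles, coded as plain scalar loops so they
# share no code path with the vectorised implementations they check.
# All oracles assume complete data unless noted.

# Per-site pi by enumerating every pair of called alleles.
oracle_site_pi <- function(geno) {
  alleles <- integer(0)
  for (g in geno) if (!is.na(g)) alleles <- c(alleles, c(g >= 1, g >= 2))
  n <- length(alleles)
  if (sum(!is.na(geno)) < 2) return(NA_real_)  # needs 2+ called individuals
  diff_pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (alleles[i] != alleles[j]) diff_pairs <- diff_pairs + 1
  diff_pairs / choose(n, 2)
}

# Tajima's D for one bin of complete-data SNP columns (samples x SNPs),
# evaluating the formula from first principles.
oracle_tajima_d <- function(G) {
  n <- 2 * nrow(G)
  S <- 0
  khat <- 0
  for (j in seq_len(ncol(G))) {
    ac <- sum(G[, j])
    if (ac > 0 && ac < n) S <- S + 1
    khat <- khat + oracle_site_pi(G[, j])
  }
  if (S == 0) return(NA_real_)
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Squared Pearson correlation over pairwise-complete observations.
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

# Weir & Cockerham (1984) theta for one SNP and two groups of
# genotypes, written as direct scalar arithmetic.
oracle_wc_snp <- function(g1, g2) {
  grp <- list(g1[!is.na(g1)], g2[!is.na(g2)])
  r <- 2
  n_i <- sapply(grp, length)
  if (any(n_i < 1)) return(c(a = NA, d = NA))
  p_i <- sapply(grp, function(g) sum(g) / (2 * length(g)))
  h_i <- sapply(grp, function(g) mean(g == 1))
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  if (nbar <= 1) return(c(a = NA, d = NA))
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, d = a + b + cc)
}

# One-way ANOVA from hand-computed sums of squares.
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (lev in levels(groups)) {
    v <- values[groups == lev]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  F <- (ssb / df_b) / (ssw / df_w)
  list(F = F, p = stats::pf(F, df_b, df_w, lower.tail = FALSE))
}
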