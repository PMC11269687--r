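## Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so package functions never perturb user simulations.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# TRUE for sites whose 0-based position falls in any half-open interval
# of `iv` on the matching chromosome.  `pos` is 1-based (VCF convention);
# conversion to 0-based happens here, at the boundary.
.in_intervals <- function(chrom, pos, iv) {
  pos0 <- pos - 1
  hit <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(iv))) {
    hit <- hit | (chrom == iv$chrom[k] & pos0 >= iv$start[k] & pos0 < iv$end[k])
  }
  hit
}

# Distance (bp) from each 0-based site position to the nearest edge of a
# single half-open interval; 0 inside the interval.  Sites on other
# chromosomes get NA.
.interval_distance <- function(chrom, pos, iv_chrom, iv_start, iv_end) {
  pos0 <- pos - 1
  d <- rep(NA_real_, length(pos))
  on_chrom <- chrom == iv_chrom
  d[on_chrom] <- pmax(0, pmax(iv_start - pos0[on_chrom], pos0[on_chrom] - (iv_end - 1)))
  d
}

# Squared pairwise-complete Pearson correlation between the columns of X
# and the columns of Y (samples in rows), computed exactly in one pass
# with indicator cross-products.  Returns a ncol(X) x ncol(Y) matrix;
# entries with a zero-variance member are NA.
.pairwise_r2 <- function(X, Y) {
  Mx <- !is.na(X); My <- !is.na(Y)
  X0 <- X; X0[!Mx] <- 0
  Y0 <- Y; Y0[!My] <- 0
  mx <- Mx + 0; my <- My + 0
  N   <- crossprod(mx, my)
  Sx  <- crossprod(X0, my)
  Sy  <- crossprod(mx, Y0)
  Sxy <- crossprod(X0, Y0)
  Sxx <- crossprod(X0 * X0, my)
  Syy <- crossprod(mx, Y0 * Y0)
  cov <- Sxy - Sx * Sy / N
  vx  <- Sxx - Sx * Sx / N
  vy  <- Syy - Sy * Sy / N
  r2 <- cov * cov / (vx * vy)
  r2[!is.finite(r2)] <- NA_real_
  r2[N < 2] <- NA_real_
  r2
}

# r2 for an explicit list of column pairs (ii[k], jj[k]) of G.
.pairwise_r2_pairs <- function(G, ii, jj) {
  A <- G[, ii, drop = FALSE]; B <- G[, jj, drop = FALSE]
  Ma <- !is.na(A); Mb <- !is.na(B)
  A0 <- A; A0[!Ma] <- 0
  B0 <- B; B0[!Mb] <- 0
  both <- Ma & Mb
  N <- colSums(both)
  Sx <- colSums(A0 * Mb); Sy <- colSums(B0 * Ma)
  Sxy <- colSums(A0 * B0)
  Sxx <- colSums(A0 * A0 * Mb); Syy <- colSums(B0 * B0 * Ma)
  cov <- Sxy - Sx * Sy / N
  vx <- Sxx - Sx^2 / N
  vy <- Syy - Sy^2 / N
  r2 <- cov^2 / (vx * vy)
  r2[!is.finite(r2)] <- NA_real_
  r2[N < 2] <- NA_real_
  r2
}
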