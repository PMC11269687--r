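## Admixture statistics ---------------------------------------------------
##
## f3(target; A, B) tests whether the target population is a mixture of
## populations related to A and B: significantly negative values are
## evidence of admixture.  Significance comes from a delete-one block
## jackknife over consecutive SNP blocks.  The PCA projection estimates
## per-individual admixture proportions from the position of query
## samples on a principal component built from the two source
## populations alone.

.pop_freq <- function(vm, pop) {
  g <- vm$genotypes[vm$populations == pop, , drop = FALSE]
  if (!nrow(g)) stop("population not present: ", pop)
  an <- 2 * colSums(!is.na(g))
  list(freq = colSums(g, na.rm = TRUE) / an, an = an)
}

#' f3 admixture test with block-jackknife significance
#'
#' Per SNP `f3 = (c - a)(c - b) - c(1 - c)/(n_C - 1)` where `a`, `b`,
#' `c` are the sample allele frequencies of the two sources and the
#' target and `n_C` the target's called allele count (the bias
#' correction for finite target samples).  `F3` is the mean over SNPs;
#' the standard error comes from a delete-one jackknife over consecutive
#' `block_size`-SNP blocks, `Z = F3/SE`, with a one-sided p-value for
#' `F3 < 0`.
#'
#' @param vm a `VariantMatrix`.
#' @param target,source_a,source_b population labels (each >= 2 samples).
#' @param block_size SNPs per jackknife block (default 500).
#' @param n_triads number of triads tested in the run, for Bonferroni
#'   adjustment (default 1).
#' @return list of class `f3_result`: `f3`, `se`, `z`, `p`, `p_bonf`,
#'   `n_snps`, `n_blocks`.
#' @export
f3_test <- function(vm, target, source_a, source_b, block_size = 500,
                    n_triads = 1) {
  for (p in c(target, source_a, source_b))
    if (sum(vm$populations == p) < 2) stop("population needs >= 2 samples: ", p)
  fa <- .pop_freq(vm, source_a)$freq
  fb <- .pop_freq(vm, source_b)$freq
  tc <- .pop_freq(vm, target)
  ok <- !is.na(fa) & !is.na(fb) & !is.na(tc$freq) & tc$an >= 2
  poly <- ok & (fa > 0 | fb > 0 | tc$freq > 0) & (fa < 1 | fb < 1 | tc$freq < 1)
  if (!any(poly)) {
    warning("no usable polymorphic sites; f3 undefined")
    return(structure(list(f3 = NA_real_, se = NA_real_, z = NA_real_,
                          p = NA_real_, p_bonf = NA_real_, n_snps = 0L,
                          n_blocks = 0L), class = "f3_result"))
  }
  a <- fa[poly]; b <- fb[poly]; cc <- tc$freq[poly]; nC <- tc$an[poly]
  v <- (cc - a) * (cc - b) - cc * (1 - cc) / (nC - 1)
  f3 <- mean(v)
  n_blk <- max(1L, floor(length(v) / block_size))
  if (n_blk < 2) stop("need at least 2 SNP blocks for the jackknife")
  blk <- pmin(ceiling(seq_along(v) / block_size), n_blk)
  loo <- vapply(seq_len(n_blk), function(k) mean(v[blk != k]), numeric(1))
  se <- sqrt((n_blk - 1) / n_blk * sum((loo - mean(loo))^2))
  if (n_blk < 20)
    warning("fewer than 20 jackknife blocks; f3 may be underpowered for ",
            "reduced representation data")
  z <- f3 / se
  p <- stats::pnorm(z)                 # one-sided, admixture means f3 < 0
  structure(list(f3 = f3, se = se, z = z, p = p,
                 p_bonf = min(1, p * n_triads),
                 n_snps = length(v), n_blocks = n_blk),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3 = %.4g  SE = %.3g  Z = %.2f  p = %.3g (Bonferroni %.3g)  [%d SNPs, %d blocks]\n",
              x$f3, x$se, x$z, x$p, x$p_bonf, x$n_snps, x$n_blocks))
  invisible(x)
}

#' Run f3 tests over a list of population triads
#'
#' @param vm a `VariantMatrix`.
#' @param triads data frame with columns `target`, `source_a`,
#'   `source_b`.
#' @param block_size SNPs per jackknife block.
#' @return data frame with one row per triad, Bonferroni-adjusted over
#'   all triads tested.
#' @export
f3_tests <- function(vm, triads, block_size = 500) {
  m <- nrow(triads)
  do.call(rbind, lapply(seq_len(m), function(i) {
    r <- f3_test(vm, triads$target[i], triads$source_a[i], triads$source_b[i],
                 block_size = block_size, n_triads = m)
    data.frame(target = triads$target[i], source_a = triads$source_a[i],
               source_b = triads$source_b[i], f3 = r$f3, se = r$se,
               z = r$z, p = r$p, p_bonf = r$p_bonf)
  }))
}

#' Admixture proportions from PCA projection
#'
#' A single principal component is built from the centred,
#' frequency-standardised dosages of the two source populations alone
#' (SNPs restricted to those polymorphic in the source pool); query
#' samples are projected with the same centring and loadings.  The
#' admixture proportion toward source A is
#' `alpha_hat = (xbar_B - x_query)/(xbar_B - xbar_A)`, clipped to
#' `[0, 1]`.  The axis is oriented with source A at the negative end.
#'
#' @param vm a `VariantMatrix`.
#' @param source_a,source_b disjoint source population labels, each
#'   with >= 3 samples.
#' @param query sample ids to project.
#' @return list of class `projection_result`: `coords` (per-query axis
#'   coordinate), `alpha` (named proportions), `source_means`,
#'   `loadings`.
#' @export
pca_projection <- function(vm, source_a, source_b, query) {
  sa <- vm$samples[vm$populations == source_a]
  sb <- vm$samples[vm$populations == source_b]
  if (length(intersect(sa, sb))) stop("source populations overlap")
  if (length(sa) < 3 || length(sb) < 3) stop("each source needs >= 3 samples")
  pool <- c(sa, sb)
  G <- vm$genotypes[pool, , drop = FALSE]
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no SNPs polymorphic in the source pool")
  centre <- 2 * p[poly]
  scale <- sqrt(2 * p[poly] * (1 - p[poly]))
  std <- function(g) {
    x <- sweep(g[, poly, drop = FALSE], 2, centre)
    x <- sweep(x, 2, scale, "/")
    x[is.na(x)] <- 0
    x
  }
  Xs <- std(G)
  sv <- svd(Xs, nu = 1, nv = 1)
  loadings <- sv$v[, 1]
  coords_pool <- as.numeric(Xs %*% loadings)
  names(coords_pool) <- pool
  xa <- mean(coords_pool[sa]); xb <- mean(coords_pool[sb])
  if (abs(xa - xb) < 1e-8)
    stop("sources are indistinguishable on the projection axis")
  if (xa > xb) {            # orient source A to the negative end
    loadings <- -loadings
    coords_pool <- -coords_pool
    xa <- -xa; xb <- -xb
  }
  Xq <- std(vm$genotypes[query, , drop = FALSE])
  coords <- as.numeric(Xq %*% loadings)
  names(coords) <- query
  alpha <- pmin(1, pmax(0, (xb - coords) / (xb - xa)))
  structure(list(coords = coords, alpha = alpha,
                 source_means = c(a = xa, b = xb), loadings = loadings),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat("PCA projection:", length(x$coords), "query samples\n")
  cat(sprintf("  mean admixture proportion toward source A: %.3f\n",
              mean(x$alpha)))
  invisible(x)
}
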