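## Latent-factor-adjusted genome scan ------------------------------------
##
## SNPs are tested for structure in line with a focal resistance
## genotype (dosage 0/1/2) after conditioning on genome-wide structure
## through K latent factors (principal components of the centred dosage
## matrix).  Each SNP is regressed on (intercept, focal, factors); the
## focal t-statistic is recalibrated by the genomic inflation factor
## lambda_gc = median(z^2) / 0.456 and converted to a two-sided normal
## p-value, followed by Benjamini-Hochberg adjustment.  This
## deterministic least-squares formulation targets the same quantity as
## MCMC latent factor mixed models while being exactly reproducible.

#' Latent factors of genome-wide structure
#'
#' The first `K` principal-component scores of the centred dosage
#' matrix.  Missing entries are mean-filled for factor estimation only.
#' A variance-explained profile is attached to aid the choice of K.
#'
#' @param vm a `VariantMatrix`.
#' @param K number of factors, `1 <= K < n_samples`.
#' @param seed RNG seed (the decomposition itself is deterministic; the
#'   seed is accepted for interface stability).
#' @return numeric matrix (samples x K) with attribute
#'   `"variance_explained"`.
#' @export
latent_factors <- function(vm, K, seed = 1L) {
  n <- n_samples(vm)
  if (K < 1 || K >= n) stop("K must satisfy 1 <= K < sample count")
  X <- .centred_dosage(vm)
  sv <- svd(X, nu = min(n, max(K, 25L)), nv = 0)
  scores <- sv$u[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K, K)
  # fix signs so repeated runs and duplicated inputs agree exactly
  for (k in seq_len(K)) {
    j <- which.max(abs(scores[, k]))
    if (scores[j, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- vm$samples
  attr(scores, "variance_explained") <- sv$d^2 / sum(sv$d^2)
  scores
}

.centred_dosage <- function(vm) {
  X <- vm$genotypes
  mu <- colMeans(X, na.rm = TRUE)
  X <- sweep(X, 2, mu)
  X[is.na(X)] <- 0          # mean-fill: centred missing entries are 0
  X
}

#' Genome scan conditioned on latent factors
#'
#' @param vm a `VariantMatrix`.
#' @param focal per-sample dosage of the focal mutation (0/1/2), named
#'   or in sample order; must not be constant.
#' @param K latent factor count (0 reduces to simple regression).
#' @param maf minimum minor allele frequency for a SNP to be tested
#'   (default 0.05); rarer SNPs are flagged untested.
#' @return data frame of class `assoc_scan` with per-SNP `z`, `p`,
#'   `p_adj`, `tested`; attributes `K`, `maf`, `lambda_gc`.
#' @export
lfmm_scan <- function(vm, focal, K, maf = 0.05) {
  n <- n_samples(vm)
  if (!is.null(names(focal))) focal <- focal[vm$samples]
  focal <- as.numeric(focal)
  if (length(focal) != n || anyNA(focal))
    stop("focal dosage must be defined for every retained sample")
  if (stats::var(focal) == 0) stop("focal vector is constant; no contrast to test")
  Z <- if (K > 0) latent_factors(vm, K) else NULL
  X <- cbind(1, focal, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    if (any(drop <= 2)) stop("focal vector is collinear with the intercept")
    warning("dropping ", length(drop), " collinear latent factor(s)")
    X <- X[, -drop, drop = FALSE]
    qrX <- qr(X)
  }
  p_cols <- ncol(X)
  af <- colMeans(vm$genotypes, na.rm = TRUE) / 2
  maf_snp <- pmin(af, 1 - af)
  tested <- maf_snp >= maf & !is.na(maf_snp)
  Y <- .centred_dosage(vm)[, tested, drop = FALSE]
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- n - p_cols
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXinv[2, 2])
  z <- as.numeric(beta[2, ]) / se
  z[!is.finite(z)] <- 0
  lambda <- stats::median(z^2) / 0.456
  if (lambda > 0) z <- z / sqrt(lambda)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(chrom = vm$chrom, pos = vm$pos, z = NA_real_,
                    p = NA_real_, p_adj = NA_real_, tested = tested)
  out$z[tested] <- z
  out$p[tested] <- p
  out$p_adj[tested] <- adjust_pvalues_bh(p)$p_adj
  attr(out, "K") <- K
  attr(out, "maf") <- maf
  attr(out, "lambda_gc") <- lambda
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat("Association scan:", nrow(x), "SNPs (", sum(x$tested), "tested ),",
      "K =", attr(x, "K"), "\n")
  cat(sprintf("  genomic inflation lambda_gc = %.3f\n", attr(x, "lambda_gc")))
  invisible(x)
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up BH adjusted p-values (monotone, capped at 1) via
#' [stats::p.adjust()], flagged at the given false discovery rate.
#'
#' @param p p-values in `[0, 1]`.
#' @param fdr flag threshold on the adjusted values (default 0.01).
#' @return list with `p_adj` and logical `significant`.
#' @export
adjust_pvalues_bh <- function(p, fdr = 0.01) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, significant = !is.na(p_adj) & p_adj < fdr)
}

#' Outlier threshold: the inverse of the SNP count
#'
#' @param n_snps number of SNPs tested (>= 1).
#' @return `1 / n_snps`.
#' @export
outlier_threshold <- function(n_snps) {
  if (n_snps < 1) stop("n_snps must be at least 1")
  1 / n_snps
}

#' Select outlier SNPs from one or two scans
#'
#' Outliers are SNPs with adjusted p below `threshold`.  With two scans
#' (sharing a SNP frame) the intersection set is also returned, and each
#' set can be partitioned into within-locus, within 1 Mb of the locus,
#' and elsewhere.
#'
#' @param result_a an `assoc_scan`.
#' @param result_b optional second `assoc_scan` on the same SNP frame.
#' @param threshold adjusted-p cut-off (e.g. [outlier_threshold()]).
#' @param locus optional one-row [interval_set()] for the partition.
#' @param near_bp "near locus" distance (default 1 Mb).
#' @return list with SNP index vectors `a`, `b`, `intersection`, and a
#'   `partition` function result per set when `locus` is given.
#' @export
select_outliers <- function(result_a, result_b = NULL, threshold,
                            locus = NULL, near_bp = 1e6) {
  set_a <- which(!is.na(result_a$p_adj) & result_a$p_adj < threshold)
  sets <- list(a = set_a)
  if (!is.null(result_b)) {
    if (nrow(result_b) != nrow(result_a) ||
        !identical(result_b$pos, result_a$pos) ||
        !identical(result_b$chrom, result_a$chrom))
      stop("the two scans do not share a SNP frame")
    set_b <- which(!is.na(result_b$p_adj) & result_b$p_adj < threshold)
    sets$b <- set_b
    sets$intersection <- intersect(set_a, set_b)
  }
  if (!is.null(locus)) {
    dist <- .interval_distance(result_a$chrom, result_a$pos,
                               locus$chrom[1], locus$start[1], locus$end[1])
    sets$partition <- lapply(sets[names(sets) != "partition"], function(s) {
      d <- dist[s]
      list(within_locus = s[!is.na(d) & d == 0],
           within_near = s[!is.na(d) & d > 0 & d <= near_bp],
           elsewhere = s[is.na(d) | d > near_bp])
    })
  }
  sets
}
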