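## Linkage-network scoring ------------------------------------------------
##
## Finds SNPs far from a sweep locus (>= 50 Mb on the locus chromosome,
## or on any other chromosome) that are in strong LD (r2 > 0.6) with at
## least one SNP within 1 Mb of the locus, scores each such SNP by its
## number of qualifying interactions, and accumulates the scores into
## half-open 500-kb bins.  Peaks in the histogram point at genes riding
## with the swept background.

#' Score long-range linkage interactions with a sweep locus
#'
#' @param vm a `VariantMatrix`.
#' @param members background member sample ids (>= 4).
#' @param locus one-row [interval_set()]; must lie on a chromosome
#'   present in `vm`.
#' @param r2_min interaction threshold (default 0.6).
#' @param near_bp locus neighbourhood width (default 1 Mb).
#' @param far_bp minimum same-chromosome distance for candidates
#'   (default 50 Mb); other chromosomes always qualify.
#' @param bin_bp histogram bin width (default 500 kb).
#' @param min_mac minimum minor allele count within the member subset
#'   for a SNP to enter the network (default 3).  Subset-level
#'   singletons and doubletons produce spurious r2 = 1 pairs whenever
#'   two rare alleles ride in the same individual, so they are excluded
#'   even when the full data set passed a global count filter.
#' @return list of class `linkage_histogram` with `bins` (`chrom`,
#'   `bin_start`, `count`), `snp_scores` (per qualifying SNP), counters
#'   and the parameters used.
#' @export
linkage_network <- function(vm, members, locus, r2_min = 0.6, near_bp = 1e6,
                            far_bp = 5e7, bin_bp = 5e5, min_mac = 3) {
  if (length(members) < 4) stop("linkage_network needs at least 4 members")
  if (!locus$chrom[1] %in% vm$chrom)
    stop("locus chromosome not present in the matrix")
  si <- .resolve_subset(vm, members)
  g_all <- vm$genotypes[si, , drop = FALSE]
  ac <- colSums(g_all, na.rm = TRUE)
  an <- 2L * colSums(!is.na(g_all))
  mac_ok <- pmin(ac, an - ac) >= min_mac
  dist <- .interval_distance(vm$chrom, vm$pos, locus$chrom[1],
                             locus$start[1], locus$end[1])
  near <- which(!is.na(dist) & dist <= near_bp & mac_ok)
  if (!length(near)) stop("locus has no flanking SNPs")
  cand <- which(((!is.na(dist) & dist >= far_bp) | is.na(dist)) & mac_ok)
  g <- g_all
  score <- integer(length(cand))
  n_zero_var <- 0L
  if (length(cand)) {
    r2 <- .pairwise_r2(g[, cand, drop = FALSE], g[, near, drop = FALSE])
    n_zero_var <- sum(is.na(r2))
    score <- rowSums(r2 > r2_min, na.rm = TRUE)
  }
  keep <- score > 0L
  snp_scores <- data.frame(chrom = vm$chrom[cand[keep]], pos = vm$pos[cand[keep]],
                           count = score[keep])
  if (nrow(snp_scores)) {
    bin <- floor((snp_scores$pos - 1) / bin_bp) * bin_bp
    agg <- stats::aggregate(count ~ chrom + bin,
                            data = cbind(snp_scores, bin = bin), FUN = sum)
    bins <- data.frame(chrom = agg$chrom, bin_start = agg$bin, count = agg$count)
    bins <- bins[order(bins$chrom, bins$bin_start), ]
    rownames(bins) <- NULL
  } else {
    bins <- data.frame(chrom = character(0), bin_start = numeric(0),
                       count = integer(0))
  }
  structure(list(bins = bins, snp_scores = snp_scores,
                 total_interactions = sum(score),
                 n_zero_variance = n_zero_var,
                 n_mac_filtered = sum(!mac_ok),
                 params = list(r2_min = r2_min, near_bp = near_bp,
                               far_bp = far_bp, bin_bp = bin_bp,
                               min_mac = min_mac),
                 locus = locus),
            class = "linkage_histogram")
}

#' @export
print.linkage_histogram <- function(x, ...) {
  cat("LinkageHistogram:", nrow(x$bins), "non-empty bins,",
      x$total_interactions, "interactions (r2 >", x$params$r2_min, ")\n")
  if (nrow(x$bins)) {
    top <- x$bins[order(-x$bins$count), ][1:min(5, nrow(x$bins)), ]
    cat("  top bins:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Annotate histogram bins with overlapping genes
#'
#' Each non-empty bin lists the genes whose half-open interval overlaps
#' the bin; a gene straddling a bin boundary annotates both bins.
#'
#' @param hist a `linkage_histogram`.
#' @param genes an [interval_set()] of gene coordinates.
#' @return the histogram with a `genes` column added to `bins`.
#' @export
annotate_histogram <- function(hist, genes) {
  bins <- hist$bins
  unmatched <- setdiff(unique(genes$chrom), unique(bins$chrom))
  if (length(unmatched) && nrow(bins))
    warning("gene chromosomes not present in histogram: ",
            paste(unmatched, collapse = ", "))
  bin_bp <- hist$params$bin_bp
  bins$genes <- vapply(seq_len(nrow(bins)), function(i) {
    hit <- genes$chrom == bins$chrom[i] &
      genes$start < bins$bin_start[i] + bin_bp &
      genes$end > bins$bin_start[i]
    paste(genes$name[hit], collapse = ",")
  }, character(1))
  hist$bins <- bins
  hist
}
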