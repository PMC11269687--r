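## Windowed population-genetic statistics --------------------------------
##
## Window conventions follow the VCFtools defaults used throughout the
## field: Tajima's D in half-open 5-kb bins on 0-based coordinates,
## per-site nucleotide diversity, genotype-correlation r2 with distance
## bounds, and Weir-Cockerham FST per SNP plus the windowed
## ratio-of-sums form over sliding windows.  All statistics run on
## un-imputed matrices; missing calls are excluded per site.

.new_track <- function(statistic, records) {
  rownames(records) <- NULL
  structure(records, statistic = statistic,
            class = c("WindowedStatTrack", "data.frame"))
}

#' @export
print.WindowedStatTrack <- function(x, ...) {
  cat("WindowedStatTrack (", attr(x, "statistic"), "): ", nrow(x),
      " windows on ", length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  NextMethod()
}

.resolve_subset <- function(vm, subset) {
  if (is.null(subset)) return(seq_along(vm$samples))
  si <- if (is.character(subset)) match(subset, vm$samples) else seq_along(vm$samples)[subset]
  if (anyNA(si)) stop("unknown sample ids in subset")
  si
}

#' Per-site nucleotide diversity
#'
#' For each SNP, `pi = 2 p (1 - p) n / (n - 1)` where `p` is the alt
#' allele frequency and `n` the called allele count in the subset --
#' the fraction of mismatching pairs among all pairs of called alleles.
#' Sites with fewer than two called alleles are skipped (value `NA`) and
#' counted in the `"n_skipped"` attribute.
#'
#' @param vm a `VariantMatrix`.
#' @param subset sample ids or index (default: all); at least 2 samples.
#' @return data frame `chrom`, `pos`, `pi`, `n_alleles`.
#' @export
site_pi <- function(vm, subset = NULL) {
  si <- .resolve_subset(vm, subset)
  if (length(si) < 2) stop("site_pi needs at least 2 samples")
  g <- vm$genotypes[si, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  an <- 2 * n_called
  ac <- colSums(g, na.rm = TRUE)
  p <- ac / an
  # a site called in a single individual carries no between-individual
  # information; it is skipped like an uncalled site
  pi <- ifelse(n_called >= 2, 2 * p * (1 - p) * an / (an - 1), NA_real_)
  out <- data.frame(chrom = vm$chrom, pos = vm$pos, pi = pi, n_alleles = an)
  attr(out, "n_skipped") <- sum(n_called < 2)
  out
}

# Tajima's constants a1, a2, b1, b2, c1, c2, e1, e2 for n sequences.
.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, e1 = e1, e2 = e2)
}

#' Tajima's D in fixed bins
#'
#' Per half-open bin `[k b, (k+1) b)` of 0-based coordinates: `S` is the
#' segregating site count, `k_hat` the summed per-site pairwise
#' difference values, and `D = (k_hat - S/a1) / sqrt(e1 S + e2 S(S-1))`
#' with Tajima's standard constants evaluated at the modal per-site
#' called-allele count in the bin.  Bins holding sites but no
#' segregating site are emitted with value `NA`; bins without usable
#' sites are not emitted.
#'
#' @param vm a `VariantMatrix`.
#' @param subset sample ids or index (default: all); at least 4 samples.
#' @param bin_size bin width in bp (default 5000).
#' @return a `WindowedStatTrack`.
#' @export
tajimas_d <- function(vm, subset = NULL, bin_size = 5000) {
  if (bin_size <= 0) stop("bin_size must be positive")
  si <- .resolve_subset(vm, subset)
  if (length(si) < 4) stop("tajimas_d needs at least 4 samples")
  g <- vm$genotypes[si, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  an <- 2 * n_called
  ac <- colSums(g, na.rm = TRUE)
  usable <- n_called >= 2
  p <- ac / an
  pi_site <- 2 * p * (1 - p) * an / pmax(an - 1, 1)
  seg <- usable & ac > 0 & ac < an
  bin <- floor((vm$pos - 1) / bin_size)
  key <- paste(vm$chrom, bin)
  groups <- split(which(usable), key[usable])
  vals <- vapply(groups, function(idx) {
    S <- sum(seg[idx])
    n_modal <- as.integer(names(which.max(table(an[idx]))))
    if (S == 0 || n_modal < 4) return(NA_real_)
    cst <- .tajima_constants(n_modal)
    khat <- sum(pi_site[idx][seg[idx]])
    (khat - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  }, numeric(1))
  firsts <- vapply(groups, `[`, integer(1), 1L)
  out <- data.frame(chrom = vm$chrom[firsts],
                    win_start = bin[firsts] * bin_size,
                    win_end = (bin[firsts] + 1) * bin_size,
                    value = as.numeric(vals),
                    n_sites = lengths(groups),
                    n_samples_used = length(si))
  out <- out[order(out$chrom, out$win_start), ]
  .new_track("D", out)
}

#' Binned nucleotide diversity
#'
#' Mean per-site diversity ([site_pi()]) over the usable sites of each
#' half-open bin; the per-bin companion to [tajimas_d()].
#'
#' @inheritParams tajimas_d
#' @return a `WindowedStatTrack`.
#' @export
binned_pi <- function(vm, subset = NULL, bin_size = 5000) {
  if (bin_size <= 0) stop("bin_size must be positive")
  sp <- site_pi(vm, subset)
  si <- .resolve_subset(vm, subset)
  ok <- !is.na(sp$pi)
  bin <- floor((sp$pos - 1) / bin_size)
  key <- paste(sp$chrom, bin)
  groups <- split(which(ok), key[ok])
  firsts <- vapply(groups, `[`, integer(1), 1L)
  out <- data.frame(chrom = sp$chrom[firsts],
                    win_start = bin[firsts] * bin_size,
                    win_end = (bin[firsts] + 1) * bin_size,
                    value = vapply(groups, function(idx) mean(sp$pi[idx]), numeric(1)),
                    n_sites = lengths(groups),
                    n_samples_used = length(si))
  out <- out[order(out$chrom, out$win_start), ]
  .new_track("pi", out)
}

#' Genotype-correlation linkage disequilibrium (r2)
#'
#' `r2` is the squared Pearson correlation of the dosage vectors of two
#' SNPs over the samples non-missing at both.  Same-chromosome pairs are
#' reported only when separated by `[min_bp, max_bp]`; when
#' `interchrom = TRUE` cross-chromosome pairs are included (distance
#' bounds do not apply to them).  Pairs with a zero-variance member are
#' skipped and counted in the `"n_skipped"` attribute.
#'
#' @param vm a `VariantMatrix`.
#' @param subset sample ids or index (default: all); at least 2 samples.
#' @param min_bp minimum same-chromosome separation (default 500, which
#'   avoids comparisons inside a single RAD tag).
#' @param max_bp maximum same-chromosome separation (default 100 kb);
#'   `Inf` removes the cap.
#' @param interchrom also compute cross-chromosome pairs (default FALSE).
#' @return data frame `chrom_i`, `pos_i`, `chrom_j`, `pos_j`, `r2` of
#'   class `PairwiseLD`.
#' @export
genotype_r2 <- function(vm, subset = NULL, min_bp = 500, max_bp = 1e5,
                        interchrom = FALSE) {
  si <- .resolve_subset(vm, subset)
  if (length(si) < 2) stop("genotype_r2 needs at least 2 samples")
  g <- vm$genotypes[si, , drop = FALSE]
  ii <- integer(0); jj <- integer(0)
  for (ch in unique(vm$chrom)) {
    idx <- which(vm$chrom == ch)
    p <- as.numeric(vm$pos[idx])
    # for each i, j ranges over positions within [p_i + min_bp, p_i + max_bp]
    lo <- findInterval(p + min_bp - 1e-9, p) + 1L
    lo <- pmax(lo, seq_along(p) + 1L)     # strictly later SNP: each pair once
    hi <- if (is.finite(max_bp)) findInterval(p + max_bp + 1e-9, p)
          else rep(length(p), length(p))
    hi <- pmin(hi, length(p))
    cnt <- pmax(hi - lo + 1L, 0L)
    keep <- cnt > 0L
    if (!any(keep)) next
    ii <- c(ii, idx[rep(which(keep), cnt[keep])])
    jj <- c(jj, idx[unlist(lapply(which(keep), function(i) lo[i]:hi[i]))])
  }
  if (interchrom) {
    chroms <- unique(vm$chrom)
    if (length(chroms) > 1) {
      for (a in seq_len(length(chroms) - 1)) for (b in (a + 1):length(chroms)) {
        ia <- which(vm$chrom == chroms[a]); ib <- which(vm$chrom == chroms[b])
        ii <- c(ii, rep(ia, each = length(ib)))
        jj <- c(jj, rep(ib, times = length(ia)))
      }
    }
  }
  if (!length(ii)) {
    out <- data.frame(chrom_i = character(0), pos_i = integer(0),
                      chrom_j = character(0), pos_j = integer(0), r2 = numeric(0))
    attr(out, "n_skipped") <- 0L
    class(out) <- c("PairwiseLD", "data.frame")
    return(out)
  }
  r2 <- .pairwise_r2_pairs(g, ii, jj)
  skipped <- sum(is.na(r2))
  ok <- !is.na(r2)
  out <- data.frame(chrom_i = vm$chrom[ii[ok]], pos_i = vm$pos[ii[ok]],
                    chrom_j = vm$chrom[jj[ok]], pos_j = vm$pos[jj[ok]],
                    r2 = pmin(r2[ok], 1))
  attr(out, "n_skipped") <- skipped
  class(out) <- c("PairwiseLD", "data.frame")
  out
}

# Weir & Cockerham (1984) per-SNP variance components for two groups.
# Returns a data frame with components a (among), and d = a + b + c.
.wc_components <- function(g_list) {
  r <- length(g_list)
  n_i <- sapply(g_list, function(g) colSums(!is.na(g)))          # individuals
  p_i <- sapply(g_list, function(g) colSums(g, na.rm = TRUE)) / (2 * n_i)
  h_i <- sapply(g_list, function(g) colMeans(g == 1L, na.rm = TRUE))
  nbar <- rowMeans(n_i)
  ntot <- rowSums(n_i)
  nc <- (ntot - rowSums(n_i^2) / ntot) / (r - 1)
  pbar <- rowSums(n_i * p_i) / ntot
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / ntot
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  data.frame(a = a, d = a + b + c_, n1 = n_i[, 1], n2 = n_i[, 2])
}

#' Weir-Cockerham FST, per SNP and in sliding windows
#'
#' Per SNP the among-population variance component `a` and total
#' `a + b + c` are computed from group allele frequencies, sample sizes
#' and observed heterozygosities; `theta = a / (a + b + c)` (negative
#' estimates are retained, not clipped).  The windowed value is the
#' ratio of sums `sum(a) / sum(a + b + c)` over the SNPs of each sliding
#' window; windows without SNPs are omitted.
#'
#' @param vm a `VariantMatrix`.
#' @param group_a,group_b disjoint sample id vectors, each of size >= 2.
#' @param window,step sliding-window size and step in bp (defaults 5000 / 1000).
#' @return list with `per_snp` (data frame `chrom`, `pos`, `fst`) and
#'   `windowed` (a `WindowedStatTrack`).
#' @export
wc_fst <- function(vm, group_a, group_b, window = 5000, step = 1000) {
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  ia <- .resolve_subset(vm, group_a); ib <- .resolve_subset(vm, group_b)
  if (length(ia) < 2 || length(ib) < 2) stop("each group needs at least 2 samples")
  comp <- .wc_components(list(vm$genotypes[ia, , drop = FALSE],
                              vm$genotypes[ib, , drop = FALSE]))
  ok <- is.finite(comp$a) & is.finite(comp$d) & comp$n1 >= 1 & comp$n2 >= 1
  per_snp <- data.frame(chrom = vm$chrom, pos = vm$pos,
                        fst = ifelse(ok & comp$d != 0, comp$a / comp$d, NA_real_))
  recs <- NULL
  for (ch in unique(vm$chrom)) {
    idx <- which(vm$chrom == ch & ok)
    if (!length(idx)) next
    pos0 <- as.numeric(vm$pos[idx]) - 1
    a <- comp$a[idx]; d <- comp$d[idx]
    o <- order(pos0); pos0 <- pos0[o]; a <- a[o]; d <- d[o]
    ca <- c(0, cumsum(a)); cd <- c(0, cumsum(d)); cn <- 0:length(a)
    k_min <- max(0, floor((min(pos0) - window + step) / step))
    k_max <- floor(max(pos0) / step)
    starts <- (k_min:k_max) * step
    ilo <- findInterval(starts - 1e-9, pos0) + 1L
    ihi <- findInterval(starts + window - 1 + 1e-9, pos0)
    nwin <- cn[ihi + 1L] - cn[ilo]
    keep <- nwin > 0
    sum_a <- ca[ihi + 1L] - ca[ilo]
    sum_d <- cd[ihi + 1L] - cd[ilo]
    recs <- rbind(recs, data.frame(chrom = ch, win_start = starts[keep],
                                   win_end = starts[keep] + window,
                                   value = ifelse(sum_d[keep] != 0,
                                                  sum_a[keep] / sum_d[keep], NA_real_),
                                   n_sites = nwin[keep],
                                   n_samples_used = length(ia) + length(ib)))
  }
  list(per_snp = per_snp, windowed = .new_track("fst", recs))
}

#' Simple moving average over a statistic track
#'
#' Unweighted mean over the preceding `span` records within each
#' chromosome (the SMA convention used for visualising windowed
#' statistics).  The first `span - 1` records of each chromosome are
#' undefined; `NA` values inside a window are excluded from its mean.
#'
#' @param track a `WindowedStatTrack`.
#' @param span number of records to average (default 100).
#' @return a `WindowedStatTrack` with smoothed values.
#' @export
moving_average <- function(track, span = 100) {
  if (span < 1) stop("span must be at least 1")
  out <- track
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    v <- track$value[idx]
    vv <- ifelse(is.na(v), 0, v)
    nn <- as.numeric(!is.na(v))
    cs <- c(0, cumsum(vv)); cn <- c(0, cumsum(nn))
    n <- length(v)
    res <- rep(NA_real_, n)
    if (n >= span) {
      i <- span:n
      tot <- cs[i + 1] - cs[i - span + 1]
      cnt <- cn[i + 1] - cn[i - span + 1]
      res[i] <- ifelse(cnt > 0, tot / cnt, NA_real_)
    }
    out$value[idx] <- res
  }
  .new_track(paste0(attr(track, "statistic"), "_sma"), out)
}
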