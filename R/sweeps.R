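## Sweep-background identification and characterisation ------------------
##
## Backgrounds are sets of individuals sharing an extended swept
## haplotype at a locus, found by (i) PCA + k-means clustering of
## focal-mutation homozygotes on outlier-SNP dosages and (ii) screening
## for shared homozygous multi-SNP haplotypes.  Backgrounds are then
## characterised against a wild-type cohort via differences in Tajima's
## D, nucleotide diversity and moving-averaged r2, and against each
## other via windowed Weir-Cockerham FST.

#' PCA + k-means clustering of focal homozygotes at outlier SNPs
#'
#' PCA is run on the outlier-SNP dosage submatrix of the homozygous
#' individuals (mean-filled for missing calls); seeded k-means with 50
#' restarts on the first two components assigns clusters.  Individuals
#' whose distance to their centroid exceeds the given quantile of
#' within-cluster distances are flagged uncertain -- these are typically
#' recombined or data-poor individuals lying toward the centre of the
#' PCA.
#'
#' @param vm a `VariantMatrix`.
#' @param outliers SNP index vector (e.g. from [select_outliers()]).
#' @param k_clusters number of clusters.
#' @param samples homozygote sample ids; defaults to samples whose
#'   focal-mutation genotype is `"hom-alt"`.
#' @param seed RNG seed for k-means restarts.
#' @param uncertainty_quantile distance quantile beyond which members
#'   are flagged uncertain (default 0.9).
#' @return data frame `sample`, `cluster`, `pc1`, `pc2`, `uncertain`.
#' @export
pca_cluster_homozygotes <- function(vm, outliers, k_clusters, samples = NULL,
                                    seed = 1L, uncertainty_quantile = 0.9) {
  if (!length(outliers)) stop("outlier SNP set is empty")
  if (is.null(samples)) samples <- vm$samples[vm$focal == "hom-alt"]
  if (length(samples) < k_clusters)
    stop("fewer homozygous individuals (", length(samples),
         ") than clusters (", k_clusters, ")")
  sub <- subset_variants(vm, samples = samples, snps = outliers)
  X <- .centred_dosage(sub)
  if (all(abs(X) < 1e-12)) {
    # zero-variance input: everyone identical
    return(data.frame(sample = samples, cluster = 1L, pc1 = 0, pc2 = 0,
                      uncertain = FALSE, stringsAsFactors = FALSE))
  }
  sv <- svd(X, nu = 2, nv = 0)
  scores <- sv$u %*% diag(sv$d[1:2], 2, 2)
  if (k_clusters == 1L) {
    km <- list(cluster = rep(1L, length(samples)),
               centers = matrix(colMeans(scores), 1))
  } else {
    km <- .with_seed(seed, stats::kmeans(scores, centers = k_clusters, nstart = 50))
  }
  d <- sqrt(rowSums((scores - km$centers[km$cluster, , drop = FALSE])^2))
  cut <- stats::quantile(d, uncertainty_quantile)
  data.frame(sample = samples, cluster = km$cluster,
             pc1 = scores[, 1], pc2 = scores[, 2],
             uncertain = d > cut, stringsAsFactors = FALSE)
}

#' Screen for shared homozygous multi-SNP haplotypes
#'
#' Strict members are homozygous and non-missing at every screen SNP and
#' are grouped by their homozygous haplotype string.  Relaxed members
#' have at most `max_deviation` heterozygous-or-missing screen sites and
#' are attached to the unique strict haplotype consistent with their
#' remaining sites; ambiguous individuals stay unassigned.
#'
#' @param vm a `VariantMatrix`.
#' @param screen_snps non-empty SNP index vector.
#' @param max_deviation maximum heterozygous-or-missing screen sites for
#'   relaxed membership (default 1).
#' @return list of class `sweep_screen` with `members` (data frame
#'   `sample`, `haplotype`, `mode`, `n_deviant`) and `haplotypes`
#'   (per-haplotype strict/relaxed counts).  Unassigned samples are
#'   absent from `members`.
#' @export
haplotype_screen <- function(vm, screen_snps, max_deviation = 1) {
  if (!length(screen_snps)) stop("screen SNP set is empty")
  G <- vm$genotypes[, screen_snps, drop = FALSE]
  deviant <- is.na(G) | G == 1L
  n_dev <- rowSums(deviant)
  hap_char <- matrix(".", nrow(G), ncol(G))
  hap_char[!deviant] <- as.character(G[!deviant] / 2L)
  strict <- which(n_dev == 0L)
  if (!length(strict))
    return(structure(list(members = data.frame(sample = character(0),
                                               haplotype = character(0),
                                               mode = character(0),
                                               n_deviant = integer(0)),
                          haplotypes = data.frame(haplotype = character(0),
                                                  n_strict = integer(0),
                                                  n_relaxed = integer(0))),
                     class = "sweep_screen"))
  strict_hap <- apply(hap_char[strict, , drop = FALSE], 1, paste, collapse = "")
  uniq <- unique(strict_hap)
  members <- data.frame(sample = vm$samples[strict], haplotype = strict_hap,
                        mode = "strict", n_deviant = 0L,
                        stringsAsFactors = FALSE)
  uniq_mat <- do.call(rbind, strsplit(uniq, ""))
  relaxed <- which(n_dev > 0L & n_dev <= max_deviation)
  for (i in relaxed) {
    obs <- hap_char[i, ]
    informative <- obs != "."  & !deviant[i, ]
    consistent <- vapply(seq_along(uniq), function(u)
      all(uniq_mat[u, informative] == obs[informative]), logical(1))
    if (sum(consistent) == 1L)
      members <- rbind(members,
                       data.frame(sample = vm$samples[i],
                                  haplotype = uniq[consistent],
                                  mode = "relaxed", n_deviant = n_dev[i],
                                  stringsAsFactors = FALSE))
  }
  haps <- data.frame(haplotype = uniq,
                     n_strict = as.integer(table(factor(members$haplotype[members$mode == "strict"], uniq))),
                     n_relaxed = as.integer(table(factor(members$haplotype[members$mode == "relaxed"], uniq))),
                     stringsAsFactors = FALSE)
  haps <- haps[order(-haps$n_strict), ]
  rownames(haps) <- NULL
  structure(list(members = members, haplotypes = haps), class = "sweep_screen")
}

#' @export
print.sweep_screen <- function(x, ...) {
  cat("Haplotype screen:", nrow(x$haplotypes), "strict haplotype group(s),",
      nrow(x$members), "assigned individuals\n")
  print(utils::head(x$haplotypes, 10))
  invisible(x)
}

#' Delta statistics of a sweep background against a wild-type cohort
#'
#' Computes `delta X(window) = X_background - X_wildtype` for binned
#' Tajima's D and nucleotide diversity, and the difference of
#' moving-averaged r2 profiles (pairs bounded by the usual distance
#' rules, assigned to bins by their midpoint).  Windows undefined in
#' either cohort are undefined in the difference.
#'
#' @param vm a `VariantMatrix`.
#' @param members background sample ids.
#' @param wildtype wild-type sample ids, disjoint from `members`; both
#'   cohorts need >= 4 samples.
#' @param chrom chromosome to profile.
#' @param bin_size D/pi bin width (default 5000).
#' @param ld_min_bp,ld_max_bp r2 distance bounds (defaults 500 / 100 kb).
#' @param ld_bin_bp bin width for the r2 profile (default 100 kb).
#' @param ld_span centred rolling-window span, in bins, for the
#'   pair-count-weighted r2 profile (default 40, about twice the expected
#'   swept tract length at the default bin width).
#' @param ld_min_pairs minimum r2 pairs per rolling window for the
#'   profile to be defined there (default 20).
#' @return list of class `delta_profile` with tracks `delta_d`,
#'   `delta_pi`, `delta_ld`.
#' @export
delta_stats <- function(vm, members, wildtype, chrom, bin_size = 5000,
                        ld_min_bp = 500, ld_max_bp = 1e5, ld_bin_bp = 1e5,
                        ld_span = 40, ld_min_pairs = 20) {
  if (length(intersect(members, wildtype)))
    stop("background and wild-type sets must be disjoint")
  if (length(members) < 4 || length(wildtype) < 4)
    stop("each cohort needs at least 4 samples")
  on_chrom <- vm$chrom == chrom
  if (!any(on_chrom)) stop("chromosome not present: ", chrom)
  sub <- subset_variants(vm, snps = on_chrom)
  d_bg <- tajimas_d(sub, members, bin_size)
  d_wt <- tajimas_d(sub, wildtype, bin_size)
  pi_bg <- binned_pi(sub, members, bin_size)
  pi_wt <- binned_pi(sub, wildtype, bin_size)
  ld_bg <- .ld_profile(sub, members, ld_min_bp, ld_max_bp, ld_bin_bp,
                       ld_span, ld_min_pairs)
  ld_wt <- .ld_profile(sub, wildtype, ld_min_bp, ld_max_bp, ld_bin_bp,
                       ld_span, ld_min_pairs)
  structure(list(delta_d = .track_difference(d_bg, d_wt, "delta_D"),
                 delta_pi = .track_difference(pi_bg, pi_wt, "delta_pi"),
                 delta_ld = .track_difference(ld_bg, ld_wt, "delta_LD")),
            class = "delta_profile")
}

# Smoothed r2 profile: pairs are assigned to bins by midpoint position,
# then a centred rolling window of `span` bins takes the
# pair-count-weighted mean r2, so sparse bins cannot dominate the
# profile.  Windows with fewer than `min_pairs` pairs are undefined.
.ld_profile <- function(vm, subset, min_bp, max_bp, bin_bp, span, min_pairs) {
  ld <- genotype_r2(vm, subset, min_bp = min_bp, max_bp = max_bp)
  ch <- unique(vm$chrom)[1]
  if (!nrow(ld)) {
    return(.new_track("ld", data.frame(chrom = character(0), win_start = numeric(0),
                                       win_end = numeric(0), value = numeric(0),
                                       n_sites = integer(0), n_samples_used = integer(0))))
  }
  mid <- (as.numeric(ld$pos_i) + as.numeric(ld$pos_j)) / 2
  bin <- floor((mid - 1) / bin_bp)
  grid <- min(bin):max(bin)
  s <- tapply(ld$r2, factor(bin, levels = grid), sum)
  n <- tapply(rep(1, nrow(ld)), factor(bin, levels = grid), sum)
  s[is.na(s)] <- 0; n[is.na(n)] <- 0
  half <- floor(span / 2)
  cs <- c(0, cumsum(s)); cn <- c(0, cumsum(n))
  i <- seq_along(grid)
  lo <- pmax(i - half, 1L); hi <- pmin(i + half, length(grid))
  tot <- cs[hi + 1] - cs[lo]
  cnt <- cn[hi + 1] - cn[lo]
  val <- ifelse(cnt >= min_pairs, tot / pmax(cnt, 1), NA_real_)
  recs <- data.frame(chrom = ch, win_start = grid * bin_bp,
                     win_end = (grid + 1) * bin_bp, value = val,
                     n_sites = as.integer(cnt),
                     n_samples_used = NA_integer_)
  .new_track("ld", recs)
}

# Align two tracks on the union of their window frames and subtract.
.track_difference <- function(ta, tb, name) {
  key_a <- paste(ta$chrom, ta$win_start)
  key_b <- paste(tb$chrom, tb$win_start)
  keys <- union(key_a, key_b)
  src <- rbind(ta[c("chrom", "win_start", "win_end")],
               tb[c("chrom", "win_start", "win_end")])
  src <- src[match(keys, c(key_a, key_b)), ]
  va <- ta$value[match(keys, key_a)]
  vb <- tb$value[match(keys, key_b)]
  recs <- data.frame(chrom = src$chrom, win_start = src$win_start,
                     win_end = src$win_end, value = va - vb,
                     n_sites = pmin(ta$n_sites[match(keys, key_a)],
                                    tb$n_sites[match(keys, key_b)], na.rm = FALSE),
                     n_samples_used = NA_integer_)
  recs$n_sites[is.na(recs$n_sites)] <- 1L
  recs <- recs[order(recs$chrom, recs$win_start), ]
  .new_track(name, recs)
}

#' @export
print.delta_profile <- function(x, ...) {
  for (nm in names(x)) {
    t <- x[[nm]]
    cat(sprintf("%-9s: %d windows, min %.4f at %s:%d\n", nm, nrow(t),
                suppressWarnings(min(t$value, na.rm = TRUE)),
                t$chrom[which.min(t$value)], t$win_start[which.min(t$value)]))
  }
  invisible(x)
}

#' Scan-to-screen pipeline: recover sweep backgrounds at a locus
#'
#' Runs one latent-factor genome scan per focal dosage vector, takes the
#' outliers (adjusted p below the inverse of the tested SNP count) that
#' fall inside the locus interval, pools them across scans into the
#' screen set, and screens for shared homozygous haplotypes.  When
#' thresholding leaves fewer than `min_screen` screen SNPs the set is
#' topped up with the most strongly associated in-locus SNPs, since a
#' degenerate one- or two-SNP screen cannot separate backgrounds from
#' chance homozygosity.
#'
#' @param vm a `VariantMatrix`.
#' @param focals named list of per-sample focal dosage vectors (one per
#'   focal mutation), each as accepted by [lfmm_scan()].
#' @param K latent factor count for the scans.
#' @param locus one-row [interval_set()] around the sweep locus.
#' @param maf scan minor-allele-frequency cut-off (default 0.05).
#' @param min_screen minimum screen-set size (default 8).
#' @param max_deviation relaxed-membership allowance (default 1).
#' @param min_strict minimum strict members for a haplotype group to be
#'   called a sweep background (default 5); smaller groups are usually
#'   chance homozygosity rather than a shared swept haplotype.
#' @return list with `scans`, `threshold`, `screen_snps` (SNP index),
#'   `screen` (a `sweep_screen`), `backgrounds` (haplotype ids of the
#'   groups large enough to call) and `members` (their member table).
#' @export
recover_backgrounds <- function(vm, focals, K, locus, maf = 0.05,
                                min_screen = 8, max_deviation = 1,
                                min_strict = 5) {
  scans <- lapply(focals, function(f) lfmm_scan(vm, f, K = K, maf = maf))
  threshold <- outlier_threshold(sum(scans[[1]]$tested))
  dist <- .interval_distance(vm$chrom, vm$pos, locus$chrom[1],
                             locus$start[1], locus$end[1])
  in_locus <- which(!is.na(dist) & dist == 0)
  screen_snps <- integer(0)
  for (sc in scans) {
    out <- which(!is.na(sc$p_adj) & sc$p_adj < threshold)
    screen_snps <- union(screen_snps, intersect(out, in_locus))
  }
  if (length(screen_snps) < min_screen) {
    cand <- in_locus[scans[[1]]$tested[in_locus]]
    best_p <- do.call(pmin, c(lapply(scans, function(sc) sc$p_adj[cand]),
                              list(na.rm = TRUE)))
    top <- cand[order(best_p)][seq_len(min(min_screen, length(cand)))]
    screen_snps <- union(screen_snps, top)
  }
  screen_snps <- sort(screen_snps)
  screen <- haplotype_screen(vm, screen_snps, max_deviation = max_deviation)
  backgrounds <- screen$haplotypes$haplotype[screen$haplotypes$n_strict >= min_strict]
  list(scans = scans, threshold = threshold, screen_snps = screen_snps,
       screen = screen, backgrounds = backgrounds,
       members = screen$members[screen$members$haplotype %in% backgrounds, ])
}

#' Windowed FST between two sweep backgrounds
#'
#' Wraps [wc_fst()] between the member sets, returns per-SNP values
#' above the highlight threshold with coordinates, and reports the
#' genome-wide and per-chromosome window maxima.
#'
#' @param vm a `VariantMatrix`.
#' @param members_a,members_b disjoint background member sets (>= 2 each).
#' @param window,step sliding-window parameters (defaults 5000 / 1000).
#' @param highlight per-SNP FST highlight threshold (default 0.25).
#' @return list with `windowed` track, `per_snp`, `highlighted`
#'   (per-SNP values above threshold), `max_window` (genome-wide) and
#'   `chrom_max` (per chromosome).
#' @export
pairwise_background_fst <- function(vm, members_a, members_b, window = 5000,
                                    step = 1000, highlight = 0.25) {
  res <- wc_fst(vm, members_a, members_b, window = window, step = step)
  hi <- res$per_snp[!is.na(res$per_snp$fst) & res$per_snp$fst > highlight, ]
  w <- res$windowed
  defined <- which(!is.na(w$value))
  best <- defined[which.max(w$value[defined])]
  chrom_max <- do.call(rbind, lapply(split(w[defined, ], w$chrom[defined]), function(d)
    d[which.max(d$value), ]))
  list(windowed = w, per_snp = res$per_snp, highlighted = hi,
       max_window = w[best, ], chrom_max = chrom_max)
}
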