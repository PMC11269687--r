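## Read-depth copy-number ratios -----------------------------------------
##
## Copy number at a target gene region (e.g. a GST epsilon cluster) is
## inferred per individual as the ratio of mean read depth at sites
## inside the coding intervals to the mean depth at sites within a
## 10-Mb flank upstream and downstream of the region span.  Sites below
## 1X depth are excluded per sample, and samples with fewer than 500
## retained coding sites are omitted, mirroring standard practice for
## reduced-representation depth data.

#' Per-sample depth ratio at a coding region
#'
#' @param depths a `DepthMatrix` covering the region and its flanks.
#' @param coding an [interval_set()] of coding intervals, all on one
#'   chromosome.
#' @param flank_bp flank width on each side of the outermost coding
#'   span (default 10 Mb); the span interior is excluded from the flank.
#' @param min_sites minimum retained coding sites per sample (default 500).
#' @param min_depth per-sample site inclusion threshold (default 1X).
#' @param regions optional named map sample -> region label for group
#'   summaries.
#' @param equal_flank_weight average the upstream and downstream window
#'   means instead of pooling their sites (default FALSE: pooled).
#' @return data frame of class `depth_ratio_result` with per-sample
#'   `n_coding_sites`, `mean_coding_depth`, `mean_flank_depth`,
#'   `flank_up_mean`, `flank_down_mean`, `ratio`, `included`; group
#'   summaries in attribute `"groups"` when `regions` is given.
#' @export
depth_ratio <- function(depths, coding, flank_bp = 1e7, min_sites = 500,
                        min_depth = 1, regions = NULL,
                        equal_flank_weight = FALSE) {
  if (!nrow(coding)) stop("coding interval set is empty")
  if (length(unique(coding$chrom)) != 1)
    stop("coding intervals must lie on a single chromosome")
  ch <- coding$chrom[1]
  span_start <- min(coding$start); span_end <- max(coding$end)
  pos0 <- depths$pos - 1
  on_ch <- depths$chrom == ch
  in_coding <- on_ch & .in_intervals(depths$chrom, depths$pos, coding)
  up <- on_ch & pos0 >= span_start - flank_bp & pos0 < span_start
  down <- on_ch & pos0 >= span_end & pos0 < span_end + flank_bp
  if (!any(up | down)) stop("no flank sites within ", flank_bp, " bp of the region")
  D <- depths$depth
  out <- data.frame(sample = depths$samples, n_coding_sites = NA_integer_,
                    mean_coding_depth = NA_real_, mean_flank_depth = NA_real_,
                    flank_up_mean = NA_real_, flank_down_mean = NA_real_,
                    ratio = NA_real_, included = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(depths$samples)) {
    keep <- !is.na(D[i, ]) & D[i, ] >= min_depth
    cod <- which(keep & in_coding)
    u <- which(keep & up); dn <- which(keep & down)
    out$n_coding_sites[i] <- length(cod)
    if (length(cod)) out$mean_coding_depth[i] <- mean(D[i, cod])
    if (length(u)) out$flank_up_mean[i] <- mean(D[i, u])
    if (length(dn)) out$flank_down_mean[i] <- mean(D[i, dn])
    fl <- if (equal_flank_weight)
      mean(c(out$flank_up_mean[i], out$flank_down_mean[i]), na.rm = TRUE)
    else if (length(u) + length(dn) > 0) mean(D[i, c(u, dn)]) else NA_real_
    out$mean_flank_depth[i] <- fl
    ok <- length(cod) >= min_sites && !is.na(fl) && fl > 0
    out$included[i] <- ok
    if (ok) out$ratio[i] <- out$mean_coding_depth[i] / fl
  }
  if (!is.null(regions)) {
    inc <- out[out$included, ]
    lab <- regions[inc$sample]
    groups <- data.frame(region = names(tapply(inc$ratio, lab, mean)),
                         mean_ratio = as.numeric(tapply(inc$ratio, lab, mean)),
                         n = as.integer(table(lab)[names(tapply(inc$ratio, lab, mean))]))
    attr(out, "groups") <- groups
  }
  class(out) <- c("depth_ratio_result", "data.frame")
  out
}

#' Upstream/downstream flank depth consistency
#'
#' Squared Pearson correlation, across included samples, of the
#' per-sample upstream and downstream flank mean depths.  Both flanks
#' scale with the same per-individual sequencing effort, so values near
#' 1 indicate the flanks are a sound copy-number baseline.
#'
#' @param result a `depth_ratio_result`.
#' @return R^2, or `NA` with a warning when fewer than 3 samples have
#'   both flank means.
#' @export
flank_consistency <- function(result) {
  ok <- result$included & !is.na(result$flank_up_mean) &
    !is.na(result$flank_down_mean)
  if (sum(ok) < 3) {
    warning("fewer than 3 samples with both flank means; R^2 undefined")
    return(NA_real_)
  }
  stats::cor(result$flank_up_mean[ok], result$flank_down_mean[ok])^2
}

#' One-way ANOVA of depth ratios across groups
#'
#' Fixed-effects one-way ANOVA of the included samples' ratios on a
#' grouping label (typically geographic region), with degrees of
#' freedom `(groups - 1, n - groups)`.  A grouping with zero
#' within-group variance yields an infinite F and p of 0.
#'
#' @param result a `depth_ratio_result`.
#' @param grouping named map sample -> group label.
#' @return list `F`, `df_between`, `df_within`, `p`.
#' @export
group_anova <- function(result, grouping) {
  inc <- result[result$included & !is.na(result$ratio), ]
  g <- factor(grouping[inc$sample])
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need at least 2 groups with at least 2 included samples each")
  fit <- stats::lm(inc$ratio ~ g)
  an <- stats::anova(fit)
  Fv <- an$`F value`[1]
  df_b <- an$Df[1]; df_w <- an$Df[2]
  p <- an$`Pr(>F)`[1]
  ssb <- an$`Sum Sq`[1]; ssw <- an$`Sum Sq`[2]
  if (!is.finite(Fv) || ssw <= 1e-12 * (ssb + ssw)) {
    # zero within-group variance: the contrast is exact, F diverges
    if (ssb > 0) { Fv <- Inf; p <- 0 } else { Fv <- NaN; p <- NA_real_ }
  }
  list(F = Fv, df_between = df_b, df_within = df_w, p = p)
}
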