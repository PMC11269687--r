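## Genotype containers and I/O -------------------------------------------
##
## A VariantMatrix stores unphased alt-allele dosages (0/1/2, NA = missing
## call) for n samples at m biallelic SNPs, together with the per-sample
## metadata the downstream stages need: population of origin, geographic
## region, and the genotype at a focal resistance mutation (e.g. a VSSC
## kdr substitution), recorded as "wild-type" / "het" / "hom-alt" /
## "unknown".  SNP coordinates are 1-based VCF positions, strictly
## increasing within each chromosome.

FOCAL_LEVELS <- c("wild-type", "het", "hom-alt", "unknown")

#' Construct a VariantMatrix
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns;
#'   entries in \{0, 1, 2\} or `NA` for missing calls.
#' @param chrom character vector of chromosome ids, one per SNP.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param samples sample ids; defaults to the rownames of `genotypes`.
#' @param populations named character vector mapping sample -> population.
#' @param regions named character vector mapping sample -> geographic
#'   region; defaults to `populations`.
#' @param focal named character vector mapping sample -> focal-mutation
#'   genotype, one of "wild-type", "het", "hom-alt", "unknown".
#' @param ref,alt optional REF/ALT alleles per SNP (used when writing VCF).
#' @return an object of class `VariantMatrix`.
#' @export
variant_matrix <- function(genotypes, chrom, pos, samples = rownames(genotypes),
                           populations = NULL, regions = NULL, focal = NULL,
                           ref = NULL, alt = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (n < 1L) stop("VariantMatrix requires at least one sample")
  if (m < 1L) stop("VariantMatrix requires at least one SNP")
  if (is.null(samples)) samples <- paste0("sample", seq_len(n))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != m || length(pos) != m)
    stop("chrom/pos length must equal the SNP count")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotypes must be 0, 1, 2 or NA")
  populations <- .sample_map(populations, samples, "pop1")
  regions <- if (is.null(regions)) populations else .sample_map(regions, samples, "region1")
  focal <- .sample_map(focal, samples, "unknown")
  if (!all(focal %in% FOCAL_LEVELS))
    stop("focal genotypes must be one of: ", paste(FOCAL_LEVELS, collapse = ", "))
  rownames(genotypes) <- samples
  structure(list(samples = samples, populations = populations,
                 regions = regions, focal = focal,
                 chrom = chrom, pos = pos, genotypes = genotypes,
                 ref = ref, alt = alt),
            class = "VariantMatrix")
}

.sample_map <- function(x, samples, default) {
  if (is.null(x)) return(stats::setNames(rep(default, length(samples)), samples))
  x <- stats::setNames(as.character(x), if (is.null(names(x))) samples else names(x))
  if (!setequal(names(x), samples))
    stop("metadata mapping keys must be exactly the sample set; offending: ",
         paste(union(setdiff(names(x), samples), setdiff(samples, names(x))), collapse = ", "))
  x[samples]
}

#' @export
print.VariantMatrix <- function(x, ...) {
  cat("VariantMatrix:", n_samples(x), "samples x", n_snps(x), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  cat("  populations:", paste(names(table(x$populations)), "(", table(x$populations), ")",
                              collapse = ", "), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / SNPs in a VariantMatrix
#' @param vm a `VariantMatrix`.
#' @export
n_samples <- function(vm) length(vm$samples)

#' @rdname n_samples
#' @export
n_snps <- function(vm) length(vm$pos)

#' Subset a VariantMatrix by samples and/or SNPs
#'
#' @param vm a `VariantMatrix`.
#' @param samples sample ids (or logical/integer index) to keep.
#' @param snps SNP index (logical or integer) to keep.
#' @return a `VariantMatrix`.
#' @export
subset_variants <- function(vm, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_along(vm$samples) else {
    if (is.character(samples)) match(samples, vm$samples) else seq_along(vm$samples)[samples]
  }
  if (anyNA(si)) stop("unknown sample ids")
  vi <- if (is.null(snps)) seq_along(vm$pos) else seq_along(vm$pos)[snps]
  variant_matrix(vm$genotypes[si, vi, drop = FALSE],
                 chrom = vm$chrom[vi], pos = vm$pos[vi],
                 samples = vm$samples[si],
                 populations = vm$populations[si],
                 regions = vm$regions[si],
                 focal = vm$focal[si],
                 ref = vm$ref[vi], alt = vm$alt[vi])
}

#' Construct a DepthMatrix
#'
#' Per-sample, per-site read depth on the same coordinate conventions as
#' [variant_matrix()].  Sites need not be polymorphic.
#'
#' @param depth non-negative integer matrix, samples in rows, sites in columns.
#' @param chrom,pos site coordinates (1-based, sorted within chromosome).
#' @param samples sample ids.
#' @return an object of class `DepthMatrix`.
#' @export
depth_matrix <- function(depth, chrom, pos, samples = rownames(depth)) {
  depth <- as.matrix(depth)
  if (any(depth[!is.na(depth)] < 0)) stop("depths must be non-negative")
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != ncol(depth) || length(pos) != ncol(depth))
    stop("chrom/pos length must equal the site count")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) stop("site positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(depth)))
  rownames(depth) <- samples
  structure(list(samples = as.character(samples), chrom = chrom, pos = pos,
                 depth = depth),
            class = "DepthMatrix")
}

#' @export
print.DepthMatrix <- function(x, ...) {
  cat("DepthMatrix:", length(x$samples), "samples x", length(x$pos), "sites\n")
  cat(sprintf("  mean depth: %.2f\n", mean(x$depth, na.rm = TRUE)))
  invisible(x)
}

#' Construct an IntervalSet
#'
#' Genomic intervals in the BED convention: half-open, zero-based
#' `[start, end)`.  Names must be unique within a set.
#'
#' @param chrom,start,end,name interval fields.
#' @return a data frame of class `IntervalSet`.
#' @export
interval_set <- function(chrom, start, end, name = NULL) {
  if (is.null(name)) name <- paste0("iv", seq_along(chrom))
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = as.character(name),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("interval start must be < end")
  if (anyDuplicated(df$name)) stop("interval names must be unique")
  class(df) <- c("IntervalSet", "data.frame")
  df
}

#' Read a BED file into an IntervalSet
#' @param path BED file (3 or 4+ columns, tab separated, no header).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  nm <- if (ncol(df) >= 4) as.character(df[[4]]) else NULL
  interval_set(df[[1]], df[[2]], df[[3]], nm)
}

#' Read a sample metadata table
#'
#' Tab-separated with header `sample  population  region  focal_genotype`.
#'
#' @param path TSV file.
#' @return data frame with those columns.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "population", "region", "focal_genotype")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  md
}

#' Read a multi-sample VCF into a VariantMatrix (and DepthMatrix)
#'
#' Keeps biallelic SNP rows only; multi-allelic and indel records are
#' dropped and counted.  Genotypes are mapped to alt-allele dosage,
#' missing calls to `NA`.  When the VCF carries per-genotype `DP` fields
#' a [depth_matrix()] is returned alongside.
#'
#' @param path VCF 4.x file (plain or gzipped).
#' @param metadata data frame as returned by [read_metadata()], covering
#'   all VCF samples, or `NULL` to use defaults.
#' @return a list with elements `vm` (`VariantMatrix`), `depth`
#'   (`DepthMatrix` or `NULL`) and `n_dropped` (excluded row count).
#' @export
read_vcf <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  dose <- .gt_to_dosage(gt)                  # SNPs x samples
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  md <- .match_metadata(metadata, samples)
  vm <- variant_matrix(t(dose), chrom = chrom, pos = pos, samples = samples,
                       populations = md$populations, regions = md$regions,
                       focal = md$focal, ref = ref[keep], alt = alt[keep])
  depth <- NULL
  fmt <- unique(v@gt[, "FORMAT"])
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
    depth <- depth_matrix(t(dp), chrom = chrom, pos = pos, samples = samples)
  }
  list(vm = vm, depth = depth, n_dropped = n_dropped)
}

.gt_to_dosage <- function(gt) {
  gt <- gsub("\\|", "/", gt)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0")] <- 0L
  dose[gt %in% c("0/1", "1/0")] <- 1L
  dose[gt %in% c("1/1")] <- 2L
  dose
}

.match_metadata <- function(metadata, samples) {
  if (is.null(metadata))
    return(list(populations = NULL, regions = NULL, focal = NULL))
  missing_ids <- setdiff(samples, metadata$sample)
  if (length(missing_ids))
    stop("metadata does not cover VCF samples: ", paste(missing_ids, collapse = ", "))
  md <- metadata[match(samples, metadata$sample), ]
  list(populations = stats::setNames(md$population, samples),
       regions = stats::setNames(md$region, samples),
       focal = stats::setNames(md$focal_genotype, samples))
}

#' Write a VariantMatrix as a VCF 4.2 file
#'
#' Emits GT fields (and DP when a matching [depth_matrix()] is supplied);
#' missing genotypes are written as `./.`.  Reading the file back with
#' [read_vcf()] reproduces the genotype matrix exactly.
#'
#' @param vm a `VariantMatrix`.
#' @param path output file.
#' @param depth optional `DepthMatrix` on the same coordinate frame.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vm, path, depth = NULL) {
  stopifnot(inherits(vm, "VariantMatrix"))
  ref <- if (is.null(vm$ref)) rep("A", n_snps(vm)) else vm$ref
  alt <- if (is.null(vm$alt)) rep("T", n_snps(vm)) else vm$alt
  gt_codes <- c("0/0", "0/1", "1/1")
  g <- t(vm$genotypes)                       # SNPs x samples
  gt <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  gt[ok] <- gt_codes[g[ok] + 1L]
  fmt <- "GT"
  if (!is.null(depth)) {
    if (!identical(depth$chrom, vm$chrom) || !identical(depth$pos, vm$pos) ||
        !identical(depth$samples, vm$samples))
      stop("depth matrix coordinate frame does not match the VariantMatrix")
    gt <- matrix(paste(gt, t(depth$depth), sep = ":"), nrow(g), ncol(g))
    fmt <- "GT:DP"
  }
  body <- cbind(vm$chrom, vm$pos, ".", ref, alt, ".", "PASS", ".", fmt, gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               if (!is.null(depth))
                 "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vm$samples), collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Apply the study's SNP retention filters
#'
#' Retains SNPs called in at least `min_pop_call` of the individuals of
#' every population, in at least `min_total_call` of all individuals, and
#' with minor allele count at least `min_mac`.
#'
#' @param vm a `VariantMatrix` with populations defined.
#' @param min_pop_call minimum per-population call-rate fraction (default 0.5).
#' @param min_total_call minimum total call-rate fraction (default 0.9).
#' @param min_mac minimum minor allele count (default 3).
#' @return the filtered `VariantMatrix`; attribute `"removed"` carries
#'   per-rule removal counts.
#' @export
filter_variants <- function(vm, min_pop_call = 0.5, min_total_call = 0.9,
                            min_mac = 3) {
  if (min_pop_call < 0 || min_pop_call > 1 || min_total_call < 0 || min_total_call > 1)
    stop("call-rate thresholds must lie in [0, 1]")
  if (min_mac < 0) stop("min_mac must be non-negative")
  g <- vm$genotypes
  called <- !is.na(g)
  pops <- split(seq_along(vm$samples), vm$populations)
  pop_ok <- rep(TRUE, n_snps(vm))
  for (idx in pops) {
    rate <- colMeans(called[idx, , drop = FALSE])
    pop_ok <- pop_ok & rate >= min_pop_call
  }
  total_ok <- colMeans(called) >= min_total_call
  ac <- colSums(g, na.rm = TRUE)
  an <- 2L * colSums(called)
  mac <- pmin(ac, an - ac)
  mac_ok <- mac >= min_mac
  keep <- pop_ok & total_ok & mac_ok
  if (!any(keep)) stop("no SNPs pass the filters")
  out <- subset_variants(vm, snps = keep)
  attr(out, "removed") <- c(pop_call = sum(!pop_ok),
                            total_call = sum(!total_ok),
                            mac = sum(!mac_ok))
  out
}

#' Impute missing genotypes by the per-SNP modal genotype
#'
#' Each missing call is replaced by the most frequent observed genotype
#' at that SNP; ties are broken toward the lower dosage.  Non-missing
#' genotypes are never altered.
#'
#' @param vm a `VariantMatrix` with no fully missing SNP.
#' @return a `VariantMatrix` with no missing genotypes.
#' @export
impute_missing <- function(vm) {
  g <- vm$genotypes
  miss <- colSums(is.na(g))
  if (any(miss == nrow(g))) {
    j <- which(miss == nrow(g))[1]
    stop("SNP at ", vm$chrom[j], ":", vm$pos[j], " is missing in all samples")
  }
  for (j in which(miss > 0L)) {
    counts <- tabulate(g[, j] + 1L, nbins = 3L)
    modal <- which.max(counts) - 1L          # which.max takes the first max
    g[is.na(g[, j]), j] <- modal
  }
  vm$genotypes <- g
  vm
}

#' Alternate allele frequency at one SNP
#'
#' Alt allele count divided by called allele count, ignoring missing
#' calls, over a subset of samples.
#'
#' @param vm a `VariantMatrix`.
#' @param snp SNP index (single integer).
#' @param samples sample ids or index; defaults to all samples.
#' @return frequency in `[0, 1]`, or `NA` with a warning when every call
#'   in the subset is missing.
#' @export
allele_frequency <- function(vm, snp, samples = NULL) {
  if (is.null(samples)) samples <- vm$samples
  si <- if (is.character(samples)) match(samples, vm$samples) else samples
  if (length(si) == 0) stop("sample subset is empty")
  g <- vm$genotypes[si, snp]
  if (all(is.na(g))) {
    warning("all calls missing at the requested SNP; frequency undefined")
    return(NA_real_)
  }
  sum(g, na.rm = TRUE) / (2 * sum(!is.na(g)))
}
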