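# Small in-code fixtures shared across test files.

# Build a VariantMatrix from a genotype matrix with evenly spaced SNPs.
toy_vm <- function(geno, chrom = NULL, pos = NULL, populations = NULL,
                   focal = NULL, spacing = 1000L) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * spacing
  variant_matrix(geno, chrom = chrom, pos = pos,
                 samples = paste0("s", seq_len(nrow(geno))),
                 populations = populations, focal = focal)
}

# Random small instance for oracle-equivalence checks: <= 6 samples,
# <= 10 SNPs, moderate missingness.
random_vm <- function(seed, max_n = 6, max_m = 10, missing = 0.1) {
  set.seed(seed)
  n <- sample(4:max_n, 1)
  m <- sample(2:max_m, 1)
  g <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(0.4, 0.3, 0.3)), n, m)
  if (missing > 0) g[runif(n * m) < missing] <- NA
  # guarantee at least one fully called polymorphic SNP
  g[, 1] <- rep_len(c(0L, 1L, 2L), n)
  toy_vm(g, pos = sort(sample.int(20000L, m)))
}

# The standard two-background partial-sweep study used by the
# end-to-end checks: 2 pops x 50, 5,000 SNPs, carriers 30% / 20%,
# sweep locus at 50 Mb on chr1.
sweep_study <- function(seed) {
  cfg <- sim_config(seed = seed, sweeps = list(
    sweep_spec("chr1", 5e7, "bgA", carrier_fraction = 0.3),
    sweep_spec("chr1", 5e7, "bgB", carrier_fraction = 0.2)))
  d <- simulate_dataset(cfg)
  d$locus <- interval_set("chr1", 5e7 - 5e5, 5e7 + 5e5, "locus")
  d$truth <- split(d$carriers$sample, d$carriers$background)
  d
}

# Carrier-indicator focal dosage vectors (one per background), the
# analog of typing each resistance mutation separately.
carrier_focals <- function(vm, truth) {
  lapply(truth, function(mem)
    stats::setNames(ifelse(vm$samples %in% mem, 2, 0), vm$samples))
}

# Window midpoint distance from a track extremum to a locus position.
extremum_distance <- function(track, locus_pos, which_fun = which.min) {
  i <- which_fun(track$value)
  abs((track$win_start[i] + track$win_end[i]) / 2 - locus_pos)
}
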