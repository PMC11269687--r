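## Synthetic data with known ground truth --------------------------------
##
## The generator builds multi-population genotype data under the
## Balding-Nichols model and then plants the three sweep signatures
## directly: shared extended homozygous haplotypes around a focal locus
## with recombination-decayed (exponential) tract lengths, an injected
## excess of rare variants on swept chromosomes, and segregating
## (partial) carrier frequencies.  Forward construction is used instead
## of coalescent simulation so that background membership and tract
## extent are known exactly for every individual.

#' Simulation configuration
#'
#' Defaults describe the standard study conditions used throughout the
#' package tests: two 150-Mb chromosomes carrying 5,000 SNPs, two
#' populations of 50 diploids differentiated at F = 0.1, 0.5% missing
#' calls, and a mean sequencing depth of 20x.
#'
#' @param seed integer RNG seed.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_snps total SNP count (split evenly across chromosomes).
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals per population.
#' @param drift_F per-population Balding-Nichols differentiation
#'   parameter in (0, 1); scalar or one value per population.
#' @param missing_rate fraction of genotypes masked missing, in `[0, 1)`.
#' @param depth_mean expected per-site read depth.
#' @param sweeps list of [sweep_spec()] objects.
#' @param cnv optional [cnv_spec()].
#' @param admixture optional list `(source_a, source_b, alpha, n)`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 1.5e8,
                       n_snps = 5000L, n_pops = 2L, n_per_pop = 50L,
                       drift_F = 0.1, missing_rate = 0.005,
                       depth_mean = 20, sweeps = list(), cnv = NULL,
                       admixture = NULL) {
  if (n_chrom < 1 || n_snps < 1 || n_pops < 1 || n_per_pop < 1)
    stop("counts must be at least 1")
  if (any(drift_F <= 0) || any(drift_F >= 1)) stop("drift_F must lie in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (n_snps > n_chrom * chrom_length)
    stop("n_snps exceeds the genome's site capacity")
  if (!is.null(admixture) && (admixture$alpha < 0 || admixture$alpha > 1))
    stop("admixture alpha must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_length = chrom_length, n_snps = as.integer(n_snps),
                 n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
                 drift_F = rep_len(drift_F, n_pops),
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 sweeps = sweeps, cnv = cnv, admixture = admixture),
            class = "sim_config")
}

#' Specification of one planted partial sweep
#'
#' @param chrom chromosome carrying the sweep locus.
#' @param locus_pos 1-based position of the focal locus.
#' @param background_label name of the swept background.
#' @param carrier_fraction fraction of each population that are
#'   homozygous carriers; scalar or one value per population.
#' @param het_fraction fraction of heterozygous carriers (default 0).
#' @param mean_tract expected one-sided swept tract length in bp
#'   (exponential decay models post-sweep recombination erosion).
#' @param core_halfwidth half-width of the always-swept core in bp.
#' @param rare_mut_rate expected number of new private singleton
#'   variants per swept chromosome (placed at SNPs inside the tract).
#' @return a list of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, locus_pos, background_label,
                       carrier_fraction, het_fraction = 0,
                       mean_tract = 2e6, core_halfwidth = 5e5,
                       rare_mut_rate = 0.5) {
  if (any(carrier_fraction < 0) || any(carrier_fraction > 1))
    stop("carrier_fraction must lie in [0, 1]")
  if (!(mean_tract > core_halfwidth) || core_halfwidth < 0)
    stop("need mean_tract > core_halfwidth >= 0")
  structure(list(chrom = as.character(chrom), locus_pos = locus_pos,
                 background_label = background_label,
                 carrier_fraction = carrier_fraction,
                 het_fraction = het_fraction,
                 mean_tract = mean_tract, core_halfwidth = core_halfwidth,
                 rare_mut_rate = rare_mut_rate),
            class = "sweep_spec")
}

#' Specification of a copy-number-variable region
#'
#' @param region one-row [interval_set()] naming the CNV region.
#' @param copy_number diploid copy number inside the region: a scalar,
#'   or a named vector keyed by population label.
#' @return a list of class `cnv_spec`.
#' @export
cnv_spec <- function(region, copy_number = 2) {
  if (any(copy_number < 0)) stop("copy_number must be non-negative")
  structure(list(region = region, copy_number = copy_number),
            class = "cnv_spec")
}

#' Read a simulation configuration from YAML
#' @param path YAML file mirroring the [sim_config()] fields.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads exponents without a sign ("2.0e7") as strings
  num <- function(x) if (is.character(x)) as.numeric(x) else x
  numeric_fields <- c("seed", "n_chrom", "chrom_length", "n_snps", "n_pops",
                      "n_per_pop", "drift_F", "missing_rate", "depth_mean")
  for (f in intersect(names(y), numeric_fields)) y[[f]] <- num(y[[f]])
  sweeps <- lapply(y$sweeps, function(s) {
    for (f in setdiff(names(s), c("chrom", "background_label")))
      s[[f]] <- num(s[[f]])
    do.call(sweep_spec, s)
  })
  y$sweeps <- NULL
  cnv <- NULL
  if (!is.null(y$cnv)) {
    cnv <- cnv_spec(interval_set(y$cnv$chrom, num(y$cnv$start),
                                 num(y$cnv$end), y$cnv$name),
                    num(y$cnv$copy_number))
    y$cnv <- NULL
  }
  do.call(sim_config, c(y, list(sweeps = sweeps, cnv = cnv)))
}

#' Simulate neutral structured genotypes (Balding-Nichols model)
#'
#' SNP positions are drawn uniformly without replacement within each
#' chromosome and sorted.  Each SNP gets an ancestral frequency
#' `p ~ Uniform(0.05, 0.95)`; each population draws its own frequency
#' `p_j ~ Beta(p(1-F_j)/F_j, (1-p)(1-F_j)/F_j)` and genotypes are
#' `Binomial(2, p_j)`, then masked missing at `missing_rate`.  Output is
#' identical for identical seeds.
#'
#' @param config a [sim_config()].
#' @return a `VariantMatrix`.
#' @export
simulate_neutral <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    per_chrom <- diff(round(seq(0, config$n_snps, length.out = config$n_chrom + 1)))
    chrom <- character(0); pos <- integer(0)
    for (c_i in seq_len(config$n_chrom)) {
      p <- sort(sample.int(config$chrom_length, per_chrom[c_i]))
      chrom <- c(chrom, rep(paste0("chr", c_i), per_chrom[c_i]))
      pos <- c(pos, p)
    }
    m <- length(pos)
    p_anc <- stats::runif(m, 0.05, 0.95)
    n_tot <- config$n_pops * config$n_per_pop
    g <- matrix(NA_integer_, n_tot, m)
    pops <- rep(paste0("pop", seq_len(config$n_pops)), each = config$n_per_pop)
    for (j in seq_len(config$n_pops)) {
      F_j <- config$drift_F[j]
      pj <- stats::rbeta(m, p_anc * (1 - F_j) / F_j, (1 - p_anc) * (1 - F_j) / F_j)
      rows <- which(pops == paste0("pop", j))
      g[rows, ] <- matrix(stats::rbinom(length(rows) * m, 2, rep(pj, each = length(rows))),
                          nrow = length(rows))
    }
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(g)) < config$missing_rate
      g[mask] <- NA_integer_
    }
    samples <- paste0(pops, "_", sequence(rep(config$n_per_pop, config$n_pops)))
    variant_matrix(g, chrom = chrom, pos = pos, samples = samples,
                   populations = stats::setNames(pops, samples),
                   focal = stats::setNames(rep("wild-type", n_tot), samples))
  })
}

#' Overlay a partial sweep on a genotype matrix
#'
#' For every carrier chromosome a swept tract
#' `[locus - max(core, E_left), locus + max(core, E_right)]` with
#' `E ~ Exponential(mean_tract)` per side is drawn; inside the tract the
#' chromosome's alleles are overwritten by the background haplotype (one
#' fixed allele per SNP, drawn once per call from the pooled sample
#' allele frequency).  `Poisson(rare_mut_rate)` private singleton
#' variants are then added at random tract SNPs of each swept
#' chromosome.  Homozygous carriers receive two swept chromosomes,
#' heterozygous carriers one.  Missing calls stay missing; non-carrier
#' genotypes are never touched.
#'
#' @param vm a `VariantMatrix`.
#' @param spec a [sweep_spec()].
#' @param seed RNG seed.
#' @param exclude sample ids ineligible as carriers (e.g. carriers of a
#'   previously overlaid background).
#' @return a list with elements `vm` (modified matrix) and `carriers`
#'   (data frame `sample`, `background`, `zygosity`, `tract_start`,
#'   `tract_end`).
#' @export
overlay_sweep <- function(vm, spec, seed = 1L, exclude = character(0)) {
  stopifnot(inherits(vm, "VariantMatrix"), inherits(spec, "sweep_spec"))
  if (!spec$chrom %in% vm$chrom)
    stop("sweep chromosome ", spec$chrom, " not present in the matrix")
  ci <- which(vm$chrom == spec$chrom)
  p <- as.numeric(vm$pos[ci])
  .with_seed(seed, {
    pools <- split(vm$samples, vm$populations)
    frac <- rep_len(spec$carrier_fraction, length(pools))
    hfrac <- rep_len(spec$het_fraction, length(pools))
    hom <- character(0); het <- character(0)
    for (k in seq_along(pools)) {
      eligible <- setdiff(pools[[k]], exclude)
      n_hom <- min(round(frac[k] * length(pools[[k]])), length(eligible))
      pick <- if (n_hom > 0) sample(eligible, n_hom) else character(0)
      hom <- c(hom, pick)
      eligible <- setdiff(eligible, pick)
      n_het <- min(round(hfrac[k] * length(pools[[k]])), length(eligible))
      if (n_het > 0) het <- c(het, sample(eligible, n_het))
    }
    if (length(hom) + length(het) == 0) {
      warning("carrier fractions yield no carriers; returning input unchanged")
      return(list(vm = vm,
                  carriers = data.frame(sample = character(0), background = character(0),
                                        zygosity = character(0), tract_start = numeric(0),
                                        tract_end = numeric(0))))
    }
    pooled_freq <- colMeans(vm$genotypes[, ci, drop = FALSE], na.rm = TRUE) / 2
    pooled_freq[is.na(pooled_freq)] <- 0.5
    bg <- stats::rbinom(length(ci), 1, pooled_freq)   # the background haplotype
    carriers <- data.frame(sample = c(hom, het),
                           background = spec$background_label,
                           zygosity = rep(c("hom", "het"), c(length(hom), length(het))),
                           tract_start = NA_real_, tract_end = NA_real_,
                           stringsAsFactors = FALSE)
    for (r in seq_len(nrow(carriers))) {
      s <- carriers$sample[r]
      n_copies <- if (carriers$zygosity[r] == "hom") 2L else 1L
      g <- vm$genotypes[s, ci]
      h1 <- integer(length(g)); h2 <- integer(length(g))
      h1[which(g == 2L)] <- 1L
      hets <- which(g == 1L)
      if (length(hets)) h1[hets] <- stats::rbinom(length(hets), 1, 0.5)
      h2 <- g - h1
      lo <- Inf; hi <- -Inf
      for (cp in seq_len(n_copies)) {
        L <- max(spec$core_halfwidth, stats::rexp(1, 1 / spec$mean_tract))
        R <- max(spec$core_halfwidth, stats::rexp(1, 1 / spec$mean_tract))
        lo <- min(lo, spec$locus_pos - L); hi <- max(hi, spec$locus_pos + R)
        tract <- which(p >= spec$locus_pos - L & p <= spec$locus_pos + R & !is.na(g))
        hap <- if (cp == 1L) "h1" else "h2"
        if (hap == "h1") h1[tract] <- bg[tract] else h2[tract] <- bg[tract]
        n_mut <- stats::rpois(1, spec$rare_mut_rate)
        if (n_mut > 0 && length(tract) > 0) {
          at <- sample(tract, min(n_mut, length(tract)))
          if (hap == "h1") h1[at] <- 1L - bg[at] else h2[at] <- 1L - bg[at]
        }
      }
      gi <- h1 + h2
      gi[is.na(g)] <- NA_integer_
      vm$genotypes[s, ci] <- gi
      carriers$tract_start[r] <- lo; carriers$tract_end[r] <- hi
    }
    list(vm = vm, carriers = carriers)
  })
}

#' Simulate a complete study data set
#'
#' Runs [simulate_neutral()], overlays every sweep in the configuration
#' with mutually exclusive carrier sets, sets the focal-mutation
#' genotype of carriers (`hom-alt`/`het`) and wild types, and optionally
#' appends admixed individuals.
#'
#' @param config a [sim_config()].
#' @return list with `vm` (`VariantMatrix`) and `carriers` (ground-truth
#'   carrier table across all backgrounds).
#' @export
simulate_dataset <- function(config) {
  vm <- simulate_neutral(config)
  carriers <- NULL
  taken <- character(0)
  for (k in seq_along(config$sweeps)) {
    res <- overlay_sweep(vm, config$sweeps[[k]],
                         seed = config$seed + 10000L * k, exclude = taken)
    vm <- res$vm
    carriers <- rbind(carriers, res$carriers)
    taken <- c(taken, res$carriers$sample)
  }
  if (!is.null(carriers) && nrow(carriers)) {
    vm$focal[] <- "wild-type"
    vm$focal[carriers$sample[carriers$zygosity == "hom"]] <- "hom-alt"
    vm$focal[carriers$sample[carriers$zygosity == "het"]] <- "het"
  }
  if (!is.null(config$admixture)) {
    a <- config$admixture
    vm <- simulate_admixture(vm, a$source_a, a$source_b, a$alpha, a$n,
                             seed = config$seed + 99991L)
  }
  list(vm = vm, carriers = carriers)
}

#' Simulate per-individual, per-site read depths
#'
#' Each individual gets a sequencing-effort multiplier
#' `s_i ~ Gamma(shape, mean = depth_mean)`; depth at site r is
#' `Poisson(s_i * c_{i,r} / 2)` where `c` is the copy number inside the
#' CNV region (default diploid 2 everywhere).
#'
#' @param sites data frame with columns `chrom` and `pos` (1-based),
#'   sorted within chromosome; sites need not be polymorphic.
#' @param samples sample ids.
#' @param depth_mean expected depth at diploid copy number; must be > 0.
#' @param cnv optional [cnv_spec()].
#' @param populations named population map (needed when the CNV copy
#'   number is specified per population).
#' @param seed RNG seed.
#' @param gamma_shape shape of the effort distribution (default 10).
#' @return a `DepthMatrix`.
#' @export
simulate_depth <- function(sites, samples, depth_mean = 20, cnv = NULL,
                           populations = NULL, seed = 1L, gamma_shape = 10) {
  if (depth_mean <= 0) stop("depth_mean must be positive")
  n <- length(samples); m <- nrow(sites)
  .with_seed(seed, {
    s <- stats::rgamma(n, shape = gamma_shape, scale = depth_mean / gamma_shape)
    lam <- matrix(s, n, m)
    if (!is.null(cnv)) {
      cn <- rep_len(2, n)
      if (is.null(names(cnv$copy_number))) {
        cn <- rep_len(cnv$copy_number, n)
      } else {
        if (is.null(populations)) stop("per-population copy numbers need a population map")
        hit <- match(populations[samples], names(cnv$copy_number))
        cn[!is.na(hit)] <- cnv$copy_number[hit[!is.na(hit)]]
      }
      inside <- .in_intervals(sites$chrom, sites$pos, cnv$region)
      lam[, inside] <- lam[, inside] * (cn / 2)
    }
    depth <- matrix(stats::rpois(n * m, lam), n, m)
    depth_matrix(depth, chrom = sites$chrom, pos = sites$pos, samples = samples)
  })
}

#' Append admixed individuals drawn from two source populations
#'
#' Each admixed allele is drawn from source A's empirical allele
#' frequency with probability `alpha`, else from source B's.  Optional
#' post-admixture drift resamples the admixed frequency vector
#' binomially for `drift_generations` generations at size `drift_N`.
#'
#' @param vm a `VariantMatrix` containing both source populations.
#' @param pop_a,pop_b source population labels.
#' @param alpha mixing fraction toward source A, in `[0, 1]`.
#' @param n number of admixed individuals to append.
#' @param seed RNG seed.
#' @param drift_generations,drift_N post-admixture drift parameters.
#' @param label population label given to the new individuals.
#' @return the extended `VariantMatrix` (identical input when `n = 0`).
#' @export
simulate_admixture <- function(vm, pop_a, pop_b, alpha, n, seed = 1L,
                               drift_generations = 0L, drift_N = 200L,
                               label = "admixed") {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (n == 0) return(vm)
  for (p in c(pop_a, pop_b))
    if (!p %in% vm$populations) stop("source population not present: ", p)
  .with_seed(seed, {
    fa <- colMeans(vm$genotypes[vm$populations == pop_a, , drop = FALSE], na.rm = TRUE) / 2
    fb <- colMeans(vm$genotypes[vm$populations == pop_b, , drop = FALSE], na.rm = TRUE) / 2
    fa[is.na(fa)] <- 0.5; fb[is.na(fb)] <- 0.5
    f <- alpha * fa + (1 - alpha) * fb
    if (drift_generations > 0) {
      for (g in seq_len(drift_generations))
        f <- stats::rbinom(length(f), 2L * drift_N, f) / (2 * drift_N)
    }
    m <- n_snps(vm)
    g_new <- matrix(stats::rbinom(n * m, 2, rep(f, each = n)), nrow = n)
    ids <- paste0(label, "_", seq_len(n))
    geno <- rbind(vm$genotypes, g_new)
    rownames(geno) <- c(vm$samples, ids)
    variant_matrix(geno, chrom = vm$chrom, pos = vm$pos,
                   samples = c(vm$samples, ids),
                   populations = stats::setNames(c(vm$populations, rep(label, n)),
                                                 c(vm$samples, ids)),
                   regions = stats::setNames(c(vm$regions, rep(label, n)),
                                             c(vm$samples, ids)),
                   focal = stats::setNames(c(vm$focal, rep("unknown", n)),
                                           c(vm$samples, ids)),
                   ref = vm$ref, alt = vm$alt)
  })
}
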