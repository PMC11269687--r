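test_that("all generators are reproducible bit-for-bit under a fixed seed", {
  cfg <- sim_config(seed = 9, n_snps = 400, chrom_length = 1e7)
  expect_identical(simulate_neutral(cfg), simulate_neutral(cfg))

  vm <- simulate_neutral(cfg)
  spec <- sweep_spec("chr1", 5e6, "bg", carrier_fraction = 0.3,
                     mean_tract = 1e6, core_halfwidth = 2e5)
  expect_identical(overlay_sweep(vm, spec, seed = 4), overlay_sweep(vm, spec, seed = 4))

  sites <- data.frame(chrom = "chr1", pos = seq(1, 2e6, by = 1000))
  expect_identical(simulate_depth(sites, paste0("x", 1:5), seed = 3),
                   simulate_depth(sites, paste0("x", 1:5), seed = 3))

  expect_identical(simulate_admixture(vm, "pop1", "pop2", 0.5, 5, seed = 8),
                   simulate_admixture(vm, "pop1", "pop2", 0.5, 5, seed = 8))
})

test_that("Balding-Nichols drift produces the expected differentiation", {
  # near-zero drift: genome-wide weighted FST near zero
  vm0 <- simulate_neutral(sim_config(seed = 1, drift_F = 1e-6))
  comp <- sweepscape:::.wc_components(list(
    vm0$genotypes[vm0$populations == "pop1", ],
    vm0$genotypes[vm0$populations == "pop2", ]))
  expect_lt(abs(sum(comp$a, na.rm = TRUE) / sum(comp$d, na.rm = TRUE)), 0.01)

  # F = 0.1: weighted FST close to F, averaged over seeds
  fst <- sapply(1:20, function(s) {
    vm <- simulate_neutral(sim_config(seed = s))
    comp <- sweepscape:::.wc_components(list(
      vm$genotypes[vm$populations == "pop1", ],
      vm$genotypes[vm$populations == "pop2", ]))
    sum(comp$a, na.rm = TRUE) / sum(comp$d, na.rm = TRUE)
  })
  expect_gte(mean(fst), 0.07)
  expect_lte(mean(fst), 0.13)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(drift_F = 0), "\\(0, 1\\)")
  expect_error(sim_config(missing_rate = 1), "\\[0, 1\\)")
  expect_error(sim_config(n_snps = 100, chrom_length = 10, n_chrom = 1),
               "capacity")
  expect_error(sweep_spec("chr1", 100, "b", carrier_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sweep_spec("chr1", 100, "b", 0.5, mean_tract = 100,
                          core_halfwidth = 200), "mean_tract")
  expect_error(cnv_spec(interval_set("chr1", 0, 10), copy_number = -1),
               "non-negative")
  expect_error(simulate_depth(data.frame(chrom = "chr1", pos = 1),
                              "s1", depth_mean = 0), "positive")
})

test_that("sweep overlays touch carriers only and respect zero fractions", {
  cfg <- sim_config(seed = 12, n_snps = 600, chrom_length = 2e7)
  vm <- simulate_neutral(cfg)

  spec0 <- sweep_spec("chr1", 1e7, "bg", carrier_fraction = 0)
  expect_warning(res0 <- overlay_sweep(vm, spec0, seed = 1), "no carriers")
  expect_identical(res0$vm$genotypes, vm$genotypes)

  spec <- sweep_spec("chr1", 1e7, "bg", carrier_fraction = 0.3,
                     mean_tract = 2e6, core_halfwidth = 5e5)
  res <- overlay_sweep(vm, spec, seed = 2)
  non_carriers <- setdiff(vm$samples, res$carriers$sample)
  expect_identical(res$vm$genotypes[non_carriers, ], vm$genotypes[non_carriers, ])
  # missingness is preserved where it was
  expect_identical(is.na(res$vm$genotypes), is.na(vm$genotypes))
})

test_that("two backgrounds at one locus are fixed-different at core SNPs", {
  # no new mutations, no missing calls: the construction alone decides
  cfg <- sim_config(seed = 1, missing_rate = 0, sweeps = list(
    sweep_spec("chr1", 5e7, "bgA", 0.3, rare_mut_rate = 0),
    sweep_spec("chr1", 5e7, "bgB", 0.2, rare_mut_rate = 0)))
  d <- simulate_dataset(cfg)
  vm <- d$vm
  truth <- split(d$carriers$sample, d$carriers$background)
  core <- which(vm$chrom == "chr1" & abs(vm$pos - 5e7) <= 5e5)
  fa <- colMeans(vm$genotypes[truth$bgA, core]) / 2
  fb <- colMeans(vm$genotypes[truth$bgB, core]) / 2
  differing <- which((fa == 0 & fb == 1) | (fa == 1 & fb == 0))
  expect_gt(length(differing), 0)
  res <- wc_fst(vm, truth$bgA, truth$bgB)
  expect_equal(res$per_snp$fst[core[differing]], rep(1, length(differing)))
})

test_that("swept carriers carry the three sweep signatures", {
  hits <- sapply(1:10, function(seed) {
    d <- sweep_study(seed)
    vm <- d$vm
    wt <- setdiff(vm$samples, unlist(d$truth))
    sub <- subset_variants(vm, snps = vm$chrom == "chr1")
    locus_bin <- function(track) {
      i <- which(track$win_start <= 5e7 & track$win_end > 5e7 - 1e6 &
                   track$win_start < 5e7 + 1e6)
      track$value[i]
    }
    # carrier-only D near the locus below the carrier genome median
    dA <- tajimas_d(sub, d$truth$bgA)
    med <- stats::median(dA$value, na.rm = TRUE)
    near <- dA$win_start >= 5e7 - 1e6 & dA$win_end <= 5e7 + 1e6
    d_low <- min(dA$value[near], na.rm = TRUE) < med
    # carrier-vs-wildtype delta pi < 0 at the locus region
    dp <- delta_stats(vm, d$truth$bgA, wt, "chrom" = "chr1")
    near_pi <- dp$delta_pi$win_start >= 5e7 - 1e6 & dp$delta_pi$win_end <= 5e7 + 1e6
    pi_neg <- mean(dp$delta_pi$value[near_pi], na.rm = TRUE) < 0
    # delta LD positive around the locus
    near_ld <- dp$delta_ld$win_start >= 5e7 - 2e6 & dp$delta_ld$win_end <= 5e7 + 2e6
    ld_pos <- mean(dp$delta_ld$value[near_ld], na.rm = TRUE) > 0
    # carrier-group FST peak at the locus
    fst <- pairwise_background_fst(vm, d$truth$bgA, d$truth$bgB)
    fst_peak <- abs((fst$max_window$win_start + fst$max_window$win_end) / 2 - 5e7) <= 1e6
    c(d_low, pi_neg, ld_pos, fst_peak)
  })
  expect_gte(sum(hits[1, ]), 9)
  expect_gte(sum(hits[2, ]), 9)
  expect_gte(sum(hits[3, ]), 9)
  expect_gte(sum(hits[4, ]), 9)
})

test_that("simulated depths follow the copy-number model", {
  set.seed(2)
  coding <- interval_set("chr1", 5e6, 6e6, "region")
  pos <- sort(sample.int(2e7, 6000))
  sites <- data.frame(chrom = "chr1", pos = pos)

  # diploid everywhere: in-region vs flank ratio centred at 1
  dm <- simulate_depth(sites, paste0("s", 1:50), depth_mean = 20, seed = 5)
  dr <- depth_ratio(dm, coding, flank_bp = 5e6, min_sites = 100)
  expect_lt(abs(mean(dr$ratio[dr$included]) - 1), 0.05)

  # copy number 4 in one population doubles that population's ratio
  pops <- stats::setNames(rep(c("p1", "p2"), each = 25), paste0("s", 1:50))
  cn <- cnv_spec(coding, copy_number = c(p2 = 4))
  dm4 <- simulate_depth(sites, paste0("s", 1:50), depth_mean = 20, cnv = cn,
                        populations = pops, seed = 6)
  dr4 <- depth_ratio(dm4, coding, flank_bp = 5e6, min_sites = 100)
  r1 <- mean(dr4$ratio[dr4$included & pops[dr4$sample] == "p1"])
  r2 <- mean(dr4$ratio[dr4$included & pops[dr4$sample] == "p2"])
  expect_lt(abs(r1 - 1), 0.1)
  expect_lt(abs(r2 - 2), 0.2)
})

test_that("admixture endpoints and edge cases behave", {
  vm <- simulate_neutral(sim_config(seed = 21))
  # alpha = 1: admixed frequencies track source A
  adm <- simulate_admixture(vm, "pop1", "pop2", alpha = 1, n = 150, seed = 2,
                            label = "adm")
  fa <- colMeans(vm$genotypes[vm$populations == "pop1", ], na.rm = TRUE)
  fq <- colMeans(adm$genotypes[adm$populations == "adm", ], na.rm = TRUE)
  expect_gt(stats::cor(fa, fq, use = "complete.obs"), 0.99)

  # n = 0: identity
  expect_identical(simulate_admixture(vm, "pop1", "pop2", 0.5, 0), vm)
  expect_error(simulate_admixture(vm, "pop1", "pop2", 1.5, 3), "\\[0, 1\\]")
  expect_error(simulate_admixture(vm, "pop1", "nope", 0.5, 3), "not present")
})

test_that("YAML configurations round-trip into sim_config objects", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 3", "n_chrom: 1", "chrom_length: 2.0e7", "n_snps: 500",
    "n_pops: 2", "n_per_pop: 10", "drift_F: 0.15", "missing_rate: 0.01",
    "depth_mean: 25",
    "sweeps:",
    "  - chrom: chr1", "    locus_pos: 1.0e7", "    background_label: bg1",
    "    carrier_fraction: 0.4",
    "cnv:",
    "  chrom: chr1", "  start: 5.0e6", "  end: 6.0e6", "  name: gst",
    "  copy_number: 4"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$drift_F, rep(0.15, 2))
  expect_length(cfg$sweeps, 1)
  expect_equal(cfg$sweeps[[1]]$background_label, "bg1")
  expect_equal(cfg$cnv$copy_number, 4)
  vm <- simulate_neutral(cfg)
  expect_equal(n_samples(vm), 20)
  expect_equal(n_snps(vm), 500)
})
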