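test_that("per-site diversity matches pairwise-difference enumeration", {
  # genotypes {0,1,1,2}: 8 alleles, p = 0.5, 16 mismatching pairs of 28
  vm <- toy_vm(matrix(c(0L, 1L, 1L, 2L), 4, 1))
  expect_equal(site_pi(vm)$pi, 16 / 28)
  expect_equal(site_pi(vm)$pi, oracle_site_pi(c(0, 1, 1, 2)))

  # monomorphic site
  expect_equal(site_pi(toy_vm(matrix(2L, 4, 1)))$pi, 0)

  # a site called in one sample is skipped and counted
  g <- cbind(c(0L, 1L, 2L, 0L), c(1L, NA, NA, NA))
  sp <- site_pi(toy_vm(g))
  expect_true(is.na(sp$pi[2]))
  expect_equal(attr(sp, "n_skipped"), 1L)
})

test_that("binned Tajima's D agrees with the brute-force oracle", {
  # 6 diploids, one 5-kb bin, 4 SNPs with stated genotypes
  G <- rbind(c(0L, 1L, 0L, 2L),
             c(1L, 1L, 0L, 2L),
             c(0L, 0L, 1L, 1L),
             c(2L, 1L, 0L, 2L),
             c(0L, 0L, 0L, 2L),
             c(1L, 2L, 0L, 2L))
  vm <- toy_vm(G, pos = c(500L, 1500L, 2500L, 3500L))
  d <- tajimas_d(vm, bin_size = 5000)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$value - oracle_tajima_d(G)), 1e-12)
  expect_equal(d$n_sites, 4L)

  # a bin whose sites are all monomorphic is emitted undefined
  g2 <- cbind(G, matrix(2L, 6, 2))
  vm2 <- toy_vm(g2, pos = c(500L, 1500L, 2500L, 3500L, 6000L, 7000L))
  d2 <- tajimas_d(vm2, bin_size = 5000)
  expect_equal(nrow(d2), 2L)
  expect_true(is.na(d2$value[2]))

  expect_error(tajimas_d(vm, bin_size = 0), "positive")
  expect_error(tajimas_d(vm, subset = paste0("s", 1:3)), "at least 4")
})

test_that("genotype r2 obeys the distance rules and matches cor()", {
  # identical dosage vectors 10 kb apart
  g <- cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L))
  vm <- toy_vm(g, pos = c(1000L, 11000L))
  expect_equal(genotype_r2(vm)$r2, 1.0)

  # a pair 300 bp apart is excluded by the lower distance bound
  vm2 <- toy_vm(g, pos = c(1000L, 1300L))
  expect_equal(nrow(genotype_r2(vm2)), 0L)

  # worked dosage example against the textbook correlation routine
  g3 <- cbind(c(0L, 1L, 2L, 0L), c(0L, 0L, 2L, 2L))
  vm3 <- toy_vm(g3, pos = c(1000L, 11000L))
  expect_lt(abs(genotype_r2(vm3)$r2 - oracle_r2(g3[, 1], g3[, 2])), 1e-12)

  # zero-variance member: pair skipped and counted
  g4 <- cbind(c(0L, 1L, 2L, 0L), c(1L, 1L, 1L, 1L))
  ld4 <- genotype_r2(toy_vm(g4, pos = c(1000L, 11000L)))
  expect_equal(nrow(ld4), 0L)
  expect_equal(attr(ld4, "n_skipped"), 1L)

  # interchromosomal pairs only under the flag, with no distance cap
  vm5 <- toy_vm(g3, chrom = c("chr1", "chr2"), pos = c(1000L, 1000L))
  expect_equal(nrow(genotype_r2(vm5)), 0L)
  ld5 <- genotype_r2(vm5, interchrom = TRUE)
  expect_equal(nrow(ld5), 1L)
  expect_lt(abs(ld5$r2 - oracle_r2(g3[, 1], g3[, 2])), 1e-12)
})

test_that("Weir-Cockerham FST handles fixed and absent differentiation", {
  # group A all hom-ref, group B all hom-alt: theta = 1 per SNP
  g <- rbind(matrix(0L, 10, 3), matrix(2L, 10, 3))
  vm <- toy_vm(g)
  res <- wc_fst(vm, paste0("s", 1:10), paste0("s", 11:20))
  expect_equal(res$per_snp$fst, rep(1, 3))

  # identical frequency and heterozygosity in both groups: theta <= 0
  g2 <- rbind(matrix(rep(c(0L, 1L, 2L, 1L), 5), 20, 3),
              matrix(rep(c(0L, 1L, 2L, 1L), 5), 20, 3))
  vm2 <- toy_vm(g2)
  res2 <- wc_fst(vm2, paste0("s", 1:20), paste0("s", 21:40))
  expect_true(all(res2$per_snp$fst <= 0))   # estimator may go slightly negative
  expect_lt(abs(res2$windowed$value[1]), 0.1)

  expect_error(wc_fst(vm, paste0("s", 1:10), paste0("s", 10:20)), "disjoint")
})

test_that("each statistic equals its oracle on random small instances", {
  for (seed in 1:200) {
    vm <- random_vm(seed)
    n <- n_samples(vm); m <- n_snps(vm)

    sp <- site_pi(vm)
    for (j in seq_len(m)) {
      o <- oracle_site_pi(vm$genotypes[, j])
      if (is.na(o)) expect_true(is.na(sp$pi[j]))
      else expect_lt(abs(sp$pi[j] - o), 1e-10)
    }

    # D on the complete-data submatrix so the oracle's single n applies
    cc <- !anyNA(vm$genotypes)
    if (cc) {
      d <- tajimas_d(vm, bin_size = 1e6)
      expect_lt(abs(d$value[1] - oracle_tajima_d(vm$genotypes)), 1e-10)
    }

    if (m >= 2) {
      ld <- genotype_r2(vm, min_bp = 0, max_bp = Inf)
      for (k in seq_len(nrow(ld))) {
        i <- which(vm$pos == ld$pos_i[k]); j <- which(vm$pos == ld$pos_j[k])
        expect_lt(abs(ld$r2[k] - oracle_r2(vm$genotypes[, i], vm$genotypes[, j])), 1e-10)
      }
    }

    half <- floor(n / 2)
    ga <- vm$samples[1:half]; gb <- vm$samples[(half + 1):n]
    if (half >= 2 && n - half >= 2) {
      res <- wc_fst(vm, ga, gb)
      for (j in seq_len(m)) {
        o <- oracle_wc_snp(vm$genotypes[ga, j], vm$genotypes[gb, j])
        if (!is.na(o["d"]) && o["d"] != 0)
          expect_lt(abs(res$per_snp$fst[j] - o["a"] / o["d"]), 1e-10)
      }
    }
  }
})

test_that("statistics are invariant under sample-order permutation", {
  vm <- random_vm(77, max_n = 6, max_m = 8)
  set.seed(1); perm <- sample(vm$samples)
  vmp <- subset_variants(vm, samples = perm)
  expect_equal(site_pi(vm)$pi, site_pi(vmp)$pi)
  expect_equal(tajimas_d(vm, bin_size = 1e6)$value,
               tajimas_d(vmp, bin_size = 1e6)$value)
  expect_equal(genotype_r2(vm, min_bp = 0, max_bp = Inf)$r2,
               genotype_r2(vmp, min_bp = 0, max_bp = Inf)$r2)
  ga <- vm$samples[1:3]; gb <- vm$samples[4:n_samples(vm)]
  expect_equal(wc_fst(vm, ga, gb)$per_snp$fst, wc_fst(vmp, ga, gb)$per_snp$fst)
})

test_that("moving averages follow the simple trailing-window convention", {
  tr <- sweepscape:::.new_track("D", data.frame(
    chrom = "chr1", win_start = (0:3) * 5000, win_end = (1:4) * 5000,
    value = c(1, 2, 3, 4), n_sites = 1L, n_samples_used = 4L))
  expect_equal(moving_average(tr, 3)$value, c(NA, NA, 2, 3))
  expect_equal(moving_average(tr, 1)$value, c(1, 2, 3, 4))
  const <- tr; const$value <- rep(2, 4)
  expect_equal(moving_average(const, 2)$value[-1], rep(2, 3))
  expect_error(moving_average(tr, 0), "at least 1")
})

test_that("windowed FST uses the ratio-of-sums over sliding windows", {
  set.seed(5)
  g <- rbind(matrix(rbinom(40, 2, 0.2), 4, 10), matrix(rbinom(40, 2, 0.8), 4, 10))
  vm <- toy_vm(g, pos = as.integer(seq(500, 9500, length.out = 10)))
  res <- wc_fst(vm, paste0("s", 1:4), paste0("s", 5:8), window = 5000, step = 1000)
  w <- res$windowed
  # recompute one window by hand from per-SNP components
  comp <- sweepscape:::.wc_components(list(vm$genotypes[1:4, ], vm$genotypes[5:8, ]))
  k <- which(w$win_start == 0)
  inw <- vm$pos - 1 >= 0 & vm$pos - 1 < 5000
  expect_lt(abs(w$value[k] - sum(comp$a[inw]) / sum(comp$d[inw])), 1e-12)
  expect_true(all(w$value <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(w$n_sites >= 1))
})
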