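# Build a matrix with two groups fixed for opposite homozygous
# haplotypes at `k` screen SNPs, plus unstructured noise SNPs.
two_haplotype_fixture <- function(seed, n_a = 12, n_b = 8, n_wt = 20, k = 10,
                                  noise = 40) {
  set.seed(seed)
  n <- n_a + n_b + n_wt
  hapA <- sample(0:1, k, TRUE)
  hapB <- 1 - hapA
  core <- rbind(matrix(rep(2L * hapA, n_a), n_a, k, byrow = TRUE),
                matrix(rep(2L * hapB, n_b), n_b, k, byrow = TRUE),
                matrix(sample(0:2, n_wt * k, TRUE), n_wt, k))
  g <- cbind(core, matrix(sample(0:2, n * noise, TRUE), n, noise))
  vm <- toy_vm(g, focal = c(rep("hom-alt", n_a + n_b), rep("wild-type", n_wt)))
  list(vm = vm, screen = 1:k,
       a = vm$samples[1:n_a], b = vm$samples[n_a + 1:n_b],
       wt = vm$samples[n_a + n_b + 1:n_wt])
}

test_that("k-means on outlier-SNP PCA recovers disjoint core haplotypes", {
  for (seed in 1:10) {
    fx <- two_haplotype_fixture(seed)
    cl <- pca_cluster_homozygotes(fx$vm, fx$screen, k_clusters = 2, seed = seed)
    tab <- table(cl$cluster, cl$sample %in% fx$a)
    expect_equal(sum(tab) - sum(apply(tab, 2, max)), 0)
  }
})

test_that("clustering handles the degenerate and single-cluster cases", {
  fx <- two_haplotype_fixture(1)
  one <- pca_cluster_homozygotes(fx$vm, fx$screen, k_clusters = 1)
  expect_true(all(one$cluster == 1L))

  # one individual duplicated: zero-variance PCA, all in cluster 1 at origin
  g <- matrix(rep(c(0L, 2L, 2L, 0L, 2L), 6), 6, 5, byrow = TRUE)
  dup <- toy_vm(g, focal = rep("hom-alt", 6))
  cl <- pca_cluster_homozygotes(dup, 1:5, k_clusters = 1)
  expect_true(all(cl$cluster == 1L))
  expect_true(all(cl$pc1 == 0) && all(cl$pc2 == 0))

  expect_error(pca_cluster_homozygotes(fx$vm, integer(0), 2), "empty")
  expect_error(pca_cluster_homozygotes(fx$vm, fx$screen, k_clusters = 50),
               "fewer homozygous")
})

test_that("haplotype screening applies the strict and relaxed rules", {
  fx <- two_haplotype_fixture(3)
  vm <- fx$vm
  # individual 1: pristine strict member of haplotype A
  # individual 2: one heterozygous screen site -> relaxed only
  vm$genotypes[2, fx$screen[4]] <- 1L
  # individual 3: two missing screen sites -> unassigned
  vm$genotypes[3, fx$screen[1:2]] <- NA
  scr <- haplotype_screen(vm, fx$screen, max_deviation = 1)
  m <- scr$members
  expect_equal(m$mode[m$sample == "s1"], "strict")
  expect_equal(m$mode[m$sample == "s2"], "relaxed")
  expect_false("s3" %in% m$sample)
  # the relaxed member attaches to the same haplotype as its group
  expect_equal(m$haplotype[m$sample == "s2"], m$haplotype[m$sample == "s1"])
  expect_error(haplotype_screen(vm, integer(0)), "empty")
})

test_that("screening is invariant to sample order and non-screen SNPs", {
  fx <- two_haplotype_fixture(4)
  scr1 <- haplotype_screen(fx$vm, fx$screen)
  perm <- sweepscape:::.with_seed(1, sample(fx$vm$samples))
  scr2 <- haplotype_screen(subset_variants(fx$vm, samples = perm), fx$screen)
  o1 <- scr1$members[order(scr1$members$sample), c("sample", "haplotype", "mode")]
  o2 <- scr2$members[order(scr2$members$sample), c("sample", "haplotype", "mode")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)

  # appending unrelated SNPs to the matrix does not change membership
  set.seed(9)
  extra <- matrix(sample(0:2, n_samples(fx$vm) * 5, TRUE), n_samples(fx$vm), 5)
  big <- variant_matrix(cbind(fx$vm$genotypes, extra),
                        c(fx$vm$chrom, rep("chr2", 5)),
                        c(fx$vm$pos, 1:5 * 100L),
                        samples = fx$vm$samples)
  scr3 <- haplotype_screen(big, fx$screen)
  expect_equal(scr1$members, scr3$members)
})

test_that("delta statistics are antisymmetric and refuse overlapping sets", {
  d <- sweep_study(2)
  vm <- d$vm
  wt <- setdiff(vm$samples, unlist(d$truth))[1:30]
  dp <- delta_stats(vm, d$truth$bgA, wt, "chr1")
  dq <- delta_stats(vm, wt, d$truth$bgA, "chr1")
  expect_equal(dp$delta_d$value, -dq$delta_d$value)
  expect_equal(dp$delta_pi$value, -dq$delta_pi$value)
  expect_equal(dp$delta_ld$value, -dq$delta_ld$value)

  expect_error(delta_stats(vm, d$truth$bgA, c(wt, d$truth$bgA[1]), "chr1"),
               "disjoint")
  expect_error(delta_stats(vm, d$truth$bgA[1:3], wt, "chr1"), "at least 4")
})

test_that("delta minima and LD maximum localise the sweep", {
  hits <- sapply(1:10, function(seed) {
    d <- sweep_study(seed)
    vm <- d$vm
    wt <- setdiff(vm$samples, unlist(d$truth))
    dp <- delta_stats(vm, d$truth$bgA, wt, "chr1")
    c(d = extremum_distance(moving_average(dp$delta_d, 10), 5e7) <= 1e6,
      pi = extremum_distance(moving_average(dp$delta_pi, 10), 5e7) <= 1e6,
      ld = extremum_distance(dp$delta_ld, 5e7, which.max) <= 2e6)
  })
  expect_gte(sum(hits["d", ]), 9)
  expect_gte(sum(hits["pi", ]), 9)
  expect_gte(sum(hits["ld", ]), 9)
})

test_that("between-background FST peaks at the locus and flags fixed SNPs", {
  d <- sweep_study(5)
  vm <- d$vm
  res <- pairwise_background_fst(vm, d$truth$bgA, d$truth$bgB)
  mid <- (res$max_window$win_start + res$max_window$win_end) / 2
  expect_lte(abs(mid - 5e7), 1e6)
  expect_true(all(res$highlighted$fst > 0.25))

  # a single fixed difference with no other variation is the sole highlight
  g <- cbind(c(rep(0L, 5), rep(2L, 5)), rep(1L, 10), rep(c(0L, 1L), 5))
  vm2 <- toy_vm(g)
  r2 <- pairwise_background_fst(vm2, paste0("s", 1:5), paste0("s", 6:10))
  expect_equal(r2$highlighted$pos, vm2$pos[1])
})

test_that("the scan-to-screen pipeline recovers carriers cleanly", {
  rec <- 0; tot <- 0; wt_strict <- 0
  for (seed in c(1, 6)) {
    d <- sweep_study(seed)
    vm <- d$vm
    rb <- recover_backgrounds(vm, carrier_focals(vm, d$truth), K = 1,
                              locus = d$locus)
    rec <- rec + sum(rb$members$sample %in% unlist(d$truth))
    tot <- tot + length(unlist(d$truth))
    strict <- rb$members[rb$members$mode == "strict", ]
    wt_strict <- wt_strict + sum(!strict$sample %in% unlist(d$truth))
  }
  expect_gte(rec / tot, 0.9)
  expect_equal(wt_strict, 0)
})
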