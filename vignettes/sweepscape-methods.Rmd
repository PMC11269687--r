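---
title: "Methods: detecting partial selective sweeps at resistance loci"
author: "sweepscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting partial selective sweeps at resistance loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Insecticide resistance alleles — kdr point mutations in the
voltage-sensitive sodium channel gene, or variants at detoxification
gene clusters such as the glutathione S-transferase epsilon array —
spread through pest populations by strong positive selection, often
without reaching fixation.  A *partial* sweep leaves the selected
haplotype segregating alongside wild-type backgrounds, frequently in
many populations at once and sometimes as several evolutionarily
independent backgrounds at the same locus.  `sweepscape` identifies
such backgrounds in reduced-representation SNP data (individuals ×
biallelic SNPs, unphased dosages 0/1/2 with missing calls) and
quantifies the three classical sweep signatures: locally elevated
linkage disequilibrium, an excess of low-frequency variants, and strong
differentiation between backgrounds.

# The pipeline and its assumptions

## Variant filtering and imputation

SNPs are retained when called in at least 50% of the individuals of
every population, 90% of individuals overall, and with minor allele
count ≥ 3 (`filter_variants`).  The per-population rule is evaluated
literally on the population column, including small populations;
merging small populations is done by editing that column upstream, not
by special-casing.  Multi-allelic records and indels are dropped at VCF
ingestion, never decomposed.

Missing-data imputation (`impute_missing`) replaces each missing call
with the per-SNP modal genotype, ties broken toward the lower dosage.
This deliberately simple rule replaces haplotype-reference imputation,
which would require phased panels that reduced-representation data
rarely support; it is deterministic and auditable.  Imputation is used
only upstream of the latent-factor scan.  **All windowed statistics,
Δ contrasts and depth ratios run on un-imputed matrices** — imputed
genotypes would bias diversity and LD estimates toward the major
haplotype.

## The structure-adjusted genome scan

`lfmm_scan` regresses each SNP's dosage on an intercept, the focal
resistance genotype (dosage 0/1/2), and K latent factors taken as the
first K principal components of the mean-filled, centred genotype
matrix (`latent_factors`).  The focal-coefficient t-statistic is
treated as a z-score, recalibrated by the genomic inflation factor
λ~gc~ = median(z²)/0.456 (0.456 being the median of a χ²₁ variate), and
converted to a two-sided normal p-value.  Benjamini–Hochberg adjustment
is applied over tested SNPs, and outliers are declared below the
inverse of the tested-SNP count — a deliberately harsh threshold that
keeps genome-wide false discoveries near zero.

This is a deterministic least-squares counterpart of MCMC latent factor
mixed models: the estimand (structure-adjusted association) is the
same, but repeated runs agree exactly and no convergence diagnostics
are needed.  The cost is that K must be supplied; a variance-explained
profile is attached to the factor matrix to guide the choice, and for
simulated two-population data K = 1 is correct.  SNPs with minor allele
frequency below 5% are not tested (association estimates there are
dominated by a handful of carriers).  Samples with unknown focal
genotype should be dropped before scanning.

## Background identification

Outlier SNPs inside the locus interval form the *screen set*.
`haplotype_screen` groups individuals that are homozygous and
non-missing at every screen SNP by their haplotype string (strict
members); individuals with at most one heterozygous-or-missing screen
site attach to the unique strict haplotype consistent with their
remaining sites, and ambiguous individuals stay unassigned rather than
being guessed.  Two safeguards in `recover_backgrounds` matter in
practice:

* **Minimum screen size** (default 8 SNPs).  When thresholding leaves
  fewer in-locus outliers, the set is topped up with the most strongly
  associated in-locus SNPs.  A one- or two-SNP screen cannot separate a
  shared swept haplotype from chance homozygosity.
* **Minimum group size** (default 5 strict members).  Haplotype groups
  smaller than this are usually wild types that happen to be homozygous
  at the screen SNPs, not swept backgrounds.

`pca_cluster_homozygotes` offers the complementary view: PCA of the
focal homozygotes on the outlier-SNP dosages with seeded k-means (50
restarts) on the first two components.  Individuals far from their
centroid (beyond the 0.9 distance quantile by default) are flagged
uncertain — typically recombinants or data-poor individuals drifting
toward the PCA centre.  Cluster assignment by eye is replaced by an
explicit, reproducible rule; a manual assignment can still be supplied
downstream wherever member sets are accepted.

## Windowed statistics

* **Tajima's D** (`tajimas_d`): half-open 5-kb bins `[5000k, 5000(k+1))`
  on 0-based coordinates.  Per bin, S counts segregating sites, k̂ sums
  the per-site unbiased pairwise-difference values
  2p(1−p)·n/(n−1), and D applies Tajima's constants evaluated at the
  modal per-site called-allele count in the bin.  Under missingness the
  modal count is a declared approximation; at the low missing rates the
  filters enforce it coincides with the complete-data formula.  Bins
  with usable sites but S = 0 are emitted with an undefined value; a
  site called in fewer than two individuals is skipped.
* **Nucleotide diversity** (`site_pi`, `binned_pi`): per-site values,
  averaged per bin over usable sites.
* **Genotype r²** (`genotype_r2`): squared Pearson correlation of
  dosage vectors over pairwise-complete samples.  Same-chromosome pairs
  are bounded to 500 bp – 100 kb separation: the lower bound removes
  within-RAD-tag comparisons, the upper bound caps the quadratic pair
  count.  Interchromosomal mode lifts the bounds entirely.
* **Weir–Cockerham F~ST~** (`wc_fst`): the 1984 variance components a,
  b, c per SNP; negative per-SNP estimates are retained, and windowed
  values use the ratio of sums Σa/Σ(a+b+c) over 5-kb windows sliding by
  1 kb.
* **Moving averages** (`moving_average`): unweighted means over the
  preceding `span` records within each chromosome (default 100 for
  genome-scale tracks); undefined values inside a window are excluded
  from its mean rather than poisoning it, and the first span−1 records
  are undefined.

## Δ contrasts and the LD profile

`delta_stats` computes ΔX(window) = X~background~ − X~wildtype~ for
binned D and π; windows undefined in either cohort are undefined in the
difference, and swapping the cohorts negates every defined value
exactly.  The wild-type cohort is the analyst's choice — all wild types
or population-matched wild types — and should match the populations the
background segregates in.

The ΔLD track needs more care than D and π because r² pairs are
unevenly distributed: a remote 100-kb bin holding three noisy pairs
must not outvote a locus bin holding three hundred.  The profile
therefore takes a **pair-count-weighted** mean over a centred rolling
window of 40 bins (≈ 4 Mb, about twice the expected swept-tract
length, so the window always brackets the tract), and windows with
fewer than 20 pairs in a cohort are undefined.  With unweighted means
or small windows the ΔLD maximum frequently lands on a sparse distant
bin; the weighted 4-Mb window localises it at the locus in 9 of 10
simulated replicates, with the residual misses reflecting genuinely
one-sided tract draws.

## Linkage networks

`linkage_network` scores SNPs at least 50 Mb from the locus (distance
measured from the nearest locus-interval edge; other chromosomes always
qualify) by their number of r² > 0.6 interactions with SNPs within
1 Mb of the locus, accumulated into half-open 500-kb bins.  The 100-kb
LD cap deliberately does **not** apply — long-range pairs are the whole
point.  One filter is essential: SNPs whose minor allele count *within
the analysis subset* is below 3 are excluded, because two subset-level
singletons riding in the same individual give r² = 1 regardless of any
selective history, and such pairs otherwise dominate the histogram
tails.  Total histogram mass always equals the number of qualifying
(candidate, near) pairs.  Gene annotation uses half-open interval
overlap, so a gene straddling a bin boundary annotates both bins.

## Copy number from depth ratios

`depth_ratio` computes, per individual, mean read depth over sites
inside the coding intervals of the target cluster divided by mean depth
over sites within 10 Mb upstream and downstream of the outermost coding
span (the span interior is excluded from the flank).  Sites below 1X
depth are excluded per sample — different samples may therefore use
different site sets, mirroring per-individual genotype filtering — and
individuals with fewer than 500 retained coding sites are omitted.
Flank sites are pooled (site-count weighting); an equal-window
weighting flag exists for sensitivity analysis.  The per-individual
sequencing-effort multiplier cancels exactly in the ratio, which is why
`flank_consistency` (the squared correlation of upstream and downstream
flank means across individuals) sits near 1 whenever the flanks are a
sound baseline.  Regional comparison uses one-way fixed-effects ANOVA;
a grouping with zero within-group variance reports an infinite F and
p = 0 rather than an error.

## Admixture

`f3_test` uses the bias-corrected per-SNP statistic
(c−a)(c−b) − c(1−c)/(n~C~−1), averaged over SNPs, with a delete-one
jackknife over consecutive 500-SNP blocks for the standard error and a
one-sided p-value for f3 < 0.  A warning is raised below 20 blocks,
where the jackknife is unreliable — a realistic concern for
reduced-representation panels.  `pca_projection` builds PC1 from the
centred, frequency-standardised dosages of the two source populations
only (SNPs restricted to those polymorphic in the source pool,
standardised by √(2p(1−p))), projects query samples with the same
centring and loadings, and reads the admixture proportion off the line
between the source means, clipped to [0, 1].  The axis is oriented with
source A at the negative end so the proportion is well-defined.

# The synthetic-data generator

The generator produces data with known ground truth for every stage; it
is not a population-genetic forward simulator.

* **Structure**: the Balding–Nichols model — ancestral frequencies
  Uniform(0.05, 0.95), population frequencies Beta-distributed around
  them with drift parameter F, genotypes binomial.  The defaults (two
  populations of 50 diploids, F = 0.1, 5,000 SNPs on two 150-Mb
  chromosomes, 0.5% missing calls, depth 20X) describe a clean
  post-filter reduced-representation panel of moderately differentiated
  populations; the measured genome-wide weighted F~ST~ under these
  defaults is 0.10.
* **Sweeps** are planted by forward construction: each carrier
  chromosome receives a swept tract extending
  max(core, Exponential(mean tract)) on each side of the locus, inside
  which its alleles are overwritten by the background haplotype (one
  allele per SNP, drawn from the pooled sample frequency so the
  background looks like a plausible haplotype rather than an alien
  one).  Homozygous carriers get two swept chromosomes.  Defaults:
  2-Mb mean tract, 0.5-Mb always-swept core, and 0.5 new private
  singleton variants per swept chromosome placed at random tract SNPs —
  few enough to be realistic at reduced-representation SNP density,
  numerous enough that the rare-variant excess is present by
  construction and not an artifact of the overwrite.  Forward
  construction was chosen over coalescent simulation precisely because
  it yields exact per-individual membership and tract extent, which is
  what the screening and Δ stages are tested against.
* **Depth**: per-individual effort Gamma(shape 10, mean 20X), per-site
  depth Poisson(effort × copy/2), with the copy number raised inside a
  declared CNV region.
* **Admixture**: admixed allele frequencies are the α-mixture of the
  two sources' empirical frequencies, optionally drifted by binomial
  resampling (e.g. 20 generations at N = 200) before genotypes are
  drawn.

What the generator does *not* emulate: linkage disequilibrium in the
neutral background (SNPs are exchangeable given population
frequencies), mutation-rate heterogeneity, selection coefficients or
sweep timing, sequencing error in genotypes, and reference bias.
Passing the simulated suites therefore demonstrates that the estimators
and the pipeline logic are correct under the stated generative model —
not that real data meet that model.  In particular, real background LD
will widen the scan's outlier clusters, and real sweep ages affect
tract lengths in ways the single mean-tract knob only summarises.

# Numerical and design choices

* Coordinates: VCF positions are 1-based; all intervals are half-open
  0-based (BED convention); conversion happens only at I/O boundaries.
* Genotype r² pairs are computed exactly over pairwise-complete samples
  via indicator cross-products — no mean-filling in LD.
* Zero-variance SNPs in LD computations are skipped and counted, never
  silently returned as 0 or 1.
* k-means uses a fixed seed and 50 restarts; PCA signs are fixed by
  orienting the largest-magnitude score positive, so repeated runs and
  duplicated inputs agree exactly.
* The f3 block size defaults to 500 SNPs; the Bonferroni adjustment
  spans all triads tested in one run.
* Degenerate inputs have defined behaviour: fully missing SNPs raise an
  error naming the site; constant focal vectors are rejected; an
  all-identical PCA input yields a single cluster at the origin;
  perfect ANOVA fits report F = ∞, p = 0.
* Problem sizes in the test and acceptance suites — 100 individuals,
  5,000 SNPs, ten replicate seeds for the recovery and localisation
  suites, 200 random instances for oracle equivalence, 10,000 SNPs for
  f3 — were chosen as the smallest sizes at which the expected effects
  are comfortably resolved.

# Known limitations

* The scan's least-squares formulation does not model relatedness
  beyond the latent factors; cryptic kinship inflates z-scores.
* The haplotype screen assumes the swept core is homozygous in
  carriers; soft sweeps from standing variation with multiple core
  haplotypes per selection event will be split into separate groups.
* Depth ratios are relative to the individual's own flanks: a CNV
  spanning both the target and its flanks is invisible.
* f3 on reduced-representation data is underpowered for old or
  asymmetric admixture; a non-significant f3 is not evidence of no
  admixture.
* Per-region mean depth ratios depend on library depth profiles and are
  comparable within a study, not across studies.
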