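# riskenhancer

Post-GWAS functional annotation of risk loci in regulatory chromatin, as a
tested R pipeline with a synthetic ground truth.

A genome-wide association study reports *index SNPs* that tag risk
haplotypes; the causal variants are usually other SNPs in linkage
disequilibrium (LD) with them, sitting in cell-type-specific regulatory
elements. `riskenhancer` implements the full annotation chain for that
hypothesis, for analysts who want each stage testable rather than taken on
faith:

* **LD expansion** — per-population proxy search from phased haplotype
  panels: r² by direct haplotype counting
  (`r² = D² / p_A(1−p_A) p_B(1−p_B)`), a centered window (default
  ± 500 kb), cutoff r² ≥ 0.5, cross-population tiers (`shared`,
  `shared_high`).
* **Chromatin filtering & classification** — membership in biofeature
  tracks (DNase I, histone marks, TF ChIP-seq peaks), strand-aware
  promoter windows (−1000 bp to +100 bp of the TSS), one class per SNP
  under an explicit precedence (coding exon > miR-UTR > promoter >
  enhancer), locus merging by union-find, Jaccard/average-linkage
  clustering of the SNP × biofeature matrix.
* **Motif disruption** — a positionally weighted, consensus-normalized PWM
  score `s = Π_i (f_i,b / max_b f_i,b)^{w_i}` with information-content
  weights: consensus scores exactly 1, zero-frequency bases (pseudocount
  off) score exactly 0. Allele-aware scanning calls a *disruption* when
  the stronger allele reaches `tau_match` and the allelic difference
  reaches `tau_delta`.
* **Bootstrap enrichment** — per-PWM z scores
  `z = (n − μ_B) / σ_B` against 200 resampled draws of 663 SNPs from a
  background universe (optionally biofeature-restricted), with
  Bonferroni-corrected empirical 95% intervals.
* **Hierarchical Bayesian reporter model** — for luciferase plate data,
  `log y ~ N(L0 + E_e + A_e·D + P_p + T_t + B_b, σ_g)` with the stated
  t/Cauchy/normal priors, fit by adaptive Metropolis-within-Gibbs with
  recentering moves; posterior contrasts for basal allelic activity and
  androgen induction with 95% credible intervals and R-hat/ESS
  diagnostics.
* **Synthetic data with known truth** — block-LD haplotype panels (target
  pairwise r² hit analytically), two-population panels with planted
  dual-population proxies, biofeature tracks, PWM libraries with planted
  allele-disrupting variants, and plate-structured reporter data — plus
  writers/readers for phased VCF, BED, JASPAR-like PWM text and plate
  CSV.

See `vignettes/methods.Rmd` for the models, priors, numerical choices and
their rationale.

## Worked example

Simulate a two-population study, expand an index SNP, and filter by
chromatin:

```r
library(riskenhancer)

gs <- genome_spec("chr1", 10e6, seed = 1)
tp <- simulate_two_population_panels(gs, shared_variants = 120,
                                     ld_divergence = 0.5, seed = 1,
                                     n_samples = 250, n_pairs = 20)
tracks <- generate_biofeature_tracks(gs, c("DNaseI", "H3K27Ac", "AR"),
                                     density = 50,
                                     width_range = c(1000, 3000), seed = 2)
idx <- tp$truth$index_id[1]
corr <- find_correlated_snps(tp$panels, idx, window = 1e6, r2_min = 0.5)
corr <- intersect_populations(corr, c("popA", "popB"))
ann <- annotate_biofeatures(corr, tracks)
ann[, c("id", "pos", "r2_popA", "r2_popB", "tier", "n_biofeatures")]
#>        id    pos   r2_popA   r2_popB        tier n_biofeatures
#> 1 snp0001  82645 1.0000000 1.0000000 shared_high             1
#> 2 snp0002 165289 0.8957917 0.9107479 shared_high             1
```

The index (`snp0001`) and its planted proxy (`snp0002`, pairwise r² ≈ 0.9
in both populations, hence `shared_high`) both fall in a biofeature and
survive; unlinked variants do not.

Fit the reporter model to simulated plate data for two alleles of one
enhancer (true basal ratio e^0.33 ≈ 1.39, true induction of the A allele
e^1.9 ≈ 6.7, true induction ratio e^0.25 ≈ 1.28):

```r
sim <- simulate_luciferase_dataset(
  c("JAZF1_G", "JAZF1_A"),
  true_params = list(L0 = 2,
                     E = c(JAZF1_G = 0.80, JAZF1_A = 0.47),
                     A = c(JAZF1_G = 1.65, JAZF1_A = 1.90),
                     P_sd = 0.1, T_sd = 0.1, B_sd = 0.1),
  n_batches = 2, noise_sd = 0.1, seed = 5
)
fit <- fit_model(build_design(sim$observations), chains = 2,
                 iterations = 4000, warmup = 2000, seed = 6)
contrast_basal(fit, "JAZF1_G", "JAZF1_A")
#> basal JAZF1_G / JAZF1_A: 1.440 (95% CI 1.247-1.659, fold scale)
contrast_induction(fit, "JAZF1_A")
#> induction JAZF1_A: 6.544 (95% CI 6.338-6.747, fold scale)
contrast_induction_ratio(fit, "JAZF1_A", "JAZF1_G")
#> induction ratio JAZF1_A / JAZF1_G: 1.259 (95% CI 1.209-1.312, fold scale)
fit$converged
#> [1] TRUE
```

Each 95% credible interval covers its generating truth; the
`converged` flag reports split-chain R-hat ≤ 1.05 on all enhancer and
androgen effects.

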