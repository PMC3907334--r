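---
title: "Methods: from GWAS tag SNPs to risk enhancers and allele-specific activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from GWAS tag SNPs to risk enhancers and allele-specific activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskenhancer)
```

# The problem

A genome-wide association study reports *index SNPs*: variants whose
genotypes correlate with disease risk. An index SNP is rarely the causal
variant; it tags a haplotype block, and any variant in strong linkage
disequilibrium (LD) with it is an equally good statistical candidate. Most
such variants fall outside protein-coding sequence, so the working
hypothesis is that the causal alleles perturb *regulatory* elements —
enhancers and promoters active in the disease-relevant cell type. This
package implements, end to end and on testable synthetic data, the standard
post-GWAS functional-annotation chain:

1. **LD expansion** — find all variants correlated with each index SNP
   (r² at or above a cutoff, within a window), separately per population.
2. **Chromatin filtering** — keep variants inside cell-type-specific
   "biofeatures" (DNase I hypersensitive sites, histone-mark and
   transcription-factor ChIP-seq peaks) and classify them as promoter,
   enhancer, coding-exon or microRNA-target variants.
3. **Response-element disruption** — score both alleles of each candidate
   against a transcription-factor motif library and flag variants whose
   alleles differ enough to plausibly alter binding.
4. **Enrichment** — ask whether specific factors' motifs are disrupted more
   often than expected under resampled SNP backgrounds.
5. **Reporter-assay modelling** — for candidate enhancers cloned into
   luciferase constructs, estimate allele-specific basal activity and
   androgen induction with a hierarchical Bayesian model that accounts for
   the nuisance structure of plate experiments.

Every stage is driven by a synthetic-data generator with known ground
truth, so the pipeline's operating characteristics (recovery, calibration,
false-positive behaviour) are measured rather than assumed.

# Linkage disequilibrium

r² between two biallelic variants is computed by direct counting on phased
haplotypes: with haplotype frequency $p_{AB}$ and allele frequencies
$p_A, p_B$,

$$D = p_{AB} - p_A p_B, \qquad
  r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}.$$

Unphased input is rejected rather than EM-imputed: reference panels of the
kind this analysis consumes are phased, and direct counting is exactly
testable against enumeration. Monomorphic sites have undefined LD and are
skipped with a warning. The proxy search takes "a 1 Mb window" to mean
index ± 500 kb (the window is *centered*; the bound is configurable), uses
r² ≥ 0.5 by default, computes LD separately for each population in which an
index SNP was reported, and always includes the index SNP itself among the
candidates. Cross-population support is tiered: `shared` means the proxy
holds r² ≥ 0.5 in every requested population, `shared_high` raises the bar
to 0.8.

**LD simulation.** Within a block, every variant copies a template
haplotype, resampling each haplotype's allele with probability
$\varepsilon$; a variant then correlates with the template at
$r = 1-\varepsilon$ and a pair of block-mates achieves
$r^2 = (1-\varepsilon)^4$ in expectation, so
$\varepsilon = 1 - \rho^{1/4}$ hits a target pairwise r² of $\rho$
analytically — no tuning loop. Allele frequency is drawn per block from
`maf_range` (default 0.05–0.5); allele 0 is the reference. The
two-population generator plants index/proxy pairs that are in high LD in
both populations or in one only, in a controlled ratio (`ld_divergence`),
and records the assignment in a truth table. What this emulates is block
LD with known pairwise targets; it does **not** emulate recombination
gradients, allele-frequency divergence between populations, or realistic
human LD maps — passing tests show correctness of the machinery, not
realism of the haplotypes.

# Functional classification

SNP positions are intersected with interval tracks. Internally all interval
work uses 1-based closed `GRanges`; BED files are half-open on disk and
converted on ingest, so a SNP at a BED interval's `end` coordinate is *not*
a member. Promoter windows are computed strand-aware as −1000 bp to
+100 bp around each transcription start site. A variant matching several
categories is counted once under an explicit precedence:

> coding exon > miR-target-in-UTR > promoter > enhancer > unclassified.

The source analyses this mirrors never state their assignment rule (their
per-class counts don't quite sum to their total); ours is explicit and
configurable, and class counts partition the classified set by
construction. Index SNPs are merged into risk loci by union-find: two
indexes join when their pairwise r² reaches `merge_r2` (default 0.5) in any
shared population or when they share at least `shared_min` (default 3)
correlated SNPs; loci are numbered in genomic order. The SNP-by-biofeature
incidence matrix is clustered with Jaccard distance and average linkage,
rows and columns pre-sorted by label so results are order-invariant.

# Motif scoring

The literature this package operationalizes states only the *properties*
of its motif score — it ranges from 0 to 1 and weights positions by
importance. The score implemented here is the positionally weighted,
consensus-normalized product

$$s(\text{seq}) \;=\; \prod_{i=1}^{L}
  \left(\frac{f_{i,b_i}}{\max_b f_{i,b}}\right)^{w_i},
\qquad
 w_i = \frac{\mathrm{IC}_i}{\max_j \mathrm{IC}_j},
\qquad
 \mathrm{IC}_i = 2 + \sum_b f_{i,b}\log_2 f_{i,b},$$

an explicit stand-in chosen to satisfy those properties: the consensus
sequence scores exactly 1, a zero-frequency base (with pseudocounts
disabled) scores exactly 0, substituting a lower-frequency base can never
raise the score, and information-rich positions dominate. Both knobs are
switchable (`weights = "ic"` or `"uniform"`; pseudocount default 0.001,
disable with 0), and with uniform weights the score reduces to the plain
consensus-normalized product. Scanning covers both strands with ties broken
toward the smallest offset and the + strand.

A variant's *disruption call* restricts scanning to placements covering the
variant, scores each allele, and applies two thresholds: the stronger
allele must reach `tau_match = 0.8` (the variant sits in a plausible
binding site at all) and the allelic score difference must reach
`tau_delta = 0.2` (binding plausibly differs by allele). Neither threshold
is inherited from the source analyses, which state none; both are exposed
and reported. This separation — disruption, not mere membership — is what
the enrichment stage counts.

# Enrichment against resampled backgrounds

For each motif $f$ and background $B$, the observed disruption count
$n_f$ is standardized,

$$z_f^B = \frac{n_f - \mu_f^B}{\sigma_f^B},$$

with $\mu, \sigma$ the mean and (n−1) standard deviation of per-draw counts
over 200 draws of 663 SNPs sampled uniformly *without replacement within a
draw* (draws independent of each other) from the background universe —
either unrestricted SNPs or SNPs inside the same biofeature regions used
upstream. Per-motif empirical 95% intervals use type-7 quantiles at
2.5%/97.5%; the Bonferroni-corrected variant divides across the $m$ motifs
tested (probabilities $\alpha/2m$, $1-\alpha/2m$). A stated lower quantile
of "2.75%" in the source is treated as a typo for 2.5% — it is paired with
97.5% to form "the 95% confidence interval" — and both modes are
available. Motifs with zero background variance are reported with an
undefined z rather than dropped. A Shapiro–Wilk statistic on the finite z
values is reported as a diagnostic only; nothing is gated on it.

# The luciferase model

Each measurement is a luminescence reading from one well: enhancer-allele
construct $e$, DHT indicator $D$, plasmid prep $p$, transfection $t$,
plate batch $b$. On the natural-log scale,

$$\log y_i \sim \mathcal N\!\big(\mu_i,\ \sigma_{g(i)}\big), \qquad
\mu_i = L_0 + E_{e(i)} + A_{e(i)} D_i + P_{p(i)} + T_{t(i)} + B_{b(i)}.$$

Priors follow the stated hierarchy, with every exponential parameterized by
its **mean**: $E \sim t(\nu_E, s_E)$, $\nu_E \sim \mathrm{Exp}(20)$,
$s_E \sim \mathrm{Exp}(8)$; $A \sim \mathrm{Cauchy}(0, s_A)$,
$s_A \sim \mathrm{Exp}(1/2)$; $P \sim \mathcal N(0, s_P)$,
$s_P \sim \mathrm{Exp}(1)$; $T \sim t(\nu_T, s_T)$,
$\nu_T \sim \mathrm{Exp}(3)$, $s_T \sim \mathrm{Exp}(1/2)$. Two points the
source leaves open were decided as follows:

* **Batch prior.** No prior is stated for $B$; we use
  $B \sim \mathcal N(0, s_B)$, $s_B \sim \mathrm{Exp}(1)$, mirroring the
  prep effect.
* **Noise pooling.** The noise scales are "exchangeable" with an
  exponential hyperprior of mean 1 but their intermediate distribution is
  not recoverable; the default is one scale per enhancer × condition
  group, $\sigma_g \sim \text{half-}\mathcal N(\tau)$,
  $\tau \sim \mathrm{Exp}(1)$, with a `noise = "global"` switch.
* **Reference level.** $L_0$ is "the average of all data for the two
  negative control enhancers"; we implement this as a hard constraint —
  $L_0$ fixed at the empirical mean of the log negative-control readings,
  the two negative-control $E$ pinned at 0 — which keeps the posterior
  proper and makes all contrasts invariant to rescaling the luminometer
  (adding a constant to all log readings shifts $L_0$ only).

**Sampling.** The model is fit by adaptive Metropolis-within-Gibbs.
Within one factor, levels touch disjoint observations, so all levels are
proposed and accepted *simultaneously* with per-level random-walk steps
(positive parameters walk on the log scale with the Jacobian included).
Proposal scales adapt during warmup toward ≈0.35 acceptance and are frozen
afterwards. Because additive hierarchies create likelihood-flat ridges
(e.g. $E_e + \delta$, all its $P_p - \delta$), the sampler interleaves
likelihood-invariant *recentering moves* along the E↔P, P↔T, B↔T and E↔T
ridges, accepted on prior ratios alone; these are cheap and repeated five
times per sweep, and are what makes the chains mix across the
decomposition rather than within one arbitrary one. Chains start jittered;
split-chain R-hat and autocorrelation ESS are computed for every stored
parameter, and a fit whose enhancer or androgen effects exceed R-hat 1.05
carries an explicit non-convergence flag. Defaults are 4 chains of 4,000
iterations (half warmup); the gradient-free sampler is an implementation
vehicle, not a claim — any sampler meeting the same contract may back it.

Contrasts are per-draw transforms summarized by mean and 2.5th/97.5th
percentiles: basal allelic fold $\exp(E_1 - E_2)$, androgen induction
$\exp(A_e)$, and induction ratio $\exp(A_1 - A_2)$.

**Simulator.** The generative counterpart draws nuisance effects
$P, T, B$ as zero-centered normals at given scales and reproduces the
typical plate layout: 6 preps per enhancer, 4 transfections per prep per
batch, duplicate wells, vehicle and DHT arms, and the two negative
controls plus the positive control on every batch. With all nuisance
scales and the noise set to zero the log readings equal the linear
predictor exactly.

# Calibration and problem sizes

The package's own checks run at desk scale, chosen once as the smallest
sizes at which the statistical assertions are meaningful:

* **LD oracle**: 100 random panels (≤ 50 variants, ≤ 200 haplotypes)
  against brute-force counting at 10⁻¹² tolerance.
* **End-to-end recovery**: a 10 Mb genome, 120 shared variants, 20 planted
  index/proxy pairs at divergence 0.5, 250 samples per population, three
  biofeature tracks at 50 features/Mb; the surviving SNP set
  {± 500 kb, r² ≥ 0.5, ≥ 1 biofeature} must equal an
  independently-computed oracle set exactly, and the `shared` tier must
  equal the planted dual-population pairs.
* **Enrichment null**: a 20,000-SNP universe with 20 motifs at disruption
  rates 0.05–0.5 (rates high enough that count discreteness does not
  distort interval coverage), 200 draws of 663, 500 null replicates;
  uncorrected 95% intervals should contain ≈ 95% of null counts and the
  mean null z should sit within ±0.1 of 0.
* **Credible-interval calibration**: 50 replicates of a reduced design
  (2 enhancers × 2 alleles, 3 preps, 2 transfections, 2 batches,
  duplicates) with effects and hyperparameters drawn from the priors —
  extreme hyperparameter draws truncated (scales capped, effects clipped
  to ±3) so simulated luminescence stays finite — noise sd 0.1, refit with
  2 chains × 1,200 iterations. The nominal 95% interval for the basal
  allelic contrast should cover truth ≈ 95% of the time, and the
  posterior-mean log contrast should be unbiased within 0.05. Because the
  fitted priors are slightly wider than the truncated generating ones,
  coverage errs mildly conservative. Nuisance transfection effects are
  generated normal while the model fits them with a t prior; at these
  scales the effect on contrast coverage is negligible.

# Known limitations

* The motif score and its positional weights are principled stand-ins for
  an under-specified original; absolute score values should not be
  compared across implementations, only the documented properties relied
  on.
* The LD generator produces exchangeable block structure, not coalescent
  haplotypes; population divergence is modelled only as presence/absence
  of pairwise LD.
* The enrichment backgrounds resample labels, not sequence; motif-to-motif
  correlation (overlapping binding sites) is present only to the extent
  the label matrix encodes it.
* The luciferase model assumes log-normal noise and additive effects on
  the log scale; saturation or plate-position gradients are out of scope.
* Real ChIP-seq data and reference genotype panels are deliberately out of
  scope for testing; all guarantees are relative to the synthetic
  generators above.
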