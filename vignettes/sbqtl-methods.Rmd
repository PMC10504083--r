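---
title: "Sex-biased QTL mapping with sbqtl: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-biased QTL mapping with sbqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sbqtl` implements a complete analysis chain for sex differences in the
genetic regulation of molecular traits: preprocessing, sex-differential
expression, two-stage sex-biased QTL (sb-QTL) discovery, replication
statistics, and sex-stratified causal integration. This vignette is the
package's own account of the statistical machinery: what each model assumes,
which knobs matter, what the synthetic cohorts do and do not emulate, and
where the design was genuinely open.

## 1. The regression engine

Every scan in the package is ordinary least squares with t-based inference
(`ols_fit()`, QR decomposition, pivot tolerance 1e-10; rank deficiency is an
error that names the offending columns rather than a silent drop). The
genome-scale scans do not call `ols_fit()` per pair — that would be millions
of QR factorizations — but use the Frisch–Waugh–Lovell reduction: the
response, the dosage, and (for the interaction model) the dosage-by-sex
product are each residualized once on the fixed covariate block
(intercept, sex where applicable, surrogate variables, genetic PCs), after
which the per-pair fit is a closed-form one- or two-predictor regression
with degrees of freedom adjusted for the full design. This is algebraically
identical to the full OLS — the test suite asserts equality against
`ols_fit()` to 1e-10 — and is what makes a 50-replicate null-calibration
study affordable on one CPU.

Assumptions inherited from OLS: homoscedastic residuals within the analyzed
stratum, effects linear in allele count, independent samples (relatedness is
handled upstream by `kinship_prune()`). Hemizygous male X genotypes coded
0/2 double the male dosage variance on X; the interaction test compares
per-allele slopes between sexes under that coding, which is the convention
the dosage container enforces.

## 2. Preprocessing and the protected sex effect

Proteomic matrices pass through missingness filtering (gene dropped when
missing in more than 50% of samples, strict), per-sample total-abundance
normalization with log2 transform (scale-invariant per sample), iterative
PC outlier removal (samples beyond 4 SD on PC1/PC2, iterated to a fixed
point, hard error after 20 iterations), nuisance regression (batch, age,
post-mortem interval, diagnosis — sex is a *protected* variable and passing
it is an error), and per-gene z-scoring. Transcript counts instead use a
per-diagnosis-group CPM filter (kept if any diagnosis group expresses the
transcript at ≥ 1 CPM in more than half its samples) followed by
log2(CPM + 0.5). The variance-stabilizing transform used by count-model
packages was deliberately replaced by log-CPM: it is transparent, exactly
reproducible, and adequate for the filtered, moderately expressed
transcripts this pipeline analyzes; heteroskedasticity at very low counts
is the known cost.

Hidden-factor estimation (`estimate_svs()`) residualizes the expression
matrix on sex, takes the SVD of the residual, and keeps leading components
whose singular values exceed the 95th percentile of singular values from 20
row-wise permutations (parallel analysis). Because the matrix is
residualized on sex *before* the SVD, every surrogate variable is orthogonal
to the sex indicator by construction — the protection contract is a theorem
about the algorithm, not an empirical hope, and the tests assert it to
1e-8. A fixed component count (`n_sv`) is available for studies that fix k
a priori. The trade-off versus iteratively-reweighted surrogate-variable
estimation: no reweighting toward null genes, hence somewhat conservative k
when signal is pervasive; in exchange the algorithm is deterministic,
seedable, and its selection rule is directly testable.

## 3. The two-stage sb-QTL procedure

Stage 1 scans every cis pair (variant within 500 kb of the gene body,
1-based inclusive arithmetic) three times — jointly with sex as a covariate,
and within each sex — and takes the union of BH-significant pairs
(FDR < 0.05 per mode, across all tested pairs of that mode). Stage 2 fits
the interaction model and declares sb-QTLs at interaction FDR < 0.05 among
stage-1 pairs.

**The stage-2 FDR universe was the one genuinely open design decision.**
Two readings exist: adjust over the stage-1 pairs only, or over all tested
cis pairs. The package implements both (`interaction_scan(universe=)`) and
defaults to **all tested pairs**, for a calibration reason discovered during
development: a pair can enter stage 1 through a single sex's scan alone,
and such pairs are selected for a large per-sex slope — a winner's-curse
conditioning that inflates their interaction statistic even when the true
interaction is zero. With the small stage-1-only universe the BH threshold
is lenient and these pairs become false sb-QTL genes at far above the
nominal rate (empirical gene-level FDR around 0.6 in null simulations);
with the all-pairs universe the threshold is strict enough that calibration
holds (empirical FDR ≈ 0.04 at nominal 0.05 over 50 null replicates, and
genomic-control λ of the interaction p-values ≈ 1.00). The
larger universe costs power only for marginal effects.

Significant pairs are LD-clumped per gene: greedily take the smallest-p
unassigned record as an index (ties broken by position, then id) and absorb
unassigned records within 250 kb at r² ≥ 0.5 (r² from mean-imputed,
standardized dosages in the full analysis sample — not per sex). The index
count at r² ≥ 0.1 is reported alongside as the independent-signal count.
Index records are classified from the per-sex scans (both-concordant /
both-discordant / male-only / female-only); stage-1 pairs carried only by
the joint scan are assigned by the larger per-sex |Z| and flagged
`joint_only` rather than discarded.

The largest raw interaction p among significant records (`stage_p`) is the
p-value threshold implied by the FDR cut; it parameterizes the
environment-confounding check, which (i) tests each environment variable
for a sex difference, (ii) screens index SNPs for SNP-by-environment
interactions at `stage_p`, and (iii) refits flagged SNPs with both
interaction terms, labelling the record `robust` or `attenuated` by whether
the SNP-by-sex term survives.

## 4. Replication: Storey's π1

`storey_pi1()` implements the λ-grid estimator (0.05–0.95 in steps of
0.05), natural-cubic-spline smoothing with evaluation at λ = 0.95 and
clipping to [0, 1]; below 50 p-values, or if the spline degenerates, it
falls back to the fixed-λ = 0.5 estimate. The smoother is the right default
for thousands of tests, but its boundary evaluation is noisy below roughly
two thousand p-values — its null 95th percentile stays above 0.1 in that
regime. Discovery index sets in this pipeline number in the tens to low
hundreds, so `pi1_replication()` defaults to the fixed-λ estimator (the
same conservative choice the small-sample fallback prescribes) and exposes
`method = "smoother"` for large replication panels. Replication records are
matched by gene, variant and alleles, with swapped-allele records
harmonized by a sign flip (which leaves the interaction p unchanged).

## 5. Sex-stratified causal integration

Per sex: (i) cis heritability by single-variance-component REML — kernel
XXᵀ/m on standardized cis dosages, intercept projected out, restricted
likelihood profiled over h² on a 0.01 grid with local refinement from one
eigendecomposition; the LRT against h² = 0 uses the boundary mixture
½χ²₀ + ½χ²₁, and `heritable` means p < 0.01. (ii) For heritable genes,
expression weights from ridge (a BLUP-style shrinkage fit), lasso and
elastic net, each with inner-CV penalty selection, scored by out-of-fold R²
over 5 seeded folds; the best model's weights are kept. An MCMC-based
sparse mixed model was deliberately excluded — best-of-three preserves the
"best-performing prediction model" selection semantics at a small cost in
sparse-architecture accuracy. (iii) PWAS: z = wᵀz_gwas / √(wᵀRw) with 0.01
added to R's diagonal as a ridge stabilizer; alleles harmonized by id with
sign flips for swaps and strand-ambiguous (A/T, C/G) variants dropped; BH
across genes within stratum. The LD reference defaults to the analysis
cohort itself; an external panel can be supplied. (iv) Colocalization by
per-variant Wakefield log-ABFs, log ABF = ½[log(1−r) + r·z²] with
r = W/(W + se²) and prior effect SD 0.15 (0.2 recommended for binary
traits), hypothesis sums in log space, priors p1 = p2 = 10⁻⁴, p12 = 10⁻⁵;
posteriors PP0–PP4 normalized to 1 within 1e-10. Where only z and n are
available, se is reconstructed as 1/√n on the standardized scale.

A gene is **female-only causal** when its female PWAS is FDR-significant
(q < 0.05), female PP4 > 0.75, and the male PWAS is either absent — not
heritable in males, logged as such — or has raw p > 0.05; male-only is
symmetric, `both` requires the q and PP4 conditions in both sexes. The rule
treats non-heritability and missingness identically (both are an absent
record), which is the only coherent reading when a stratum cannot be tested.

## 6. The synthetic cohorts

`sim_config()` defines the generative model: balanced-sex cohorts (default
n = 700, matching a realistically sized joint discovery set), 100 genes ×
50 cis SNPs, MAF ~ U(0.05, 0.5), LD from thresholded latent-Gaussian blocks
(block size 10, ρ = 0.8) — fast and adequate for clumping and
colocalization, though without recombination-map realism — 10% of genes on
X with hemizygous male coding, sparse effect classes (sex main effects:
15% of genes at SD 0.5; cis effects: 40% at SD 0.5; interactions: 10% at
SD 0.4; three hidden factors loading on 30% of genes at SD 0.4; unit noise).
Hidden factors are drawn independent of sex so the protection contract is
testable; a sex-correlated environmental driver can be planted explicitly
to exercise the confounding check. Replication pairs share the variant
layout and discovery truth, retain a configurable fraction of nonzero
interaction effects, and default to the discovery sample size — equal sizes
make π1 estimate the planted replication fraction rather than replication
power, which is the quantity the recovery checks need; unequal real-world
splits are reproduced by setting `n_replication`. GWAS summary statistics
come from an independent 20,000-sample cohort (regenerated gene-by-gene
from per-gene seeds, so memory stays flat) with a phenotype mediated by the
simulated proteins through sex-specific effects.

What the simulator does *not* emulate: missing-not-at-random proteomics,
batch structure within mass-spectrometry runs, population stratification
beyond a two-group toy, fine-scale recombination, and trans effects.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not robustness to every
artifact of real cohorts.

## 7. Numerical choices and problem sizes

Tie-breaks: clumping resolves equal p by position then variant id; isoform
selection resolves equal means lexicographically. Degenerate inputs:
monomorphic variants are skipped with counts (scans) or return p = 1 (HWE);
collinear interaction designs (dosage constant within one sex) are skipped
with a reason; constant expression is an error for heritability and a
warned drop for z-scoring. Zero p-values are clamped to the smallest
positive double in λ computation with a warning. All randomness flows
through explicit seeds; helper RNG state is saved and restored so library
calls never perturb the caller's stream, and the full pipeline is
byte-identical across reruns with the same seed.

The validation studies run at: 50 null replicates of 100 genes × 50 SNPs ×
700 samples for FDR calibration and λ; 200 planted interactions for bias;
3-point grids in effect size and sample size for power monotonicity (100
genes per cell); two pooled discovery/replication pairs of 300 genes per
replication fraction for π1; 50 seeded colocalization panels and 50
end-to-end mediation runs for the causal layer. These sizes were chosen to
put Monte-Carlo error comfortably below the tolerances being asserted while
staying desk-scale.

## 8. Known limitations

Single-variant association only (no conditional analysis beyond clumping,
no fine-mapping); no multi-region meta-analysis — multi-region inputs are
analyzed per region and reported side by side; OLS rather than mixed models
(close relatives must be pruned, residual structure beyond the surrogate
variables is not modeled); the coloc layer assumes at most one causal
variant per trait per locus; and the environment check is a screen at the
stage threshold, not a causal decomposition of the interaction.
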