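---
title: "Methods: paired BS/oxBS hydroxymethylome analysis with oxbspipe"
author: "oxbspipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired BS/oxBS hydroxymethylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxbspipe)
```

## The measurement problem

Conventional bisulfite (BS) conversion leaves both 5-methylcytosine (5mC)
and 5-hydroxymethylcytosine (5hmC) protected, so a BS array beta value at a
CpG reads the sum `m + h` of the two modification fractions. Oxidative
bisulfite (oxBS) conversion first oxidizes 5hmC so that it converts like
unmodified cytosine: an oxBS beta reads `m` alone. Profiling the same DNA
through both channels therefore turns hydroxymethylation into a paired
deconvolution problem: per CpG and per culture replicate,

- BS channel: `beta_bs` estimates `m + h`,
- oxBS channel: `beta_ox` estimates `m`,
- the naive 5hmC signal is `beta_bs - beta_ox`.

`oxbspipe` implements this analysis end to end for a three-condition liver
progenitor design — proliferative cells, cells after one week of
differentiation, and differentiating cells treated with an adenosine
derivative ("ifc") — with 2, 2 and 3 independent cultures respectively,
each culture measured once per channel.

## Measurement model and the binomial MLE

Array intensities carry no read counts, so the package models each beta as
a binomial count fraction at a *pseudo-coverage* `N` (default 1000, set per
probe x sample in the `beta_matrix` container and logged in the manifest):

    x_bs ~ Binomial(n_bs, m + h),   x_ox ~ Binomial(n_ox, m),
    x = round(beta * n).

`oxbs_mle()` maximizes the joint log-likelihood under the simplex
constraints `m >= 0, h >= 0, m + h <= 1`. The solution is closed-form:

- if the BS count fraction is at least the oxBS count fraction, the
  interior optimum is `m_hat = x_ox/n_ox`, `h_hat = x_bs/n_bs - x_ox/n_ox`;
- otherwise the optimum sits on the `h = 0` boundary; the 5hmC estimate is
  reported as `NA` (the convention for a negative difference) while
  `m_hat = (x_bs + x_ox)/(n_bs + n_ox)` remains a meaningful pooled 5mC
  estimate.

Ties (`equal count fractions`) take the interior solution `h_hat = 0`.
Classification is done on the rounded-count fractions, which is what the
likelihood actually sees; on simulated data betas are exact count
fractions, so this coincides with comparing the raw betas. The test suite
checks the closed form against a coarse-to-fine lattice maximization of
the likelihood on a 1e-4 grid.

### The NA convention is not free

Censoring negative differences truncates the noise distribution. At true
`h` near zero the paired difference `beta_bs - beta_ox` has standard
deviation about `sqrt(2 p (1-p) / N)` — roughly 0.022 at `p ~ 0.52`,
`N = 1000` — so a cell with true `h = 0.022` goes `NA` about 16% of the
time, and the mean over the *retained* cells overestimates the truth by
roughly `sigma * phi(h/sigma) / Phi(h/sigma)` (about +0.6 percentage
points at `h = 2.2%`, about +0.2 at `h = 4.1%`). This bias is intrinsic to
the censored estimator at finite pseudo-coverage, shrinks with `N`, and
grows with per-probe dispersion of the truth. Users comparing recovered
condition means against generator targets should expect it; the package
deliberately does not "correct" the estimator, because the NA convention
is part of the method being implemented.

## The synthetic-data generator

The generator exists so every stage has ground truth. It emulates:

- a single 5 Mb toy chromosome with 50 non-overlapping genes (exon/intron
  structure, strands, TSSs), CpG islands over 60% of TSSs, and a
  chromatin-state tiling;
- expression-derived gene sets: 25% upregulated, 25% downregulated, 10%
  housekeeping;
- a probe layout of 10 gene-body probes (confined to the 5'-most 8 kb of
  the body, emulating the 5' bias of array probe density and keeping
  within-gene probe spacing under typical region-calling gaps), 2 promoter
  probes, 1 probe per island, and a sparse intergenic backbone — about one
  thousand probes;
- per-condition true methylomes: gene-body means calibrated exactly to the
  configured targets (defaults 2.2/4.1/3.5% 5hmC and 51.7/49.1/50.5% 5mC
  for proliferative/differentiating/ifc), 5hmC gain concentrated on the
  bodies of upregulated genes (weight 1.8 vs 0.75/0.85/1.0 for
  down/housekeeping/none in the differentiating condition) and on introns
  (1.15 vs 0.75 for exons), depressed 5hmC at promoters and islands;
- per-probe truth drawn from beta distributions around the regional means
  (precision 1500 for h, 150 for m) through one shared quantile per probe,
  so conditions are coherently ordered probe by probe;
- four planted 3-CpG gene-body blocks with a true 5hmC gain of +0.25 in
  the differentiating condition over a baseline of 0.06 — ground truth for
  differential-position and region calling. The baseline sits above the
  measurement-noise floor so both groups of the contrast are defined after
  NA censoring; the treated condition does not carry the gain, encoding a
  treatment that reverts the differentiation-specific change;
- binomial measurement noise at pseudo-coverage `N` per culture and
  channel, plus a detection-failure model: 5% of probes are failure-prone
  (per-cell failure rate 0.5) against a background rate of 0.005, giving
  the detection filter a real target. Failure-prone probes are drawn
  outside the planted blocks, since the two plantings test different
  stages.

Weights, precisions and the block design are free parameters of this
package, chosen once as plausible for a differentiation hydroxymethylome,
and are not claims about any particular cell system. The generator does
*not* model Infinium type-I/II chemistry, dye bias, batch effects,
cross-reactive probes, or biological replicate variance beyond the
binomial draw — so passing tests demonstrate correctness of the analysis
under its stated model, not robustness to every artifact of real arrays.

## Preprocessing

`filter_probes()` pools BS and oxBS samples into one panel and removes a
probe from both matrices when its detection p-value exceeds 0.01 in
strictly more than 10% of samples ("more than" is a strict inequality: a
probe failing in exactly 10% of samples survives). Filtering jointly
across channels is this package's documented choice; it keeps the
matrices paired.

`normalize_stratified_quantile()` maps each sample's betas onto the
across-sample mean quantile function within probe strata. It is the
pipeline's normalization slot but is **off by default**: binomially
simulated channels need none, and chemistry-aware within-array
normalization of real Infinium data requires probe-type information this
data model does not carry. The stratified quantile substitute is
deliberately transparent: rank-preserving within stratum, fixed point on
already-identical distributions.

## Differential testing

`fit_group_model()` is per-probe OLS for a two-group contrast: effect =
difference of group means, pooled residual variance, degrees of freedom
counted after per-probe NA removal; probes with fewer than two defined
values in either group are flagged untestable and excluded from multiple
testing (not assigned p = 1, which would dilute the FDR).

`moderate_ebayes()` is the standard moderated-t construction: the
variance ensemble is modelled as scaled chi-square around a prior
`(d0, s0^2)` estimated by method of moments on `log s^2` (trigamma
matching, Newton inversion to 1e-8, `d0` above 1e6 treated as infinite).
Numerical choices worth knowing:

- sample variances are floored at `1e-5 * median` before taking logs;
  count-discretized betas produce occasional near-zero variances whose
  logs would otherwise dominate the moment fit and collapse `d0`;
- when the ensemble shows no excess dispersion (`var(e) <=
  mean(trigamma(df/2))`), shrinkage is complete: `d0 = Inf` and `s0^2` is
  the mean observed variance, so a constant-variance ensemble shrinks to
  exactly that common value;
- `prior_df = 0` switches shrinkage off and reproduces the classical
  two-sample t exactly — both limits are tested, and the estimated prior
  is cross-checked against an independent reference implementation.

Positions are called significant at FDR (Benjamini–Hochberg, strict
`< alpha`) plus an effect-size floor: 20% delta-beta for differential
positions, 10% for 5hmC presence peaks (the documented sensitivity floor
of the paired technique). Both thresholds are exposed rather than
reconciled, since they operate at different stages.

`call_hmc_peaks()` tests mean paired delta > 0 one-sided (a peak is
defined by signal *loss* after oxidation), per condition, paired by
culture.

## Region calling

`call_regions()` replaces kernel-based region machinery with a
transparent, fully specified rule: cluster consecutive significant CpGs
with successive gaps <= 1000 bp, keep clusters of >= 3 CpGs, score each
region by the Stouffer combination `z = sum(z_i)/sqrt(k)` of member
z-scores with a two-sided normal p and BH across regions. Region spans
are 0-based half-open from the first member CpG to one past the last.
The defaults (1 kb gap, 3 CpGs) mirror common proximity criteria for
array DMRs; they are documented choices, not inferred ones.

## Genomic context

- Feature precedence: promoter > exon > intron > intergenic, with the
  promoter window (-2000, +500) bp around the TSS in gene orientation (a
  documented, configurable choice; the toy gene models carry no CDS/UTR
  structure, so UTR-exon subtypes collapse into "exon").
- CGI context follows the universal convention: island; shore within
  2 kb of an island edge; shelf within 2–4 kb; open sea beyond.
- Nearest gene is by TSS distance, signed negative upstream in gene
  orientation, ties broken toward the lexicographically smaller gene id.
- Enrichment against the array background uses per-category 2x2 Fisher
  tests of foreground vs background-minus-foreground with Haldane +0.5
  only when a zero cell occurs; a foreground that exhausts the background
  has no complement to compare against and reports OR = 1, p = 1.
- Metagene profiles scale each gene body to 20 bins TSS->TES in gene
  orientation with five 400 bp bins per 2 kb flank (bin counts are
  defaults of this package; strand-flip symmetry and bin-mass
  conservation are tested invariants).
- Gene-body condition summaries average all defined (non-NA) estimates at
  exon/intron probes and report percent; pairwise condition comparisons
  use the two-sided rank-sum test on per-gene body means (exact when the
  pooled size is <= 12 without ties, otherwise the tie-corrected normal
  approximation without continuity correction so identical groups give
  p = 1 exactly).

## Bench-assay formulas

`relative_expression_ddct()` implements `2^-(dCt - control_mean_dct)`
with amplification efficiency fixed at 2. `hmedip_percent_input()`
implements `2^((Ct_input - f) - Ct_IP) * 100`; the default compensatory
factor is the printed 3.32 to reproduce the published arithmetic
bit-for-bit, while `dilution_factor(d) = log2(d)` provides the exact
value (3.3219... for a 1:10 input). `methylation_index()` is the SAM/SAH
concentration ratio with a guarded denominator.

## Problem sizes and determinism

Default analyses run on ~1,000 probes x 14 samples (a 50-gene toy
chromosome), which the package treats as its reference desk-scale design;
property-style tests use ensembles of 200–5,000 probes and 10–20 seeds.
Every source of randomness flows from explicit integer seeds
(`sim_config(seed=)`, `pipeline_config(seed=)`); stage-specific streams
are derived as small fixed offsets of the run seed, and identical
configurations reproduce byte-identical result tables (the JSON manifest
differs only in its timestamp).

## Known limitations

- The censored-MLE truncation bias described above: recovered condition
  means of low-5hmC conditions sit a few tenths of a percentage point
  above the generator truth at the default pseudo-coverage.
- Pseudo-coverage is a stand-in for unavailable array intensity weights;
  absolute significance levels depend on it.
- No modelling of probe chemistry or batch structure; the normalization
  slot is a documented substitute, not a re-implementation of
  chemistry-aware within-array normalization.
- Region statistics are proximity/Stouffer-based; no kernel smoothing or
  permutation-based region FDR.
- The hypergeometric overlap test treats gene sets as exchangeable draws
  from the stated universe; choosing that universe is the caller's
  responsibility.
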