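---
title: "Scoring and classifying variant function from saturation genome editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying variant function from saturation genome editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgescore)
```

## The assay and its statistical structure

Saturation genome editing (SGE) introduces every possible variant across a
short region — either all 63 non-wildtype codons at a saturated residue via a
degenerate (NNN) single-stranded oligo donor, or every single-nucleotide
variant (SNV) across an exon — by CRISPR-Cas9 homology-directed repair (HDR)
in cells whose survival depends on the targeted gene. Each repair template
carries a fixed synonymous PAM edit (the *HDR marker*) that blocks Cas9
re-cutting; a sequencing read is attributed to a library variant only when
the marker is present and no other substitution or indel is seen. Cells are
sampled shortly after editing (day 3) and again after selection (day 14)
under a vehicle arm (DMSO) and two DNA-damage arms (cisplatin and the PARP
inhibitor olaparib), in two independent replicates.

The *function score* (FS) of a variant in an arm is

$$\mathrm{FS} = \log_2 \frac{f_{14}}{f_3},$$

where $f_d$ is the variant's read frequency at day $d$, computed with a
pseudocount of 1 and the per-sample total of aligned reads as denominator.
Loss-of-function variants deplete (FS near $-3$ in these data), functional
variants stay near 0, and *hypomorphs* — partial-function variants — survive
in DMSO but deplete under the drug arms, which is why the drug arms carry
real classification signal.

Synonymous variants (known functional) and nonsense variants (known
non-functional) are the internal controls every downstream calibration
uses.

## Read handling

Overlapping read pairs are merged by scanning every overlap at or above
`min_overlap` and keeping the lowest-mismatch overlap (ties to the longest);
disagreements are resolved toward the higher base quality. Merged reads
containing `N` are rejected. Each merged read is aligned to the reference
amplicon by global Needleman–Wunsch alignment with linear scoring (match
$+2$, mismatch $-1$, gap $-2$; all configurable). The algorithm's
tie-breaking is fixed — substitution over gap, gap-in-read over
gap-in-reference — and gap runs are left-aligned afterwards, so indel
positions are reproducible run to run. Reads scoring below 60% of the
perfect score are excluded from totals as alignment failures; the threshold
is a package decision, exposed as `min_score_frac`.

One consequence of linear (non-affine) gap scoring is that a long deletion
may align as several short gaps when splitting gains matches; indel spectra
therefore key on the leftmost gap edge. Spectra are reported as per-sample
frequencies by signed size and by offset from the cut site, plus a z-score
view per size bin across samples (zero-SD bins get z = 0).

Marker-only reads are counted as the wildtype-codon-with-marker key
(`WT_marker`): the NNN library includes the wildtype codon, and that allele
is a marker-synonymous control.

## The simulator

`sim_config()` / `simulate_ground_truth()` / `simulate_counts()` /
`simulate_reads()` generate fully ground-truthed experiments. Defaults are
the study conditions the pipeline is built for: 2×10⁶ reads per sample
(the assay's 1–3M range), HDR rate 1% (observed 0.3–2.3%), an NHEJ indel
fraction of 5% with a size/offset spectrum centred on the cut site,
functional effects near 0 (SD 0.3), non-functional effects near $-3$ log2
units (SD 0.5), a 5% hypomorph class (≈0 in DMSO, $-2$ in the drug arms),
per-replicate log2 noise of SD 0.1, and Dirichlet day-3 abundances with
concentration 50 (the per-variant day-3 dispersion is not constrained by
published data; the concentration is a free parameter chosen to reproduce a
realistic day-3 replicate correlation). Counts are multinomial rather than
Poisson so per-sample totals are exact, matching fixed sequencing depth.
Out-of-frame indel alleles are lethal ($-3$), in-frame ones neutral.
Positional editing-rate bias can be injected as a smooth sinusoidal additive
term on the log2 ratio to exercise the loess correction.

What the generator does *not* emulate: PCR duplicates and chimeras,
realistic quality-score profiles, sgRNA-specific cut efficiencies, and
between-arm correlation structure beyond the shared day-3 pool. Passing
recovery tests on simulated data therefore demonstrates the pipeline's
statistical correctness under the assay's assumed generative model, not
robustness to every artefact of real sequencing.

## Filters

Two filter sets mirror the two experimental designs:

* **Codon path**: a variant is kept only when its day-3 frequency exceeds
  1 in 10⁵ in *both* replicates (the any-replicate removal rule). The
  boundary case (exactly 1e-5) is excluded, because keeping requires
  strictly "more than" the threshold.
* **SNV path**: day-3 read count below 10 or day-3 frequency at or below
  1e-5 in any replicate removes a variant; so does a DMSO replicate
  post/pre-ratio discordance of more than 2-fold *combined with* divergent
  preliminary class calls, or that same two-part discordance in two or more
  conditions. "Difference of more than 2" between two ratios is read as a
  fold difference (ratios are multiplicative); an arithmetic option exists
  behind `diff_mode`. The preliminary per-replicate class call — an
  implementation detail the protocol leaves open — is a threshold test
  against the midpoint of the synonymous and nonsense control medians.

## Positional-bias correction and score anchoring

Editing rates vary smoothly with distance from the cut site. On the SNV
path the per-variant log2 global ratio (weighted mean of the per-condition
mean post/pre ratios with weights 0.4 DMSO / 0.25 cisplatin / 0.25
olaparib, normalized by the 0.9 weight sum) is regressed on position with a
tricube-weighted local linear smoother (`stats::loess`, degree 1, span
0.75). Only near-neutral variants — within 1.25-fold of no change,
$|\log_2 r| \le \log_2 1.25$ — enter the fit, so genuine biological effects
do not leak into the correction; a one-sided $r \ge 1.25$ alternative is
available behind `side`. The fitted value is subtracted from every
variant's score; predictions outside the fitted range take the nearest
fitted value. At least 10 included variants are required, otherwise the fit
errors explicitly.

Corrected scores are then anchored: per exon, the two-point affine map
taking (exon synonymous median, exon nonsense median) onto the global
medians is applied to all of the exon's variants. The map is monotone, so
within-exon rankings never change; with a single exon it is the identity.
Within-exon scaling and cross-exon normalization are deliberately one
affine step, since both are defined by the same pair of control medians.

## The probit PIF classifier (codon path)

A linear three-variable probit regression is trained on the control
variants, predictors being the replicate-averaged FS in DMSO, cisplatin and
olaparib; the *probability of impact on function* (PIF) of any variant is
the fitted probability of being non-functional,
$\Phi(\beta_0 + \beta^\top \mathrm{FS})$. Because the control classes are
usually linearly separable, the unpenalized maximum-likelihood fit diverges
(quasi-separation); the package detects this (coefficient blow-up or
near-zero negative log-likelihood) and refits with a small ridge penalty
($10^{-4}$) on the slopes, keeping PIFs finite without changing training
accuracy. Categories: PIF ≤ 0.05 functional, PIF > 0.99 non-functional,
otherwise intermediate (0.05 is functional, 0.99 is intermediate — both
boundaries as stated).

Model assessment:

* **Model-fit accuracy** — fraction of correct training assignments at a
  0.5 cutoff. The 0.5 cutoff for accuracy and cross-validation is a package
  decision (the three-way 0.05/0.99 rule does not define "correct"), and is
  configurable.
* **K-fold cross-validation** — unstratified random folds whose sizes
  differ by at most one (a stratified option exists for small classes);
  per-fold accuracies are averaged unweighted; sensitivity and specificity
  are averaged over the folds containing the respective class.
* **Perturbation confidence intervals** — 10,000 refits by default, each
  perturbing every *training* predictor value (never the full-table
  predictors) by Normal(0, 0.05) noise; per-variant 95% CIs are percentile
  quantiles of the simulated PIFs. Extreme variants get near-zero widths;
  variants near the decision boundary the widest. Percentile CIs need not
  bracket the point estimate and the package does not pretend they do.
* **One-variable models** — the same probit per single assay, to quantify
  what the drug arms add; hypomorph-like variants are invisible to the
  DMSO-only model.

## The Gaussian-mixture classifier (SNV path)

The exon-wide classifier is a supervised class-conditional Gaussian model
(model-based discriminant analysis) on the single normalized function
score: each class gets its sample mean and SD (pooled-variance and
equal-priors switches exist), priors default to training proportions, and
the posterior probability of pathogenicity is the two-component Bayes
ratio. It is train-then-predict, not unsupervised EM, which matches how the
assay uses its labelled controls. Categories: posterior > 0.99 pathogenic,
< 0.05 benign, otherwise intermediate (strict inequalities).

Evaluation: sensitivity and specificity on percent scales, with
intermediates counted against their true class (conservative; an "exclude
intermediates" option exists); likelihood ratios LR+ = sens/(100 − spec)
and LR− = (100 − sens)/spec; ROC/AUC by threshold sweep with rank-averaged
ties (equal to the Mann–Whitney statistic); and OddsPath evidence
calibration, $P_1$ the pathogenic fraction of controls,
$P_2^{path} = n_{pred\,path}/(n_{pred\,path}+1)$,
$P_2^{benign} = 1/(n_{pred\,benign}+1)$,
$\mathrm{OP} = P_2(1-P_1) / ((1-P_2)P_1)$, mapped to ACMG PS3/BS3 strength
bands (supporting/moderate/strong/very strong at 2.1/4.3/18.7/350 and
0.48/0.23/0.053/0.0029).

The published description of the exon-wide training set is ambiguous ("43
synonymous and 8 nonsense" in one place, "42 functional and 12
non-functional" — which adds ClinVar-classified variants — in another);
`gmm_classify()` takes whatever labelled control set the analyst assembles,
so both configurations are expressible.

## Numerical and boundary decisions

All strict/closed boundary choices live in one place conceptually and are
tested: day-3 frequency must be strictly above 1e-5 to keep; PIF 0.05
closed-functional, 0.99 open-intermediate; posterior 0.99/0.05 strict;
SpliceAI splice flag strictly above 0.2. Degenerate cases error loudly
rather than guess: single-class training sets, zero-variance mixture
classes (with a pointer to the pooled-variance option), equal control
medians in anchoring, too few near-neutral variants for the loess,
zero-read samples in frequency computations. All simulator and classifier
randomness flows from explicit integer seeds; equal seeds give bit-identical
outputs, which the tests assert.

## Problem sizes used in the test-suite and acceptance runs

The shipped checks simulate 3 saturated codons (189 variants) for the codon
path and a 124-position SNV library (369 variants) for the exon path, at
the default 2×10⁶ reads per sample, because count-level simulation is cheap
at full depth. Read-level checks (merging, alignment, marker gating,
round-trips) use a few hundred read pairs, where exact ground-truth
bookkeeping is feasible; CI perturbation checks use a few hundred refits
while the package default remains 10,000.

## A worked example

```{r example, eval = FALSE}
library(sgescore)
res <- run_sge_pipeline(seed = 1, mode = "pif")
print(res$model)
head(res$results)
res$metrics
```

## Known limitations

* Single-amplicon scope: no genome-wide liftover, no multi-amplicon joint
  modelling beyond the cross-exon anchoring step.
* No empirical-Bayes moderation of scores; raw ratios are used, as in the
  assay's own analysis.
* The merger models a flat per-base error, so base-quality-aware merging is
  only exercised at the rule level.
* Splice-effect assessment consumes precomputed SpliceAI scores as an
  annotation column (cutoff 0.2); the package never computes them.
* With linear gap penalties, long indels can be reported as their leftmost
  fragment; spectra are designed around this.
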