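---
title: "Methods: scoring a proximity-labeling interactome"
author: "proxitome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring a proximity-labeling interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxitome)
```

## The analysis problem

TurboID (and BioID) proximity labeling biotinylates proteins that come
close to a bait fusion protein in vivo; streptavidin enrichment followed
by mass spectrometry then yields, for each detected protein, a spectral
count per sample. The analytical task is to decide which proteins are
*enriched* near the bait relative to an untagged control strain, to
compare the candidate neighborhoods of two baits that mark the same
organelle (here, components of the C. elegans germline P granule), and
to characterise the candidates: how many curated granule components they
recover, and whether they are biased toward intrinsically disordered
proteins. A companion imaging readout quantifies whether granules sit at
the nuclear periphery or disperse into the rachis, the shared
cytoplasmic core of the gonad.

`proxitome` implements this analysis as a set of composable,
tibble-in/tibble-out functions plus a one-call pipeline, together with a
seeded synthetic-data generator that reproduces the statistical
structure of every input, so the entire workflow is testable without any
external download.

## Enrichment calling

For each protein the bait and control group means over the replicates
(three per group in the emulated design) are compared through two
filters applied jointly:

* **Pseudo-count fold change.** With group means $\bar{b}$ and $\bar{c}$
  and pseudo-count $c_0 = 0.01$,
  $\mathrm{FC} = (\bar{b} + c_0) / (\bar{c} + c_0)$. The pseudo-count
  keeps the ratio finite for proteins never detected in the control —
  exactly the bait-specific candidates the screen is designed to find.
  The call threshold is $\log_2 \mathrm{FC} \ge 3$, i.e.
  $\mathrm{FC} \ge 8$, applied inclusively; the two formulations are
  exactly equivalent by monotonicity of $\log_2$, which the test suite
  checks on random mean pairs.
* **One-tailed Student t-test.** A pooled-variance two-sample t-test of
  bait $>$ control on the raw replicate counts, $p < 0.05$ strict, with
  $\mathrm{df} = n_1 + n_2 - 2$. By default the pseudo-count enters only
  the fold change, not the test: adding a constant to every count
  changes neither the mean difference nor the variances, so the switch
  that adds it before testing (`pseudo_count_scope =
  "fold-change-and-test"`) is provided for completeness but is a no-op
  on the pooled statistic.

Two degenerate cases are resolved by the limits of the t statistic
rather than left as division-by-zero: zero pooled variance with zero
mean difference gives $p = 1$; zero pooled variance with a bait excess
gives $p \to 0$, stored as $10^{-300}$ and flagged `degenerate` so
downstream consumers can audit those records. `stats::t.test()` refuses
constant data outright, which is why the test is implemented in-package
(vectorised over proteins); on non-degenerate inputs the suite verifies
exact agreement with `stats::t.test()` for both the pooled and the
Welch variant.

Choices a user can revisit: Welch instead of pooled variance
(`variance_model`), a Benjamini–Hochberg adjusted column
(`p_adjust = "benjamini-hochberg"`, reported alongside but never
changing the default call, which uses raw p as in the emulated
screen), and the test tail. Counts are taken as already-normalized
spectral counts; proteins undetected in a sample are zeros, not missing
values.

Candidate lists from two baits are intersected with exact set algebra
(`intersect_enrichment()`), and recovery of curated reference sets
(`recovery()`) is an exact intersection after both sides are mapped to
upper-cased canonical gene names, optionally through a user-supplied
alias table (synonyms are common in the C. elegans literature, e.g.
WAGO-9/HRDE-1). Alias maps are single-step by design: chains or
conflicting targets are errors, not silently resolved.

## Disorder analysis

Per-residue disorder scores in $[0,1]$ (as produced by predictors such
as IUPred; the predictor itself is out of scope and its scores are
consumed as input) are summarised per protein as the mean score,
$\bar{d} = \sum_i s_i / L$, after restricting the proteome to the
longest isoform per gene (ties broken by the lexicographically smallest
isoform id, so the filter is deterministic). Score tables with missing
residue positions are rejected rather than imputed.

The disorder of a target set (by default the proteins enriched by both
baits) is compared to a size-matched random control drawn uniformly
without replacement from the remaining proteome, with a Wilcoxon
rank-sum test. Two decisions here were genuinely open:

* **Control pool.** The default excludes the target proteins from the
  sampling pool — sampling targets into their own control only dilutes
  the contrast — but `exclude_targets = FALSE` restores naive
  whole-proteome sampling for users who want to mirror a single naive
  draw.
* **Sidedness.** Two-sided by default, configurable; a one-sided
  "greater" alternative is defensible when the hypothesis is
  directional.

The control draw is a pure function of the mandatory seed; with
`n_draws > 1` the median p across draws is reported together with every
per-draw result, which is more honest than a single lucky draw.

The rank-sum test itself uses midranks and, for tie-free samples whose
smaller group has at most 10 observations, an exact p-value computed
from the full null distribution of the rank-sum statistic (a
subset-sum dynamic program over rank assignments); larger or tied
samples use the normal approximation with tie correction and continuity
correction. The exact path is validated against a brute-force
enumeration over all $\binom{n_1+n_2}{n_1}$ assignments and against
`stats::wilcox.test()`, which serves as a cross-check, not as the
implementation.

## ROI quantification

The imaging readout reduces each animal to four ROI mean gray values:
the rachis, the two germline edges, and an off-animal background. The
summary statistic is the background-corrected rachis-to-edge ratio

$$ R = \frac{2(\mathrm{rachis} - \mathrm{bg})}
            {\mathrm{edge}_1 + \mathrm{edge}_2 - 2\,\mathrm{bg}} . $$

The printed form of this formula subtracts the background only once in
the numerator while subtracting it twice in the denominator; we read
that as a typesetting artifact and correct both terms symmetrically by
default, because only the symmetric form is invariant under an affine
intensity transform $v \mapsto a v + b$ (detector gain and baseline).
The literal reading is preserved behind `mode = "literal"`; note that
both modes tolerate a pure gain change (any ratio of intensity-linear
forms does) — the offset is what separates them, and the regression
tests document exactly that. Records with a non-positive denominator
are flagged and excluded from group aggregates. Genotype groups are
compared with two-tailed pooled t-tests on the per-animal ratios (four
animals per genotype in the emulated design).

## The synthetic study generator

Every generator is a pure function of a `simulation_spec()` — the same
seed gives byte-identical output, and each generator draws from its own
sub-stream derived from the master seed, so adding a stage never
perturbs another stage's draws.

The defaults are the emulated study conditions, chosen once:

* **Counts.** 2,000 detected proteins, 3 replicates per group.
  Contaminant background: negative binomial with mean 10 spectral
  counts and size 5 (moderate overdispersion, typical of spectral
  counts of the streptavidin background). Detection dropout: a
  measurement drops to zero with probability 0.10 at background
  abundance, decaying exponentially as the expected abundance rises —
  detection failure in MS affects low-abundance proteins, not a protein
  yielding hundreds of spectra. Planted enrichment: 16-fold, one
  doubling above the FC ≥ 8 calling threshold, mirroring the clear
  separation of bona fide granule components on a volcano plot; an
  8-fold effect would sit exactly on the threshold and be undetectable
  by construction.
* **Dual-bait bundle.** Truth sets of 155 and 127 proteins with 78
  shared (the scale of the emulated screen), drawn against a shared
  control.
* **Disorder.** Protein lengths log-normal (median 400 residues,
  minimum 30); per-protein disorder propensity Beta-distributed with
  mean 0.35 and concentration 6 (so propensities spread realistically
  across proteins); per-residue scores Beta-centred on the propensity
  with concentration 3. The target class's propensity mean is shifted
  by +0.2. The hierarchical structure matters: without protein-level
  propensity variation, any shift would be detected with probability
  one and the power analysis would be vacuous.
* **References.** Sets of 20, 2 and 11 proteins overlapping the
  enriched truth by 18, 2 and 0 respectively, so recovery fractions of
  0.90, 1.00 and 0.00 are reproduced structurally.
* **ROI.** Planted per-genotype ratios (0.30 wild-type rising to 0.90
  in the double mutant), edges at 100 gray values over a background of
  10, additive Gaussian noise of 2; with zero noise the symmetric ratio
  recovers the planted value exactly.

What the generator does *not* emulate: correlated contaminant structure
(keratins and ribosomal proteins co-varying across runs), abundance-
dependent spectral-count saturation, shared peptides between isoforms,
and batch effects between strains. Tests passing on synthetic data
therefore demonstrate the correctness and calibration of the
*computation*, not the biological validity of any particular screen.

## Calibration and power, as measured by the suite

The acceptance tests (which are ordinary `testthat` tests) recompute,
at a fixed scale, the properties a user should expect:

* Under a pure null (no planted proteins), the fraction of proteins
  with $p < 0.05$ averages 0.05 within the binomial sampling error of
  one 2,000-protein simulation, over 200 seeds; the fraction actually
  *called* (p and FC jointly) is bounded above by it, and is far
  smaller.
* A 50-protein, 16-fold spike-in under low-noise conditions (negative
  binomial size 50, detection dropout 0.005) is recovered with ≥ 95%
  sensitivity at ≤ 1% FDR. The low-noise setting is deliberate: with
  10% detection dropout, a genuinely null protein whose three control
  measurements all drop out is — correctly, given the data — called
  enriched through the pseudo-count, which is an inherent property of
  spectral-count screens rather than a defect of the caller, and it
  dominates the false-discovery count at default noise.
* The disorder comparison at $n = 78$ per group rejects a +0.2
  propensity shift at $\alpha = 0.01$ in ≥ 95% of 200 seeds, and its
  p-values are approximately uniform when the shift is zero.
* The pipeline's `summary.json` is byte-identical across reruns with
  the same seed.

Problem sizes used throughout the suite (2,000 proteins for count
simulations, 200 proteins for per-residue disorder simulations, 200
seeds for the calibration loops) were chosen as the smallest scales at
which the binomial error bands above are meaningful.

## Reproducing the published analysis

The published screen's deposited inputs (normalized spectral counts and
the curated granule lists) are not redistributable with this package.
The reproduction path is implemented and tested: placing the deposited
tables under `inst/extdata/deposited/` (as
`counts_glh1.tsv`/`samples_glh1.tsv`, `counts_deps1.tsv`/
`samples_deps1.tsv`, `reference_sets.tsv`) lets the corresponding
acceptance test run `call_enrichment()` with the default configuration
and check the published candidate counts, overlap and recovery
directly. Two documented switches span the analysis choices the
original description leaves open (`pseudo_count_scope`,
`variance_model`).

## Worked example

```{r example}
spec <- simulation_spec(seed = 1)
bundle <- simulate_bundle(spec)
cfg <- pipeline_config(
  bundle$bait_a$counts, bundle$bait_a$samples,
  bundle$bait_b$counts, bundle$bait_b$samples,
  references = bundle$references,
  disorder = bundle$disorder$summaries,
  roi = bundle$roi,
  seed = 1
)
report <- run_pipeline(cfg)
report
```

```{r plots, fig.width = 5, fig.height = 3.5}
autoplot(report$enrichment_a)
autoplot(report$disorder)
autoplot(report$roi)
```

## Known limitations

* Spectral counts are a semi-quantitative abundance proxy; the caller
  implements the screen's thresholding procedure and does not attempt
  probabilistic interaction scoring or label-free quantification
  models.
* The t-test's normality assumption is only approximate for counts at
  $n = 3$; the calibration test shows the practical rejection rate is
  nevertheless accurate at the default settings, but heavy
  zero-inflation will push degenerate records into the flagged path.
* Recovery scoring is exact set intersection: it is only as good as the
  identifier harmonisation, which is why the alias table is a
  first-class input.
* GO enrichment and protein-network construction are intentionally not
  stages; the pipeline exports plain candidate lists for those external
  tools.
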