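# proxitome

Analysis toolkit for **TurboID/BioID proximity-labeling proteomics** of
membraneless organelles, built around the dual-bait germ-granule screen
design in *C. elegans*: two biotin-ligase bait fusions marking the same
perinuclear condensate (the P granule), each compared against an
untagged control strain over replicate spectral-count measurements.

It is written for proteomics analysts who have spectral-count tables
and want a reproducible, inspectable path from counts to candidate
lists — not a black-box scoring model.

## What it computes

**Enrichment calling.** Per protein, with bait/control group means
$\bar b$, $\bar c$ over $n=3$ replicates and pseudo-count $c_0 = 0.01$:

$$\mathrm{FC} = \frac{\bar b + c_0}{\bar c + c_0},\qquad
  \text{call enriched} \iff \log_2\mathrm{FC}\ge 3\ \text{and}\ p < 0.05,$$

where $p$ is a one-tailed pooled-variance Student t-test of bait >
control on the replicate counts (Welch, Benjamini–Hochberg and a
pseudo-count-in-test variant are available behind configuration
switches). Zero-variance cases are resolved by the limits of the t
statistic and flagged. Candidate lists of two baits are intersected
(Venn counts), and recovery of curated reference sets (known P granule,
Z granule, Mutator foci proteins) is scored by exact intersection after
gene-name harmonisation through an optional alias table.

**Disorder analysis.** Per-residue disorder scores in [0, 1] are
summarised to per-protein mean disorder $\bar d = \sum_i s_i / L$
(longest isoform per gene), and a target set is compared against a
seeded, size-matched random control with a Wilcoxon rank-sum test —
exact by enumeration of rank assignments for small tie-free samples,
normal approximation with tie and continuity correction otherwise.

**ROI quantification.** Per animal, the background-corrected
rachis/edge fluorescence ratio
$2(\mathrm{rachis}-\mathrm{bg}) / (\mathrm{edge}_1+\mathrm{edge}_2-2\,\mathrm{bg})$,
with pairwise two-tailed t-tests between genotype groups.

**Synthetic study generator.** Seeded generators reproduce the
statistical structure of every input (zero-inflated negative-binomial
counts with a planted enriched subset, hierarchical Beta disorder
scores with a shifted target class, reference sets with configured
overlap, ROI records with additive noise), so the full pipeline runs
and is tested without any external data.

## Worked example

```r
library(proxitome)

spec   <- simulation_spec(seed = 1)      # emulated study conditions
bundle <- simulate_bundle(spec)          # two baits, shared control

cfg <- pipeline_config(
  bundle$bait_a$counts, bundle$bait_a$samples,
  bundle$bait_b$counts, bundle$bait_b$samples,
  references = bundle$references,
  disorder   = bundle$disorder$summaries,
  roi        = bundle$roi,
  seed       = 1
)
report <- run_pipeline(cfg)
report
#> Proximity-labeling pipeline report
#>   enriched: bait A 144, bait B 128; both 59, union 213
#>   recovery Mutator foci: 0/11 (0%)
#>   recovery P granule: 18/20 (90%)
#>   recovery Z granule: 2/2 (100%)
#>   disorder p = 1.56e-10
```

Out of 2,000 simulated proteins (155 and 127 planted enriched with 78
shared), 144 and 128 are called at the default thresholds with 59
called by both — the shortfall against the planted truth is the
caller's honest operating characteristic at 3 replicates, not a bug.
The candidate union recovers 18/20 of the simulated P granule reference
set and none of the Mutator foci set, and the shared candidates are
markedly more disordered than a size-matched random control:

```r
glance(report$disorder)
#> # A tibble: 1 × 9
#>   target_n control_n statistic  p_value median_target median_control ...
#> 1       59        59      4700 1.56e-10         0.538          0.319
```

Each stage is also a standalone, pipe-friendly function returning a
tibble — `call_enrichment()`, `intersect_enrichment()`, `recovery()`,
`summarize_disorder()`, `compare_to_random()`, `rachis_edge_ratio()`,
`ratio_summary()` — with `tidy()`/`glance()` methods and volcano /
boxplot `autoplot()`s:

```r
wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#> # A tibble: 1 × 5
#>   statistic     u p_value method degenerate
#> 1         6     0     0.1 exact  FALSE

autoplot(report$enrichment_a)   # volcano plot
```

## Documentation

The methods vignette (`vignettes/proxitome-methods.Rmd`) describes the
statistical model of each stage, the generator's assumptions and what
they do and do not emulate, the calibration and power properties the
test suite measures, and every genuinely open design decision with its
rationale.
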