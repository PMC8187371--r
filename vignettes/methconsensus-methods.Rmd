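---
title: "Methods and conventions in methconsensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and conventions in methconsensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methconsensus)
library(data.table)
```

`methconsensus` implements the downstream half of a nanopore CpG methylation
benchmarking workflow: it starts from the per-read score tables that the
callers (or their converters) emit, and ends at per-site methylation
frequencies, caller-vs-caller consensus predictions, and concordance
statistics against bisulfite data. This vignette records the models,
conventions, and parameter choices, particularly the places where a
convention had to be fixed because the common usage of the field is
ambiguous.

## Score standardization

Every caller scores a CpG in a read on its own scale. The package maps all
of them onto one orientation — **higher score, more likely methylated**:

| dialect    | native score                               | standardized score        |
|------------|--------------------------------------------|---------------------------|
| nanopolish | log-likelihood ratio (positive = 5mC)      | unchanged                 |
| guppy      | log-likelihood ratio (converted output)    | unchanged                 |
| tombo      | statistic, positive = canonical            | negated                   |
| deepsignal | P(m), P(u) probabilities                   | log2(P(m)/P(u))           |
| megalodon  | natural-log probabilities log M, log C     | log M − log C             |

Probabilities are clamped to [1e−12, 1 − 1e−12] before log ratios so that
degenerate rows (P(u) = 0) stay finite; clamped rows are counted and
reported, never silently dropped. Rows with unparsable scores or invalid
coordinates are rejected and counted.

**Coordinates.** Internally all positions are 0-based and anchored at the
forward-strand C of the CpG. A minus-strand call whose native coordinate is
the reverse-strand C is lifted by subtracting 1; Tombo's wiggle-derived
tables are treated as 1-based. Each dialect spec declares its coordinate
base and lifting behaviour, and column names are overridable per dialect so
version-to-version layout drift is absorbed by configuration rather than
code.

**Nanopolish CpG groups.** Nearby CpGs sharing a log-likelihood ratio are
split into one row per constituent site by scanning the group's sequence
context for CG occurrences; a row whose declared CpG count disagrees with
the context is rejected and counted. Splitting conserves calls: output rows
equal the sum of per-group CpG counts over accepted rows.

**DeepMod** provides no per-read output; it participates only at the
per-site bedMethyl level and is excluded from per-read and consensus
operations.

## Cutoff rules and per-site aggregation

A *single* rule classifies every read: methylated iff score ≥ t. A *double*
rule leaves an uncertainty band: methylated iff score ≥ t_high, unmethylated
iff score ≤ t_low, discarded in between. Because published descriptions mix
strict and non-strict inequalities, one convention is fixed: **boundary
scores belong to the decided states** (`boundary = "decide"`). The one
exception is the central discard band (below), which must remove exactly the
selected reads and therefore uses closed-band semantics
(`boundary = "discard"`).

Default rules per caller: Nanopolish ±2.5 on the log-likelihood ratio;
Tombo's native −1.5/2.5 becomes (−2.5, +1.5) after the orientation flip;
DeepSignal methylated iff P(m) ≥ P(u) (single cutoff at 0); Guppy single
cutoff at 0; Megalodon requires probability ≥ 0.75 for whichever call is
made, implemented directly on the probability columns rather than assuming
P(m) + P(u) = 1 on the log-ratio scale.

Per site and strand, frequency = methylated reads / used reads, where used =
methylated + unmethylated (discards reduce the denominator). Sites where
every read was discarded are omitted (and counted), not reported as 0/0.
Strand merging onto the forward anchor takes the **unweighted mean** of the
two strand frequencies and sums the coverage; a site seen on one strand
keeps its frequency. The unweighted mean is a deliberate choice — a
coverage-weighted mean would also be defensible, but plain averaging is the
convention this package follows, and it is what makes merged frequency
different from pooled n_meth/n_used when the strands disagree.

## Cutoff derivation from labeled reads

All four strategies operate on the empirical rate path: candidate thresholds
are the distinct observed scores (plus ±∞ sentinels), rates are exact
empirical proportions under "score ≥ t ⇒ positive", and no interpolation is
used except the equal-error midpoint. This makes every selector exactly
reproducible by a brute-force scan, which the tests exploit.

* **Youden**: argmax TPR − FPR. Ties are broken toward higher TPR, then the
  lower threshold — the strategies exist to recover methylated sites, so
  ties favour sensitivity.
* **ROC corner**: argmin FPR² + (1 − TPR)², same tie-breaks.
* **Equal-error crossing**: FPR(t) is non-increasing and FNR(t) = 1 − TPR(t)
  non-decreasing, so the two step functions are equal over an interval
  between observed scores rather than at a point. The crossing is defined as
  the midpoint between the last candidate with FPR > FNR and the first with
  FPR ≤ FNR; when equality is attained exactly at an observed score, that
  score is the right endpoint of the equality interval and the midpoint
  convention still applies.
* **Central discard band**: ⌈fraction · N⌉ calls closest in score to the
  crossing are removed, over **all** calls without class stratification
  (the removal is described on reads, not per class); the band spans the
  extreme removed scores inclusively. Default fraction 0.10.
* **Rate-bound band**: t_high = smallest candidate with FPR ≤ α, t_low =
  largest candidate with FNR ≤ α (α = 0.05 by default). On well-separated
  scores the band inverts (t_low ≥ t_high); the selector then falls back to
  a single cutoff at the crossing with a warning, discarding nothing.

## The consensus models

Reads scored by every input tool (an **intersection join** on read, contig,
position and strand) form the score matrix; per-tool retention fractions are
reported so the read loss is visible. The intersection is applied to both
model kinds for uniformity, although only the regression strictly requires
complete rows. Scores are min–max scaled to [0, 1] with constants fitted on
the training data only (inside cross-validation, on the training folds
only — no leakage); at prediction, values outside the training range clip
to [0, 1].

* **RF**: a random forest with `max.depth = 3` and `num.trees = 10`
  (deliberately small: two to five bounded trees per tool pair are enough
  for a two-column matrix and keep the model fast and stable), fitted with
  `ranger` under a fixed seed, single-threaded for bit reproducibility.
* **REG**: ridge regression of the 0/1 labels on the scaled scores with an
  unpenalized intercept and no further standardization, the penalty chosen
  by internal fivefold cross-validation over the fixed grid
  {0.01, 0.1, 1, 10, 100}; the chosen penalty is recorded in the model.
  The solver is the closed-form ridge normal equation, written in the
  package so its semantics (what is penalized, what is not) are explicit
  and versioned with the model object.

Consensus scores are the forest's methylated-class probability or the
clipped regression prediction, always in [0, 1]. The decision rule is
strictly two-sided: methylated above 0.5, unmethylated below, and a
prediction of exactly 0.5 is discarded and counted, since neither side
claims it.

Cross-validated curves use stratified folds under a seed; per-fold ROC and
PR curves are **vertically averaged** on a fixed 101-point FPR (recall)
grid — threshold averaging would be the alternative, but vertical averaging
is the common convention for fold-averaged curves and is what the package
fixes. The PR area integrates the precision envelope (best precision at
recall ≥ r), so a separable score reaches area 1.

## Controlled mixtures

Singleton CpG sites have no other CG start within `flank` bases on either
side and sit at least `flank` bases from contig edges. The default flank is
10 nt; descriptions of this window in the field vary between 9 and 10 nt
per side, so the flank is a parameter rather than a constant.

Mixtures at levels m ∈ {0, 0.1, …, 1} draw, per site and level,
`round_half_up(m · n)` reads from the methylated pool and the rest from the
unmethylated pool, without replacement within a level, deterministically
under a seed (pools are sorted by read identifier before the seeded
shuffle). Round-half-up makes the composition exact and reproducible; with
n = 24 reads the attainable fractions are multiples of 1/24, which puts a
floor of about 0.011 on the RMSE against the designed levels even for a
perfect caller — visible in the package's own benchmark output.

Evaluation pools all (site, level) pairs for Pearson r, r², Spearman ρ and
RMSE (per-level tables are also emitted, since within one level the
designed value is constant and correlations are undefined there). The
agreement window around level m is [max(0, m − 0.05), min(1, m + 0.05)],
boundaries inclusive — the ±5% window with clipping at the extremes.

## WGBS concordance

Replicates are outer-joined; sites with zero coverage in both are dropped.
The replicate frequency difference is filtered to its [0.1, 0.9] quantile
range — quantiles by linear interpolation (R type 7), boundaries inclusive,
so identical replicates (all differences zero) retain everything, and
continuous differences retain 80% by construction. Sites covered by only
one replicate have no difference to test and are retained; the combined
frequency is the unweighted mean of the available replicate frequencies
(mirroring the strand-merge convention).

Binning by WGBS level uses [0, 0.3), [0.3, 0.7), [0.7, 1]: half-open below
so the printed overlapping endpoints resolve deterministically, with the
top bin closed so frequency 1 is binned. Coverage-stratified correlation
restricts to sites at or above each threshold of the input coverage;
subsampling draws exactly `level` reads per site, only from sites with at
least `max(levels)` reads, so the site set is identical across levels and
level effects are not confounded with site composition.

## The synthetic-data generator

The generator emulates exactly what the downstream machinery consumes:

* genomes with background sequence whose accidental CG dinucleotides are
  suppressed and singleton CpGs planted every `cpg_spacing` bases, so the
  emitted site list provably coincides with the singleton detector's output;
* per-read scores from two Gaussian components (one per true state) — the
  minimal model for the unimodal per-class score distributions of real
  callers. A profile's separation can be calibrated to a target per-read
  AUC via `profiles_for_auc()` (AUC = Φ(Δ/√2) for unit variances). A shared
  latent factor with weight w induces cross-tool noise correlation (w = 0:
  independent tools); per-tool missingness drops rows independently;
* WGBS replicates as Binomial(coverage, m) counts.

What it does **not** emulate: sequence-dependent error (real callers are
biased by k-mer context — the k-mer module measures this on real data but
the generator does not produce it), heavy-tailed or multimodal score
distributions, read-length and mapping effects, and the ~95% efficiency of
the enzymatic methylation control. Tests passing on this generator
therefore establish the correctness of the machinery and the qualitative
behaviour of the strategies, not the quantitative accuracy of any real
caller.

## Benchmark problem sizes

The package's end-to-end experiments use, as their default study
conditions: 100 singleton sites × 24 reads × 11 mixture levels for the
recovery experiment (with a high-separability profile, means ±4, sd 1, and
the Youden cutoff learned from 40-read fully methylated/unmethylated
pools); and, for the consensus-vs-single-tool comparison, two tools at
per-read AUC 0.85 with independent noise, 2,000 balanced reads for the
cross-validated AUC and 50 sites × 20 reads × 11 levels for the mixture
RMSE, averaged over ten seeds, with models trained on one mixture set and
evaluated on an independent one (different sites and reads). These mirror
the real-data study design at a scale where the full suite runs in well
under a minute on one core.

## Known limitations

* The k-mer residue-enrichment statistic is a per-position binomial test
  with Bonferroni correction across the 24 (position, residue) tests — a
  transparent stand-in for dedicated motif-logo significance tools, not a
  reimplementation of any of them.
* bedMethyl stores the methylation percentage as an integer, so per-site
  round trips through bedMethyl are exact only to 1%; the standard TSV
  round trip is exact.
* The Megalodon default rule needs the dialect's probability columns; a
  standardized table stripped of `p_mod`/`p_can` can only use score-based
  rules.
* Consensus models require ≥ 2 tools, complete rows, and both classes in
  training; all violations are hard errors rather than silent degradation.
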