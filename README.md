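# methconsensus

Downstream analysis of per-read 5mC CpG calls from nanopore methylation
callers, for anyone benchmarking callers against controlled mixtures or
bisulfite data, or combining several callers into one consensus prediction.

Nanopore callers (Nanopolish, Tombo, DeepSignal, Megalodon, Guppy, DeepMod)
disagree in score conventions, coordinate conventions, and accuracy profiles:
each has its own trade-off between false positives and false negatives, and
per-site methylation frequencies show high dispersion around the expected
stoichiometry. `methconsensus` provides the machinery to quantify and improve
this:

* **Standardized ingestion** of each caller's per-read output dialect onto
  one table: scores oriented so that higher means more likely methylated
  (Tombo statistics negated; DeepSignal probabilities as `log2 P(m)/P(u)`;
  Megalodon log probabilities as `log M − log C`; Nanopolish/Guppy
  log-likelihood ratios as-is; Nanopolish CpG groups split into constituent
  sites), with all coordinates normalized to the 0-based forward-strand C of
  the CpG. DeepMod is supported at the per-site bedMethyl level only, since
  it provides no per-read output.
* **Per-site aggregation** under single or double (discard-band) cutoff
  rules: frequency = methylated reads / used reads, with strand merging onto
  the forward anchor (unweighted mean of the two strand frequencies, summed
  coverage).
* **Cutoff derivation** from labeled reads: the Youden point
  (argmax TPR − FPR), the ROC corner (argmin FPR² + (1 − TPR)²), the
  equal-error discard band (remove the fraction of reads closest to the
  score where FPR = 1 − TPR), and the rate-bound band (FPR ≤ α above,
  FNR ≤ α below).
* **METEORE-style consensus**: per-tool min–max scaling to [0, 1], an
  intersection join of reads scored by every tool, then either a small
  random forest (max depth 3, 10 trees) or a ridge regression with
  fivefold-CV penalty selection over {0.01, 0.1, 1, 10, 100}; per-read
  consensus scores in [0, 1] with the strict 0.5 decision rule.
* **Mixture benchmarking**: singleton-CpG site selection (no other CG within
  a 10 nt flank), controlled mixtures at levels 0, 0.1, …, 1 with exact
  (round-half-up) methylated counts, and the evaluation statistics:
  Pearson r, r², Spearman ρ, RMSE, outside-±5%-window proportions, and
  TN/TP threshold ECDFs.
* **WGBS concordance**: replicate combination, the 0.1/0.9
  replicate-difference quantile filter, concordance reports
  (N, r, r², ρ, RMSE), methylation-level binning, coverage-stratified
  correlation, and fixed-site coverage subsampling.
* **8-mer context bias**: NNNCGNNN context extraction, absolute
  nanopore-vs-WGBS discrepancy, low (= 0) / high (> 0.5) discrepancy
  labeling, GC-content grouping, and per-position residue enrichment with
  binomial tests.
* **A synthetic-data generator** (genomes with spaced singleton CpGs,
  two-component Gaussian score profiles with controlled separability,
  cross-tool correlation and missingness, binomial WGBS replicates) that
  exercises the full pipeline with known truth.

## Worked example

Two synthetic callers calibrated to a per-read AUC of 0.85 with independent
errors, combined by the consensus models:

```r
library(methconsensus)

profiles <- profiles_for_auc(c("megalodon_like", "deepsignal_like"), auc = 0.85)
g <- simulate_genome(n_contigs = 1, length = 3100, cpg_spacing = 30, seed = 11)
sim <- simulate_read_scores(g$sites, coverage = 30, m = 0.5,
                            profiles = profiles, seed = 11)
matrix <- join_reads_across_tools(sim$calls)

sapply(c("megalodon_like", "deepsignal_like"), function(tl)
  auc_roc(rate_path(matrix[[tl]], matrix$label)))
#>  megalodon_like deepsignal_like
#>       0.8453940       0.8497835

cv <- cross_validated_curves(matrix, k = 10, seed = 11, kind = "rf")
round(cv$mean_auc_roc, 4)
#> [1] 0.9177
```

Each tool alone reaches a per-read AUC of about 0.85; the cross-validated
random-forest consensus of the two reaches about 0.92 — combining callers
recovers accuracy neither reaches alone.

```r
model <- train_consensus(matrix, kind = "reg", seed = 11)
model
#> consensus_model (REG) over tools: megalodon_like, deepsignal_like
#>   ridge lambda = 0.01; coefficients: megalodon_like=1.5145, deepsignal_like=1.5550; intercept -1.1306
```

The ridge consensus weights the two equally informative tools almost
identically. The full mixture pipeline (100 singleton sites × 24 reads × 11
mixture levels, high-separability caller, Youden cutoff learned from the
fully methylated/unmethylated pools):

```r
mr <- mixture_recovery_experiment(seed = 11)
mr$evaluation$pooled
#>        n pearson_r r_squared spearman_rho       rmse
#> 1:  1100 0.9994069 0.9988142            1 0.01123666
```

Predicted per-site frequencies track the designed mixture levels with
r > 0.999; the residual RMSE of ~0.011 is the rounding of 24-read
compositions to whole reads.

A thin command-line front end covering ingestion, aggregation, cutoff
derivation and simulation is installed under `exec/methconsensus`:

```sh
methconsensus ingest --tool deepsignal --in calls.tsv --out std.tsv
methconsensus aggregate --in std.tsv --rule double:lo=-2.5,hi=2.5 \
    --merge-strands --out sites.bed
methconsensus cutoffs --in labeled.tsv --strategy band:0.10 --out rule.txt
```

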