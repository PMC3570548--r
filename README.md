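# dacr — cell-of-origin classification of DLBCL by balanced ensemble voting

Diffuse large B-cell lymphoma (DLBCL) splits into cell-of-origin classes —
activated B-cell-like (**ABC**), germinal-center B-cell-like (**GCB**) and an
unclassified **Type-III** "molecular gray zone" — with different biology and
survival. Classifiers for these classes are often tied to one microarray
platform; `dacr` implements a platform-independent classifier plus the
comparative meta-analysis machinery around it, end-to-end testable on
synthetic cohorts.

## What it computes

**The ensemble classifier.** Per-gene Z-scores of a compact classifier-gene
panel feed four probabilistic learners — a multinomial logistic model
(LMT-like), a pruned decision tree with Laplace-smoothed leaves (J48-like),
a 100-tree random forest (RF100) and a calibrated linear-kernel
maximum-margin classifier (SMO-like). Votes are combined by the
average-of-probabilities rule,

p(c | x) = (1/M) Σₘ pₘ(c | x),  c ∈ {ABC, GCB, Type-III},

and a case is assigned to argmax_c p(c | x); an optional hard threshold τ
reassigns ABC/GCB calls with confidence ≤ τ to Type-III. Single samples are
classified by appending them one at a time to a background cohort (> 30
samples from the equivalent platform) before quantile normalization and
Z-scoring.

**The LPS comparator.** The classical linear predictor score
S = Σⱼ aⱼ xⱼ with t-statistic weights aⱼ, class posteriors
P(ABC | S) = φ(S; μ_ABC, σ_ABC) / (φ(S; μ_ABC, σ_ABC) + φ(S; μ_GCB, σ_GCB)),
thresholded at 0.8/0.9.

**The pipeline around them.** Quantile normalization; probe→gene collapse by
the per-sample median or by the correlation-gated rule (average probes with
mean pairwise Pearson r > 0.2, otherwise take the per-sample maximum); HGNC
symbol re-annotation; survival-based ranking of classifier variants (Cox
proportional hazards, GCB vs ABC hazard ratio, Efron ties, Wald p);
moderated-t differential expression between assigned classes (empirical-Bayes
variance shrinkage, BH correction); cross-dataset meta-profiles ranked by
(number of data sets class-associated, median normalized fold change);
pairwise dataset concordance and gene-signature/cytoband enrichment scored by
hypergeometric tests with Monte-Carlo empirical-null Z-scores,
Z = (k − μ_rand) / σ_rand.

## Worked example

```r
library(dacr)

# 240-sample training cohort shaped like the published reference
# (73 ABC / 115 GCB / 52 Type-III), probe-level with planted class structure
co <- simulate_cohort(cohort_spec(seed = 0))
z  <- gene_zscores(merge_probes(quantile_normalize(co$expression), co$probe_map))
feats <- assemble_features(z, dac_classifier_genes()$gene)

fit <- dac(feats, co$labels, seed = 0)
fit
#> DLBCL cell-of-origin ensemble classifier
#>   learners: LMT + J48 + RF100 + SMO
#>   genes:    19 classifier genes
#>   trained:  240 samples  (seed 0  fingerprint 0f0c34f3 )

heldout <- simulate_cohort(cohort_spec(seed = 1))
zh <- gene_zscores(merge_probes(quantile_normalize(heldout$expression), heldout$probe_map))
calls <- predict(fit, assemble_features(zh, dac_classifier_genes()$gene))
calls
#> <dac_calls> 240 samples: ABC=73 GCB=115 TYPE_III=52
#>     sample_id   P_ABC   P_GCB P_TYPE_III predicted confidence
#> 1  SAMPLE_001 0.98382 0.00427     0.0119       ABC      0.984
#> 2  SAMPLE_002 0.00324 0.97654     0.0202       GCB      0.977
#> ...
mean(calls$predicted == heldout$labels)   # held-out accuracy: 1.0

# survival separation of the assigned classes (planted GCB-vs-ABC HR 0.4)
sv <- simulate_survival(heldout$labels, hr_gcb_vs_abc = 0.4, seed = 0)
survival_separation(calls, sv)
#> GCB vs ABC hazard ratio 0.419 (95% CI 0.292-0.601), Wald p = 2.2e-06
#>   n: ABC 73, GCB 115, Type-III excluded 52, events 146
```

The probability columns are the averaged learner probabilities (rows sum
to 1); `confidence` is the winning probability; the hazard ratio below 1
reflects the better outcome of the GCB class against the ABC baseline.

A shell entry point wrapping the same functions ships at
`inst/cli/dac.R` (`train`, `classify`, `enrich` subcommands).

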