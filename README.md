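# csrec — drug-interaction-aware medication recommendation from longitudinal health records

`csrec` fits a hypertension medication recommender on longitudinal
electronic health record (EHR) cohorts. A patient is an ordered sequence of
visits, each a set of diagnosis codes, procedure codes and prescribed
medications; the model predicts the medication set of each visit from the
visit's diagnoses/procedures and the patient's earlier history, as a
multilabel classification over the medication vocabulary.

The model has three parts:

1. **Heterogeneous graph collaboration.** A medication co-occurrence graph
   penalised by known drug–drug interactions,
   `G_m = clip(A_mm − λ·A_ddi, 0)`, plus per-visit complete bipartite graphs
   pairing diagnoses↔procedures and the previous visit's medications with
   the current diagnoses/procedures. Node representations are updated with a
   neighbour-focused multi-head graph attention layer
   (`α_ij ∝ exp(LeakyReLU(aᵀ[h_i‖h_j]))`, aggregation over neighbours only —
   the node's own feature is excluded).
2. **Bidirectional temporal selection.** Per entity type, pooled visit
   vectors pass through a forward GRU (coefficients
   `α_j = tanh(W_α g_j + b_α)`) and a backward GRU (coefficients
   `β_j = tanhshrink(W_β h_j + b_β)`, with `tanhshrink(x) = x − tanh(x)`);
   the patient representation is the gated sum `Σ_j α_j ⊙ β_j ⊙ V_j`.
3. **Prediction head.** `ŷ = sigmoid(W_o [d_t; p_t; m_{t−1}])`, trained with
   summed binary cross-entropy, Adam, L2 weight decay and early stopping on
   validation Jaccard; medications above a threshold are recommended.

Evaluation uses the field's four standard metrics — Jaccard, PRAUC
(average-precision form), F1 and DDI rate — and the package ships all the
published ablation variants (`WO_S`, `WO_C`, `GAT_GCN`, `WO_DM`, `WO_PM`,
`WO_DP`, `WO_MM`), a k-most-frequent baseline, an experiment-grid runner and
a seeded synthetic EHR generator with planted, recoverable prescription
rules, so every stage is testable without access to credentialed clinical
data. See `vignettes/csrec-methods.Rmd` for the full model description and
design rationale.

## Worked example

```r
library(csrec)

# simulate a small cohort with planted diagnosis -> medication rules
sim <- generate_cohort(synth_profile("mimic4_like", n_patients = 600, seed = 3))
print(sim$report)
#> generator report: 600 patients, 1654 visits
#>   realized means: visits 2.7567, diagnoses 9.2866, procedures 2.5544, medications 1.1808
#>   rule P(med | diag): 0.891 0.901 0.891 0.893
#>   DDI co-prescription rate: 0.1028

cohort <- filter_cohort(sim$cohort, min_visits = 2)
parts  <- split_cohort(cohort, ratio = c(23, 16, 16), seed = 1)

cfg <- csrec_config(embed_dim = 24, heads = 3, learning_rate = 3e-3,
                    max_epochs = 20, patience = 8, seed = 1)
fit <- csrec(parts$train, sim$ddi_pairs, cfg, val = parts$val,
             vocab = build_vocabulary(cohort))
print(fit)
#> csrec fit: variant full, width 24 (H=3), |D|=200 |P|=100 |M|=18
#>   epochs run 13, best epoch 5 (monitor Jaccard 0.7750), stop: early_stopping

ev <- evaluate_model(fit, parts$test)
round(ev$metrics, 4)
#> jaccard   prauc      f1     ddi
#>  0.7325  0.8759  0.4791  0.0329

# sanity floor: recommend the k most frequent training medications
k  <- max(1, round(cohort_stats(parts$train)$mean_med))
bl <- frequency_baseline(parts$train, k, fit$vocab)
jaccard(predict(bl, parts$test))
#> [1] 0.1967
```

The test-set Jaccard of 0.73 means the recommended medication sets overlap
the prescribed sets by 73% on average — the planted diagnosis-to-medication
rules (which fire with probability 0.9, so even a perfect learner cannot
reach 1) are recovered — while the constant most-frequent baseline manages
0.20. The DDI rate of 0.033 is the fraction of recommended medication pairs
that are contraindicated.

The fitted object supports `print`, `summary`, `coef`, `plot` (training
curves) and `predict` (per-visit recommendation batches directly consumable
by the metric functions); `save_csrec()`/`load_csrec()` round-trip a model
through a single portable JSON checkpoint.

A thin command-line wrapper lives at `inst/cli/csrec`
(`csrec simulate | train | evaluate | score | grid`).

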