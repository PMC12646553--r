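---
title: "Methods: graph-collaborative, temporally selective medication recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-collaborative, temporally selective medication recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given a patient's longitudinal electronic health record — an ordered sequence
of visits, each carrying a set of diagnosis codes, a set of procedure codes
and a set of prescribed medications — the package predicts the medication set
of the current visit from the current diagnoses/procedures and the history of
earlier visits. The task is multilabel classification over a medication
vocabulary of size $|M|$ (ATC-level classes; 14–18 classes at the
granularities this package targets), with drug–drug interaction (DDI)
awareness: recommending two medications known to interact harmfully is
penalised structurally, and measured by a dedicated metric.

## Model

Write $V_t = (V_d^t, V_p^t, V_m^t)$ for the multi-hot encodings of visit
$t$'s diagnosis, procedure and medication sets over vocabularies of sizes
$|D|, |P|, |M|$.

**Collaborative module.** Three ingredients:

1. *Medication graph.* A co-occurrence matrix $A_{mm}$ counts, over the
   patient's previous visits, how often each unordered medication pair was
   prescribed together. A binary matrix $A_{ddi}$ flags contraindicated
   pairs. The combined graph is $G_m = A_{mm} - \lambda A_{ddi}$ with
   negative entries clipped to zero (a negative edge weight is undefined in
   the attention layer that consumes the graph; clipping removes the edge).
   $\lambda \ge 0$ (default 1) controls how aggressively interaction
   penalties sever co-occurrence edges. By default the graph is built from
   the *patient's own* history and rebuilt at every prediction step; a
   cohort-global variant is available (`cooccur_scope = "cohort"`).
2. *Per-visit heterogeneous graphs.* For each visit, complete bipartite
   graphs pair the visit's diagnoses with its procedures ($G_{dp}$), and the
   *previous* visit's medications with the current diagnoses ($G_{md}$) and
   procedures ($G_{mp}$) — the current visit's medications are the target,
   never an input.
3. *Neighbour-focused multi-head graph attention.* For a node $i$ with
   neighbour set $N_i$, per head: $h = XW$, attention logits
   $g_{ij} = \mathrm{LeakyReLU}(a^\top [h_i \Vert h_j])$, weights
   $\alpha_{ij} = \exp(g_{ij}) / \sum_{k \in N_i} \exp(g_{ik})$, and update
   $e_i = \sigma(\sum_{j \in N_i} \alpha_{ij} h_j)$ with ELU activation.
   Unlike standard graph attention the node's **own feature is excluded**
   from the aggregation — the update is built entirely from neighbours, so
   cross-entity collaboration dominates over self-information. Heads are
   concatenated; with $H$ heads and per-head width $d_H$ the representation
   width is $r = H d_H$.

Propagation is staged: medications update over $G_m$; diagnoses and
procedures update over $G_{dp}$; finally cross-updates run over $G_{md}$ then
$G_{mp}$, refreshing all three entity types. The result is one node matrix
per visit and entity type.

**Temporal selectivity module.** Per entity type, each visit's node matrix
is mean-pooled to one vector. A forward GRU over the pooled sequence yields
states $g_1..g_t$ and *forward selection coefficients*
$\alpha_j = \tanh(W_\alpha g_j + b_\alpha)$; a backward GRU over the reversed
sequence yields states $h_j$ and *backward coefficients*
$\beta_j = \mathrm{tanhshrink}(W_\beta h_j + b_\beta)$, where
$\mathrm{tanhshrink}(x) = x - \tanh(x)$. The aggregated representation is the
coefficient-gated sum $\sum_j \alpha_j \odot \beta_j \odot V^j$, computed
independently for diagnoses ($d_t$, over visits $1..t$), procedures ($p_t$)
and medications ($m_{t-1}$, over visits $1..t\!-\!1$; the zero vector when
there is no history — the cold-start case). Each entity type has its own GRU
and coefficient parameters.

**Prediction.** $\hat y_t = \mathrm{sigmoid}(W_o [d_t ; p_t ; m_{t-1}] + b_o)$
with a single learnable linear layer mapping $3r \to |M|$ (the concatenated
representation cannot be an $|M|$-vector without one). Medications with
probability strictly above the threshold (default 0.5) are recommended.

**Training.** Summed binary cross-entropy over every visit and medication;
for a patient with $T$ visits, each visit $t$ is a training example using
history $< t$. Adam (learning rate $10^{-3}$ by default) with L2 weight
decay, one patient per optimisation step, global gradient-norm clipping at
5, early stopping on validation Jaccard with best-epoch restoration.
Training is exactly reproducible for a fixed seed.

## Ablation variants

All variants share one code path, switched by `variant`:

* `WO_S` — no temporal selection; the last visit's pooled representation is
  used directly.
* `WO_C` — no graph collaboration; raw pooled embeddings enter the temporal
  module.
* `GAT_GCN` — degree-normalised graph convolution (with self-loops) replaces
  attention in every stage.
* `WO_DM`, `WO_PM`, `WO_DP` — drop the medication–diagnosis,
  medication–procedure or diagnosis–procedure graph.
* `WO_MM` — drop the medication graph entirely (both co-occurrence and DDI);
  the DDI *metric* still uses the interaction matrix.

## Evaluation metrics

All four are computed per visit and macro-averaged over the visits pooled
across test patients:

* **Jaccard** $|y \cap \hat y| / |y \cup \hat y|$; a visit where both sets
  are empty scores 1 (the equation is 0/0 there; the recommendation is
  exactly right).
* **PRAUC** — step-integrated precision–recall area over the medication
  ranking (average-precision form); ties broken by ascending medication
  index for determinism; visits with an empty truth set are excluded with a
  warning (recall is undefined).
* **F1** — harmonic mean of per-visit precision and recall, any 0/0 taken
  as 0 (note the deliberate asymmetry with Jaccard's both-empty convention:
  an empty prediction against an empty truth is a *correct set* for Jaccard
  but carries no precision/recall information).
* **DDI rate** — fraction of unordered recommended pairs flagged in the
  interaction matrix; visits recommending fewer than two medications have no
  pairs and contribute 0.

## Synthetic cohorts

Real ICU prescribing data requires credentialed access, so the package ships
a seeded generator (`generate_cohort()`) whose *marginals* match the
published hypertension cohort summaries the model family is evaluated on:
`mimic4_like` targets mean 2.8169 visits/patient, 9.3666 diagnoses and
2.5492 procedures per visit; `mimic3_like` targets 2.3361 / 10.9262 /
4.0609. Desk-scale vocabularies are $|D| = 200$, $|P| = 100$, $|M| = 18$.

Mechanics and the reasoning behind them:

* Visits per patient are $1 + X$ with $X$ a zero-truncated Poisson whose
  rate is calibrated by root-finding so the *realized* mean matches the
  target (every patient has at least two visits, matching the standard
  inclusion filter). Diagnosis-set sizes use the same calibration;
  procedure counts are plain Poisson.
* Codes are drawn without replacement from a Zipf-like popularity
  distribution (weight $\propto$ rank$^{-0.8}$), so a small set of codes is
  common — as in real coding data. A diagnosis recurs at the next visit
  with probability 0.6 (chronic-condition carryover); carried sets are
  subsampled to the drawn size so the size calibration is preserved.
* Medications are the union of (i) planted prescription rules — by default
  four rules mapping a mid-popularity diagnosis to a medication with firing
  probability 0.9, the recoverable signal a learner must find; (ii)
  co-prescription clusters (two pairs, firing per visit with probability
  0.06) that create strong co-occurrence edges; and (iii) per-medication
  Bernoulli noise at 0.005. With these defaults the realized medication
  mean per visit lands near the published 1.14; it is emergent, not a dial.
* Two contraindicated pairs are planted: one inside a co-prescription
  cluster and one spanning two rule medications, so DDI-flagged pairs do
  co-occur in the data and the $\lambda$ penalty has something to act on.
  The generator report computes realized means, per-rule conditional
  frequencies and the DDI co-prescription rate exactly from the emitted
  cohort.

What the generator does **not** emulate: real ICD/ATC semantics, calendar
time between visits, dose or duration, diagnosis-set correlation structure
beyond persistence, and — importantly — *temporal prescribing dynamics*:
planted rules fire from the current visit's diagnoses only. A model that
perfectly summarises the current visit can therefore match the temporal
module on this data (see "Limitations"). Passing tests on synthetic cohorts
demonstrates mechanical and statistical correctness of the implementation,
not clinical performance.

## Numerical choices

* **tanhshrink initialisation.** $\mathrm{tanhshrink}(x) = x - \tanh(x)$ is
  cubically flat at the origin ($\approx x^3/3$). With conventional
  zero-initialised biases the backward coefficients start at $\sim 10^{-3}$,
  the gated sum is numerically dead, and the whole selection path trains an
  order of magnitude slower than the rest of the network (we observed the
  full model stuck far below its ablations for tens of epochs). The
  coefficient-head bias $b_\beta$ is therefore initialised at 1, which
  starts the gate in tanhshrink's responsive range; everything else is
  Xavier-uniform, biases zero.
* **Width convention.** The internal width is $r = H \cdot
  \mathrm{round}(d/H)$ so per-head slices tile exactly and ablation variants
  that bypass attention remain dimension-compatible for every head count
  (`embed_dim = 64`, `heads = 3` gives $r = 63$).
* **Degenerate graphs.** A node that is merely isolated inside a non-empty
  graph keeps its linearly mapped feature (there is nothing to aggregate;
  mapping keeps the output width per head). A graph with *no edges at all*
  is skipped entirely — features pass through unchanged — which makes the
  full model with empty graphs coincide exactly with `WO_C`.
* **Clipping and thresholds.** Probabilities are clipped to
  $[10^{-7}, 1 - 10^{-7}]$ inside the loss; recommendation uses a strict
  inequality, so a probability exactly at the threshold is not recommended.
* **Loss reduction.** The summed (not averaged) cross-entropy matches the
  training objective as defined; a mean-reduction flag exists for
  experimentation with scale-sensitive optimisers.
* **Filter order.** `filter_cohort()` removes rare medications *before*
  dropping short patients, making the medication vocabulary independent of
  the visit-count cut; the two filters are individually standard but their
  order is not dictated, so it is fixed and documented here.
* **Patient-level split.** The 23:16:16 train/validation/test split is by
  patient (all of a patient's visits stay together), the standard choice in
  medication recommendation; remainder patients go to training.

## Gradient engines

Training needs gradients of the loss through graph attention, six GRUs and
the selection gates. The package carries three implementations of the same
forward computation: a plain-R numeric path (the readable reference, used by
`predict(..., engine = "r")`), a small reverse-mode tape in R, and a
compiled RcppArmadillo kernel with hand-derived backpropagation that does
the actual training work. The test suite pins all three together to
$10^{-8}$ or better across every ablation variant, and checks the compiled
gradients against central finite differences on a small model. The tape is
deliberately independent of the kernel — it differentiates each primitive
op, while the kernel implements the chain rule per layer — so agreement is a
meaningful cross-check rather than a tautology.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data at
sizes chosen for a single CPU: oracle and property checks use hundreds to a
thousand random instances; capacity (memorisation) checks use 20 patients;
learning and baseline-margin checks use cohorts of 1,200–2,000 patients;
ablation and interaction-penalty experiments use 300-patient cohorts with
five seeds, and the head-count stability check a 1,000-patient cohort (the
sample size at which between-run sampling noise falls below the band being
checked). Ablation comparisons train at a capacity (embedding width 48) at
which the full model has converged; smaller widths leave it undertrained
relative to its simpler ablations. The acceptance script trains one
full model on a 1,200-patient cohort and reports test metrics, the
frequency-baseline margin and the realized generator marginals.

## Limitations

* On the shipped generator the planted signal is memoryless given the
  current visit, so the `WO_S` ablation — which keeps only the last visit's
  representation — is close to a sufficient statistic and can match or
  exceed the full model; the temporal module's advantage on real cohorts
  (where prescribing has genuine history dependence) is not reproduced by
  construction here.
* The DDI penalty acts only through the graph structure (edge removal at
  the clipping threshold); with feature-only attention the effect on
  recommended sets is indirect and can be weak at desk scale.
* Co-occurrence graphs are dense matrices; vocabularies beyond a few
  thousand medications would need a sparse rewrite.
* The per-patient co-occurrence scope rebuilds $A_{mm}$ at every prediction
  step, which is faithful but quadratic in history medications; the
  cohort-global option trades fidelity for speed.
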