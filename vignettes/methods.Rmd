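---
title: "Adaptive combination of screening scales: model, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive combination of screening scales: model, simulation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screentree)
```

## The problem

Mental-health screening instruments come in two shapes. Comprehensive
scales (the 90-item adult symptom checklist is the canonical example)
cover many symptom dimensions at once but are long and unspecific;
single-assessment scales target one symptom with high specificity but
cannot triage a multi-symptom presentation. `screentree` implements a
combined administration strategy: use historical diagnosis data to decide
*in which order* symptoms should be probed, screen each symptom cheaply
with its comprehensive-scale block, and descend into the dedicated
single-assessment scale only when the block suggests a positive — with
early stopping once the confirmation is mathematically settled.

## The model

Responses use five ordinal options scored $u \in \{0,1,2,3,4\}$ (*none,
mild, moderate, severe, extreme*). An item response is **positive** when
$u \ge v$; the conventional criterion is $v = 2$ (moderate-or-worse), and
severity-restricted screening conditions move $v$ over $1..4$.

Two empirical indices are estimated from a historical dataset carrying
per-respondent item responses and per-symptom positive/negative diagnosis
annotations:

* the **first-order probability index** of symptom label $r_i$,
  $P(i) = N(i)/N_C$ — the fraction of comprehensive-scale respondents
  diagnosed positive for $r_i$;
* the **second-order probability index** of confirmation item $s_{i,j}$,
  $P_{i,j} = N_{i,j}/N_S$ — the fraction of that single scale's
  respondents answering the item positively, with $N_S$ counted per
  single scale (its own respondent pool).

Symptom blocks are sorted by descending $P(i)$ and confirmation items by
descending $P_{i,j}$ (both sorts stable, ties broken by input order, so
output is deterministic; labels absent from history get index 0 and sort
last). Items *within* a comprehensive block are never sorted — blocks are
small and the first-tier rate is order-invariant. The sorted system is
materialized as a depth-2 **scale tree**: a sentinel root whose children
are the symptom blocks, each linked to its single-assessment leaf. The
tree is an explicit data structure (not implicit iteration) so that the
ablation variants can swap traversal policies.

## The decision engine

For each label, all $N_{C',r_i}$ items of its block are administered and
the first-order positivity rate $P_{1,u,r_i} = n_{u,C',r_i}/N_{C',r_i}$
is compared with the preset $P_{1,\text{preset}} = s_{1,\min}/s_{1,\text{total}}$
(default 0.5, the worked one-of-two example). The boundary is inclusive
at both tiers (`>=`). A first-tier positive triggers the second tier: the
single scale is administered in optimized order, and after each answer the
second-order rate $P_{2,u,S_i'} = n_{u,S_i'}/N_{S_i'}$ is updated with the
**total** item count as a fixed denominator. The test stops positive the
moment the rate reaches $P_{2,\text{preset}}$ — and because the
denominator is fixed, the early verdict provably equals the verdict from
complete administration (the test suite checks this exhaustively). The
final classification of a label is the second-tier verdict.

Numerical/degenerate choices:

* the first-order rate is computed after the whole block (the denominator
  is the full block size, so "real-time" evaluation per block is exact);
* a label without a confirmation scale keeps its first-tier verdict;
* a zero-item block is an error, never a silent zero rate;
* block score (`num`) and single-scale score (`count`) are logged for
  auditability but enter no decision rule, matching their definitional
  role;
* whether the second-tier denominator is items-answered-so-far or total
  items is ambiguous in the protocol's prose; fixed-total is adopted,
  consistent with the rate's printed definition — this is also what makes
  early stopping sound.

Ablation variants (`ablation_variant()`): `no_sorting` keeps descent and
early stopping but uses input order; `comprehensive_only` classifies by
the first tier alone on the sorted comprehensive scale; `no_indices`
administers the unsorted comprehensive scale and always descends into the
full single scale without early stopping. Because classifications are
order-invariant under complete information, `full` and `no_sorting`
produce identical classifications — sorting buys question count, not
accuracy — while removing the second tier (or forcing it everywhere)
changes the decisions themselves.

## The synthetic cohort

`generate_cohort()` produces the simulated world the evaluation runs on.
Stated parameters: 2134 respondents; three templates on 5-point options —
90 items/11 labels (adults), 60/10 (adolescents), 40/8 (children) — with
age-matched assignment; affected-label severity mild/moderate/severe =
60/30/10% (severity bands map to scores 1–2, 3, 4); 30% single-symptom vs
70% comorbid cases; 5% of respondents get one contradictory annotation
(a positively annotated label flipped negative, as in a record marked "no
depression" while endorsing severe-depression items). Ground truth is
latent severity ≥ moderate, mirroring the moderate-or-worse response
criterion.

Where the protocol is silent, the generator commits once to a realistic
choice (these are design constants, not tuning knobs):

* **comorbid breadth**: comorbid cases affect $2 + \mathrm{Bin}(5, 0.5)$
  labels — broad checklists typically show several elevated subscales in
  comorbid patients;
* **co-occurrence coupling**: the "conditional dependency" between
  symptoms is a symmetric pairwise sampling-weight boost (×2 for a label
  coupled to an already-affected one; anxiety↔depression everywhere,
  plus somatization↔anxiety on the adult template) — the minimal
  mechanism reproducing the stated co-occurrence intent without inventing
  a network structure;
* **response style**: an affected item is answered at the *top* score of
  its severity band (mild→2, moderate→3, severe→4; the condition-matching
  higher-score option is prioritized), jittered ±1 with probability 0.15
  per direction, and *under-reported* to option 0/1 with probability
  0.30 — patients selecting low-score options despite real symptoms is
  exactly the misclassification mechanism the screening literature
  describes, and without it moderate-severity sensitivity would be
  trivially 100%;
* **background endorsement**: unaffected labels are answered 1 with
  probability 0.60 (clinical cohorts endorse "a little bit" widely); this
  is what caps accuracy under the mild screening criterion;
* **age mixture** 50/30/20 adult/adolescent/child; 10-item single scales;
  sexes 50/50 (recorded, not used by any mechanism).

Mild severity is the designed hard case: its band top-score of 2 counts
as a positive response while its ground truth is negative, so mild cases
are systematically over-called — the engine's known limitation.

What a green test does **not** establish: the generator has no item
response theory model, no item-level discrimination, no cultural or
longitudinal structure, and its annotations are derived from the latent
state rather than clinician judgement. Passing metrics mean the algorithm
behaves as specified *on this stated world*, not that the clinical
figures would replicate on real patients.

## Evaluation protocol

`stratified_kfold()` stratifies by age group, then by dominant (maximum)
latent severity, dealing shuffled strata cyclically into folds (each
fold matches the cohort within one respondent per stratum; 2134
respondents split 427/427/427/427/426). Training folds fit the indices —
the algorithm's only trained component; validation respondents are
administered adaptively with full state reset in between. Metrics are
pooled per (respondent, label) pair within a fold, macro-averaged over
folds, and averaged over `n_trials` re-draws of respondent jitter
(default 100, scaled from the reference 1000; the report carries 95% CI
half-widths over trials so the scaling is auditable).

Metric readings (the reference table never defines them precisely):

* **accuracy** — per-pair agreement with ground truth over all pairs;
* **sensitivity (moderate symptoms)** — recall restricted to pairs whose
  latent severity is moderate, under the default criterion;
* **specificity (severe symptoms)** — true-negative rate with the
  screening criterion at the severe level ($v = 3$) and level-matched
  ground truth (positive ⇔ severity ≥ $v$); the moderate stratum then
  forms the hard negatives whose bleed-through degrades specificity.

Level-matched truth reduces to the stored annotations at the default
level, and makes the severity sweep meaningful at every level. At the
extreme level no latent stratum reaches truth-positive, so sensitivity is
reported `NA` with a warning rather than 0.

Test duration is reported as **question count**; wall-clock minutes are
hardware- and respondent-dependent and are deliberately not reproduced.

## Known limitations

* Indices assume symptom independence; comorbidity is simulated but not
  modelled in the estimator.
* The mild-severity limitation is structural (band top-score 2 is a
  positive response with negative truth) and is asserted as an accuracy
  *cap*, not fixed.
* The annotation-column contract cannot recover any particular published
  index table; printed index values are used only as ordering/arithmetic
  fixtures in the tests.
* Sub-second-tier adaptivity (re-estimating indices mid-session,
  learned truncation) is out of scope.
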