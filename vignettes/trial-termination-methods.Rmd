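---
title: "Modelling premature termination of registered clinical trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling premature termination of registered clinical trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialterm)
```

## The problem

A substantial fraction of registered clinical trials stop prematurely —
because of insufficient enrolment, funding or business decisions, safety
signals, or administrative failure. Public registries record, for every
study, its recruitment status alongside rich structured and free-text
metadata. `trialterm` treats termination as a supervised learning problem on
those records: which registered characteristics of a trial are associated
with premature termination, and how well can termination be predicted before
it happens?

The package covers the full analysis path: parsing registry XML, cohort
selection, three families of engineered features, filter-based factor
ranking fused across methods, class-imbalance-aware ensemble prediction, and
the statistical machinery for comparing models.

## Cohort selection

Records are parsed from the registry's public per-study XML schema. The
analysis cohort keeps trials that are

* **Completed** or **Terminated** (label 1 for terminated) — "Withdrawn"
  studies never enrolled a participant and are excluded, as are all ongoing
  or unverified statuses;
* started in or after 2000 (a record whose start date cannot be parsed to a
  year is excluded with a logged reason);
* located mainly in a *top country*. A trial's main country is the country
  with the most sites, ties broken by the first country listed. Top
  countries are those contributing at least 1,000 trials in the full input —
  a threshold rule rather than a fixed list, so it scales to synthetic
  corpora (the threshold is an argument of `select_cohort()`);
* complete in the keyword and detailed-description fields, where an absent
  element, an empty string and whitespace-only text all count as missing.

Every input record lands either in the cohort or in an exclusion log with
the first rule it failed, so the filter is auditable and conserves records.

## Feature engineering

### Statistics features (40)

Administrative, study-information, study-design and eligibility counts.
The canonical 40-name catalog ships as a plain CSV
(`extdata/stat_feature_catalog.csv`) so names can be corrected without code
changes. Encodings worth noting:

* The main collaborator class is the modal class of the collaborator list,
  ties broken by first appearance — the same rule as for countries.
* The eight trial phases are one-hot encoded (missing phase counts as
  "No Phase"), so the phase block always sums to one.
* Tristate registry fields (DMC oversight, FDA regulation, expanded access,
  randomization, placebo group, healthy volunteers) encode *yes* as 1 and
  both *no* and *missing* as 0, keeping the matrix at exactly 40 columns
  with no separate missingness level.
* The responsible-party field contributes a single indicator
  (`Responsible Party: Sponsor`). Adding indicators for the other two party
  types would overshoot the fixed 40-column design, and the sponsor
  indicator is the one with an established association with termination.

The eligibility text block is parsed by counting rules only: lines are
newline-separated non-blank rows with bullet markers stripped; the
case-insensitive headers "Inclusion Criteria" / "Exclusion Criteria" switch
the scope and are not themselves counted; a numeric token is any
whitespace-delimited token containing a digit (so both "18" and "5mg"
count). Text before any header contributes to the *total* scope only, which
is why `inclusion + exclusion <= total` holds rather than with equality.

### Keyword features (500)

The keyword field is tokenized by splitting on punctuation and whitespace,
lower-casing, and removing a fixed English stop-word list shipped with the
package; two multi-word terms such as "Ankle Joint" and "Osteoarthritis"
therefore yield three tokens. TF-IDF uses the classical variant: raw
in-document term frequency and `idf = ln(N / df)`. The vocabulary is the 500
tokens with the largest corpus score (the sum of tf×idf over documents),
ties broken lexicographically. Note that under this classical idf a token
occurring in *every* document has idf exactly 0 — it is a non-discriminator
and effectively never enters the top 500 on a realistic corpus.

By default the vocabulary is fitted on the training split of each
evaluation repetition (`leakage_mode = "train_only"`). Fitting on the full
cohort before splitting — the whole-corpus variant — is available as
`leakage_mode = "all"`; it leaks test-set document counts into the idf and
is provided for procedure-replication purposes only.

### Embedding features (100)

The detailed-description field is embedded with paragraph vectors in the
distributed-memory formulation (PV-DM): each word owns an input vector,
each document an additional paragraph vector, and the mean of the paragraph
vector and the context word vectors predicts the center word through a
negative-sampling objective. Defaults: dimension 100, window 5, minimum
word count 2, 20 epochs, 5 negative samples, learning rate 0.025 decaying
linearly to 1e-4. Training is single-threaded with an internal
xorshift RNG, so models are bit-reproducible under a fixed seed — a
deliberate trade of speed for exact reproducibility.

The embedding model is fitted on the training split of each repetition and
vectors are *inferred* (word and output matrices frozen, a fresh paragraph
vector trained) for both training and test documents, so train and test
vectors are produced by the same operation. A document with no
in-vocabulary words maps to the zero vector, with a message.

At the defaults the three families assemble to 40 + 500 + 100 = 640 named
columns with no missing values.

## Ranking termination factors

Five filter methods rank all features by relevance to the label:

* **ANOVA** — one-way F statistic (a perfectly separating feature has
  infinite F and ranks first);
* **Mutual information** — plug-in MI after equal-frequency discretization
  into 10 bins (bin count configurable; 10 bins keep ~n/10 observations per
  cell at the cohort sizes used here);
* **ReliefF** — k = 10 nearest hits/misses per instance, all instances
  used, Manhattan distance on range-normalized features;
* **CIFE** — greedy forward selection under
  relevance − Σ redundancy + Σ conditional redundancy;
* **ICAP** — greedy forward selection under
  relevance − Σ max(0, interaction), capping negative interactions at zero.

CIFE and ICAP are run to exhaustion so that they, too, produce complete
permutations — Dowdall aggregation needs full rankings. The **Dowdall**
score of a feature is the sum over methods of 1/rank: a Borda-count variant
that favours features with many first preferences, while an accidental
bottom rank contributes only a negligible fraction. All ties — in scores,
in greedy selection, in aggregation — break lexicographically by feature
name, so every ranking is reproducible.

## Predicting termination under class imbalance

The cohort is imbalanced at roughly 1:7.75 terminated to completed. A model
trained on the raw data is dominated by the majority class: it scores high
accuracy but chance-level balanced accuracy and near-zero F1 on the
terminated class. The package therefore repeats balanced random
undersampling 10 times — each round keeps every terminated trial plus an
equal-sized uniform draw of completed trials (exactly 1:1, sampling without
replacement) — trains one base model per round, and averages the members'
predicted probabilities (majority voting is available as
`combination = "vote"`). Averaging is the default because it preserves
score granularity for AUC; with 10 members a vote yields only 11 distinct
scores.

Four base-learner families are supported: a one-hidden-layer neural network
with 100 nodes (inputs standardized), a random forest of 1,000 fully grown
trees, gradient boosted trees, and logistic regression. Remaining
hyperparameters are overridable defaults, not tuned claims.

## Evaluation

`run_experiment()` repeats a stratified 80/20 holdout split (default 5
repetitions), refits the text models per repetition according to the
leakage mode, and evaluates each learner both as a single no-sampling model
and as an undersampling ensemble. Metrics are reported on a percent scale:
accuracy, balanced accuracy (mean of per-class recalls), F1 for the
terminated class (the minority positive class — with the majority as
positive the near-zero single-model F1 phenomenon would be invisible), and
AUC via the rank statistic (ties get half credit; scores at exactly the
threshold classify as terminated, a documented boundary convention).

Ensembles are compared to their single counterparts with the **corrected
resampled t-test**, `t = mean(d) / sqrt((1/k + n_test/n_train) var(d))`,
which inflates the variance for the overlap of resampled training sets;
multiple comparisons are Holm-Bonferroni adjusted. Across feature
combinations, classifier families are compared with the **Friedman test**
on within-dataset ranks and the **Nemenyi critical difference**
`CD = q_alpha(k) sqrt(k(k+1)/(6N))`, with the q table shipped for
k ≤ 10 and alpha ∈ {0.05, 0.10}. For four classifiers over the seven
feature combinations these evaluate to 1.58 (alpha = 0.10) and 1.77
(alpha = 0.05).

## The synthetic cohort generator

Real registry snapshots are large and not redistributable, so the package
ships a generator whose output has known ground truth at every stage:

* Structural fields (sponsor class, collaborators, phase, sites, design,
  eligibility blocks, ...) are drawn first, with marginals chosen to
  resemble a registry corpus (e.g. interventional share 0.82, a
  US-dominated country mix).
* The termination label is then drawn from a logistic model over the
  record's *own* 40 statistics features, with user-specified log-odds
  `effect_weights`; the intercept is calibrated numerically so the marginal
  termination rate hits its target (default 11.46%, i.e. 1:7.75). Because
  labels are generated from features — not the reverse — a planted binary
  effect of weight w has exact population odds ratio `exp(w)`, and
  parameter-recovery and ranking tests have analytic truth. The generator
  also exposes its Bayes-oracle scores (`oracle_auc()`), the best any model
  on the statistics features could do.
* Keyword text is drawn conditionally on the label from a 600-term
  vocabulary with heavy-tailed base frequencies; a 20-term rare-disease
  subset is over-represented (×4) among terminated trials, mimicking the
  enrichment of rare-oncology terms among terminated studies.
* Description text is a two-topic mixture whose topic-B share is 0.35 for
  completed and 0.65 for terminated trials (signal 0.30), giving the
  embedding stage a recoverable signal of known strength.
* Eligibility blocks are emitted with exact expected counts, the ground
  truth for the parser.

What the generator does *not* emulate: real marginal country or MeSH
frequencies, correlated missingness patterns, semantic structure in
eligibility text, or temporal drift. Tests passing on synthetic data
therefore validate the machinery — parsing, counting, ranking, sampling,
combination, statistics — not the real-world effect sizes; headline scores
from the genuine registry snapshot are not reproducible from this package
alone.

## Numerical choices and problem sizes

* All randomness flows through explicit integer seeds; ensemble member
  seeds derive from the master seed, and the embedding trainer is serial by
  design, so entire experiment reports are reproducible bit for bit.
* Degenerate inputs have defined behaviour: single-class labels raise
  errors (undersampling, AUC, ranking), constant features receive defined
  ranks via the lexicographic tie-break, a fully tied Friedman matrix
  returns statistic 0 and p = 1, and zero-variance non-zero mean
  differences in the corrected t-test report p → 0 with a flag.
* Test and example problem sizes (cohorts of 500–5,000 trials, embedding
  dimensions 16–100, 100-replicate ranking studies) are chosen so the full
  validation suite runs on a single CPU in minutes while keeping
  Monte-Carlo error well inside the asserted margins; the planted-signal
  constructions are strong by design (oracle AUC > 0.95) because they test
  recovery machinery, not detection power.

## Known limitations

* The eligibility parser is deliberately count-based; it does not interpret
  criteria semantically or normalize age units.
* CIFE/ICAP run in O(p²) pairwise information computations; for the 640-
  feature matrix this is minutes of compute, which is why `run_experiment()`
  leaves full ranking to an explicit `ranking_report()` call.
* The PV-DM implementation is single-threaded; corpora of hundreds of
  thousands of documents would need a parallel trainer, at the cost of
  run-to-run bit reproducibility.
* The registry's post-2019 JSON API dialect is out of scope; inputs follow
  the classic per-study XML schema.
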