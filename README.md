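# carenet

Hierarchical attention networks for diagnosing emergency-department
dyspnoea visits from health-system event streams.

## What this is for

Dyspnoea is one of the ED's most common and most dangerous chief
complaints, and its three dominant causes — acute heart failure (AHF),
exacerbated COPD (eCOPD) and pneumonia — are frequently confused at
presentation. `carenet` implements **CareNet**, a clinical attention-based
recurrent encoder network that classifies an ED dyspnoea visit into AHF,
eCOPD, pneumonia and "other diagnoses" at triage time, using the patient's
time-stamped, context-grouped event history (diagnoses, complaints,
medications, procedures, binned labs, vitals) plus onsite triage variables.
It is aimed at methods researchers in clinical machine learning who want a
complete, testable, CPU-scale implementation of the architecture, its
evaluation protocol and its interpretability statistic — including a
synthetic EHR generator with planted ground truth, since the original
regional cohort is not public.

## The model in brief

A visit's pre-index window (default 52 weeks) is cut into *M* = 10 equal
periods and its events grouped by (period, care context) with six contexts.
Three stacked layers, each a bidirectional GRU encoder plus attention
pooling, build the representation:

* events in a cell → **context embedding** (skip-gram-initialized token
  embeddings; empty cells contribute a learned per-context empty vector),
* six context embeddings (+ per-period vitals) → **period representation**,
* *M* period representations (+ onsite triage vector) → **patient
  representation** → feed-forward head.

The attention form is `u_t = tanh(W h_t + b)`, `a = softmax(u_t · q)`,
`s = Σ a_t h_t`. The head is *evidential*: per label it emits a
non-negative evidence pair `(e⁺, e⁻)` defining a Beta(α, β) posterior with
`α = e⁺ + 1`, `β = e⁻ + 1`; the reported score is `p̂ = α/(α+β)` and
`u = 2/(α+β)` quantifies uncertainty. Labels are not jointly normalized, so
`Σ p̂` may exceed 1 (multilabel by design). The loss per label is the Beta
Bayes risk `(y − p̂)² + p̂(1−p̂)/(S+1)` plus an annealed KL penalty on
misleading evidence.

Evaluation follows the matching protocol: 10-fold CV with 10 bootstrap
evaluations per fold on 90% of the held-out fold, summarized as median
micro-averaged AUROC (2.5–97.5 percentile), plus maximum sensitivity at
specificity > 75%. Interpretability ranks event codes by the attention
product (event × context × period weights) summed over the cohort.

## Worked example

Simulate a cohort with planted diagnostic signal, pretrain embeddings,
train, evaluate against the information ceiling, and rank variables:

```r
library(carenet)

cohort <- generate_cohort(sim_config(n_visits = 800, seed = 42))
vocab <- build_vocabulary(
  cohort$events$code[!cohort$events$code %in% default_numeric_vars()],
  min_count = 5)
bundles <- cohort_bundles(cohort$events, cohort$visits, vocab, timeline_config())

emb <- train_skipgram(build_corpus(cohort$events, vocab), vocab, d = 16,
                      epochs = 2, seed = 1)
model <- carenet_init(vocab, n_period_numeric = 5,
                      n_onsite = length(bundles[[1]]$onsite),
                      embeddings = emb, seed = 1)
train_idx <- 1:640; test_idx <- 641:800
model <- carenet_train(model, bundles[train_idx], seed = 1)
#> <carenet_model> d=16 H=16 | P=5 per-period + Q=14 onsite numerics |
#>   22,488 parameters | trained 20 epochs, final loss 0.5838

scores <- carenet_predict(model, bundles[test_idx])
labels <- bundle_labels(bundles[test_idx])
micro_auroc(scores, labels)
bayes_oracle_auc(cohort$truth, idx = test_idx)$micro
#> held-out micro AUROC: 0.947 (oracle ceiling 1.000)

imps <- lapply(bundles, function(b) {
  fr <- carenet_forward(model, b)
  visit_event_importance(fr$state, b, vocab)
})
head(cohort_ranking(imps), 5)
#>   rank    code importance
#> 1    1 EV:0114   59.93756
#> 2    2 EV:0154   59.19834
#> 3    3 EV:0131   46.40572
#> 4    4 EV:0111   46.38212
#> 5    5 EV:0020   42.35067
sum(unlist(cohort$truth$signal_codes) %in% head(cohort_ranking(imps)$code, 30))
#> planted signal codes in top 30: 9 / 20
```

The held-out micro AUROC of 0.947 sits a few points under the Bayes
ceiling computed from the generator's exact posterior logits — the most any
classifier could score on this cohort. All five top-ranked codes above are
planted signal codes; at this small demonstration scale 9 of the 20 planted
codes reach the top 30, and at the package's full study size (2,000 visits)
18–20 of 20 typically do.

A command-line wrapper covers the same pipeline
(`simulate | pretrain | train | evaluate | rank | baseline | smoke`):

```sh
Rscript inst/cli/carenet-cli.R smoke --out /tmp/carenet-smoke --seed 7
```

## Package layout

* `R/ehr-model.R`, `R/io.R`, `R/bundles.R` — data model, TSV interchange
  formats, label mapping, timeline segmentation, vocabulary, visit tensors.
* `R/synthetic.R` — cohort generator with planted signal and exact
  posterior oracle.
* `R/embeddings.R`, `src/skipgram.cpp` — skip-gram pretraining.
* `R/carenet-model.R`, `src/carenet.cpp` — the network, loss, training.
* `R/evaluation.R` — micro AUROC, CV×bootstrap, sensitivity at floor,
  subgroups.
* `R/interpretability.R` — attention-product importance and plot data.
* `R/baseline.R` — nine expert features, MissForest-style imputation,
  boosted trees.
* `R/cli.R`, `inst/cli/carenet-cli.R` — command-line orchestration.
* `vignettes/carenet-methods.Rmd` — the model, its assumptions, design
  decisions and limitations.
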