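---
title: "Aggregating crowdsourced skin-lesion labels: models, metrics and the synthetic crowd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregating crowdsourced skin-lesion labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdlaw)
```

## The problem

Labeling medical images at scale is expensive when every label requires an
expert. An alternative is to collect many cheap, noisy decisions from a
heterogeneous crowd and aggregate them. `crowdlaw` implements a complete
pipeline for the seven-class skin-lesion setting (AKIEC, BCC, BKL, DF, MEL,
NV, VASC; AKIEC, BCC and MEL form the malignant group): annotators first make
decisions on a *training* split with known labels, those decisions are used to
profile each annotator, and the profiles then weight (or select) their
decisions on a *test* split whose crowd label is the quantity of interest.

## Data model and cleaning

All stages exchange a long-format decision table: one row per
(participant, image, split, true label, response, response time, day).
Responses with response times strictly longer than 20 s, or with missing or
negative response times, are discarded before any estimation (a response of
exactly 20 s is kept — the rule is "longer than"). The 20 s default is the
task's response deadline; it is a tunable argument of `clean_decisions()`.
Profiles are estimated on cleaned decisions by default. Whether the original
study applied the filter before or after computing training accuracies is not
stated; cleaning first is this package's choice, and passing the uncleaned
table to `build_profiles()` reverses it.

## Annotator profiles

For participant $j$ with at least one training decision, the training
accuracy $a_j$ is the fraction correct on the training split. The individual
confusion matrix has entries $c_{d,T} = P(\text{response}=d \mid
\text{true}=T)$, estimated as empirical row proportions of the participant's
training decisions. Because individual matrices are noisy, they are used only
for participants with at least `min_individual_n` training decisions
(default 100; 500 is the sensitivity value); everyone else falls back to the
group-level matrix pooled over all participants. Pooling over *all*
participants (rather than only non-fallback ones) is a package choice; the
source material does not specify. A participant who appears only in the test
split gets the group accuracy as well.

Two estimation details matter for the log weights downstream:

* **Clamping.** Every probability entering a logarithm is clamped into
  $[\tau, 1-\tau]$ with $\tau = 0.02$ by default, so weights stay finite even
  for raw 0/1 estimates. Clamped rows are *not* renormalized (the clamp is a
  hard boundary, not a smoothing scheme); `renormalize = TRUE` exists for
  sensitivity analysis. Results are insensitive to $\tau$ below about 0.1.
* **Zero rows.** A true class a participant never saw in training yields an
  empty confusion row; it is replaced by the uniform row (1/7), the unique
  non-informative and clamp-safe choice, and flagged.

Prevalence priors $\pi_T$ come from the *train image composition* — the
fraction of distinct training images of each class — not from decision
counts, because training presentation is counterbalanced across classes and
decision counts would therefore distort prevalence. A class absent from the
training pool is floored at $\tau$ and the vector renormalized, with a flag.

## Aggregation schemes

On test image $i$ with crowd $C_i$, every scheme assigns each decision a
weight vector $w_T(d)$ over the seven classes, sums the vectors, and takes
the argmax:

$$D_i = \arg\max_{T} \sum_{d \in C_i} w_T(d)\;(+\log \pi_T).$$

* **SV** (simple voting): $w_T(d) = 1$ if $d = T$, else 0 — the
  majority-plurality rule.
* **SAW** (simple accuracy weighting): $a_j$ on the chosen class, 0
  elsewhere.
* **LAW-E** (log accuracy, equal off-diagonal): $\log a_j$ on the chosen
  class and $\log\left((1-a_j)/6\right)$ on the other six. This is the
  log-likelihood of the responses under a model where errors are uniform over
  the six non-chosen classes, so summed scores are log posterior
  probabilities up to a constant.
* **LAW-CA / LAW-CI** (confusion weighting): $w_T(d) = \log c_{d,T}$ read
  from the group (CA) or individual-with-fallback (CI) confusion matrix.
  These capture *which* errors an annotator makes, e.g. that NV is drawn
  toward MEL far more than toward AKIEC.
* **Priors**: appending `P` adds $\log \pi_T$ once per image. Priors are a
  Bayesian construct, so requesting them with SV or SAW is a contract error
  rather than being silently defined.
* **Selection**: `select_top_r()` keeps the $r$ decisions from the
  highest-training-accuracy annotators (all of them if the image has fewer
  than $r$ decisions); `r = "ALL"` disables selection. The full factorial of
  selection × scheme × prior is `run_switchboard()`.

Numerical choices: score ties at the argmax are broken toward the class with
the highest training prevalence by default (deterministic, auditable, and
aligned with how an indifferent Bayesian would break ties); lexicographic and
seeded-random rules are available. Selection ranking ties default to
lexicographic participant id. Priors enter once per image, not once per
decision. Posterior probabilities are computed with max-subtracted
exponentiation. Selection ranks annotators by their own training accuracy
even when their confusion matrix fell back to the group level.

## Metrics

Four metrics, computed by `metric_report()`:

* **Accuracy** — fraction of images labeled correctly. A constant-NV
  classifier on the study's test composition scores 60.1%, the NV prevalence.
* **Balanced accuracy** — unweighted mean of per-class sensitivities
  $TP_T/(TP_T+FN_T)$; the same constant classifier scores $1/7$.
* **Mean ROC-AUC** — mean of the seven one-vs-rest AUCs using the class
  scores $w_T$; AUC is the tie-corrected rank (Mann–Whitney) statistic.
* **Malignant ROC-AUC** — AUC of $w_{\text{cancer}} = w_{AKIEC} + w_{BCC} +
  w_{MEL}$ against truth-malignancy. The literal sum is used even on the log
  scale, where summing is not probabilistically meaningful, because that is
  the published definition; `use_posterior = TRUE` substitutes
  $P(AKIEC)+P(BCC)+P(MEL)$ from the softmax posterior as a sanity option.
  Raw summed weights are likewise the default scores for the mean ROC-AUC.

Algorithms are compared by percentile bootstrap over test images
(`bootstrap_ci_difference()`, default 10,000 resamples — the interval type
and count are package choices; percentile intervals match the plain reading
of "bootstrapped 95% confidence intervals" and 10,000 is cheap at this
scale). A resample on which a metric is undefined (a class vanishing) is
redrawn and counted, rather than imputed. `crowd_size_curve()` subsamples
$n$ decisions per image without replacement (25 repetitions per size by
default) to trace performance against crowd size.

## The synthetic crowd

The raw study data is available only on request, so the package ships a
generator whose defaults state the study's observed world:

* ~300 annotators; per-annotator total decision counts are log-normal
  (median ≈ 135, a rare individual above 10,000 — `meanlog = log 135`,
  `sdlog = 1.6`).
* Latent skill and log participation are drawn from a bivariate normal with
  correlation 0.67 (the reported skill–effort correlation; the copula is a
  package choice, as only the marginal correlation is reported).
* Skill maps to per-class diagonal accuracy through a logistic link floored
  at chance: $acc_{j,T} = 1/7 + (6/7)\,\mathrm{logit}^{-1}(z_j + \delta_T)$.
  The class offsets $\delta_T$ make VASC easy and AKIEC hard, matching the
  reported pooled confusion structure. The skill mean (−1.028) and SD (1.381)
  were calibrated numerically, before any test was run, so the individual
  mean training accuracy is ≈ 0.42 with IQR ≈ 0.28–0.57.
* Off-diagonal row mass is distributed proportionally to a class-similarity
  kernel encoding the reported *relative* affinities (e.g. true NV is drawn
  to MEL ≈ 3.5× as strongly as to AKIEC); each annotator's rows then get
  Dirichlet noise (concentration 60) to create idiosyncratic response styles.
* The train image pool is skewed like the published composition
  (NV ≈ 67% of train images) while the *presentation* of train images is
  counterbalanced across classes — this distinction is what makes the
  estimated priors skewed even though every class is practiced equally.
  Test truth follows the published test prevalence (NV 60.1%).
* 75% of each annotator's decisions are on train images; every test image is
  staffed by 21–25 distinct annotators sampled with probability proportional
  to participation, so heavy contributors dominate the test crowd exactly as
  heavy-tailed participation implies.
* Response times are log-normal with median 8.5 s and `sdlog = 0.355`,
  chosen so ≈ 0.8% of decisions exceed the 20 s cutoff (the reported discard
  rate), plus a 0.2% invalid (missing) rate, so the cleaning stage is
  genuinely exercised. Days are a participation partition only — no learning
  dynamics.

What the generator does **not** emulate: correlated errors across annotators
(responses are conditionally independent given the true label — this is what
licenses the brute-force Bayes oracle tests and the crowd-size monotonicity
property), incentive-driven behavior, accuracy drift over days, and
within-annotator dependence between response time and correctness. The
consequence is visible and worth stating plainly: a conditionally independent
crowd of 21–25 decisions aggregates far better (accuracy ≈ 0.98 at desk
scale) than the real crowd (≈ 0.78), because real annotators share biases. A
green qualitative test therefore establishes the *direction* of each effect
(selection, weighting, priors), never the published magnitudes.

## What the acceptance tests establish

Exact analytic examples (constant-classifier metrics, cost arithmetic,
composition percentages) are asserted at printed precision. Everything else
is property-based at fixed seeds: LAW scores equal a brute-force enumeration
of $P(T \mid d_1, \dots, d_n)$ to 1e−9; homogeneous-accuracy LAW-E/SAW reduce
to simple voting on images without plurality ties (exact ties are broken by
floating-point summation order, so tied images are excluded rather than
pretending the algebra decides them); profile estimates recover generative
parameters within binomial error; bootstrap CIs cover a known +5-point
accuracy difference ≈ 95% of the time; and the four qualitative crowd
patterns replicate: crowd size helps with diminishing returns, top-1
selection hurts balanced accuracy, a confusion-matched LAW-CI does not lose
to voting, and priors trade balanced accuracy for accuracy.

The prior pattern is tested at selection size $r = 2$: with a full
conditionally independent crowd the summed likelihood term dwarfs a
single $\log \pi_T$ and the prior flips nothing, while at $r = 1$ the prior
can only *override* the single best annotator — including on reliably-made
rare-class calls it cannot see are reliable — which lowers accuracy. At
$r = 2$ the prior arbitrates between two conflicting decisions, which is the
regime the published discussion points to ("the priors play a bigger role"
when few decisions are selected).

## Worked example

```{r example, eval = FALSE}
library(crowdlaw)

sim <- simulate_crowd(simulation_config(n_annotators = 150,
                                        n_train_images = 1500,
                                        n_test_images = 800, seed = 1))
tab <- clean_decisions(sim$table)$table
profiles <- build_profiles(tab, min_individual_n = 100, tau = 0.02)

grid <- default_grid(r_values = list(1, 2, 7, "ALL"))
sw <- run_switchboard(tab, grid, profiles)
subset(sw$metrics, metric == "accuracy" & scheme == "LAW_CI")
```

## Known limitations

* No inter-annotator correlation model and no joint truth/confusion
  inference (Dawid–Skene style): truth for profiling comes from the training
  split only.
* No parameterized (e.g. sigmoid) weight functions; the switchboard is a
  factorial comparison, not an optimizer.
* The clamp is assumed sufficient to handle response classes unobserved
  under every hypothesis; no additional smoothing is applied.
* The cost helper reports single-reader time as images × seconds per
  decision; at the published 8.5 s per decision, 1,511 images come to ≈ 3.6
  h, so the widely quoted multi-week figure must refer to a much larger
  labeling effort than the test set alone.
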