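---
title: "A comorbidity burden index from survey diseases and disability weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A comorbidity burden index from survey diseases and disability weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbindex)
```

## The problem

Behavioural-risk-factor surveillance surveys interview adults (18–69) monthly
and record, among much else, whether a doctor has ever diagnosed any of ten
non-communicable diseases, self-rated health on an ordinal 1–5 scale
(1 = excellent, 5 = very bad), and sociodemographics: sex, age, a binary
education level (below high school vs at least high school), and a binary
economic-difficulty indicator. A respondent declaring several chronic
diseases carries more health burden than one declaring a single mild
condition, but a raw disease count cannot say *how much* more: diseases
differ enormously in the disability they impose.

The Global Burden of Disease (GBD) project publishes *disability weights*:
values in [0, 1] attached to several hundred precisely described health
states, where 0 is full health and 1 is equivalent to death. `comorbindex`
bridges the two data sources — coarse questionnaire disease categories on one
side, fine-grained weighted health states on the other — to produce a
per-respondent comorbidity burden index that can then be analysed across
socioeconomic subgroups.

## The procedure

### Step 1: keyword matching

Each of the ten questionnaire categories carries an ordered keyword list
(`default_keyword_registry()`, editable via a YAML/JSON file, a copy of which
ships in `inst/extdata/keywords.yaml`). A health state is assigned to a
category when its *normalized* name — lowercased, punctuation collapsed to
single spaces — contains at least one normalized keyword as a substring.
Substring (rather than whole-word) matching is a deliberate choice: stem-like
keywords such as `diabet` then cover "diabetes", "diabetic", plural forms and
compounds without a stemming dependency. The result per category is a
*weight bundle*: the set of distinct matched weights, plus every matched
state name for audit.

Two conventions are worth spelling out:

- **Deduplication by value.** Different health states sometimes share a
  weight; the bundle keeps each distinct weight once (the audit trail keeps
  all state names). The perceived-health mean at level 4 therefore averages
  distinct values, not states.
- **Keyword provenance.** The diabetes list follows the published keyword
  set for that category ("diabet", "diabetes", "diabetic", "diabeetus",
  "diabetes mellitus", "hypertension", "obesity", "insulin"). The other nine
  lists are package defaults derived from the questionnaire wording plus
  common clinical synonyms; any concrete study should review them with domain
  experts and supply its own registry file. Rare health states are retained
  by default; `build_bundles(exclude_states = ...)` supports manual omission.

Matching is deterministic and invariant to table row order, keyword order and
letter case, and enlarging a keyword list can only grow a bundle — all
property-tested. A category matching *nothing* is an error at bundle-build
time, because a silent empty bundle would quietly zero out a disease
downstream.

### Step 2: perceived-health selection

The bundle still holds one weight per matched severity level, while the
questionnaire only tells us the disease is present. Self-rated health breaks
the tie: respondents rating their health 1–3 receive the **minimum** bundle
weight for each declared disease, a rating of 4 the **mean** of the distinct
weights, a rating of 5 the **maximum**. The selection is applied per disease
independently — a respondent in very bad health with two diseases has *both*
counted at their worst — and is weakly increasing in the rating, so reported
ill-health can only raise the index.

Records with a missing rating are excluded with a warning by default;
`build_index(impute_ph = 3)` optionally fills in the middle category instead.

### Step 3: combination

Writing $W_{ij}$ for the selected weight of disease $i$ in respondent $j$
(zero if undeclared), the three combined indices are

$$D^{sum}_j = \sum_{i=1}^{10} W_{ij}, \qquad
  D^{max}_j = \max_i W_{ij}, \qquad
  D^{mult}_j = 1 - \prod_{i=1}^{10}(1 - W_{ij}).$$

The additive form assumes burdens accumulate linearly (it can exceed 1; its
maximum is 10); the maximum form counts only the most burdensome disease; the
multiplicative form assumes each extra disease removes a constant *proportion*
of the remaining health, so it stays in [0, 1]. The empty product is defined
as 1, making all three indices zero for disease-free respondents, and
$D^{max}_j \le D^{mult}_j \le D^{sum}_j$ always, with equality when at most
one disease is declared. Internals run at full floating precision; pipeline
CSV output rounds to 4 decimals.

## The synthetic-data generator

Real surveillance microdata are restricted, so `generate_population()`
produces samples with the statistical structure the analysis assumes. The
defaults are calibrated once to the 2019 survey wave and define the package's
reference conditions:

| parameter | default | note |
|---|---|---|
| `n` | 31,746 | 2019 interview count |
| `p_female` | 0.514 | published marginal |
| `p_econ_problems` | 0.56 | published marginal |
| `p_high_edu` | 0.678 | published marginal |
| `age_range` | [18, 69], uniform | survey's target population |
| `edu_econ_log_or` | 1.2 | low education ↔ economic problems |
| `seed` | single integer | all streams derive from it |

Two documented judgement calls:

- The survey description states both a mean age of 45 and a uniform age
  distribution on 18–69 (whose mean is 43.5). The generator prioritises
  uniformity; 45 is not a calibration target.
- Education and economic status are associated by default (log-odds ratio
  1.2, with the conditional baselines solved numerically so the configured
  *marginals* are preserved exactly in expectation). This reproduces the
  importance-confounding phenomenon the subgroup analysis is known to show
  on real data; `edu_econ_log_or = 0` restores independence.

Disease indicators follow a per-disease logistic model in age (slope per
decade), low education, and economic problems; perceived health follows a
proportional-odds model whose linear predictor combines the *count* of
declared diseases and their summed nominal severity. **These parametric forms
and their default parameters are illustrative**: no public source prints
subgroup prevalences for these categories, so the defaults were chosen once
to give realistic overall prevalences (roughly 1–15 % per disease),
age-increasing chronic-disease risk, and a modest social gradient. They live
in `generator_config()`, never hard-coded. Consequently, passing tests show
the *machinery* behaves correctly under plausible structure — monotone
age–prevalence, marginal calibration, index ordering — not that any real
population has these parameter values. The generator also makes no attempt to
emulate the survey's complex sampling design, weighting, or nonresponse.

`fixture_weight_table()` complements it with a deterministic table of ~40
synthetic health states (names explicitly prefixed "synthetic") embedding the
default keywords, at least three states with distinct weights per category
plus decoys, so matching, selection and combination are exercisable offline.

## The subgroup analysis

The index is a semi-continuous, zero-inflated, multimodal response, so the
analysis layer uses a nonparametric learner: a random-forest regression on
age (numeric), sex, education, and economic status ({0,1}-coded). Because no
standard hyperparameters exist for this problem, the package fixes defaults
in `fit_predictor()` — 500 trees, the usual regression split-candidate count
`max(floor(p/3), 1) = 1`, node size 5 — and exposes all of them.

- **Importance** is classic out-of-bag permutation importance: the mean
  over trees of the increase in OOB mean-squared error when one covariate is
  permuted, min–max scaled to [0, 100]. Scaling preserves ranks and is
  invariant to affine rescaling; if all raw importances tie (degenerate fit),
  all scaled values are set to 0 with a warning. The conditional variant of
  permutation importance is *not* implemented — the standard procedure is.
- **Curves**: predictions at every integer age 18–69 for the 8
  sex × education × economic subgroups (52 points per curve). The 95 %
  prediction band uses the empirical 0.025/0.975 quantiles of the per-tree
  predictions at each grid point — a pragmatic choice; per-tree quantiles
  understate true predictive uncertainty and should be read as ensemble
  spread, not calibrated coverage.
- **Method comparison**: mean absolute difference (and sd of absolute
  differences) between two methods' subgroup prediction vectors, a scalar
  summary of how much the combination choice matters.

## Numerical and interface choices

- Bundle dispersion uses the sample (n−1) standard deviation by default with
  a `sd_type = "population"` switch, since either convention is defensible.
- Interval weight cells `"m (l–u)"` accept hyphen, en- or em-dash; bounds
  must bracket the point weight and stay in [0, 1], enforced row by row.
- Weight tables are CSV or TSV by extension; registries YAML or JSON.
- The pipeline (`run_pipeline()`) validates its configuration before any
  stage runs, derives every random stream from one seed, stamps each CSV with
  a `#` header (package version, seed, configuration hash), rounds numeric
  output to 4 decimals, and writes an md5 manifest — reruns with identical
  configuration are byte-identical. The package is driven from R; the
  pipeline functions plus `scripts/acceptance.R` are the command-line
  surface.

## Problem sizes in the test suite

The suite exercises combination functions on 1,000 random weight vectors
against naive loop oracles (tolerance 1e−12), the selection rule on
enumerated bundles of size ≤ 5 against brute force, generator calibration at
the full n = 31,746, marginal-recovery properties at n = 10,000–20,000 over
fixed seeds, and forest behaviour at n = 6,000 with 150 trees — sizes chosen
so the entire suite runs in about a minute while keeping Monte-Carlo bands
(3 standard errors) meaningful.

## Limitations

- Keyword substring matching is deliberately simple: no edit distance, no
  ontology (ICD/SNOMED) mapping. Over- and under-matching are controlled only
  by the quality of the keyword lists, which for nine of the ten categories
  are package defaults awaiting expert review.
- The perceived-health rule attributes the respondent's global rating to
  every declared disease; mental-health or transient factors in that rating
  propagate into the index.
- All ten diseases are treated as chronic, so duration weighting (and any
  years-lived-with-disability computation) is out of scope.
- Synthetic defaults are illustrative; quantitative results on synthetic
  data characterise the method, not any real population.
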