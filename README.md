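# comorbindex

A comorbidity **burden** index for behavioural-risk-factor surveillance
microdata, built from the Global Burden of Disease (GBD) disability weights.

Surveillance systems such as the Italian PASSI (or the US BRFSS) record, for
each adult respondent, ten self-reported non-communicable diseases, self-rated
("perceived") health on a 1–5 scale, and sociodemographics — but no measure of
how *burdensome* the declared diseases are. `comorbindex` closes that gap in
three steps:

1. **Keyword matching.** Each questionnaire disease category (diabetes, kidney
   failure, bronchitis/emphysema, myocardial infarction, tumor, chronic liver
   disease, stroke, heart diseases, bronchial asthma, arthrosis/arthritis) is
   resolved to a *bundle* of candidate GBD disability weights: every health
   state whose normalized name contains one of the category's keywords as a
   substring (stem-like keywords such as `diabet` cover singular/plural and
   derived forms).
2. **Perceived-health selection.** A respondent rating their health 1–3 gets
   the minimum weight of each declared disease's bundle, a rating of 4 the
   mean of the distinct weights, a rating of 5 the maximum.
3. **Combination.** The selected weights W_ij (0 for undeclared diseases) are
   combined per respondent j into three indices:

   - additive: D_sum = Σᵢ W_ij
   - maximum: D_max = maxᵢ W_ij
   - multiplicative: D_mult = 1 − Πᵢ (1 − W_ij)

   which always satisfy D_max ≤ D_mult ≤ D_sum, with equality when at most
   one disease is declared.

Because real surveillance microdata are restricted, the package ships a
calibrated synthetic generator (`generate_population()`) emulating the 2019
survey wave (n = 31,746; 51.4 % women; 56 % with economic problems; 67.8 %
with high education; age uniform on 18–69) with a logistic age/SES disease
prevalence model and an ordinal perceived-health model, plus a synthetic
fixture weight table so the whole pipeline runs without downloads. The
analysis layer fits a random-forest regression of the index on age, sex,
education, and economic status, reports out-of-bag permutation importance
min–max scaled to [0, 100], predicts age-profile curves for the 8
sex × education × economic subgroups with per-tree 95 % prediction intervals,
and compares the three combination methods by mean absolute difference (MAD)
of their subgroup predictions.

## Worked example

```r
library(comorbindex)

bundles <- build_bundles(fixture_weight_table(seed = 1))
bundles$diabetes
#> <weight_bundle> diabetes: 3 distinct weights (mean 0.113, sd 0.036), 3 matched states

pop <- generate_population(generator_config(n = 5000, seed = 42))
idx <- build_index(pop$records, bundles)
round(colMeans(idx[c("d_sum", "d_max", "d_mult")]), 4)
#>  d_sum  d_max d_mult
#> 0.0686 0.0578 0.0644

an <- run_analysis(idx, ntree = 200, seed = 42)
an$importance$multiplicative
#>    variable      raw scaled
#> 1       age 2.01e-03 100.00
#> 2 education 1.14e-04   4.68
#> 3  economic 6.93e-05   2.43
#> 4       sex 2.10e-05   0.00
an$comparison
#>                         pair     mad   sd_ad
#> 1        additive vs maximum 0.01142 0.00867
#> 2 additive vs multiplicative 0.00454 0.00355
#> 3  maximum vs multiplicative 0.00709 0.00665
```

The mean index is highest under the additive combination and lowest under the
maximum, as the ordering guarantees. Age dominates the permutation importance
(scaled 100), while one of the correlated education/economic pair collapses
toward 0 — the confounding the generator deliberately reproduces. The three
combination methods' subgroup predictions differ by a MAD an order of
magnitude below the index scale, so conclusions are robust to the choice of
combination. At age 69 the predicted index is highest for the low-education /
economic-problems subgroup (0.145 for women) and lowest for the
high-education / no-problems subgroup (0.090), the socioeconomic gradient the
index is designed to expose:

```r
cv <- subset(an$curves, method == "multiplicative" & age == 69)
cv[order(-cv$pred), c("subgroup", "pred", "lower", "upper")]
#>             subgroup   pred  lower upper
#>  female.low.problems 0.1447 0.0609 0.333
#>    male.low.problems 0.1416 0.0681 0.334
#>  ...
#>     female.high.none 0.0903 0.0486 0.202
#>       male.high.none 0.0902 0.0487 0.167
```

An end-to-end run writing checksummed CSV artifacts
(`microdata.csv`, `bundles.csv`, `indexed.csv`, `importance.csv`,
`curves.csv`, `comparison.csv`, `manifest.csv`):

```r
run_pipeline(pipeline_config(out_dir = "out", seed = 1))
```

Reruns with the same configuration and seed are byte-identical.

## Package layout

- `R/vocabulary.R` — weight-table parsing (plain and interval dialects),
  text normalization, keyword matching, bundle statistics and audit.
- `R/index.R` — perceived-health weight selection and the three combination
  functions, per-record and vectorised.
- `R/simulate.R` — generator configuration/validation, synthetic microdata,
  synthetic fixture weight table.
- `R/analysis.R` — regression forest, scaled permutation importance,
  subgroup curves, method comparison.
- `R/pipeline.R` — configuration validation and the deterministic
  end-to-end driver.
- `vignettes/comorbidity-burden-index.Rmd` — the methods vignette: model,
  assumptions, parameter choices, and limitations.
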