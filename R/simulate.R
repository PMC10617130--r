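#' Default disease-prevalence model
#'
#' Logistic model per disease: `logit P(dx_i = 1) = intercept +
#' beta_age_decade * (age - 18)/10 + beta_low_edu * I(education = low) +
#' beta_econ * I(economic = problems)`. Intercepts are at the reference
#' (age 18, high education, no economic problems). The parameter values are
#' illustrative: no surveillance publication prints subgroup prevalences for
#' these categories, so they were chosen once to give adult-population overall
#' prevalences of roughly 1--15% with age-increasing chronic-disease risk and
#' a modest social gradient.
#'
#' @return data.frame with one row per disease category.
#' @export
default_prevalence_model <- function() {
  data.frame(
    disease = disease_categories()$id,
    intercept = c(-5.0, -6.0, -5.2, -6.5, -5.5, -5.8, -6.5, -5.5, -2.8, -3.6),
    beta_age_decade = c(0.55, 0.35, 0.50, 0.75, 0.60, 0.30, 0.60, 0.55, 0.05, 0.55),
    beta_low_edu = c(0.35, 0.25, 0.40, 0.30, 0.00, 0.30, 0.30, 0.25, 0.10, 0.40),
    beta_econ = c(0.25, 0.25, 0.30, 0.25, 0.10, 0.30, 0.25, 0.20, 0.15, 0.30),
    stringsAsFactors = FALSE
  )
}

#' Default perceived-health model
#'
#' Proportional-odds model for the ordinal self-rated health response
#' (1 = excellent ... 5 = very bad): `P(ph <= k) = plogis(cut_k - eta)` with
#' `eta = beta_count * (number of declared diseases) + beta_severity *
#' (summed nominal severity of declared diseases)`. The per-disease nominal
#' severities are order-of-magnitude typical disability weights; they tie
#' worse self-rated health to both how many and how burdensome the declared
#' diseases are, which is all the downstream index computation assumes.
#'
#' @return list with `cutpoints` (length 4, increasing), `beta_count`,
#'   `beta_severity`, `severity` (named per-disease vector).
#' @export
default_ph_model <- function() {
  sev <- c(diabetes = 0.06, kidney_failure = 0.10, bronchitis = 0.20,
           myocardial_infarction = 0.08, tumor = 0.30, liver_disease = 0.15,
           stroke = 0.30, heart_disease = 0.10, asthma = 0.05,
           arthritis = 0.12)
  list(cutpoints = c(-1.2, 1.4, 3.0, 4.6),
       beta_count = 0.8, beta_severity = 3.0, severity = sev)
}

#' Generator configuration
#'
#' Defaults are calibrated to the 2019 survey wave: n = 31,746 interviews,
#' 51.4% women, 56% with economic problems, 67.8% with high formal education,
#' age uniform on 18--69. Education and economic status are associated by
#' default (log-odds ratio `edu_econ_log_or` between low education and
#' economic problems, solved so the configured marginals are preserved);
#' set it to 0 for independent sociodemographics.
#'
#' @param n sample size.
#' @param p_female probability of sex = female.
#' @param p_econ_problems marginal probability of economic problems.
#' @param p_high_edu probability of high education.
#' @param age_range integer interval within \[18, 69\]; ages drawn uniformly.
#' @param edu_econ_log_or log-odds ratio linking low education to economic
#'   problems (0 = independence).
#' @param prevalence_model per-disease logistic parameters, see
#'   [default_prevalence_model()].
#' @param ph_model ordinal perceived-health parameters, see
#'   [default_ph_model()].
#' @param seed integer seed; all random streams derive from it.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n = 31746L, p_female = 0.514,
                             p_econ_problems = 0.56, p_high_edu = 0.678,
                             age_range = c(18L, 69L), edu_econ_log_or = 1.2,
                             prevalence_model = default_prevalence_model(),
                             ph_model = default_ph_model(), seed = 1L) {
  cfg <- structure(list(n = as.integer(n), p_female = p_female,
                        p_econ_problems = p_econ_problems,
                        p_high_edu = p_high_edu,
                        age_range = as.integer(age_range),
                        edu_econ_log_or = edu_econ_log_or,
                        prevalence_model = prevalence_model,
                        ph_model = ph_model, seed = as.integer(seed)),
                   class = "generator_config")
  msg <- validate_generator_config(cfg)
  if (length(msg)) stop_input("invalid generator config: %s",
                              paste(msg, collapse = "; "))
  cfg
}

#' Validate a generator configuration
#'
#' @param cfg `generator_config` (or plain list with the same fields).
#' @return character vector of findings; empty when valid.
#' @export
validate_generator_config <- function(cfg) {
  f <- character(0)
  if (!is.numeric(cfg$n) || length(cfg$n) != 1L || is.na(cfg$n) || cfg$n < 1)
    f <- c(f, "n must be a positive integer")
  for (p in c("p_female", "p_econ_problems", "p_high_edu"))
    if (!is_prob(cfg[[p]])) f <- c(f, sprintf("%s must be a probability in [0,1]", p))
  ar <- cfg$age_range
  if (length(ar) != 2L || anyNA(ar) || ar[1] > ar[2] || ar[1] < 18 || ar[2] > 69)
    f <- c(f, "age_range must be a non-empty integer interval within [18, 69]")
  pm <- cfg$prevalence_model
  need <- c("disease", "intercept", "beta_age_decade", "beta_low_edu", "beta_econ")
  if (!is.data.frame(pm) || !all(need %in% names(pm)) ||
      !setequal(pm$disease, disease_categories()$id))
    f <- c(f, "prevalence_model must cover the 10 diseases with logistic parameters")
  ph <- cfg$ph_model
  if (!is.list(ph) || length(ph$cutpoints) != 4L || is.unsorted(ph$cutpoints))
    f <- c(f, "ph_model must have 4 increasing cutpoints")
  f
}

# Solve the conditional baselines of P(econ problems | education) so the
# marginal equals p_econ while logit differs by log_or between low and high
# education.
econ_conditionals <- function(p_econ, p_high_edu, log_or) {
  if (log_or == 0 || p_high_edu %in% c(0, 1))
    return(c(high = p_econ, low = p_econ))
  g <- function(a) p_high_edu * stats::plogis(a) +
    (1 - p_high_edu) * stats::plogis(a + log_or) - p_econ
  a <- stats::uniroot(g, c(-40, 40), tol = 1e-12)$root
  c(high = stats::plogis(a), low = stats::plogis(a + log_or))
}

#' Generate synthetic survey microdata
#'
#' Draws a sample in the package's microdata schema: sex and education are
#' independent Bernoulli draws at the configured marginals; economic problems
#' are drawn conditionally on education (association controlled by
#' `edu_econ_log_or`, marginal preserved); age is uniform on the configured
#' range; the ten disease indicators follow the logistic prevalence model
#' given age, education and economic status; perceived health follows the
#' ordinal model given the declared diseases. Fully reproducible for a fixed
#' seed.
#'
#' @param config `generator_config`.
#' @param seed optional override of `config$seed`.
#' @return list with `records` (data.frame, one row per respondent) and
#'   `truth` (per-subject latent quantities: the 10 true disease
#'   probabilities, the perceived-health linear predictor, and the summed
#'   nominal severity of declared diseases).
#' @export
generate_population <- function(config = generator_config(), seed = NULL) {
  msg <- validate_generator_config(config)
  if (length(msg)) stop_input("invalid generator config: %s",
                              paste(msg, collapse = "; "))
  seed <- as.integer(seed %||% config$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  n <- config$n
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  education <- ifelse(stats::runif(n) < config$p_high_edu, "high", "low")
  pe <- econ_conditionals(config$p_econ_problems, config$p_high_edu,
                          config$edu_econ_log_or)
  economic <- ifelse(stats::runif(n) < pe[education], "problems", "none")
  ages <- seq(config$age_range[1], config$age_range[2])
  age <- ages[sample.int(length(ages), n, replace = TRUE)]

  pm <- config$prevalence_model
  pm <- pm[match(disease_categories()$id, pm$disease), ]
  low <- as.numeric(education == "low")
  econ <- as.numeric(economic == "problems")
  dec <- (age - 18) / 10
  prob <- sapply(seq_len(nrow(pm)), function(i) {
    stats::plogis(pm$intercept[i] + pm$beta_age_decade[i] * dec +
                    pm$beta_low_edu[i] * low + pm$beta_econ[i] * econ)
  })
  colnames(prob) <- pm$disease
  dx <- matrix(as.integer(stats::runif(n * ncol(prob)) < prob), nrow = n,
               dimnames = dimnames(prob))

  phm <- config$ph_model
  sev <- phm$severity[colnames(dx)]
  burden <- as.numeric(dx %*% sev)
  count <- rowSums(dx)
  eta <- phm$beta_count * count + phm$beta_severity * burden
  cum <- stats::plogis(outer(-eta, phm$cutpoints, `+`))   # n x 4, P(ph <= k)
  u <- stats::runif(n)
  perceived_health <- 1L + rowSums(u > cum)

  records <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                        sex = sex, age = age, education = education,
                        economic = economic,
                        perceived_health = perceived_health,
                        stringsAsFactors = FALSE)
  dxdf <- as.data.frame(dx)
  names(dxdf) <- paste0("dx_", colnames(dx))
  records <- cbind(records, dxdf)
  truth <- list(disease_prob = prob, ph_eta = eta, severity_burden = burden,
                seed = seed)
  list(records = records, truth = truth)
}

#' Synthetic fixture disability-weight table
#'
#' Builds a deterministic table of synthetic health states whose names embed
#' the default keywords, with at least three states (distinct weights) per
#' disease category plus a few decoy states that match nothing. It lets the
#' whole matching / selection / combination pipeline run without the real GBD
#' download; all states are explicitly labelled synthetic.
#'
#' @param seed integer; the same seed always yields the identical table.
#' @return `dw_table` of ~40 records with weights in (0, 1).
#' @export
fixture_weight_table <- function(seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  stems <- list(
    diabetes = c("diabetes mellitus", "diabetic neuropathy", "diabetic foot"),
    kidney_failure = c("chronic kidney disease", "end stage renal disease",
                       "kidney dysfunction"),
    bronchitis = c("chronic bronchitis", "emphysema", "copd exacerbation"),
    myocardial_infarction = c("acute myocardial infarction", "angina pectoris",
                              "coronary syndrome"),
    tumor = c("colon cancer", "metastatic carcinoma", "lymphoma remission"),
    liver_disease = c("decompensated cirrhosis", "chronic hepatitis",
                      "liver fibrosis"),
    stroke = c("stroke long term sequelae", "cerebrovascular accident",
               "post stroke hemiplegia"),
    heart_disease = c("congestive heart failure", "valvular heart disease",
                      "cardiomyopathy"),
    asthma = c("controlled asthma", "partially controlled asthma",
               "severe asthmatic episode"),
    arthritis = c("mild osteoarthritis", "rheumatoid arthritis", "gout flare")
  )
  # disease-specific weight ranges echoing the field's typical magnitudes
  lo <- c(0.02, 0.05, 0.03, 0.03, 0.05, 0.04, 0.05, 0.04, 0.01, 0.02)
  hi <- c(0.25, 0.45, 0.50, 0.45, 0.65, 0.50, 0.60, 0.45, 0.15, 0.40)
  sev_lab <- c("mild", "moderate", "severe")
  rows <- do.call(rbind, lapply(seq_along(stems), function(i) {
    k <- length(stems[[i]])
    w <- round(sort(stats::runif(k, lo[i], hi[i])), 3)
    # guarantee distinct weights after rounding
    while (anyDuplicated(w)) w <- round(w + seq_len(k) * 1e-3, 3)
    data.frame(state_name = paste("synthetic", sev_lab[seq_len(k)], stems[[i]]),
               weight = pmin(pmax(w, 0.001), 0.999), stringsAsFactors = FALSE)
  }))
  decoys <- data.frame(
    state_name = paste("synthetic decoy",
                       c("low back pain episode", "migraine attack",
                         "anxiety disorder", "iron deficiency", "hearing loss",
                         "dental caries", "sprained ankle", "common cold",
                         "insomnia", "seasonal allergy")),
    weight = round(stats::runif(10, 0.005, 0.3), 3), stringsAsFactors = FALSE)
  dw_table(rbind(rows, decoys),
           source_tag = sprintf("synthetic fixture (seed %d)", seed))
}
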