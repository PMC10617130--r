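# Encode the four sociodemographic covariates for the forest:
# age numeric, the three binary variables as {0,1}.
encode_covariates <- function(data) {
  need <- c("age", "sex", "education", "economic")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_input("covariate column(s) missing from data: %s",
               paste(miss, collapse = ", "))
  data.frame(age = as.numeric(data$age),
             sex = as.numeric(data$sex == "female"),
             education = as.numeric(data$education == "high"),
             economic = as.numeric(data$economic == "problems"))
}

#' Fit the regression forest for the comorbidity index
#'
#' Fits a random-forest regression of a comorbidity index on the four
#' sociodemographic covariates (age, sex, education, economic status). The
#' forest averages per-tree predictions and tracks out-of-bag (OOB) error, on
#' which permutation importance is based. Defaults: 500 trees, the standard
#' regression split-candidate count `max(floor(p/3), 1) = 1`, unlimited
#' depth. Reproducible for a fixed seed.
#'
#' @param data microdata data.frame with columns `age`, `sex`, `education`,
#'   `economic` (package codings).
#' @param index_values numeric response vector (one of the three indices).
#' @param ntree number of trees.
#' @param mtry split candidates per node (default `max(floor(p/3), 1)`).
#' @param nodesize minimum terminal-node size (randomForest regression
#'   default, 5).
#' @param seed integer seed for the forest's bootstrap/choice randomness.
#' @return object of class `comorbid_forest` wrapping the fitted ensemble and
#'   its hyperparameters.
#' @export
fit_predictor <- function(data, index_values, ntree = 500L, mtry = NULL,
                          nodesize = 5L, seed = 1L) {
  x <- encode_covariates(data)
  y <- as.numeric(index_values)
  if (nrow(x) == 0L) stop_input("no data to fit on")
  if (length(y) != nrow(x))
    stop_input("index_values length (%d) does not match data rows (%d)",
               length(y), nrow(x))
  if (nrow(unique(x)) < 2L) stop_input("need at least 2 distinct covariate rows")
  mtry <- mtry %||% max(floor(ncol(x) / 3), 1L)
  if (stats::var(y) == 0)
    warning("constant response: the forest will predict a constant", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  model <- randomForest::randomForest(x = x, y = y, ntree = as.integer(ntree),
                                      mtry = mtry, nodesize = nodesize,
                                      importance = TRUE, keep.forest = TRUE)
  structure(list(model = model,
                 hyperparams = list(ntree = as.integer(ntree), mtry = mtry,
                                    nodesize = nodesize, seed = as.integer(seed)),
                 covariates = names(x)),
            class = "comorbid_forest")
}

#' @export
print.comorbid_forest <- function(x, ...) {
  h <- x$hyperparams
  cat(sprintf("<comorbid_forest> %d trees, mtry=%d, nodesize=%d, seed=%d; OOB MSE %.6f\n",
              h$ntree, h$mtry, h$nodesize, h$seed,
              utils::tail(x$model$mse, 1)))
  invisible(x)
}

#' Out-of-bag permutation importance, min--max scaled
#'
#' Raw importance of a covariate is the average over trees of the increase in
#' out-of-bag mean squared error when that covariate's values are permuted.
#' Raw importances are then scaled to `100 * (raw - min) / (max - min)`, so
#' the most important covariate scores 100 and the least important 0 (when
#' raw values are not all equal; an all-equal degenerate fit scores 0
#' everywhere with a warning). Scaling preserves the raw ordering and is
#' invariant to affine rescaling of the raw values.
#'
#' @param fit `comorbid_forest` from [fit_predictor()].
#' @return data.frame of class `importance_table` with columns `variable`,
#'   `raw`, `scaled`, ordered by decreasing scaled importance.
#' @export
permutation_importance <- function(fit) {
  stopifnot(inherits(fit, "comorbid_forest"))
  imp <- fit$model$importance
  if (is.null(imp) || !"%IncMSE" %in% colnames(imp))
    stop_input("model was fitted without out-of-bag importance tracking")
  raw <- imp[, "%IncMSE"]  # mean OOB MSE increase under permutation (unscaled)
  scaled <- scale_importance(raw)
  out <- data.frame(variable = names(raw), raw = as.numeric(raw),
                    scaled = scaled, stringsAsFactors = FALSE)
  out <- out[order(-out$scaled, out$variable), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Min--max scale raw importances to \[0, 100\]
#'
#' @param raw numeric vector of raw importances.
#' @return numeric vector: `100 * (raw - min) / (max - min)`; all zero (with a
#'   warning) when the raw values are all equal.
#' @export
scale_importance <- function(raw) {
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("all raw importances equal: scaled importances degenerate to 0",
            call. = FALSE)
    return(rep(0, length(raw)))
  }
  100 * (raw - rng[1]) / diff(rng)
}

subgroup_grid <- function(ages = 18:69) {
  g <- expand.grid(age = ages, sex = c("female", "male"),
                   education = c("high", "low"),
                   economic = c("none", "problems"),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g$subgroup <- paste(g$sex, g$education, g$economic, sep = ".")
  g
}

#' Subgroup age-profile prediction curves
#'
#' Predicts the comorbidity index at every integer age 18--69 for each of the
#' 8 subgroups (sex x education x economic status). The point prediction is
#' the forest average; the prediction interval at `level` comes from the
#' empirical quantiles of the per-tree predictions at each grid point.
#'
#' @param fit `comorbid_forest`.
#' @param level interval level (default 0.95).
#' @return data.frame with columns `subgroup`, `sex`, `education`,
#'   `economic`, `age`, `pred`, `lower`, `upper` (8 x 52 rows).
#' @export
predict_curves <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "comorbid_forest"), is_prob(level))
  grid <- subgroup_grid()
  pr <- stats::predict(fit$model, encode_covariates(grid), predict.all = TRUE)
  a <- (1 - level) / 2
  qs <- t(apply(pr$individual, 1, stats::quantile, probs = c(a, 1 - a),
                names = FALSE))
  out <- grid[c("subgroup", "sex", "education", "economic", "age")]
  out$pred <- as.numeric(pr$aggregate)
  out$lower <- qs[, 1]
  out$upper <- qs[, 2]
  out
}

#' Compare predictions from two combination approaches
#'
#' Summarises how far apart the predictions of two index-combination methods
#' are: the mean absolute difference (MAD) of the two prediction vectors and
#' the sample standard deviation of the absolute differences. Symmetric in
#' its arguments.
#'
#' @param pred_a,pred_b equal-length numeric prediction vectors.
#' @param label optional pair label (e.g. "additive vs multiplicative").
#' @return data.frame with `pair`, `mad`, `sd_ad`.
#' @export
compare_methods <- function(pred_a, pred_b, label = "a vs b") {
  if (length(pred_a) != length(pred_b))
    stop_input("prediction vectors differ in length (%d vs %d)",
               length(pred_a), length(pred_b))
  d <- abs(as.numeric(pred_a) - as.numeric(pred_b))
  data.frame(pair = label, mad = mean(d),
             sd_ad = if (length(d) > 1) stats::sd(d) else 0,
             stringsAsFactors = FALSE)
}

#' Full subgroup analysis of the comorbidity index
#'
#' Convenience wrapper reproducing the analysis stage: fits one forest per
#' combination method on indexed microdata, extracts scaled permutation
#' importance (reported for the first method), predicts the 8 subgroup age
#' curves per method, and compares the methods' subgroup predictions
#' pairwise.
#'
#' @param indexed microdata with `d_sum`, `d_max`, `d_mult` columns (from
#'   [build_index()]).
#' @param methods subset of `c("additive", "maximum", "multiplicative")`.
#' @param ntree,mtry,nodesize forest hyperparameters, see [fit_predictor()].
#' @param seed integer seed.
#' @param level prediction-interval level.
#' @return list with `fits`, `importance` (named list of `importance_table`),
#'   `curves` (stacked data.frame with a `method` column), `comparison`
#'   (pairwise MAD table; NULL with a single method).
#' @export
run_analysis <- function(indexed,
                         methods = c("additive", "maximum", "multiplicative"),
                         ntree = 500L, mtry = NULL, nodesize = 5L, seed = 1L,
                         level = 0.95) {
  methods <- match.arg(methods, several.ok = TRUE)
  col <- c(additive = "d_sum", maximum = "d_max", multiplicative = "d_mult")[methods]
  miss <- setdiff(col, names(indexed))
  if (length(miss))
    stop_input("indexed data lacks column(s): %s (run build_index first)",
               paste(miss, collapse = ", "))
  fits <- lapply(col, function(cl)
    fit_predictor(indexed, indexed[[cl]], ntree = ntree, mtry = mtry,
                  nodesize = nodesize, seed = seed))
  names(fits) <- methods
  importance <- lapply(fits, permutation_importance)
  curves <- do.call(rbind, lapply(methods, function(m) {
    cv <- predict_curves(fits[[m]], level = level)
    cbind(method = m, cv, stringsAsFactors = FALSE)
  }))
  comparison <- NULL
  if (length(methods) > 1) {
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    comparison <- do.call(rbind, lapply(pairs, function(p) {
      a <- curves$pred[curves$method == p[1]]
      b <- curves$pred[curves$method == p[2]]
      compare_methods(a, b, label = paste(p[1], "vs", p[2]))
    }))
  }
  list(fits = fits, importance = importance, curves = curves,
       comparison = comparison)
}
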