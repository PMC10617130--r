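#' Select one disability weight from a bundle via perceived health
#'
#' The text-matching step leaves several candidate weights per disease (one
#' per matched severity level of the health state). Self-rated health is used
#' to pick one: respondents rating their health 1--3 (excellent to fair) get
#' the minimum candidate weight, a rating of 4 the arithmetic mean of the
#' distinct candidates, and 5 (very bad) the maximum. The selected weight is
#' therefore weakly increasing in perceived health.
#'
#' @param bundle `weight_bundle` (non-empty).
#' @param perceived_health integer in 1..5 (1 = excellent, 5 = very bad).
#' @return a single disability weight in \[0,1\].
#' @export
#' @examples
#' b <- structure(list(disease = "toy", weights = c(0.1, 0.2, 0.6),
#'                     matched_states = letters[1:3]), class = "weight_bundle")
#' select_weight(b, 2)  # 0.1
#' select_weight(b, 4)  # 0.3
#' select_weight(b, 5)  # 0.6
select_weight <- function(bundle, perceived_health) {
  stopifnot(inherits(bundle, "weight_bundle"))
  if (length(bundle$weights) == 0L)
    stop_input("empty bundle for disease '%s'", bundle$disease)
  ph <- perceived_health
  if (length(ph) != 1L || is.na(ph) || ph != as.integer(ph) || ph < 1 || ph > 5)
    stop_input("perceived_health must be a single integer in 1..5 (got %s)",
               format(ph))
  w <- bundle$weights
  if (ph <= 3) min(w) else if (ph == 4) mean(w) else max(w)
}

# 5 x 10 matrix of selected weights, one row per perceived-health level;
# vectorises index computation over a whole survey.
selection_matrix <- function(bundles) {
  ids <- names(bundles)
  m <- sapply(bundles, function(b) vapply(1:5, function(ph) select_weight(b, ph),
                                          numeric(1)))
  dimnames(m) <- list(ph = 1:5, disease = ids)
  m
}

# pull the 10 dx_<id> indicator columns (0/1) in bundle order
disease_matrix <- function(data, ids) {
  cols <- paste0("dx_", ids)
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop_input("microdata is missing disease indicator column(s): %s",
               paste(missing, collapse = ", "))
  m <- as.matrix(data[cols])
  if (!all(m %in% c(0, 1)))
    stop_input("disease indicators must be coded 0/1")
  m
}

#' Per-subject selected-weight vector
#'
#' For one survey record, returns the vector W of ten disability weights: the
#' weight selected by [select_weight()] for every declared disease, 0 for
#' diseases the respondent does not declare.
#'
#' @param record one-row data.frame (or list) with `perceived_health` and the
#'   ten `dx_<disease id>` indicators.
#' @param bundles named list of `weight_bundle` covering all ten diseases.
#' @return named numeric vector of length 10, entries in \[0,1\].
#' @export
subject_weights <- function(record, bundles) {
  ids <- names(bundles)
  miss <- setdiff(disease_categories()$id, ids)
  if (length(miss))
    stop_input("bundles must cover all 10 diseases; missing: %s",
               paste(miss, collapse = ", "))
  ind <- vapply(paste0("dx_", ids), function(cl) {
    v <- record[[cl]]
    if (is.null(v) || is.na(v)) stop_input("record lacks indicator '%s'", cl)
    as.numeric(v)
  }, numeric(1))
  if (!all(ind %in% c(0, 1))) stop_input("disease indicators must be coded 0/1")
  sel <- vapply(bundles, function(b) select_weight(b, record$perceived_health),
                numeric(1))
  w <- ind * sel
  names(w) <- ids
  w
}

check_w <- function(w) {
  if (!is.numeric(w) || anyNA(w) || any(w < 0) || any(w > 1))
    stop_input("selected weights must be numeric in [0,1]")
  w
}

#' Additive combination of selected disability weights
#'
#' `D_sum = sum_i W_i`. Unbounded above by 1 (maximum 10 with all ten diseases
#' at full weight); equal to the single weight when at most one disease is
#' declared.
#'
#' @param w numeric vector of selected weights in \[0,1\].
#' @return non-negative real.
#' @export
combine_additive <- function(w) sum(check_w(w))

#' Maximum combination of selected disability weights
#'
#' `D_max = max_i W_i` (0 for the all-zero vector): only the most burdensome
#' declared disease counts.
#'
#' @inheritParams combine_additive
#' @return real in \[0,1\].
#' @export
combine_maximum <- function(w) {
  w <- check_w(w)
  if (length(w) == 0L) 0 else max(w, 0)
}

#' Multiplicative combination of selected disability weights
#'
#' `D_mult = 1 - prod_i (1 - W_i)`: each additional disease removes a constant
#' proportion of the residual health `1 - D`. The empty product is 1, so the
#' index is 0 with no declared disease, and the three combinations coincide
#' when at most one weight is nonzero.
#'
#' @inheritParams combine_additive
#' @return real in \[0,1\].
#' @export
combine_multiplicative <- function(w) 1 - prod(1 - check_w(w))

#' Comorbidity index for one survey record
#'
#' Composes [subject_weights()] with the three combination functions.
#'
#' @inheritParams subject_weights
#' @return list with `d_sum`, `d_max`, `d_mult`. They satisfy
#'   `d_max <= d_mult <= d_sum` and are all zero when no disease is declared.
#' @export
compute_index <- function(record, bundles) {
  w <- subject_weights(record, bundles)
  list(d_sum = combine_additive(w),
       d_max = combine_maximum(w),
       d_mult = combine_multiplicative(w))
}

#' Comorbidity index for a whole survey
#'
#' Vectorised version of [compute_index()]: appends `d_sum`, `d_max`,
#' `d_mult` columns to the microdata. Records with missing perceived health
#' are excluded with a warning unless `impute_ph` supplies a level to fill in.
#'
#' @param data microdata data.frame in the package schema (`subject_id, sex,
#'   age, education, economic, perceived_health, dx_<id>` x 10).
#' @param bundles named list of `weight_bundle` covering the ten diseases.
#' @param impute_ph optional integer 1..5 used for records with missing
#'   perceived health (default `NULL`: such records are dropped).
#' @return `data` (possibly minus excluded rows) with the three index columns.
#' @export
build_index <- function(data, bundles, impute_ph = NULL) {
  ids <- disease_categories()$id
  miss <- setdiff(ids, names(bundles))
  if (length(miss))
    stop_input("bundles must cover all 10 diseases; missing: %s",
               paste(miss, collapse = ", "))
  bundles <- bundles[ids]
  ph <- data$perceived_health
  if (anyNA(ph)) {
    if (!is.null(impute_ph)) {
      if (!impute_ph %in% 1:5) stop_input("impute_ph must be in 1..5")
      ph[is.na(ph)] <- impute_ph
    } else {
      warning(sprintf("%d record(s) with missing perceived health excluded from index computation",
                      sum(is.na(ph))), call. = FALSE)
      data <- data[!is.na(ph), , drop = FALSE]
      ph <- ph[!is.na(ph)]
    }
  }
  if (length(ph) && (any(ph < 1) || any(ph > 5)))
    stop_input("perceived_health outside 1..5")
  if (nrow(data) == 0L) {
    data$d_sum <- data$d_max <- data$d_mult <- numeric(0)
    return(data)
  }
  ind <- disease_matrix(data, ids)
  sel <- selection_matrix(bundles)            # 5 x 10
  W <- ind * sel[ph, , drop = FALSE]          # n x 10 selected weights
  data$d_sum <- as.numeric(rowSums(W))
  data$d_max <- as.numeric(apply(W, 1, max))
  data$d_mult <- as.numeric(1 - apply(1 - W, 1, prod))
  data
}
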