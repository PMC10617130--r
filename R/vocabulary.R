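#' The ten questionnaire disease categories
#'
#' The surveillance questionnaire asks whether a doctor has ever diagnosed
#' one or more of ten non-communicable diseases. Each category gets a stable
#' canonical id used as the key of keyword registries, weight bundles, and the
#' `dx_<id>` indicator columns of the microdata schema.
#'
#' @return A data.frame with columns `id` (canonical token) and `label`
#'   (questionnaire wording).
#' @export
#' @examples
#' disease_categories()
disease_categories <- function() {
  data.frame(
    id = c("diabetes", "kidney_failure", "bronchitis", "myocardial_infarction",
           "tumor", "liver_disease", "stroke", "heart_disease", "asthma",
           "arthritis"),
    label = c(
      "diabetes",
      "kidney failure",
      "bronchitis/emphysema/respiratory failure",
      "myocardial infarction/cardiac ischemia/coronary artery disease",
      "tumor",
      "chronic liver disease/cirrhosis",
      "stroke/cerebral ischemia",
      "heart diseases",
      "bronchial asthma",
      "arthrosis/arthritis"),
    stringsAsFactors = FALSE
  )
}

#' Normalize free text for keyword matching
#'
#' Lowercases, replaces every punctuation/non-alphanumeric run by a single
#' space, and collapses surrounding whitespace. The transform is deterministic
#' and idempotent, so matching is insensitive to letter case and punctuation
#' on both sides (health-state names and keywords).
#'
#' @param s character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_text("Diabetic foot, severe")  # "diabetic foot severe"
normalize_text <- function(s) {
  s <- tolower(as.character(s))
  s <- gsub("[^a-z0-9]+", " ", s)
  trimws(gsub(" +", " ", s))
}

#' Keyword registry constructor
#'
#' A keyword registry maps each disease-category id to an ordered list of
#' keywords. Keywords are stored lowercase and stripped; matching treats each
#' as a substring of the normalized health-state name, so stem-like entries
#' ("diabet") cover singular, plural and derived forms without a stemmer.
#'
#' @param entries named list of character vectors (name = disease id).
#' @return object of class `keyword_registry`.
#' @export
keyword_registry <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) || any(names(entries) == ""))
    stop_input("registry entries must be a named list of keyword vectors")
  entries <- lapply(entries, function(k) {
    k <- trimws(tolower(as.character(k)))
    k <- k[nzchar(k)]
    if (length(k) == 0L) stop_input("every disease needs at least one keyword")
    k
  })
  structure(entries, class = "keyword_registry")
}

#' Default keyword registry
#'
#' The diabetes list follows the published keyword set for that category
#' ("diabet", "diabetes", "diabetic", "diabeetus", "diabetes mellitus",
#' "hypertension", "obesity", "insulin"). The other nine lists are package
#' defaults derived from the questionnaire disease labels plus common clinical
#' synonyms; they are meant to be reviewed and edited for any concrete study
#' (see [load_keyword_registry()] for supplying your own file).
#'
#' @return `keyword_registry` covering the ten disease categories.
#' @export
default_keyword_registry <- function() {
  keyword_registry(list(
    diabetes = c("diabet", "diabetes", "diabetic", "diabeetus",
                 "diabetes mellitus", "hypertension", "obesity", "insulin"),
    kidney_failure = c("kidney", "renal", "nephritis", "dialysis"),
    bronchitis = c("bronchitis", "emphysema", "copd",
                   "chronic obstructive pulmonary", "respiratory"),
    myocardial_infarction = c("myocardial", "infarct", "angina",
                              "ischemic heart", "coronary"),
    tumor = c("cancer", "tumor", "tumour", "neoplasm", "leukemia", "lymphoma",
              "carcinoma", "metastatic"),
    liver_disease = c("liver", "cirrhosis", "hepatitis", "hepatic"),
    stroke = c("stroke", "cerebrovascular", "cerebral ischemia", "hemiplegia"),
    heart_disease = c("heart failure", "valvular", "cardiomyopathy",
                      "heart disease", "atrial fibrillation"),
    asthma = c("asthma", "asthmatic", "wheezing"),
    arthritis = c("arthritis", "arthrosis", "osteoarthritis", "rheumatoid",
                  "gout", "lupus", "fibromyalgia", "musculoskeletal")
  ))
}

#' Load a keyword registry from YAML or JSON
#'
#' @param path config file mapping disease id to a list of keywords; format
#'   chosen by extension (`.yaml`/`.yml` vs `.json`).
#' @return `keyword_registry`.
#' @export
load_keyword_registry <- function(path) {
  if (!file.exists(path)) stop_input("registry file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  entries <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop_input("unsupported registry format '.%s' (use YAML or JSON)", ext)
  keyword_registry(entries)
}

# internal: validate a parsed weight table
validate_dw <- function(df, source_tag) {
  bad <- which(!is.finite(df$weight) | df$weight < 0 | df$weight > 1)
  if (length(bad))
    stop_input("weight outside [0,1] at row %d (state '%s', weight %s)",
               bad[1], df$state_name[bad[1]], format(df$weight[bad[1]]))
  if (any(!nzchar(trimws(df$state_name))))
    stop_input("empty state_name at row %d", which(!nzchar(trimws(df$state_name)))[1])
  has_b <- !is.na(df$lower) & !is.na(df$upper)
  bad <- which(has_b & (df$lower > df$weight | df$weight > df$upper |
                          df$lower < 0 | df$upper > 1))
  if (length(bad))
    stop_input("inconsistent uncertainty interval at row %d (state '%s')",
               bad[1], df$state_name[bad[1]])
  structure(df, class = c("dw_table", "data.frame"), source_tag = source_tag)
}

#' Construct a disability-weight table from a data.frame
#'
#' @param df data.frame with columns `state_name`, `weight`, and optionally
#'   `lower`, `upper` (all weights on the 0--1 disability scale, where 0 is
#'   full health and 1 is equivalent to death).
#' @param source_tag provenance string stored as an attribute.
#' @return object of class `dw_table` (a validated data.frame).
#' @export
dw_table <- function(df, source_tag = "in-memory") {
  if (!all(c("state_name", "weight") %in% names(df)))
    stop_input("a weight table needs 'state_name' and 'weight' columns")
  df$state_name <- as.character(df$state_name)
  df$weight <- as.numeric(df$weight)
  if (is.null(df$lower)) df$lower <- NA_real_
  if (is.null(df$upper)) df$upper <- NA_real_
  rownames(df) <- NULL
  validate_dw(df[c("state_name", "weight", "lower", "upper")], source_tag)
}

# "0.233 (0.156-0.320)" -> c(weight, lower, upper); hyphen, en- or em-dash.
parse_interval_cell <- function(cell) {
  m <- regmatches(cell, regexec(
    "^\\s*([0-9]*\\.?[0-9]+)\\s*\\(\\s*([0-9]*\\.?[0-9]+)\\s*[-–—]\\s*([0-9]*\\.?[0-9]+)\\s*\\)\\s*$",
    cell))[[1]]
  if (length(m) != 4L)
    stop_input("unparseable weight cell '%s' (expected 'm (l-u)')", cell)
  as.numeric(m[2:4])
}

#' Load a disability-weight table from delimited text
#'
#' Reads a catalogue of health states in the layout of the GBD disability
#' weight downloads: one row per health state with the state name and a weight
#' in \[0,1\]. Two dialects are supported: `plain` expects a bare numeric
#' `weight` column; `gbd_interval` expects a `weight_interval` column holding
#' cells of the form `"m (l-u)"` (hyphen or en-dash), which are parsed into
#' the point weight and its 95% uncertainty bounds.
#'
#' The delimiter is chosen from the extension (`.csv` comma, `.tsv`/`.txt`
#' tab).
#'
#' @param path file path.
#' @param dialect `"plain"` or `"gbd_interval"`.
#' @return `dw_table`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("state_name,weight", "toy mild state,0.2"), f)
#' load_weight_table(f, "plain")
load_weight_table <- function(path, dialect = c("plain", "gbd_interval")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("weight table file not found: %s", path)
  df <- read_delim_auto(path)
  state_col <- intersect(c("state_name", "health_state", "state", "name"), names(df))
  if (length(state_col) == 0L)
    stop_input("no state-name column found (expected one of: state_name, health_state, state, name)")
  out <- data.frame(state_name = as.character(df[[state_col[1]]]),
                    stringsAsFactors = FALSE)
  if (dialect == "plain") {
    if (!"weight" %in% names(df)) stop_input("dialect 'plain' needs a 'weight' column")
    w <- suppressWarnings(as.numeric(df$weight))
    if (anyNA(w))
      stop_input("unparseable weight cell '%s' at row %d",
                 df$weight[which(is.na(w))[1]], which(is.na(w))[1])
    out$weight <- w
    out$lower <- NA_real_
    out$upper <- NA_real_
  } else {
    if (!"weight_interval" %in% names(df))
      stop_input("dialect 'gbd_interval' needs a 'weight_interval' column")
    parsed <- t(vapply(as.character(df$weight_interval), parse_interval_cell,
                       numeric(3)))
    out$weight <- parsed[, 1]
    out$lower <- parsed[, 2]
    out$upper <- parsed[, 3]
  }
  validate_dw(out, source_tag = path)
}

#' Match a disease category's keywords against a weight table
#'
#' Implements the text-matching step that associates each questionnaire
#' disease with a bundle of candidate disability weights: a health state is
#' selected when its normalized name contains at least one normalized keyword
#' as a substring. Weights are deduplicated by value (distinct weights define
#' the bundle); all matching state names are retained for audit. The result
#' does not depend on the ordering of table rows or keywords.
#'
#' @param table `dw_table`.
#' @param registry `keyword_registry`.
#' @param disease disease-category id present in `registry`.
#' @return object of class `weight_bundle`: list with `disease`, `weights`
#'   (sorted distinct values), `matched_states`.
#' @export
match_keywords <- function(table, registry, disease) {
  stopifnot(inherits(table, "dw_table"))
  if (!inherits(registry, "keyword_registry")) registry <- keyword_registry(registry)
  if (!disease %in% names(registry))
    stop_input("disease '%s' not present in the keyword registry", disease)
  keys <- normalize_text(registry[[disease]])
  states <- normalize_text(table$state_name)
  hit <- rep(FALSE, length(states))
  for (k in keys) hit <- hit | grepl(k, states, fixed = TRUE)
  if (!any(hit))
    stop_input("no health state matches any keyword for disease '%s'", disease)
  structure(list(disease = disease,
                 weights = sort(unique(table$weight[hit])),
                 matched_states = table$state_name[hit]),
            class = "weight_bundle")
}

#' Build weight bundles for every disease in a registry
#'
#' @param table `dw_table`.
#' @param registry `keyword_registry` (default: [default_keyword_registry()]).
#' @param exclude_states optional character vector of state names to drop from
#'   the table before matching (e.g. to omit very rare health states; all
#'   states are kept by default).
#' @return named list of `weight_bundle`, one per registry entry.
#' @export
build_bundles <- function(table, registry = default_keyword_registry(),
                          exclude_states = NULL) {
  if (!inherits(registry, "keyword_registry")) registry <- keyword_registry(registry)
  if (!is.null(exclude_states)) {
    keep <- !(normalize_text(table$state_name) %in% normalize_text(exclude_states))
    table <- validate_dw(as.data.frame(table)[keep, , drop = FALSE],
                         attr(table, "source_tag"))
  }
  bundles <- lapply(names(registry), function(d) match_keywords(table, registry, d))
  names(bundles) <- names(registry)
  bundles
}

#' Summary statistics of a weight bundle
#'
#' @param bundle `weight_bundle`.
#' @param sd_type `"sample"` (n-1 denominator, the default) or
#'   `"population"` (n denominator). With a single distinct weight the sd is 0.
#' @return list with `count` (number of distinct weights), `mean`, `sd`.
#' @export
bundle_stats <- function(bundle, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(bundle, "weight_bundle"))
  w <- bundle$weights
  if (length(w) == 0L) stop_input("empty bundle for disease '%s'", bundle$disease)
  n <- length(w)
  s <- if (n == 1L) 0 else stats::sd(w)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  list(count = n, mean = mean(w), sd = s)
}

#' @export
print.weight_bundle <- function(x, ...) {
  st <- bundle_stats(x)
  cat(sprintf("<weight_bundle> %s: %d distinct weights (mean %.3f, sd %.3f), %d matched states\n",
              x$disease, st$count, st$mean, st$sd, length(x$matched_states)))
  invisible(x)
}

#' Per-disease bundle audit table
#'
#' @param bundles named list of `weight_bundle` from [build_bundles()].
#' @param sd_type passed to [bundle_stats()].
#' @return data.frame with one row per disease: count, mean, sd of the
#'   distinct matched weights and the matched state names (';'-separated).
#' @export
bundle_audit <- function(bundles, sd_type = "sample") {
  do.call(rbind, lapply(bundles, function(b) {
    st <- bundle_stats(b, sd_type)
    data.frame(disease = b$disease, n_weights = st$count, mean = st$mean,
               sd = st$sd, n_states = length(b$matched_states),
               matched_states = paste(b$matched_states, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
}

#' Check bundle dispersion against the GBD 2019 reference catalogue
#'
#' Loads the GBD 2019 disability-weight file (not redistributed with the
#' package; download it from the GHDx catalogue, save the sequela/health-state
#' table as delimited text with columns `state_name` and `weight` or
#' `weight_interval`, and pass its path or set
#' `options(comorbindex.gbd_path=)`), builds the ten bundles with the default
#' registry, and returns the per-disease audit.
#'
#' @param path path to the GBD weight table; defaults to the
#'   `comorbindex.gbd_path` option, falling back to
#'   `inst/extdata/gbd2019_disability_weights.csv` inside the installed
#'   package.
#' @param dialect table dialect, see [load_weight_table()].
#' @return data.frame as returned by [bundle_audit()].
#' @export
check_gbd_reference <- function(path = getOption("comorbindex.gbd_path",
                                                 system.file("extdata", "gbd2019_disability_weights.csv",
                                                             package = "comorbindex")),
                                dialect = "gbd_interval") {
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop_input(paste0("GBD 2019 disability-weight file not available; download it ",
                      "from the GHDx catalogue and pass its path (or set ",
                      "options(comorbindex.gbd_path=))"))
  bundle_audit(build_bundles(load_weight_table(path, dialect)))
}
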