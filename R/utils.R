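`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
is_prob <- function(p) is.numeric(p) && length(p) == 1L && !is.na(p) && p >= 0 && p <= 1

# Delimiter from file extension: .tsv/.tab/.txt -> tab, anything else comma.
delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

read_delim_auto <- function(path) {
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    quote = "\"", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# md5 of an arbitrary R object via its canonical JSON serialisation;
# used to stamp outputs with a configuration fingerprint.
object_md5 <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# CSV writer with a single '#'-prefixed metadata header line.
# Numeric columns are rounded to 4 decimals so repeated runs with the same
# seed are byte-identical.
write_output_csv <- function(df, path, seed = NA, config_md5 = NA) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 4))
  header <- sprintf("# comorbindex %s; seed=%s; config_md5=%s",
                    as.character(utils::packageVersion("comorbindex")),
                    seed, config_md5)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_output_csv <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
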