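# shared in-code fixtures and independent oracles

make_bundle <- function(weights, disease = "toy") {
  structure(list(disease = disease, weights = sort(unique(weights)),
                 matched_states = paste0("state", seq_along(weights))),
            class = "weight_bundle")
}

write_weight_csv <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# naive loop-based evaluations of the three combination functions,
# kept deliberately independent of the package implementations
oracle_sum <- function(w) { s <- 0; for (x in w) s <- s + x; s }
oracle_max <- function(w) { m <- 0; for (x in w) if (x > m) m <- x; m }
oracle_mult <- function(w) { p <- 1; for (x in w) p <- p * (1 - x); 1 - p }

# brute-force min / mean / max by scanning, for the perceived-health rule
oracle_select <- function(w, ph) {
  if (ph <= 3) { m <- w[1]; for (x in w) if (x < m) m <- x; m }
  else if (ph == 4) oracle_sum(w) / length(w)
  else { m <- w[1]; for (x in w) if (x > m) m <- x; m }
}

# minimal bundle set covering all ten diseases with known weights
toy_bundles <- function() {
  ids <- disease_categories()$id
  stats::setNames(lapply(seq_along(ids), function(i)
    make_bundle(c(0.05, 0.1, 0.3) + i / 100, disease = ids[i])), ids)
}

# a bare survey record as a one-row data.frame
toy_record <- function(ph = 3, declared = character(0)) {
  ids <- disease_categories()$id
  rec <- data.frame(subject_id = "S1", sex = "female", age = 40,
                    education = "high", economic = "none",
                    perceived_health = ph, stringsAsFactors = FALSE)
  for (id in ids) rec[[paste0("dx_", id)]] <- as.integer(id %in% declared)
  rec
}
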