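test_that("plain and interval weight-table dialects parse correctly", {
  f <- write_weight_csv(c("state_name,weight", "toy mild state,0.2"))
  tab <- load_weight_table(f, "plain")
  expect_s3_class(tab, "dw_table")
  expect_equal(tab$weight, 0.2)
  expect_true(is.na(tab$lower))

  # en-dash and plain hyphen interval cells parse to the same triple
  g <- write_weight_csv(c("state_name,weight_interval",
                          "\"toy state a\",\"0.233 (0.156–0.320)\"",
                          "\"toy state b\",\"0.233 (0.156-0.320)\""))
  tab2 <- load_weight_table(g, "gbd_interval")
  expect_equal(tab2$weight, c(0.233, 0.233))
  expect_equal(tab2$lower, c(0.156, 0.156))
  expect_equal(tab2$upper, c(0.320, 0.320))

  # tab-delimited table picked up from the extension
  h <- write_weight_csv(c("state_name\tweight", "toy tsv state\t0.4"), ext = ".tsv")
  expect_equal(load_weight_table(h, "plain")$weight, 0.4)
})

test_that("weight-table validation rejects malformed input", {
  f <- write_weight_csv(c("state_name,weight", "bad state,1.2"))
  expect_error(load_weight_table(f, "plain"), "outside \\[0,1\\].*row 1")

  g <- write_weight_csv(c("state_name,weight", "bad state,abc"))
  expect_error(load_weight_table(g, "plain"), "unparseable")

  h <- write_weight_csv(c("state_name,weight_interval", "bad,\"0.2 0.1 0.3\""))
  expect_error(load_weight_table(h, "gbd_interval"), "unparseable")

  i <- write_weight_csv(c("foo,weight", "x,0.2"))
  expect_error(load_weight_table(i, "plain"), "state-name column")

  j <- write_weight_csv(c("state_name,weight_interval",
                          "\"bad bounds\",\"0.2 (0.25-0.3)\""))
  expect_error(load_weight_table(j, "gbd_interval"), "interval")
})

test_that("text normalization lowercases, strips punctuation, and is idempotent", {
  expect_equal(normalize_text("Diabetic foot, severe"), "diabetic foot severe")
  expect_equal(normalize_text("ASTHMA"), "asthma")
  expect_equal(normalize_text(""), "")
  set.seed(42)
  for (i in 1:50) {
    s <- paste(sample(c(LETTERS, letters, 0:9, ",", ".", "(", ")", "-", " "),
                      30, replace = TRUE), collapse = "")
    expect_identical(normalize_text(normalize_text(s)), normalize_text(s))
  }
})

test_that("keyword matching selects by substring and dedups by weight value", {
  tab <- dw_table(data.frame(
    state_name = c("type 2 diabetes mellitus mild", "controlled asthma",
                   "Diabetic neuropathy", "insulin dependent state"),
    weight = c(0.05, 0.02, 0.10, 0.05)))
  reg <- default_keyword_registry()
  b <- match_keywords(tab, reg, "diabetes")
  expect_setequal(b$weights, c(0.05, 0.10))          # 0.05 appears twice, kept once
  expect_setequal(b$matched_states,
                  c("type 2 diabetes mellitus mild", "Diabetic neuropathy",
                    "insulin dependent state"))
  expect_true(length(b$weights) <= length(b$matched_states))

  expect_error(match_keywords(tab, keyword_registry(list(x = "zzz")), "x"),
               "no health state matches")
  expect_error(match_keywords(tab, reg, "not_a_disease"), "not present")
})

test_that("matching is invariant to row order, keyword order, and case", {
  tab <- fixture_weight_table(3)
  reg <- default_keyword_registry()
  set.seed(9)
  for (d in c("diabetes", "arthritis", "stroke")) {
    b0 <- match_keywords(tab, reg, d)
    perm <- dw_table(as.data.frame(tab)[sample(nrow(tab)), ])
    b1 <- match_keywords(perm, reg, d)
    expect_identical(b0$weights, b1$weights)
    expect_setequal(b0$matched_states, b1$matched_states)
    shuf <- keyword_registry(stats::setNames(list(sample(toupper(reg[[d]]))), d))
    b2 <- match_keywords(tab, shuf, d)
    expect_identical(b0$weights, b2$weights)
  }
})

test_that("enlarging the keyword list never shrinks a bundle", {
  tab <- fixture_weight_table(4)
  reg <- default_keyword_registry()
  for (d in names(reg)) {
    base <- match_keywords(tab, reg, d)
    grown <- reg
    grown[[d]] <- c(grown[[d]], "asthma")  # borrow another disease's keyword
    g <- match_keywords(tab, keyword_registry(unclass(grown)), d)
    expect_true(all(base$weights %in% g$weights))
    expect_true(all(base$matched_states %in% g$matched_states))
  }
})

test_that("bundle statistics use the sample sd with a population switch", {
  b <- make_bundle(c(0.2, 0.4))
  st <- bundle_stats(b)
  expect_equal(st$count, 2)
  expect_equal(st$mean, 0.3)
  expect_equal(st$sd, sqrt((0.2 - 0.3)^2 + (0.4 - 0.3)^2))  # n-1 denominator
  expect_equal(bundle_stats(b, sd_type = "population")$sd,
               sqrt(((0.2 - 0.3)^2 + (0.4 - 0.3)^2) / 2))
  st1 <- bundle_stats(make_bundle(0.5))
  expect_equal(unlist(st1), c(count = 1, mean = 0.5, sd = 0))
  expect_error(bundle_stats(make_bundle(numeric(0))), "empty bundle")
})

test_that("registry round-trips through YAML and JSON config files", {
  reg <- default_keyword_registry()
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(reg), fy)
  expect_identical(unclass(load_keyword_registry(fy)), unclass(reg))
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(reg), fj)
  expect_identical(unclass(load_keyword_registry(fj)), unclass(reg))
  expect_error(load_keyword_registry(tempfile(fileext = ".yaml")), "not found")
})

test_that("bundle audit covers all diseases and an exclusion list removes states", {
  tab <- fixture_weight_table(1)
  bundles <- build_bundles(tab)
  aud <- bundle_audit(bundles)
  expect_setequal(aud$disease, disease_categories()$id)
  expect_true(all(aud$n_weights >= 2))
  expect_true(all(aud$mean >= 0 & aud$mean <= 1))

  drop <- bundles$asthma$matched_states[1]
  b2 <- build_bundles(tab, exclude_states = drop)
  expect_false(drop %in% b2$asthma$matched_states)
  expect_lt(length(b2$asthma$matched_states),
            length(bundles$asthma$matched_states))
})
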