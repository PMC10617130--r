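test_that("perceived health selects min, mean, or max of the bundle", {
  b <- make_bundle(c(0.1, 0.2, 0.6))
  expect_equal(select_weight(b, 1), 0.1)
  expect_equal(select_weight(b, 2), 0.1)
  expect_equal(select_weight(b, 3), 0.1)
  expect_equal(select_weight(b, 4), 0.3)
  expect_equal(select_weight(b, 5), 0.6)
  expect_error(select_weight(b, 0), "1\\.\\.5")
  expect_error(select_weight(b, 6), "1\\.\\.5")
  expect_error(select_weight(b, 2.5), "1\\.\\.5")
  expect_error(select_weight(make_bundle(numeric(0)), 3), "empty bundle")
})

test_that("selection matches brute force on enumerated bundles of size <= 5", {
  set.seed(11)
  for (k in 1:5) {
    for (rep in 1:20) {
      w <- sort(unique(round(runif(k), 6)))
      b <- make_bundle(w)
      for (ph in 1:5)
        expect_equal(select_weight(b, ph), oracle_select(b$weights, ph))
      # weakly increasing in perceived health
      sel <- vapply(1:5, function(ph) select_weight(b, ph), numeric(1))
      expect_true(all(diff(sel) >= 0))
    }
  }
})

test_that("subject weight vector is zero exactly for undeclared diseases", {
  bundles <- toy_bundles()
  w0 <- subject_weights(toy_record(ph = 3), bundles)
  expect_equal(unname(w0), rep(0, 10))

  bundles$diabetes <- make_bundle(c(0.1, 0.2, 0.6), "diabetes")
  w1 <- subject_weights(toy_record(ph = 2, declared = "diabetes"), bundles)
  expect_equal(unname(w1[names(w1) == "diabetes"]), 0.1)
  expect_equal(sum(w1 != 0), 1)

  # nonzero entries weakly larger under ph = 5 than ph = 1
  declared <- c("diabetes", "tumor", "asthma")
  lo <- subject_weights(toy_record(ph = 1, declared = declared), bundles)
  hi <- subject_weights(toy_record(ph = 5, declared = declared), bundles)
  expect_true(all(hi >= lo))
  expect_identical(lo != 0, hi != 0)
})

test_that("combination functions reproduce hand-computed values", {
  w <- numeric(10)
  expect_equal(combine_additive(w), 0)
  expect_equal(combine_maximum(w), 0)
  expect_equal(combine_multiplicative(w), 0)
  w[1:2] <- c(0.2, 0.3)
  expect_equal(combine_additive(w), 0.5)
  expect_equal(combine_maximum(w), 0.3)
  expect_equal(combine_multiplicative(w), 1 - 0.8 * 0.7)  # 0.44
  expect_equal(combine_additive(rep(1, 10)), 10)
  expect_equal(combine_maximum(rep(0.5, 10)), 0.5)
  v <- numeric(10); v[7] <- 0.37
  expect_equal(combine_multiplicative(v), 0.37)
  expect_error(combine_additive(c(0.2, 1.4)), "\\[0,1\\]")
})

test_that("combinations match naive loop oracles and respect the ordering", {
  set.seed(21)
  for (i in 1:300) {
    k <- sample(0:10, 1)
    w <- numeric(10)
    if (k > 0) w[sample(10, k)] <- runif(k)
    expect_equal(combine_additive(w), oracle_sum(w), tolerance = 1e-12)
    expect_equal(combine_maximum(w), oracle_max(w), tolerance = 1e-12)
    expect_equal(combine_multiplicative(w), oracle_mult(w), tolerance = 1e-12)
    expect_true(combine_maximum(w) <= combine_multiplicative(w) + 1e-15)
    expect_true(combine_multiplicative(w) <= combine_additive(w) + 1e-15)
  }
})

test_that("raising one weight weakly raises every combination", {
  set.seed(22)
  for (i in 1:50) {
    w <- runif(10) * rbinom(10, 1, 0.4)
    j <- sample(10, 1)
    w2 <- w
    w2[j] <- min(1, w[j] + runif(1, 0, 1 - w[j]))
    expect_gte(combine_additive(w2), combine_additive(w))
    expect_gte(combine_maximum(w2), combine_maximum(w))
    expect_gte(combine_multiplicative(w2) - combine_multiplicative(w), -1e-15)
  }
})

test_that("the three indices coincide for a single declared disease", {
  bundles <- toy_bundles()
  bundles$diabetes <- make_bundle(c(0.1, 0.2, 0.6), "diabetes")
  idx <- compute_index(toy_record(ph = 2, declared = "diabetes"), bundles)
  expect_equal(idx, list(d_sum = 0.1, d_max = 0.1, d_mult = 0.1))
  idx0 <- compute_index(toy_record(ph = 3), bundles)
  expect_equal(idx0, list(d_sum = 0, d_max = 0, d_mult = 0))
})

test_that("vectorised index agrees with per-record computation", {
  bundles <- build_bundles(fixture_weight_table(2))
  pop <- generate_population(generator_config(n = 300, seed = 13))
  indexed <- build_index(pop$records, bundles)
  expect_true(all(indexed$d_max <= indexed$d_mult + 1e-12))
  expect_true(all(indexed$d_mult <= indexed$d_sum + 1e-12))
  for (i in sample(nrow(indexed), 25)) {
    ref <- compute_index(pop$records[i, ], bundles)
    expect_equal(indexed$d_sum[i], ref$d_sum)
    expect_equal(indexed$d_max[i], ref$d_max)
    expect_equal(indexed$d_mult[i], ref$d_mult)
  }
})

test_that("missing perceived health is excluded with a warning unless imputed", {
  bundles <- build_bundles(fixture_weight_table(2))
  pop <- generate_population(generator_config(n = 50, seed = 14))
  rec <- pop$records
  rec$perceived_health[c(3, 7)] <- NA
  expect_warning(out <- build_index(rec, bundles), "2 record\\(s\\)")
  expect_equal(nrow(out), 48)
  out2 <- build_index(rec, bundles, impute_ph = 3)
  expect_equal(nrow(out2), 50)
  imputed <- build_index(transform(rec[c(3, 7), ], perceived_health = 3), bundles)
  expect_equal(out2$d_sum[c(3, 7)], imputed$d_sum)
})
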