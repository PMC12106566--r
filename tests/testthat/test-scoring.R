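test_that("the packaged model encodes the frozen coefficient table, verified through computation", {
  # zero-input evaluation through the scoring path recovers each intercept;
  # unit finite differences recover each slope
  for (lev in lumbar_levels) {
    tab <- frozen_table[[lev]]
    base <- score_at(lev)
    expect_equal(base, tab[["intercept"]], tolerance = 1e-12)
    # unit finite differences agree to far beyond the printed precision
    # (1e-6 relative; the subtraction itself costs ~1e-9)
    expect_equal(score_at(lev, t2 = 1) - base, tab[["t2"]],
                 tolerance = 1e-6)
    expect_equal(score_at(lev, ht = 1) - base, tab[["height"]],
                 tolerance = 1e-6)
    expect_equal(score_at(lev, area = 1) - base, tab[["area"]],
                 tolerance = 1e-6)
    expect_equal(score_at(lev, vol = 1) - base, tab[["volume"]],
                 tolerance = 1e-6)
    expect_equal(default_coefficients()[[lev]]$rmse_years, tab[["rmse"]])
  }
  # worked example: L1-L2 at NP T2 = 100 ms, everything else zero
  expect_equal(score_at("L1-L2", t2 = 100), 142.3 - 39.50, tolerance = 1e-9)
})

test_that("scoring is exactly linear in each predictor", {
  coefs <- default_coefficients()
  withr::with_seed(42, {
    for (lev in lumbar_levels) {
      t2 <- runif(1, 40, 120); ht <- runif(1, 60, 75)
      ar <- runif(1, 400, 800); vol <- runif(1, 8000, 25000)
      base <- score_at(lev, t2, ht, ar, vol)
      expect_equal(score_at(lev, t2 + 1, ht, ar, vol) - base,
                   coefs[[lev]]$coef_t2, tolerance = 1e-12)
      expect_equal(score_at(lev, t2, ht, ar, vol + 100) - base,
                   100 * coefs[[lev]]$coef_volume, tolerance = 1e-9)
    }
  })
  # level mismatch and unknown levels are input errors
  p <- disc_predictors("L1-L2", 80, 66, 500, 12000)
  expect_error(effective_age(p, default_coefficients()[["L2-L3"]]),
               "mismatch")
  expect_error(disc_predictors("L6-S1", 80, 66, 500, 12000), "unknown level")
})

test_that("classification uses a strict threshold and is monotone", {
  expect_equal(classify_delta(0, 8.8), "normal")
  expect_equal(classify_delta(9.0, 8.8), "accelerated")      # L3-L4 default
  expect_equal(classify_delta(8.8, 8.8), "normal")           # boundary
  expect_equal(classify_delta(-9.0, 8.8), "younger-than-expected")
  expect_error(classify_delta(1, 0), "> 0")

  # monotone in delta for fixed threshold
  deltas <- seq(-30, 30, by = 0.5)
  cls <- classify_delta(deltas, 10)
  rank <- c("younger-than-expected" = 1, "normal" = 2, "accelerated" = 3)
  expect_true(all(diff(rank[cls]) >= 0))

  # larger threshold never increases the accelerated count
  withr::with_seed(7, {
    d <- rnorm(500, 0, 12)
    n_acc <- vapply(c(5, 8.8, 12, 20), function(th)
      sum(classify_delta(d, th) == "accelerated"), numeric(1))
    expect_true(all(diff(n_acc) <= 0))
  })
})

test_that("coefficient documents round-trip and are schema-checked", {
  set <- default_coefficients()
  path <- withr::local_tempfile(fileext = ".json")
  save_coefficients(set, path)
  again <- load_coefficients(path)
  expect_equal(again, set)

  # packaged value spot check
  expect_equal(set[["L5-S1"]]$coef_volume, 0.004336)

  # four levels only -> schema error
  doc <- jsonlite::read_json(path)
  jsonlite::write_json(doc[1:4], path, auto_unbox = TRUE, digits = NA)
  expect_error(load_coefficients(path), "five levels")

  # missing coefficient -> schema error
  doc2 <- doc
  doc2[["L1-L2"]]$coef_t2_per_ms <- NULL
  jsonlite::write_json(doc2, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_coefficients(path), "missing field")

  # duplicate level -> error
  lst <- lapply(set, identity)
  lst[[2]] <- lst[[1]]
  expect_error(discage:::new_coefficient_set(lst), "duplicate|five levels")
})

test_that("centimetre heights compose with scoring through unit conversion", {
  p_in <- disc_predictors("L2-L3", 85, 66, 520, 14000)
  p_cm <- disc_predictors("L2-L3", 85, 66 * 2.54, 520, 14000,
                          height_units = "cm")
  expect_equal(effective_age(p_cm), effective_age(p_in), tolerance = 1e-12)

  tab <- data.frame(level = "L2-L3", np_t2 = 85, subject_height = 66 * 2.54,
                    midsag_area = 520, volume = 14000, true_age = 50)
  s_cm <- score_cohort(tab, height_units = "cm")
  expect_equal(s_cm$effective_age, as.numeric(effective_age(p_in)))
})

test_that("cohort scoring is self-consistent, collects row errors, and flags injected discs", {
  # a noiseless cohort generated from the packaged model scores delta == 0
  co0 <- suppressMessages(generate_cohort(cohort_spec(seed = 11,
                                                      noise_sd = 0)))
  s0 <- score_cohort(co0$table)
  expect_equal(max(abs(s0$delta)), 0, tolerance = 1e-9)
  expect_true(all(s0$classification == "normal"))

  # empty table in, empty table out
  s_empty <- score_cohort(co0$table[0, ])
  expect_equal(nrow(s_empty), 0)

  # unknown level is a per-row error, not fatal
  tab <- co0$table[1:3, ]
  tab$level[2] <- "T12-L1"
  s_bad <- score_cohort(tab)
  expect_true(is.na(s_bad$effective_age[2]))
  expect_match(s_bad$error[2], "T12-L1")
  expect_false(anyNA(s_bad$effective_age[c(1, 3)]))

  # discs injected with +25 years of excess phenotype age are mostly
  # caught at the L3-L4 RMSE threshold; detection is well above the
  # false-positive rate overall
  det <- fp <- numeric(5)
  for (i in 1:5) {
    co <- suppressMessages(generate_cohort(cohort_spec(seed = 300 + i)))
    co <- inject_accelerated_discs(co, fraction = 0.2, excess_years = 25,
                                   seed = 400 + i)
    sc <- score_cohort(co$table)
    l34 <- sc$level == "L3-L4"
    det[i] <- mean(sc$classification[l34 & sc$accelerated_truth] ==
                     "accelerated")
    fp[i] <- mean(sc$classification[!sc$accelerated_truth] == "accelerated")
  }
  expect_gt(mean(det), 0.5)
  expect_gt(mean(det), mean(fp) + 0.2)
})
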