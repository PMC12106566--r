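make_level_table <- function(n, seed, gen) {
  withr::with_seed(seed, {
    df <- gen(n)
    df$level <- "L3-L4"
    df
  })
}

test_that("exact linear data is fit exactly", {
  tab <- make_level_table(40, 1, function(n) {
    x1 <- runif(n, 0, 10)
    data.frame(x1 = x1, age = 2 * x1 + 5)
  })
  f <- suppressWarnings(fit_level_model(tab, "L3-L4", "x1"))  # perfect fit
  expect_equal(f$intercept, 5, tolerance = 1e-10)
  expect_equal(unname(f$coefficients["x1"]), 2, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$rmse_years, 0, tolerance = 1e-8)
})

test_that("OLS agrees with a normal-equations oracle on random designs", {
  for (seed in 1:5) {
    tab <- make_level_table(60, seed, function(n) {
      X <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(NULL, paste0("x", 1:4)))
      data.frame(X, age = 50 + X %*% c(1, -2, 0.5, 3) + rnorm(n, 0, 5))
    })
    preds <- paste0("x", 1:4)
    f <- fit_level_model(tab, "L3-L4", preds)
    oracle <- ols_oracle(tab[preds], tab$age)
    expect_equal(unname(c(f$intercept, f$coefficients)), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  tab <- make_level_table(30, 2, function(n) {
    x1 <- rnorm(n)
    data.frame(x1 = x1, x2 = x1, age = x1 + rnorm(n))
  })
  expect_error(fit_level_model(tab, "L3-L4", c("x1", "x2")), "x2")
})

test_that("standardized betas follow their closed forms", {
  # single predictor: standardized beta equals the Pearson correlation
  tab <- make_level_table(50, 3, function(n) {
    x <- rnorm(n); data.frame(x = x, age = 40 + 3 * x + rnorm(n, 0, 4))
  })
  f <- fit_level_model(tab, "L3-L4", "x")
  expect_equal(unname(f$std_beta["x"]), cor(tab$x, tab$age),
               tolerance = 1e-12)

  # rescaling a predictor's units leaves its standardized beta unchanged
  tab$x_scaled <- tab$x * 1000
  f2 <- fit_level_model(tab, "L3-L4", "x_scaled")
  expect_equal(unname(f2$std_beta), unname(f$std_beta), tolerance = 1e-12)

  # orthonormalized predictors: betas proportional to raw coefficients
  tab3 <- make_level_table(64, 4, function(n) {
    Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
    Q <- scale(Q)  # unit sample SD, orthogonal columns
    colnames(Q) <- paste0("q", 1:3)
    data.frame(Q, age = 50 + Q %*% c(4, -2, 1) + rnorm(n, 0, 2))
  })
  f3 <- fit_level_model(tab3, "L3-L4", paste0("q", 1:3))
  expect_equal(unname(f3$std_beta),
               unname(f3$coefficients) / sd(tab3$age), tolerance = 1e-10)

  # zero-variance predictor is an error
  tab$z <- 1
  expect_error(fit_level_model(tab, "L3-L4", c("x", "z")), "z")
})

test_that("variance inflation factors match their definition and car::vif", {
  # independent predictors at large n: VIF near 1; never below 1
  tab <- make_level_table(2000, 5, function(n) {
    data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
               age = 50 + rnorm(n))
  })
  v <- vif_values(tab, "L3-L4", c("a", "b", "c"))
  expect_true(all(v >= 1))
  expect_true(all(v < 1.02))

  # known collinearity: VIF = 1 / (1 - realized r^2)
  tab2 <- make_level_table(200, 6, function(n) {
    x1 <- rnorm(n); x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
    data.frame(x1 = x1, x2 = x2, age = 50 + x1 + rnorm(n))
  })
  v2 <- vif_values(tab2, "L3-L4", c("x1", "x2"))
  r2_realized <- cor(tab2$x1, tab2$x2)^2
  expect_equal(unname(v2), rep(1 / (1 - r2_realized), 2), tolerance = 1e-10)

  # cross-check against an established implementation
  fit <- lm(age ~ x1 + x2, data = tab2)
  expect_equal(unname(v2), unname(car::vif(fit)), tolerance = 1e-10)

  # perfect collinearity flagged as infinite
  tab2$x3 <- tab2$x1
  v3 <- suppressWarnings(vif_values(tab2, "L3-L4", c("x1", "x3")))
  expect_true(all(is.infinite(v3)))
})

test_that("all-subsets search is exhaustive, optimal and reproducible", {
  # planted signal: age is exactly x3
  tab <- make_level_table(40, 7, function(n) {
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = runif(n, 20, 80),
                    x4 = rnorm(n), x5 = rnorm(n), x6 = rnorm(n))
    X$age <- X$x3
    X
  })
  res <- all_subsets_search(tab, paste0("x", 1:6), sizes = c(1, 2),
                            levels = "L3-L4")
  expect_equal(res$best$subset[res$best$size == 1], "x3")
  expect_equal(res$best$pooled_r2[res$best$size == 1], 1, tolerance = 1e-12)

  # best criterion is monotone non-decreasing in subset size
  co <- quick_cohort(21)
  cands <- c(model_predictors, "disc_height", "disc_width", "aaf_t2",
             "wedge_angle")
  res2 <- all_subsets_search(co$table, cands, sizes = c(1, 2, 3, 4))
  expect_true(all(diff(res2$best$pooled_r2) >= 0))
  expect_equal(res2$n_enumerated,
               choose(8, 1) + choose(8, 2) + choose(8, 3) + choose(8, 4))

  # independent brute-force oracle over all five levels
  oracle_best <- function(tab, cands, k) {
    combos <- utils::combn(sort(cands), k, simplify = FALSE)
    score <- vapply(combos, function(ss) {
      mean(vapply(lumbar_levels, function(lev) {
        d <- tab[tab$level == lev, ]
        summary(lm(reformulate(ss, "age"), data = d))$r.squared
      }, numeric(1)))
    }, numeric(1))
    nm <- vapply(combos, paste, "", collapse = "+")
    ord <- order(-score, nm)
    list(subset = nm[ord[1]], r2 = score[ord[1]])
  }
  for (k in c(1, 2, 3)) {
    ob <- oracle_best(co$table, cands, k)
    expect_equal(res2$best$subset[res2$best$size == k], ob$subset)
    expect_equal(res2$best$pooled_r2[res2$best$size == k], ob$r2,
                 tolerance = 1e-10)
  }
})

test_that("k-fold cross-validation partitions rows with balanced folds", {
  co <- quick_cohort(22)
  cv <- kfold_cv(co$table, "L2-L3", model_predictors, k = 5, seed = 17)
  expect_equal(sort(cv$fold_sizes, decreasing = TRUE), c(17, 17, 17, 17, 16))
  expect_equal(sum(cv$fold_sizes), 84)
  expect_true(all(cv$fold_rmse > 0))
  expect_equal(cv$uncertainty_years, diff(range(cv$fold_rmse)) / 2)

  # determinism contract
  cv_same <- kfold_cv(co$table, "L2-L3", model_predictors, k = 5, seed = 17)
  expect_identical(cv$fold_rmse, cv_same$fold_rmse)
  cv_diff <- kfold_cv(co$table, "L2-L3", model_predictors, k = 5, seed = 18)
  expect_false(identical(cv$fold_rmse, cv_diff$fold_rmse))

  # zero-noise linear data: every fold validates perfectly
  tab0 <- make_level_table(30, 8, function(n) {
    x <- runif(n); data.frame(x = x, age = 20 + 50 * x)
  })
  cv0 <- suppressWarnings(kfold_cv(tab0, "L3-L4", "x", k = 5, seed = 1))
  expect_equal(max(cv0$fold_rmse), 0, tolerance = 1e-9)

  expect_error(kfold_cv(tab0[1:8, ], "L3-L4", "x", k = 5, seed = 1),
               "at least")
  expect_error(kfold_cv(tab0, "L3-L4", "x", k = 5), "seed")
})

test_that("single-predictor screening ranks by fit and reports slope signs", {
  co <- quick_cohort(23)
  scr <- screen_single_predictors(co$table, "L3-L4",
                                  c(model_predictors, "disc_width"))
  # nucleus T2 carries the strongest age signal and falls with age
  expect_equal(scr$predictor[1], "np_t2")
  expect_equal(scr$slope_sign[scr$predictor == "np_t2"], -1)
  expect_true(all(diff(scr$r2) <= 0))

  # zero-variance candidate skipped with a flag
  tab <- co$table
  tab$flat <- 1
  scr2 <- screen_single_predictors(tab, "L3-L4", c("np_t2", "flat"))
  expect_equal(attr(scr2, "skipped"), "flat")

  expect_identical(nrow(screen_single_predictors(co$table, "L3-L4",
                                                 character(0))), 0L)
})

test_that("nested fits: R2 never decreases, residual-df RMSE can increase", {
  tab <- make_level_table(25, 9, function(n) {
    data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
               age = 50 + rnorm(n, 0, 10))
  })
  f1 <- fit_level_model(tab, "L3-L4", "x1")
  f2 <- fit_level_model(tab, "L3-L4", c("x1", "x2"))
  f3 <- fit_level_model(tab, "L3-L4", c("x1", "x2", "x3"))
  expect_true(f2$r2 >= f1$r2 && f3$r2 >= f2$r2)
  # pure-noise predictors: the df-penalized RMSE rises somewhere in the nest
  expect_true(f2$rmse_years > f1$rmse_years || f3$rmse_years > f2$rmse_years)
  # the n-denominator variant never increases along a nest
  g1 <- fit_level_model(tab, "L3-L4", "x1", rmse_denominator = "n")
  g2 <- fit_level_model(tab, "L3-L4", c("x1", "x2"), rmse_denominator = "n")
  expect_lte(g2$rmse_years, g1$rmse_years)
})
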