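#' Fit a level-specific age-prediction model
#'
#' Ordinary least squares of true age on the requested predictors, with
#' intercept, restricted to one spine level. Rows with missing values in
#' the response or any used predictor are dropped (listwise deletion) and
#' the dropped count recorded.
#'
#' @param table Cohort data frame: one row per disc observation with
#'   columns `level`, `age` and the candidate predictors.
#' @param level Level label to fit.
#' @param predictors Character vector of predictor column names.
#' @param rmse_denominator `"n-p-1"` (residual degrees of freedom, the
#'   reporting convention adopted here, default) or `"n"`.
#' @return An object of class `fit_summary`: intercept, named
#'   `coefficients`, `r2`, `rmse_years`, `std_beta`, `vif`, `p_values`,
#'   `n`, `n_dropped`, plus the underlying model frame in `data`.
#' @export
fit_level_model <- function(table, level, predictors,
                            rmse_denominator = c("n-p-1", "n")) {
  rmse_denominator <- match.arg(rmse_denominator)
  check_cohort(table, predictors)
  rows <- table[table$level == level, c("age", predictors), drop = FALSE]
  cc <- stats::complete.cases(rows)
  n_dropped <- sum(!cc)
  rows <- rows[cc, , drop = FALSE]
  n <- nrow(rows)
  p <- length(predictors)
  if (n < p + 2L)
    stop(sprintf("level %s has %d complete rows; need at least %d for %d predictors",
                 level, n, p + 2L, p), call. = FALSE)

  fml <- stats::reformulate(sprintf("`%s`", predictors), response = "age")
  fit <- stats::lm(fml, data = rows)
  if (fit$rank < p + 1L) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop(sprintf("rank-deficient design at level %s; collinear column(s): %s",
                 level, paste(gsub("`", "", aliased), collapse = ", ")),
         call. = FALSE)
  }
  sm <- summary(fit)
  sse <- sum(stats::resid(fit)^2)
  denom <- if (rmse_denominator == "n-p-1") n - p - 1L else n
  rmse <- sqrt(sse / denom)
  coefs <- stats::coef(fit)
  names(coefs) <- gsub("`", "", names(coefs))
  pv <- sm$coefficients[, "Pr(>|t|)"]
  names(pv) <- gsub("`", "", names(pv))

  out <- structure(list(
    level = level,
    predictors = predictors,
    intercept = unname(coefs["(Intercept)"]),
    coefficients = coefs[predictors],
    r2 = sm$r.squared,
    rmse_years = rmse,
    p_values = pv[predictors],
    n = n,
    n_dropped = n_dropped,
    rmse_denominator = rmse_denominator,
    data = rows
  ), class = "fit_summary")
  out$std_beta <- standardized_betas(out)
  out$vif <- vif_values(table, level, predictors)
  out
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("level %s: n = %d (%d dropped), R2 = %.3f, RMSE = %.2f years\n",
              x$level, x$n, x$n_dropped, x$r2, x$rmse_years))
  df <- data.frame(coefficient = x$coefficients,
                   std_beta = x$std_beta[x$predictors],
                   vif = x$vif[x$predictors],
                   p = signif(x$p_values[x$predictors], 3))
  cat(sprintf("intercept: %.4g\n", x$intercept))
  print(df)
  invisible(x)
}

#' Standardized regression coefficients
#'
#' For each predictor j, beta_j = b_j * sd(x_j) / sd(y) using sample
#' standard deviations over the fitted rows: the unit-free effect size of
#' one predictor SD in response SDs. For a single-predictor model this
#' equals the Pearson correlation of x and y.
#'
#' @param fit A [fit_level_model()] result.
#' @return Named numeric vector of standardized betas.
#' @export
standardized_betas <- function(fit) {
  stopifnot(inherits(fit, "fit_summary"))
  y_sd <- stats::sd(fit$data$age)
  vapply(fit$predictors, function(p) {
    x_sd <- stats::sd(fit$data[[p]])
    if (x_sd == 0)
      stop(sprintf("predictor '%s' has zero variance", p), call. = FALSE)
    unname(fit$coefficients[p]) * x_sd / y_sd
  }, numeric(1))
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from regressing predictor j
#' on the remaining predictors (with intercept) over the level's complete
#' rows. A single-predictor model has VIF 1 by convention; perfect
#' collinearity is reported as `Inf`.
#'
#' @inheritParams fit_level_model
#' @return Named numeric vector of VIFs (always >= 1).
#' @export
vif_values <- function(table, level, predictors) {
  check_cohort(table, predictors)
  rows <- table[table$level == level, predictors, drop = FALSE]
  rows <- rows[stats::complete.cases(rows), , drop = FALSE]
  p <- length(predictors)
  if (nrow(rows) < p + 2L)
    stop("not enough complete rows for VIF computation", call. = FALSE)
  if (p == 1L) return(stats::setNames(1, predictors))
  vapply(predictors, function(pr) {
    others <- setdiff(predictors, pr)
    fml <- stats::reformulate(sprintf("`%s`", others),
                              response = sprintf("`%s`", pr))
    r2j <- summary(stats::lm(fml, data = rows))$r.squared
    if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }, numeric(1))
}

# fast OLS used inside the subset search; returns NULL on failure
ols_quick <- function(X, y, rmse_denominator = "n-p-1") {
  Xi <- cbind(1, X)
  n <- nrow(Xi); p <- ncol(Xi) - 1L
  if (n < p + 2L) return(NULL)
  fit <- stats::.lm.fit(Xi, y)
  if (fit$rank < ncol(Xi)) return(NULL)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  denom <- if (rmse_denominator == "n-p-1") n - p - 1L else n
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / denom))
}

#' All-possible-subsets predictor search
#'
#' Exhaustively enumerates every predictor subset of each requested size.
#' Each subset is scored by fitting the level-specific model at all five
#' spine levels and pooling the criterion across levels (default: mean R^2;
#' `"rmse"` pools mean RMSE and lower is better). A subset whose fit fails
#' at any level (rank deficiency, too few rows) is skipped and counted.
#' Criterion ties are broken towards the lexicographically smallest
#' predictor-name set.
#'
#' @inheritParams fit_level_model
#' @param candidates Character vector of candidate predictor columns.
#' @param sizes Subset sizes to search (default `c(1, 2, 4, 6, 8)`).
#' @param criterion `"r2"` (maximized, default) or `"rmse"` (minimized).
#' @param levels Spine levels pooled over (default all five).
#' @return An object of class `subset_search`: `best` (one row per size
#'   with the winning subset and pooled criteria), `ranking` (all
#'   enumerated subsets), and `n_enumerated`/`n_failed` bookkeeping.
#' @export
all_subsets_search <- function(table, candidates, sizes = c(1, 2, 4, 6, 8),
                               criterion = c("r2", "rmse"),
                               levels = lumbar_levels,
                               rmse_denominator = "n-p-1") {
  criterion <- match.arg(criterion)
  check_cohort(table, candidates)
  if (any(sizes < 1) || any(sizes > length(candidates)))
    stop("sizes must lie in 1..length(candidates)", call. = FALSE)

  # pre-split complete design matrices per level
  per_level <- lapply(levels, function(lev) {
    rows <- table[table$level == lev, c("age", candidates), drop = FALSE]
    rows <- rows[stats::complete.cases(rows), , drop = FALSE]
    list(X = as.matrix(rows[candidates]), y = rows$age)
  })
  names(per_level) <- levels

  ranking <- list()
  n_failed <- 0L
  for (k in sizes) {
    combos <- utils::combn(sort(candidates), k, simplify = FALSE)
    for (subset in combos) {
      r2s <- numeric(0); rmses <- numeric(0); failed <- FALSE
      for (lev in levels) {
        d <- per_level[[lev]]
        res <- ols_quick(d$X[, subset, drop = FALSE], d$y, rmse_denominator)
        if (is.null(res)) { failed <- TRUE; break }
        r2s <- c(r2s, res$r2); rmses <- c(rmses, res$rmse)
      }
      if (failed) { n_failed <- n_failed + 1L; next }
      ranking[[length(ranking) + 1L]] <- data.frame(
        size = k, subset = paste(subset, collapse = "+"),
        pooled_r2 = mean(r2s), pooled_rmse = mean(rmses))
    }
  }
  if (length(ranking) == 0L)
    stop("every enumerated subset failed to fit", call. = FALSE)
  ranking <- do.call(rbind, ranking)
  # order by criterion, then lexicographic subset name for ties
  key <- if (criterion == "r2") -ranking$pooled_r2 else ranking$pooled_rmse
  ranking <- ranking[order(ranking$size, key, ranking$subset), ]
  rownames(ranking) <- NULL
  best <- ranking[!duplicated(ranking$size), ]
  rownames(best) <- NULL
  structure(list(best = best, ranking = ranking, criterion = criterion,
                 sizes = sizes,
                 n_enumerated = nrow(ranking) + n_failed,
                 n_failed = n_failed),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("all-subsets search (%d subsets enumerated, %d failed), criterion %s:\n",
              x$n_enumerated, x$n_failed, x$criterion))
  print(x$best)
  invisible(x)
}

#' Fivefold (k-fold) cross-validation of a level model
#'
#' Rows of the level are shuffled with a mandatory seed and dealt
#' round-robin into k folds whose sizes differ by at most one. Each fold in
#' turn is held out: the model is fit on the remaining folds and the
#' validation RMSE (root mean squared prediction error on the held-out
#' rows) recorded. Model uncertainty is half the range of the fold RMSEs.
#'
#' @inheritParams fit_level_model
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment (mandatory, reported).
#' @return An object of class `cv_report`: `fold_rmse` (length k),
#'   `full_rmse` (all-data fit), `uncertainty_years`, `fold_sizes`, `seed`.
#' @export
kfold_cv <- function(table, level, predictors, k = 5L, seed,
                     rmse_denominator = "n-p-1") {
  if (missing(seed)) stop("a fold-assignment seed is required", call. = FALSE)
  check_cohort(table, predictors)
  rows <- table[table$level == level, c("age", predictors), drop = FALSE]
  rows <- rows[stats::complete.cases(rows), , drop = FALSE]
  n <- nrow(rows)
  if (n < 2L * k)
    stop(sprintf("need at least %d rows for %d-fold CV, have %d", 2L * k, k, n),
         call. = FALSE)

  ord <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[ord] <- rep(seq_len(k), length.out = n)

  fml <- stats::reformulate(sprintf("`%s`", predictors), response = "age")
  fold_rmse <- vapply(seq_len(k), function(f) {
    train <- rows[fold != f, , drop = FALSE]
    test <- rows[fold == f, , drop = FALSE]
    fit <- stats::lm(fml, data = train)
    pred <- stats::predict(fit, newdata = test)
    sqrt(mean((test$age - pred)^2))
  }, numeric(1))

  full <- fit_level_model(table, level, predictors,
                          rmse_denominator = rmse_denominator)
  structure(list(level = level, predictors = predictors, k = k,
                 fold_rmse = fold_rmse,
                 full_rmse = full$rmse_years,
                 uncertainty_years = diff(range(fold_rmse)) / 2,
                 fold_sizes = as.integer(base::table(fold)),
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV at %s (seed %d): fold RMSE %s years\n",
              x$k, x$level, x$seed,
              paste(sprintf("%.2f", x$fold_rmse), collapse = ", ")))
  cat(sprintf("full-data RMSE %.2f years, uncertainty +/- %.2f years\n",
              x$full_rmse, x$uncertainty_years))
  invisible(x)
}

#' Single-predictor screening
#'
#' Simple linear regression of age on each candidate in turn at one level,
#' ranked by R^2 (descending, ties broken alphabetically). Zero-variance
#' candidates are skipped and flagged.
#'
#' @inheritParams all_subsets_search
#' @return Data frame with columns `predictor`, `r2`, `slope`,
#'   `slope_sign`; skipped candidates in attribute `skipped`.
#' @export
screen_single_predictors <- function(table, level, candidates) {
  if (length(candidates) == 0L) {
    out <- data.frame(predictor = character(0), r2 = numeric(0),
                      slope = numeric(0), slope_sign = integer(0))
    attr(out, "skipped") <- character(0)
    return(out)
  }
  check_cohort(table, candidates)
  skipped <- character(0)
  res <- lapply(sort(candidates), function(p) {
    rows <- table[table$level == level, c("age", p), drop = FALSE]
    rows <- rows[stats::complete.cases(rows), , drop = FALSE]
    if (nrow(rows) < 3L || stats::sd(rows[[p]]) == 0) {
      skipped <<- c(skipped, p)
      return(NULL)
    }
    fit <- stats::lm(rows$age ~ rows[[p]])
    slope <- unname(stats::coef(fit)[2])
    data.frame(predictor = p, r2 = summary(fit)$r.squared,
               slope = slope, slope_sign = sign(slope))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(predictor = character(0), r2 = numeric(0),
                      slope = numeric(0), slope_sign = integer(0))
  else {
    out <- out[order(-out$r2, out$predictor), ]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}

check_cohort <- function(table, predictors) {
  if (!is.data.frame(table))
    stop("cohort table must be a data frame", call. = FALSE)
  missing <- setdiff(c("level", "age", predictors), names(table))
  if (length(missing))
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
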