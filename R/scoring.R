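#' The five lumbar disc levels
#'
#' Level labels used throughout the package, superior to inferior.
#' @export
lumbar_levels <- c("L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S1")

#' Level-specific effective-disc-age model coefficients
#'
#' One spine level's intercept and slopes for the four-predictor linear
#' model: effective age (years) = intercept + coef_t2 * NP T2 (ms) +
#' coef_height * subject height (inches) + coef_area * mid-sagittal disc
#' area (mm^2) + coef_volume * 3D disc volume (mm^3).
#'
#' @param level Level label, one of [lumbar_levels].
#' @param intercept Intercept in years.
#' @param coef_t2 Years per ms of nucleus pulposus T2 time.
#' @param coef_height Years per inch of subject height.
#' @param coef_area Years per mm^2 of mid-sagittal disc area.
#' @param coef_volume Years per mm^3 of 3D disc volume.
#' @param r2,rmse_years Optional fit metadata of the model these
#'   coefficients came from; `rmse_years` doubles as the default
#'   classification threshold.
#' @return An object of class `level_coefficients`.
#' @export
level_coefficients <- function(level, intercept, coef_t2, coef_height,
                               coef_area, coef_volume,
                               r2 = NA_real_, rmse_years = NA_real_) {
  if (!level %in% lumbar_levels)
    stop(sprintf("unknown level '%s' (expected one of %s)", level,
                 paste(lumbar_levels, collapse = ", ")), call. = FALSE)
  for (v in c(intercept, coef_t2, coef_height, coef_area, coef_volume))
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("all coefficients must be single non-missing numbers",
           call. = FALSE)
  structure(list(level = level, intercept = intercept, coef_t2 = coef_t2,
                 coef_height = coef_height, coef_area = coef_area,
                 coef_volume = coef_volume, r2 = r2,
                 rmse_years = rmse_years),
            class = "level_coefficients")
}

new_coefficient_set <- function(lst) {
  levels <- vapply(lst, `[[`, "", "level")
  if (anyDuplicated(levels))
    stop("duplicate level in coefficient set", call. = FALSE)
  if (!setequal(levels, lumbar_levels))
    stop(sprintf("coefficient set must cover exactly the five levels %s",
                 paste(lumbar_levels, collapse = ", ")), call. = FALSE)
  names(lst) <- levels
  structure(lst[lumbar_levels], class = "coefficient_set")
}

#' Packaged effective-disc-age coefficients
#'
#' The frozen level-specific four-predictor model shipped with the package
#' (intercepts, slopes, R^2 and RMSE for L1-L2 through L5-S1), read from
#' `extdata/effective_age_coefficients.json`.
#'
#' @return A `coefficient_set` of five [level_coefficients()].
#' @export
default_coefficients <- function() {
  load_coefficients(system.file("extdata", "effective_age_coefficients.json",
                                package = "discage", mustWork = TRUE))
}

#' Read / write a coefficient document
#'
#' JSON schema: an object keyed by level label, each entry holding
#' `intercept`, `coef_t2_per_ms`, `coef_height_per_inch`,
#' `coef_area_per_mm2`, `coef_volume_per_mm3` and optionally `r2`,
#' `rmse_years`. Save-then-load is an identity.
#'
#' @param path File path of the JSON document.
#' @return `load_coefficients()` returns a `coefficient_set`;
#'   `save_coefficients()` invisibly returns `path`.
#' @export
load_coefficients <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("intercept", "coef_t2_per_ms", "coef_height_per_inch",
                "coef_area_per_mm2", "coef_volume_per_mm3")
  lst <- lapply(names(doc), function(lev) {
    rec <- doc[[lev]]
    missing <- setdiff(required, names(rec))
    if (length(missing))
      stop(sprintf("level %s is missing field(s): %s", lev,
                   paste(missing, collapse = ", ")), call. = FALSE)
    level_coefficients(
      level = lev,
      intercept = rec$intercept,
      coef_t2 = rec$coef_t2_per_ms,
      coef_height = rec$coef_height_per_inch,
      coef_area = rec$coef_area_per_mm2,
      coef_volume = rec$coef_volume_per_mm3,
      r2 = if (is.null(rec$r2)) NA_real_ else rec$r2,
      rmse_years = if (is.null(rec$rmse_years)) NA_real_ else rec$rmse_years)
  })
  new_coefficient_set(lst)
}

#' @rdname load_coefficients
#' @param set A `coefficient_set`.
#' @export
save_coefficients <- function(set, path) {
  stopifnot(inherits(set, "coefficient_set"))
  doc <- lapply(set, function(cc) {
    list(intercept = cc$intercept,
         coef_t2_per_ms = cc$coef_t2,
         coef_height_per_inch = cc$coef_height,
         coef_area_per_mm2 = cc$coef_area,
         coef_volume_per_mm3 = cc$coef_volume,
         r2 = cc$r2, rmse_years = cc$rmse_years)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("effective disc age coefficients (per level):\n")
  df <- do.call(rbind, lapply(x, function(cc)
    data.frame(level = cc$level, intercept = cc$intercept,
               coef_t2 = cc$coef_t2, coef_height = cc$coef_height,
               coef_area = cc$coef_area, coef_volume = cc$coef_volume,
               r2 = cc$r2, rmse_years = cc$rmse_years)))
  rownames(df) <- NULL
  print(df)
  invisible(x)
}

#' The four model inputs for one disc
#'
#' @param level Level label.
#' @param np_t2 Nucleus pulposus T2 time in ms (> 0).
#' @param subject_height Subject standing height (> 0), in the units given
#'   by `height_units`; stored internally in inches (1 in = 2.54 cm).
#' @param midsag_area Mid-sagittal disc area in mm^2 (> 0).
#' @param volume 3D disc volume in mm^3 (> 0).
#' @param true_age Optional chronological age in years.
#' @param height_units `"in"` (default) or `"cm"`; no unit guessing.
#' @param test_mode Permit zero predictor values (flagged); used for
#'   coefficient-encoding checks, never for real discs.
#' @return An object of class `disc_predictors`.
#' @export
disc_predictors <- function(level, np_t2, subject_height, midsag_area, volume,
                            true_age = NULL,
                            height_units = c("in", "cm"),
                            test_mode = FALSE) {
  height_units <- match.arg(height_units)
  if (height_units == "cm") subject_height <- subject_height / 2.54
  if (!level %in% lumbar_levels)
    stop(sprintf("unknown level '%s'", level), call. = FALSE)
  vals <- c(np_t2 = np_t2, subject_height = subject_height,
            midsag_area = midsag_area, volume = volume)
  if (any(!is.finite(vals)))
    stop("predictors must be finite numbers", call. = FALSE)
  if (!test_mode && any(vals <= 0))
    stop("predictors must be strictly positive (use test_mode to allow zeros)",
         call. = FALSE)
  structure(list(level = level, np_t2 = np_t2,
                 subject_height = subject_height, midsag_area = midsag_area,
                 volume = volume, true_age = true_age,
                 test_mode = isTRUE(test_mode) && any(vals <= 0)),
            class = "disc_predictors")
}

#' Effective disc age of one disc
#'
#' The age at which normal aging would, on average, produce the disc's
#' observed phenotype: a level-specific linear combination of NP T2 time,
#' subject height, mid-sagittal area and volume.
#'
#' @param predictors A [disc_predictors()].
#' @param coefficients A [level_coefficients()] for the same level (by
#'   default taken from [default_coefficients()]).
#' @return Effective age in years. Values outside the 18-83 year development
#'   range are returned unclipped with attribute `out_of_range = TRUE`.
#' @export
effective_age <- function(predictors,
                          coefficients = default_coefficients()[[predictors$level]]) {
  stopifnot(inherits(predictors, "disc_predictors"),
            inherits(coefficients, "level_coefficients"))
  if (predictors$level != coefficients$level)
    stop(sprintf("level mismatch: predictors are %s, coefficients are %s",
                 predictors$level, coefficients$level), call. = FALSE)
  cc <- coefficients
  age <- cc$intercept + cc$coef_t2 * predictors$np_t2 +
    cc$coef_height * predictors$subject_height +
    cc$coef_area * predictors$midsag_area +
    cc$coef_volume * predictors$volume
  if (age < 18 || age > 83) attr(age, "out_of_range") <- TRUE
  age
}

#' Classify a disc by its age delta
#'
#' Delta = effective age - true age. A disc is `"accelerated"` when delta
#' strictly exceeds the threshold, `"younger-than-expected"` when delta is
#' strictly below minus the threshold, and `"normal"` otherwise (so a delta
#' exactly at the threshold is still normal).
#'
#' @param delta Age difference(s) in years.
#' @param threshold_years Positive threshold in years; the packaged default
#'   policy uses the level's model RMSE.
#' @return Character vector of classifications.
#' @export
classify_delta <- function(delta, threshold_years) {
  if (!is.numeric(threshold_years) || any(threshold_years <= 0))
    stop("threshold_years must be > 0", call. = FALSE)
  out <- rep("normal", length(delta))
  out[delta > threshold_years] <- "accelerated"
  out[delta < -threshold_years] <- "younger-than-expected"
  out[is.na(delta)] <- NA_character_
  out
}

#' Score a cohort table of disc observations
#'
#' Vectorized effective-age scoring plus normal-vs-accelerated
#' classification. Rows whose level is not covered by the coefficient set
#' are not fatal: they receive `NA` results and an error message in the
#' `error` column.
#'
#' @param table Data frame with columns `level`, `np_t2`, `subject_height`,
#'   `midsag_area`, `volume` and optionally `true_age` (plus any id
#'   columns, carried through).
#' @param coefficients A `coefficient_set` (default: the packaged model).
#' @param threshold_policy `"rmse"` (level-specific model RMSE, default) or
#'   `"fixed"` (use `threshold_years`).
#' @param threshold_years Fixed threshold in years when
#'   `threshold_policy = "fixed"`.
#' @param height_units `"in"` (default) or `"cm"` for the
#'   `subject_height` column.
#' @return The input table with columns `effective_age`, `delta`,
#'   `classification`, `threshold_years`, `out_of_range` and `error`
#'   appended; classification counts are attached as attribute `summary`
#'   and shown by `print`.
#' @export
score_cohort <- function(table, coefficients = default_coefficients(),
                         threshold_policy = c("rmse", "fixed"),
                         threshold_years = NULL,
                         height_units = c("in", "cm")) {
  threshold_policy <- match.arg(threshold_policy)
  height_units <- match.arg(height_units)
  stopifnot(inherits(coefficients, "coefficient_set"))
  needed <- c("level", "np_t2", "subject_height", "midsag_area", "volume")
  missing <- setdiff(needed, names(table))
  if (length(missing))
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (threshold_policy == "fixed" &&
      (is.null(threshold_years) || threshold_years <= 0))
    stop("fixed threshold policy requires threshold_years > 0", call. = FALSE)

  n <- nrow(table)
  out <- table
  out$effective_age <- rep(NA_real_, n)
  out$delta <- rep(NA_real_, n)
  out$classification <- rep(NA_character_, n)
  out$threshold_years <- rep(NA_real_, n)
  out$out_of_range <- rep(FALSE, n)
  out$error <- rep(NA_character_, n)
  if (n == 0L) return(structure(out, class = c("scored_cohort", class(out))))

  height_in <- if (height_units == "cm") table$subject_height / 2.54
               else table$subject_height
  # accept either a 'true_age' column or the cohort-table 'age' column
  if (!"true_age" %in% names(table) && "age" %in% names(table))
    table$true_age <- table$age
  has_age <- "true_age" %in% names(table)
  for (lev in unique(as.character(table$level))) {
    rows <- which(table$level == lev)
    if (!lev %in% names(coefficients)) {
      out$error[rows] <- sprintf("no coefficients for level '%s'", lev)
      next
    }
    cc <- coefficients[[lev]]
    eff <- cc$intercept + cc$coef_t2 * table$np_t2[rows] +
      cc$coef_height * height_in[rows] +
      cc$coef_area * table$midsag_area[rows] +
      cc$coef_volume * table$volume[rows]
    out$effective_age[rows] <- eff
    out$out_of_range[rows] <- !is.na(eff) & (eff < 18 | eff > 83)
    thr <- if (threshold_policy == "rmse") cc$rmse_years else threshold_years
    if (is.na(thr))
      out$error[rows] <- sprintf(
        "rmse threshold policy but no rmse_years for level '%s'", lev)
    out$threshold_years[rows] <- thr
    if (has_age && !is.na(thr)) {
      delta <- eff - table$true_age[rows]
      out$delta[rows] <- delta
      out$classification[rows] <- classify_delta(delta, thr)
    }
  }
  counts <- base::table(factor(out$classification,
                         levels = c("normal", "accelerated",
                                    "younger-than-expected")))
  attr(out, "summary") <- counts
  class(out) <- c("scored_cohort", class(table))
  out
}

#' @export
print.scored_cohort <- function(x, ...) {
  NextMethod()
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat("\nclassification counts:\n")
    print(s)
  }
  invisible(x)
}
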