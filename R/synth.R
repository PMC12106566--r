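#' Specification of a synthetic disc-aging cohort
#'
#' Describes the simulated study design: 84 subjects with latent ages drawn
#' uniformly over 18-83 years and balanced sex, five lumbar levels per
#' subject, level-specific predictor means that drift linearly with age
#' (nucleus T2 falling with age and with inferior level; geometry growing
#' inferiorly; disc height falling and width/area/volume/bulge rising with
#' age), and a planted forward model: the recorded age of each disc row is
#' regenerated as `intercept + sum(coef * predictor) + N(0, noise_sd)` from
#' the planted `coefficients`, so refitting recovers known ground truth.
#'
#' The disc-volume age slope is solved per level from the planted
#' coefficients so that the planted linear score rises with latent age at
#' rate `signal_slope` (years of effective age per year of latent age) and
#' is centred mid-range; this keeps regenerated ages inside `age_range`, so
#' range-clipping (which would bias coefficient recovery) stays negligible.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Latent-age range in years (uniform draw, and the
#'   clipping range for regenerated ages).
#' @param coefficients Planted `coefficient_set` (default: the packaged
#'   effective-age model).
#' @param noise_sd Residual SD of the regenerated age, years.
#' @param signal_slope Rate at which the planted score tracks latent age.
#' @param height_mean,height_sd Subject height distribution, inches
#'   (mean refers to a mid-range-age subject).
#' @param height_age_slope Cross-sectional height drift, inches per year of
#'   age (stature loss plus secular trend; negative).
#' @param t2_young Per-level NP T2 mean at age 18, ms.
#' @param t2_age_slope NP T2 drift, ms per year (negative).
#' @param t2_sd NP T2 scatter about its conditional mean, ms.
#' @param area_base Per-level mid-sagittal area mean at age 18, mm^2.
#' @param area_age_slope Area drift, mm^2 per year.
#' @param area_sd Area scatter about its conditional mean, mm^2.
#' @param volume_sd Volume scatter about its conditional mean, mm^3.
#' @param area_height_slope,volume_height_slope Allometric scaling of disc
#'   size with stature, mm^2 and mm^3 per inch of (age-adjusted) height.
#' @param volume_area_slope Coupling of volume to the non-stature part of
#'   area scatter, mm^3 per mm^2 (volume ~ area x disc depth).
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 84L,
                        age_range = c(18, 83),
                        coefficients = default_coefficients(),
                        noise_sd = 8.8,
                        signal_slope = 0.45,
                        height_mean = 67, height_sd = 3.5,
                        height_age_slope = -0.05,
                        t2_young = c("L1-L2" = 118, "L2-L3" = 115,
                                     "L3-L4" = 112, "L4-L5" = 106,
                                     "L5-S1" = 100),
                        t2_age_slope = -0.95, t2_sd = 6,
                        area_base = c("L1-L2" = 480, "L2-L3" = 510,
                                      "L3-L4" = 540, "L4-L5" = 570,
                                      "L5-S1" = 600),
                        area_age_slope = 0.8, area_sd = 25,
                        volume_sd = 700,
                        area_height_slope = 5,
                        volume_height_slope = 400,
                        volume_area_slope = 25,
                        seed) {
  if (missing(seed)) stop("cohort_spec requires a seed", call. = FALSE)
  stopifnot(inherits(coefficients, "coefficient_set"),
            length(age_range) == 2L, age_range[1] < age_range[2])
  if (noise_sd < 0 || t2_sd < 0 || area_sd < 0 || volume_sd < 0 ||
      height_sd < 0)
    stop("scatter/noise SDs must be nonnegative", call. = FALSE)
  if (!setequal(names(t2_young), lumbar_levels) ||
      !setequal(names(area_base), lumbar_levels))
    stop("t2_young and area_base must be named over the five lumbar levels",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 coefficients = coefficients, noise_sd = noise_sd,
                 signal_slope = signal_slope,
                 height_mean = height_mean, height_sd = height_sd,
                 height_age_slope = height_age_slope,
                 t2_young = t2_young[lumbar_levels],
                 t2_age_slope = t2_age_slope, t2_sd = t2_sd,
                 area_base = area_base[lumbar_levels],
                 area_age_slope = area_age_slope, area_sd = area_sd,
                 volume_sd = volume_sd,
                 area_height_slope = area_height_slope,
                 volume_height_slope = volume_height_slope,
                 volume_area_slope = volume_area_slope,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# per-level volume age slope and base solved from the planted coefficients
# so that the planted score has slope `signal_slope` in latent age and is
# centred at mid-range (see ?cohort_spec)
volume_trend <- function(spec) {
  a0 <- spec$age_range[1]
  mid <- mean(spec$age_range)
  out <- lapply(lumbar_levels, function(lev) {
    cc <- spec$coefficients[[lev]]
    slope <- (spec$signal_slope - cc$coef_t2 * spec$t2_age_slope -
                cc$coef_height * spec$height_age_slope -
                cc$coef_area * spec$area_age_slope) / cc$coef_volume
    t2_mid <- spec$t2_young[lev] + spec$t2_age_slope * (mid - a0)
    area_mid <- spec$area_base[lev] + spec$area_age_slope * (mid - a0)
    vol_mid <- (mid - cc$intercept - cc$coef_t2 * t2_mid -
                  cc$coef_height * spec$height_mean -
                  cc$coef_area * area_mid) / cc$coef_volume
    c(slope = unname(slope), base = unname(vol_mid - slope * (mid - a0)))
  })
  names(out) <- lumbar_levels
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws the cohort described by a [cohort_spec()]: predictors first, then
#' the recorded age regenerated from the planted linear model plus Gaussian
#' noise, clipped to the age range (clip count logged in the truth record).
#' Besides the four model predictors, twelve further candidate columns
#' (subject traits, disc geometry, regional T2 values) are generated with
#' age/level trends of the conventional signs, for use in predictor
#' screening and subset-search exercises.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synth_cohort`: `table` (one row per subject
#'   x level with columns `subject`, `sex`, `level`, `age` and 16 candidate
#'   predictors) and `truth` (planted coefficients, noise SD, per-predictor
#'   age trends, clip count, seed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  vt <- volume_trend(spec)
  a0 <- spec$age_range[1]

  with_seed(spec$seed, {
    n <- spec$n_subjects
    subject <- sprintf("S%03d", seq_len(n))
    sex <- sample(rep(c("F", "M"), length.out = n))
    latent <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    dh <- stats::rnorm(n, 0, spec$height_sd)  # stature deviation
    height <- spec$height_mean +
      spec$height_age_slope * (latent - mean(spec$age_range)) + dh
    weight <- -60 + 3.4 * height + stats::rnorm(n, 0, 18)
    bmi <- 703 * weight / height^2

    tab <- do.call(rbind, lapply(seq_along(lumbar_levels), function(li) {
      lev <- lumbar_levels[li]
      aa <- latent - a0
      np_t2 <- spec$t2_young[lev] + spec$t2_age_slope * aa +
        stats::rnorm(n, 0, spec$t2_sd)
      da <- stats::rnorm(n, 0, spec$area_sd)   # non-stature area scatter
      area <- spec$area_base[lev] + spec$area_age_slope * aa +
        spec$area_height_slope * dh + da
      volume <- vt[[lev]]["base"] + vt[[lev]]["slope"] * aa +
        spec$volume_height_slope * dh + spec$volume_area_slope * da +
        stats::rnorm(n, 0, spec$volume_sd)
      data.frame(
        subject = subject, sex = sex, level = lev,
        latent_age = latent,
        subject_height = height, subject_weight = weight, subject_bmi = bmi,
        np_t2 = np_t2, midsag_area = area, volume = volume,
        disc_height = 9 + 0.5 * (li - 1) - 0.02 * aa + stats::rnorm(n, 0, 0.8),
        disc_width = 38 + 2 * (li - 1) + 0.04 * aa + stats::rnorm(n, 0, 2),
        anterior_bulge = pmax(0, 4 + 0.8 * (li - 1) + 0.06 * aa +
                                stats::rnorm(n, 0, 2)),
        posterior_bulge = pmax(0, 3 + 0.5 * (li - 1) + 0.04 * aa +
                                 stats::rnorm(n, 0, 1.5)),
        wedge_angle = 2 + 1.6 * (li - 1) + 0.01 * aa + stats::rnorm(n, 0, 2),
        aaf_t2 = 42 + 0.12 * aa + stats::rnorm(n, 0, 5),
        paf_t2 = 40 + 0.12 * aa + stats::rnorm(n, 0, 5),
        atrans_t2 = 0.7 * spec$t2_young[lev] - 0.5 * aa +
          stats::rnorm(n, 0, 6),
        ptrans_t2 = 0.68 * spec$t2_young[lev] - 0.5 * aa +
          stats::rnorm(n, 0, 6),
        np_regional_t2 = np_t2 + stats::rnorm(n, 0, 4),
        row.names = NULL)
    }))

    # regenerate the recorded age from the planted forward model
    age <- numeric(nrow(tab))
    for (lev in lumbar_levels) {
      idx <- tab$level == lev
      cc <- spec$coefficients[[lev]]
      age[idx] <- cc$intercept + cc$coef_t2 * tab$np_t2[idx] +
        cc$coef_height * tab$subject_height[idx] +
        cc$coef_area * tab$midsag_area[idx] +
        cc$coef_volume * tab$volume[idx] +
        stats::rnorm(sum(idx), 0, spec$noise_sd)
    }
    clipped <- age < spec$age_range[1] | age > spec$age_range[2]
    age <- pmin(pmax(age, spec$age_range[1]), spec$age_range[2])
    tab$age <- age

    truth <- list(
      coefficients = spec$coefficients,
      noise_sd = spec$noise_sd,
      signal_slope = spec$signal_slope,
      trends = list(
        np_t2 = spec$t2_age_slope,
        subject_height = spec$height_age_slope,
        midsag_area = spec$area_age_slope,
        volume = stats::setNames(
          vapply(vt, `[[`, numeric(1), "slope"), lumbar_levels),
        disc_height = -0.02, disc_width = 0.04,
        anterior_bulge = 0.06, posterior_bulge = 0.04, wedge_angle = 0.01,
        aaf_t2 = 0.12, paf_t2 = 0.12, atrans_t2 = -0.5, ptrans_t2 = -0.5,
        np_regional_t2 = spec$t2_age_slope),
      n_clipped = sum(clipped),
      seed = spec$seed)
    if (truth$n_clipped > 0)
      message(sprintf("generate_cohort: %d of %d regenerated ages clipped to [%g, %g]",
                      truth$n_clipped, nrow(tab),
                      spec$age_range[1], spec$age_range[2]))
    structure(list(table = tab, truth = truth), class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d rows (%d subjects x %d levels), seed %d, %d ages clipped\n",
              nrow(x$table), length(unique(x$table$subject)),
              length(unique(x$table$level)), x$truth$seed,
              x$truth$n_clipped))
  invisible(x)
}

#' Inject accelerated-degeneration discs
#'
#' For a seeded random subset of rows, shifts every age-trended predictor
#' to its conditional-mean value at (latent age + `excess_years`) while
#' leaving the recorded true age unchanged -- emulating discs whose
#' phenotype is `excess_years` ahead of their chronology. Injected rows are
#' marked in a logical `accelerated_truth` column for downstream
#' sensitivity/specificity bookkeeping.
#'
#' @param cohort A `synth_cohort` from [generate_cohort()].
#' @param fraction Fraction of rows to inject, in `[0, 1]`.
#' @param excess_years Years of excess phenotype age (> 0).
#' @param seed Integer seed for the row selection.
#' @return The modified `synth_cohort`.
#' @export
inject_accelerated_discs <- function(cohort, fraction, excess_years, seed) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  if (excess_years <= 0) stop("excess_years must be > 0", call. = FALSE)
  tab <- cohort$table
  tab$accelerated_truth <- FALSE
  n_inject <- round(fraction * nrow(tab))
  if (n_inject > 0) {
    rows <- with_seed(seed, sample.int(nrow(tab), n_inject))
    tr <- cohort$truth$trends
    for (p in setdiff(names(tr), "volume"))
      tab[[p]][rows] <- tab[[p]][rows] + tr[[p]] * excess_years
    tab$volume[rows] <- tab$volume[rows] +
      tr$volume[as.character(tab$level[rows])] * excess_years
    tab$accelerated_truth[rows] <- TRUE
  }
  cohort$table <- tab
  cohort$truth$injection <- list(fraction = fraction,
                                 excess_years = excess_years, seed = seed,
                                 n_injected = n_inject)
  cohort
}

#' Specification of an analytic image phantom
#'
#' An ellipsoidal "disc" voxelized on a regular grid, with per-region T2
#' values laid out in five anterior-posterior bands, a mono-exponential
#' signal per voxel, optional Rician corruption, and four fiducial markers
#' bounding a trapezoidal interspace with known height and wedge angle.
#'
#' @param semi_axes Ellipsoid semi-axes in mm, `c(ap, si, lr)`
#'   (anterior-posterior, superior-inferior, left-right).
#' @param spacing Voxel spacing in mm (scalar isotropic or length 3).
#' @param t2_regions T2 in ms: either a single value or a named vector over
#'   `c("AAF","Atrans","NP","Ptrans","PAF")`.
#' @param boundary_fractions Band cut points as in [regional_t2()].
#' @param s0 Initial signal, arbitrary units.
#' @param noise_sigma Rician noise sigma (0 = noiseless).
#' @param echo_times Echo-time grid in ms.
#' @param interspace_width Fiducial segment span in mm (anterior fiducials
#'   sit at +width/2, posterior at -width/2).
#' @param gap_anterior,gap_posterior Half-gap between upper and lower
#'   fiducials at the anterior/posterior side, mm. Equal gaps give a
#'   rectangular interspace (wedge angle 0).
#' @param margin_mm Empty margin around the ellipsoid, mm.
#' @param grid_dim Optional fixed grid dimension (voxels, length 3); errors
#'   if the phantom does not fit.
#' @param seed Seed for the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes = c(ap = 20, si = 5, lr = 15),
                         spacing = 0.5,
                         t2_regions = 70,
                         boundary_fractions = c(0.15, 0.30, 0.70, 0.85),
                         s0 = 1000, noise_sigma = 0,
                         echo_times = default_echo_times(),
                         interspace_width = 44,
                         gap_anterior = 6, gap_posterior = 6,
                         margin_mm = 2, grid_dim = NULL, seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  region_labels <- c("AAF", "Atrans", "NP", "Ptrans", "PAF")
  if (length(t2_regions) == 1L && is.null(names(t2_regions)))
    t2_regions <- stats::setNames(rep(t2_regions, 5L), region_labels)
  if (!setequal(names(t2_regions), region_labels))
    stop("t2_regions must be a single value or named over AAF/Atrans/NP/Ptrans/PAF",
         call. = FALSE)
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0), all(spacing > 0),
            all(diff(echo_times) > 0), noise_sigma >= 0, s0 > 0,
            all(t2_regions > 0))
  structure(list(semi_axes = semi_axes, spacing = spacing,
                 t2_regions = t2_regions[region_labels],
                 boundary_fractions = boundary_fractions, s0 = s0,
                 noise_sigma = noise_sigma, echo_times = echo_times,
                 interspace_width = interspace_width,
                 gap_anterior = gap_anterior, gap_posterior = gap_posterior,
                 margin_mm = margin_mm, grid_dim = grid_dim,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate an analytic multi-echo phantom
#'
#' Voxelizes the ellipsoid (a voxel is inside when its centre satisfies the
#' ellipsoid equation), builds the mid-sagittal multi-echo magnitude stack
#' from `S0 * exp(-TE / T2(region))` with optional Rician corruption,
#' places the fiducial markers, and records the analytic ground truth
#' (volume 4/3*pi*abc, mid-sagittal area pi*a_ap*a_si, width 2*a_ap, and
#' the constructed interspace height and wedge angle).
#'
#' @param spec A [phantom_spec()].
#' @return A list: `mask` ([segmentation_mask()]), `stack` (mid-sagittal
#'   multi-echo array with `echo_times` attribute), `fiducials`
#'   ([fiducial_set()]), `truth` (analytic values), `origin_mm` (mm
#'   coordinate of the array corner; fiducials are expressed in the
#'   canonical voxel-centre frame used by the morphometry functions).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- spec$semi_axes; sp <- spec$spacing
  half_extent <- ax + spec$margin_mm
  dims <- unname(ceiling(2 * half_extent / sp))
  if (!is.null(spec$grid_dim)) {
    if (any(spec$grid_dim < dims))
      stop("phantom exceeds the requested grid dimensions", call. = FALSE)
    dims <- spec$grid_dim
  }
  # voxel-centre coordinates, ellipsoid centred on the grid
  coord <- lapply(1:3, function(d) ((seq_len(dims[d]) - 0.5) * sp[d]) -
                    dims[d] * sp[d] / 2)
  xa <- coord[[1]] / ax[1]; xs <- coord[[2]] / ax[2]; xl <- coord[[3]] / ax[3]
  inside <- outer(outer(xa^2, xs^2, `+`), xl^2, `+`) <= 1
  midsag_k <- which.min(abs(coord[[3]]))
  mask <- segmentation_mask(inside, spacing = sp, midsag_slice = midsag_k)

  # mid-sagittal multi-echo stack with banded T2
  sl <- inside[, , midsag_k]
  t2map <- matrix(NA_real_, nrow = dims[1], ncol = dims[2])
  if (any(sl)) {
    vox <- which(sl, arr.ind = TRUE)
    a_lo <- min(vox[, 1]); a_hi <- max(vox[, 1])
    frac <- (a_hi + 0.5 - vox[, 1]) / (a_hi - a_lo + 1)
    band <- cut(frac, breaks = c(-Inf, spec$boundary_fractions, Inf),
                labels = names(spec$t2_regions))
    t2map[vox] <- spec$t2_regions[as.character(band)]
  }
  stack <- array(0, dim = c(dims[1], dims[2], length(spec$echo_times)))
  for (e in seq_along(spec$echo_times)) {
    img <- matrix(0, dims[1], dims[2])
    in_sl <- !is.na(t2map)
    img[in_sl] <- spec$s0 * exp(-spec$echo_times[e] / t2map[in_sl])
    stack[, , e] <- img
  }
  if (spec$noise_sigma > 0)
    stack <- array(rician_noise(as.vector(stack), spec$noise_sigma,
                                seed = spec$seed), dim = dim(stack))
  attr(stack, "echo_times") <- spec$echo_times

  # fiducials in the voxel-centre mm frame (array corner at 0)
  ctr <- dims[1:2] * sp[1:2] / 2
  w2 <- spec$interspace_width / 2
  fid <- fiducial_set(
    upper_anterior = ctr + c(w2, spec$gap_anterior),
    upper_posterior = ctr + c(-w2, spec$gap_posterior),
    lower_anterior = ctr + c(w2, -spec$gap_anterior),
    lower_posterior = ctr + c(-w2, -spec$gap_posterior))

  w <- spec$interspace_width
  dh <- spec$gap_anterior - spec$gap_posterior
  area_quad <- w * (spec$gap_anterior + spec$gap_posterior)
  seg <- sqrt(w^2 + dh^2)
  truth <- list(volume = 4 / 3 * pi * prod(ax),
                midsag_area = pi * ax[1] * ax[2],
                width = 2 * ax[1],
                height = area_quad / seg,
                wedge_angle = 2 * atan2(dh, w) * 180 / pi,
                t2_regions = spec$t2_regions, s0 = spec$s0)
  list(mask = mask, stack = stack, fiducials = fid, truth = truth,
       origin_mm = c(0, 0, 0))
}

#' Rician-corrupt a magnitude signal
#'
#' Returns `sqrt((s + g1)^2 + g2^2)` with `g1`, `g2` independent
#' `N(0, sigma)` -- the magnitude of a complex signal with Gaussian noise
#' in both channels. With `s = 0` the output is Rayleigh with mean
#' `sigma * sqrt(pi / 2)`.
#'
#' @param signal Nonnegative numeric vector.
#' @param sigma Noise SD (>= 0); 0 returns the signal unchanged.
#' @param seed Optional integer seed.
#' @return Nonnegative numeric vector of the same length.
#' @export
rician_noise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  if (sigma == 0) return(signal)
  with_seed(seed, {
    n <- length(signal)
    sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  })
}
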