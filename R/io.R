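#' Read a multi-echo NIfTI stack with its echo-time sidecar
#'
#' Accepts either a single 3D/4D NIfTI whose last dimension indexes echoes,
#' or one file per echo (all the same shape). Echo times come from a JSON
#' sidecar containing an `echo_times_ms` array.
#'
#' @param paths Character vector of NIfTI path(s).
#' @param sidecar Path to the JSON sidecar (default: first path with its
#'   extension replaced by `.json`).
#' @return A 3D array `[row, col, echo]` with attribute `echo_times`,
#'   ready for [extract_roi_decay()] / [regional_t2()].
#' @export
read_echo_stack <- function(paths, sidecar = NULL) {
  if (is.null(sidecar))
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", paths[1])
  if (!file.exists(sidecar))
    stop("echo-time sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$echo_times_ms))
    stop("sidecar must contain an 'echo_times_ms' array", call. = FALSE)
  et <- as.numeric(meta$echo_times_ms)

  if (length(paths) == 1L) {
    img <- RNifti::readNifti(paths)
    arr <- as.array(img)
    d <- dim(arr)
    if (length(d) == 4L) {
      if (d[3] == 1L) arr <- array(arr, dim = d[c(1, 2, 4)])
      else stop("4D stack must be a single slice per echo", call. = FALSE)
    }
    if (length(dim(arr)) != 3L)
      stop("expected a 2D-slice-by-echo stack", call. = FALSE)
  } else {
    slices <- lapply(paths, function(p) {
      a <- as.array(RNifti::readNifti(p))
      if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1]
      if (length(dim(a)) != 2L)
        stop("per-echo files must each hold one 2D slice", call. = FALSE)
      a
    })
    arr <- array(unlist(slices), dim = c(dim(slices[[1]]), length(slices)))
  }
  if (dim(arr)[3] != length(et))
    stop(sprintf("stack has %d echoes but sidecar lists %d echo times",
                 dim(arr)[3], length(et)), call. = FALSE)
  attr(arr, "echo_times") <- et
  arr
}

#' Read a segmentation mask from NIfTI
#'
#' @param path NIfTI path.
#' @param midsag_slice Mid-sagittal slice index (1-based) along the
#'   left-right axis; defaults to the slice with the most segmented voxels.
#' @param convention An [axis_convention()] for the raw array.
#' @param label Optional label to select from a multi-label segmentation.
#' @return A [segmentation_mask()] (spacing taken from the NIfTI header).
#' @export
read_mask_nifti <- function(path, midsag_slice = NULL,
                            convention = axis_convention("+1", "+2"),
                            label = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("segmentation mask must be a 3D volume", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  if (is.null(midsag_slice)) {
    lr_axis <- setdiff(1:3, c(convention$anterior$axis,
                              convention$superior$axis))
    counts <- apply(arr != 0, lr_axis, sum)
    midsag_slice <- which.max(counts)
  }
  segmentation_mask(arr, spacing = spacing, midsag_slice = midsag_slice,
                    convention = convention, label = label)
}

#' Read / write fiducial markers
#'
#' CSV schema: columns `point` (`ua`, `up`, `la`, `lp`), `anterior_mm`,
#' `superior_mm`; JSON schema: an object with those four keys each holding
#' `[anterior_mm, superior_mm]`.
#'
#' @param path CSV or JSON file path (by extension).
#' @return A [fiducial_set()].
#' @export
read_fiducials <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- lapply(c("ua", "up", "la", "lp"), function(k) {
      if (is.null(doc[[k]]))
        stop("fiducial JSON missing point '", k, "'", call. = FALSE)
      as.numeric(doc[[k]])
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("point", "anterior_mm", "superior_mm")
    if (!all(need %in% names(df)))
      stop("fiducial CSV needs columns point, anterior_mm, superior_mm",
           call. = FALSE)
    pts <- lapply(c("ua", "up", "la", "lp"), function(k) {
      row <- df[df$point == k, ]
      if (nrow(row) != 1L)
        stop("fiducial CSV must contain exactly one row for point '", k, "'",
             call. = FALSE)
      c(row$anterior_mm, row$superior_mm)
    })
  }
  fiducial_set(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

#' @rdname read_fiducials
#' @param fiducials A [fiducial_set()].
#' @export
write_fiducials <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  df <- data.frame(point = c("ua", "up", "la", "lp"),
                   anterior_mm = vapply(fiducials[c("ua", "up", "la", "lp")],
                                        `[`, numeric(1), 1),
                   superior_mm = vapply(fiducials[c("ua", "up", "la", "lp")],
                                        `[`, numeric(1), 2))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a phantom to NIfTI plus JSON sidecars
#'
#' Emits `mask.nii.gz`, `echoes.nii.gz`, `echoes.json` (echo times),
#' `fiducials.csv` and `truth.json` into a directory.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask <- phantom$mask
  mimg <- RNifti::asNifti(array(as.integer(mask$array), dim = dim(mask$array)))
  RNifti::pixdim(mimg) <- mask$spacing
  RNifti::writeNifti(mimg, file.path(dir, "mask.nii.gz"))
  st <- phantom$stack
  RNifti::writeNifti(RNifti::asNifti(array(st, dim = dim(st))),
                     file.path(dir, "echoes.nii.gz"))
  jsonlite::write_json(list(echo_times_ms = attr(st, "echo_times")),
                       file.path(dir, "echoes.json"), auto_unbox = FALSE,
                       digits = NA)
  write_fiducials(phantom$fiducials, file.path(dir, "fiducials.csv"))
  jsonlite::write_json(phantom$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read / write a cohort table
#'
#' Thin CSV wrappers kept for a stable on-disk contract: `level` must be
#' one of the five lumbar labels and `age` numeric.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv()` returns a data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("level" %in% names(df)) {
    bad <- setdiff(unique(df$level), lumbar_levels)
    if (length(bad))
      warning("unknown level label(s): ", paste(bad, collapse = ", "),
              call. = FALSE)
  }
  df
}

#' @rdname read_cohort_csv
#' @param table Data frame to write.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
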