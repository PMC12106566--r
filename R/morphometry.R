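#' Disc segmentation mask with physical spacing
#'
#' Wraps a 3D binary segmentation so all downstream geometry is computed in
#' physical units and in the canonical anatomical orientation (axis 1
#' anterior, axis 2 superior, axis 3 left-right).
#'
#' @param array3d 3D logical/0-1 array (or labelled integers, see `label`).
#' @param spacing Voxel spacing in mm per raw array axis (length 3, > 0).
#' @param midsag_slice Mid-sagittal slice index (1-based, along the
#'   left-right axis of the raw array).
#' @param convention An [axis_convention()] naming the anterior and superior
#'   raw axes; the remaining axis is left-right.
#' @param label Optional integer label to select from a multi-label mask.
#' @return An object of class `segmentation_mask` holding the canonical
#'   array, reordered spacing and mid-sagittal index.
#' @export
segmentation_mask <- function(array3d, spacing, midsag_slice,
                              convention = axis_convention("+1", "+2"),
                              label = NULL) {
  stopifnot(length(dim(array3d)) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive",
                              call. = FALSE)
  m <- if (is.null(label)) array3d != 0 else array3d == label
  if (!any(m)) stop("segmentation mask is empty", call. = FALSE)
  can <- canonicalize_volume(m, convention)
  lr_axis <- can$perm[3]
  if (midsag_slice < 1L || midsag_slice > dim(array3d)[lr_axis])
    stop("midsag_slice index out of bounds", call. = FALSE)
  structure(list(array = can$array,
                 spacing = spacing[can$perm],
                 midsag_slice = as.integer(midsag_slice)),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation mask: %s voxels of %s at %.3gx%.3gx%.3g mm, mid-sagittal slice %d\n",
              format(sum(x$array), big.mark = ","),
              paste(dim(x$array), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3], x$midsag_slice))
  invisible(x)
}

midsag <- function(mask) mask$array[, , mask$midsag_slice]

#' Four vertebral-body fiducial markers bounding the disc interspace
#'
#' Points are given in mm in the mid-sagittal plane, in canonical
#' coordinates `c(anterior, superior)` -- the same frame as voxel centres of
#' a canonicalized [segmentation_mask()] (voxel centre = (index - 0.5) *
#' spacing).
#'
#' @param upper_anterior,upper_posterior Points on the vertebral body above.
#' @param lower_anterior,lower_posterior Points on the vertebral body below.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(upper_anterior, upper_posterior,
                         lower_anterior, lower_posterior) {
  pts <- list(ua = as.numeric(upper_anterior), up = as.numeric(upper_posterior),
              la = as.numeric(lower_anterior), lp = as.numeric(lower_posterior))
  if (any(vapply(pts, length, 1L) != 2L))
    stop("each fiducial must be a 2D point c(anterior_mm, superior_mm)",
         call. = FALSE)
  cmb <- utils::combn(names(pts), 2)
  for (k in seq_len(ncol(cmb))) {
    d <- pts[[cmb[1, k]]] - pts[[cmb[2, k]]]
    if (sqrt(sum(d^2)) < 1e-9)
      stop(sprintf("fiducials '%s' and '%s' coincide", cmb[1, k], cmb[2, k]),
           call. = FALSE)
  }
  structure(pts, class = "fiducial_set")
}

#' Disc volume from the segmentation
#'
#' True-voxel count times the unit voxel volume.
#' @param mask A [segmentation_mask()].
#' @return Volume in mm^3.
#' @export
compute_volume <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  sum(mask$array) * prod(mask$spacing)
}

#' Mid-sagittal disc area
#'
#' True-voxel count in the mid-sagittal slice times the unit in-plane voxel
#' area.
#' @inheritParams compute_volume
#' @return Area in mm^2.
#' @export
compute_midsag_area <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  sl <- midsag(mask)
  if (!any(sl))
    stop("mid-sagittal slice contains no segmented voxels (mask nonempty elsewhere)",
         call. = FALSE)
  sum(sl) * prod(mask$spacing[1:2])
}

#' Anterior-posterior disc width at mid-height
#'
#' Mid-height is the midpoint of the superior-inferior extent of the masked
#' mid-sagittal region; the width is the anterior-posterior span of the mask
#' at that row, in mm. If the mid-height row is empty the nearest nonempty
#' row is used and flagged (attribute `fallback_row`).
#'
#' @inheritParams compute_volume
#' @return Width in mm.
#' @export
compute_width <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  sl <- midsag(mask)
  if (!any(sl))
    stop("mid-sagittal slice contains no segmented voxels", call. = FALSE)
  s_any <- which(apply(sl, 2, any))
  mid_s <- round(mean(range(s_any)))
  fallback <- FALSE
  if (!any(sl[, mid_s])) {
    mid_s <- s_any[which.min(abs(s_any - mid_s))]
    fallback <- TRUE
  }
  a_idx <- which(sl[, mid_s])
  w <- (max(a_idx) - min(a_idx) + 1L) * mask$spacing[1]
  if (fallback) attr(w, "fallback_row") <- mid_s
  w
}

shoelace_area <- function(p) {
  # p: list of 2D points in order
  n <- length(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + p[[i]][1] * p[[j]][2] - p[[j]][1] * p[[i]][2]
  }
  abs(s) / 2
}

segments_intersect <- function(p1, p2, q1, q2) {
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  d1 <- cross(q1, q2, p1); d2 <- cross(q1, q2, p2)
  d3 <- cross(p1, p2, q1); d4 <- cross(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Disc height from the interspace quadrilateral
#'
#' The interspace is the quadrilateral upper-anterior, upper-posterior,
#' lower-posterior, lower-anterior. Height = shoelace area of that
#' quadrilateral divided by the interspace width, where the width is taken
#' as the mean of the upper and lower fiducial segment lengths (this reduces
#' to the obvious width for a rectangular interspace).
#'
#' @param fiducials A [fiducial_set()].
#' @return Height in mm.
#' @export
compute_height <- function(fiducials) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  f <- fiducials
  quad <- list(f$ua, f$up, f$lp, f$la)
  if (segments_intersect(f$ua, f$up, f$lp, f$la) ||
      segments_intersect(f$up, f$lp, f$la, f$ua))
    stop("fiducial quadrilateral is self-intersecting", call. = FALSE)
  area <- shoelace_area(quad)
  w_upper <- sqrt(sum((f$ua - f$up)^2))
  w_lower <- sqrt(sum((f$la - f$lp)^2))
  width <- (w_upper + w_lower) / 2
  if (width < 1e-9) stop("interspace width is zero", call. = FALSE)
  area / width
}

# unit normal of the line p1->p2, oriented towards `towards` (+1 anterior,
# -1 posterior). Errors if the line is parallel to the anterior axis.
oriented_normal <- function(p1, p2, towards) {
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("fiducial line has zero length", call. = FALSE)
  u <- c(-d[2], d[1]) / len
  a_comp <- u[1]  # anterior component
  if (abs(a_comp) < 1e-12)
    stop("fiducial line is parallel to the anterior axis; bulge side undefined",
         call. = FALSE)
  if (sign(a_comp) != sign(towards)) u <- -u
  u
}

#' Anterior and posterior disc bulge areas
#'
#' Bulge is the masked mid-sagittal area lying strictly outside the
#' interspace: anterior of the line through the two anterior fiducials, and
#' posterior of the line through the two posterior fiducials. Voxels are
#' classified by the signed distance of their centre; centres exactly on a
#' line count as inside the interspace.
#'
#' @inheritParams compute_volume
#' @inheritParams compute_height
#' @return Named numeric `c(anterior = ..., posterior = ...)` in mm^2.
#' @export
compute_bulge <- function(mask, fiducials) {
  stopifnot(inherits(mask, "segmentation_mask"),
            inherits(fiducials, "fiducial_set"))
  sl <- midsag(mask)
  if (!any(sl))
    stop("mid-sagittal slice contains no segmented voxels", call. = FALSE)
  vox <- which(sl, arr.ind = TRUE)
  centers <- cbind((vox[, 1] - 0.5) * mask$spacing[1],
                   (vox[, 2] - 0.5) * mask$spacing[2])
  f <- fiducials
  n_ant <- oriented_normal(f$ua, f$la, towards = +1)
  n_post <- oriented_normal(f$up, f$lp, towards = -1)
  d_ant <- (centers[, 1] - f$ua[1]) * n_ant[1] +
    (centers[, 2] - f$ua[2]) * n_ant[2]
  d_post <- (centers[, 1] - f$up[1]) * n_post[1] +
    (centers[, 2] - f$up[2]) * n_post[2]
  px_area <- prod(mask$spacing[1:2])
  c(anterior = sum(d_ant > 0) * px_area,
    posterior = sum(d_post > 0) * px_area)
}

#' Disc wedge angle
#'
#' Signed angle between the superior and inferior fiducial segments,
#' positive when the interspace opens anteriorly (a lordotic wedge). The
#' angle is computed as the difference of the posterior-to-anterior segment
#' directions of the upper and lower vertebral bodies, so it is invariant
#' under a common rigid rotation of all four markers.
#'
#' @inheritParams compute_height
#' @return Angle in degrees, in (-180, 180].
#' @export
compute_wedge_angle <- function(fiducials) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  f <- fiducials
  u <- f$ua - f$up   # upper body, posterior -> anterior
  v <- f$la - f$lp   # lower body, posterior -> anterior
  ang <- (atan2(u[2], u[1]) - atan2(v[2], v[1])) * 180 / pi
  if (ang > 180) ang <- ang - 360
  if (ang <= -180) ang <- ang + 360
  ang
}

#' All disc geometry measures for one disc
#'
#' Aggregates [compute_volume()], [compute_midsag_area()], [compute_width()],
#' [compute_height()], [compute_bulge()] and [compute_wedge_angle()];
#' component failures are recorded per field rather than aborting.
#'
#' @inheritParams compute_bulge
#' @return An object of class `disc_geometry` with fields `volume`,
#'   `midsag_area`, `width`, `height`, `anterior_bulge`, `posterior_bulge`,
#'   `wedge_angle` (each `NA` on failure) and a `flags` character vector.
#' @export
derive_geometry <- function(mask, fiducials) {
  flags <- character(0)
  grab <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      flags <<- c(flags, sprintf("%s: %s", what, conditionMessage(e)))
      NA_real_
    })
  }
  vol <- grab("volume", compute_volume(mask))
  area <- grab("midsag_area", compute_midsag_area(mask))
  width <- grab("width", as.numeric(compute_width(mask)))
  height <- grab("height", compute_height(fiducials))
  bulge <- grab("bulge", compute_bulge(mask, fiducials))
  wedge <- grab("wedge_angle", compute_wedge_angle(fiducials))
  if (length(bulge) == 1L && is.na(bulge)) bulge <- c(anterior = NA_real_,
                                                      posterior = NA_real_)
  structure(list(volume = vol, midsag_area = area, width = width,
                 height = height,
                 anterior_bulge = unname(bulge["anterior"]),
                 posterior_bulge = unname(bulge["posterior"]),
                 wedge_angle = wedge, flags = flags),
            class = "disc_geometry")
}

#' @export
print.disc_geometry <- function(x, ...) {
  cat("disc geometry:\n")
  cat(sprintf("  volume          %10.1f mm^3\n", x$volume))
  cat(sprintf("  mid-sag area    %10.1f mm^2\n", x$midsag_area))
  cat(sprintf("  width           %10.2f mm\n", x$width))
  cat(sprintf("  height          %10.2f mm\n", x$height))
  cat(sprintf("  anterior bulge  %10.2f mm^2\n", x$anterior_bulge))
  cat(sprintf("  posterior bulge %10.2f mm^2\n", x$posterior_bulge))
  cat(sprintf("  wedge angle     %10.2f deg\n", x$wedge_angle))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.disc_geometry <- function(x, ...) {
  data.frame(volume = x$volume, midsag_area = x$midsag_area, width = x$width,
             height = x$height, anterior_bulge = x$anterior_bulge,
             posterior_bulge = x$posterior_bulge, wedge_angle = x$wedge_angle,
             flags = paste(x$flags, collapse = "; "))
}
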