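test_that("volume and area are voxel counts times unit measure", {
  m <- box_mask(c(12, 12, 12), a = c(2, 11), s = c(2, 11), l = c(2, 11))
  expect_equal(compute_volume(m), 1000)

  m2 <- box_mask(c(12, 12, 12), a = c(2, 11), s = c(2, 11), l = c(2, 11),
                 spacing = c(0.5, 0.5, 2))
  expect_equal(compute_volume(m2), 500)

  # 10x10 mid-sagittal square at 1 mm
  expect_equal(compute_midsag_area(m), 100)

  expect_error(segmentation_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1), 2),
               "empty")
  # nonempty volume but empty mid-sagittal slice: distinct error
  arr <- array(FALSE, c(6, 6, 6)); arr[2:4, 2:4, 1] <- TRUE
  m3 <- segmentation_mask(arr, c(1, 1, 1), midsag_slice = 4)
  expect_error(compute_midsag_area(m3), "mid-sagittal")
  expect_equal(compute_volume(m3), 9)
})

test_that("width is the anterior-posterior span at mid-height", {
  m <- box_mask(c(50, 20, 5), a = c(4, 43), s = c(5, 14))
  expect_equal(as.numeric(compute_width(m)), 40)
  m2 <- box_mask(c(50, 20, 5), a = c(4, 43), s = c(5, 14),
                 spacing = c(0.6, 0.6, 1))
  expect_equal(as.numeric(compute_width(m2)), 24)
})

test_that("interspace height and wedge angle follow the fiducial geometry", {
  # rectangle 40 wide x 10 tall
  f <- rect_fiducials(40, 5)
  expect_equal(compute_height(f), 10)
  expect_equal(compute_wedge_angle(f), 0)

  # trapezoid: anterior gap 8, posterior gap 12, widths 40 -> area 400
  ft <- rect_fiducials(40, ha = 4, hp = 6)
  w_seg <- sqrt(40^2 + 2^2)  # fiducial segments tilt by the gap difference
  expect_equal(compute_height(ft), 400 / w_seg)

  # constructed 10 degree anterior opening about the posterior ends
  up <- c(-20, 6); la0 <- c(-20, -6)
  th <- -10 * pi / 180
  la <- la0 + 40 * c(cos(th), sin(th))
  f10 <- fiducial_set(c(20, 6), up, la, la0)
  expect_equal(compute_wedge_angle(f10), 10, tolerance = 1e-10)

  # invariance under a common rigid rotation of all four markers
  rot <- function(p, phi) c(cos(phi) * p[1] - sin(phi) * p[2],
                            sin(phi) * p[1] + cos(phi) * p[2])
  fr <- fiducial_set(rot(c(20, 6), 0.4), rot(up, 0.4),
                     rot(la, 0.4), rot(la0, 0.4))
  expect_equal(compute_wedge_angle(fr), 10, tolerance = 1e-10)
  expect_equal(compute_height(fr), compute_height(f10), tolerance = 1e-10)

  expect_error(fiducial_set(c(0, 0), c(0, 0), c(1, 1), c(2, 2)), "coincide")
  # bow-tie ordering is rejected
  expect_error(compute_height(fiducial_set(c(1, 1), c(-1, -1),
                                           c(1, -1), c(-1, 1))),
               "self-intersecting")
})

test_that("bulge counts masked area strictly outside the interspace lines", {
  # 20-column rectangle centred; anterior fiducial line leaves a 2-column
  # overhang over 10 rows -> anterior bulge 20 mm^2
  arr <- array(FALSE, c(30, 20, 3))
  arr[6:25, 6:15, 2] <- TRUE  # anterior voxel centres at 5.5..24.5 mm
  m <- box_mask(c(30, 20, 3), a = c(6, 25), s = c(6, 15))
  f_in <- fiducial_set(c(28, 15), c(2, 15), c(28, 5), c(2, 5))
  expect_equal(unname(compute_bulge(m, f_in)), c(0, 0))

  f_cut <- fiducial_set(c(22.5, 15), c(2, 15), c(22.5, 5), c(2, 5))
  b <- compute_bulge(m, f_cut)
  expect_equal(unname(b["anterior"]), 2 * 10)
  expect_equal(unname(b["posterior"]), 0)

  # voxel centres exactly on the line count as inside (half-open rule)
  f_edge <- fiducial_set(c(24.5, 15), c(2, 15), c(24.5, 5), c(2, 5))
  expect_equal(unname(compute_bulge(m, f_edge)["anterior"]), 0)

  # symmetric overhang on a symmetric mask (centres 5.5..24.5, midpoint 15)
  f_sym <- fiducial_set(c(23.5, 15), c(6.5, 15), c(23.5, 5), c(6.5, 5))
  bs <- compute_bulge(m, f_sym)
  expect_equal(unname(bs["anterior"]), unname(bs["posterior"]))
})

test_that("ellipsoid phantom measures converge to the analytic values", {
  rel_errs <- function(axes, h) {
    ph <- generate_phantom(phantom_spec(semi_axes = axes, spacing = h))
    c(vol = abs(compute_volume(ph$mask) - ph$truth$volume) / ph$truth$volume,
      area = abs(compute_midsag_area(ph$mask) - ph$truth$midsag_area) /
        ph$truth$midsag_area,
      width = abs(as.numeric(compute_width(ph$mask)) - ph$truth$width))
  }

  # canonical 20 x 5 x 15 mm phantom: within 2% of the closed forms at
  # 0.5 mm; width within one voxel
  e05 <- rel_errs(c(20, 5, 15), 0.5)
  expect_lt(e05[["vol"]], 0.02)
  expect_lt(e05[["area"]], 0.02)
  expect_lte(e05[["width"]], 0.5)

  # refinement study on a grid-incommensurate ellipsoid (integer-mm axes
  # alias against the voxel lattice: the 20 x 5 x 15 count at 0.25 mm is
  # exactly 8x its 0.5 mm count, so its error plateaus by coincidence)
  errs <- sapply(c(1.0, 0.5, 0.25), function(h)
    rel_errs(c(19.7, 5.3, 14.9), h))
  expect_true(all(diff(errs["vol", ]) < 0))
  expect_true(all(diff(errs["area", ]) < 0))
  expect_true(all(diff(errs["width", ]) <= 0))
})

test_that("geometry respects spacing rescale and axis relabeling", {
  phm <- generate_phantom(phantom_spec(spacing = 1))$mask
  arr <- phm$array; ms <- phm$midsag_slice
  m1 <- segmentation_mask(arr, c(1, 1, 1), midsag_slice = ms)
  m2 <- segmentation_mask(arr, c(2, 2, 2), midsag_slice = ms)
  expect_equal(compute_volume(m2), 8 * compute_volume(m1))
  expect_equal(compute_midsag_area(m2), 4 * compute_midsag_area(m1))
  expect_equal(as.numeric(compute_width(m2)), 2 * as.numeric(compute_width(m1)))

  # permute the raw axes and declare the permutation: outputs unchanged
  arrp <- aperm(arr, c(3, 1, 2))         # now [lr, anterior, superior]
  arrp <- arrp[, rev(seq_len(dim(arrp)[2])), ]  # flip the anterior axis
  mp <- segmentation_mask(arrp, c(1, 1, 1)[c(3, 1, 2)], midsag_slice = ms,
                          convention = axis_convention("-2", "+3"))
  expect_equal(compute_volume(mp), compute_volume(m1))
  expect_equal(compute_midsag_area(mp), compute_midsag_area(m1))
  expect_equal(as.numeric(compute_width(mp)), as.numeric(compute_width(m1)))
})

test_that("derive_geometry aggregates measures and collects flags", {
  ph <- generate_phantom(phantom_spec(spacing = 0.5))
  g <- derive_geometry(ph$mask, ph$fiducials)
  expect_s3_class(g, "disc_geometry")
  expect_equal(g$volume, compute_volume(ph$mask))
  expect_equal(g$height, ph$truth$height, tolerance = 1e-10)
  expect_equal(g$wedge_angle, ph$truth$wedge_angle, tolerance = 1e-10)
  expect_equal(g$anterior_bulge, 0)
  expect_length(g$flags, 0)
  expect_equal(nrow(as.data.frame(g)), 1)
})
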