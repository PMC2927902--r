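test_that("flat/dark normalization maps the beam levels correctly", {
  P <- 4; W <- 8
  flats <- list(matrix(100, 1, W)); darks <- list(matrix(10, 1, W))
  # blank beam -> 1, dark level -> 0, halfway -> 0.5
  expect_equal(normalize_projections(matrix(100, P, W), darks, flats),
               matrix(1, P, W))
  expect_equal(normalize_projections(matrix(10, P, W), darks, flats),
               matrix(0, P, W))
  expect_equal(normalize_projections(matrix(55, P, W), darks, flats),
               matrix(0.5, P, W))
  # clipping at both ends
  expect_equal(normalize_projections(matrix(0, P, W), darks, flats),
               matrix(0, P, W))
  expect_equal(normalize_projections(matrix(1e6, P, W), darks, flats,
                                     clip_max = 2),
               matrix(2, P, W))
  # dead detector column is an error, not silent garbage
  f2 <- list(matrix(100, 1, W)); f2[[1]][1, 3] <- 10
  expect_error(normalize_projections(matrix(50, P, W), darks, f2), "dead")
  expect_error(normalize_projections(matrix(50, P, W)), "required")
})

test_that("transmittance round trip recovers the line integrals", {
  d <- disc_phantom(96, 20)
  g <- scan_geometry(96, 1)
  ideal <- forward_project(d, subscan_angles(16))
  subs <- simulate_subscans(d, g, 16, noise_sd = 0,
                            mode = "transmittance", mu_scale = 0.005)
  norm <- normalize_projections(subs[[1]])
  back <- absorption_from_transmittance(norm, mu_scale = 0.005)
  expect_equal(back$projections, ideal$projections, tolerance = 1e-8)
  expect_equal(back$mode, "absorption")
})

test_that("flip-and-stitch merging reproduces the direct wide scan", {
  w <- 128
  p <- shepp_logan(w)
  n360 <- 32
  # centered axis: stitched result equals the 180-degree scan exactly
  s0 <- forward_project(p, subscan_angles(n360, full_circle = TRUE))
  merged0 <- flip_stitch_360(s0)
  direct <- forward_project(p, subscan_angles(n360 / 2))
  expect_equal(dim(merged0$projections), dim(direct$projections))
  expect_equal(merged0$projections, direct$projections, tolerance = 1e-10)
  # off-center axis at W/4: width grows to W + 2*offset and matches a
  # virtual wide detector
  off <- w / 4
  s1 <- forward_project(p, subscan_angles(n360, full_circle = TRUE),
                        offset_px = off)
  merged1 <- flip_stitch_360(s1)
  expect_equal(ncol(merged1$projections), w + 2 * off)
  wide <- forward_project(p, subscan_angles(n360 / 2),
                          detector_width_px = w + 2 * off)
  expect_lt(max(abs(merged1$projections - wide$projections)) /
              max(abs(wide$projections)), 1e-3)
  # failure modes
  expect_error(flip_stitch_360(s1$projections[1:31, ], off), "odd")
  expect_error(flip_stitch_360(s1$projections, w / 2), "overlap")
  expect_error(flip_stitch_360(s1$projections, 0.5), "integer")
  expect_error(flip_stitch_360(forward_project(p, subscan_angles(8))),
               "360")
})

test_that("angular interpolation preserves measured projections", {
  d <- disc_phantom(64, 12)
  s <- forward_project(d, subscan_angles(8))
  # identity at ratio 1
  expect_identical(interpolate_missing(s, 8)$projections, s$projections)
  out <- interpolate_missing(s, 32)
  expect_equal(nrow(out$projections), 32)
  # original rows preserved exactly at their angles
  expect_identical(out$projections[seq(1, 32, by = 4), ], s$projections)
  # inserted rows are the midpoints of their surviving neighbours
  mid16 <- interpolate_missing(s, 16)$projections
  expect_equal(mid16[2, ], (s$projections[1, ] + s$projections[2, ]) / 2)
  # wrap row of a centered subscan is the mirrored first projection
  expect_equal(mid16[16, ],
               (s$projections[8, ] +
                  s$projections[1, rev(seq_len(64))]) / 2)
  expect_error(interpolate_missing(s, 24), "power of two")
  expect_error(interpolate_missing(s, 4), "power of two")
})

test_that("interpolated projections stay close to a dense acquisition", {
  d <- disc_phantom(96, 24)
  coarse <- forward_project(d, subscan_angles(64))
  dense <- forward_project(d, subscan_angles(128))
  interp <- interpolate_missing(coarse, 128)
  relerr <- max(abs(interp$projections - dense$projections)) /
    max(abs(dense$projections))
  expect_lt(relerr, 0.02)
  # mass conserved per projection (to the projector's own accuracy)
  expect_lt(max(abs(rowSums(interp$projections) / sum(d) - 1)), 2e-3)
})

test_that("cutline search recovers known lateral misregistrations", {
  p <- shepp_logan(384)
  g <- scan_geometry(160, 3, 48, desired_fov_px = 384)
  subs <- simulate_subscans(p, g, rep(24, 3))
  left <- subs[[1]]$projections
  right <- subs[[2]]$projections
  # perfectly registered strips
  cl0 <- find_cutline(left, right, 48)
  expect_equal(cl0$shift_px, 0L)
  expect_lt(cl0$msd, 1e-12)
  # right strip sampled 3 px too far right: recovered as shift -3
  right3 <- forward_project(p, subscan_angles(24),
                            offset_px = g$offsets_px[2] + 3,
                            detector_width_px = 160)$projections
  cl3 <- find_cutline(left, right3, 48)
  expect_equal(cl3$shift_px, -3L)
  # uninformative overlap: warning + nominal center
  expect_warning(
    clf <- find_cutline(matrix(1, 10, 60), matrix(1, 10, 60), 20),
    "flat")
  expect_equal(clf$cut_col, 10L)
  expect_error(find_cutline(matrix(1, 3, 8), matrix(1, 4, 8), 4), "rows")
})

test_that("stitched projections equal a virtual wide-detector scan", {
  p <- shepp_logan(384)
  g <- scan_geometry(160, 3, 48, desired_fov_px = 384)
  expect_equal(covered_width(g), 384)
  subs <- simulate_subscans(p, g, rep(16, 3))
  wide <- stitch_projections(subs, g)
  expect_s3_class(wide, "wide_projections")
  expect_equal(ncol(wide$projections), 384)
  direct <- forward_project(p, subscan_angles(16),
                            detector_width_px = 384)
  expect_lt(max(abs(wide$projections - direct$projections)) /
              max(abs(direct$projections)), 1e-10)
  # provenance covers all columns in order
  expect_equal(length(wide$provenance), 384)
  expect_true(all(diff(wide$provenance) >= 0))
  expect_equal(sort(unique(wide$provenance)), 1:3)
  expect_equal(wide$cutlines_px,
               cumsum(rle(wide$provenance)$lengths)[1:2])
})

test_that("stitching validates its inputs and handles one subscan", {
  p <- shepp_logan(100)
  g1 <- scan_geometry(100, 1)
  s <- simulate_subscans(p, g1, 8)
  w1 <- stitch_projections(s, g1)
  expect_identical(w1$projections, s[[1]]$projections)
  expect_equal(w1$cutlines_px, integer(0))
  g3 <- scan_geometry(100, 3, 10)
  expect_error(stitch_projections(s, g3), "expected 3 subscans")
  bad <- simulate_subscans(p, g3, c(8, 8, 16))
  expect_error(stitch_projections(bad, g3), "angle grid")
  # merged width follows sum(widths) - sum(overlaps)
  subs3 <- simulate_subscans(p, g3, rep(8, 3))
  expect_equal(ncol(stitch_projections(subs3, g3)$projections), 280)
  expect_error(stitch_projections(subs3, g3, cutlines = c(0, 5)),
               "within")
})

test_that("sinogram assembly is a pure re-indexing", {
  arr <- array(rnorm(6 * 4 * 10), c(6, 4, 10))     # P x n_rows x W
  stack <- build_sinograms(arr)
  expect_equal(dim(stack$sinograms), c(4, 6, 10))
  expect_equal(stack$sinograms[3, 2, 7], arr[2, 3, 7])
  expect_identical(projections_from_sinograms(stack), arr)
  # matrix input is treated as a single detector row
  m <- matrix(rnorm(12), 3, 4)
  sm <- build_sinograms(m)
  expect_equal(dim(sm$sinograms), c(1, 3, 4))
  expect_equal(sm$sinograms[1, , ], m)
  # every sinogram row of a centered disc is (nearly) the same profile:
  # rotation invariance up to the projector's few-percent discretization
  d <- disc_phantom(48, 10)
  s <- forward_project(d, subscan_angles(9))
  sd <- build_sinograms(s)
  expect_equal(sd$angles_deg, s$angles_deg)
  # (up to the discrete projector's few-percent angular variation)
  dev <- sweep(sd$sinograms[1, , ], 2, sd$sinograms[1, 1, ])
  expect_lt(sqrt(mean(dev^2)), 0.03 * max(s$projections))
  expect_gt(min(cor(t(sd$sinograms[1, , ]))), 0.995)
})
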