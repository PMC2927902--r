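test_that("region growing selects the seeded connected component", {
  # uniform volume: growing floods everything in the interval
  v <- array(1, c(4, 4, 4))
  r <- region_grow(v, c(2, 2, 2), c(0.5, 1.5))
  expect_s3_class(r, "segmented_region")
  expect_true(all(r$mask))
  # two disjoint blobs: only the seeded one is selected
  v2 <- array(0, c(10, 10, 3))
  v2[2:4, 2:4, 1:2] <- 1
  v2[7:9, 7:9, 2:3] <- 1
  rA <- region_grow(v2, c(3, 3, 1), c(0.5, 1.5))
  expect_equal(sum(rA$mask), 18)
  expect_true(all(which(rA$mask) %in% which(v2 == 1 &
    slice.index(v2, 1) <= 4)))
  rB <- region_grow(v2, c(8, 8, 3), c(0.5, 1.5))
  expect_equal(sum(rA$mask & rB$mask), 0)
  expect_equal(sum(rA$mask) + sum(rB$mask), sum(v2))
  # 6- vs 26-connectivity: diagonal touch joins only under 26
  v3 <- array(0, c(4, 4, 1))
  v3[1, 1, 1] <- 1; v3[2, 2, 1] <- 1
  expect_equal(sum(region_grow(v3, c(1, 1, 1), c(0.5, 1.5), 26)$mask), 2)
  expect_equal(sum(region_grow(v3, c(1, 1, 1), c(0.5, 1.5), 6)$mask), 1)
  expect_error(region_grow(v2, c(50, 1, 1), c(0, 1)), "outside the volume")
  expect_error(region_grow(v2, c(1, 1, 1), c(0.5, 1.5)),
               "outside the interval")
})

test_that("flood fill matches the iterative-dilation oracle", {
  set.seed(31)
  cand <- array(runif(9 * 9 * 5) < 0.45, c(9, 9, 5))
  seeds <- which(cand)
  for (sd_idx in seeds[c(1, length(seeds) %/% 2, length(seeds))]) {
    fast <- widefieldct:::flood_fill(cand, sd_idx)
    slow <- flood_oracle(cand, arrayInd(sd_idx, dim(cand)))
    expect_identical(fast, slow)
  }
  # growing again from any voxel of a grown region returns the same region
  r1 <- widefieldct:::flood_fill(cand, seeds[1])
  again <- widefieldct:::flood_fill(cand, which(r1)[sum(r1)])
  expect_identical(again, r1)
})

test_that("component labeling and small-component removal are consistent", {
  v <- array(0, c(12, 12, 1))
  v[2:3, 2:3, 1] <- 1        # size 4
  v[6, 6, 1] <- 1            # size 1
  v[9:12, 9:12, 1] <- 1      # size 16
  lab <- label_components(v)
  expect_equal(max(lab), 3)
  expect_equal(sort(tabulate(lab[lab > 0])), c(1, 4, 16))
  expect_equal(unique(lab[v == 0]), 0L)
  # labels partition the foreground
  expect_equal(sum(lab > 0), sum(v))
  # min_voxels 1 keeps everything; 5 keeps only the big blob
  expect_equal(sum(remove_small_components(v, 1)), 21)
  expect_equal(sum(remove_small_components(v, 5)), 16)
  expect_equal(sum(remove_small_components(v, 500)), 0)
  # removal never adds voxels and is idempotent
  cleaned <- remove_small_components(v, 5)
  expect_true(all(v[cleaned]== 1))
  expect_identical(remove_small_components(cleaned, 5), cleaned)
})

test_that("distance transform has closed-form values on simple masks", {
  # single background voxel at the corner of a 5^3 cube
  m <- array(TRUE, c(5, 5, 5)); m[1, 1, 1] <- FALSE
  d <- euclidean_distance_transform(m)
  expect_equal(d[1, 1, 1], 0)
  expect_equal(d[2, 1, 1], 1)
  expect_equal(d[2, 2, 2], sqrt(3))
  expect_equal(d[5, 5, 5], sqrt(3 * 16))
  # voxel size scales distances linearly
  expect_equal(euclidean_distance_transform(m, voxel_size_um = 2.5),
               2.5 * d)
  expect_error(euclidean_distance_transform(array(TRUE, c(3, 3, 3))),
               "all-foreground")
})

test_that("distance transform equals the brute-force oracle", {
  set.seed(8)
  m <- array(runif(12^3) < 0.6, c(12, 12, 12))
  m[1, 1, 1] <- FALSE
  expect_equal(euclidean_distance_transform(m), edt_oracle(m),
               tolerance = 1e-12)
})

test_that("distance transform of a ball peaks at its radius", {
  w <- 21; r <- 8
  ax <- seq_len(w) - (w + 1) / 2
  ball <- array(outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= r^2,
                c(w, w, w))
  d <- euclidean_distance_transform(ball)
  expect_lt(abs(max(d) - r) , 1.1)        # center-to-shell, lattice coarse
  expect_equal(which.max(d), (w^3 + 1) %/% 2)  # maximum at the center
  # 1-Lipschitz along every axis
  expect_lte(max(abs(diff(d[, 11, 11]))), 1 + 1e-12)
  expect_lte(max(abs(diff(d[11, , 11]))), 1 + 1e-12)
  expect_lte(max(abs(diff(d[11, 11, ]))), 1 + 1e-12)
})

test_that("distance histograms conserve the foreground voxel count", {
  m <- array(TRUE, c(7, 7, 7)); m[1, , ] <- FALSE
  d <- euclidean_distance_transform(m, voxel_size_um = 1.48)
  h <- distance_histogram(d, bin_width_um = 1, roi_id = "roi1")
  expect_s3_class(h, "wf_distance_histogram")
  expect_equal(sum(h$count), sum(m))
  expect_equal(h$bin_hi - h$bin_lo, rep(1, nrow(h)))
  expect_equal(h$roi_id, rep("roi1", nrow(h)))
  # plane background: distance = 1.48 * (x - 1); check the first bin
  expect_equal(h$count[1], sum(d > 0 & d <= 1))
  # empty foreground gives a zero histogram, not an error
  h0 <- distance_histogram(array(0, c(3, 3, 3)))
  expect_equal(sum(h0$count), 0)
  expect_error(distance_histogram(d, bin_width_um = 0), "positive")
})

test_that("ROI extraction is bit-exact cropping", {
  set.seed(77)
  v <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  roi <- extract_roi(v, c(2, 3, 4), 3)
  expect_equal(dim(roi), c(3, 3, 3))
  expect_identical(roi, v[2:4, 3:5, 4:6])
  expect_identical(extract_roi(v, c(1, 1, 1), c(6, 7, 8)), v)
  expect_error(extract_roi(v, c(5, 5, 5), 4), "bounds")
  expect_error(extract_roi(v, c(0, 1, 1), 2), "bounds")
})
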