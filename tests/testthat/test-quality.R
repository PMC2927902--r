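test_that("Otsu threshold separates a two-delta histogram", {
  img <- matrix(c(rep(0, 60), rep(1, 40)), 10, 10)
  th <- otsu_threshold(img)
  expect_gt(th, 0); expect_lt(th, 1)
  expect_equal(sum(binarize_otsu(img)), 40)
  expect_error(otsu_threshold(matrix(3, 4, 4)), "constant")
})

test_that("Otsu matches the exhaustive between-class-variance oracle", {
  set.seed(7)
  for (rep in 1:3) {
    v <- c(rnorm(400, 0, 0.5), rnorm(300, 4, 0.7))
    expect_equal(otsu_threshold(v), otsu_oracle(v))
  }
})

test_that("Otsu misclassifies under 1% of a well-separated mixture", {
  set.seed(21)
  n0 <- 7000; n1 <- 3000
  v <- c(rnorm(n0, 0, 0.4), rnorm(n1, 3, 0.4))
  b <- binarize_otsu(matrix(v, 100, 100))
  truth <- matrix(rep(c(0, 1), c(n0, n1)), 100, 100)
  expect_lt(slice_difference(b, truth) / length(v), 0.01)
})

test_that("Otsu agrees with the EBImage reference on [0,1] data", {
  skip_if_not_installed("EBImage")
  set.seed(5)
  img <- matrix(pmin(pmax(c(rnorm(2000, 0.3, 0.08),
                            rnorm(2000, 0.7, 0.08)), 0), 1), 80, 50)
  ours <- otsu_threshold(img)
  # EBImage computes over a fixed [0,1] range; rebuild on the data range
  ref <- EBImage::otsu(EBImage::Image(img), range = range(img))
  expect_lt(abs(ours - ref), diff(range(img)) / 256 + 1e-12)
})

test_that("slice difference is the binary disagreement count", {
  a <- matrix(c(1, 0, 1, 0), 2, 2)
  b <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(slice_difference(a, a), 0)
  expect_equal(slice_difference(a, b), 2)
  expect_equal(slice_difference(a, 1 - a), 4)
  expect_equal(slice_difference(a, b), slice_difference(b, a))
  expect_error(slice_difference(a, matrix(0, 3, 3)), "shape")
  expect_error(slice_difference(a * 2, a), "binarized")
})

test_that("protocol error samples slices at the stated stride", {
  # stride 5 on 1024 slices: indices 1, 6, ..., 1021 -> 205 slices
  expect_equal(length(seq(1, 1024, by = 5)), 205)
  set.seed(3)
  vol_b <- array(rnorm(20 * 20 * 23), c(20, 20, 23))
  vol_i <- vol_b + rnorm(length(vol_b), sd = 0.4)
  rep5 <- protocol_error(vol_i, vol_b, slice_stride = 5, label = "X")
  expect_s3_class(rep5, "wf_quality_report")
  expect_equal(rep5$n_slices_evaluated, 5)    # 1, 6, 11, 16, 21
  expect_equal(rep5$label, "X")
  # ceil(n / stride) sampling property over several strides
  for (st in c(1, 2, 7, 23))
    expect_equal(protocol_error(vol_i, vol_b, st)$n_slices_evaluated,
                 ceiling(23 / st))
  # a volume against itself has zero error
  self <- protocol_error(vol_b, vol_b, 5)
  expect_equal(self$mean_E, 0)
  expect_equal(self$std_E, 0)
  # recompute mean/sd from the per-slice column
  E <- rep5$per_slice_E[[1]]
  expect_equal(rep5$mean_E, mean(E))
  expect_equal(rep5$std_E, sd(E))
  # manual oracle for one sampled slice
  expect_equal(E[2],
               slice_difference(binarize_otsu(vol_i[, , 6]),
                                binarize_otsu(vol_b[, , 6])))
  expect_error(protocol_error(vol_i, vol_b[, , 1:10], 5), "depth")
  expect_error(protocol_error(vol_i, vol_b, 0), "stride")
})

test_that("quality normalization is affine and order-reversing", {
  E <- c(100, 50, 20, 10)
  q <- normalize_quality(E)
  expect_equal(q[1], 16)          # worst -> low end
  expect_equal(q[4], 116)         # best -> high end
  expect_true(all(diff(q) > 0))
  # affine in E: interior point by hand
  expect_equal(q[2], 16 + (100 - 50) / 90 * 100)
  q2 <- normalize_quality(E, range = c(0, 1))
  expect_equal(q2, (max(E) - E) / diff(range(E)))
  expect_error(normalize_quality(5), "at least two")
  expect_error(normalize_quality(c(3, 3)), "degenerate")
})

test_that("line fit matches the normal equations", {
  expect_equal(fit_line(c(0, 1), c(1, 3))$slope, 2)
  expect_equal(fit_line(c(0, 1), c(1, 3))$intercept, 1)
  set.seed(12)
  x <- runif(30, 0, 100); y <- 0.8 * x + 22 + rnorm(30, sd = 3)
  f <- fit_line(x, y)
  # independent normal-equation oracle
  sl <- cov(x, y) / var(x)
  expect_equal(f$slope, sl, tolerance = 1e-10)
  expect_equal(f$intercept, mean(y) - sl * mean(x), tolerance = 1e-10)
  expect_equal(f$r_squared, cor(x, y)^2, tolerance = 1e-10)
  expect_gt(f$r_squared, 0.9)
  # tidy/glance accessors
  td <- generics::tidy(f)
  expect_equal(td$estimate, c(f$intercept, f$slope))
  expect_equal(generics::glance(f)$r.squared, f$r_squared)
  expect_error(fit_line(1:3, 1:4), "equal length")
  expect_error(fit_line(c(2, 2, 2), 1:3), "degenerate")
})

test_that("the L1 gray-value score is a metric", {
  l1 <- function(a, b) sum(abs(a - b))
  set.seed(9)
  a <- matrix(rnorm(100), 10); b <- matrix(rnorm(100), 10)
  c_ <- matrix(rnorm(100), 10)
  expect_equal(l1(a, a), 0)
  expect_gt(l1(a, b), 0)
  expect_equal(l1(a, b), l1(b, a))
  expect_lte(l1(a, c_), l1(a, b) + l1(b, c_))
})
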