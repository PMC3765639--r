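test_that("Hann window zeroes corners, peaks at odd-size centers, and is separable", {
  img <- matrix(1, 33, 17)
  w <- hann2d(img)
  expect_equal(w[1, 1], 0)
  expect_equal(w[1, 17], 0)
  expect_equal(w[33, 1], 0)
  expect_equal(w[33, 17], 0)
  expect_equal(w[17, 9], 1)
  h1 <- basketweave:::hann1d(33)
  h2 <- basketweave:::hann1d(17)
  expect_equal(w, outer(h1, h2), tolerance = 1e-14)
})

test_that("constant images transform to a pure DC bin", {
  spec <- amplitude_spectrum(matrix(3.5, 32, 32))
  dc <- attr(spec, "dc")
  expect_equal(dc, c(17L, 17L))
  expect_equal(spec[dc[1], dc[2]], 3.5)
  off <- spec
  off[dc[1], dc[2]] <- 0
  expect_lt(max(off), 1e-12)
})

test_that("a bin-aligned cosine yields two half-amplitude peaks", {
  n <- 64
  xs <- matrix(seq_len(n) - 1, n, n, byrow = TRUE) # x advances columns
  img <- cos(2 * pi * (4 / 64) * xs)
  spec <- amplitude_spectrum(img)
  dc <- attr(spec, "dc")
  expect_equal(spec[dc[1], dc[2] + 4], 0.5, tolerance = 1e-12)
  expect_equal(spec[dc[1], dc[2] - 4], 0.5, tolerance = 1e-12)
  spec[dc[1], dc[2] + c(-4, 4)] <- 0
  expect_lt(max(spec), 1e-12)
})

test_that("amplitude spectrum matches the direct double-sum oracle", {
  for (seed in 1:2) {
    img <- fixture_matrix(8, 8, seed)
    expect_lt(max(abs(amplitude_spectrum(img) - oracle_dft_amplitude(img))),
              1e-10)
  }
  img <- fixture_matrix(8, 6, seed = 9) # non-square dims
  expect_lt(max(abs(amplitude_spectrum(img) - oracle_dft_amplitude(img))),
            1e-10)
})

test_that("Parseval's identity holds under the 1/(MN) normalization", {
  for (seed in 1:3) {
    img <- fixture_matrix(24, 20, seed)
    spec <- amplitude_spectrum(img)
    lhs <- sum(spec^2)
    rhs <- sum(img^2) / length(img)
    expect_lt(abs(lhs - rhs) / rhs, 1e-9)
  }
})

test_that("amplitude spectrum is invariant to cyclic translation", {
  img <- fixture_matrix(32, 32, seed = 6)
  shifted <- img[c(9:32, 1:8), c(20:32, 1:19)]
  expect_equal(amplitude_spectrum(img), amplitude_spectrum(shifted),
               tolerance = 1e-10)
})

test_that("binarization keeps a single central bin when only it is nonzero", {
  spec <- matrix(0, 33, 33)
  spec[17, 17] <- 5
  attr(spec, "dc") <- c(17L, 17L)
  mask <- binarize_spectrum(spec, quantile = 0.9)
  expect_true(mask[17, 17])
  expect_equal(sum(mask), 1L)
})

test_that("the central component beats a disjoint larger blob", {
  spec <- matrix(0, 41, 41)
  spec[20:22, 20:22] <- 3        # centered 3x3 blob (contains DC at 21,21)
  spec[2:6, 2:6] <- 3            # larger corner blob
  attr(spec, "dc") <- c(21L, 21L)
  mask <- binarize_spectrum(spec, quantile = 0.99)
  expect_true(all(mask[20:22, 20:22]))
  expect_false(any(mask[2:6, 2:6]))
  expect_equal(sum(mask), 9L)
})

test_that("component = 'none' returns the full supra-threshold scatter", {
  spec <- matrix(0, 41, 41)
  spec[20:22, 20:22] <- 3
  spec[2:6, 2:6] <- 3
  attr(spec, "dc") <- c(21L, 21L)
  mask <- binarize_spectrum(spec, quantile = 0.99, component = "none")
  expect_true(all(mask[2:6, 2:6]))
  expect_true(all(mask[20:22, 20:22]))
  expect_equal(sum(mask), 34L)
})

test_that("an anisotropic Gaussian spectrum yields a 4:1 central blob", {
  n <- 101
  u <- matrix(seq_len(n) - 51, n, n, byrow = TRUE)
  v <- matrix(seq_len(n) - 51, n, n)
  spec <- exp(-(u^2 / (2 * 8^2) + v^2 / (2 * 2^2)))
  attr(spec, "dc") <- c(51L, 51L)
  mask <- binarize_spectrum(spec, quantile = 0.95)
  # the surviving mask must match the direct supra-threshold enumeration
  thr <- quantile(log1p(spec), 0.95)
  expect_equal(unname(sum(mask)), unname(sum(log1p(spec) >= thr)))
  e <- equivalent_ellipse(mask)
  expect_lt(abs(e$long_axis / e$short_axis - 4), 0.4)
  expect_lt(abs(e$orientation), 3)
})

test_that("degenerate thresholds are reported", {
  spec <- matrix(1, 33, 33)
  attr(spec, "dc") <- c(17L, 17L)
  expect_error(binarize_spectrum(spec, quantile = 1.2), "quantile",
               class = "bw_error")
  expect_error(binarize_spectrum(spec, quantile = 0), "quantile",
               class = "bw_error")
})

test_that("moment ellipse of a digital disk is circular", {
  n <- 41
  d <- sqrt(outer(seq_len(n) - 21, rep(1, n))^2 +
              outer(rep(1, n), seq_len(n) - 21)^2)
  e <- equivalent_ellipse(d <= 10)
  expect_lt(e$long_axis / e$short_axis, 1.02)
})

test_that("moment ellipse of a 40x10 rectangle has a 4:1 axis ratio", {
  mask <- matrix(FALSE, 60, 80)
  mask[26:35, 21:60] <- TRUE # 10 rows x 40 columns
  e <- equivalent_ellipse(mask)
  expect_lt(abs(e$long_axis / e$short_axis - 4), 0.08)
  expect_equal(e$orientation, 0)
  # exhaustive second-moment check over the 400 bins
  pts <- which(mask, arr.ind = TRUE)
  vr <- mean((pts[, 1] - mean(pts[, 1]))^2)
  vc <- mean((pts[, 2] - mean(pts[, 2]))^2)
  expect_equal(e$long_axis, 4 * sqrt(vc), tolerance = 1e-12)
  expect_equal(e$short_axis, 4 * sqrt(vr), tolerance = 1e-12)
})

test_that("single-bin masks degenerate to unit axes", {
  mask <- matrix(FALSE, 33, 33)
  mask[5, 9] <- TRUE
  e <- equivalent_ellipse(mask)
  expect_equal(e$long_axis, 1)
  expect_equal(e$short_axis, 1)
  expect_equal(n_omega(e), 0)
  expect_error(equivalent_ellipse(matrix(FALSE, 3, 3)), "empty",
               class = "bw_degenerate")
})

test_that("axis ratios are scale-invariant and transpose swaps orientation", {
  disk <- function(n, r) {
    d <- sqrt(outer(seq_len(n) - (n + 1) / 2, rep(1, n))^2 +
                outer(rep(1, n), seq_len(n) - (n + 1) / 2)^2)
    d <= r
  }
  e1 <- equivalent_ellipse(disk(41, 8))
  e2 <- equivalent_ellipse(disk(101, 40))
  expect_lt(abs(e1$long_axis / e1$short_axis -
                  e2$long_axis / e2$short_axis), 0.02)
  mask <- matrix(FALSE, 60, 80)
  mask[26:35, 21:60] <- TRUE
  et <- equivalent_ellipse(t(mask))
  e <- equivalent_ellipse(mask)
  expect_equal(et$long_axis, e$long_axis)
  expect_equal(et$short_axis, e$short_axis)
  expect_equal(abs(et$orientation - e$orientation), 90)
})
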