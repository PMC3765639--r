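test_that("phantom rendering is seed-deterministic", {
  sp <- phantom_spec(height = 96, width = 96, seed = 42,
                     angular_jitter_sd = 15)
  expect_identical(generate_basketweave(sp), generate_basketweave(sp))
  sp2 <- phantom_spec(height = 96, width = 96, seed = 43,
                      angular_jitter_sd = 15)
  expect_false(identical(unclass(generate_basketweave(sp))[, ],
                         unclass(generate_basketweave(sp2))[, ]))
})

test_that("a zero-fiber spec renders background plus noise only", {
  sp <- phantom_spec(height = 64, width = 64, n_fibers_per_family = 0,
                     background = 0.2, noise_sd = 0.01, seed = 3)
  img <- generate_basketweave(sp)
  expect_lt(abs(mean(img) - 0.2), 0.01)
  expect_lt(sd(img), 0.02)
})

test_that("phantom values stay in [0, 1] and invalid specs are rejected", {
  img <- generate_basketweave(phantom_spec(height = 64, width = 64,
                                           seed = 9))
  expect_gte(min(img), 0)
  expect_lte(max(img), 1)
  expect_error(phantom_spec(fiber_width = 0), "fiber_width",
               class = "bw_error")
  expect_error(phantom_spec(fiber_spacing = 2, fiber_width = 3), "exceed",
               class = "bw_error")
  expect_error(phantom_spec(angular_jitter_sd = -1), ">= 0",
               class = "bw_error")
})

test_that("zero-jitter spectra concentrate along the family directions", {
  img <- generate_basketweave(phantom_spec(seed = 1))
  spec <- amplitude_spectrum(hann2d(img - mean(img)))
  # a fibre family at angle a concentrates spectral energy along a + 90;
  # with families at 45/135 the two wedge directions are again 45 and 135
  wedges <- wedge_energy(spec, 45) + wedge_energy(spec, 135)
  dc <- attr(spec, "dc")
  rows <- matrix(seq_len(nrow(spec)) - dc[1], nrow(spec), ncol(spec))
  cols <- matrix(seq_len(ncol(spec)) - dc[2], nrow(spec), ncol(spec),
                 byrow = TRUE)
  total <- sum(spec[sqrt(rows^2 + cols^2) >= 3]^2)
  expect_gt(wedges / total, 0.5)
})

test_that("dominant spectral wedges match the configured family angles", {
  img <- generate_basketweave(phantom_spec(height = 128, width = 128,
                                           seed = 2))
  spec <- amplitude_spectrum(hann2d(img - mean(img)))
  scan <- oracle_wedge_scan(spec, half_width = 5)
  top <- order(scan, decreasing = TRUE)[1]
  err <- min(abs(((top - 1) - c(45, 135)) %% 180),
             abs((c(45, 135) - (top - 1)) %% 180))
  expect_lte(err, 3)
})

test_that("angular jitter lowers wedge-energy concentration on average", {
  conc <- function(jit) {
    mean(vapply(1:10, function(s) {
      img <- generate_basketweave(
        phantom_spec(height = 128, width = 128, angular_jitter_sd = jit,
                     seed = 100 + s))
      spec <- amplitude_spectrum(hann2d(img - mean(img)))
      dc <- attr(spec, "dc")
      rows <- matrix(seq_len(nrow(spec)) - dc[1], nrow(spec), ncol(spec))
      cols <- matrix(seq_len(ncol(spec)) - dc[2], nrow(spec), ncol(spec),
                     byrow = TRUE)
      total <- sum(spec[sqrt(rows^2 + cols^2) >= 3]^2)
      (wedge_energy(spec, 45) + wedge_energy(spec, 135)) / total
    }, numeric(1)))
  }
  c0 <- conc(0)
  c15 <- conc(15)
  c35 <- conc(35)
  expect_gt(c0, c15)
  expect_gt(c15, c35)
})

test_that("isotropic controls are reproducible with a sane mean", {
  a <- generate_isotropic(128, 128, seed = 5)
  b <- generate_isotropic(128, 128, seed = 5)
  expect_identical(a, b)
  expect_false(identical(generate_isotropic(128, 128, seed = 6)[1:10, 1],
                         a[1:10, 1]))
  # clipping at [0,1] barely moves the mean at sd = 0.15
  se <- 0.15 / sqrt(length(a))
  expect_lt(abs(mean(a) - 0.5), 3 * se + 1e-3)
})

test_that("rotation by zero and quarter turns is lossless", {
  img <- generate_basketweave(phantom_spec(height = 96, width = 96,
                                           seed = 10))
  expect_identical(rotate_crop(img, 0), img)
  r90 <- rotate_crop(img, 90)
  expect_equal(dim(r90), dim(img))
  expect_equal(sort(as.vector(r90)), sort(as.vector(img)))
  expect_identical(rotate_crop(rotate_crop(img, 90), -90)[, ], img[, ])
})

test_that("small-angle rotation approximately inverts", {
  img <- generate_basketweave(phantom_spec(height = 192, width = 192,
                                           seed = 11))
  fwd <- rotate_crop(img, 5)
  back <- rotate_crop(fwd, -5)
  side <- nrow(back) - 8
  ctr <- function(m) {
    r0 <- (nrow(m) - side) %/% 2
    m[r0 + seq_len(side), r0 + seq_len(side)]
  }
  expect_gt(cor(as.vector(ctr(back)), as.vector(ctr(img))), 0.98)
})

test_that("rotations that would undercut the minimum size are rejected", {
  img <- generate_basketweave(phantom_spec(height = 80, width = 80,
                                           seed = 12))
  expect_error(rotate_crop(img, 40), "64", class = "bw_error")
  expect_error(rotate_crop(img, 60), "45", class = "bw_error")
})
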