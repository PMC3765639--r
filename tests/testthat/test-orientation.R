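test_that("per-direction elongation follows 1 - short/long", {
  expect_equal(n_omega(7, 7), 0)     # circle
  expect_equal(n_omega(10, 5), 0.5)
  expect_equal(n_omega(4, 3), 0.25)
  expect_error(n_omega(3, 4), "exceeds", class = "bw_error")
  expect_error(n_omega(3, 0), "positive", class = "bw_error")
})

test_that("orientation index is the max/min ratio with a degeneracy guard", {
  expect_identical(orientation_index(c(0.3, 0.3, 0.3, 0.3)), 1)
  expect_equal(orientation_index(c(0.8, 0.2, 0.8, 0.2)), 4)
  expect_error(orientation_index(c(0.5, 0, 0.5, 0.5)), "degenerate",
               class = "bw_degenerate")
  expect_error(orientation_index(c(0.5, 0.5, 0.5)), "four",
               class = "bw_error")
})

test_that("a circularly symmetric spectrum scores zero elongation", {
  n <- 101
  d <- sqrt(outer(seq_len(n) - 51, rep(1, n))^2 +
              outer(rep(1, n), seq_len(n) - 51)^2)
  e <- equivalent_ellipse(d <= 15)
  expect_lt(n_omega(e), 0.02)
})

test_that("the intact basketweave loads the diagonal channels most", {
  img <- generate_basketweave(phantom_spec(seed = 1))
  r <- analyze_image_gabor(img, image_id = "phantom")
  diag_nw <- c(r$n_omega_45, r$n_omega_135)
  axial_nw <- c(r$n_omega_0, r$n_omega_90)
  expect_gt(min(diag_nw), max(axial_nw))
  expect_gt(r$index_N, 1)
  expect_equal(r$method, "gabor_fft")
  expect_equal(r$status, "ok")
})

test_that("analysis is deterministic for fixed input and config", {
  img <- generate_basketweave(phantom_spec(height = 96, width = 96,
                                           seed = 8))
  cfg <- bw_config()
  r1 <- analyze_image(img, cfg, image_id = "x")
  r2 <- analyze_image(img, cfg, image_id = "x")
  expect_identical(r1, r2)
})

test_that("the index is at least 1 for any analyzed content", {
  imgs <- list(
    generate_basketweave(phantom_spec(height = 128, width = 128, seed = 2)),
    generate_basketweave(phantom_spec(height = 128, width = 128, seed = 3,
                                      angular_jitter_sd = 25)),
    generate_isotropic(128, 128, seed = 4)
  )
  for (img in imgs) {
    expect_gte(analyze_image_gabor(img)$index_N, 1)
  }
})

test_that("the FFT-only baseline separates a grating from isotropy", {
  grating <- generate_basketweave(
    phantom_spec(height = 256, width = 256, family_angles = c(45, 45),
                 seed = 6))
  iso <- generate_isotropic(256, 256, seed = 6)
  r_g <- analyze_image_fft_only(grating)
  r_i <- analyze_image_fft_only(iso)
  expect_gt(r_g$index_N, r_i$index_N)
  expect_lt(r_i$index_N, 0.3) # near-circular scatter for white noise
  expect_equal(r_g$n_omega_0, r_g$index_N) # single value copied across
})

test_that("undersized images are rejected at the analysis entry", {
  expect_error(analyze_image_gabor(matrix(0.5, 32, 32)), "64",
               class = "bw_error")
})

test_that("per-animal aggregation averages only matching results", {
  rows <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(image = paste0("im", i), animal = NA_character_,
                   compartment = NA_character_, method = "gabor_fft",
                   n_omega_0 = 0.5, n_omega_45 = 0.5, n_omega_90 = 0.5,
                   n_omega_135 = 0.5,
                   index_N = c(2, 3, 4, 10, 20, 30)[i],
                   config_hash = "h", status = "ok")
  }))
  map <- tibble::tibble(image = paste0("im", 1:6),
                        animal = rep(c("A", "B"), each = 3))
  rows$animal <- NULL
  out <- aggregate_by_animal(rows, map)
  expect_equal(nrow(out), 2L)
  expect_equal(out$mean_index[out$animal == "A"], 3)
  expect_equal(out$mean_index[out$animal == "B"], 20)
  expect_equal(out$n_images, c(3L, 3L))
})

test_that("aggregation warns below three images and rejects unmapped ids", {
  one <- tibble::tibble(image = "only", compartment = NA_character_,
                        method = "gabor_fft", n_omega_0 = 0.5,
                        n_omega_45 = 0.5, n_omega_90 = 0.5,
                        n_omega_135 = 0.5, index_N = 2.5,
                        config_hash = "h", status = "ok")
  map <- tibble::tibble(image = "only", animal = "A")
  expect_warning(out <- aggregate_by_animal(one, map), "fewer than 3")
  expect_equal(out$mean_index, 2.5)
  expect_error(
    aggregate_by_animal(dplyr::mutate(one, image = "ghost"), map),
    "unmapped", class = "bw_error")
})

test_that("interleaved animals aggregate into separate rows", {
  rows <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(image = paste0("im", i),
                   animal = c("A", "B", "A", "B")[i],
                   compartment = NA_character_, method = "gabor_fft",
                   n_omega_0 = 0.4, n_omega_45 = 0.4, n_omega_90 = 0.4,
                   n_omega_135 = 0.4, index_N = c(1, 5, 3, 7)[i],
                   config_hash = "h", status = "ok")
  }))
  out <- suppressWarnings(aggregate_by_animal(rows))
  expect_equal(out$mean_index[out$animal == "A"], 2)
  expect_equal(out$mean_index[out$animal == "B"], 6)
})
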