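# Independent brute-force oracles. These deliberately share no code with the
# package internals: direct double sums, exhaustive window scans, naive
# loops.

# Direct evaluation of the 2-D DFT modulus with the 1/(MN) prefactor,
# centered. O(M^2 N^2); use on tiny images only.
oracle_dft_amplitude <- function(img) {
  m <- nrow(img)
  n <- ncol(img)
  out <- matrix(0, m, n)
  for (u in 0:(m - 1)) {
    for (v in 0:(n - 1)) {
      acc <- 0 + 0i
      for (x in 0:(m - 1)) {
        for (y in 0:(n - 1)) {
          acc <- acc + img[x + 1, y + 1] *
            exp(-2i * pi * (u * x / m + v * y / n))
        }
      }
      out[u + 1, v + 1] <- Mod(acc) / (m * n)
    }
  }
  # center DC the same way a centered spectrum is displayed
  ri <- ((seq_len(m) - 1 - m %/% 2) %% m) + 1
  ci <- ((seq_len(n) - 1 - n %/% 2) %% n) + 1
  out[ri, ci]
}

# Exhaustive sliding-window 3x3 median with reflect (edge-inclusive) padding.
oracle_median3x3 <- function(img) {
  m <- nrow(img)
  n <- ncol(img)
  refl <- function(i, k) {
    if (i < 1) 1 - i else if (i > k) 2 * k - i + 1 else i
  }
  out <- matrix(0, m, n)
  for (i in 1:m) {
    for (j in 1:n) {
      vals <- numeric(9)
      t <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          t <- t + 1
          vals[t] <- img[refl(i + di, m), refl(j + dj, n)]
        }
      }
      out[i, j] <- sort(vals)[5]
    }
  }
  out
}

# Naive double-loop correlation of an image with an odd kernel under
# reflect padding; matches the bank's boundary convention by construction.
oracle_convolve_reflect <- function(img, k) {
  r <- (nrow(k) - 1) %/% 2
  m <- nrow(img)
  n <- ncol(img)
  refl <- function(i, kk) {
    if (i < 1) 1 - i else if (i > kk) 2 * kk - i + 1 else i
  }
  out <- matrix(0, m, n)
  for (i in 1:m) {
    for (j in 1:n) {
      acc <- 0
      for (a in -r:r) {
        for (b in -r:r) {
          acc <- acc + k[a + r + 1, b + r + 1] *
            img[refl(i + a, m), refl(j + b, n)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Definitional Pearson correlation: covariance over SD product.
oracle_pearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
}

# Exhaustive wedge-energy scan of a centered spectrum: returns the angle
# (degrees mod 180, 1-degree steps) with maximal energy in a +/-half_width
# wedge, excluding a small DC disk. Direct summation over all bins.
oracle_wedge_scan <- function(spec, half_width = 5, min_radius = 3) {
  dc <- c(nrow(spec) %/% 2 + 1, ncol(spec) %/% 2 + 1)
  dr <- outer(seq_len(nrow(spec)) - dc[1], rep(1, ncol(spec)))
  dcc <- outer(rep(1, nrow(spec)), seq_len(ncol(spec)) - dc[2])
  rad <- sqrt(dr^2 + dcc^2)
  ang <- (atan2(dr, dcc) * 180 / pi) %% 180
  e2 <- spec^2
  vapply(0:179, function(a) {
    d <- abs(ang - a)
    d <- pmin(d, 180 - d)
    sum(e2[rad >= min_radius & d <= half_width])
  }, numeric(1))
}

oracle_dominant_angle <- function(spec, half_width = 5, min_radius = 3) {
  which.max(oracle_wedge_scan(spec, half_width, min_radius)) - 1L
}

# Small deterministic test images.
fixture_matrix <- function(m, n, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(m * n), m, n))
}

fixture_ramp <- function(m, n) {
  outer(seq_len(m), seq_len(n), function(i, j) i + 100 * j)
}
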