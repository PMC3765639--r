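#' Per-direction elongation score
#'
#' The elongation of a binarized spectral blob,
#' \eqn{N_\omega = 1 - \mathrm{short}/\mathrm{long}}: 0 for a circular blob
#' (isotropic texture in that channel), approaching 1 for a needle-like blob
#' (strongly oriented texture).
#'
#' @param long_axis Either an ellipse from [equivalent_ellipse()] or the
#'   long-axis length.
#' @param short_axis Short-axis length (ignored when an ellipse is given).
#' @return A number in `[0, 1)`.
#' @examples
#' n_omega(10, 5) # 0.5
#' n_omega(4, 3)  # 0.25
#' @export
n_omega <- function(long_axis, short_axis = NULL) {
  if (inherits(long_axis, "bw_ellipse")) {
    short_axis <- long_axis$short_axis
    long_axis <- long_axis$long_axis
  }
  if (!is.numeric(long_axis) || !is.numeric(short_axis) ||
      length(long_axis) != 1L || length(short_axis) != 1L) {
    abort("n_omega() expects scalar axis lengths", class = "bw_error")
  }
  if (short_axis <= 0 || long_axis <= 0) {
    abort("axis lengths must be positive", class = "bw_error")
  }
  if (short_axis > long_axis + 1e-12) {
    abort("short axis exceeds long axis", class = "bw_error")
  }
  max(1 - short_axis / long_axis, 0)
}

#' Overall collagen orientation index
#'
#' The ratio of the largest to the smallest of the four per-channel
#' elongation scores, \eqn{N = \max N_\omega / \min N_\omega}. If the
#' spectral ellipses are equal in all directions (disordered texture) the
#' ratio is close to 1; an intact basketweave loads the two diagonal
#' channels, producing a larger index.
#'
#' A channel elongation at or below `epsilon_floor` means that channel's blob
#' was essentially circular; rather than dividing by a near-zero value the
#' function signals a `bw_degenerate` error so such pathologies surface in
#' QC output.
#'
#' @param n_values Four elongation scores in `[0, 1)`.
#' @param epsilon_floor Degeneracy guard on the smallest value.
#' @return A number `>= 1`.
#' @examples
#' orientation_index(c(0.3, 0.3, 0.3, 0.3)) # exactly 1
#' orientation_index(c(0.8, 0.2, 0.8, 0.2)) # 4
#' @export
orientation_index <- function(n_values, epsilon_floor = 1e-3) {
  if (!is.numeric(n_values) || length(n_values) != 4L) {
    abort("orientation_index() expects four N_omega values",
          class = "bw_error")
  }
  if (any(!is.finite(n_values)) || any(n_values < 0) || any(n_values >= 1)) {
    abort("N_omega values must lie in [0, 1)", class = "bw_error")
  }
  if (any(n_values <= epsilon_floor)) {
    abort(paste0("degenerate isotropy: a channel elongation is at or below ",
                 "the epsilon floor (", format(epsilon_floor), ")"),
          class = "bw_degenerate")
  }
  max(n_values) / min(n_values)
}

# Window -> spectrum -> binarize -> ellipse for one channel.
#
# The ellipse is measured on the full supra-threshold scatter pattern
# (component = "none"): spectra of textured images are speckled, so a
# single connected component is a noise fragment, while the whole
# centrosymmetric scatter is the stable "binary ellipse" of the spectrum.
#
# For Gabor channels (`zero_dc = TRUE`) the window-weighted mean is removed
# first: sum(w * (ch - mu)) == 0 zeroes the DC bin exactly, so a residual
# DC spike never outshines the band-pass structure. The unfiltered baseline
# keeps its DC, which anchors the center of its scatter.
channel_ellipse <- function(channel, config, zero_dc = FALSE) {
  use_hann <- config$spectrum_window == "hann"
  if (zero_dc) {
    wts <- if (use_hann) {
      tcrossprod(hann1d(nrow(channel)), hann1d(ncol(channel)))
    } else {
      matrix(1, nrow(channel), ncol(channel))
    }
    channel <- channel - sum(wts * channel) / sum(wts)
  }
  w <- if (use_hann) hann2d(channel) else channel
  spec <- amplitude_spectrum(w)
  mask <- binarize_spectrum(spec, quantile = config$spectrum_quantile,
                            log_compress = config$spectrum_log_compress,
                            component = "none")
  equivalent_ellipse(mask)
}

#' Analyze one image with the Gabor + FFT pipeline
#'
#' Runs the full chain: 3x3 median filter, mean-subtracted four-channel
#' Gabor bank, per-channel Hann window, centered FFT amplitude spectrum,
#' quantile binarization, moment-equivalent ellipse, per-channel elongation
#' \eqn{N_\omega} and overall index \eqn{N = \max/\min}. Deterministic for a
#' fixed image and configuration.
#'
#' @param img Numeric matrix (grayscale image), each side at least
#'   `config$min_size`.
#' @param config A [bw_config()].
#' @param image_id,compartment Provenance labels copied into the result row.
#' @param median_filter Apply the 3x3 median prefilter (disable only for
#'   noise-free synthetic input where you want the raw texture).
#' @return A one-row tibble with columns `image`, `compartment`, `method`,
#'   `n_omega_0`, `n_omega_45`, `n_omega_90`, `n_omega_135`, `index_N`,
#'   `config_hash`, `status`.
#' @examples
#' img <- generate_basketweave(phantom_spec(seed = 1))
#' analyze_image_gabor(img, image_id = "phantom_1")
#' @export
analyze_image_gabor <- function(img, config = bw_config(),
                                image_id = NA_character_,
                                compartment = NA_character_,
                                median_filter = TRUE) {
  stopifnot(inherits(config, "bw_config"))
  check_min_size(img, config)
  pre <- if (median_filter) median3x3(img) else img
  params <- gabor_params(config$gabor_sigma_x, config$gabor_sigma_y,
                         config$gabor_freq,
                         support_radius = config$gabor_support_radius)
  bank <- apply_gabor_bank(pre, params, response = config$gabor_response)
  nw <- vapply(bank,
               function(ch) n_omega(channel_ellipse(ch, config,
                                                    zero_dc = TRUE)),
               numeric(1))
  idx <- orientation_index(unname(nw), epsilon_floor = config$epsilon_floor)
  result_row(image_id, compartment, "gabor_fft", nw, idx, config)
}

#' Analyze one image with the FFT-only baseline
#'
#' The pre-Gabor reference method: median filter, Hann window, centered FFT
#' amplitude spectrum of the single unfiltered image, binarization and
#' ellipse measurement. Because only one spectrum exists, the reported index
#' is the elongation \eqn{N_\omega = 1 - \mathrm{short}/\mathrm{long}} of
#' that spectrum itself (near 0 for isotropic texture, larger for oriented
#' texture); the four `n_omega_*` columns all carry this single value.
#'
#' @inheritParams analyze_image_gabor
#' @return A one-row tibble (see [analyze_image_gabor()]).
#' @export
analyze_image_fft_only <- function(img, config = bw_config(),
                                   image_id = NA_character_,
                                   compartment = NA_character_,
                                   median_filter = TRUE) {
  stopifnot(inherits(config, "bw_config"))
  check_min_size(img, config)
  pre <- if (median_filter) median3x3(img) else img
  nw <- n_omega(channel_ellipse(pre, config))
  result_row(image_id, compartment, "fft_only", rep(nw, 4), nw, config)
}

#' Analyze one image with one or both methods
#'
#' @inheritParams analyze_image_gabor
#' @param method `"gabor_fft"`, `"fft_only"` or `"both"`.
#' @return A tibble with one row per method.
#' @export
analyze_image <- function(img, config = bw_config(),
                          method = c("both", "gabor_fft", "fft_only"),
                          image_id = NA_character_,
                          compartment = NA_character_,
                          median_filter = TRUE) {
  method <- match.arg(method)
  rows <- list()
  if (method %in% c("both", "gabor_fft")) {
    rows <- c(rows, list(analyze_image_gabor(img, config, image_id,
                                             compartment, median_filter)))
  }
  if (method %in% c("both", "fft_only")) {
    rows <- c(rows, list(analyze_image_fft_only(img, config, image_id,
                                                compartment, median_filter)))
  }
  dplyr::bind_rows(rows)
}

check_min_size <- function(img, config) {
  check_gray(img)
  if (nrow(img) < config$min_size || ncol(img) < config$min_size) {
    abort(sprintf("image must be at least %d x %d for spectral analysis",
                  config$min_size, config$min_size), class = "bw_error")
  }
  invisible(img)
}

result_row <- function(image_id, compartment, method, nw, idx, config) {
  tibble(
    image = as.character(image_id),
    animal = NA_character_,
    compartment = as.character(compartment),
    method = method,
    n_omega_0 = unname(nw[1]),
    n_omega_45 = unname(nw[2]),
    n_omega_90 = unname(nw[3]),
    n_omega_135 = unname(nw[4]),
    index_N = idx,
    config_hash = config_hash(config),
    status = "ok"
  )
}

#' Aggregate image-level indices to per-animal means
#'
#' Images are captured at several locations per animal and averaged to give
#' one value per animal (at least three locations are expected; fewer raises
#' a warning). Aggregation is the arithmetic mean of `index_N` per animal,
#' method and compartment.
#'
#' @param results Tibble of rows from [analyze_image()] (or
#'   [run_analyze()]); only rows with `status == "ok"` are averaged.
#' @param animal_map Optional tibble with columns `image`, `animal` mapping
#'   image ids to animal ids. If omitted, `results` must already carry an
#'   `animal` column.
#' @return A tibble with columns `animal`, `method`, `compartment`,
#'   `mean_index`, `sd_index`, `n_images`.
#' @export
aggregate_by_animal <- function(results, animal_map = NULL) {
  stopifnot(is.data.frame(results))
  if (!is.null(animal_map)) {
    stopifnot(all(c("image", "animal") %in% names(animal_map)))
    unmapped <- setdiff(unique(results$image), animal_map$image)
    if (length(unmapped)) {
      abort(paste0("unmapped image id(s): ",
                   paste(unmapped, collapse = ", ")), class = "bw_error")
    }
    results <- dplyr::left_join(results, animal_map, by = "image")
  }
  if (!"animal" %in% names(results)) {
    abort("results need an `animal` column or an animal_map",
          class = "bw_error")
  }
  out <- results |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$animal, .data$method, .data$compartment) |>
    dplyr::summarise(
      mean_index = mean(.data$index_N),
      sd_index = sd(.data$index_N),
      n_images = dplyr::n(),
      .groups = "drop"
    )
  low <- out |> dplyr::filter(.data$n_images < 3L)
  if (nrow(low)) {
    warn(paste0("fewer than 3 images for animal(s): ",
                paste(unique(low$animal), collapse = ", ")))
  }
  out
}
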