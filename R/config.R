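#' Pipeline configuration
#'
#' Collects every tunable parameter of the orientation-index pipeline in one
#' validated list. Index values are only comparable between images analyzed
#' under the same configuration, so every result row carries
#' `config_hash(config)`.
#'
#' @param gabor_sigma_x Gaussian spread along the carrier axis, pixels.
#' @param gabor_sigma_y Gaussian spread orthogonal to the carrier, pixels.
#' @param gabor_freq Carrier frequency, cycles/pixel; must lie in (0, 0.5)
#'   (below Nyquist). The default period of 12.5 px resolves fibre bundles at
#'   the 90X scale the method was designed for; retune for other
#'   magnifications.
#' @param gabor_support_radius Half-size of the sampled kernel, pixels; must
#'   be at least `ceil(3 * max(sigma_x, sigma_y))` so the Gaussian envelope is
#'   captured.
#' @param gabor_response `"real"` (cosine-carrier response, the default) or
#'   `"magnitude"` (modulus of the complex cosine/sine pair).
#' @param spectrum_quantile Quantile (0,1) of the (optionally log-compressed)
#'   amplitude spectrum used as the binarization threshold.
#' @param spectrum_log_compress Threshold `log1p(amplitude)` rather than raw
#'   amplitude; tames the DC-dominated dynamic range.
#' @param spectrum_window `"hann"` or `"none"`: windowing applied before the
#'   FFT to suppress the axis-aligned cross from frame-edge discontinuities.
#' @param epsilon_floor Smallest admissible per-channel elongation
#'   \eqn{N_\omega}; any channel at or below it signals a degenerate-isotropy
#'   error instead of being silently clamped.
#' @param min_size Minimum image side, pixels, accepted by the image-level
#'   analyses (stable spectra need some support).
#'
#' @return A named list of class `bw_config`.
#' @examples
#' cfg <- bw_config()
#' config_hash(cfg)
#' @export
bw_config <- function(gabor_sigma_x = 4,
                      gabor_sigma_y = 4,
                      gabor_freq = 0.08,
                      gabor_support_radius = 15L,
                      gabor_response = c("real", "magnitude"),
                      spectrum_quantile = 0.995,
                      spectrum_log_compress = TRUE,
                      spectrum_window = c("hann", "none"),
                      epsilon_floor = 1e-3,
                      min_size = 64L) {
  cfg <- list(
    gabor_sigma_x = as.numeric(gabor_sigma_x),
    gabor_sigma_y = as.numeric(gabor_sigma_y),
    gabor_freq = as.numeric(gabor_freq),
    gabor_support_radius = as.integer(gabor_support_radius),
    gabor_response = match.arg(gabor_response),
    spectrum_quantile = as.numeric(spectrum_quantile),
    spectrum_log_compress = isTRUE(spectrum_log_compress),
    spectrum_window = match.arg(spectrum_window),
    epsilon_floor = as.numeric(epsilon_floor),
    min_size = as.integer(min_size)
  )
  if (cfg$gabor_sigma_x <= 0 || cfg$gabor_sigma_y <= 0) {
    abort("gabor sigmas must be positive", class = "bw_error")
  }
  if (cfg$gabor_freq <= 0 || cfg$gabor_freq >= 0.5) {
    abort("gabor_freq must lie in (0, 0.5) cycles/pixel", class = "bw_error")
  }
  min_support <- ceiling(3 * max(cfg$gabor_sigma_x, cfg$gabor_sigma_y))
  if (cfg$gabor_support_radius < min_support) {
    abort(sprintf("gabor_support_radius must be >= %d for these sigmas",
                  min_support), class = "bw_error")
  }
  if (cfg$spectrum_quantile <= 0 || cfg$spectrum_quantile >= 1) {
    abort("spectrum_quantile must lie in (0, 1)", class = "bw_error")
  }
  if (cfg$epsilon_floor <= 0) {
    abort("epsilon_floor must be positive", class = "bw_error")
  }
  structure(cfg, class = "bw_config")
}

#' @export
print.bw_config <- function(x, ...) {
  cat("<bw_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  cat(sprintf("  %-22s %s\n", "config_hash", config_hash(x)))
  invisible(x)
}

#' Fingerprint of a configuration
#'
#' Index values are only comparable within one configuration; the hash of the
#' canonical serialization is stored in every result row so mixed-config
#' tables are detectable.
#'
#' @param config A [bw_config()] list.
#' @return A short hexadecimal string.
#' @export
config_hash <- function(config = bw_config()) {
  stopifnot(inherits(config, "bw_config"))
  rlang::hash(config[order(names(config))])
}

#' Read / write a configuration as YAML
#'
#' Round-trips the flat key-value form used by the command-line driver.
#'
#' @param path File path.
#' @param config A [bw_config()] list.
#' @return `read_config()` returns a `bw_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(bw_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "bw_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
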