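#' Batch-analyze a set of images
#'
#' Runs [analyze_image()] over image files (optionally restricted to ROI
#' rectangles from a ROI table), never aborting the batch: failures are
#' recorded per row with their error message in `status` and `NA` indices.
#'
#' @param inputs Character vector of image paths, or a single directory
#'   (all `.png`/`.tif`/`.tiff` files in it).
#' @param config A [bw_config()].
#' @param method `"both"`, `"gabor_fft"` or `"fft_only"`.
#' @param roi_file Optional path to a ROI CSV (see [read_roi_csv()]); images
#'   listed there are analyzed per compartment rectangle, others whole.
#' @param output_dir Optional directory: writes `results.csv` and the exact
#'   `config.yaml` used.
#' @return A tibble with one row per image x ROI x method.
#' @export
run_analyze <- function(inputs, config = bw_config(),
                        method = c("both", "gabor_fft", "fft_only"),
                        roi_file = NULL, output_dir = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(config, "bw_config"))
  if (length(inputs) == 1L && dir.exists(inputs)) {
    inputs <- list.files(inputs, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE)
  }
  if (length(inputs) == 0L) {
    abort("no input images", class = "bw_error")
  }
  rois <- if (!is.null(roi_file)) read_roi_csv(roi_file) else NULL
  methods <- if (method == "both") c("gabor_fft", "fft_only") else method

  analyze_one <- function(path, roi, label) {
    purrr::map(methods, function(m) {
      tryCatch({
        img <- read_gray(path)
        if (!is.null(roi)) img <- crop_roi(img, roi)
        if (m == "gabor_fft") {
          analyze_image_gabor(img, config, image_id = basename(path),
                              compartment = label)
        } else {
          analyze_image_fft_only(img, config, image_id = basename(path),
                                 compartment = label)
        }
      }, error = function(e) {
        fail_row(basename(path), label, m, conditionMessage(e), config)
      })
    }) |> dplyr::bind_rows()
  }

  rows <- purrr::map(inputs, function(path) {
    img_rois <- if (!is.null(rois)) {
      dplyr::filter(rois, .data$image == basename(path))
    } else {
      NULL
    }
    if (!is.null(img_rois) && nrow(img_rois)) {
      purrr::pmap(img_rois, function(image, compartment_label, row0, col0,
                                     height, width, ...) {
        analyze_one(path, rect_roi(row0, col0, height, width,
                                   compartment_label),
                    compartment_label)
      }) |> dplyr::bind_rows()
    } else {
      analyze_one(path, NULL, NA_character_)
    }
  }) |> dplyr::bind_rows()

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(rows, file.path(output_dir, "results.csv"))
    write_config(config, file.path(output_dir, "config.yaml"))
  }
  rows
}

fail_row <- function(image_id, compartment, method, msg, config) {
  tibble(image = as.character(image_id), animal = NA_character_,
         compartment = as.character(compartment), method = method,
         n_omega_0 = NA_real_, n_omega_45 = NA_real_, n_omega_90 = NA_real_,
         n_omega_135 = NA_real_, index_N = NA_real_,
         config_hash = config_hash(config),
         status = paste0("error: ", msg))
}

#' Generate a phantom series on disk
#'
#' Writes one PNG per (jitter level, replicate) plus a `manifest.csv`
#' recording every generator parameter and seed, so a pipeline run on the
#' series is reproducible end to end.
#'
#' @param output_dir Directory to create.
#' @param jitter_grid Angular-jitter SDs (degrees), non-empty.
#' @param n_seeds Replicates per level.
#' @param base_spec A [phantom_spec()] providing all non-jitter parameters.
#' @param master_seed Integer; per-image seeds are derived from it.
#' @return The manifest tibble, invisibly.
#' @export
run_phantoms <- function(output_dir, jitter_grid = c(0, 10, 20, 30, 40),
                         n_seeds = 10L, base_spec = phantom_spec(),
                         master_seed = 1L) {
  if (length(jitter_grid) == 0L) {
    abort("jitter_grid must be non-empty", class = "bw_error")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(master_seed, length(jitter_grid) * n_seeds)
  manifest <- tidyr::expand_grid(jitter = jitter_grid,
                                 replicate = seq_len(n_seeds))
  manifest$seed <- seeds
  manifest$image <- sprintf("phantom_j%02.0f_r%02d.png",
                            manifest$jitter, manifest$replicate)
  for (i in seq_len(nrow(manifest))) {
    sp <- phantom_spec(height = base_spec$height, width = base_spec$width,
                       fiber_width = base_spec$fiber_width,
                       fiber_spacing = base_spec$fiber_spacing,
                       family_angles = base_spec$family_angles,
                       angular_jitter_sd = manifest$jitter[i],
                       position_jitter_sd = base_spec$position_jitter_sd,
                       n_fibers_per_family = base_spec$n_fibers_per_family,
                       fiber_intensity = base_spec$fiber_intensity,
                       noise_sd = base_spec$noise_sd,
                       background = base_spec$background,
                       seed = manifest$seed[i])
    write_gray_png(generate_basketweave(sp),
                   file.path(output_dir, manifest$image[i]))
  }
  out <- dplyr::bind_cols(
    manifest,
    tibble(height = base_spec$height, width = base_spec$width,
           fiber_width = base_spec$fiber_width,
           fiber_spacing = base_spec$fiber_spacing,
           angle_1 = base_spec$family_angles[1],
           angle_2 = base_spec$family_angles[2],
           fiber_intensity = base_spec$fiber_intensity,
           noise_sd = base_spec$noise_sd,
           background = base_spec$background)
  )
  readr::write_csv(out, file.path(output_dir, "manifest.csv"))
  invisible(out)
}

# Sub-seeds derived deterministically from one master seed; kept below 2^31.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max, n))
}

#' Degradation-monotonicity experiment
#'
#' The package's core sensitivity claim, run as one recipe: render phantom
#' series over a grid of angular-jitter levels, analyze each with both the
#' Gabor+FFT method and the FFT-only baseline, and report per-level means,
#' the Pearson correlation of mean index against jitter per method, and
#' Cohen's d for each adjacent jitter pair per method. For an index that
#' tracks basketweave degradation the mean should fall monotonically with
#' jitter and correlate strongly and negatively with it.
#'
#' @param config A [bw_config()].
#' @param jitter_grid Angular-jitter SDs in degrees.
#' @param n_seeds Phantom replicates per level.
#' @param image_size Phantom side length, pixels.
#' @param master_seed Integer seed for the whole experiment.
#' @param methods Methods to run.
#' @return A list of class `bw_jitter_experiment` with tibbles `per_image`,
#'   `summary`, `correlation`, `effect_sizes`, plus the config.
#' @export
run_experiment_monotonicity <- function(config = bw_config(),
                                        jitter_grid = c(0, 10, 20, 30, 40),
                                        n_seeds = 10L,
                                        image_size = 256L,
                                        master_seed = 1L,
                                        methods = c("gabor_fft",
                                                    "fft_only")) {
  stopifnot(inherits(config, "bw_config"))
  if (length(jitter_grid) < 2L) {
    abort("need at least two jitter levels", class = "bw_error")
  }
  grid <- tidyr::expand_grid(jitter = jitter_grid,
                             replicate = seq_len(n_seeds))
  grid$seed <- derive_seeds(master_seed, nrow(grid))
  per_image <- purrr::pmap(grid, function(jitter, replicate, seed) {
    img <- generate_basketweave(
      phantom_spec(height = image_size, width = image_size,
                   angular_jitter_sd = jitter, seed = seed))
    rows <- purrr::map(methods, function(m) {
      id <- sprintf("j%02.0f_r%02d", jitter, replicate)
      # a degenerate-isotropy image is recorded, not fatal to the series
      tryCatch({
        if (m == "gabor_fft") {
          analyze_image_gabor(img, config, image_id = id)
        } else {
          analyze_image_fft_only(img, config, image_id = id)
        }
      }, error = function(e) fail_row(id, NA_character_, m,
                                      conditionMessage(e), config))
    }) |> dplyr::bind_rows()
    rows$jitter <- jitter
    rows$replicate <- replicate
    rows$seed <- seed
    rows
  }) |> dplyr::bind_rows()

  summary <- per_image |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$method, .data$jitter) |>
    dplyr::summarise(mean_index = mean(.data$index_N),
                     sd_index = sd(.data$index_N),
                     n = dplyr::n(), .groups = "drop")

  correlation <- summary |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3L) {
        # Pearson needs >= 3 level means; report NA for shorter grids
        return(tibble(r = NA_real_, r2 = NA_real_, p = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      n = nrow(d)))
      }
      pearson_report(x = d$jitter, y = d$mean_index)
    }) |>
    dplyr::ungroup()

  ok <- dplyr::filter(per_image, .data$status == "ok")
  effect_sizes <- purrr::map(methods, function(m) {
    lv <- sort(unique(ok$jitter))
    purrr::map(seq_len(length(lv) - 1L), function(i) {
      lo <- ok$index_N[ok$method == m & ok$jitter == lv[i]]
      hi <- ok$index_N[ok$method == m & ok$jitter == lv[i + 1L]]
      tibble(method = m, jitter_low = lv[i], jitter_high = lv[i + 1L],
             cohens_d = cohens_d(lo, hi))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  structure(list(per_image = per_image, summary = summary,
                 correlation = correlation, effect_sizes = effect_sizes,
                 config = config, jitter_grid = jitter_grid,
                 n_seeds = n_seeds, image_size = image_size,
                 master_seed = master_seed),
            class = "bw_jitter_experiment")
}

#' @export
print.bw_jitter_experiment <- function(x, ...) {
  cat(sprintf(
    "<bw_jitter_experiment> %d jitter levels x %d seeds, %d x %d phantoms\n",
    length(x$jitter_grid), x$n_seeds, x$image_size, x$image_size))
  cat("\nPer-level means:\n")
  print(x$summary)
  cat("\nIndex vs jitter correlation:\n")
  print(x$correlation)
  invisible(x)
}

#' @rdname run_experiment_monotonicity
#' @param x A `bw_jitter_experiment`.
#' @param ... Unused.
#' @export
tidy.bw_jitter_experiment <- function(x, ...) x$summary

#' @rdname run_experiment_monotonicity
#' @export
glance.bw_jitter_experiment <- function(x, ...) x$correlation

#' Rotation-sensitivity experiment
#'
#' The method is tuned to the filter-bank orientations, so it tolerates
#' small in-plane rotations but loses sensitivity when the weave rotates out
#' of phase with the bank (toward 22.5-45 degrees). This recipe renders
#' intact (low-jitter) and degraded (high-jitter) phantoms on an oversized
#' canvas, pre-rotates them by each requested angle (0 always included),
#' crops to a common size, and analyzes with the Gabor+FFT method.
#'
#' @param config A [bw_config()].
#' @param angles Pre-rotation angles in degrees (0 is always added).
#' @param intact_jitter,degraded_jitter Jitter SDs defining the two groups.
#' @param n_seeds Replicates per group.
#' @param image_size Side of the analyzed (cropped) square, pixels.
#' @param master_seed Integer seed.
#' @return A list of class `bw_rotation_experiment` with `per_image` and
#'   `summary` tibbles.
#' @export
run_experiment_rotation <- function(config = bw_config(),
                                    angles = c(5, 25),
                                    intact_jitter = 0,
                                    degraded_jitter = 30,
                                    n_seeds = 10L,
                                    image_size = 256L,
                                    master_seed = 1L) {
  stopifnot(inherits(config, "bw_config"))
  angles <- sort(unique(c(0, angles)))
  canvas <- as.integer(ceiling(image_size * 1.6))
  conds <- tibble(condition = c("intact", "degraded"),
                  jitter = c(intact_jitter, degraded_jitter))
  grid <- tidyr::expand_grid(conds, replicate = seq_len(n_seeds))
  grid$seed <- derive_seeds(master_seed, nrow(grid))
  per_image <- purrr::pmap(grid, function(condition, jitter, replicate,
                                          seed) {
    big <- generate_basketweave(
      phantom_spec(height = canvas, width = canvas,
                   angular_jitter_sd = jitter, seed = seed))
    purrr::map(angles, function(a) {
      rot <- if (a == 0) big else rotate_crop(big, a)
      crop <- center_crop(rot, image_size)
      id <- sprintf("%s_r%02d_a%02.0f", condition, replicate, a)
      row <- tryCatch(
        analyze_image_gabor(crop, config, image_id = id),
        error = function(e) fail_row(id, NA_character_, "gabor_fft",
                                     conditionMessage(e), config))
      row$condition <- condition
      row$angle <- a
      row$replicate <- replicate
      row
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  summary <- per_image |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$condition, .data$angle) |>
    dplyr::summarise(mean_index = mean(.data$index_N),
                     sd_index = sd(.data$index_N),
                     n = dplyr::n(), .groups = "drop")

  structure(list(per_image = per_image, summary = summary, config = config,
                 angles = angles, n_seeds = n_seeds,
                 image_size = image_size, master_seed = master_seed),
            class = "bw_rotation_experiment")
}

#' @export
print.bw_rotation_experiment <- function(x, ...) {
  cat(sprintf("<bw_rotation_experiment> angles %s, %d seeds/group\n",
              paste(x$angles, collapse = "/"), x$n_seeds))
  print(x$summary)
  invisible(x)
}

#' @rdname run_experiment_rotation
#' @param x A `bw_rotation_experiment`.
#' @param ... Unused.
#' @export
tidy.bw_rotation_experiment <- function(x, ...) x$summary

center_crop <- function(img, side) {
  if (nrow(img) < side || ncol(img) < side) {
    abort("image smaller than requested crop", class = "bw_error")
  }
  r0 <- (nrow(img) - side) %/% 2L
  c0 <- (ncol(img) - side) %/% 2L
  img[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
}
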