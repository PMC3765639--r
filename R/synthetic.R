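#' Basketweave phantom specification
#'
#' Parameters for the synthetic texture that stands in for cross-polar
#' images of healthy dermis: two families of roughly parallel bright fibres
#' crossing at about 90 degrees (defaults 45 and 135 in the image frame) on
#' a dark background, as birefringent collagen appears between crossed
#' polarizers. The `angular_jitter_sd` knob perturbs each fibre's
#' orientation with a zero-mean normal draw and is the degradation dial:
#' 0 renders an intact weave, larger values progressively relax it toward
#' isotropy, emulating ageing or diabetic skin.
#'
#' @param height,width Image size in pixels.
#' @param fiber_width Fibre thickness, pixels (>= 1).
#' @param fiber_spacing Center-to-center spacing within a family, pixels;
#'   must exceed `fiber_width`.
#' @param family_angles Two base orientations in degrees.
#' @param angular_jitter_sd SD of the per-fibre orientation perturbation,
#'   degrees (>= 0).
#' @param position_jitter_sd SD (pixels) of the per-fibre perturbation of
#'   its position along the family normal. Real fibre bundles are not
#'   periodic; without this irregularity a phantom is a perfect lattice
#'   whose spectrum collapses into a harmonic comb instead of the
#'   continuous directional ridge that tissue texture produces. Defaults to
#'   a third of the spacing.
#' @param n_fibers_per_family Fibres rendered per family; `NULL` picks
#'   enough to cover the frame at the given spacing.
#' @param fiber_intensity Additive brightness of one fibre.
#' @param noise_sd SD of additive Gaussian intensity noise.
#' @param background Background level in `[0, 1)`.
#' @param seed Integer seed; recorded in the output metadata so every
#'   phantom is reproducible.
#' @return A list of class `bw_phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L,
                         fiber_width = 3, fiber_spacing = 12,
                         family_angles = c(45, 135),
                         angular_jitter_sd = 0,
                         position_jitter_sd = NULL,
                         n_fibers_per_family = NULL,
                         fiber_intensity = 0.6,
                         noise_sd = 0.05,
                         background = 0.05,
                         seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               fiber_width = as.numeric(fiber_width),
               fiber_spacing = as.numeric(fiber_spacing),
               family_angles = as.numeric(family_angles),
               angular_jitter_sd = as.numeric(angular_jitter_sd),
               position_jitter_sd = as.numeric(position_jitter_sd %||%
                                                 (fiber_spacing / 3)),
               n_fibers_per_family = n_fibers_per_family,
               fiber_intensity = as.numeric(fiber_intensity),
               noise_sd = as.numeric(noise_sd),
               background = as.numeric(background),
               seed = as.integer(seed))
  if (spec$fiber_width < 1) {
    abort("fiber_width must be >= 1 pixel", class = "bw_error")
  }
  if (spec$fiber_spacing <= spec$fiber_width) {
    abort("fiber_spacing must exceed fiber_width", class = "bw_error")
  }
  if (spec$angular_jitter_sd < 0) {
    abort("angular_jitter_sd must be >= 0", class = "bw_error")
  }
  if (spec$position_jitter_sd < 0) {
    abort("position_jitter_sd must be >= 0", class = "bw_error")
  }
  if (length(spec$family_angles) != 2L) {
    abort("family_angles must hold two orientations", class = "bw_error")
  }
  if (is.null(spec$n_fibers_per_family)) {
    spec$n_fibers_per_family <- as.integer(
      ceiling(sqrt(spec$height^2 + spec$width^2) / spec$fiber_spacing) + 1L)
  } else {
    spec$n_fibers_per_family <- as.integer(spec$n_fibers_per_family)
  }
  structure(spec, class = "bw_phantom_spec")
}

#' Render a basketweave phantom
#'
#' Draws two families of anti-aliased straight fibres. Fibres within a
#' family are laid out at regular spacing along the family's normal; each
#' fibre's own orientation is the family angle plus a zero-mean normal draw
#' with SD `angular_jitter_sd`. Fibre intensities add where fibres overlap
#' (bright birefringent crossings), Gaussian intensity noise is added, and
#' the result is clipped to `[0, 1]`. Identical spec and seed give an
#' identical image.
#'
#' @param spec A [phantom_spec()].
#' @return A numeric matrix in `[0, 1]` with attributes `phantom_spec` and
#'   `seed`.
#' @examples
#' img <- generate_basketweave(phantom_spec(height = 128, width = 128,
#'                                          seed = 7))
#' range(img)
#' @export
generate_basketweave <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "bw_phantom_spec"))
  h <- spec$height
  w <- spec$width
  xs <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  ys <- matrix(seq_len(h), nrow = h, ncol = w)
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  img <- withr::with_seed(spec$seed, {
    acc <- matrix(spec$background, h, w)
    nf <- spec$n_fibers_per_family
    for (alpha in spec$family_angles) {
      a0 <- deg2rad(alpha)
      # regular positions along the family normal, centered on the frame
      offs <- (seq_len(nf) - (nf + 1) / 2) * spec$fiber_spacing +
        rnorm(nf, mean = 0, sd = spec$position_jitter_sd)
      jit <- rnorm(nf, mean = 0, sd = spec$angular_jitter_sd)
      for (i in seq_len(nf)) {
        px <- cx - sin(a0) * offs[i]
        py <- cy + cos(a0) * offs[i]
        ai <- deg2rad(alpha + jit[i])
        dist <- abs((xs - px) * (-sin(ai)) + (ys - py) * cos(ai))
        prof <- pmin(1, pmax(0, spec$fiber_width / 2 + 0.5 - dist))
        acc <- acc + spec$fiber_intensity * prof
      }
    }
    if (spec$noise_sd > 0) {
      acc <- acc + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    acc
  })
  img <- clip01(img)
  attr(img, "phantom_spec") <- spec
  attr(img, "seed") <- spec$seed
  img
}

#' Isotropic white-noise control image
#'
#' The fully disordered control: Gaussian white noise clipped to `[0, 1]`,
#' with no directional structure, realizing the equal-ellipse regime where
#' the orientation index approaches 1.
#'
#' @param height,width Image size, each at least 64.
#' @param seed Integer seed.
#' @param mean,sd Noise mean and SD before clipping.
#' @return A numeric matrix in `[0, 1]` with attribute `seed`.
#' @export
generate_isotropic <- function(height = 512L, width = 512L, seed = 1L,
                               mean = 0.5, sd = 0.15) {
  height <- as.integer(height)
  width <- as.integer(width)
  if (height < 64L || width < 64L) {
    abort("isotropic controls must be at least 64 x 64", class = "bw_error")
  }
  img <- withr::with_seed(as.integer(seed), {
    matrix(rnorm(height * width, mean, sd), height, width)
  })
  img <- clip01(img)
  attr(img, "seed") <- as.integer(seed)
  img
}

#' Rotate an image and crop away the padding
#'
#' Multiples of 90 degrees are exact quarter-turn permutations with no crop.
#' Other angles (|angle| <= 45) use bilinear interpolation about the image
#' center followed by a central crop to the largest axis-aligned square
#' guaranteed free of out-of-frame padding. Used for the rotation-
#' sensitivity experiments.
#'
#' @param img Numeric matrix.
#' @param angle Degrees; positive rotates texture orientation by `+angle`
#'   (counter-clockwise in the column-x/row-y frame).
#' @return A numeric matrix.
#' @export
rotate_crop <- function(img, angle) {
  stop_not_matrix(img)
  if (abs(angle - round(angle / 90) * 90) < 1e-9) {
    # rot90_ccw turns orientation by -90, so a +90 texture rotation is k = -1
    return(rot90_ccw(img, -as.integer(round(angle / 90))))
  }
  if (abs(angle) > 45) {
    abort("interpolated rotation supports |angle| <= 45 degrees",
          class = "bw_error")
  }
  h <- nrow(img)
  w <- ncol(img)
  a <- deg2rad(angle)
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  xs <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE) - cx
  ys <- matrix(seq_len(h), nrow = h, ncol = w) - cy
  # inverse map: sample the source at the backward-rotated location
  sx <- cos(a) * xs + sin(a) * ys + cx
  sy <- -sin(a) * xs + cos(a) * ys + cy
  x0 <- pmin(pmax(floor(sx), 1), w - 1)
  y0 <- pmin(pmax(floor(sy), 1), h - 1)
  fx <- sx - x0
  fy <- sy - y0
  idx <- function(r, c) img[cbind(as.vector(r), as.vector(c))]
  v <- (1 - fx) * (1 - fy) * idx(y0, x0) +
    fx * (1 - fy) * idx(y0, x0 + 1) +
    (1 - fx) * fy * idx(y0 + 1, x0) +
    fx * fy * idx(y0 + 1, x0 + 1)
  rot <- matrix(v, h, w)
  side <- floor(min(h, w) / (abs(cos(a)) + abs(sin(a)))) - 2L
  if (side < 64L) {
    abort("rotated central crop would be smaller than 64 x 64",
          class = "bw_error")
  }
  r0 <- floor((h - side) / 2)
  c0 <- floor((w - side) / 2)
  rot[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
}

#' Wedge-integrated spectral energy
#'
#' Ground-truth oracle for phantom orientation: sums squared amplitudes of a
#' centered spectrum over bins whose frequency angle lies within
#' `half_width` of `angle` (mod 180), excluding a small radius around DC.
#' A fibre family at orientation alpha concentrates spectral energy along
#' the perpendicular direction alpha + 90.
#'
#' @param spec Centered amplitude spectrum.
#' @param angle Wedge center, degrees (mod 180).
#' @param half_width Wedge half-width, degrees.
#' @param min_radius Bins closer to DC than this are excluded.
#' @return Scalar energy.
#' @export
wedge_energy <- function(spec, angle, half_width = 10, min_radius = 3) {
  stop_not_matrix(spec, "spectrum")
  dc <- attr(spec, "dc") %||% dc_index(dim(spec))
  rows <- matrix(seq_len(nrow(spec)) - dc[1], nrow(spec), ncol(spec))
  cols <- matrix(seq_len(ncol(spec)) - dc[2], nrow(spec), ncol(spec),
                 byrow = TRUE)
  rad <- sqrt(rows^2 + cols^2)
  ang <- (atan2(rows, cols) * 180 / pi) %% 180
  diff <- abs(ang - (angle %% 180))
  diff <- pmin(diff, 180 - diff)
  sel <- rad >= min_radius & diff <= half_width
  sum(spec[sel]^2)
}
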