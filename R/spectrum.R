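#' 2-D Hann window
#'
#' Multiplies an image by the separable product of two 1-D Hann windows.
#' Without windowing, the frame-edge discontinuities of a finite image leak a
#' bright axis-aligned cross into the Fourier spectrum that would corrupt the
#' ellipse measurements; the Hann taper (zero at the frame edges, unity at
#' the center of odd-sized frames) suppresses it.
#'
#' @param img Numeric matrix, at least 16 x 16.
#' @return Matrix of the same dimensions.
#' @export
hann2d <- function(img) {
  check_gray(img)
  wr <- hann1d(nrow(img))
  wc <- hann1d(ncol(img))
  img * tcrossprod(wr, wc)
}

# Symmetric Hann window of length n: 0 at both endpoints, 1 at the midpoint
# for odd n.
hann1d <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Centered FFT amplitude spectrum
#'
#' Computes the modulus of the 2-D discrete Fourier transform under the
#' `1/(MN)` normalization
#' \deqn{F(u,v) = \frac{1}{MN}\sum_{x=0}^{M-1}\sum_{y=0}^{N-1} f(x,y)\,
#'   e^{-j 2\pi (ux/M + vy/N)}}
#' and shifts it so the zero-frequency (DC) bin sits at the array center
#' (index `(floor(M/2)+1, floor(N/2)+1)`). Under this normalization a
#' constant image of value `c` has DC amplitude exactly `c`, and Parseval's
#' identity reads `sum(|F|^2) = mean(f^2)`.
#'
#' @param img Numeric matrix of finite values.
#' @return A non-negative matrix of the same dimensions, DC at the center,
#'   with attribute `dc` giving the DC bin index.
#' @examples
#' a <- amplitude_spectrum(matrix(3, 32, 32))
#' a[17, 17]      # DC bin = the image mean
#' sum(a) - 3     # every other bin is 0
#' @export
amplitude_spectrum <- function(img) {
  stop_not_matrix(img, "spectrum input")
  f <- stats::fft(img) / length(img)
  out <- fftshift2(Mod(f))
  attr(out, "dc") <- dc_index(dim(img))
  out
}

#' Binarize an amplitude spectrum into its "binary ellipse"
#'
#' Thresholds the (optionally log-compressed) spectrum at a high quantile.
#' Log compression tames the DC-dominated dynamic range and the quantile
#' form makes the mask invariant to image gain.
#'
#' With `component = "central"` a single connected component is kept: the
#' one containing the DC bin if it is above threshold, otherwise the largest
#' component (8-connectivity, so oblique spectral ridges stay whole). This
#' is appropriate for smooth, single-blob spectra. With `component = "none"`
#' the whole supra-threshold scatter is returned; because amplitude spectra
#' of real images are centrosymmetric, this set is a centered binary scatter
#' pattern, and it is what the analysis pipeline measures: the spectra of
#' textured images are speckled, so their supra-threshold sets fragment into
#' many small components, and a single fragment's shape reflects speckle
#' noise rather than the texture's orientation distribution.
#'
#' @param spec Matrix from [amplitude_spectrum()].
#' @param quantile Threshold quantile in (0, 1).
#' @param log_compress Threshold `log1p(spec)` instead of `spec`.
#' @param component `"central"` (keep the DC/largest connected component) or
#'   `"none"` (keep the full scatter).
#' @return A logical matrix marking the surviving bins.
#' @export
binarize_spectrum <- function(spec, quantile = 0.995, log_compress = TRUE,
                              component = c("central", "none")) {
  component <- match.arg(component)
  stop_not_matrix(spec, "spectrum")
  if (quantile <= 0 || quantile >= 1) {
    abort("quantile must lie in (0, 1)", class = "bw_error")
  }
  v <- if (log_compress) log1p(spec) else spec
  thr <- stats::quantile(v, quantile, names = FALSE)
  # zero-amplitude bins carry no energy and can never belong to a blob,
  # even when a sparse spectrum pulls the quantile threshold down to zero
  mask <- v >= thr & spec > 0
  if (!any(mask)) {
    abort("degenerate spectrum: no bins at or above threshold",
          class = "bw_degenerate")
  }
  if (component == "none") return(mask)
  lab <- label_components8(mask)
  dc <- attr(spec, "dc") %||% dc_index(dim(spec))
  dc_lab <- lab[dc[1], dc[2]]
  keep <- if (!is.na(dc_lab) && dc_lab > 0L) {
    dc_lab
  } else {
    tab <- tabulate(lab[mask])
    which.max(tab)
  }
  out <- lab == keep
  out[is.na(out)] <- FALSE
  out
}

# 8-connected component labels of a logical mask; 0 for background. Built on
# a sparse pixel graph so cost scales with the number of set bins, not the
# frame size.
label_components8 <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- length(idx)
  if (n == 0L) return(lab)
  nr <- nrow(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  key <- as.numeric(idx)
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + d[1]
    c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= ncol(mask)
    nb_key <- (as.numeric(c2) - 1) * nr + r2
    nb_key[!ok] <- NA_real_
    hit <- match(nb_key, key)
    src <- which(!is.na(hit))
    if (length(src)) edges <- c(edges, rbind(src, hit[src]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

#' Moment-equivalent ellipse of a binary blob
#'
#' Summarizes a binary region by the ellipse sharing its second central
#' moments: axis lengths are `4 * sqrt(eigenvalues)` of the covariance of the
#' set-bin coordinates (the convention used by standard region-properties
#' tools), and the orientation is the principal eigenvector's angle. Axes are
#' floored at 1 bin so a single-bin (or collinear) mask degenerates to a
#' declared `long = short = 1` rather than a zero axis.
#'
#' @param mask Logical matrix with at least one set bin.
#' @return A list of class `bw_ellipse` with fields `long_axis`,
#'   `short_axis`, `orientation` (degrees in (-90, 90], measured from the
#'   column axis) and `n_bins`.
#' @examples
#' m <- matrix(FALSE, 64, 64)
#' m[30:33, 10:49] <- TRUE      # a 4 x 40 bar
#' e <- equivalent_ellipse(m)
#' e$long_axis / e$short_axis   # close to 10
#' @export
equivalent_ellipse <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("mask must be a logical matrix", class = "bw_error")
  }
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L) abort("empty mask", class = "bw_degenerate")
  if (n == 1L) {
    return(structure(list(long_axis = 1, short_axis = 1, orientation = 0,
                          n_bins = 1L), class = "bw_ellipse"))
  }
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  cv <- crossprod(d) / n
  eg <- eigen(cv, symmetric = TRUE)
  axes <- pmax(4 * sqrt(pmax(eg$values, 0)), 1)
  v <- eg$vectors[, 1] # (row, col) components of the major axis
  ang <- atan2(v[1], v[2]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  if (ang == -90) ang <- 90
  structure(list(long_axis = axes[1], short_axis = axes[2],
                 orientation = ang, n_bins = as.integer(n)),
            class = "bw_ellipse")
}

#' @export
print.bw_ellipse <- function(x, ...) {
  cat(sprintf(
    "<bw_ellipse> long %.3f, short %.3f, orientation %.1f deg, %d bins\n",
    x$long_axis, x$short_axis, x$orientation, x$n_bins))
  invisible(x)
}
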