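# Internal numeric helpers shared across the pipeline.

# Reflect padding including the edge sample: for r = 2 the rows above the
# image read (row2, row1 | row1, row2, ...). Requires r <= dim.
pad_reflect <- function(m, r) {
  if (r == 0L) return(m)
  nr <- nrow(m)
  nc <- ncol(m)
  if (r > nr || r > nc) {
    abort("reflect padding radius exceeds image size", class = "bw_error")
  }
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

# Circular shift so the (1,1) element moves to (floor(nr/2)+1, floor(nc/2)+1);
# the standard fftshift placing DC at the array center.
fftshift2 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- ((seq_len(nr) - 1L - nr %/% 2L) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - nc %/% 2L) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

# 1-based index of the DC bin in a centered spectrum.
dc_index <- function(dims) c(dims[1] %/% 2L + 1L, dims[2] %/% 2L + 1L)

# Exact counter-clockwise quarter turn (visual orientation alpha -> alpha-90
# in the col-x / row-y frame used throughout).
rot90_ccw <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

deg2rad <- function(d) d * pi / 180

# Clip to [0, 1] preserving dim/attributes (pmin/pmax with a scalar first
# argument would drop them).
clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

stop_not_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(paste0(what, " must be a numeric matrix"), class = "bw_error")
  }
  if (!all(is.finite(x))) {
    abort(paste0(what, " contains non-finite values"), class = "bw_error")
  }
  invisible(x)
}
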