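#' Define an axon path for kymograph extraction and tracking
#'
#' @param vertices Data frame or matrix of `x`, `y` pixel coordinates (0-based
#'   arc length is measured from the first vertex, which is declared to be the
#'   soma end; positions therefore increase toward the presynapse).
#' @param width Transverse extraction width, pixels (`>= 1`).
#' @return List of class `axq_axon_path` with resampled arc-length samples.
#' @export
axon_path <- function(vertices, width = 5) {
  v <- as.matrix(as.data.frame(vertices)[, c("x", "y")])
  if (nrow(v) < 2L) stopf("an axon path needs at least 2 vertices")
  if (width < 1) stopf("`width` must be >= 1 pixel")
  seglen <- sqrt(rowSums(diff(v)^2))
  if (sum(seglen) <= 0) stopf("axon path has zero arc length")
  structure(list(vertices = v, width = width,
                 length_px = sum(seglen)), class = "axq_axon_path")
}

# Resample the path at `step` px arc-length intervals; returns positions and
# unit normals at each sample.
resample_path <- function(path, step = 1) {
  v <- path$vertices
  seglen <- sqrt(rowSums(diff(v)^2))
  s_vert <- c(0, cumsum(seglen))
  s_out <- seq(0, path$length_px, by = step)
  x <- stats::approx(s_vert, v[, 1], xout = s_out)$y
  y <- stats::approx(s_vert, v[, 2], xout = s_out)$y
  # Tangents by central differences; normals are perpendicular.
  tx <- c(diff(x)[1], (x[-1] - x[-length(x)]))
  ty <- c(diff(y)[1], (y[-1] - y[-length(y)]))
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  list(s = s_out, x = x, y = y, nx = -ty / nrm, ny = tx / nrm,
       tx = tx / nrm, ty = ty / nrm)
}

#' Extract a kymograph from a movie along an axon path
#'
#' Builds the classic space-time image: each row is one frame, each column an
#' arc-length bin along the path (one bin per pixel), and each cell holds the
#' maximum intensity across the path's transverse width at that bin. Moving
#' vesicles appear as sloped lines whose slope encodes velocity.
#'
#' @param movie Array `[y, x, frame]` (as produced by
#'   [simulate_axonal_movie()] or [read_stack()]).
#' @param path An [axon_path()].
#' @return Matrix of class `axq_kymograph` (`frames x bins`) with attributes
#'   `bin_size_um`, `frame_interval` and `pixel_size`.
#' @export
extract_kymograph <- function(movie, path) {
  stopifnot(inherits(path, "axq_axon_path"))
  ny <- dim(movie)[1]; nx <- dim(movie)[2]; nf <- dim(movie)[3]
  rs <- resample_path(path, step = 1)
  w2 <- floor(path$width / 2)
  offsets <- seq(-w2, w2)
  # Nearest-pixel sample coordinates for every (bin, transverse offset).
  xs <- round(outer(rs$x, offsets * 0, `+`) + outer(rs$nx, offsets))
  ys <- round(outer(rs$y, offsets * 0, `+`) + outer(rs$ny, offsets))
  if (any(xs < 1 | xs > nx | ys < 1 | ys > ny))
    stopf("axon path (with width %d) exits the image bounds", path$width)
  idx2d <- cbind(as.vector(ys), as.vector(xs))
  nbin <- length(rs$s)
  kymo <- matrix(0, nf, nbin)
  for (f in seq_len(nf)) {
    frame <- movie[, , f]
    vals <- matrix(frame[idx2d], nbin, length(offsets))
    kymo[f, ] <- apply(vals, 1L, max)
  }
  px <- attr(movie, "pixel_size") %||% 0.1
  structure(kymo, class = "axq_kymograph",
            bin_size_um = px, pixel_size = px,
            frame_interval = attr(movie, "frame_interval") %||% 0.2)
}
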