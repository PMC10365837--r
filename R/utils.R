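# Internal geometry and rendering helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && abs(x - round(x)) < 1e-8

#' @keywords internal
#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single value in [0, 1]", name)
  invisible(x)
}

# Signed shoelace area of a single ring given as a list(x, y) or matrix.
shoelace_area <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Minimal Euclidean distance from points (px, py) to a polyline given by
# vertex matrix `line` (n x 2). Vectorised over points.
dist_to_polyline <- function(px, py, line) {
  stopifnot(nrow(line) >= 2L)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(line) - 1L)) {
    ax <- line[i, 1]; ay <- line[i, 2]
    bx <- line[i + 1L, 1]; by <- line[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
      di <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
      di <- (px - ax - t * vx)^2 + (py - ay - t * vy)^2
    }
    d2 <- pmin(d2, di)
  }
  sqrt(d2)
}

# Points strictly inside or on the boundary of a simple polygon.
points_in_polygon <- function(px, py, poly) {
  if (length(px) == 0L) return(logical(0))
  pracma::inpolygon(px, py, poly[, 1], poly[, 2], boundary = TRUE)
}

# Do any two non-adjacent edges of the closed ring intersect?
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  seg <- function(i) {
    j <- if (i == n) 1L else i + 1L
    rbind(poly[i, ], poly[j, ])
  }
  ccw <- function(a, b, c)
    (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  intersects <- function(s1, s2) {
    a <- s1[1, ]; b <- s1[2, ]; c <- s2[1, ]; d <- s2[2, ]
    ccw(a, c, d) != ccw(b, c, d) && ccw(a, b, c) != ccw(a, b, d)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (intersects(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

# Add a Gaussian spot (peak `amplitude`, s.d. `sigma` px) into matrix `frame`
# at sub-pixel centre (x, y); frame is indexed [row = y, col = x].
add_spot <- function(frame, x, y, amplitude, sigma) {
  r <- ceiling(4 * sigma)
  nx <- ncol(frame); ny <- nrow(frame)
  xs <- max(1L, floor(x - r)):min(nx, ceiling(x + r))
  ys <- max(1L, floor(y - r)):min(ny, ceiling(y + r))
  if (length(xs) == 0L || length(ys) == 0L) return(frame)
  gx <- exp(-((xs - x)^2) / (2 * sigma^2))
  gy <- exp(-((ys - y)^2) / (2 * sigma^2))
  frame[ys, xs] <- frame[ys, xs] + amplitude * outer(gy, gx)
  frame
}

# Apply the configured shot/read noise model to a clean photon-count stack.
apply_noise <- function(stack, noise_model, noise_sd = NULL) {
  switch(noise_model,
    none = stack,
    poisson = {
      out <- stack
      out[] <- stats::rpois(length(stack), lambda = pmax(stack, 0))
      out
    },
    gaussian = {
      sd <- noise_sd %||% sqrt(mean(stack))
      stack + stats::rnorm(length(stack), sd = sd)
    },
    stopf("unknown noise_model '%s' (use 'poisson', 'gaussian' or 'none')",
          noise_model)
  )
}

# md5 of the canonical JSON serialisation of a config list.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}
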