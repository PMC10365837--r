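#' Simulate an annotated presynaptic terminal for EM morphometry
#'
#' Generates a terminal outline (a radially perturbed ellipse), an active-zone
#' polyline along the PSD-facing (bottom) stretch of the membrane, and vesicle
#' centroids placed uniformly within requested distance bands from the active
#' zone, clipped to the terminal. Centroids respect a hard-core constraint of
#' `2 * vesicle_radius` (synaptic vesicles do not interpenetrate). All
#' coordinates are in nanometres.
#'
#' @param terminal_shape List with `width`, `height` (nm), optional
#'   `irregularity` (radial noise fraction, default 0.12), `n_vertices`
#'   (default 28) and `az_fraction` (fraction of the boundary forming the
#'   active zone, default 0.3).
#' @param n_vesicles Number of vesicle centroids.
#' @param zone_mix Length-4 proportions over
#'   `c(zone1, zone2, zone3, beyond)`; must sum to 1. Bands are
#'   `[0, 40)`, `[40, 80)`, `[80, 120)` and `[120, Inf)` nm from the active
#'   zone (with the default `band_width`). The default mix is bottom-heavy:
#'   the proximal zone (readily releasable pool) holds few vesicles while
#'   most of the pool sits beyond 120 nm, as in presynaptic sections.
#' @param vesicle_radius Vesicle radius, nm.
#' @param band_width Zone width, nm (default 40).
#' @param seed Integer seed.
#'
#' @return A list with:
#'   * `geometry`: list of class `axq_synapse_geometry` with `terminal`
#'     (closed ring, matrix nm), `active_zone` (polyline matrix nm),
#'     `vesicles` (tibble `x`, `y`) and `vesicle_radius`;
#'   * `truth`: tibble `(vesicle, x, y, zone, distance_nm)`.
#' @export
simulate_em_synapse <- function(terminal_shape = list(width = 600, height = 360),
                                n_vesicles = 40,
                                zone_mix = c(zone1 = 0.12, zone2 = 0.18,
                                             zone3 = 0.25, beyond = 0.45),
                                vesicle_radius = 20,
                                band_width = 40,
                                seed = 1L) {
  if (abs(sum(zone_mix) - 1) > 1e-8) stopf("`zone_mix` must sum to 1")
  if (length(zone_mix) != 4L) stopf("`zone_mix` must have 4 components")
  set.seed(as.integer(seed))

  a <- terminal_shape$width / 2
  b <- terminal_shape$height / 2
  irr <- terminal_shape$irregularity %||% 0.12
  nv <- terminal_shape$n_vertices %||% 28L
  azf <- terminal_shape$az_fraction %||% 0.3

  theta <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  rad <- 1 + stats::runif(nv, -irr, irr)
  terminal <- cbind(x = a * rad * cos(theta), y = b * rad * sin(theta))

  # Active zone: the bottom arc of the boundary, centred at angle -pi/2.
  half <- azf * pi
  az_theta <- seq(-pi / 2 - half, -pi / 2 + half, length.out = 9L)
  az_rad <- stats::approx(
    x = c(theta, theta[1L] + 2 * pi), y = c(rad, rad[1L]),
    xout = az_theta %% (2 * pi))$y
  active_zone <- cbind(x = a * az_rad * cos(az_theta),
                       y = b * az_rad * sin(az_theta))

  zones <- c("zone1", "zone2", "zone3", "beyond")
  assigned <- if (n_vesicles > 0)
    sample(zones, n_vesicles, replace = TRUE, prob = zone_mix) else character()

  bbox <- apply(terminal, 2, range)
  # place the narrow proximal bands first: they are the tightest under the
  # hard-core constraint; a failed configuration is reshuffled and retried
  order_idx <- order(match(assigned, zones))
  pts <- matrix(NA_real_, n_vesicles, 2L)
  dists <- numeric(n_vesicles)
  for (attempt in seq_len(5L)) {
    pts[] <- NA_real_
    failed_band <- NULL
    for (i in order_idx) {
      band <- match(assigned[i], zones)
      lo <- (band - 1L) * band_width
      hi <- if (band == 4L) Inf else band * band_width
      placed <- FALSE
      for (try in seq_len(8000L)) {
        x <- stats::runif(1L, bbox[1, 1], bbox[2, 1])
        y <- stats::runif(1L, bbox[1, 2], bbox[2, 2])
        if (!points_in_polygon(x, y, terminal)) next
        d <- dist_to_polyline(x, y, active_zone)
        if (d < lo || d >= hi) next
        prev <- pts[!is.na(pts[, 1]), , drop = FALSE]
        if (nrow(prev) && any((prev[, 1] - x)^2 + (prev[, 2] - y)^2 <
                              (2 * vesicle_radius)^2)) next
        pts[i, ] <- c(x, y); dists[i] <- d; placed <- TRUE
        break
      }
      if (!placed) { failed_band <- c(lo, hi); break }
    }
    if (is.null(failed_band)) break
    if (attempt == 5L)
      stopf("could not place a vesicle in band [%g, %g) nm: band empty after clipping or overcrowded",
            failed_band[1], failed_band[2])
  }

  geometry <- structure(list(
    terminal = terminal, active_zone = active_zone,
    vesicles = tibble::tibble(x = pts[, 1], y = pts[, 2]),
    vesicle_radius = vesicle_radius), class = "axq_synapse_geometry")
  truth <- tibble::tibble(vesicle = seq_len(n_vesicles),
                          x = pts[, 1], y = pts[, 2],
                          zone = assigned, distance_nm = dists)
  list(geometry = geometry, truth = truth)
}
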