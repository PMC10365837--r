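#' Area of a presynaptic terminal outline
#'
#' Shoelace area of the closed terminal polygon, converted from nm^2 to um^2.
#' Vertex orientation does not matter; self-intersecting outlines are
#' rejected.
#'
#' @param outline Matrix or data frame of `x`, `y` vertices in nm (ring not
#'   repeated).
#' @return Area in um^2.
#' @export
terminal_area <- function(outline) {
  m <- as.matrix(as.data.frame(outline)[, 1:2])
  if (nrow(m) < 3L) stopf("a polygon needs at least 3 vertices")
  if (!polygon_is_simple(m)) stopf("terminal outline is self-intersecting")
  abs(shoelace_area(m)) * 1e-6
}

#' Vesicle density of a terminal
#'
#' @param count Number of vesicles (`>= 0`).
#' @param area Terminal area in um^2 (`> 0`).
#' @return Vesicles per um^2.
#' @export
vesicle_density <- function(count, area) {
  if (area <= 0) stopf("`area` must be > 0")
  count / area
}

#' Synapse density per region
#'
#' Synapse counts are made on axon-free neuropil regions and expressed per
#' 100 um^2.
#'
#' @param synapse_count Number of synapses (`>= 0`).
#' @param region_area Region area in um^2 (`> 0`).
#' @return Synapses per 100 um^2.
#' @export
synapse_density <- function(synapse_count, region_area) {
  if (region_area <= 0) stopf("`region_area` must be > 0")
  100 * synapse_count / region_area
}

#' Partition a presynaptic terminal into distance zones from the active zone
#'
#' Builds the 40-nm-wide zones: band `k` contains the points of the terminal
#' whose minimal Euclidean distance to the active-zone polyline lies in
#' `[(k-1) w, k w)` nm. Band regions are constructed as Clipper buffer
#' differences around the polyline, clipped to the terminal outline; their
#' areas are shoelace areas of the clipped rings.
#'
#' @param geometry An `axq_synapse_geometry` (see [simulate_em_synapse()]) or
#'   a list with `terminal` and `active_zone` matrices in nm.
#' @param band_width Zone width in nm (default 40).
#' @param n_bands Number of zones (default 3, so boundaries fall at 40, 80
#'   and 120 nm).
#' @param arc_tol Clipper arc-approximation tolerance in nm (smaller = finer
#'   circular joins).
#' @return List of class `axq_zone_partition` with `bands`, a tibble
#'   `(zone, d_min_nm, d_max_nm, area_um2)`, `polygons` (per-zone lists of
#'   coordinate rings, nm), `band_width` and `n_bands`.
#' @export
partition_zones <- function(geometry, band_width = 40, n_bands = 3L,
                            arc_tol = 0.05) {
  az <- geometry$active_zone
  term <- geometry$terminal
  if (nrow(az) < 2L || sum(sqrt(rowSums(diff(az)^2))) <= 0)
    stopf("active zone polyline is degenerate (zero length)")
  az_l <- list(x = az[, 1], y = az[, 2])
  term_l <- list(list(x = term[, 1], y = term[, 2]))

  buffer <- function(d) {
    polyclip::polylineoffset(az_l, d, jointype = "round",
                             endtype = "openround", arctol = arc_tol)
  }
  ring_area <- function(rings)
    sum(vapply(rings, function(r) shoelace_area(r$x, r$y), numeric(1)))

  prev <- NULL
  polys <- vector("list", n_bands)
  areas <- numeric(n_bands)
  for (k in seq_len(n_bands)) {
    outer_buf <- buffer(k * band_width)
    band <- if (is.null(prev)) outer_buf else
      polyclip::polyclip(outer_buf, prev, op = "minus")
    clipped <- polyclip::polyclip(band, term_l, op = "intersection")
    polys[[k]] <- clipped
    areas[k] <- abs(ring_area(clipped)) * 1e-6
    prev <- outer_buf
  }
  structure(list(
    bands = tibble::tibble(
      zone = paste0("zone", seq_len(n_bands)),
      d_min_nm = (seq_len(n_bands) - 1) * band_width,
      d_max_nm = seq_len(n_bands) * band_width,
      area_um2 = areas),
    polygons = polys,
    band_width = band_width, n_bands = as.integer(n_bands)),
    class = "axq_zone_partition")
}

#' Assign vesicle centroids to distance zones
#'
#' Each centroid inside the terminal is assigned to the unique half-open band
#' `[(k-1) w, k w)` containing its minimal Euclidean distance to the
#' active-zone polyline; centroids at `>= n_bands * w` are labelled
#' `"beyond"`. Centroids outside the terminal are excluded (zone
#' `"excluded"`) with a warning.
#'
#' @inheritParams partition_zones
#' @param partition A [partition_zones()] result for the same geometry.
#' @return Tibble `(vesicle, x, y, distance_nm, zone)`.
#' @export
assign_vesicles <- function(geometry, partition) {
  stopifnot(inherits(partition, "axq_zone_partition"))
  ves <- tibble::as_tibble(geometry$vesicles)
  if (nrow(ves) == 0L)
    return(tibble::tibble(vesicle = integer(), x = numeric(), y = numeric(),
                          distance_nm = numeric(), zone = character()))
  w <- partition$band_width
  nb <- partition$n_bands
  d <- dist_to_polyline(ves$x, ves$y, geometry$active_zone)
  inside <- points_in_polygon(ves$x, ves$y, geometry$terminal)
  band <- floor(d / w) + 1
  zone <- ifelse(!inside, "excluded",
                 ifelse(band <= nb, paste0("zone", pmin(band, nb)), "beyond"))
  if (any(!inside))
    warnf("%d centroid(s) outside the terminal excluded from zone counts",
          sum(!inside))
  tibble::tibble(vesicle = seq_len(nrow(ves)), x = ves$x, y = ves$y,
                 distance_nm = d, zone = zone)
}

#' Per-zone vesicle counts
#'
#' @param assignments Output of [assign_vesicles()].
#' @param n_bands Number of named zones.
#' @return Tibble `(zone, n)` covering every zone plus `beyond` and
#'   `excluded`; counts sum to the number of centroids (conservation).
#' @export
zone_counts <- function(assignments, n_bands = 3L) {
  levels <- c(paste0("zone", seq_len(n_bands)), "beyond", "excluded")
  tibble::tibble(zone = levels) |>
    dplyr::left_join(dplyr::count(assignments, .data$zone), by = "zone") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Full morphometry of one annotated synapse
#'
#' @inheritParams partition_zones
#' @return One-row tibble with the terminal area, vesicle count and density,
#'   and per-zone counts, areas and densities (`zoneK_n`, `zoneK_area_um2`,
#'   `zoneK_density`).
#' @export
em_metrics <- function(geometry, band_width = 40, n_bands = 3L) {
  part <- partition_zones(geometry, band_width, n_bands)
  asg <- assign_vesicles(geometry, part)
  cnt <- zone_counts(asg, n_bands)
  area <- terminal_area(geometry$terminal)
  n_inside <- sum(asg$zone != "excluded")
  out <- tibble::tibble(terminal_area_um2 = area,
                        vesicle_count = n_inside,
                        density_per_um2 = n_inside / area)
  for (k in seq_len(n_bands)) {
    z <- paste0("zone", k)
    nk <- cnt$n[cnt$zone == z]
    ak <- part$bands$area_um2[k]
    out[[paste0(z, "_n")]] <- nk
    out[[paste0(z, "_area_um2")]] <- ak
    out[[paste0(z, "_density")]] <- if (ak > 0) nk / ak else NA_real_
  }
  out$beyond_n <- cnt$n[cnt$zone == "beyond"]
  out
}
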