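test_that("terminal area and densities follow closed forms", {
  square <- cbind(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
  expect_equal(terminal_area(square), 1.0)
  tri <- cbind(x = c(0, 1000, 0), y = c(0, 0, 2000))
  expect_equal(terminal_area(tri), 1.0)
  expect_equal(terminal_area(square[4:1, ]), 1.0)   # orientation invariant
  bow <- cbind(x = c(0, 100, 0, 100), y = c(0, 100, 100, 0))
  expect_error(terminal_area(bow), "self-intersecting")

  expect_equal(vesicle_density(10, 1), 10)
  expect_equal(vesicle_density(0, 2.5), 0)
  expect_equal(vesicle_density(12, 4), vesicle_density(12, 2) / 2)
  expect_error(vesicle_density(3, 0), "> 0")

  expect_equal(synapse_density(5, 250), 2)
  expect_equal(synapse_density(0, 10), 0)
  expect_equal(synapse_density(10, 500), synapse_density(5, 250))
})

test_that("zone partition produces 40-nm bands with the expected areas", {
  geom <- rect_geometry(width = 400, height = 200)
  part <- partition_zones(geom)
  expect_equal(part$bands$d_min_nm, c(0, 40, 80))
  expect_equal(part$bands$d_max_nm, c(40, 80, 120))
  # active zone spans the full bottom edge: each clipped band is ~ L x w
  expect_equal(part$bands$area_um2, rep(400 * 40 * 1e-6, 3),
               tolerance = 0.01)

  # a terminal shallower than 120 nm clips the distal band, never below 0
  shallow <- rect_geometry(width = 400, height = 100)
  p2 <- partition_zones(shallow)
  expect_equal(p2$bands$area_um2[3], 400 * 20 * 1e-6, tolerance = 0.02)
  expect_true(all(p2$bands$area_um2 >= 0))

  degen <- rect_geometry()
  degen$active_zone <- cbind(x = c(10, 10), y = c(0, 0))
  expect_error(partition_zones(degen), "degenerate")
})

test_that("vesicle assignment uses half-open bands and conserves counts", {
  geom <- rect_geometry(width = 400, height = 300)
  geom$vesicles <- tibble::tibble(
    x = c(200, 200, 200, 200, 200, 500),
    y = c(0, 100, 150, 39.9999, 40, 10))   # distances to the bottom edge
  part <- partition_zones(geom)
  expect_warning(asg <- assign_vesicles(geom, part), "outside the terminal")
  expect_equal(asg$zone,
               c("zone1", "zone3", "beyond", "zone1", "zone2", "excluded"))
  cnt <- zone_counts(asg)
  expect_equal(sum(cnt$n), nrow(geom$vesicles))   # conservation

  # rigid rotation + translation leaves assignments unchanged
  th <- 33 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(m) sweep(as.matrix(m) %*% t(R), 2, c(-120, 77), `+`)
  geom_rot <- geom
  geom_rot$terminal <- rot(geom$terminal)
  geom_rot$active_zone <- rot(geom$active_zone)
  ves_rot <- rot(cbind(geom$vesicles$x, geom$vesicles$y))
  geom_rot$vesicles <- tibble::tibble(x = ves_rot[, 1], y = ves_rot[, 2])
  expect_warning(asg_rot <- assign_vesicles(geom_rot,
                                            partition_zones(geom_rot)))
  expect_equal(asg_rot$zone, asg$zone)
})

test_that("zone counts on simulated synapses equal the generator truth", {
  for (seed in c(3, 17, 40)) {
    sim <- simulate_em_synapse(n_vesicles = 30, seed = seed)
    part <- partition_zones(sim$geometry)
    asg <- assign_vesicles(sim$geometry, part)
    expect_equal(asg$zone, sim$truth$zone)
  }
})

test_that("em_metrics assembles densities consistent with their parts", {
  sim <- simulate_em_synapse(n_vesicles = 30, seed = 12)
  met <- em_metrics(sim$geometry)
  expect_equal(met$density_per_um2,
               met$vesicle_count / met$terminal_area_um2)
  expect_equal(met$zone1_n + met$zone2_n + met$zone3_n + met$beyond_n,
               30L)
  part <- partition_zones(sim$geometry)
  expect_equal(met$zone2_area_um2, part$bands$area_um2[2])
})
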