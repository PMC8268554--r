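# Synthetic torso phantom: mesh validity, electrode placement, heating and
# anomaly operators, canonical scenario fixtures.

test_that("default phantom mesh is valid and volume-accurate", {
  ph <- build_phantom(phantom_spec(target_elements = 8000))
  mesh <- ph$mesh
  expect_s3_class(mesh, "eit_mesh")
  v <- tet_volumes(mesh)
  expect_true(all(v > 0))
  # every default tissue structure shows up in the labels
  want <- tissue_id(c("muscle", "fat", "skin", "bone", "organ", "urine",
                      "tumor"))
  expect_true(all(want %in% mesh$labels))
  # discretized volume vs analytic elliptic cylinder pi*a*b*h within 2%
  expect_lt(abs(sum(v) / (pi * 0.15 * 0.10 * 0.20) - 1), 0.02)
  # element count within 30% of target
  expect_lt(abs(nrow(mesh$tets) - 8000) / 8000, 0.3)
  # conductivity populated from the table
  expect_equal(ph$sigma, sigma_from_labels(mesh$labels))
})

test_that("phantom generation is deterministic and rejects bad geometry", {
  a <- build_phantom(phantom_spec(target_elements = 3000))
  b <- build_phantom(phantom_spec(target_elements = 3000))
  expect_identical(a$mesh$nodes, b$mesh$nodes)
  expect_identical(a$mesh$tets, b$mesh$tets)
  expect_identical(a$sigma, b$sigma)
  expect_error(phantom_spec(a = -0.1), "degenerate")
  expect_error(phantom_spec(inclusions = list(
    list(tissue = "tumor", shape = "sphere", center = c(0.5, 0, 0),
         radius = 0.01))), "outside")
})

test_that("phantom without inclusions is homogeneous muscle", {
  ph <- build_phantom(phantom_spec(target_elements = 3000,
                                   inclusions = list()))
  expect_equal(unique(ph$mesh$labels), tissue_id("muscle"))
  expect_equal(length(unique(ph$sigma)), 1L)
})

test_that("electrode rings are interleaved with the prescribed spacing", {
  fx <- fx_phantom()
  mesh <- fx$mesh
  en <- mesh$electrode_nodes
  expect_length(en, 16L)
  xyz <- mesh$nodes[en, ]
  # two rings at +-height/4, consecutive electrodes alternating
  expect_equal(xyz[, 3], rep(c(-0.05, 0.05), 8))
  # elliptic parameter angle advances by 22.5 degrees per electrode
  ang <- atan2(xyz[, 2] / 0.10, xyz[, 1] / 0.15) %% (2 * pi)
  expect_equal(ang, (seq_len(16) - 1) * pi / 8, tolerance = 1e-9)
  # per-ring spacing 45 degrees, half-spacing offset between rings
  ring1 <- sort(ang[seq(1, 16, 2)])
  ring2 <- sort(ang[seq(2, 16, 2)])
  expect_equal(diff(ring1), rep(pi / 4, 7), tolerance = 1e-9)
  expect_equal(ring2 - ring1, rep(pi / 8, 8), tolerance = 1e-9)
  # snapping is exact on the structured boundary
  expect_true(all(mesh$electrode_snap < 1e-9))
})

test_that("single-ring placement gives 45 degree spacing", {
  ph <- build_phantom(phantom_spec(target_elements = 3000))
  mesh <- place_electrodes(ph$mesh, 8L, 1L)
  xyz <- mesh$nodes[mesh$electrode_nodes, ]
  expect_equal(xyz[, 3], rep(0, 8))
  ang <- atan2(xyz[, 2] / 0.10, xyz[, 1] / 0.15) %% (2 * pi)
  expect_equal(sort(ang), (0:7) * pi / 4, tolerance = 1e-9)
  expect_error(place_electrodes(ph$mesh, 15L, 2L), "divisible")
})

test_that("Gaussian heating multiplier matches its closed form", {
  fx <- fx_phantom()
  sc <- heating_scenario(center = c(-0.05, 0.01, 0), R = 0.03, peak = 0.4,
                         diameter = 0.12)
  heated <- apply_gaussian_heating(fx$sigma, sc, fx$mesh)
  ctr <- tet_centroids(fx$mesh)
  r <- sqrt((ctr[, 1] + 0.05)^2 + (ctr[, 2] - 0.01)^2 + ctr[, 3]^2)
  mult <- heated / fx$sigma
  inside <- r <= 0.06 & fx$sigma > 0
  expect_equal(mult[inside], 1 + 0.4 * exp(-r[inside]^2 / (2 * 0.03^2)),
               tolerance = 1e-12)
  expect_true(all(mult[r > 0.06 & fx$sigma > 0] == 1))
  # peak increase at the centre is 40%; multiplier bounded in [1, 1.4],
  # radially non-increasing
  expect_equal(max(mult[fx$sigma > 0]),
               1 + 0.4 * exp(-min(r[inside])^2 / (2 * 0.03^2)))
  expect_true(all(mult >= 1 - 1e-15 & mult <= 1.4 + 1e-15, na.rm = TRUE))
  o <- order(r[inside])
  expect_true(all(diff(mult[inside][o]) <= 1e-12))
  # r = R evaluates to 1 + 0.4 exp(-1/2)
  expect_equal(1 + 0.4 * exp(-0.03^2 / (2 * 0.03^2)), 1.2426122,
               tolerance = 1e-6)
  # zero peak is the identity
  sc0 <- heating_scenario(center = c(0, 0, 0), R = 0.03, peak = 0)
  expect_identical(apply_gaussian_heating(fx$sigma, sc0, fx$mesh), fx$sigma)
})

test_that("spherical anomaly partitions elements by centroid", {
  fx <- fx_phantom()
  ctr <- tet_centroids(fx$mesh)
  cen <- c(0.0417, 0.025, 0.015)
  out <- insert_spherical_anomaly(fx$sigma, fx$mesh, cen, 0.05, 0)
  inside <- (ctr[, 1] - cen[1])^2 + (ctr[, 2] - cen[2])^2 +
            (ctr[, 3] - cen[3])^2 <= 0.025^2
  expect_true(all(out[inside] == 0))
  expect_identical(out[!inside], fx$sigma[!inside])
  expect_warning(
    insert_spherical_anomaly(fx$sigma, fx$mesh, cen, 1e-6, 0),
    "no element")
})

test_that("canonical scenario fixtures carry the published geometry", {
  expect_equal(scenario_fixture("P2")$diameter, 0.040)
  expect_equal(vapply(c("P1", "P2", "P3", "P4", "P5"),
                      function(id) scenario_fixture(id)$diameter,
                      numeric(1), USE.NAMES = FALSE),
               c(0.060, 0.040, 0.080, 0.060, 0.060))
  # P1-P3 share a centre; all use the 3 cm Gaussian width and 40% peak
  expect_equal(scenario_fixture("P1")$center, scenario_fixture("P2")$center)
  expect_equal(scenario_fixture("P1")$center, scenario_fixture("P3")$center)
  for (id in c("P1", "P4", "P5")) {
    sc <- scenario_fixture(id)
    expect_equal(sc$R, 0.03)
    expect_equal(sc$peak, 0.4)
  }
  air <- scenario_fixture("air")
  expect_equal(air$anomaly$sigma_value, 0)
  expect_equal(air$anomaly$diameter, 0.050)
  expect_error(scenario_fixture("P9"))
})
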