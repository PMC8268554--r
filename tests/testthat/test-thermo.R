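# Pennes bioheat solver, perfusion curves and the conductivity-temperature
# coupling model.

test_that("unheated tissue stays at the arterial temperature", {
  g <- thermal_grid(phantom_spec(target_elements = 3000), spacing = 0.01)
  tf <- solve_pennes(g, rep(0, prod(g$dims)), duration = 50, dt = 10)
  expect_lt(max(abs(tf$T[g$labels >= 1] - 37)), 1e-9)
})

test_that("1-D slab steady state matches the closed-form thermal length
           profile", {
  tab <- tissue_table()
  s <- 0.004
  nx <- 62L
  dims <- c(nx, 3L, 3L)
  lab <- array(NA_integer_, dims)
  lab[2:(nx - 1L), 2L, 2L] <- tissue_id("muscle", tab)
  lab[c(1L, nx), 2L, 2L] <- 0L
  g <- structure(list(dims = dims, spacing = s, origin = c(0, 0, 0),
                      labels = as.integer(lab)), class = "thermal_grid")
  dT0 <- 1.5
  tb <- rep(37, prod(dims))
  tb[1L + (2L - 1L) * nx + (2L - 1L) * nx * 3L] <- 37 + dT0  # x = 1 voxel
  tf <- solve_pennes(g, rep(0, prod(dims)), tab,
                     perfusion_model("pessimistic"),
                     duration = 4e4, dt = 50, boundary_temperature = tb)
  act <- which(!is.na(lab) & lab >= 1L)
  x <- (which(lab == tissue_id("muscle", tab), arr.ind = TRUE)[, 1] - 1) * s
  theta <- tf$T[act] - 37
  wb <- tab["muscle", "wb0"]; k <- tab["muscle", "k"]
  L <- sqrt(k / (wb * eitherm:::BLOOD_C))
  Lx <- (nx - 1) * s
  analytic <- dT0 * sinh((Lx - x) / L) / sinh(Lx / L)
  expect_lt(max(abs(theta - analytic)) / dT0, 0.02)
  # the characteristic length itself is of order 1 cm
  expect_gt(L, 0.005); expect_lt(L, 0.02)
})

test_that("steady state balances power against perfusion sink and boundary
           flux", {
  spec <- phantom_spec(target_elements = 3000)
  tab <- tissue_table()
  g <- thermal_grid(spec, spacing = 0.01)
  q <- gaussian_power_deposition(g, c(0.035, 0.015, -0.01), 0.025,
                                 peak = 2e4)
  tf <- solve_pennes(g, q, tab, perfusion_model("pessimistic"),
                     duration = 4e4, dt = 50)
  s <- g$spacing
  d <- g$dims
  lab <- array(g$labels, d)
  theta <- array(ifelse(is.na(tf$T), 0, tf$T - 37), d)
  act <- !is.na(lab) & lab >= 1L
  p_in <- sum(q) * s^3
  om <- perfusion_ratio(37 + theta[act], tab$name[lab[act]],
                        perfusion_model("pessimistic"), tab)
  p_perf <- sum(tab$wb0[lab[act]] * om * eitherm:::BLOOD_C *
                theta[act] * s^3)
  # conductive flux through faces to exterior (label 0) voxels
  p_bc <- 0
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    nb_lab <- eitherm:::shift_array(array(as.numeric(lab), d), sh)
    bc <- act & !is.na(nb_lab) & nb_lab == 0
    p_bc <- p_bc + sum(tab$k[lab[bc]] * s * theta[bc])
  }
  expect_lt(abs((p_perf + p_bc) / p_in - 1), 0.01)
  # maximum principle: no cooling below the arterial temperature
  expect_gte(min(tf$T, na.rm = TRUE), 37 - 1e-9)
})

test_that("explicit scheme agrees with implicit and rejects unstable steps", {
  g <- thermal_grid(phantom_spec(target_elements = 3000), spacing = 0.01)
  q <- gaussian_power_deposition(g, c(0.035, 0.015, -0.01), 0.025,
                                 peak = 2e4)
  t_im <- solve_pennes(g, q, duration = 600, dt = 5)
  t_ex <- solve_pennes(g, q, duration = 600, dt = 5, scheme = "explicit")
  act <- g$labels >= 1
  expect_lt(max(abs(t_im$T[act] - t_ex$T[act])), 0.05)
  expect_error(solve_pennes(g, q, duration = 600, dt = 500,
                            scheme = "explicit"), "unstable")
})

test_that("perfusion curves: baseline, plateau and variant ordering", {
  for (tis in c("muscle", "fat", "tumor", "bone")) {
    expect_equal(perfusion_ratio(37, tis), 1)
    expect_equal(perfusion_ratio(50, tis, perfusion_model("optimistic")),
                 perfusion_ratio(46, tis, perfusion_model("optimistic")))
  }
  expect_equal(perfusion_ratio(50, "muscle", perfusion_model("optimistic")),
               12)
  Ts <- seq(37, 47, by = 0.5)
  for (tis in c("muscle", "fat", "tumor")) {
    o <- perfusion_ratio(Ts, tis, perfusion_model("optimistic"))
    p <- perfusion_ratio(Ts, tis, perfusion_model("pessimistic"))
    expect_true(all(o >= p))
    expect_true(all(diff(o) >= 0))
  }
})

test_that("conductivity-change model evaluates and inverts exactly", {
  m_hf <- conductivity_change_model(tc = 0.02, alpha = 0.08)
  expect_equal(conductivity_change(0, 1, m_hf), 0)
  expect_equal(conductivity_change(0, 2, m_hf), 0.08 * (sqrt(2) - 1),
               tolerance = 1e-12)
  expect_equal(0.08 * (sqrt(2) - 1), 0.033137, tolerance = 1e-5)
  expect_equal(conductivity_change(4, 4, m_hf), 0.08 + 0.08 * 1 * 1.08,
               tolerance = 1e-12)
  expect_equal(conductivity_change(4, 4, m_hf), 0.1664)
  # pure-Tc inversion is linear
  expect_equal(temperature_from_conductivity(0.04,
               conductivity_change_model(0.02, 0)), 2, ignore_attr = TRUE)
  expect_equal(temperature_from_conductivity(0,
               conductivity_change_model(0.02, 0)), 0, ignore_attr = TRUE)
  # roundtrip through the perfusion-coupled model
  for (tis in c("muscle", "fat", "tumor")) {
    curve <- function(T) perfusion_ratio(T, tis, perfusion_model("optimistic"))
    mdl <- conductivity_change_model(0.02, 0.24)
    for (Tt in seq(37, 45, by = 1)) {
      ds <- conductivity_change(Tt - 37, curve(Tt), mdl)
      Tr <- temperature_from_conductivity(ds, mdl, curve)
      expect_lt(abs(Tr - (Tt - 37)), 1e-5)
    }
  }
  # out-of-range input is clipped and flagged
  r <- temperature_from_conductivity(5, conductivity_change_model(0.02, 0.24),
                                     function(T) rep(1, length(T)))
  expect_true(length(attr(r, "clipped")) == 1)
})

test_that("conductivity change is monotone in T and larger at LF", {
  Ts <- seq(37, 46, by = 0.5)
  for (tis in c("muscle", "fat", "tumor"))
    for (variant in c("optimistic", "pessimistic")) {
      om <- perfusion_ratio(Ts, tis, perfusion_model(variant))
      lf <- conductivity_change(Ts - 37, om, conductivity_change_model(0.02, 0.24))
      hf <- conductivity_change(Ts - 37, om, conductivity_change_model(0.02, 0.08))
      expect_true(all(diff(lf) > 0))
      expect_true(all(lf >= hf))
    }
})

test_that("power deposition field is non-negative with the requested
           normalization", {
  g <- thermal_grid(phantom_spec(target_elements = 3000), spacing = 0.008)
  ctr <- c(0.035, 0.015, -0.01)
  q <- gaussian_power_deposition(g, ctr, 0.02, peak = 1e4)
  expect_true(all(q >= 0))
  pts <- grid_coords(g)
  i <- which.min((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
                 (pts[, 3] - ctr[3])^2)
  expect_gt(q[i], 1e4 * 0.99)
  qt <- gaussian_power_deposition(g, ctr, 0.02, total_power = 40)
  expect_lt(abs(sum(qt) * g$spacing^3 - 40) / 40, 0.02)
})

test_that("temperature and perfusion fields map to conductivity per tissue", {
  tab <- tissue_table()
  lab <- tissue_id(c("muscle", "bone", "tumor"), tab)
  sref <- sigma_from_labels(lab, tab)
  # baseline maps to itself
  expect_equal(fields_to_sigma(rep(0, 3), rep(1, 3), sref, lab, tab, "lf"),
               sref)
  # uniform 5 C with no perfusion scales all tissues by 1.10
  expect_equal(fields_to_sigma(rep(5, 3), rep(1, 3), sref, lab, tab, "lf"),
               1.10 * sref, tolerance = 1e-12)
  # non-responsive bone only gets the Tc term even at omega = 3
  out <- fields_to_sigma(rep(5, 3), rep(3, 3), sref, lab, tab, "lf")
  expect_equal(out[2], sref[2] * 1.10, tolerance = 1e-12)
  expect_gt(out[1], sref[1] * 1.10)
})
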