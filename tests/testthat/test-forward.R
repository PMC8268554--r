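# Forward solver: stimulation pattern bookkeeping, FEM assembly, solution
# properties (linearity, reciprocity, analytic sphere), adjoint Jacobian and
# measurement noise.

test_that("pair-drive pattern enumerates the prescribed measurements", {
  p <- build_pattern(16L, 7L)
  expect_equal(nrow(p$measurements), 192L)
  expect_equal(nrow(p$injections), 16L)
  # independent enumeration oracle for 8 electrodes, offset 3
  n <- 8L; off <- 3L
  cnt <- 0L
  for (i in seq_len(n)) {
    inj <- c(i, (i - 1L + off) %% n + 1L)
    for (j in seq_len(n)) {
      pair <- c(j, j %% n + 1L)
      if (!any(pair %in% inj)) cnt <- cnt + 1L
    }
  }
  expect_equal(cnt, 32L)
  p8 <- build_pattern(8L, 3L)
  expect_equal(nrow(p8$measurements), cnt)
  # no measurement pair shares an electrode with its injection pair
  for (p2 in list(p, p8)) {
    md <- p2$measurements
    inj <- p2$injections[md$injection, , drop = FALSE]
    expect_false(any(md$m1 == inj[, 1] | md$m1 == inj[, 2] |
                     md$m2 == inj[, 1] | md$m2 == inj[, 2]))
  }
  expect_error(build_pattern(16L, 1L), "adjacent")
  expect_error(build_pattern(16L, 15L), "adjacent")
})

test_that("assembled conductance matrix is a grounded Neumann operator", {
  fx <- fx_tiny()
  A0 <- assemble_conductance(fx$mesh, fx$sigma, ground = FALSE)
  expect_equal(max(abs(A0 - Matrix::t(A0))), 0)
  expect_lt(max(abs(Matrix::rowSums(A0))), 1e-12 * max(abs(A0)))
  # single reference tetrahedron against the hand-assembled local stiffness
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tet <- matrix(1:4, nrow = 1)
  mesh1 <- eitherm:::new_eit_mesh(nodes, tet)
  g <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  K <- 2.5 * (1 / 6) * g %*% t(g)      # sigma * |T| * grad_i . grad_j
  A1 <- assemble_conductance(mesh1, 2.5, ground = FALSE)
  expect_equal(as.matrix(A1), K, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("forward voltages scale inversely with conductivity", {
  fx <- fx_phantom()
  v1 <- fx$vref$values
  v2 <- solve_forward(fx$mesh, 2 * fx$sigma, fx$pattern)$values
  expect_equal(2 * v2, v1, tolerance = 1e-12)
})

test_that("reciprocity holds on the heterogeneous phantom", {
  fx <- fx_tiny()
  en <- fx$mesh$electrode_nodes
  A <- assemble_conductance(fx$mesh, fx$sigma)
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  b <- matrix(0, nrow(fx$mesh$nodes), 2)
  b[en[1], 1] <- 1; b[en[4], 1] <- -1
  b[en[2], 2] <- 1; b[en[7], 2] <- -1
  u <- as.matrix(Matrix::solve(ch, b))
  z12 <- u[en[2], 1] - u[en[7], 1]
  z21 <- u[en[1], 2] - u[en[4], 2]
  expect_lt(abs(z12 - z21) / abs(z12), 1e-8)
})

test_that("transfer impedances are symmetric and scale as 1/sigma", {
  fx <- fx_tiny()
  Z <- transfer_impedance_matrix(fx$mesh, fx$sigma)
  expect_equal(Z, t(Z), tolerance = 1e-10)
  expect_equal(diag(Z), rep(0, nrow(Z)))
  Z2 <- transfer_impedance_matrix(fx$mesh, 1.4 * fx$sigma)
  off <- upper.tri(Z)
  expect_equal(Z2[off], Z[off] / 1.4, tolerance = 1e-10)
})

test_that("four-electrode impedance on a homogeneous sphere matches the
           closed-form series solution and converges under refinement", {
  # potential on a unit-current dipole at the poles of a homogeneous
  # conducting sphere: closed form of sum (2n+1)/n Pn
  u_pole <- function(theta, sigma, a) {
    s <- sin(theta / 2); cc <- cos(theta / 2)
    ((1 / s - 2 - log(s * (1 + s))) -
     (1 / cc - 2 - log(cc * (1 + cc)))) / (4 * pi * sigma * a)
  }
  z4_mesh <- function(n_theta, m, n_psi) {
    s <- sphere_mesh(radius = 0.1, n_theta = n_theta, m = m, n_psi = n_psi)
    rho <- s$node_info$rho; lev <- s$node_info$level
    ang <- s$node_info$angle
    lat <- which(rho > 1 - 1e-9 & abs(ang) < 1e-9)
    psi <- pi * lev[lat] / n_psi
    Cn <- lat[which.min(abs(psi - pi * 0.375))]
    Dn <- lat[which.min(abs(psi - pi * 0.625))]
    s$electrode_nodes <- c(s$geometry$poles, Cn, Dn)
    Z <- transfer_impedance_matrix(s, rep(1, nrow(s$tets)))
    list(z = (Z[1, 4] + Z[2, 3] - Z[1, 3] - Z[2, 4]) / 2,
         thC = pi * lev[Cn] / n_psi, thD = pi * lev[Dn] / n_psi)
  }
  coarse <- z4_mesh(16L, 4L, 8L)
  fine <- z4_mesh(32L, 8L, 16L)
  za <- u_pole(coarse$thC, 1, 0.1) - u_pole(coarse$thD, 1, 0.1)
  expect_lt(abs(coarse$z / za - 1), 0.05)
  expect_lt(abs(fine$z / za - 1), abs(coarse$z / za - 1))
})

test_that("adjoint Jacobian matches central finite differences", {
  fx <- fx_tiny()
  cj <- compute_jacobian(fx$mesh, fx$sigma, fx$pattern)
  scale <- max(abs(cj$J))
  for (e in c(which.max(colSums(abs(cj$J))), 50L)) {
    h <- 1e-6 * fx$sigma[e]
    sp <- fx$sigma; sp[e] <- sp[e] + h
    sm <- fx$sigma; sm[e] <- sm[e] - h
    fd <- (solve_forward(fx$mesh, sp, fx$pattern)$values -
           solve_forward(fx$mesh, sm, fx$pattern)$values) / (2 * h)
    expect_lt(max(abs(fd - cj$J[, e])) / scale, 1e-4)
  }
})

test_that("Jacobian scales as 1/sigma^2 under global conductivity scaling", {
  fx <- fx_tiny()
  J1 <- compute_jacobian(fx$mesh, fx$sigma, fx$pattern)$J
  J2 <- compute_jacobian(fx$mesh, 2 * fx$sigma, fx$pattern)$J
  expect_equal(4 * J2, J1, tolerance = 1e-10)
  expect_equal(as.numeric(J1 %*% rep(0, ncol(J1))), rep(0, nrow(J1)))
})

test_that("measurement noise follows the SNR definition", {
  fx <- fx_phantom()
  p1 <- fx_p1()
  dv_rms <- sqrt(mean((p1$v$values - fx$vref$values)^2))
  # infinite SNR: unchanged
  expect_identical(add_measurement_noise(p1$v, fx$vref, Inf)$values,
                   p1$v$values)
  # snr = 0 dB: noise sd equals the rms change; pooled draws across seeds
  draws0 <- unlist(lapply(1:50, function(s)
    add_measurement_noise(p1$v, fx$vref, 0, s)$values - p1$v$values))
  expect_equal(sd(draws0), dv_rms, tolerance = 0.02)
  # snr = 20 dB: sd within 0.5% of rms/10 at ~1e5 draws
  draws <- unlist(lapply(1:600, function(s)
    add_measurement_noise(p1$v, fx$vref, 20, s)$values - p1$v$values))
  expect_equal(sd(draws), dv_rms / 10, tolerance = 0.005)
  # deterministic under a fixed seed, and the session RNG is untouched
  set.seed(99); before <- .Random.seed
  a <- add_measurement_noise(p1$v, fx$vref, 20, 7L)$values
  expect_identical(.Random.seed, before)
  b <- add_measurement_noise(p1$v, fx$vref, 20, 7L)$values
  expect_identical(a, b)
  expect_error(add_measurement_noise(fx$vref, fx$vref, 20, 1L), "SNR")
})
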