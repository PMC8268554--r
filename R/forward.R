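# Quasi-static conduction forward problem: linear P1 FEM on tetrahedra with
# point electrodes, pair-drive stimulation, adjoint sensitivities and
# SNR-parameterized measurement noise.

#' Build a pair-drive stimulation pattern
#'
#' Current is injected through electrode pairs `(i, i + offset)` (modular) for
#' every electrode `i`; for each injection, differential voltages are taken on
#' all adjacent electrode pairs `(j, j + 1)` that do not involve an injecting
#' electrode. For 16 electrodes with offset 7 this yields 16 injections of 12
#' measurements each, 192 in total.
#'
#' @param n_electrodes number of electrodes (>= 3).
#' @param injection_offset index offset between the electrodes of an
#'   injection pair; must be in `[2, n_electrodes - 2]` so injection pairs
#'   are never adjacent.
#' @param current injected current amplitude (A).
#' @return list of class `eit_pattern` with `injections` (matrix, one row per
#'   injection) and `measurements` (data.frame: injection index, electrode
#'   pair `m1`, `m2`) in pattern order.
#' @export
#' @examples
#' nrow(build_pattern(16, 7)$measurements)  # 192
build_pattern <- function(n_electrodes = 16L, injection_offset = 7L,
                          current = 1e-3) {
  n <- as.integer(n_electrodes)
  off <- as.integer(injection_offset)
  stopifnot(n >= 3L, current > 0)
  if (off < 2L || off > n - 2L)
    stop("injection_offset would produce adjacent injection pairs")
  inj <- cbind(seq_len(n), ((seq_len(n) - 1L + off) %% n) + 1L)
  adj <- cbind(seq_len(n), (seq_len(n) %% n) + 1L)
  meas <- do.call(rbind, lapply(seq_len(n), function(i) {
    keep <- !(adj[, 1L] %in% inj[i, ] | adj[, 2L] %in% inj[i, ])
    cbind(injection = i, m1 = adj[keep, 1L], m2 = adj[keep, 2L])
  }))
  structure(list(n_electrodes = n, injection_offset = off, current = current,
                 injections = inj, measurements = as.data.frame(meas)),
            class = "eit_pattern")
}

#' Differential-voltage measurement frame
#'
#' @param values numeric vector, one differential voltage (V) per pattern
#'   measurement, in pattern order.
#' @param pattern the `eit_pattern` the values belong to.
#' @param frequency `"lf"` or `"hf"` tag.
#' @return list of class `eit_frame`.
#' @export
new_frame <- function(values, pattern, frequency = "lf") {
  stopifnot(length(values) == nrow(pattern$measurements))
  structure(list(values = as.numeric(values), pattern = pattern,
                 frequency = frequency), class = "eit_frame")
}

# per-element P1 basis gradients (lists Gx, Gy, Gz of n x 4 matrices) and
# element volumes
element_gradients <- function(mesh) {
  p1 <- mesh$nodes[mesh$tets[, 1L], , drop = FALSE]
  e1 <- mesh$nodes[mesh$tets[, 2L], , drop = FALSE] - p1
  e2 <- mesh$nodes[mesh$tets[, 3L], , drop = FALSE] - p1
  e3 <- mesh$nodes[mesh$tets[, 4L], , drop = FALSE] - p1
  det <- e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
         e1[, 2L] * (e2[, 1L] * e3[, 3L] - e2[, 3L] * e3[, 1L]) +
         e1[, 3L] * (e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L])
  # rows of inv([e1;e2;e3])^T: gradients of barycentric coords 2..4
  g2 <- cbind(e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L],
              e2[, 3L] * e3[, 1L] - e2[, 1L] * e3[, 3L],
              e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L]) / det
  g3 <- cbind(e3[, 2L] * e1[, 3L] - e3[, 3L] * e1[, 2L],
              e3[, 3L] * e1[, 1L] - e3[, 1L] * e1[, 3L],
              e3[, 1L] * e1[, 2L] - e3[, 2L] * e1[, 1L]) / det
  g4 <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]) / det
  g1 <- -(g2 + g3 + g4)
  list(Gx = cbind(g1[, 1L], g2[, 1L], g3[, 1L], g4[, 1L]),
       Gy = cbind(g1[, 2L], g2[, 2L], g3[, 2L], g4[, 2L]),
       Gz = cbind(g1[, 3L], g2[, 3L], g3[, 3L], g4[, 3L]),
       vol = abs(det) / 6)
}

#' Assemble the FEM conductance (stiffness) matrix
#'
#' Linear P1 assembly of the operator `-div(sigma grad u)` with natural
#' (no-flux) boundary conditions. The raw operator is symmetric with zero row
#' sums; grounding (fixing the potential at one reference node, plus any
#' electrically isolated nodes inside zero-conductivity regions) makes it
#' positive definite.
#'
#' @param mesh an `eit_mesh`.
#' @param sigma per-element conductivity (S/m, >= 0).
#' @param ground `TRUE` to pin the reference node (default), `FALSE` to
#'   return the singular pure-Neumann operator.
#' @return a sparse symmetric `Matrix`; the reference node index is attached
#'   as attribute `"ground_node"` when grounded.
#' @export
assemble_conductance <- function(mesh, sigma, ground = TRUE) {
  stopifnot(length(sigma) == nrow(mesh$tets), all(sigma >= 0),
            all(is.finite(sigma)))
  eg <- element_gradients(mesh)
  w <- sigma * eg$vol
  nn <- nrow(mesh$nodes)
  ii <- jj <- xx <- vector("list", 16L)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    ii[[k]] <- mesh$tets[, i]
    jj[[k]] <- mesh$tets[, j]
    xx[[k]] <- w * (eg$Gx[, i] * eg$Gx[, j] + eg$Gy[, i] * eg$Gy[, j] +
                    eg$Gz[, i] * eg$Gz[, j])
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nn, nn))
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  if (!ground) return(A)
  ctr <- colMeans(mesh$nodes)
  gnd <- which.min((mesh$nodes[, 1L] - ctr[1])^2 +
                   (mesh$nodes[, 2L] - ctr[2])^2 +
                   (mesh$nodes[, 3L] - ctr[3])^2)
  pin <- unique(c(gnd, which(Matrix::diag(A) == 0)))
  A <- as(A, "CsparseMatrix")
  A[pin, ] <- 0
  A[, pin] <- 0
  Matrix::diag(A)[pin] <- 1
  A <- Matrix::forceSymmetric(A)
  attr(A, "ground_node") <- gnd
  if (length(pin) > 1L) attr(A, "isolated_nodes") <- setdiff(pin, gnd)
  A
}

# Shared factorized forward machinery: node potentials for all injection and
# measurement-pair unit drives at one factorization.
fem_solution <- function(mesh, sigma, pattern, want_jacobian = FALSE) {
  en <- mesh$electrode_nodes
  if (length(en) < pattern$n_electrodes)
    stop("mesh has fewer electrodes than the pattern requires")
  A <- assemble_conductance(mesh, sigma)
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  inj <- pattern$injections
  ninj <- nrow(inj)
  mp <- unique(pattern$measurements[, c("m1", "m2")])
  nmp <- nrow(mp)
  nn <- nrow(mesh$nodes)
  B <- matrix(0, nrow = nn, ncol = ninj + if (want_jacobian) nmp else 0L)
  for (i in seq_len(ninj)) {
    B[en[inj[i, 1L]], i] <- B[en[inj[i, 1L]], i] + pattern$current
    B[en[inj[i, 2L]], i] <- B[en[inj[i, 2L]], i] - pattern$current
  }
  if (want_jacobian) {
    for (p in seq_len(nmp)) {                       # unit-current adjoint drives
      B[en[mp$m1[p]], ninj + p] <- B[en[mp$m1[p]], ninj + p] + 1
      B[en[mp$m2[p]], ninj + p] <- B[en[mp$m2[p]], ninj + p] - 1
    }
  }
  U <- as.matrix(Matrix::solve(ch, B))
  md <- pattern$measurements
  v <- U[cbind(en[md$m1], md$injection)] - U[cbind(en[md$m2], md$injection)]
  out <- list(frame = new_frame(v, pattern), potentials = U[, seq_len(ninj),
                                                            drop = FALSE])
  if (want_jacobian) {
    eg <- element_gradients(mesh)
    t1 <- mesh$tets[, 1L]; t2 <- mesh$tets[, 2L]
    t3 <- mesh$tets[, 3L]; t4 <- mesh$tets[, 4L]
    nf <- ninj + nmp
    ne <- nrow(mesh$tets)
    gx <- gy <- gz <- matrix(0, nrow = ne, ncol = nf)
    for (f in seq_len(nf)) {
      uf <- U[, f]
      gx[, f] <- eg$Gx[, 1L] * uf[t1] + eg$Gx[, 2L] * uf[t2] +
                 eg$Gx[, 3L] * uf[t3] + eg$Gx[, 4L] * uf[t4]
      gy[, f] <- eg$Gy[, 1L] * uf[t1] + eg$Gy[, 2L] * uf[t2] +
                 eg$Gy[, 3L] * uf[t3] + eg$Gy[, 4L] * uf[t4]
      gz[, f] <- eg$Gz[, 1L] * uf[t1] + eg$Gz[, 2L] * uf[t2] +
                 eg$Gz[, 3L] * uf[t3] + eg$Gz[, 4L] * uf[t4]
    }
    pidx <- match(paste(md$m1, md$m2), paste(mp$m1, mp$m2))
    J <- matrix(0, nrow = nrow(md), ncol = ne)
    for (r in seq_len(nrow(md))) {
      d <- md$injection[r]; p <- ninj + pidx[r]
      J[r, ] <- -eg$vol * (gx[, d] * gx[, p] + gy[, d] * gy[, p] +
                           gz[, d] * gz[, p])
    }
    out$jacobian <- J
  }
  out
}

#' Solve the EIT forward problem
#'
#' Computes node potentials for every injection of the pattern (point
#' electrodes, one sparse Cholesky factorization for all drives) and
#' assembles the differential voltages in pattern order.
#'
#' @param mesh an `eit_mesh` with electrodes placed.
#' @param sigma per-element conductivity (S/m).
#' @param pattern an `eit_pattern`.
#' @param frequency frequency tag attached to the returned frame.
#' @param potentials if `TRUE`, attach the node-potential matrix (one column
#'   per injection).
#' @return an `eit_frame`.
#' @export
solve_forward <- function(mesh, sigma, pattern, frequency = "lf",
                          potentials = FALSE) {
  sol <- fem_solution(mesh, sigma, pattern)
  fr <- sol$frame
  fr$frequency <- frequency
  if (potentials) fr$potentials <- sol$potentials
  fr
}

#' Adjoint sensitivity (Jacobian) matrix
#'
#' Sensitivity of every pattern measurement to every element conductivity,
#' computed with the adjoint formula
#' `J[m, e] = -int_e grad(u_drive) . grad(u_meas) dV`, where `u_meas` is the
#' potential field of a unit current driven through the measurement pair.
#' Agrees with finite-difference perturbation of [solve_forward()].
#'
#' @inheritParams solve_forward
#' @return list with `J` (measurements x elements matrix, V per (S/m)) and
#'   `frame` (the forward solution at `sigma`).
#' @export
compute_jacobian <- function(mesh, sigma, pattern) {
  sol <- fem_solution(mesh, sigma, pattern, want_jacobian = TRUE)
  list(J = sol$jacobian, frame = sol$frame)
}

#' Pairwise transfer-impedance matrix
#'
#' `Z[i, j]` is the voltage between electrodes i and j per unit current
#' injected through (i, j). Symmetric by reciprocity; the diagonal is 0 by
#' convention.
#'
#' @param mesh an `eit_mesh` with electrodes placed.
#' @param sigma per-element conductivity (S/m).
#' @return dense symmetric matrix (Ohm).
#' @export
transfer_impedance_matrix <- function(mesh, sigma) {
  en <- mesh$electrode_nodes
  ne <- length(en)
  stopifnot(ne >= 2L)
  A <- assemble_conductance(mesh, sigma)
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  B <- matrix(0, nrow = nrow(mesh$nodes), ncol = ne)
  B[cbind(en, seq_len(ne))] <- 1
  U <- as.matrix(Matrix::solve(ch, B))
  M <- U[en, , drop = FALSE]                    # M[i, j] = potential at i for source at j
  Z <- outer(diag(M), diag(M), "+") - M - t(M)
  diag(Z) <- 0
  Z
}

#' Add SNR-parameterized measurement noise
#'
#' Adds zero-mean white Gaussian noise to the heated-state frame `v`. The
#' noise standard deviation is set from the signal-to-noise ratio of the
#' heating-induced voltage change:
#' `sigma_n = rms(v - vref) / 10^(snr_db / 20)`.
#'
#' @param v measurement frame of the changed (heated) state.
#' @param vref reference frame (same pattern); defines the signal rms.
#' @param snr_db signal-to-noise ratio in dB (`Inf` returns `v` unchanged).
#' @param seed integer seed for reproducible noise; the caller's RNG state is
#'   left untouched.
#' @return `v` with noise added.
#' @export
add_measurement_noise <- function(v, vref, snr_db, seed = NULL) {
  stopifnot(length(v$values) == length(vref$values))
  if (is.infinite(snr_db)) return(v)
  dv <- v$values - vref$values
  rms <- sqrt(mean(dv^2))
  if (rms == 0) stop("rms voltage change is zero; SNR undefined")
  sn <- rms / 10^(snr_db / 20)
  n <- length(v$values)
  noise <- if (is.null(seed)) stats::rnorm(n, 0, sn) else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    stats::rnorm(n, 0, sn)
  }
  v$values <- v$values + noise
  v
}
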