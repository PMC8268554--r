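# Building blocks of the regularized one-step Gauss-Newton difference imaging:
# sensitivity-scaled diagonal regularization with spatial penalties,
# tissue-dependent penalty values, positivity constraint, voltage rescaling
# and thermal-length smoothing.

#' Sensitivity-scaled diagonal regularization matrix
#'
#' `R_ii = sqrt((J^T J)_ii) * penalty_i`, i.e. the column 2-norm of the
#' Jacobian scaled by a per-element penalty (1 outside any prior region).
#' Zero-sensitivity columns are floored at `1e-12 * max(R_ii)` so the
#' diagonal stays invertible.
#'
#' @param J Jacobian matrix (measurements x elements).
#' @param penalty per-element penalty vector (> 0), or a scalar.
#' @return numeric vector of diagonal entries `R_ii`.
#' @export
regularization_matrix <- function(J, penalty = 1) {
  cn <- sqrt(colSums(J^2))
  if (max(cn) == 0) stop("all-zero Jacobian")
  if (length(penalty) == 1L) penalty <- rep(penalty, length(cn))
  stopifnot(length(penalty) == length(cn), all(penalty > 0))
  r <- cn * penalty
  pmax(r, 1e-12 * max(r))
}

#' One-step linear Gauss-Newton update
#'
#' Solves the regularized linearized problem
#' `min ||y - J x||^2 + lambda^2 x^T R x` through the identity
#' `x = P J^T (J P J^T + lambda^2 I)^{-1} y` with `P = R^{-1}`, which only
#' inverts a measurements-sized system and equals the normal-equations form
#' `(J^T J + lambda^2 R)^{-1} J^T y` on well-conditioned instances.
#'
#' @param J Jacobian (measurements x elements).
#' @param y voltage-difference vector.
#' @param lambda regularization hyperparameter (> 0).
#' @param R diagonal regularization entries from [regularization_matrix()].
#' @return per-element conductivity update.
#' @export
one_step_gn <- function(J, y, lambda, R) {
  stopifnot(length(y) == nrow(J), length(R) == ncol(J), lambda > 0,
            all(R > 0))
  P <- 1 / R
  JP <- sweep(J, 2L, P, "*")
  S <- JP %*% t(J)
  diag(S) <- diag(S) + lambda^2
  rc <- rcond(S)
  if (!is.finite(rc) || rc < 1e-15)
    stop("inner Gauss-Newton system is numerically singular (rcond ",
         signif(rc, 3), ")")
  as.numeric(P * crossprod(J, solve(S, y)))
}

#' Tissue-dependent penalty values
#'
#' Constant penalties overestimate changes in low-conductivity tissues and
#' underestimate them in high-conductivity ones (the solver minimizes overall
#' voltage misfit). Scaling the penalty inversely with the reference
#' conductivity, anchored at muscle, equalizes percentage-scale sensitivity:
#' `penalty_i = base * sigma_muscle / sigma_ref_i`, clipped to
#' `[base/10, base*100]`.
#'
#' @param sigma_ref per-element reference conductivity (S/m).
#' @param labels per-element tissue ids.
#' @param base_penalty penalty assigned to muscle.
#' @param table tissue table (identifies the muscle label; if the mesh
#'   contains no muscle the median positive reference conductivity is the
#'   anchor).
#' @return per-element penalty vector.
#' @export
tissue_dependent_penalty <- function(sigma_ref, labels,
                                     base_penalty = 0.001,
                                     table = tissue_table()) {
  stopifnot(base_penalty > 0, length(sigma_ref) == length(labels))
  mus <- which(labels == match("muscle", table$name))
  anchor <- if (length(mus)) stats::median(sigma_ref[mus]) else
    stats::median(sigma_ref[sigma_ref > 0])
  pen <- ifelse(sigma_ref > 0, base_penalty * anchor / sigma_ref,
                base_penalty * 100)
  pmin(pmax(pen, base_penalty / 10), base_penalty * 100)
}

#' Positivity constraint on conductivity changes
#'
#' Zeroes negative entries of a conductivity-change vector (imposed before
#' each reconstruction iteration when only heating-induced, positive changes
#' are physical).
#'
#' @param delta_sigma per-element conductivity change.
#' @return the vector with negative entries set to 0.
#' @export
positivity_constraint <- function(delta_sigma) pmax(delta_sigma, 0)

#' Rescale measured voltages to a model reference
#'
#' Channel-wise rescaling `v * vref_model / vref_meas`, compensating global
#' anatomical differences between the measured subject and the reference
#' model using the measurable pre-heating voltages. Channels whose reference
#' magnitude falls below `1e-3` of the median are passed through unscaled and
#' flagged.
#'
#' @param v_meas measured frame of the changed state.
#' @param vref_meas measured pre-heating reference frame.
#' @param vref_model model-predicted pre-heating frame.
#' @return an `eit_frame`; indices of unscaled channels in
#'   `$unscaled_channels`.
#' @export
rescale_voltages <- function(v_meas, vref_meas, vref_model) {
  n <- length(v_meas$values)
  if (length(vref_meas$values) != n || length(vref_model$values) != n)
    stop("frames do not share a pattern")
  lo <- abs(vref_meas$values) < 1e-3 * stats::median(abs(vref_meas$values))
  ratio <- ifelse(lo, 1, vref_model$values / vref_meas$values)
  out <- v_meas
  out$values <- v_meas$values * ratio
  out$unscaled_channels <- which(lo)
  out
}

#' Gaussian smoothing of a per-element field
#'
#' Gaussian-weighted average over element centroids within `3 * radius`,
#' with weights `exp(-d^2 / (2 radius^2))` times element volume, normalized.
#' The default 1 cm radius matches the characteristic thermal length of
#' perfused tissue, i.e. the expected smoothness of a heating pattern.
#'
#' @param field per-element values.
#' @param mesh the `eit_mesh`.
#' @param radius Gaussian radius (m); 0 returns the field unchanged.
#' @return smoothed per-element values.
#' @export
smooth_field <- function(field, mesh, radius = 0.01) {
  stopifnot(length(field) == nrow(mesh$tets), radius >= 0)
  if (radius == 0) return(field)
  ctr <- tet_centroids(mesh)
  vol <- tet_volumes(mesh)
  cut <- 3 * radius
  lo <- apply(ctr, 2L, min)
  ci <- floor(sweep(ctr, 2L, lo, "-") / cut)
  nc <- apply(ci, 2L, max) + 1L
  key <- ci[, 1L] + nc[1L] * (ci[, 2L] + nc[2L] * ci[, 3L])
  groups <- split(seq_along(key), key)
  keymat <- unique(ci)
  out <- numeric(length(field))
  neigh <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  keyof <- function(ix, iy, iz) ix + nc[1L] * (iy + nc[2L] * iz)
  for (g in seq_len(nrow(keymat))) {
    cx <- keymat[g, 1L]; cy <- keymat[g, 2L]; cz <- keymat[g, 3L]
    M <- groups[[as.character(keyof(cx, cy, cz))]]
    cand <- unlist(lapply(seq_len(27L), function(q) {
      groups[[as.character(keyof(cx + neigh$dx[q], cy + neigh$dy[q],
                                 cz + neigh$dz[q]))]]
    }), use.names = FALSE)
    d2 <- outer(ctr[M, 1L], ctr[cand, 1L], "-")^2 +
          outer(ctr[M, 2L], ctr[cand, 2L], "-")^2 +
          outer(ctr[M, 3L], ctr[cand, 3L], "-")^2
    W <- exp(-d2 / (2 * radius^2))
    W[d2 > cut^2] <- 0
    W <- sweep(W, 2L, vol[cand], "*")
    out[M] <- (W %*% field[cand]) / rowSums(W)
  }
  out
}
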