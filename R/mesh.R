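# Structured tetrahedral meshing of swept bodies (elliptic cylinder, sphere).
#
# All meshes are built from a structured triangulated disk template swept along
# the z axis; prisms between layers are split into tetrahedra with the
# global-index diagonal rule, which guarantees conforming faces between
# neighbouring prisms. Generation is fully deterministic.

# Triangulated unit disk: one centre node, m concentric rings of n_theta nodes.
disk_template <- function(n_theta = 32L, m = 8L) {
  stopifnot(n_theta >= 3L, m >= 1L)
  ang <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  rho <- rep(seq_len(m) / m, each = n_theta)
  nodes <- rbind(c(0, 0),
                 cbind(rep(cos(ang), m) * rho, rep(sin(ang), m) * rho))
  ring_of <- c(0, rep(seq_len(m), each = n_theta))        # 0 = centre
  angle_of <- c(0, rep(ang, m))
  idx <- function(j, k) 1L + (j - 1L) * n_theta + ((k - 1L) %% n_theta) + 1L
  tris <- matrix(0L, nrow = n_theta * (2L * m - 1L), ncol = 3L)
  r <- 0L
  for (k in seq_len(n_theta)) {                           # centre fan
    r <- r + 1L
    tris[r, ] <- c(1L, idx(1L, k), idx(1L, k + 1L))
  }
  if (m > 1L) {
    for (j in seq_len(m - 1L)) {
      for (k in seq_len(n_theta)) {
        a <- idx(j, k); b <- idx(j, k + 1L)
        c2 <- idx(j + 1L, k + 1L); d <- idx(j + 1L, k)
        r <- r + 1L; tris[r, ] <- c(a, b, c2)
        r <- r + 1L; tris[r, ] <- c(a, c2, d)
      }
    }
  }
  list(nodes = nodes, tris = tris, ring = ring_of, angle = angle_of,
       n_theta = n_theta, m = m)
}

# Split a set of prisms (rows: 6 global node ids, verticals (1,4),(2,5),(3,6))
# into 3 tets each, with quad-face diagonals through the smallest global index
# so that neighbouring prisms generate matching faces.
split_prisms <- function(pr) {
  perms <- list(c(1L, 2L, 3L, 4L, 5L, 6L), c(2L, 3L, 1L, 5L, 6L, 4L),
                c(3L, 1L, 2L, 6L, 4L, 5L), c(4L, 6L, 5L, 1L, 3L, 2L),
                c(5L, 4L, 6L, 2L, 1L, 3L), c(6L, 5L, 4L, 3L, 2L, 1L))
  amin <- max.col(-pr, ties.method = "first")
  norm <- pr
  for (p in 2:6) {
    sel <- amin == p
    if (any(sel)) norm[sel, ] <- pr[sel, perms[[p]], drop = FALSE]
  }
  c1 <- pmin(norm[, 2L], norm[, 6L]) < pmin(norm[, 3L], norm[, 5L])
  n <- nrow(norm)
  tets <- matrix(0L, nrow = 3L * n, ncol = 4L)
  # case TRUE: (1,2,3,6),(1,2,6,5),(1,5,6,4); FALSE: (1,2,3,5),(1,5,3,6),(1,5,6,4)
  t1 <- cbind(norm[, 1L], norm[, 2L], norm[, 3L], ifelse(c1, norm[, 6L], norm[, 5L]))
  t2 <- cbind(norm[, 1L],
              ifelse(c1, norm[, 2L], norm[, 5L]),
              ifelse(c1, norm[, 6L], norm[, 3L]),
              ifelse(c1, norm[, 5L], norm[, 6L]))
  t3 <- cbind(norm[, 1L], norm[, 5L], norm[, 6L], norm[, 4L])
  tets[seq(1L, 3L * n, by = 3L), ] <- t1
  tets[seq(2L, 3L * n, by = 3L), ] <- t2
  tets[seq(3L, 3L * n, by = 3L), ] <- t3
  tets
}

orient_tets <- function(nodes, tets) {
  v <- signed_tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
  tets
}

signed_tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE] - a
  c2 <- nodes[tets[, 3L], , drop = FALSE] - a
  d <- nodes[tets[, 4L], , drop = FALSE] - a
  (b[, 1L] * (c2[, 2L] * d[, 3L] - c2[, 3L] * d[, 2L]) -
   b[, 2L] * (c2[, 1L] * d[, 3L] - c2[, 3L] * d[, 1L]) +
   b[, 3L] * (c2[, 1L] * d[, 2L] - c2[, 2L] * d[, 1L])) / 6
}

new_eit_mesh <- function(nodes, tets, labels = rep(1L, nrow(tets)),
                         geometry = list(), node_info = list()) {
  tets <- orient_tets(nodes, tets)
  structure(list(nodes = nodes, tets = tets, labels = as.integer(labels),
                 geometry = geometry, node_info = node_info,
                 electrode_nodes = integer(0)),
            class = "eit_mesh")
}

#' Tetrahedral element volumes and centroids
#'
#' @param mesh an `eit_mesh`.
#' @return `tet_volumes`: numeric vector of (positive) element volumes (m^3);
#'   `tet_centroids`: n x 3 matrix of element centroids (m).
#' @export
tet_volumes <- function(mesh) abs(signed_tet_volumes(mesh$nodes, mesh$tets))

#' @rdname tet_volumes
#' @export
tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4
}

#' Structured tetrahedral mesh of an elliptic cylinder
#'
#' Sweeps a structured triangulated disk (centre node plus `m` rings of
#' `n_theta` nodes each, scaled to half-axes `a` and `b`) along z through
#' `nz` layers. The lateral boundary polygon is inscribed in the ellipse, so
#' boundary nodes lie exactly on it. The z origin is at mid-height.
#'
#' @param a,b outer half-axes of the elliptic cross-section (m).
#' @param height extrusion height (m).
#' @param n_theta nodes per ring (also the lateral angular resolution).
#' @param m number of radial rings.
#' @param nz number of element layers along z.
#' @return an `eit_mesh` with `n_theta * (2*m - 1) * nz * 3` tetrahedra.
#' @export
cylinder_mesh <- function(a = 0.15, b = 0.10, height = 0.20,
                          n_theta = 32L, m = 8L, nz = 20L) {
  stopifnot(a > 0, b > 0, height > 0, nz >= 1L)
  tpl <- disk_template(n_theta, m)
  n2 <- nrow(tpl$nodes)
  z <- seq(-height / 2, height / 2, length.out = nz + 1L)
  nodes <- cbind(rep(tpl$nodes[, 1L], nz + 1L) * a,
                 rep(tpl$nodes[, 2L], nz + 1L) * b,
                 rep(z, each = n2))
  ntri <- nrow(tpl$tris)
  pr <- matrix(0L, nrow = ntri * nz, ncol = 6L)
  for (l in seq_len(nz)) {
    off <- (l - 1L) * n2
    pr[(l - 1L) * ntri + seq_len(ntri), ] <-
      cbind(tpl$tris + off, tpl$tris + off + n2)
  }
  node_info <- list(
    rho = rep(tpl$ring / tpl$m, nz + 1L),
    angle = rep(tpl$angle, nz + 1L),
    level = rep(seq_len(nz + 1L) - 1L, each = n2))
  new_eit_mesh(nodes, split_prisms(pr),
               geometry = list(type = "elliptic_cylinder", a = a, b = b,
                               height = height, n_theta = n_theta,
                               m = m, nz = nz),
               node_info = node_info)
}

#' Structured tetrahedral mesh of a sphere
#'
#' Solid sphere built from `n_psi - 1` disk layers at equispaced polar angles
#' plus two pole caps; used mainly as a verification phantom for which a
#' closed-form transfer-impedance solution exists.
#'
#' @param radius sphere radius (m).
#' @param n_theta,m disk resolution (see [cylinder_mesh()]).
#' @param n_psi number of polar subdivisions (>= 3).
#' @return an `eit_mesh`; pole node indices are stored in
#'   `mesh$geometry$poles`.
#' @export
sphere_mesh <- function(radius = 0.1, n_theta = 16L, m = 4L, n_psi = 8L) {
  stopifnot(radius > 0, n_psi >= 3L)
  tpl <- disk_template(n_theta, m)
  n2 <- nrow(tpl$nodes)
  psi <- pi * seq_len(n_psi - 1L) / n_psi
  nlay <- length(psi)
  nodes <- matrix(0, nrow = nlay * n2 + 2L, ncol = 3L)
  for (l in seq_len(nlay)) {
    r <- radius * sin(psi[l])
    nodes[(l - 1L) * n2 + seq_len(n2), ] <-
      cbind(tpl$nodes * r, radius * cos(psi[l]))
  }
  top <- nlay * n2 + 1L
  bot <- nlay * n2 + 2L
  nodes[top, ] <- c(0, 0, radius)
  nodes[bot, ] <- c(0, 0, -radius)
  ntri <- nrow(tpl$tris)
  pr <- matrix(0L, nrow = ntri * (nlay - 1L), ncol = 6L)
  for (l in seq_len(nlay - 1L)) {
    off <- (l - 1L) * n2
    pr[(l - 1L) * ntri + seq_len(ntri), ] <-
      cbind(tpl$tris + off + n2, tpl$tris + off)  # lower layer first
  }
  tets <- split_prisms(pr)
  cap_top <- cbind(tpl$tris, top)                         # first layer to +pole
  cap_bot <- cbind(tpl$tris + (nlay - 1L) * n2, bot)
  tets <- rbind(tets, cap_top, cap_bot)
  rho <- rep(tpl$ring / tpl$m, nlay)
  node_info <- list(
    rho = c(rho, 0, 0),
    angle = c(rep(tpl$angle, nlay), 0, 0),
    level = c(rep(seq_len(nlay), each = n2), 0L, n_psi))
  new_eit_mesh(nodes, tets,
               geometry = list(type = "sphere", radius = radius,
                               n_theta = n_theta, m = m, n_psi = n_psi,
                               poles = c(top, bot)),
               node_info = node_info)
}

#' Boundary surface nodes of a structured mesh
#'
#' For the elliptic cylinder, "lateral" selects the outermost node ring.
#'
#' @param mesh an `eit_mesh`.
#' @param which `"lateral"` (outer ring, cylinder), or `"all"`.
#' @return integer node indices.
#' @export
boundary_nodes <- function(mesh, which = c("lateral", "all")) {
  which <- match.arg(which)
  rho <- mesh$node_info$rho
  if (is.null(rho)) stop("mesh carries no structured node info")
  lateral <- which(rho > 1 - 1e-9)
  if (which == "lateral") return(lateral)
  g <- mesh$geometry
  if (identical(g$type, "elliptic_cylinder")) {
    lev <- mesh$node_info$level
    sort(unique(c(lateral, which(lev == 0L | lev == g$nz))))
  } else lateral
}

#' Validate an `eit_mesh`
#'
#' Checks positive element volumes, label range and index bounds; errors on
#' violation.
#'
#' @param mesh an `eit_mesh`.
#' @param n_tissues number of tissue table rows labels may refer to.
#' @return the mesh, invisibly.
#' @export
check_mesh <- function(mesh, n_tissues = nrow(tissue_table())) {
  stopifnot(inherits(mesh, "eit_mesh"))
  if (any(mesh$tets < 1L) || any(mesh$tets > nrow(mesh$nodes)))
    stop("tet node index out of range")
  v <- signed_tet_volumes(mesh$nodes, mesh$tets)
  if (any(v <= 0)) stop("non-positive tetrahedron volume")
  if (length(mesh$labels) != nrow(mesh$tets))
    stop("label count does not match element count")
  if (any(mesh$labels < 1L) || any(mesh$labels > n_tissues))
    stop("tissue label outside table")
  invisible(mesh)
}

#' @export
print.eit_mesh <- function(x, ...) {
  g <- x$geometry
  cat("EIT tetrahedral mesh (", if (!is.null(g$type)) g$type else "generic",
      ")\n  nodes: ", nrow(x$nodes), ", elements: ", nrow(x$tets),
      ", tissues: ", length(unique(x$labels)),
      ", electrodes: ", length(x$electrode_nodes), "\n", sep = "")
  invisible(x)
}
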