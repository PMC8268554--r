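# Rectilinear grid support: construction from a phantom spec, grid <-> mesh
# transfer and the cubic spatial-averaging filter.

#' Rectilinear thermal grid over a phantom
#'
#' Voxelizes the phantom bounding box at the given spacing and labels voxel
#' centres with the phantom's analytic regions. Voxels outside the phantom
#' get label 0 and act as fixed-temperature (body-surface) boundary voxels in
#' the thermal solver; `NA` labels (only in hand-built grids) are insulated
#' voids.
#'
#' @param spec a [phantom_spec()].
#' @param spacing voxel edge length (m).
#' @param table tissue table.
#' @return list of class `thermal_grid` with `dims`, `spacing`, `origin`
#'   (centre of voxel (1,1,1)) and integer `labels` (length prod(dims)).
#' @export
thermal_grid <- function(spec, spacing = 0.004, table = tissue_table()) {
  stopifnot(spacing > 0)
  lim <- rbind(c(-spec$a, spec$a), c(-spec$b, spec$b),
               c(-spec$height / 2, spec$height / 2))
  dims <- as.integer(ceiling((lim[, 2] - lim[, 1]) / spacing)) + 2L
  origin <- (lim[, 1] + lim[, 2]) / 2 - (dims - 1) / 2 * spacing
  pts <- grid_coords(list(dims = dims, spacing = spacing, origin = origin))
  lab <- phantom_label_points(pts, spec, table)
  lab[is.na(lab)] <- 0L
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 labels = lab, spec = spec),
            class = "thermal_grid")
}

#' Voxel-centre coordinates of a grid
#'
#' @param grid a `thermal_grid` (or list with `dims`, `spacing`, `origin`).
#' @return prod(dims) x 3 matrix, x fastest.
#' @export
grid_coords <- function(grid) {
  d <- grid$dims
  ix <- rep.int(seq_len(d[1]), d[2] * d[3])
  iy <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
  iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  cbind(grid$origin[1] + (ix - 1) * grid$spacing,
        grid$origin[2] + (iy - 1) * grid$spacing,
        grid$origin[3] + (iz - 1) * grid$spacing)
}

#' Trilinear interpolation of a voxel field at points
#'
#' @param grid a `thermal_grid`.
#' @param values per-voxel values (length prod(dims)).
#' @param points n x 3 matrix (m); coordinates are clamped to the grid.
#' @return numeric vector of interpolated values.
#' @export
interp_grid_at <- function(grid, values, points) {
  d <- grid$dims
  s <- grid$spacing
  u <- sweep(points, 2L, grid$origin, "-") / s
  u <- pmin(pmax(u, 0), matrix(rep(d - 1L, each = nrow(points)), ncol = 3) - 1e-9)
  i0 <- pmin(floor(u), matrix(rep(d - 2L, each = nrow(points)), ncol = 3))
  f <- u - i0
  arr <- array(values, dim = d)
  idx <- function(ox, oy, oz)
    arr[cbind(i0[, 1] + 1L + ox, i0[, 2] + 1L + oy, i0[, 3] + 1L + oz)]
  v000 <- idx(0L, 0L, 0L); v100 <- idx(1L, 0L, 0L)
  v010 <- idx(0L, 1L, 0L); v110 <- idx(1L, 1L, 0L)
  v001 <- idx(0L, 0L, 1L); v101 <- idx(1L, 0L, 1L)
  v011 <- idx(0L, 1L, 1L); v111 <- idx(1L, 1L, 1L)
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
              fy * ((1 - fx) * v010 + fx * v110)) +
    fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
          fy * ((1 - fx) * v011 + fx * v111))
}

# volume-weighted binning of point values into voxels; empty in-phantom
# voxels are filled by iterative nearest-neighbour dilation
points_to_grid <- function(grid, points, values, weights = NULL) {
  d <- grid$dims
  s <- grid$spacing
  if (is.null(weights)) weights <- rep(1, length(values))
  ii <- round(sweep(points, 2L, grid$origin, "-") / s) + 1L
  ok <- ii[, 1] >= 1L & ii[, 1] <= d[1] & ii[, 2] >= 1L & ii[, 2] <= d[2] &
        ii[, 3] >= 1L & ii[, 3] <= d[3]
  lin <- ii[ok, 1] + d[1] * (ii[ok, 2] - 1L) + d[1] * d[2] * (ii[ok, 3] - 1L)
  num <- rep(0, prod(d)); den <- rep(0, prod(d))
  wv <- weights[ok] * values[ok]
  agg <- rowsum(cbind(wv, weights[ok]), lin)
  at <- as.integer(rownames(agg))
  num[at] <- agg[, 1]; den[at] <- agg[, 2]
  out <- ifelse(den > 0, num / den, NA_real_)
  inside <- grid$labels >= 1L
  # dilate into empty in-phantom voxels
  arr <- array(out, dim = d)
  ins <- array(inside, dim = d)
  for (it in 1:100) {
    need <- ins & is.na(arr)
    if (!any(need)) break
    acc <- array(0, dim = d); cnt <- array(0, dim = d)
    shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
    for (sh in shifts) {
      src <- shift_array(arr, sh)
      has <- !is.na(src)
      acc[has] <- acc[has] + src[has]
      cnt <- cnt + has
    }
    fill <- need & cnt > 0
    arr[fill] <- acc[fill] / cnt[fill]
  }
  out <- as.numeric(arr)
  out[!inside] <- NA_real_
  out
}

shift_array <- function(a, sh) {
  d <- dim(a)
  out <- array(NA_real_, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - sh[1]; fy <- sy - sh[2]; fz <- sz - sh[3]
  okx <- fx >= 1 & fx <= d[1]; oky <- fy >= 1 & fy <= d[2]
  okz <- fz >= 1 & fz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[fx[okx], fy[oky], fz[okz]]
  out
}

# 1-D running mean of width w along one array axis, ignoring NAs
box_1d <- function(arr, w, axis) {
  if (w <= 1L) return(arr)
  d <- dim(arr)
  half <- (w - 1L) %/% 2L
  vals <- ifelse(is.na(arr), 0, arr)
  cnt <- array(as.numeric(!is.na(arr)), dim = d)
  acc <- array(0, dim = d); n <- array(0, dim = d)
  for (o in seq(-half, half)) {
    sh <- c(0, 0, 0); sh[axis] <- o
    sv <- shift_array(vals, sh); sc <- shift_array(cnt, sh)
    sv[is.na(sv)] <- 0; sc[is.na(sc)] <- 0
    acc <- acc + sv; n <- n + sc
  }
  out <- acc / n
  out[n == 0] <- NA_real_
  out[is.na(arr)] <- NA_real_
  out
}

#' Interpolate an element field to the grid and apply the averaging filter
#'
#' Volume-weighted interpolation of a per-element field onto the rectilinear
#' grid followed by a cubic box average (edge 1.2 cm by default), the
#' analysis path used before computing error statistics: the filter mimics
#' the expected smoothness of a heat distribution in perfused tissue.
#'
#' @param field per-element values.
#' @param mesh the `eit_mesh` the field lives on.
#' @param grid target `thermal_grid`.
#' @param edge filter cube edge length (m); must be >= the grid spacing.
#' @return per-voxel values (`NA` outside the phantom).
#' @export
interpolate_and_filter <- function(field, mesh, grid, edge = 0.012) {
  stopifnot(edge >= grid$spacing)
  vox <- points_to_grid(grid, tet_centroids(mesh), field, tet_volumes(mesh))
  w <- max(1L, round(edge / grid$spacing))
  if (w %% 2L == 0L) w <- w + 1L
  arr <- array(vox, dim = grid$dims)
  for (ax in 1:3) arr <- box_1d(arr, w, ax)
  as.numeric(arr)
}
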