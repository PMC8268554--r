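# Synthetic layered torso phantom: an elliptic cylinder with skin/fat shells,
# a muscle background and parametric inclusions (spine-like bone, liver-like
# organ, urine-filled bladder, tumor). Stands in for licensed anatomical
# models while reproducing the torso's conductivity heterogeneity
# (~0 S/m internal air up to 3 S/m urine).

#' Phantom geometry specification
#'
#' Defines the outer elliptic-cylinder geometry, the mesh-size target and the
#' embedded tissue structures. Inclusions are assigned to elements by centroid
#' membership; later list entries override earlier ones. Lengths are meters,
#' the origin is at the torso-section centre, z along the body axis.
#'
#' @param a,b outer half-axes of the elliptic cross-section (m).
#' @param height section height (m).
#' @param target_elements requested tetrahedron count (achieved within ±30%).
#' @param inclusions list of regions; each entry a list with `tissue` and
#'   either `shape = "shell"` (fields `rho_range`, normalized elliptic radius
#'   interval), `shape = "sphere"` (`center`, `radius`) or
#'   `shape = "cylinder"` (`center` = c(x, y), `radius`, axis along z).
#'   `NULL` selects the default torso structures; `list()` gives a
#'   homogeneous muscle phantom.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(a = 0.15, b = 0.10, height = 0.20,
                         target_elements = 28800L, inclusions = NULL) {
  if (a <= 0 || b <= 0 || height <= 0)
    stop("degenerate geometry: half-axes and height must be positive")
  if (is.null(inclusions)) {
    inclusions <- list(
      list(tissue = "fat",   shape = "shell",  rho_range = c(0.80, 0.90)),
      list(tissue = "skin",  shape = "shell",  rho_range = c(0.90, 1.001)),
      list(tissue = "bone",  shape = "cylinder", center = c(0, -0.06),
           radius = 0.02),
      list(tissue = "organ", shape = "sphere", center = c(-0.07, 0.02, 0.02),
           radius = 0.045),
      list(tissue = "urine", shape = "sphere", center = c(0.03, 0.00, -0.03),
           radius = 0.028),
      list(tissue = "tumor", shape = "sphere", center = c(0.035, 0.015, -0.01),
           radius = 0.015))
  }
  for (inc in inclusions) {
    if (identical(inc$shape, "sphere")) {
      ctr <- inc$center
      if ((ctr[1] / a)^2 + (ctr[2] / b)^2 >= 1 || abs(ctr[3]) > height / 2)
        stop("inclusion '", inc$tissue, "' lies outside the outer boundary")
    }
    if (identical(inc$shape, "cylinder")) {
      ctr <- inc$center
      if ((ctr[1] / a)^2 + (ctr[2] / b)^2 >= 1)
        stop("inclusion '", inc$tissue, "' lies outside the outer boundary")
    }
  }
  structure(list(a = a, b = b, height = height,
                 target_elements = as.integer(target_elements),
                 inclusions = inclusions, background = "muscle"),
            class = "phantom_spec")
}

#' Tissue labels at arbitrary points of a phantom
#'
#' Applies the phantom's analytic region definitions (background, shells,
#' inclusions) to a set of points. Shared by the mesh builder and the
#' rectilinear thermal grid so both discretizations see the same anatomy.
#'
#' @param points n x 3 matrix of coordinates (m).
#' @param spec a [phantom_spec()].
#' @param table tissue table (defines the label ids).
#' @return integer tissue ids (NA outside the phantom).
#' @export
phantom_label_points <- function(points, spec, table = tissue_table()) {
  x <- points[, 1L]; y <- points[, 2L]; z <- points[, 3L]
  rho <- sqrt((x / spec$a)^2 + (y / spec$b)^2)
  lab <- rep(tissue_id(spec$background, table), nrow(points))
  for (inc in spec$inclusions) {
    id <- tissue_id(inc$tissue, table)
    sel <- switch(inc$shape,
      shell = rho > inc$rho_range[1] & rho <= inc$rho_range[2],
      sphere = (x - inc$center[1])^2 + (y - inc$center[2])^2 +
               (z - inc$center[3])^2 <= inc$radius^2,
      cylinder = (x - inc$center[1])^2 + (y - inc$center[2])^2 <=
                 inc$radius^2,
      stop("unknown inclusion shape: ", inc$shape))
    lab[sel] <- id
  }
  lab[rho > 1 + 1e-9 | abs(z) > spec$height / 2 + 1e-9] <- NA_integer_
  lab
}

#' Build the synthetic torso phantom
#'
#' Meshes the elliptic cylinder at a resolution matching
#' `spec$target_elements`, labels elements by centroid membership in the
#' spec's regions, and populates the per-element reference conductivity from
#' the tissue table.
#'
#' @param spec a [phantom_spec()].
#' @param table tissue table.
#' @param frequency `"lf"` or `"hf"` conductivity assignment.
#' @return list with `mesh` (an `eit_mesh`, labels set) and `sigma`
#'   (numeric per-element conductivity, S/m).
#' @export
#' @examples
#' ph <- build_phantom(phantom_spec(target_elements = 5000))
#' ph$mesh
build_phantom <- function(spec = phantom_spec(), table = tissue_table(),
                          frequency = c("lf", "hf")) {
  frequency <- match.arg(frequency)
  n_theta <- 32L
  f <- (spec$target_elements / 28800)^(1 / 3)
  m <- max(3L, as.integer(round(8 * f)))
  # nz divisible by 4 so the electrode rings at +-height/4 fall on mesh
  # node levels exactly
  nz <- max(4L, 4L * as.integer(round(
    spec$target_elements / (3 * n_theta * (2 * m - 1)) / 4)))
  mesh <- cylinder_mesh(spec$a, spec$b, spec$height, n_theta, m, nz)
  got <- nrow(mesh$tets)
  if (abs(got - spec$target_elements) > 0.3 * spec$target_elements)
    warning("element count ", got, " misses target ", spec$target_elements)
  mesh$labels <- phantom_label_points(tet_centroids(mesh), spec, table)
  mesh$geometry$spec <- spec
  check_mesh(mesh, nrow(table))
  list(mesh = mesh, sigma = sigma_from_labels(mesh$labels, table, frequency))
}

#' Place ring electrodes on the lateral boundary
#'
#' Positions `n_electrodes` point electrodes in `rings` rings of equal size at
#' distinct heights, equally spaced in the elliptic parameter angle within
#' each ring with a half-spacing azimuthal offset between rings. Consecutive
#' electrode indices alternate between rings (interleaved arrangement), so
#' with two rings of eight the azimuth advances by 22.5 degrees per electrode
#' index. Requested positions are snapped to the nearest lateral boundary
#' node.
#'
#' @param mesh an `eit_mesh` from [cylinder_mesh()]/[build_phantom()].
#' @param n_electrodes electrode count (divisible by `rings`).
#' @param rings number of rings.
#' @param heights ring heights (m); default places rings at ±height/4 for two
#'   rings, or equispaced interior heights otherwise.
#' @return the mesh with `electrode_nodes` set (ordered electrode node
#'   indices) and snap distances in `mesh$electrode_snap`.
#' @export
place_electrodes <- function(mesh, n_electrodes = 16L, rings = 2L,
                             heights = NULL) {
  if (n_electrodes %% rings != 0L)
    stop("n_electrodes must be divisible by rings")
  g <- mesh$geometry
  h <- g$height
  if (is.null(heights)) {
    heights <- if (rings == 1L) 0 else
      if (rings == 2L) c(-h / 4, h / 4) else
      seq(-h / 4, h / 4, length.out = rings)
  }
  stopifnot(length(heights) == rings)
  per <- n_electrodes / rings
  j <- seq_len(n_electrodes)
  angle <- (j - 1L) * 2 * pi / n_electrodes
  ring <- ((j - 1L) %% rings) + 1L
  target <- cbind(g$a * cos(angle), g$b * sin(angle), heights[ring])
  lat <- boundary_nodes(mesh, "lateral")
  latxyz <- mesh$nodes[lat, , drop = FALSE]
  enodes <- integer(n_electrodes)
  snap <- numeric(n_electrodes)
  for (i in j) {
    d2 <- (latxyz[, 1L] - target[i, 1L])^2 + (latxyz[, 2L] - target[i, 2L])^2 +
          (latxyz[, 3L] - target[i, 3L])^2
    k <- which.min(d2)
    enodes[i] <- lat[k]
    snap[i] <- sqrt(d2[k])
  }
  edge <- max(2 * pi * max(g$a, g$b) / g$n_theta, h / g$nz)
  if (any(snap > 2 * edge))
    stop("electrode snap distance exceeds 2 local edge lengths (max ",
         signif(max(snap), 3), " m)")
  if (anyDuplicated(enodes))
    stop("electrode placement collapsed onto duplicate nodes; refine the mesh")
  mesh$electrode_nodes <- enodes
  mesh$electrode_snap <- snap
  mesh
}

#' Heating scenario description
#'
#' A spherical heated region in which the reference conductivity is
#' multiplied by `1 + peak * exp(-r^2 / (2 R^2))` (r: distance from the
#' centre), optionally accompanied by a spherical conductivity anomaly
#' outside the heated region (e.g. a gas pocket).
#'
#' @param center heated-region centre (m, length 3).
#' @param R Gaussian width parameter (m).
#' @param peak peak relative conductivity increase (0.4 = 40%).
#' @param diameter nominal diameter of the heated sphere (m); defaults to
#'   `2 * R`. Used as the prior-region radius.
#' @param anomaly optional list with `center` (m), `diameter` (m) and
#'   `sigma_value` (S/m).
#' @return list of class `heating_scenario`.
#' @export
heating_scenario <- function(center, R, peak = 0.4, diameter = 2 * R,
                             anomaly = NULL) {
  stopifnot(length(center) == 3, R > 0, peak >= 0, diameter > 0)
  if (!is.null(anomaly))
    stopifnot(length(anomaly$center) == 3, anomaly$diameter > 0,
              anomaly$sigma_value >= 0)
  structure(list(center = as.numeric(center), R = R, peak = peak,
                 diameter = diameter, anomaly = anomaly),
            class = "heating_scenario")
}

#' Apply Gaussian heating to a conductivity field
#'
#' Multiplies the conductivity of the elements whose centroid lies inside the
#' scenario's heated sphere (diameter `scenario$diameter`) by
#' `1 + peak * exp(-r^2 / (2 R^2))`, with `r` the distance from the element
#' centroid to the scenario centre. At the centre the relative increase
#' equals `peak` (40% for the canonical scenarios); elements outside the
#' sphere are unchanged, so the heated region has compact, known support.
#'
#' @param sigma per-element conductivity (S/m).
#' @param scenario a [heating_scenario()].
#' @param mesh the `eit_mesh` the field lives on.
#' @return modified conductivity vector.
#' @export
apply_gaussian_heating <- function(sigma, scenario, mesh) {
  stopifnot(inherits(scenario, "heating_scenario"),
            length(sigma) == nrow(mesh$tets))
  ctr <- tet_centroids(mesh)
  r2 <- (ctr[, 1L] - scenario$center[1])^2 +
        (ctr[, 2L] - scenario$center[2])^2 +
        (ctr[, 3L] - scenario$center[3])^2
  mult <- 1 + scenario$peak * exp(-r2 / (2 * scenario$R^2))
  inside <- r2 <= (scenario$diameter / 2)^2
  sigma[inside] <- sigma[inside] * mult[inside]
  sigma
}

#' Insert a spherical conductivity anomaly
#'
#' Sets the conductivity of all elements whose centroid lies inside the given
#' sphere to `sigma_value` (e.g. 0 S/m for a gas pocket); all other elements
#' are unchanged.
#'
#' @param sigma per-element conductivity (S/m).
#' @param mesh the `eit_mesh`.
#' @param center sphere centre (m).
#' @param diameter sphere diameter (m).
#' @param sigma_value conductivity assigned inside (S/m, >= 0).
#' @return modified conductivity vector.
#' @export
insert_spherical_anomaly <- function(sigma, mesh, center, diameter,
                                     sigma_value) {
  stopifnot(diameter > 0, sigma_value >= 0, length(sigma) == nrow(mesh$tets))
  ctr <- tet_centroids(mesh)
  inside <- (ctr[, 1L] - center[1])^2 + (ctr[, 2L] - center[2])^2 +
            (ctr[, 3L] - center[3])^2 <= (diameter / 2)^2
  if (!any(inside))
    warning("anomaly sphere contains no element centroids; field unchanged")
  sigma[inside] <- sigma_value
  sigma
}

# Published heated-region scenarios are given in the reference anatomy's
# coordinate frame; map them into the phantom by per-axis linear scaling.
.map_reference_frame <- function(p_mm) {
  c(p_mm[1] * 150 / 180, p_mm[2] * 100 / 120, p_mm[3]) / 1000
}

#' Canonical heated-region scenarios
#'
#' The five spherical heating scenarios (P1-P5: diameters 60, 40, 80, 60 and
#' 60 mm; P1-P3 share one deep centre, P4 and P5 probe other locations) plus
#' the "air" case: the P1 heating with an additional 50 mm diameter, 0 S/m
#' spherical anomaly outside the prior region. Positions are mapped from the
#' reference-anatomy frame into the phantom cross-section by linear axis
#' scaling.
#'
#' @param id one of `"P1"` ... `"P5"`, `"air"`.
#' @return a [heating_scenario()].
#' @export
#' @examples
#' scenario_fixture("P2")$diameter  # 0.04 m
scenario_fixture <- function(id = c("P1", "P2", "P3", "P4", "P5", "air")) {
  id <- match.arg(id)
  centers <- list(P1 = c(-90, 20, 15), P2 = c(-90, 20, 15),
                  P3 = c(-90, 20, 15), P4 = c(-40, 50, 15),
                  P5 = c(30, 50, 15))
  diam_mm <- c(P1 = 60, P2 = 40, P3 = 80, P4 = 60, P5 = 60)
  air_center <- .map_reference_frame(c(50, 30, 15))
  if (id == "air") {
    sc <- scenario_fixture("P1")
    sc$anomaly <- list(center = air_center, diameter = 0.050, sigma_value = 0)
    return(sc)
  }
  d <- diam_mm[[id]] / 1000
  heating_scenario(center = .map_reference_frame(centers[[id]]),
                   R = 0.03, peak = 0.4, diameter = d)
}

#' Prior-region mask for a heated sphere
#'
#' Elements whose centroid lies within the scenario's nominal heated sphere.
#'
#' @param mesh an `eit_mesh`.
#' @param scenario a [heating_scenario()].
#' @return logical vector per element.
#' @export
scenario_prior_mask <- function(mesh, scenario) {
  ctr <- tet_centroids(mesh)
  (ctr[, 1L] - scenario$center[1])^2 + (ctr[, 2L] - scenario$center[2])^2 +
    (ctr[, 3L] - scenario$center[3])^2 <= (scenario$diameter / 2)^2
}
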