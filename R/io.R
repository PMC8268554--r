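# Plain-text interchange: legacy VTK and Gmsh MSH v2 for meshes with cell
# data, CSV for measurement frames, JSON summaries for reconstructions.

#' Write a mesh with cell data as a legacy ASCII VTK file
#'
#' Unstructured-grid output readable by ParaView and meshio; tissue labels
#' and any per-element fields are written as CELL_DATA.
#'
#' @param mesh an `eit_mesh`.
#' @param path output file path (conventionally `.vtk`).
#' @param cell_data named list of per-element numeric vectors (tissue labels
#'   are always included).
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, cell_data = list()) {
  nt <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "eitherm mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(mesh$nodes), "double")), con)
  utils::write.table(format(mesh$nodes, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("CELLS", nt, nt * 5L), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(paste("CELL_TYPES", nt), con)
  writeLines(as.character(rep(10L, nt)), con)
  cell_data <- c(list(tissue = as.numeric(mesh$labels)), cell_data)
  writeLines(paste("CELL_DATA", nt), con)
  for (nm in names(cell_data)) {
    writeLines(c(paste("SCALARS", nm, "double", 1), "LOOKUP_TABLE default"),
               con)
    writeLines(format(cell_data[[nm]], digits = 10, trim = TRUE), con)
  }
  invisible(path)
}

#' Write / read a mesh in Gmsh MSH v2 ASCII format
#'
#' Tetrahedra are written as element type 4 with the tissue label as the
#' physical tag. `read_msh_mesh` accepts meshes written by this package or
#' by Gmsh (only tetrahedral elements are kept).
#'
#' @param mesh an `eit_mesh`.
#' @param path file path.
#' @return `write_msh_mesh`: `path` invisibly; `read_msh_mesh`: an
#'   `eit_mesh` (without structured node info).
#' @export
write_msh_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  utils::write.table(cbind(seq_len(nrow(mesh$nodes)),
                           format(mesh$nodes, digits = 10, trim = TRUE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$tets))), con)
  utils::write.table(cbind(seq_len(nrow(mesh$tets)), 4L, 2L, mesh$labels,
                           mesh$labels, mesh$tets),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$EndElements", con)
  invisible(path)
}

#' @rdname write_msh_mesh
#' @export
read_msh_mesh <- function(path) {
  ln <- readLines(path)
  ni <- which(ln == "$Nodes")
  nn <- as.integer(ln[ni + 1L])
  nodes <- do.call(rbind, lapply(strsplit(trimws(
    ln[ni + 1L + seq_len(nn)]), "\\s+"), as.numeric))[, 2:4, drop = FALSE]
  ei <- which(ln == "$Elements")
  ne <- as.integer(ln[ei + 1L])
  rows <- strsplit(trimws(ln[ei + 1L + seq_len(ne)]), "\\s+")
  tets <- list(); labs <- list()
  for (r in rows) {
    v <- as.integer(r)
    if (v[2] != 4L) next
    ntag <- v[3]
    tets[[length(tets) + 1L]] <- v[(4L + ntag):(7L + ntag)]
    labs[[length(labs) + 1L]] <- if (ntag >= 1L) v[4L] else 1L
  }
  new_eit_mesh(nodes, do.call(rbind, tets), unlist(labs))
}

#' Write / read a measurement frame as CSV
#'
#' Columns: injection electrode pair, measurement electrode pair, voltage.
#'
#' @param frame an `eit_frame`.
#' @param path file path.
#' @param pattern (read) the `eit_pattern` the file is checked against.
#' @return the path / the `eit_frame`.
#' @export
write_frame_csv <- function(frame, path) {
  md <- frame$pattern$measurements
  inj <- frame$pattern$injections
  utils::write.csv(data.frame(inj_a = inj[md$injection, 1L],
                              inj_b = inj[md$injection, 2L],
                              meas_a = md$m1, meas_b = md$m2,
                              voltage = frame$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path, pattern) {
  d <- utils::read.csv(path)
  if (nrow(d) != nrow(pattern$measurements))
    stop("frame length does not match pattern")
  new_frame(d$voltage, pattern)
}

#' JSON summary of a reconstruction
#'
#' @param fit an `eit_recon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recon_json <- function(fit, path) {
  d <- fit$delta_pct[is.finite(fit$delta_pct)]
  jsonlite::write_json(list(
    n_elements = length(fit$delta_sigma),
    n_solves = fit$n_solves,
    diverged = fit$diverged,
    lambda = fit$config$lambda,
    penalty = fit$config$penalty,
    residual_mean_abs = fit$residuals$mean_abs,
    delta_pct_range = range(d),
    delta_pct_median = stats::median(d)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
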