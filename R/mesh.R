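#' Construct a triangulated surface mesh
#'
#' @param vertex_xyz Numeric matrix `n x 3` of vertex coordinates (mm).
#' @param faces Integer matrix `m x 3` of 0-based vertex indices.
#' @param vertex_flat Optional `n x 2` flattened-patch coordinates (mm).
#' @param vertex_sphere Optional `n x 3` unit-sphere coordinates from
#'   spherical registration.
#'
#' @return A `surface_mesh` list with the inputs plus `neighbors` (ring-1
#'   adjacency derived from faces, symmetric) and `mesh_id`, a content hash
#'   used to catch silent mesh mismatches.
#' @export
surface_mesh <- function(vertex_xyz, faces, vertex_flat = NULL, vertex_sphere = NULL) {
  vertex_xyz <- as.matrix(vertex_xyz)
  storage.mode(vertex_xyz) <- "double"
  dimnames(vertex_xyz) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  n_v <- nrow(vertex_xyz)
  stopifnot(ncol(vertex_xyz) == 3, ncol(faces) == 3)
  if (any(faces < 0L) || any(faces >= n_v)) {
    abort("surface_mesh: faces reference vertices outside 0..(n_vertices - 1).")
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3])) {
    abort("surface_mesh: degenerate (repeated-index) triangle found.")
  }
  if (!is.null(vertex_flat)) {
    vertex_flat <- as.matrix(vertex_flat)
    storage.mode(vertex_flat) <- "double"
    stopifnot(nrow(vertex_flat) == n_v, ncol(vertex_flat) == 2)
  }
  if (!is.null(vertex_sphere)) {
    vertex_sphere <- as.matrix(vertex_sphere)
    storage.mode(vertex_sphere) <- "double"
    stopifnot(nrow(vertex_sphere) == n_v, ncol(vertex_sphere) == 3)
    vertex_sphere <- vertex_sphere / sqrt(rowSums(vertex_sphere^2))
  }

  mesh <- list(
    vertex_xyz = vertex_xyz,
    faces = faces,
    vertex_flat = vertex_flat,
    vertex_sphere = vertex_sphere,
    neighbors = face_adjacency(faces, n_v)
  )
  mesh$mesh_id <- mesh_hash(mesh)
  structure(mesh, class = "surface_mesh")
}

## Ring-1 adjacency list (1-based list indexed by vertex + 1, 0-based members).
face_adjacency <- function(faces, n_v) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  adj <- split(e[, 2], factor(e[, 1], levels = 0:(n_v - 1L)))
  lapply(adj, function(v) sort(as.integer(v)))
}

## Content hash: cheap numeric digest over vertices and faces.
mesh_hash <- function(mesh) {
  v <- mesh$vertex_xyz
  f <- mesh$faces
  sums <- c(dim(v), dim(f),
            sum(v) %% 1e9, sum(v^2) %% 1e9,
            sum(as.numeric(f)) %% 1e9)
  paste0("mesh-", paste(formatC(sums, format = "g", digits = 12), collapse = "-"))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> %d vertices, %d faces%s%s\n",
    nrow(x$vertex_xyz), nrow(x$faces),
    if (!is.null(x$vertex_flat)) ", flat coords" else "",
    if (!is.null(x$vertex_sphere)) ", sphere coords" else ""
  ))
  invisible(x)
}

#' Number of vertices in a mesh
#' @param mesh A [surface_mesh()].
#' @export
mesh_n_vertices <- function(mesh) nrow(mesh$vertex_xyz)

#' Ring-1 neighbors of a vertex
#' @param mesh A [surface_mesh()].
#' @param vertex 0-based vertex index.
#' @return Sorted 0-based neighbor indices.
#' @export
mesh_neighbors <- function(mesh, vertex) {
  mesh$neighbors[[vertex + 1L]]
}

#' Regular triangulated flat grid mesh
#'
#' Builds an `nx x ny` rectangular grid of vertices at `spacing_mm`
#' resolution, triangulated so that interior vertices have 6 neighbors.
#' Flat coordinates equal the 3D (z = 0) plane coordinates; vertex ids run
#' row-major from 0 (x fastest).
#'
#' @param nx,ny Grid dimensions (each at least 2).
#' @param spacing_mm Vertex spacing in mm.
#' @return A [surface_mesh()] with `2 * (nx - 1) * (ny - 1)` faces.
#' @export
#' @examples
#' make_flat_grid_mesh(10, 10) # 100 vertices, 162 triangles
make_flat_grid_mesh <- function(nx, ny, spacing_mm = 1) {
  stopifnot(nx >= 2, ny >= 2, spacing_mm > 0)
  ix <- rep(0:(nx - 1L), times = ny)
  iy <- rep(0:(ny - 1L), each = nx)
  xyz <- cbind(ix * spacing_mm, iy * spacing_mm, 0)
  vid <- function(i, j) j * nx + i # 0-based
  faces <- NULL
  i <- rep(0:(nx - 2L), times = ny - 1L)
  j <- rep(0:(ny - 2L), each = nx - 1L)
  v00 <- vid(i, j); v10 <- vid(i + 1L, j)
  v01 <- vid(i, j + 1L); v11 <- vid(i + 1L, j + 1L)
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  surface_mesh(xyz, faces, vertex_flat = xyz[, 1:2])
}

#' Interior vertices of a flat grid mesh
#'
#' Vertices whose full 6-neighbor ring lies inside the patch; useful for
#' excluding boundary effects in gradient-field checks.
#'
#' @param mesh A mesh from [make_flat_grid_mesh()].
#' @return 0-based vertex ids with 6 neighbors.
#' @export
mesh_interior_vertices <- function(mesh) {
  deg <- lengths(mesh$neighbors)
  which(deg == 6L) - 1L
}
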