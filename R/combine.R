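#' Vector-average complex activation maps across scans
#'
#' Per-unit complex arithmetic mean of the input maps' (re, im) values. Units
#' absent (e.g. sub-threshold) in one input contribute complex zero, with the
#' number of maps in which each unit was present recorded in `valid_n`.
#'
#' @param maps List of [activation_map()]s in the same space.
#' @param weight `"equal"` divides every unit's sum by the number of maps
#'   (the default, matching averaging of same-length scan lists); `"valid"`
#'   divides by the per-unit count of maps in which it was present.
#' @return An [activation_map()] with `provenance = "scan_average"`.
#' @export
average_scans <- function(maps, weight = c("equal", "valid")) {
  combine_maps(maps, weight = match.arg(weight), provenance = "scan_average")
}

#' Vector-average complex activation maps across subjects
#'
#' Vertex-wise complex mean over `N` subject maps resampled to one common
#' mesh. Identical arithmetic to [average_scans()] but requires a common-mesh
#' space and tags the result as a group average.
#'
#' @inheritParams average_scans
#' @return An [activation_map()] with `provenance = "group_average"`.
#' @export
average_group <- function(maps, weight = c("equal", "valid")) {
  spaces <- vapply(maps, function(m) attr(m, "space") %||% "", "")
  ids <- vapply(maps, function(m) attr(m, "mesh_id") %||% "", "")
  if (length(unique(spaces)) > 1L || length(unique(ids)) > 1L) {
    abort("average_group: all maps must live on the same common mesh.")
  }
  combine_maps(maps, weight = match.arg(weight), provenance = "group_average")
}

combine_maps <- function(maps, weight, provenance) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  spaces <- unique(vapply(maps, function(m) attr(m, "space") %||% "volume", ""))
  if (length(spaces) > 1L) abort("maps live in different spaces; cannot average.")
  ids <- unique(vapply(maps, function(m) attr(m, "mesh_id") %||% "", ""))
  if (length(ids) > 1L) abort("maps reference different meshes; cannot average.")
  k <- length(maps)

  long <- dplyr::bind_rows(lapply(maps, function(m) {
    tibble::tibble(unit_id = as.integer(m$unit_id), re = m$re, im = m$im)
  }))
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$unit_id),
    sum_re = sum(.data$re), sum_im = sum(.data$im),
    valid_n = dplyr::n(), .groups = "drop"
  )
  denom <- if (weight == "equal") k else agg$valid_n
  out <- tibble::tibble(
    unit_id = agg$unit_id,
    re = agg$sum_re / denom,
    im = agg$sum_im / denom,
    valid_n = agg$valid_n
  )
  out <- dplyr::arrange(out, .data$unit_id)
  activation_map(out,
    space = spaces, mesh_id = if (nzchar(ids)) ids else NULL,
    provenance = provenance,
    partition = attr(maps[[1]], "partition")
  )
}

#' Nearest-neighbor resampling between spherically registered meshes
#'
#' Transfers per-vertex complex values from a native mesh to a common mesh:
#' each target vertex takes the value of the great-circle-nearest source
#' vertex on the unit sphere. Ties break deterministically to the lowest
#' source index.
#'
#' @param map An [activation_map()] on `source_mesh` (vertex ids index the
#'   source mesh).
#' @param source_mesh,target_mesh [surface_mesh()]es carrying
#'   `vertex_sphere` coordinates.
#' @return An [activation_map()] on the target mesh (space `common_mesh`),
#'   with every target vertex populated.
#' @export
resample_nearest_sphere <- function(map, source_mesh, target_mesh) {
  if (is.null(source_mesh$vertex_sphere) || is.null(target_mesh$vertex_sphere)) {
    abort("resample_nearest_sphere: both meshes need unit-sphere coordinates.")
  }
  src <- source_mesh$vertex_sphere
  tgt <- target_mesh$vertex_sphere
  ## Great-circle distance is monotone in the dot product; nearest source =
  ## max cosine. which.max returns the first (lowest-index) maximum.
  dots <- tcrossprod(tgt, src) # n_target x n_source
  nn <- apply(dots, 1L, which.max) # 1-based source row
  values <- complex_by_vertex(map, mesh_n_vertices(source_mesh))
  out <- tibble::tibble(
    unit_id = 0:(nrow(tgt) - 1L),
    re = Re(values)[nn],
    im = Im(values)[nn],
    valid_n = attr(values, "valid_n")[nn]
  )
  activation_map(out,
    space = "common_mesh", mesh_id = target_mesh$mesh_id,
    provenance = attr(map, "provenance") %||% "single_scan",
    partition = attr(map, "partition")
  )
}

## Dense complex vector indexed by vertex id (+1); absent vertices are 0.
complex_by_vertex <- function(map, n_vertices) {
  v <- complex(real = rep(0, n_vertices), imaginary = rep(0, n_vertices))
  valid <- integer(n_vertices)
  idx <- map$unit_id + 1L
  v[idx] <- complex(real = map$re, imaginary = map$im)
  valid[idx] <- map$valid_n %||% 1L
  attr(v, "valid_n") <- valid
  v
}

#' Sample a volumetric activation map onto a surface mesh
#'
#' Looks up, for each mesh vertex, the value of the nearest voxel under the
#' volume's voxel-to-world affine. Vertices falling outside the volume are
#' marked absent (dropped from the output table).
#'
#' @param map An [activation_map()] in volume space; `unit_id` is the 0-based
#'   linear voxel index (x fastest).
#' @param mesh A [surface_mesh()]; `vertex_xyz` are world coordinates (mm).
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param dim Length-3 integer volume dimensions.
#' @return An [activation_map()] in `native_surface` space with vertex ids as
#'   unit ids.
#' @export
sample_volume_to_surface <- function(map, mesh, affine, dim) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)), length(dim) == 3)
  if (abs(det(affine)) < 1e-12) abort("sample_volume_to_surface: singular affine.")
  inv <- solve(affine)
  world <- cbind(mesh$vertex_xyz, 1)
  vox <- round(world %*% t(inv))[, 1:3, drop = FALSE]
  inside <- vox[, 1] >= 0 & vox[, 1] < dim[1] &
    vox[, 2] >= 0 & vox[, 2] < dim[2] &
    vox[, 3] >= 0 & vox[, 3] < dim[3]
  lin <- vox[, 1] + dim[1] * (vox[, 2] + dim[2] * vox[, 3]) # 0-based linear index
  lookup <- match(lin[inside], map$unit_id)
  present <- !is.na(lookup)
  vid <- which(inside)[present] - 1L
  rows <- lookup[present]
  activation_map(
    tibble::tibble(
      unit_id = vid,
      re = map$re[rows], im = map$im[rows],
      valid_n = (map$valid_n %||% rep(1L, nrow(map)))[rows]
    ),
    space = "native_surface", mesh_id = mesh$mesh_id,
    provenance = attr(map, "provenance") %||% "single_scan",
    partition = attr(map, "partition")
  )
}
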