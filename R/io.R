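#' Load a 4D NIfTI volume as a scan time series
#'
#' Reads a NIfTI-1 4D image and reshapes it to one row per voxel (0-based
#' linear index, x fastest). TR is taken from the header's fourth pixdim
#' unless overridden; a mismatch between the two is logged as a warning.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param task_frequency Cycles per scan of the task (default 16).
#' @param tr_seconds Optional TR override (takes precedence over the header).
#' @return A [scan_ts()] with attributes `affine` (voxel-to-world, 0-based)
#'   and `vol_dim` (length-3 spatial dimensions).
#' @export
load_volume_timeseries <- function(path, task_frequency = 16, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    abort(sprintf("expected a 4D NIfTI image, got %d dimension(s).", length(d)))
  }
  header_tr <- RNifti::pixdim(img)[4]
  tr <- tr_seconds %||% header_tr
  if (!is.null(tr_seconds) && is.finite(header_tr) && header_tr > 0 &&
      abs(tr_seconds - header_tr) > 1e-6) {
    warn(sprintf("TR override %g s differs from header TR %g s; using the override.",
                 tr_seconds, header_tr))
  }
  if (!is.finite(tr) || tr <= 0) tr <- 1
  data <- matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4])
  ts <- scan_ts(data, tr_seconds = tr, task_frequency = task_frequency,
                unit_space = "volume")
  attr(ts, "affine") <- structure(RNifti::xform(img), class = NULL)
  attr(ts, "vol_dim") <- d[1:3]
  ts
}

#' Write a simulated scan as a 4D NIfTI volume
#'
#' @param ts A [scan_ts()] whose unit count factors into `dim`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param dim Length-3 spatial dimensions with `prod(dim) == nrow(ts)`.
#' @return `path`, invisibly.
#' @export
write_volume_timeseries <- function(ts, path, dim) {
  stopifnot(length(dim) == 3, prod(dim) == nrow(ts))
  arr <- array(as.vector(unclass(ts)), c(dim, ncol(ts)))
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, attr(ts, "tr_seconds")))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read an activation map as a delimited table with a JSON sidecar
#'
#' The canonical on-disk form: a tab-separated table
#' (`unit_id`, `re`, `im`, `valid_n`) plus `<path>.json` recording the space
#' tag, provenance, degrees of freedom and mesh id — simple, diffable and
#' byte-reproducible.
#'
#' @param map An [activation_map()].
#' @param path Output `.tsv` path; the sidecar is written next to it.
#' @return `path`, invisibly (writer); the reconstructed map (reader).
#' @export
write_map <- function(map, path) {
  df <- as.data.frame(map)[, c("unit_id", "re", "im", "valid_n")]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  part <- attr(map, "partition")
  sidecar <- list(
    space = attr(map, "space"),
    mesh_id = attr(map, "mesh_id"),
    provenance = attr(map, "provenance"),
    partition = if (!is.null(part)) {
      list(
        n_timepoints = part$n_timepoints,
        task_frequency = part$task_frequency,
        noise_frequencies = part$noise_frequencies,
        df_signal = part$df_signal,
        df_noise = part$df_noise
      )
    }
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  sidecar_path <- paste0(path, ".json")
  space <- "volume"; mesh_id <- NULL; provenance <- "single_scan"; part <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    space <- sc$space %||% space
    mesh_id <- sc$mesh_id
    provenance <- sc$provenance %||% provenance
    if (!is.null(sc$partition)) {
      part <- structure(list(
        n_timepoints = as.integer(sc$partition$n_timepoints),
        task_frequency = as.integer(sc$partition$task_frequency),
        noise_frequencies = as.integer(sc$partition$noise_frequencies),
        df_signal = as.integer(sc$partition$df_signal),
        df_noise = as.integer(sc$partition$df_noise),
        excluded = NULL
      ), class = "freq_partition")
    }
  }
  activation_map(tibble::as_tibble(df), space = space, mesh_id = mesh_id,
                 provenance = provenance, partition = part)
}

#' Write / read a surface mesh in the plain-text dialect
#'
#' Format: a comment header, a `n_vertices n_faces flags` line, then one line
#' per vertex (`x y z [fx fy] [sx sy sz]` depending on flags) and one line of
#' three 0-based indices per face.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @return `path`, invisibly (writer); the mesh (reader).
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  has_flat <- !is.null(mesh$vertex_flat)
  has_sphere <- !is.null(mesh$vertex_sphere)
  writeLines("# phasewave mesh v1", con)
  writeLines(sprintf("%d %d %d %d", nrow(mesh$vertex_xyz), nrow(mesh$faces),
                     as.integer(has_flat), as.integer(has_sphere)), con)
  v <- mesh$vertex_xyz
  if (has_flat) v <- cbind(v, mesh$vertex_flat)
  if (has_sphere) v <- cbind(v, mesh$vertex_sphere)
  utils::write.table(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(mesh$faces, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  n_v <- hdr[1]; n_f <- hdr[2]
  has_flat <- isTRUE(hdr[3] == 1L); has_sphere <- isTRUE(hdr[4] == 1L)
  n_col <- 3 + 2 * has_flat + 3 * has_sphere
  body <- lines[-1]
  if (length(body) != n_v + n_f) abort("read_mesh: vertex/face count mismatch.")
  vmat <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(n_v)]), "\\s+"))),
                 ncol = n_col, byrow = TRUE)
  fmat <- matrix(as.integer(unlist(strsplit(trimws(body[n_v + seq_len(n_f)]), "\\s+"))),
                 ncol = 3, byrow = TRUE)
  surface_mesh(
    vmat[, 1:3, drop = FALSE], fmat,
    vertex_flat = if (has_flat) vmat[, 4:5, drop = FALSE],
    vertex_sphere = if (has_sphere) vmat[, (4 + 2 * has_flat):(6 + 2 * has_flat), drop = FALSE]
  )
}

#' Read a FreeSurfer binary triangle surface
#'
#' Minimal reader for the big-endian triangle-surface format (magic
#' 16777214): two text lines, vertex and face counts, float32 coordinates
#' and int32 0-based face indices.
#'
#' @param path Surface file (e.g. `lh.white`, `lh.sphere.reg`).
#' @return A [surface_mesh()] (no flat or sphere slots; pass the result's
#'   coordinates to [surface_mesh()] yourself to tag a sphere).
#' @export
read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic_bytes <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  magic <- magic_bytes[1] * 65536 + magic_bytes[2] * 256 + magic_bytes[3]
  if (magic != 16777214) {
    abort(sprintf("not a FreeSurfer triangle surface (magic %d).", magic))
  }
  ## Creation comment: terminated by "\n\n" (one or two newline bytes).
  comment <- raw()
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) abort("unexpected end of file in surface header.")
    if (b == as.raw(10) && prev == as.raw(10)) break
    if (prev == as.raw(10) && b != as.raw(10)) {
      ## Single-newline terminator: step back one byte and stop.
      seek(con, -1, origin = "current")
      break
    }
    comment <- c(comment, b)
    prev <- b
  }
  n_v <- readBin(con, "integer", 1, size = 4, endian = "big")
  n_f <- readBin(con, "integer", 1, size = 4, endian = "big")
  vxyz <- matrix(readBin(con, "numeric", 3 * n_v, size = 4, endian = "big"),
                 ncol = 3, byrow = TRUE)
  faces <- matrix(readBin(con, "integer", 3 * n_f, size = 4, endian = "big"),
                  ncol = 3, byrow = TRUE)
  surface_mesh(vxyz, faces)
}

#' Load / write a surface ROI label
#'
#' Supports FreeSurfer-style label files (comment line, vertex count, then
#' rows whose first column is the 0-based vertex index) and JSON integer
#' arrays.
#'
#' @param path Label (`.label`) or JSON (`.json`) file.
#' @param name ROI name; defaults to the file stem.
#' @param mesh Optional [surface_mesh()] for index validation.
#' @return A [surface_roi()].
#' @export
load_label <- function(path, name = NULL, mesh = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    idx <- as.integer(unlist(jsonlite::read_json(path, simplifyVector = TRUE)))
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    n <- as.integer(trimws(lines[1]))
    if (is.na(n) || n < 1L || length(lines) < n + 1L) {
      abort("load_label: malformed or empty label file.")
    }
    idx <- vapply(lines[1L + seq_len(n)], function(l) {
      as.integer(strsplit(trimws(l), "\\s+")[[1]][1])
    }, integer(1), USE.NAMES = FALSE)
  }
  if (length(idx) == 0L) abort("load_label: label contains no vertices.")
  if (!is.null(mesh) && any(idx >= mesh_n_vertices(mesh))) {
    abort("load_label: label indexes vertices outside the mesh.")
  }
  surface_roi(idx, name = name, mesh_id = if (!is.null(mesh)) mesh$mesh_id)
}

#' @rdname load_label
#' @param roi A [surface_roi()] to write.
#' @param format `"label"` (FreeSurfer-style) or `"json"`.
#' @export
write_label <- function(roi, path, format = c("label", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(roi$vertices, path, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#!ascii label %s", roi$name), con)
    writeLines(as.character(length(roi$vertices)), con)
    writeLines(sprintf("%d 0.0 0.0 0.0 0.0", roi$vertices), con)
  }
  invisible(path)
}

#' Write / read a surge profile table
#'
#' @param profile A [surge_profile()].
#' @param path Output `.tsv`; metrics and window parameters go to
#'   `<path>.json`.
#' @param height_threshold Threshold used for the sidecar metrics.
#' @return `path`, invisibly.
#' @export
write_surge_profile <- function(profile, path, height_threshold = 2) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  spec <- attr(profile, "spec")
  metrics <- surge_metrics(profile, height_threshold)
  jsonlite::write_json(
    list(
      roi = attr(profile, "roi_name"),
      period_seconds = attr(profile, "period_seconds"),
      window_degrees = spec$window_degrees,
      step_degrees = spec$step_degrees,
      n_bins = spec$n_frames,
      f_threshold = attr(profile, "f_threshold"),
      height_threshold = height_threshold,
      metrics = as.list(metrics)
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a run configuration from JSON or YAML
#'
#' Recognized fields: `seed`, `period_seconds`, `task_frequency`,
#' `threshold` (named `"p01"`/`"p001"`/`"p0001"` or a number),
#' `window_degrees`, `step_degrees`, plus free-form paths. Missing fields get
#' the canonical defaults.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A named list with defaults filled in and `f_threshold` resolved
#'   to a numeric critical value.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- list(seed = 1L, period_seconds = 16, task_frequency = 16,
                   threshold = "p01", window_degrees = 9, step_degrees = 4.5)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  cfg$f_threshold <- resolve_threshold(cfg$threshold)
  cfg
}

resolve_threshold <- function(threshold) {
  if (is.character(threshold)) {
    th <- f_thresholds()
    if (!threshold %in% names(th)) {
      abort(sprintf("unknown threshold '%s' (use %s or a number).",
                    threshold, paste(names(th), collapse = "/")))
    }
    th[[threshold]]
  } else {
    val <- as.numeric(threshold)
    if (!is.finite(val) || val <= 0) abort("threshold must be positive.")
    val
  }
}
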