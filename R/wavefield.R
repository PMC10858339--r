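#' Minimal signed difference between angles
#'
#' `circular_difference(a, b)` is the signed difference `a - b` wrapped to
#' `[-pi, pi)`. Used everywhere phases are compared so that no global phase
#' unwrapping is ever needed.
#'
#' @param a,b Angles in radians (vectorized, recycled).
#' @return Signed differences in `[-pi, pi)`.
#' @export
#' @examples
#' circular_difference(0.1, 2 * pi - 0.1) # +0.2
circular_difference <- function(a, b) {
  ((a - b + pi) %% (2 * pi)) - pi
}

#' Moving-window specification for isophase frames and surge bins
#'
#' @param window_degrees Window width (default 9).
#' @param step_degrees Step between window centers (default 4.5; must divide
#'   360). `n_frames = 360 / step`, 80 under the defaults, i.e. 0.2 s per
#'   frame for a 16-s cycle.
#' @return A `window_spec` list with widths in degrees and radians and
#'   `n_frames`.
#' @export
window_spec <- function(window_degrees = 9, step_degrees = 4.5) {
  stopifnot(window_degrees > 0, step_degrees > 0)
  n_frames <- 360 / step_degrees
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    abort("window_spec: step must divide 360 degrees.")
  }
  structure(
    list(
      window_degrees = window_degrees,
      step_degrees = step_degrees,
      window_rad = window_degrees * pi / 180,
      step_rad = step_degrees * pi / 180,
      n_frames = as.integer(round(n_frames))
    ),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> window %g deg, step %g deg, %d frames\n",
              x$window_degrees, x$step_degrees, x$n_frames))
  invisible(x)
}

#' Phase-gradient vector field on a flattened mesh
#'
#' For every significant vertex, fits a local 2D gradient `g` (radians per
#' mm, in flattened coordinates) by least squares over its significant
#' ring-1 neighbors, using pairwise circular phase differences — never a
#' global unwrap. Vertices with fewer than 2 non-collinear significant
#' neighbors are marked invalid.
#'
#' With the default `orientation = "delay"` the fit is done on the delay
#' phase `(-theta) mod 2 pi`, so arrows point toward later-activating cortex,
#' i.e. along the direction of wave travel; `"phase"` returns the raw
#' theta-gradient (its negation).
#'
#' @param map A thresholded [activation_map()] on `mesh`.
#' @param mesh A [surface_mesh()] with flat coordinates.
#' @param orientation `"delay"` (along wave travel, default) or `"phase"`.
#' @return A tibble of class `phase_gradient_field`: `unit_id`, `gx`, `gy`
#'   (radians/mm), `residual` (RMS of the local fit), `n_neighbors`, `valid`.
#' @export
phase_gradient_field <- function(map, mesh, orientation = c("delay", "phase")) {
  orientation <- match.arg(orientation)
  if (is.null(mesh$vertex_flat)) {
    abort("phase_gradient_field: mesh has no flattened coordinates.")
  }
  theta <- map_phase(map)
  if (orientation == "delay") theta <- (-theta) %% (2 * pi)
  n_v <- mesh_n_vertices(mesh)
  sig <- logical(n_v)
  sig[map$unit_id + 1L] <- TRUE
  phase_of <- rep(NA_real_, n_v)
  phase_of[map$unit_id + 1L] <- theta
  flat <- mesh$vertex_flat

  fit_one <- function(v) { # v is 0-based
    nb <- mesh$neighbors[[v + 1L]]
    nb <- nb[sig[nb + 1L]]
    n_nb <- length(nb)
    if (n_nb < 2L) {
      return(c(NA_real_, NA_real_, NA_real_, n_nb, 0))
    }
    d <- flat[nb + 1L, , drop = FALSE] -
      matrix(flat[v + 1L, ], n_nb, 2, byrow = TRUE)
    if (qr(d)$rank < 2L) {
      return(c(NA_real_, NA_real_, NA_real_, n_nb, 0))
    }
    dphi <- circular_difference(phase_of[nb + 1L], phase_of[v + 1L])
    fit <- stats::lm.fit(d, dphi)
    c(fit$coefficients, sqrt(mean(fit$residuals^2)), n_nb, 1)
  }

  res <- vapply(map$unit_id, fit_one, numeric(5))
  out <- tibble::tibble(
    unit_id = map$unit_id,
    gx = res[1, ],
    gy = res[2, ],
    residual = res[3, ],
    n_neighbors = as.integer(res[4, ]),
    valid = res[5, ] == 1
  )
  structure(out,
    mesh_id = mesh$mesh_id,
    orientation = orientation,
    class = c("phase_gradient_field", class(tibble::tibble()))
  )
}

#' Assign significant vertices to isophase bands
#'
#' Partitions the circle by `band_edges` and labels every unit of the map
#' with the half-open band `[edge_k, edge_(k+1))` containing its phase; the
#' last band wraps from the final edge back to the first.
#'
#' @param map A (typically thresholded) [activation_map()].
#' @param band_edges Strictly increasing edges in `[0, 2 pi)`; `k` edges
#'   define `k` bands covering the circle.
#' @return Tibble `unit_id`, `theta`, `band` (0-based band index).
#' @export
isophase_bands <- function(map, band_edges) {
  band_edges <- as.numeric(band_edges)
  if (is.unsorted(band_edges, strictly = TRUE) ||
      any(band_edges < 0) || any(band_edges >= 2 * pi)) {
    abort("isophase_bands: edges must be strictly increasing within [0, 2*pi).")
  }
  theta <- map_phase(map)
  ## Rotate so the first edge is 0, then cut.
  shifted <- (theta - band_edges[1]) %% (2 * pi)
  edges0 <- c((band_edges - band_edges[1]) %% (2 * pi), 2 * pi)
  band <- findInterval(shifted, edges0, rightmost.closed = FALSE,
                       left.open = FALSE) - 1L
  tibble::tibble(unit_id = map$unit_id, theta = theta, band = band)
}

#' Movie-frame vertex masks for traveling-wave animation
#'
#' Frame `k` (k = 0 .. n_frames - 1, window center `k * step`) contains the
#' units whose phase lies within the half-open moving window
#' `[center - w/2, center + w/2)`. Under the default 9-degree window and
#' 4.5-degree step, each significant unit appears in exactly 2 of the 80
#' frames (0.2 s/frame for a 16-s cycle).
#'
#' @param map A thresholded [activation_map()].
#' @param spec A [window_spec()].
#' @return Tibble `frame_id` (0-based), `unit_id`, `theta`; every frame
#'   present even if empty (`n_frames` attribute records the total).
#' @export
movie_frames <- function(map, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  theta <- map_phase(map)
  half <- spec$window_rad / 2
  frames <- purrr::map_dfr(0:(spec$n_frames - 1L), function(k) {
    centre <- k * spec$step_rad
    d <- circular_difference(theta, centre)
    sel <- d >= -half & d < half
    tibble::tibble(frame_id = k, unit_id = map$unit_id[sel], theta = theta[sel])
  })
  attr(frames, "n_frames") <- spec$n_frames
  attr(frames, "spec") <- spec
  frames
}

#' Dominant direction of local traveling waves in an ROI
#'
#' Magnitude-weighted circular mean of the gradient directions over the
#' valid field vertices of an ROI, with the resultant length (0..1) as a
#' coherence score: 1 when all vectors agree, 0 when directions cancel.
#'
#' @param field A [phase_gradient_field()].
#' @param roi Optional 0-based vertex ids restricting the field; defaults to
#'   all field vertices.
#' @return One-row tibble: `dx`, `dy` (unit vector), `coherence`, `n_valid`.
#' @export
dominant_path_direction <- function(field, roi = NULL) {
  f <- field
  if (!is.null(roi)) f <- f[f$unit_id %in% roi, , drop = FALSE]
  f <- f[f$valid & is.finite(f$gx) & is.finite(f$gy), , drop = FALSE]
  if (nrow(f) == 0L) abort("dominant_path_direction: no valid field vertices in ROI.")
  mag <- sqrt(f$gx^2 + f$gy^2)
  keep <- mag > 0
  sx <- sum(f$gx[keep]) # magnitude-weighted sum of unit vectors = vector sum
  sy <- sum(f$gy[keep])
  r <- sqrt(sx^2 + sy^2)
  coherence <- if (sum(mag[keep]) > 0) r / sum(mag[keep]) else 0
  dir <- if (r > 0) c(sx, sy) / r else c(NA_real_, NA_real_)
  tibble::tibble(dx = dir[1], dy = dir[2],
                 coherence = coherence, n_valid = nrow(f))
}
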