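#' Surface ROI
#'
#' A named set of 0-based mesh vertex indices.
#'
#' @param vertices Integer 0-based vertex ids (non-empty, unique).
#' @param name ROI name.
#' @param mesh_id Optional mesh identifier the indices refer to.
#' @return A `surface_roi` list.
#' @export
surface_roi <- function(vertices, name = "roi", mesh_id = NULL) {
  vertices <- sort(unique(as.integer(vertices)))
  if (length(vertices) == 0L) abort("surface_roi: vertex set must be non-empty.")
  if (any(vertices < 0L)) abort("surface_roi: vertex indices are 0-based and non-negative.")
  structure(list(name = name, mesh_id = mesh_id, vertices = vertices),
            class = "surface_roi")
}

#' @export
print.surface_roi <- function(x, ...) {
  cat(sprintf("<surface_roi> '%s': %d vertices\n", x$name, length(x$vertices)))
  invisible(x)
}

#' Hemodynamic surge profile of a surface ROI
#'
#' Slides a circular window (default 9 degrees wide in 4.5-degree steps, 80
#' bins = 0.2 s/bin over a 16-s cycle) over the response phases of the ROI's
#' vertices. In each bin the complex F-values of the `V` member vertices are
#' averaged, the magnitude of the average is converted to a p-value through
#' the F distribution (magnitude squared, since complex F-values live on the
#' `sqrt(F)` scale), and the surge height is `-log10(p)`. Empty bins get
#' p = 1 (height 0).
#'
#' Bins are laid out in delay order: bin `d` is centered at delay
#' `d * step / 360 * period` seconds, and membership is evaluated on the
#' delay phase so the profile reads left-to-right in trial time.
#'
#' @param map An [activation_map()] on the ROI's mesh (typically a group
#'   average).
#' @param roi A [surface_roi()] (or bare integer vertex ids).
#' @param spec A [window_spec()].
#' @param period_seconds Trial period (default 16).
#' @param f_threshold Optional critical F applied to the vertices before
#'   gathering (`NULL` uses every ROI vertex present in the map). The
#'   significance threshold used for display maps is applied here by default.
#' @param partition Frequency partition for the p-value scale; defaults to
#'   the map's own.
#' @return A tibble of class `surge_profile` with 80 rows (under defaults):
#'   `bin`, `bin_center_rad` (delay phase), `bin_center_s`, `V`, `re`, `im`,
#'   `magnitude`, `p_value`, `height`.
#' @export
surge_profile <- function(map, roi, spec = window_spec(), period_seconds = 16,
                          f_threshold = f_thresholds()[["p01"]],
                          partition = NULL) {
  if (!inherits(roi, "surface_roi")) roi <- surface_roi(roi)
  partition <- partition %||% attr(map, "partition") %||%
    build_frequency_partition(256, 16)
  if (!is.null(roi$mesh_id) && !is.null(attr(map, "mesh_id")) &&
      !identical(roi$mesh_id, attr(map, "mesh_id"))) {
    abort("surge_profile: ROI and map reference different meshes.")
  }

  m <- map[map$unit_id %in% roi$vertices, , drop = FALSE]
  if (!is.null(f_threshold)) {
    m <- m[(m$re^2 + m$im^2) > f_threshold, , drop = FALSE]
  }
  ## Delay phase: increases with activation delay within the cycle.
  phi <- (-atan2(m$im, m$re)) %% (2 * pi)
  half <- spec$window_rad / 2

  rows <- purrr::map_dfr(0:(spec$n_frames - 1L), function(d) {
    centre <- d * spec$step_rad
    sel <- {
      dd <- circular_difference(phi, centre)
      dd >= -half & dd < half
    }
    v <- sum(sel)
    if (v == 0L) {
      tibble::tibble(bin = d, V = 0L, re = 0, im = 0)
    } else {
      tibble::tibble(bin = d, V = v, re = mean(m$re[sel]), im = mean(m$im[sel]))
    }
  })
  mag <- sqrt(rows$re^2 + rows$im^2)
  p <- ifelse(rows$V == 0L, 1, magnitude_to_p(mag, partition))
  out <- tibble::tibble(
    bin = rows$bin,
    bin_center_rad = rows$bin * spec$step_rad,
    bin_center_s = rows$bin * spec$step_rad / (2 * pi) * period_seconds,
    V = rows$V,
    re = rows$re, im = rows$im,
    magnitude = mag,
    p_value = p,
    height = -log10(p)
  )
  structure(out,
    roi_name = roi$name,
    spec = spec,
    period_seconds = period_seconds,
    f_threshold = f_threshold,
    partition = partition,
    class = c("surge_profile", class(tibble::tibble()))
  )
}

#' Arrival, ending, latency and peak of a surge profile
#'
#' Finds the longest contiguous circular run of bins whose height meets the
#' threshold. Arrival and ending are the first and last bin centers of that
#' run (in delay seconds); latency is the delay of the maximum height (ties
#' break to the earlier delay); duration is the run length times the bin
#' step. A profile with no bin at or above threshold yields an all-`NA`
#' result rather than an error.
#'
#' @param profile A [surge_profile()].
#' @param height_threshold Positive height (`-log10(p)`) cutoff, e.g. 2 for
#'   p < .01.
#' @return One-row tibble: `arrival_s`, `ending_s`, `latency_s`,
#'   `peak_height`, `duration_s`, `n_bins`.
#' @export
surge_metrics <- function(profile, height_threshold = 2) {
  stopifnot(height_threshold > 0)
  h <- profile$height
  n <- length(h)
  above <- h >= height_threshold
  if (!any(above)) {
    return(tibble::tibble(
      arrival_s = NA_real_, ending_s = NA_real_, latency_s = NA_real_,
      peak_height = NA_real_, duration_s = NA_real_, n_bins = 0L
    ))
  }
  run <- longest_circular_run(above)
  bins <- (run$start + seq_len(run$length) - 1L - 1L) %% n + 1L # 1-based indices
  step_s <- profile$bin_center_s[2] - profile$bin_center_s[1]
  peak_idx <- bins[which.max(h[bins])]
  ## Ties in peak height break to the earlier delay within the run.
  peak_h <- max(h[bins])
  tied <- bins[h[bins] == peak_h]
  peak_idx <- tied[which.min(profile$bin_center_s[tied])]
  tibble::tibble(
    arrival_s = profile$bin_center_s[bins[1]],
    ending_s = profile$bin_center_s[bins[run$length]],
    latency_s = profile$bin_center_s[peak_idx],
    peak_height = peak_h,
    duration_s = run$length * step_s,
    n_bins = run$length
  )
}

## Longest TRUE run on a circular logical vector; returns 1-based start and
## length. Ties break to the earliest start.
longest_circular_run <- function(x) {
  n <- length(x)
  if (all(x)) return(list(start = 1L, length = n))
  ## Rotate so position 1 is FALSE, find linear runs, map back.
  first_false <- which(!x)[1]
  rot <- c(x[first_false:n], x[seq_len(first_false - 1L)])
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  start_rot <- starts[best]
  list(
    start = (start_rot + first_false - 2L) %% n + 1L,
    length = r$lengths[best]
  )
}
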