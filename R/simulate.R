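#' Phase-encoded task paradigm
#'
#' The canonical rapid phase-encoded designs: 16 trials of 16 s at TR = 1 s
#' (256 samples per scan). Unimodal (read or listen only) and multimodal
#' (read aloud / shadow) tasks present stimuli in Phase 1 (0-5 s) followed by
#' rest (5-16 s); crossmodal tasks add a speech-output Phase 2 (5-10 s)
#' before a 6-s rest.
#'
#' @param task `"unimodal"`, `"multimodal"` or `"crossmodal"`.
#' @param cycle_seconds Trial period (default 16).
#' @param n_cycles Trials per scan (default 16).
#' @param tr_seconds Sampling interval (default 1).
#' @return A `task_paradigm` list with a `segments` tibble
#'   (`label`, `onset_s`, `offset_s`) tiling the cycle.
#' @export
#' @examples
#' make_paradigm("crossmodal")$segments
make_paradigm <- function(task = c("unimodal", "multimodal", "crossmodal"),
                          cycle_seconds = 16, n_cycles = 16, tr_seconds = 1) {
  task <- match.arg(task)
  segments <- if (task == "crossmodal") {
    tibble::tibble(
      label = c("Phase1", "Phase2", "PhaseR"),
      onset_s = c(0, 5, 10),
      offset_s = c(5, 10, cycle_seconds)
    )
  } else {
    tibble::tibble(
      label = c("Phase1", "PhaseR"),
      onset_s = c(0, 5),
      offset_s = c(5, cycle_seconds)
    )
  }
  n_samples <- cycle_seconds * n_cycles / tr_seconds
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    abort("make_paradigm: scan duration must be an integer number of TRs.")
  }
  structure(
    list(
      task = task,
      cycle_seconds = cycle_seconds,
      n_cycles = n_cycles,
      tr_seconds = tr_seconds,
      n_samples = as.integer(round(n_samples)),
      segments = segments
    ),
    class = "task_paradigm"
  )
}

#' @export
print.task_paradigm <- function(x, ...) {
  cat(sprintf("<task_paradigm> %s: %d cycles of %g s at TR %g s (%d samples)\n",
              x$task, x$n_cycles, x$cycle_seconds, x$tr_seconds, x$n_samples))
  print(x$segments)
  invisible(x)
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' Difference of two gamma densities with a unit peak near 5 s, the widely
#' used shape for the BOLD impulse response. The slow hemodynamics are what
#' turn an instantaneous neural event into the ~5-6 s delayed BOLD response
#' seen in phase-encoded maps.
#'
#' @param t_seconds Non-negative time grid (e.g. `0:31` at TR resolution).
#' @param peak_shape,peak_rate Gamma shape/rate of the main response
#'   (defaults 6 and 1; mode at 5 s).
#' @param undershoot_shape,undershoot_rate Gamma shape/rate of the
#'   undershoot (defaults 16 and 1).
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @return Kernel values on `t_seconds`, scaled to unit peak.
#' @export
canonical_hrf <- function(t_seconds, peak_shape = 6, peak_rate = 1,
                          undershoot_shape = 16, undershoot_rate = 1,
                          undershoot_ratio = 1 / 6) {
  if (any(t_seconds < 0)) abort("canonical_hrf: time grid must be non-negative.")
  if (peak_shape <= 0 || peak_rate <= 0 || undershoot_shape <= 0 || undershoot_rate <= 0) {
    abort("canonical_hrf: shape and rate parameters must be positive.")
  }
  h <- stats::dgamma(t_seconds, shape = peak_shape, rate = peak_rate) -
    undershoot_ratio * stats::dgamma(t_seconds, shape = undershoot_shape, rate = undershoot_rate)
  h / max(h)
}

## Periodic boxcar for one segment, shifted by extra_delay, sampled on the
## full-scan TR grid. Sample t covers [t*TR, (t+1)*TR) and takes the fraction
## of that interval inside the (wrapped) active window; at integer onsets and
## TR = 1 this is the exact 0/1 boxcar.
segment_boxcar <- function(paradigm, segment_label, extra_delay_s = 0) {
  seg <- paradigm$segments[paradigm$segments$label == segment_label, ]
  if (nrow(seg) != 1L) {
    abort(sprintf("segment '%s' not found in paradigm.", segment_label))
  }
  if (extra_delay_s < 0 || extra_delay_s >= paradigm$cycle_seconds) {
    abort("extra_delay_s must lie in [0, cycle_seconds).")
  }
  cyc <- paradigm$cycle_seconds
  on <- (seg$onset_s + extra_delay_s) %% cyc
  dur <- seg$offset_s - seg$onset_s
  t0 <- (seq_len(paradigm$n_samples) - 1L) * paradigm$tr_seconds
  tr <- paradigm$tr_seconds
  pos <- (t0 - on) %% cyc # time since (wrapped) onset at sample start
  ## Overlap of the sample interval [pos, pos + TR) with the active window
  ## [0, dur), plus the portion that wraps past the end of the cycle.
  frac <- pmin(pmax(dur - pos, 0), tr) +
    pmax(0, pmin(pos + tr - cyc, dur))
  pmin(frac, tr) / tr
}

## Circular convolution via FFT; kernel zero-padded to series length.
circular_convolve <- function(x, kernel) {
  n <- length(x)
  k <- c(kernel, rep(0, n - length(kernel)))[seq_len(n)]
  Re(fft(fft(x) * fft(k), inverse = TRUE)) / n
}

#' Simulate one unit's periodic BOLD time series
#'
#' A boxcar over the chosen paradigm segment (optionally shifted by an extra
#' onset delay) is circularly convolved with the hemodynamic kernel — the
#' steady-state periodic design makes circular convolution the natural
#' choice, and it keeps DFT phases exact — then scaled, offset by a baseline,
#' and corrupted with white Gaussian noise and an optional polynomial drift.
#'
#' @param paradigm A [make_paradigm()] object.
#' @param segment_label Responding segment (e.g. `"Phase1"`).
#' @param extra_delay_s Additional onset delay within the cycle, seconds.
#' @param amplitude Response amplitude (a.u.; 0 gives a pure-noise unit).
#' @param noise_sd White-noise standard deviation.
#' @param drift Polynomial drift coefficients (linear, quadratic, ...) on
#'   normalized time in \[0, 1\]; default none.
#' @param baseline Constant signal level (default 100, so percent signal
#'   change is meaningful).
#' @param hrf Kernel values on the TR grid; defaults to [canonical_hrf()] on
#'   `0:31` s.
#' @param seed Optional integer seed (local; the global RNG stream is left
#'   untouched).
#' @return Numeric vector of length `paradigm$n_samples`.
#' @export
simulate_unit_timeseries <- function(paradigm, segment_label = "Phase1",
                                     extra_delay_s = 0, amplitude = 5,
                                     noise_sd = 1, drift = NULL,
                                     baseline = 100, hrf = NULL, seed = NULL) {
  if (noise_sd < 0) abort("noise_sd must be non-negative.")
  if (is.null(hrf)) {
    hrf <- canonical_hrf(seq(0, 31, by = paradigm$tr_seconds))
  }
  box <- segment_boxcar(paradigm, segment_label, extra_delay_s)
  response <- amplitude * circular_convolve(box, hrf)
  n <- paradigm$n_samples
  x <- baseline + response
  if (!is.null(drift) && length(drift)) {
    tn <- (seq_len(n) - 1) / (n - 1)
    for (k in seq_along(drift)) x <- x + drift[k] * tn^k
  }
  noise_fun <- function() if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  eps <- if (is.null(seed)) noise_fun() else with_local_seed(seed, noise_fun())
  x + eps
}

## Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a multi-unit phase-encoded scan
#'
#' Vectorized wrapper around [simulate_unit_timeseries()]: one row per entry
#' of `truth`, sharing a paradigm and a single seed.
#'
#' @param truth A tibble with one row per unit; recognized columns:
#'   `segment_label`, `extra_delay_s`, `amplitude`, `noise_sd` (others are
#'   carried through untouched). Missing columns fall back to the
#'   [simulate_unit_timeseries()] defaults.
#' @param paradigm A [make_paradigm()] object.
#' @param unit_space,unit_ids Passed to [scan_ts()].
#' @param baseline,drift,hrf Shared simulation settings.
#' @param seed Integer seed for the whole scan (reproducible; local).
#' @return A [scan_ts()] with `truth` attached as the `truth` attribute.
#' @export
simulate_scan <- function(truth, paradigm = make_paradigm("crossmodal"),
                          unit_space = "volume", unit_ids = NULL,
                          baseline = 100, drift = NULL, hrf = NULL,
                          seed = NULL) {
  truth <- tibble::as_tibble(truth)
  n_u <- nrow(truth)
  seg <- rep_len(truth[["segment_label"]] %||% "Phase1", n_u)
  del <- rep_len(truth[["extra_delay_s"]] %||% 0, n_u)
  amp <- rep_len(truth[["amplitude"]] %||% 5, n_u)
  nsd <- rep_len(truth[["noise_sd"]] %||% 1, n_u)
  if (is.null(hrf)) hrf <- canonical_hrf(seq(0, 31, by = paradigm$tr_seconds))

  build <- function() {
    t(vapply(seq_len(n_u), function(i) {
      simulate_unit_timeseries(paradigm, seg[i], del[i], amp[i], nsd[i],
                               drift = drift, baseline = baseline, hrf = hrf)
    }, numeric(paradigm$n_samples)))
  }
  data <- if (is.null(seed)) build() else with_local_seed(seed, build())
  ts <- scan_ts(data,
    tr_seconds = paradigm$tr_seconds,
    task_frequency = paradigm$n_cycles,
    unit_space = unit_space, unit_ids = unit_ids
  )
  attr(ts, "truth") <- truth
  ts
}

#' Plant a traveling-wave delay map on a mesh
#'
#' Assigns each vertex an activation delay growing linearly with distance
#' (in flattened coordinates) from a seed vertex — a radial wave expanding at
#' `speed_mm_per_s` — or, if `direction` is given, with signed distance along
#' that direction (a planar wave front). Delays wrap into the cycle. The
#' result drives [simulate_scan()] vertex-by-vertex.
#'
#' @param mesh A [surface_mesh()] with flat coordinates.
#' @param seed_vertex 0-based origin vertex.
#' @param speed_mm_per_s Wave propagation speed (> 0; `Inf` gives uniform
#'   delays).
#' @param base_delay_s Delay at the seed vertex.
#' @param region Optional 0-based vertex ids to include (default: all).
#' @param direction Optional length-2 vector; when supplied the wave is
#'   planar, traveling along `direction` in flat coordinates.
#' @param cycle_seconds Cycle length used for wrapping (default 16).
#' @return A tibble (`unit_id`, `distance_mm`, `extra_delay_s`) of class
#'   `wave_truth`.
#' @export
plant_wave_truth <- function(mesh, seed_vertex = 0L, speed_mm_per_s = 10,
                             base_delay_s = 0, region = NULL, direction = NULL,
                             cycle_seconds = 16) {
  if (is.null(mesh$vertex_flat)) abort("plant_wave_truth: mesh needs flat coordinates.")
  if (speed_mm_per_s <= 0) abort("plant_wave_truth: speed must be positive.")
  ids <- region %||% (0:(mesh_n_vertices(mesh) - 1L))
  ids <- sort(unique(as.integer(ids)))
  if (!(seed_vertex %in% ids) && is.null(direction)) {
    abort("plant_wave_truth: seed vertex lies outside the region.")
  }
  flat <- mesh$vertex_flat[ids + 1L, , drop = FALSE]
  origin <- mesh$vertex_flat[seed_vertex + 1L, ]
  dist <- if (is.null(direction)) {
    sqrt((flat[, 1] - origin[1])^2 + (flat[, 2] - origin[2])^2)
  } else {
    u <- direction / sqrt(sum(direction^2))
    (flat[, 1] - origin[1]) * u[1] + (flat[, 2] - origin[2]) * u[2]
  }
  delay <- (base_delay_s + dist / speed_mm_per_s) %% cycle_seconds
  out <- tibble::tibble(
    unit_id = ids,
    distance_mm = dist,
    extra_delay_s = delay
  )
  structure(out,
    speed_mm_per_s = speed_mm_per_s,
    seed_vertex = seed_vertex,
    direction = if (is.null(direction)) NULL else direction / sqrt(sum(direction^2)),
    cycle_seconds = cycle_seconds,
    class = c("wave_truth", class(tibble::tibble()))
  )
}
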