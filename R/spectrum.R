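#' One-sided discrete Fourier spectrum of a scan
#'
#' Applies the DFT `X(w) = sum_t x(t) exp(-i 2 pi w t / N)` (t = 0..N-1) to
#' each unit's time series and keeps bins 0 .. N/2 (cycles per scan).
#'
#' @param ts A [scan_ts()] object.
#' @return Complex matrix, units in rows and frequency bins `0:(N/2)` in
#'   columns (class `dft_spectrum`), carrying the scan metadata as
#'   attributes.
#' @export
dft_spectrum <- function(ts) {
  if (!inherits(ts, "scan_ts")) ts <- scan_ts(ts)
  n_t <- ncol(ts)
  nyq <- n_t %/% 2L
  ## stats::mvfft transforms columns; rows hold units, so transpose.
  sp <- t(stats::mvfft(t(unclass(ts))))[, seq_len(nyq + 1L), drop = FALSE]
  colnames(sp) <- as.character(0:nyq)
  structure(
    sp,
    tr_seconds = attr(ts, "tr_seconds"),
    task_frequency = attr(ts, "task_frequency"),
    unit_space = attr(ts, "unit_space"),
    unit_ids = attr(ts, "unit_ids"),
    n_timepoints = n_t,
    class = c("dft_spectrum", "matrix", "array")
  )
}

spectrum_bin <- function(spectrum, bin) {
  unname(spectrum[, as.character(as.integer(bin)), drop = TRUE])
}

#' Per-unit F-statistics, phases and complex F-values
#'
#' Evaluates the signal-to-noise F-ratio of periodic activation at the task
#' frequency: `F = (|X(w_s)|^2 / df_s) / (sum_n |X(w_n)|^2 / df_n)`. The
#' phase `theta` is the task-bin phase angle mapped to \[0, 2*pi); the complex
#' F-value is `sqrt(F) * (cos(theta), sin(theta))`, which preserves phase
#' under vector averaging.
#'
#' Units with exactly zero noise power (degenerate noiseless input) get an
#' infinite F with p = 0 and a warning, so exact synthetic cases remain
#' usable.
#'
#' @param spectrum A [dft_spectrum()] matrix (or a [scan_ts()], transformed
#'   on the fly).
#' @param partition A [build_frequency_partition()] for the same number of
#'   timepoints; built with defaults when omitted.
#' @return A tibble of class `spectral_result` with one row per unit:
#'   `unit_id`, `amplitude` (|X| at the task bin), `theta`, `noise_power`,
#'   `f_stat`, `p_value`, `re`, `im`. The partition and unit space travel as
#'   attributes.
#' @export
#' @examples
#' t <- 0:255
#' x <- rbind(cos(2 * pi * 16 * t / 256), rnorm(256))
#' f_statistic(dft_spectrum(scan_ts(x)))
f_statistic <- function(spectrum, partition = NULL) {
  if (inherits(spectrum, "scan_ts")) spectrum <- dft_spectrum(spectrum)
  if (!inherits(spectrum, "dft_spectrum")) {
    abort("f_statistic: `spectrum` must be a dft_spectrum or scan_ts.")
  }
  n_t <- attr(spectrum, "n_timepoints")
  if (is.null(partition)) {
    partition <- build_frequency_partition(n_t, attr(spectrum, "task_frequency"))
  }
  if (partition$n_timepoints != n_t) {
    abort("f_statistic: partition was built for a different number of timepoints.")
  }

  x_task <- spectrum_bin(spectrum, partition$task_frequency)
  amplitude <- Mod(x_task)
  theta <- Arg(x_task) %% (2 * pi)
  noise_cols <- as.character(partition$noise_frequencies)
  noise_power <- unname(rowSums(Mod(spectrum[, noise_cols, drop = FALSE])^2))

  f <- (amplitude^2 / partition$df_signal) / (noise_power / partition$df_noise)
  ## Degenerate noiseless units: exactly zero noise power, or noise power at
  ## the rounding floor of the task-bin energy.
  degenerate <- noise_power <= amplitude^2 * 1e-20
  if (any(degenerate)) {
    f[degenerate] <- Inf
    warn(sprintf(
      "%d unit(s) have zero noise power; F set to Inf (p = 0).", sum(degenerate)
    ))
  }
  p <- f_to_p(f, partition$df_signal, partition$df_noise)
  fm <- sqrt(ifelse(is.finite(f), f, 0))
  fm[degenerate] <- Inf

  out <- tibble::tibble(
    unit_id = attr(spectrum, "unit_ids"),
    amplitude = amplitude,
    theta = theta,
    noise_power = noise_power,
    f_stat = f,
    p_value = p,
    re = ifelse(is.finite(fm), fm * cos(theta), Inf * cos(theta)),
    im = ifelse(is.finite(fm), fm * sin(theta), Inf * sin(theta))
  )
  new_spectral_result(out, partition, attr(spectrum, "unit_space"))
}

new_spectral_result <- function(df, partition, unit_space) {
  structure(
    df,
    partition = partition,
    unit_space = unit_space,
    class = c("spectral_result", class(tibble::tibble()))
  )
}

#' Promote a spectral result (or bare table) to an activation map
#'
#' An activation map is a tibble of per-unit complex F-values (`unit_id`,
#' `re`, `im`, `valid_n`) tagged with the space it lives in, its provenance
#' (single scan, scan average, or group average) and the frequency partition
#' that defines its significance scale.
#'
#' @param x A `spectral_result` or any data frame with `unit_id`, `re`, `im`.
#' @param space Space tag: `"volume"`, `"native_surface"` or `"common_mesh"`.
#' @param mesh_id Optional mesh identifier (content hash) for surface spaces.
#' @param provenance One of `"single_scan"`, `"scan_average"`,
#'   `"group_average"`.
#' @param partition The [build_frequency_partition()] defining df values.
#' @return A tibble of class `activation_map`.
#' @export
activation_map <- function(x, space = c("volume", "native_surface", "common_mesh"),
                           mesh_id = NULL,
                           provenance = c("single_scan", "scan_average", "group_average"),
                           partition = NULL) {
  space <- match.arg(space)
  provenance <- match.arg(provenance)
  if (inherits(x, "spectral_result")) {
    partition <- partition %||% attr(x, "partition")
    if (attr(x, "unit_space") == "surface" && space == "volume") space <- "native_surface"
  }
  df <- tibble::as_tibble(x)[, intersect(c("unit_id", "re", "im", "valid_n"), names(x))]
  stopifnot(all(c("unit_id", "re", "im") %in% names(df)))
  if (!"valid_n" %in% names(df)) df$valid_n <- 1L
  df$unit_id <- as.integer(df$unit_id)
  structure(
    df,
    space = space,
    mesh_id = mesh_id,
    provenance = provenance,
    partition = partition,
    class = c("activation_map", class(tibble::tibble()))
  )
}

map_magnitude <- function(map) sqrt(map$re^2 + map$im^2)

map_phase <- function(map) atan2(map$im, map$re) %% (2 * pi)

#' Threshold an activation map at a critical F value
#'
#' Retains units whose squared complex-F magnitude (i.e. their F value)
#' exceeds the threshold; sub-threshold units are dropped from the table
#' (marked absent). The retained count is recorded in the `n_retained`
#' attribute and reported.
#'
#' @param map An [activation_map()].
#' @param f_threshold Positive critical F, e.g. one of [f_thresholds()].
#' @param quiet Suppress the retained-count message.
#' @return The thresholded map with attributes `n_input`, `n_retained` and
#'   `f_threshold`.
#' @export
threshold_map <- function(map, f_threshold = f_thresholds()[["p01"]], quiet = FALSE) {
  stopifnot(f_threshold > 0)
  keep <- map_magnitude(map)^2 > f_threshold
  out <- map[keep, , drop = FALSE]
  attr(out, "space") <- attr(map, "space")
  attr(out, "mesh_id") <- attr(map, "mesh_id")
  attr(out, "provenance") <- attr(map, "provenance")
  attr(out, "partition") <- attr(map, "partition")
  attr(out, "n_input") <- nrow(map)
  attr(out, "n_retained") <- sum(keep)
  attr(out, "f_threshold") <- f_threshold
  class(out) <- class(map)
  if (!quiet) {
    inform(sprintf("threshold_map: retained %d / %d units at F > %.3g.",
                   sum(keep), nrow(map), f_threshold))
  }
  out
}

#' Convert a phase angle to an activation delay within the cycle
#'
#' Under the DFT kernel `exp(-i w t)`, a response delayed by `d` seconds has
#' its task-bin phase rotated by `-2 pi d / period`, so delay increases as
#' theta decreases: `delay = ((-theta) mod 2 pi) / (2 pi) * period`. Absolute
#' delays include the hemodynamic lag; differences between units are
#' interpretable as relative activation timing.
#'
#' @param theta Phase angles in radians (vectorized).
#' @param period_seconds Trial period (16 s for the canonical design).
#' @return Delays in `[0, period)` seconds.
#' @export
#' @examples
#' phase_to_delay(-pi / 2, 16) # quarter cycle = 4 s
phase_to_delay <- function(theta, period_seconds = 16) {
  stopifnot(period_seconds > 0)
  ((-theta) %% (2 * pi)) / (2 * pi) * period_seconds
}

#' @rdname phase_to_delay
#' @param delay_seconds Delays in seconds.
#' @export
delay_to_phase <- function(delay_seconds, period_seconds = 16) {
  stopifnot(period_seconds > 0)
  (-(delay_seconds / period_seconds) * 2 * pi) %% (2 * pi)
}

#' Cycle-averaged time course per unit
#'
#' Folds the scan into its trial cycles, averages across cycles, and (by
#' default) expresses the result as percent signal change about each unit's
#' temporal mean.
#'
#' @param ts A [scan_ts()] whose cycle length in samples is integral.
#' @param percent Convert to percent signal change (`100 * (x - m) / m` with
#'   `m` the unit's temporal mean). Units with a near-zero mean fall back to
#'   the demeaned raw signal with a warning.
#' @return A long tibble: `unit_id`, `time_s` (offset within the cycle),
#'   `signal`; `n_cycles` and `percent` recorded as attributes.
#' @export
cycle_average <- function(ts, percent = TRUE) {
  spc <- cycle_samples(ts)
  n_cyc <- ncol(ts) / spc
  x <- unclass(ts)
  ## Fold: column t belongs to cycle t %/% spc, offset t %% spc (0-based).
  avg <- vapply(seq_len(spc), function(j) {
    rowMeans(x[, j + spc * (seq_len(n_cyc) - 1L), drop = FALSE])
  }, numeric(nrow(x)))
  avg <- matrix(avg, nrow = nrow(x))
  if (percent) {
    m <- rowMeans(x)
    tiny <- abs(m) < 1e-8
    if (any(tiny)) {
      warn(sprintf(
        "%d unit(s) have near-zero mean; returning demeaned raw signal for them.",
        sum(tiny)
      ))
    }
    pct <- avg
    if (any(!tiny)) {
      pct[!tiny, ] <- 100 * (avg[!tiny, , drop = FALSE] - m[!tiny]) / m[!tiny]
    }
    if (any(tiny)) {
      sub <- avg[tiny, , drop = FALSE]
      pct[tiny, ] <- sub - rowMeans(sub)
    }
    avg <- pct
  }
  out <- tibble::tibble(
    unit_id = rep(attr(ts, "unit_ids"), times = spc),
    time_s = rep((seq_len(spc) - 1L) * attr(ts, "tr_seconds"), each = nrow(x)),
    signal = as.vector(avg)
  )
  out <- dplyr::arrange(out, .data$unit_id, .data$time_s)
  attr(out, "n_cycles") <- n_cyc
  attr(out, "percent") <- percent
  out
}
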