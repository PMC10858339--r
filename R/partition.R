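#' Partition Fourier bins into task (signal) and noise frequencies
#'
#' Splits the one-sided spectrum of an `n_timepoints`-sample scan into the
#' task bin and the set of noise bins used for the periodic-activation
#' F-statistic. By default the noise set is built from bins
#' `1 .. n_timepoints/2 - 1` minus low-frequency drift bins, the task bin and
#' its immediate neighbors, and the task harmonics up to the Nyquist. DC and
#' the Nyquist bin are never counted. For the canonical 256-sample scan with a
#' 16-cycle task this retains 115 noise bins, giving noise degrees of freedom
#' `df_noise = 230` (and `df_signal = 2`).
#'
#' @param n_timepoints Number of samples in the scan (even integer).
#' @param task_frequency Task bin index in cycles per scan; must satisfy
#'   `0 < task_frequency < n_timepoints / 2`.
#' @param drift_bins Integer bins excluded as slow scanner/physiological
#'   drift. Default `1:3`. Use `integer(0)` to keep them.
#' @param exclude_task_neighbors Drop the bins adjacent to the task bin
#'   (leakage guard). Default `TRUE`.
#' @param exclude_harmonics Drop integer multiples of the task frequency below
#'   the Nyquist bin (task waveform is periodic but not sinusoidal, so energy
#'   leaks into harmonics). Default `TRUE`.
#' @param extra_exclude Additional bin indices to drop, if any.
#'
#' @return A `freq_partition` list: `n_timepoints`, `task_frequency`,
#'   `noise_frequencies` (sorted integer bins), `df_signal` (always 2),
#'   `df_noise` (`2 * length(noise_frequencies)`), and `excluded`, a tibble of
#'   (bin, reason) pairs documenting every exclusion.
#' @export
#' @examples
#' part <- build_frequency_partition(256, 16)
#' part$df_noise # 230
build_frequency_partition <- function(n_timepoints, task_frequency,
                                      drift_bins = 1:3,
                                      exclude_task_neighbors = TRUE,
                                      exclude_harmonics = TRUE,
                                      extra_exclude = integer()) {
  n_timepoints <- as.integer(n_timepoints)
  task_frequency <- as.integer(task_frequency)
  nyquist <- n_timepoints %/% 2L
  if (task_frequency <= 0L || task_frequency >= nyquist) {
    abort(sprintf(
      "task frequency %d out of range (must lie strictly between 0 and %d).",
      task_frequency, nyquist
    ))
  }

  excl <- tibble::tibble(bin = 0L, reason = "dc")
  excl <- dplyr::bind_rows(excl, tibble::tibble(bin = nyquist, reason = "nyquist"))
  if (length(drift_bins)) {
    excl <- dplyr::bind_rows(excl, tibble::tibble(bin = as.integer(drift_bins), reason = "drift"))
  }
  excl <- dplyr::bind_rows(excl, tibble::tibble(bin = task_frequency, reason = "task"))
  if (exclude_task_neighbors) {
    excl <- dplyr::bind_rows(excl, tibble::tibble(
      bin = c(task_frequency - 1L, task_frequency + 1L),
      reason = "task_neighbor"
    ))
  }
  if (exclude_harmonics && 2L * task_frequency <= nyquist - 1L) {
    h <- seq.int(2L * task_frequency, nyquist - 1L, by = task_frequency)
    if (length(h)) {
      excl <- dplyr::bind_rows(excl, tibble::tibble(bin = h, reason = "harmonic"))
    }
  }
  if (length(extra_exclude)) {
    excl <- dplyr::bind_rows(excl, tibble::tibble(bin = as.integer(extra_exclude), reason = "extra"))
  }
  excl <- dplyr::distinct(dplyr::arrange(excl, .data$bin, .data$reason))

  noise <- setdiff(seq_len(nyquist - 1L), excl$bin)
  if (length(noise) < 2L) {
    abort("exclusions leave fewer than 2 noise frequencies.")
  }

  structure(
    list(
      n_timepoints = n_timepoints,
      task_frequency = task_frequency,
      noise_frequencies = as.integer(sort(noise)),
      df_signal = 2L,
      df_noise = 2L * length(noise),
      excluded = excl
    ),
    class = "freq_partition"
  )
}

#' @export
print.freq_partition <- function(x, ...) {
  cat(sprintf(
    "<freq_partition> n = %d, task bin = %d, %d noise bins (df = %d, %d)\n",
    x$n_timepoints, x$task_frequency, length(x$noise_frequencies),
    x$df_signal, x$df_noise
  ))
  invisible(x)
}

#' Upper-tail p-value of the periodic-activation F-statistic
#'
#' For `df_signal = 2` this is the closed form
#' `(1 + 2 f / df_noise)^(-df_noise / 2)`; the general case uses the F
#' distribution's upper tail.
#'
#' @param f Non-negative F values (vectorized).
#' @param df_signal,df_noise Degrees of freedom (2 and 230 for the canonical
#'   256-sample, 16-cycle design).
#' @return p-values in (0, 1].
#' @export
#' @examples
#' f_to_p(4.7, 2, 230) # just under 0.01
f_to_p <- function(f, df_signal = 2, df_noise = 230) {
  if (any(f < 0, na.rm = TRUE)) abort("f_to_p: F values must be non-negative.")
  if (df_signal < 1 || df_noise < 1) abort("f_to_p: degrees of freedom must be >= 1.")
  p <- pf(f, df_signal, df_noise, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  p
}

#' Critical F value for a given uncorrected p threshold
#'
#' Inverse of [f_to_p()]: the F quantile whose upper-tail probability equals
#' `p`. With `df = (2, 230)` the canonical display thresholds 4.7, 7.1 and 9.6
#' correspond to p = .01, .001 and .0001.
#'
#' @param p Tail probabilities strictly inside (0, 1) (vectorized).
#' @inheritParams f_to_p
#' @return F thresholds.
#' @export
#' @examples
#' round(critical_f(c(0.01, 0.001, 0.0001)), 1) # 4.7, 7.1, 9.6
critical_f <- function(p, df_signal = 2, df_noise = 230) {
  if (any(p <= 0 | p >= 1)) abort("critical_f: p must lie strictly in (0, 1).")
  qf(p, df_signal, df_noise, lower.tail = FALSE)
}

#' Canonical display thresholds
#'
#' The three uncorrected significance thresholds used for displaying periodic
#' activations with df = (2, 230): F > 4.7 (p < .01), F > 7.1 (p < .001),
#' F > 9.6 (p < .0001).
#'
#' @return Named numeric vector `c(p01 = 4.7, p001 = 7.1, p0001 = 9.6)`.
#' @export
f_thresholds <- function() {
  c(p01 = 4.7, p001 = 7.1, p0001 = 9.6)
}

#' p-value from a complex F-value magnitude
#'
#' Complex F-values carry magnitude `sqrt(F)`, so the magnitude is squared
#' before the F tail is evaluated. For a single unthresholded unit this
#' reproduces its original per-unit p-value exactly; applied to the magnitude
#' of a vector average it gives the significance height used in surge
#' profiles.
#'
#' @param mag Non-negative magnitudes on the `sqrt(F)` scale (vectorized).
#' @param partition A [build_frequency_partition()] object supplying the
#'   degrees of freedom.
#' @return p-values in (0, 1].
#' @export
magnitude_to_p <- function(mag, partition) {
  if (any(mag < 0, na.rm = TRUE)) abort("magnitude_to_p: magnitudes must be non-negative.")
  f_to_p(mag^2, partition$df_signal, partition$df_noise)
}
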