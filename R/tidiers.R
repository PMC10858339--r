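#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for spectral results
#'
#' `tidy()` returns the per-unit table as a plain tibble; `glance()`
#' summarizes the scan in one row (unit count, degrees of freedom, counts of
#' units exceeding the canonical thresholds).
#'
#' @param x A `spectral_result` from [f_statistic()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.spectral_result <- function(x, ...) {
  tibble::as_tibble(unclass_keep_df(x))
}

#' @rdname tidy.spectral_result
#' @export
glance.spectral_result <- function(x, ...) {
  part <- attr(x, "partition")
  th <- f_thresholds()
  tibble::tibble(
    n_units = nrow(x),
    df_signal = part$df_signal,
    df_noise = part$df_noise,
    n_p01 = sum(x$f_stat > th[["p01"]]),
    n_p001 = sum(x$f_stat > th[["p001"]]),
    n_p0001 = sum(x$f_stat > th[["p0001"]])
  )
}

#' Tidiers for surge profiles
#'
#' `tidy()` returns the 80-bin table; `glance()` returns the arrival /
#' ending / latency / peak metrics at the given height threshold.
#'
#' @param x A [surge_profile()].
#' @param height_threshold Passed to [surge_metrics()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.surge_profile <- function(x, ...) {
  tibble::as_tibble(unclass_keep_df(x))
}

#' @rdname tidy.surge_profile
#' @export
glance.surge_profile <- function(x, height_threshold = 2, ...) {
  out <- surge_metrics(x, height_threshold)
  out$roi <- attr(x, "roi_name") %||% NA_character_
  out
}

#' Tidiers for phase-gradient fields
#'
#' `tidy()` returns the per-vertex gradient table; `glance()` summarizes the
#' field with its dominant direction and coherence over valid vertices.
#'
#' @param x A [phase_gradient_field()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.phase_gradient_field <- function(x, ...) {
  tibble::as_tibble(unclass_keep_df(x))
}

#' @rdname tidy.phase_gradient_field
#' @export
glance.phase_gradient_field <- function(x, ...) {
  n_valid <- sum(x$valid, na.rm = TRUE)
  if (n_valid == 0L) {
    return(tibble::tibble(dx = NA_real_, dy = NA_real_,
                          coherence = NA_real_, n_valid = 0L,
                          n_vertices = nrow(x)))
  }
  out <- dominant_path_direction(x)
  out$n_vertices <- nrow(x)
  out
}

#' Tidiers for frequency partitions
#'
#' `tidy()` lists every one-sided bin with its role (`task`, `noise`, or the
#' exclusion reason); `glance()` gives the degrees of freedom in one row.
#'
#' @param x A [build_frequency_partition()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.freq_partition <- function(x, ...) {
  nyq <- x$n_timepoints %/% 2L
  roles <- rep("noise", nyq + 1L)
  ex <- x$excluded[!duplicated(x$excluded$bin), ]
  roles[ex$bin + 1L] <- ex$reason
  roles[x$task_frequency + 1L] <- "task"
  tibble::tibble(bin = 0:nyq, role = roles)
}

#' @rdname tidy.freq_partition
#' @export
glance.freq_partition <- function(x, ...) {
  tibble::tibble(
    n_timepoints = x$n_timepoints,
    task_frequency = x$task_frequency,
    n_noise_bins = length(x$noise_frequencies),
    df_signal = x$df_signal,
    df_noise = x$df_noise
  )
}

unclass_keep_df <- function(x) {
  class(x) <- class(tibble::tibble())
  for (a in setdiff(names(attributes(x)), c("names", "row.names", "class"))) {
    attr(x, a) <- NULL
  }
  x
}
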