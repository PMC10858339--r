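#' Construct a scan time-series object
#'
#' Bundles the per-unit (voxel or vertex) BOLD samples of one phase-encoded
#' scan with its sampling interval and task frequency. The task frequency is
#' given in cycles per scan, i.e. the Fourier bin at which task-locked signal
#' concentrates (16 for a 256-s scan with 16-s trial cycles at TR = 1 s).
#'
#' @param data Numeric matrix, units in rows and timepoints in columns, or a
#'   data frame coercible to one. All values must be finite.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param task_frequency Task frequency in cycles per scan (positive integer,
#'   below the Nyquist bin).
#' @param unit_space Either `"volume"` (voxels) or `"surface"` (vertices).
#' @param unit_ids Optional integer identifiers (0-based voxel linear index or
#'   vertex index). Defaults to `0:(n_units - 1)`.
#'
#' @return An object of class `scan_ts`: the data matrix with metadata
#'   attributes (`tr_seconds`, `task_frequency`, `unit_space`, `unit_ids`).
#' @export
#' @examples
#' ts <- scan_ts(matrix(rnorm(4 * 256), 4), tr_seconds = 1, task_frequency = 16)
#' dim(ts)
scan_ts <- function(data, tr_seconds = 1, task_frequency = 16,
                    unit_space = c("volume", "surface"), unit_ids = NULL) {
  unit_space <- match.arg(unit_space)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    abort("scan_ts: all BOLD samples must be finite.")
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    abort("scan_ts: `tr_seconds` must be a single positive number.")
  }
  n_t <- ncol(data)
  task_frequency <- as.integer(task_frequency)
  if (task_frequency < 1L || n_t < 2L * task_frequency + 2L) {
    abort(sprintf(
      "scan_ts: need n_timepoints >= 2 * task_frequency + 2 (got %d timepoints, task frequency %d).",
      n_t, task_frequency
    ))
  }
  if (is.null(unit_ids)) {
    unit_ids <- seq_len(nrow(data)) - 1L
  }
  unit_ids <- as.integer(unit_ids)
  if (length(unit_ids) != nrow(data) || anyDuplicated(unit_ids)) {
    abort("scan_ts: `unit_ids` must be unique and match the number of rows.")
  }
  structure(
    data,
    tr_seconds = as.numeric(tr_seconds),
    task_frequency = task_frequency,
    unit_space = unit_space,
    unit_ids = unit_ids,
    class = c("scan_ts", "matrix", "array")
  )
}

#' @export
print.scan_ts <- function(x, ...) {
  cat(sprintf(
    "<scan_ts> %d %s units x %d timepoints (TR %.3g s, task frequency %d cycles/scan)\n",
    nrow(x), attr(x, "unit_space"), ncol(x),
    attr(x, "tr_seconds"), attr(x, "task_frequency")
  ))
  invisible(x)
}

n_timepoints <- function(ts) ncol(ts)

cycle_samples <- function(ts) {
  n_t <- ncol(ts)
  k <- attr(ts, "task_frequency")
  spc <- n_t / k
  if (spc != round(spc)) {
    abort(sprintf(
      "cycle length in samples (%d / %d) is not integral.", n_t, k
    ))
  }
  as.integer(spc)
}

#' Trial period of a scan in seconds
#'
#' @param ts A [scan_ts()] object.
#' @return Cycle duration in seconds (`n_timepoints / task_frequency * TR`).
#' @export
scan_period <- function(ts) {
  ncol(ts) / attr(ts, "task_frequency") * attr(ts, "tr_seconds")
}
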