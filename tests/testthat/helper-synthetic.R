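# Shared fixtures, generated in code.

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# One-row scan whose only energy sits at `bin` with amplitude `amp` and
# phase `-phi` under the analysis DFT convention.
cosine_scan <- function(bin, phi = 0, amp = 1, n = 256, task_frequency = 16) {
  t <- 0:(n - 1)
  scan_ts(rbind(amp * cos(2 * pi * bin * t / n - phi)),
          task_frequency = task_frequency)
}

default_partition <- function() build_frequency_partition(256, 16)

# Analytic activation map: complex F-values with magnitude sqrt(f) and the
# phases implied by the given activation delays.
map_from_delays <- function(unit_ids, delay_s, f = 115, period = 16,
                            space = "native_surface", mesh = NULL,
                            partition = default_partition()) {
  theta <- delay_to_phase(delay_s, period)
  activation_map(
    tibble::tibble(unit_id = unit_ids,
                   re = sqrt(f) * cos(theta),
                   im = sqrt(f) * sin(theta)),
    space = space, mesh_id = if (!is.null(mesh)) mesh$mesh_id,
    provenance = "single_scan", partition = partition
  )
}

random_map <- function(n, seed, space = "common_mesh", mesh_id = "m1") {
  set.seed(seed)
  activation_map(
    tibble::tibble(unit_id = 0:(n - 1),
                   re = rnorm(n), im = rnorm(n)),
    space = space, mesh_id = mesh_id, provenance = "single_scan",
    partition = default_partition()
  )
}

# Sphere-tagged mesh from arbitrary unit vectors (faces are a placeholder;
# spherical resampling only consumes vertex_sphere).
sphere_mesh <- function(points) {
  points <- points / sqrt(rowSums(points^2))
  surface_mesh(points, faces = rbind(c(0L, 1L, 2L)), vertex_sphere = points)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
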