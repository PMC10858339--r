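test_that("task paradigms tile the 16-s cycle as designed", {
  cross <- make_paradigm("crossmodal")
  expect_identical(cross$segments$label, c("Phase1", "Phase2", "PhaseR"))
  expect_equal(cross$segments$onset_s, c(0, 5, 10))
  expect_equal(cross$segments$offset_s, c(5, 10, 16))
  for (task in c("unimodal", "multimodal")) {
    p <- make_paradigm(task)
    expect_equal(p$segments$onset_s, c(0, 5))
    expect_equal(p$segments$offset_s, c(5, 16))
  }
  # segments tile the cycle without overlap; 256 samples at TR 1 s
  expect_equal(sum(cross$segments$offset_s - cross$segments$onset_s), 16)
  expect_identical(cross$n_samples, 256L)
  expect_identical(make_paradigm("unimodal")$n_samples, 256L)
})

test_that("the hemodynamic kernel peaks at ~5 s and acts as a convolution identity", {
  t <- seq(0, 31, by = 0.5)
  h <- canonical_hrf(t)
  expect_equal(max(h), 1)
  peak_t <- t[which.max(h)]
  expect_gte(peak_t, 4); expect_lte(peak_t, 6)
  # positive lobe before the undershoot; finite mass
  expect_true(all(h[t <= peak_t] >= 0))
  expect_true(is.finite(sum(h)))
  expect_error(canonical_hrf(t, peak_shape = -1), "positive")
  expect_error(canonical_hrf(-1:5), "non-negative")

  # circular convolution with a delta reproduces the kernel
  paradigm <- make_paradigm("crossmodal")
  hk <- canonical_hrf(0:31)
  delta <- c(1, rep(0, 255))
  conv <- phasewave:::circular_convolve(delta, hk)
  expect_equal(conv[1:32], hk, tolerance = 1e-10)
  expect_equal(conv[33:256], rep(0, 224), tolerance = 1e-10)
})

test_that("simulated units are reproducible by seed and carry exact planted phase shifts", {
  p <- make_paradigm("crossmodal")
  a1 <- simulate_unit_timeseries(p, "Phase1", 0, 5, 1, seed = 7)
  a2 <- simulate_unit_timeseries(p, "Phase1", 0, 5, 1, seed = 7)
  b <- simulate_unit_timeseries(p, "Phase1", 0, 5, 1, seed = 8)
  expect_identical(a1, a2)
  expect_false(identical(a1, b))

  # integer-TR delay: task-bin phase difference exactly 2*pi*5/16
  x0 <- simulate_unit_timeseries(p, "Phase1", 0, 5, 0)
  x5 <- simulate_unit_timeseries(p, "Phase1", 5, 5, 0)
  sp <- dft_spectrum(scan_ts(rbind(x0, x5)))
  dtheta <- unname(circular_difference(Arg(sp[2, "16"]), Arg(sp[1, "16"])))
  expect_equal(dtheta, -2 * pi * 5 / 16, tolerance = 1e-9)
  # same shift obtained by responding in Phase2 instead (5 s later onset)
  y5 <- simulate_unit_timeseries(p, "Phase2", 0, 5, 0)
  sp2 <- dft_spectrum(scan_ts(rbind(x0, y5)))
  expect_equal(unname(circular_difference(Arg(sp2[2, "16"]), Arg(sp2[1, "16"]))),
               -2 * pi * 5 / 16, tolerance = 1e-9)

  expect_error(simulate_unit_timeseries(p, "Phase1", 16), "cycle")
  expect_error(simulate_unit_timeseries(p, "PhaseX"), "not found")

  # drift energy concentrates in the excluded low bins and leaves phase intact
  part <- default_partition()
  d0 <- simulate_unit_timeseries(p, "Phase1", 0, 5, 0, drift = NULL)
  d1 <- simulate_unit_timeseries(p, "Phase1", 0, 5, 0, drift = c(3, -2))
  sp_drift <- dft_spectrum(scan_ts(rbind(d1 - d0)))
  pw <- Mod(sp_drift[1, as.character(1:128)])^2
  expect_gt(sum(pw[1:3]) / sum(pw), 0.85)
  sp_both <- dft_spectrum(scan_ts(rbind(d0, d1)))
  expect_equal(unname(circular_difference(Arg(sp_both[2, "16"]), Arg(sp_both[1, "16"]))),
               0, tolerance = 0.02)
})

test_that("null simulations follow the F(2,230) law and planted effects are detected", {
  p <- make_paradigm("crossmodal")
  part <- default_partition()
  n_null <- 4000
  truth <- tibble::tibble(amplitude = rep(0, n_null), noise_sd = 1)
  ts <- simulate_scan(truth, p, seed = 12345)
  res <- f_statistic(dft_spectrum(ts), part)
  frac <- mean(res$f_stat > critical_f(0.01))
  se <- sqrt(0.01 * 0.99 / n_null)
  expect_lt(abs(frac - 0.01), 4 * se)
  # quantile agreement with the theoretical law
  expect_equal(stats::quantile(res$f_stat, 0.5, names = FALSE),
               qf(0.5, 2, 230), tolerance = 0.1)

  # planted responses at SNR 5 are essentially always detected
  truth_alt <- tibble::tibble(amplitude = rep(5, 200), noise_sd = 1)
  res_alt <- f_statistic(dft_spectrum(simulate_scan(truth_alt, p, seed = 99)), part)
  expect_gt(mean(res_alt$f_stat > 4.7), 0.99)
  expect_gt(mean(res_alt$f_stat), 100)
})

test_that("crossmodal Phase1 and Phase2 units differ by 5 s of recovered delay under noise", {
  p <- make_paradigm("crossmodal")
  part <- default_partition()
  n_rep <- 120
  truth <- tibble::tibble(
    segment_label = rep(c("Phase1", "Phase2"), each = n_rep),
    amplitude = 5, noise_sd = 1
  )
  res <- f_statistic(dft_spectrum(simulate_scan(truth, p, seed = 777)), part)
  delays <- phase_to_delay(res$theta)
  dd <- (delays[(n_rep + 1):(2 * n_rep)] - delays[1:n_rep]) %% 16
  expect_lt(abs(mean(dd) - 5), 0.25)
  expect_lt(sd(dd), 0.3)
})

test_that("flat grid meshes satisfy the counting and Euler oracles", {
  small <- make_flat_grid_mesh(2, 2)
  expect_identical(mesh_n_vertices(small), 4L)
  expect_identical(nrow(small$faces), 2L)
  grid <- make_flat_grid_mesh(10, 10)
  expect_identical(mesh_n_vertices(grid), 100L)
  expect_identical(nrow(grid$faces), 162L)

  # adjacency symmetric and equal to brute-force edge extraction
  edges <- unique(rbind(grid$faces[, 1:2], grid$faces[, 2:3], grid$faces[, c(1, 3)],
                        grid$faces[, 2:1], grid$faces[, 3:2], grid$faces[, c(3, 1)]))
  brute <- split(edges[, 2], factor(edges[, 1], levels = 0:99))
  for (v in c(0, 13, 55, 99)) {
    expect_setequal(mesh_neighbors(grid, v), brute[[as.character(v)]])
    for (u in mesh_neighbors(grid, v)) {
      expect_true(v %in% mesh_neighbors(grid, u))
    }
  }
  # Euler characteristic of a disk patch: V - E + F = 1
  n_e <- nrow(edges) / 2
  expect_identical(100 - n_e + 162, 1)
  # interior vertices have the full hexagonal ring
  expect_identical(length(mesh_interior_vertices(grid)), 64L)

  expect_error(surface_mesh(grid$vertex_xyz, rbind(c(0L, 0L, 1L))), "degenerate")
  expect_error(surface_mesh(grid$vertex_xyz, rbind(c(0L, 1L, 200L))), "outside")
})

test_that("planted waves put delays on the distance/speed line and wrap", {
  mesh <- make_flat_grid_mesh(6, 6, spacing_mm = 1)
  # infinite speed: uniform delays
  u <- plant_wave_truth(mesh, 0L, speed_mm_per_s = Inf, base_delay_s = 3)
  expect_true(all(u$extra_delay_s == 3))
  # along the first grid row, delay increments by spacing/speed
  w <- plant_wave_truth(mesh, 0L, speed_mm_per_s = 4, base_delay_s = 1)
  row0 <- w[w$unit_id %in% 0:5, ]
  expect_equal(row0$extra_delay_s, 1 + (0:5) / 4, tolerance = 1e-12)
  # wrapping into the cycle
  slow <- plant_wave_truth(mesh, 0L, speed_mm_per_s = 0.25, base_delay_s = 0)
  expect_true(all(slow$extra_delay_s >= 0 & slow$extra_delay_s < 16))
  expect_error(plant_wave_truth(mesh, 35L, region = 0:10), "outside the region")
})

test_that("an end-to-end planted wave survives simulation, mapping, and gradient recovery", {
  mesh <- make_flat_grid_mesh(12, 12)
  dir_ang <- pi / 5
  truth <- plant_wave_truth(mesh, 0L, speed_mm_per_s = 2,
                            direction = c(cos(dir_ang), sin(dir_ang)))
  sim <- tibble::tibble(
    unit_id = truth$unit_id, segment_label = "Phase1",
    extra_delay_s = truth$extra_delay_s, amplitude = 5, noise_sd = 1
  )
  ts <- simulate_scan(sim, make_paradigm("unimodal"), unit_space = "surface",
                      seed = 31415)
  res <- f_statistic(dft_spectrum(ts))
  map <- threshold_map(activation_map(res, space = "native_surface",
                                      mesh_id = mesh$mesh_id),
                       f_thresholds()[["p01"]], quiet = TRUE)
  field <- phase_gradient_field(map, mesh)
  interior <- mesh_interior_vertices(mesh)
  dom <- dominant_path_direction(field, roi = interior)
  expect_lt(abs(circular_difference(atan2(dom$dy, dom$dx), dir_ang)) * 180 / pi, 5)
  expect_gt(dom$coherence, 0.95)
  # |g| = (2*pi/period)/speed on interior vertices
  fi <- field[field$valid & field$unit_id %in% interior, ]
  gmag <- sqrt(fi$gx^2 + fi$gy^2)
  expect_lt(abs(mean(gmag) - (2 * pi / 16) / 2) / ((2 * pi / 16) / 2), 0.05)
})
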