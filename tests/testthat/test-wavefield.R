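test_that("circular differences wrap minimally and are antisymmetric", {
  expect_equal(circular_difference(0.1, 0.2), -0.1, tolerance = 1e-12)
  expect_equal(circular_difference(0.1, 2 * pi - 0.1), 0.2, tolerance = 1e-12)
  set.seed(17)
  a <- runif(1000, 0, 2 * pi)
  b <- runif(1000, 0, 2 * pi)
  d <- circular_difference(a, b)
  expect_true(all(d >= -pi & d < pi))
  at_branch <- abs(abs(d) - pi) < 1e-12
  expect_equal(circular_difference(b, a)[!at_branch], -d[!at_branch],
               tolerance = 1e-12)
})

test_that("window specification enforces the 360-degree tiling", {
  spec <- window_spec()
  expect_identical(spec$n_frames, 80L)
  expect_equal(spec$window_degrees, 2 * spec$step_degrees)
  expect_error(window_spec(step_degrees = 7), "divide 360")
})

test_that("gradient field recovers planar ramps exactly and vanishes on constants", {
  mesh <- make_flat_grid_mesh(12, 12)
  xy <- mesh$vertex_flat
  k <- 0.15
  # theta decreasing along +x = delay increasing along +x (wave travels +x)
  delays <- (xy[, 1] * k * 16 / (2 * pi)) %% 16
  map <- map_from_delays(0:(nrow(xy) - 1), delays, mesh = mesh)
  field <- phase_gradient_field(map, mesh)
  interior <- mesh_interior_vertices(mesh)
  fi <- field[field$unit_id %in% interior, ]
  expect_true(all(fi$valid))
  expect_equal(fi$gx, rep(k, nrow(fi)), tolerance = 1e-6)
  expect_equal(fi$gy, rep(0, nrow(fi)), tolerance = 1e-6)
  expect_lt(max(fi$residual), 1e-6)

  # raw-phase orientation is the negation
  field_th <- phase_gradient_field(map, mesh, orientation = "phase")
  fj <- field_th[field_th$unit_id %in% interior, ]
  expect_equal(fj$gx, rep(-k, nrow(fj)), tolerance = 1e-6)

  # constant phase -> zero vectors
  const <- map_from_delays(0:(nrow(xy) - 1), rep(3, nrow(xy)), mesh = mesh)
  f0 <- phase_gradient_field(const, mesh)
  expect_lt(max(abs(c(f0$gx, f0$gy)), na.rm = TRUE), 1e-9)

  no_flat <- surface_mesh(cbind(xy, 0), mesh$faces)
  expect_error(phase_gradient_field(map, no_flat), "flat")
})

test_that("gradient field is rotation-equivariant and ignores global phase shifts", {
  mesh <- make_flat_grid_mesh(10, 10)
  n_v <- mesh_n_vertices(mesh)
  set.seed(23)
  delays <- (0.4 * mesh$vertex_flat[, 1] + 0.25 * mesh$vertex_flat[, 2] +
               0.05 * rnorm(n_v)) %% 16
  map <- map_from_delays(0:(n_v - 1), delays, mesh = mesh)
  base <- phase_gradient_field(map, mesh)

  for (ang in c(pi / 6, pi / 2)) {
    R <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
    mesh_r <- surface_mesh(mesh$vertex_xyz, mesh$faces,
                           vertex_flat = mesh$vertex_flat %*% t(R))
    rot <- phase_gradient_field(map, mesh_r)
    g_rot_expect <- cbind(base$gx, base$gy) %*% t(R)
    ok <- base$valid & rot$valid
    expect_equal(rot$gx[ok], g_rot_expect[ok, 1], tolerance = 1e-8)
    expect_equal(rot$gy[ok], g_rot_expect[ok, 2], tolerance = 1e-8)
  }

  shifted <- map_from_delays(0:(n_v - 1), (delays + 4.21) %% 16, mesh = mesh)
  shf <- phase_gradient_field(shifted, mesh)
  ok <- base$valid & shf$valid
  expect_equal(shf$gx[ok], base$gx[ok], tolerance = 1e-9)
  expect_equal(shf$gy[ok], base$gy[ok], tolerance = 1e-9)
})

test_that("radial waves point outward from the seed and vertices with thin stencils are masked", {
  mesh <- make_flat_grid_mesh(15, 15)
  centre <- 7L + 15L * 7L
  truth <- plant_wave_truth(mesh, centre, speed_mm_per_s = 2)
  map <- map_from_delays(truth$unit_id, truth$extra_delay_s, mesh = mesh)
  field <- phase_gradient_field(map, mesh)
  xy <- mesh$vertex_flat
  interior <- mesh_interior_vertices(mesh)
  fi <- field[field$valid & field$unit_id %in% interior &
                field$unit_id != centre, ]
  radial <- xy[fi$unit_id + 1L, ] - matrix(xy[centre + 1L, ], nrow(fi), 2, byrow = TRUE)
  away <- sqrt(rowSums(radial^2)) > 2 # near the seed the field is not radial yet
  ang_err <- abs(circular_difference(atan2(fi$gy, fi$gx),
                                     atan2(radial[, 2], radial[, 1])))
  expect_lt(mean(ang_err[away]) * 180 / pi, 5)

  # a vertex with < 2 significant neighbors is invalid, not extrapolated
  sparse <- map_from_delays(c(0L, 2L, 16L), c(1, 2, 3), mesh = mesh)
  fs <- phase_gradient_field(sparse, mesh)
  expect_false(fs$valid[fs$unit_id == 16L]) # vertex 0 is its only significant neighbor
})

test_that("isophase bands equal the brute-force circular histogram", {
  set.seed(29)
  n <- 500
  theta <- runif(n, 0, 2 * pi)
  map <- activation_map(
    tibble::tibble(unit_id = 0:(n - 1),
                   re = 4 * cos(theta), im = 4 * sin(theta)),
    partition = default_partition()
  )
  # single band covers everything
  one <- isophase_bands(map, 0)
  expect_true(all(one$band == 0L))

  edges <- seq(0, 2 * pi - 1e-9, length.out = 81)[1:80]
  bands <- isophase_bands(map, edges)
  expect_true(all(table(factor(bands$unit_id)) == 1)) # each vertex exactly once
  brute <- findInterval(theta, c(edges, 2 * pi)) - 1L
  expect_identical(bands$band, brute)

  uniform <- map_from_delays(0:9, rep(5, 10))
  ub <- isophase_bands(uniform, edges)
  expect_identical(length(unique(ub$band)), 1L)

  expect_error(isophase_bands(map, c(1, 0.5)), "increasing")
})

test_that("movie frames tile the cycle with double coverage", {
  set.seed(31)
  n <- 400
  theta <- runif(n, 0, 2 * pi)
  map <- activation_map(
    tibble::tibble(unit_id = 0:(n - 1),
                   re = 4 * cos(theta), im = 4 * sin(theta)),
    partition = default_partition()
  )
  frames <- movie_frames(map)
  expect_identical(attr(frames, "n_frames"), 80L)
  expect_identical(sort(unique(frames$frame_id)), 0:79)

  # defaults: each vertex appears in exactly 2 frames; union covers the map
  counts <- table(factor(frames$unit_id, levels = 0:(n - 1)))
  expect_true(all(counts == 2))
  expect_setequal(unique(frames$unit_id), map$unit_id)

  # brute-force membership oracle for a handful of frames
  spec <- window_spec()
  for (k in c(0L, 13L, 79L)) {
    d <- circular_difference(theta, k * spec$step_rad)
    expect_setequal(frames$unit_id[frames$frame_id == k],
                    (0:(n - 1))[d >= -spec$window_rad / 2 & d < spec$window_rad / 2])
  }

  # frame masks unchanged when phases shift by full turns
  map2 <- activation_map(
    tibble::tibble(unit_id = 0:(n - 1),
                   re = 4 * cos(theta + 2 * pi), im = 4 * sin(theta + 2 * pi)),
    partition = default_partition()
  )
  frames2 <- movie_frames(map2)
  expect_identical(frames$frame_id, frames2$frame_id)
  expect_identical(frames$unit_id, frames2$unit_id)
})

test_that("dominant path direction is the coherence-weighted consensus", {
  mk_field <- function(gx, gy) {
    structure(
      tibble::tibble(unit_id = seq_along(gx) - 1L, gx = gx, gy = gy,
                     residual = 0, n_neighbors = 6L, valid = TRUE),
      class = c("phase_gradient_field", class(tibble::tibble()))
    )
  }
  all_x <- dominant_path_direction(mk_field(rep(1, 5), rep(0, 5)))
  expect_equal(c(all_x$dx, all_x$dy), c(1, 0), tolerance = 1e-12)
  expect_equal(all_x$coherence, 1, tolerance = 1e-12)

  opposed <- dominant_path_direction(mk_field(c(1, -1), c(0, 0)))
  expect_equal(opposed$coherence, 0, tolerance = 1e-12)

  # planted planar wave through an ROI
  mesh <- make_flat_grid_mesh(20, 20)
  truth <- plant_wave_truth(mesh, 0L, speed_mm_per_s = 2.5,
                            direction = c(cos(0.6), sin(0.6)))
  map <- map_from_delays(truth$unit_id, truth$extra_delay_s, mesh = mesh)
  field <- phase_gradient_field(map, mesh)
  dom <- dominant_path_direction(field, roi = mesh_interior_vertices(mesh))
  expect_lt(abs(circular_difference(atan2(dom$dy, dom$dx), 0.6)) * 180 / pi, 5)
  expect_gt(dom$coherence, 0.95)

  empty <- mk_field(numeric(0), numeric(0))
  expect_error(dominant_path_direction(empty), "no valid")
})
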