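test_that("beam fluence is linear in MU and additive over segments", {
  g <- small_grid(30, 3)
  m <- beam_model(-0.5, 4.5)
  s1 <- mlc_segment(rect_aperture(-20, 20), 100, 0)
  s2 <- mlc_segment(rect_aperture(-10, 25), 40, 0)
  f1 <- beam_fluence(list(s1), m, g)
  f2 <- beam_fluence(list(s2), m, g)
  f12 <- beam_fluence(list(s1, s2), m, g)
  expect_equal(f12$values, f1$values + f2$values)
  s1d <- mlc_segment(rect_aperture(-20, 20), 200, 0)
  expect_equal(beam_fluence(list(s1d), m, g)$values, 2 * f1$values)
  # fully open pair region with one segment of 100 MU reads 100
  expect_equal(f1$values[which.min(abs(grid_axes(g)$x)), 11], 100)
  s_rot <- mlc_segment(rect_aperture(), 10, 90)
  expect_error(beam_fluence(list(s1, s_rot), m, g), "gantry")
})

test_that("planar dose preserves a flat field and matches the brute-force kernel", {
  g <- small_grid(40, 4)
  k <- kernel_params(sigma_primary_mm = 2, sigma_scatter_mm = 8,
                     scatter_weight = 0.2)
  flat <- dose_map(g, matrix(50, g$nx, g$ny))
  d <- planar_dose(flat, k)
  centre <- d$values[11, 11]
  expect_lt(abs(centre - 50) / 50, 0.001)
  # impulse response equals the direct double-sum convolution
  imp <- matrix(0, g$nx, g$ny); imp[11, 11] <- 1
  di <- planar_dose(dose_map(g, imp), k)
  expect_equal(di$values, planar_dose_oracle(dose_map(g, imp), k),
               tolerance = 1e-10)
  # and linearity: dose(flat + impulse) = dose(flat) + dose(impulse)
  both <- planar_dose(dose_map(g, flat$values + imp), k)
  expect_equal(both$values, d$values + di$values, tolerance = 1e-12)
})

test_that("random fluence maps match the brute-force convolution oracle", {
  set.seed(11)
  g <- small_grid(24, 4)
  k <- kernel_params(sigma_primary_mm = 3, sigma_scatter_mm = 10,
                     scatter_weight = 0.15)
  v <- matrix(runif(g$nx * g$ny, 0, 10), g$nx, g$ny)
  fl <- dose_map(g, v)
  expect_equal(planar_dose(fl, k)$values, planar_dose_oracle(fl, k),
               tolerance = 1e-10)
})

test_that("point evaluation agrees with the rasterized dose at grid nodes", {
  set.seed(3)
  g <- small_grid(30, 2)
  k <- kernel_params()
  seg <- mlc_segment(random_aperture(), 80, 0)
  fl <- beam_fluence(list(seg), beam_model(-0.5, 4.5), g)
  d <- planar_dose(fl, k)
  ax <- grid_axes(g)
  ii <- c(3, 10, 17, 25); jj <- c(5, 12, 20, 28)
  got <- planar_dose_at(fl, k, ax$x[ii], ax$y[jj])
  expect_equal(got, d$values[cbind(ii, jj)], tolerance = 1e-10)
  tens <- planar_dose_at(fl, k, ax$x[ii], ax$y[jj], tensor = TRUE)
  expect_equal(tens, d$values[ii, jj], tolerance = 1e-10)
})

test_that("ray depth follows the cylinder geometry", {
  ph <- default_phantom()
  # isocenter depth equals the radius for any gantry angle
  for (th in c(0, 45, 90, 210)) expect_equal(ray_depth(0, 0, th, ph), 80)
  # anterior beam: depth of (0, z) is R - z
  expect_equal(ray_depth(0, 30, 0, ph), 50)
  expect_equal(ray_depth(0, -30, 0, ph), 110)
  # posterior beam mirrors it
  expect_equal(ray_depth(0, 30, 180, ph), 110)
  expect_error(ray_depth(100, 0, 0, ph), "outside")
})

test_that("composite point dose: single-beam attenuation and opposed-beam symmetry", {
  k <- kernel_params()
  ph <- default_phantom()
  plan1 <- tiny_plan(c(100, 0))
  g <- small_grid(60, 2)
  pt <- data.frame(x_mm = 0, y_mm = 0, z_mm = 0)
  d1 <- composite_point_dose(plan1, beam_model(0), pt, ph, k, g)
  fl <- beam_fluence(plan1$beams[[1]]$segments, beam_model(0), g)
  pd0 <- planar_dose_at(fl, k, 0, 0)
  expect_equal(d1, pd0 * exp(-k$mu_attenuation_per_cm * 8))
  # two identical opposed beams on the symmetric cylinder: each contributes
  # half of the total at the centre
  ap <- rect_aperture(-20, 20)
  plan2 <- structure(list(plan_id = "OPP", technique = "imrt", beams = list(
    list(gantry_deg = 0, segments = list(mlc_segment(ap, 50, 0))),
    list(gantry_deg = 180, segments = list(mlc_segment(ap, 50, 180)))),
    total_mu = 100, spec = NULL), class = "treatment_plan")
  dts <- composite_point_dose(plan2, beam_model(0), pt, ph, k, g)
  one <- composite_point_dose(structure(
    list(plan_id = "ONE", technique = "imrt",
         beams = plan2$beams[1], total_mu = 50, spec = NULL),
    class = "treatment_plan"), beam_model(0), pt, ph, k, g)
  expect_equal(dts, 2 * one)
})

test_that("composite point dose is non-decreasing in the leaf-tip offset", {
  set.seed(5)
  g <- small_grid(60, 2)
  ph <- default_phantom()
  k <- kernel_params()
  pts <- data.frame(x_mm = c(0, 10, -15, 0), y_mm = 0,
                    z_mm = c(0, 20, -5, -25))
  for (rep in 1:3) {
    ap <- random_aperture(n_pairs = 12)
    plan <- structure(list(plan_id = "R", technique = "imrt", beams = list(
      list(gantry_deg = runif(1, 0, 360),
           segments = list(mlc_segment(ap, 100, 0)))), total_mu = 100,
      spec = NULL), class = "treatment_plan")
    plan$beams[[1]]$segments[[1]]$gantry_deg <- plan$beams[[1]]$gantry_deg
    prev <- NULL
    for (d in seq(-1.5, 1.5, by = 0.5)) {
      v <- composite_point_dose(plan, beam_model(d, 4.5), pts, ph, k, g)
      if (!is.null(prev)) expect_true(all(v >= prev - 1e-9))
      prev <- v
    }
  }
})
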