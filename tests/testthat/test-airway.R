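make_profile <- function(r, hu, angle = 0) {
  peak_idx <- which.max(hu)
  structure(
    list(angle = angle, r_mm = r, hu = hu,
         lumen_min_hu = min(hu[seq_len(peak_idx)]),
         wall_peak_hu = hu[peak_idx]),
    class = "ray_profile"
  )
}

annulus_truth <- function(r_i = 1.8, r_o = 3.8) {
  list(la = pi * r_i^2, wa = pi * (r_o^2 - r_i^2),
       wa_pct = 100 * (r_o^2 - r_i^2) / r_o^2, pi = 2 * pi * r_i)
}

test_that("FWHM boundaries sit at the half-maximum crossings of a step profile", {
  r <- seq(0, 10, by = 0.1)
  hu <- ifelse(r < 1.8, -1000, ifelse(r <= 3.8, 0, -880))
  b <- fwhm_boundaries(make_profile(r, hu))
  expect_true(b$valid)
  expect_lt(abs(b$inner_radius_mm - 1.8), 0.1)
  expect_lt(abs(b$outer_radius_mm - 3.8), 0.1)

  # affine scaling of the profile leaves the half-max radii unchanged
  b2 <- fwhm_boundaries(make_profile(r, hu * 2))
  expect_identical(b$inner_radius_mm, b2$inner_radius_mm)
  expect_identical(b$outer_radius_mm, b2$outer_radius_mm)

  # monotone profile: no wall, flagged invalid
  b3 <- fwhm_boundaries(make_profile(r, seq(-1000, 0, length.out = length(r))))
  expect_false(b3$valid)
})

test_that("rays through a homogeneous image are constant and yield no wall", {
  flat <- structure(list(values = matrix(-880, 60, 60),
                         spacing_mm = c(0.25, 0.25), z_mm = 0),
                    class = "ct_slice")
  rays <- cast_rays(flat, c(7, 7), n_rays = 16, max_radius_mm = 5)
  expect_length(rays, 16)
  for (ray in rays) {
    expect_lt(max(abs(ray$hu - (-880))), 1e-9)
    expect_false(fwhm_boundaries(ray)$valid)
  }
  expect_error(cast_rays(flat, c(7, 7), n_rays = 4),
               class = "lungqct_parameter_error")
  expect_error(cast_rays(flat, c(-5, 7)), class = "lungqct_parameter_error")
})

test_that("ray profiles on an ideal annulus peak at the wall attenuation", {
  sl <- generate_annulus_slice(wall_hu = 0)
  rays <- cast_rays(sl, attr(sl, "center_xy_mm"), n_rays = 32)
  peaks <- vapply(rays, `[[`, numeric(1), "wall_peak_hu")
  expect_true(all(abs(peaks - 0) < 1e-9))
})

test_that("the seed refines to the lumen centre", {
  sl <- generate_annulus_slice()
  ctr <- attr(sl, "center_xy_mm")
  expect_lt(max(abs(refine_center(sl, ctr) - ctr)), 1e-6)
  refined <- refine_center(sl, ctr + c(0.5, -0.3))
  expect_lt(sqrt(sum((refined - ctr)^2)), 0.1)
  # a seed in the wall is rejected
  expect_error(refine_center(sl, ctr + c(2.8, 0)),
               class = "lungqct_parameter_error")
})

test_that("airway dimensions recover the analytic annulus geometry", {
  tr <- annulus_truth()
  sl <- generate_annulus_slice()
  m <- measure_airway(sl, attr(sl, "center_xy_mm"))
  expect_lt(abs(m$LA_mm2 - tr$la) / tr$la, 0.05)
  expect_lt(abs(m$WA_mm2 - tr$wa) / tr$wa, 0.05)
  expect_lt(abs(m$Pi_mm - tr$pi) / tr$pi, 0.05)
  expect_lt(abs(m$WA_pct - tr$wa_pct), 2)
  # the WA% arithmetic identity holds to numerical precision
  expect_equal(m$WA_pct, 100 * m$WA_mm2 / (m$WA_mm2 + m$LA_mm2),
               tolerance = 1e-9)
})

test_that("a wall as thick as sqrt(2) radii gives WA close to LA and WA% near 50", {
  sl <- generate_annulus_slice(r_inner_mm = 2, r_outer_mm = 2 * sqrt(2))
  m <- measure_airway(sl, attr(sl, "center_xy_mm"))
  expect_lt(abs(m$WA_pct - 50), 1.5)
  # constructed equality: if WA equalled LA exactly the identity gives 50
  expect_identical(100 * 7 / (7 + 7), 50)
})

test_that("measurements are rotation-invariant to better than 1 %", {
  sl <- generate_annulus_slice(center_offset_mm = c(0.08, -0.05))
  base <- measure_airway(sl, attr(sl, "center_xy_mm"))
  for (ang in c(17, 49, 113)) {
    rot <- rotate_slice(sl, ang)
    seed <- (dim(sl$values) - 1) / 2 * sl$spacing_mm
    m <- measure_airway(rot, seed)
    expect_lt(abs(m$LA_mm2 - base$LA_mm2) / base$LA_mm2, 0.01)
    expect_lt(abs(m$WA_mm2 - base$WA_mm2) / base$WA_mm2, 0.01)
    expect_lt(abs(m$Pi_mm - base$Pi_mm) / base$Pi_mm, 0.01)
  }
})

test_that("two noise renderings measured at the same seed agree", {
  tr <- annulus_truth()
  sl_fbp <- generate_annulus_slice(noise_sd_hu = 80, seed = 5)
  sl_ir <- generate_annulus_slice(noise_sd_hu = 44, seed = 6)
  ctr <- attr(sl_fbp, "center_xy_mm")
  m_fbp <- measure_airway(sl_fbp, ctr)
  m_ir <- measure_airway(sl_ir, ctr)
  expect_lt(abs(m_fbp$LA_mm2 - m_ir$LA_mm2) / tr$la, 0.10)
  expect_lt(abs(m_fbp$WA_mm2 - m_ir$WA_mm2) / tr$wa, 0.10)
  expect_lt(abs(m_fbp$Pi_mm - m_ir$Pi_mm) / tr$pi, 0.10)
})

test_that("measurement fails loudly when too few rays are usable", {
  # lumen exists but there is no wall anywhere: every ray invalid
  sl <- generate_annulus_slice(wall_hu = -870, parenchyma_hu = -880)
  expect_error(measure_airway(sl, attr(sl, "center_xy_mm")),
               class = "lungqct_measurement_failure")
})
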