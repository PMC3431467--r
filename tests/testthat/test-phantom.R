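test_that("phantom pathology fractions hit their targets", {
  ph <- generate_phantom(small_params(emphysema_fraction = 0.10,
                                      trapping_fraction = 0.15))
  tr <- ph$truth
  n_lung <- sum(tr$lung_mask)
  expect_lt(abs(sum(tr$emphysema_mask) / n_lung - 0.10), 0.01)
  expect_lt(abs(sum(tr$trapping_mask) / n_lung - 0.15), 0.01)
})

test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom(small_params(seed = 42))
  b <- generate_phantom(small_params(seed = 42))
  c <- generate_phantom(small_params(seed = 43))
  expect_identical(a$insp$values, b$insp$values)
  expect_identical(a$exp$values, b$exp$values)
  expect_identical(a$truth$emphysema_mask, b$truth$emphysema_mask)
  expect_false(identical(a$insp$values, c$insp$values))
})

test_that("zero pathology fractions give empty masks", {
  ph <- generate_phantom(small_params(emphysema_fraction = 0,
                                      trapping_fraction = 0))
  expect_identical(sum(ph$truth$emphysema_mask), 0L)
  expect_identical(sum(ph$truth$trapping_mask), 0L)
})

test_that("truth masks nest and partition correctly, airway truths are analytic", {
  ph <- generate_phantom(small_params())
  tr <- ph$truth
  expect_true(all(tr$lung_mask[tr$emphysema_mask]))
  expect_true(all(tr$lung_mask[tr$trapping_mask]))
  expect_identical(sum(tr$emphysema_mask & tr$trapping_mask), 0L)
  expect_identical(sum(tr$lung_mask & tr$airway_lumen_mask), 0L)
  p <- tr$params
  expect_equal(tr$true_LA_mm2, pi * p$airway_inner_radius_mm^2)
  expect_equal(tr$true_WA_mm2,
               pi * (p$airway_outer_radius_mm^2 - p$airway_inner_radius_mm^2))
  expect_equal(tr$true_Pi_mm, 2 * pi * p$airway_inner_radius_mm)
})

test_that("expiration shifts normal lung but not trapped or emphysematous lung", {
  p <- small_params(texture_sd_hu = 0)
  ph <- generate_phantom(p)
  normal <- ph$truth$lung_mask & !ph$truth$emphysema_mask & !ph$truth$trapping_mask
  expect_equal(mean(ph$insp$values[normal]), p$hu_normal_insp, tolerance = 1e-9)
  expect_equal(mean(ph$exp$values[normal]), p$hu_normal_exp, tolerance = 1e-9)
  expect_equal(mean(ph$exp$values[ph$truth$trapping_mask]), p$hu_trapped_exp,
               tolerance = 1e-9)
  expect_equal(mean(ph$exp$values[ph$truth$emphysema_mask]), p$hu_emphysema,
               tolerance = 1e-9)
})

test_that("parameter invariants are enforced", {
  expect_error(phantom_params(emphysema_fraction = 0.7, trapping_fraction = 0.5),
               class = "lungqct_parameter_error")
  expect_error(phantom_params(airway_inner_radius_mm = 4, airway_outer_radius_mm = 3),
               class = "lungqct_parameter_error")
  expect_error(phantom_params(hu_emphysema = -900),
               class = "lungqct_parameter_error")
  expect_error(phantom_params(voxel_spacing_mm = c(0.7, -0.7, 1)),
               class = "lungqct_parameter_error")
  expect_error(recon_params("FBP", noise_sigma_hu = -5),
               class = "lungqct_parameter_error")
  expect_error(recon_params("IR", noise_reduction = 1),
               class = "lungqct_parameter_error")
})

test_that("reconstruction noise is additive, zero-mean and scaled by the reduction", {
  block <- ct_volume(array(-880, c(50, 50, 50)), c(1, 1, 1))
  # zero noise: identity
  clean <- apply_reconstruction(block, recon_params("FBP", noise_sigma_hu = 0))
  expect_identical(clean$values, block$values)
  fbp <- apply_reconstruction(block, recon_params("FBP", 80), seed = 1)
  ir <- apply_reconstruction(block, recon_params("IR", 80), seed = 2)
  n <- length(block$values)
  expect_gte(n, 1e5)
  ratio <- sd(ir$values - block$values) / sd(fbp$values - block$values)
  expect_lt(abs(ratio - 0.55), 0.02)
  # zero-mean to within 3 sigma / sqrt(N)
  expect_lt(abs(mean(fbp$values - block$values)), 3 * 80 / sqrt(n))
  expect_identical(fbp$recon_label, "FBP")
  # same seed reproduces the noise field exactly
  fbp2 <- apply_reconstruction(block, recon_params("FBP", 80), seed = 1)
  expect_identical(fbp$values, fbp2$values)
})

test_that("cohort draws are reproducible and honour degenerate ranges", {
  a <- generate_cohort(3, seed = 5, base_params = small_params())
  b <- generate_cohort(3, seed = 5, base_params = small_params())
  expect_identical(a$insp[[1]]$values, b$insp[[1]]$values)
  expect_identical(a$subject, sprintf("S%03d", 1:3))
  expect_false(identical(a$insp[[1]]$values, a$insp[[2]]$values))

  rng <- cohort_severity_ranges()
  rng$emphysema_fraction <- c(0.08, 0.08)
  d <- draw_cohort_params(4, rng, seed = 2, base_params = small_params())
  expect_true(all(vapply(d$params, `[[`, numeric(1), "emphysema_fraction") == 0.08))
})

test_that("cohort-mean emphysema burden matches the severity-range midpoint", {
  co <- generate_cohort(30, seed = 3, base_params = small_params())
  achieved <- vapply(co$truth, function(tr) {
    sum(tr$emphysema_mask) / sum(tr$lung_mask)
  }, numeric(1))
  rng <- cohort_severity_ranges()$emphysema_fraction
  midpoint <- mean(rng)
  se <- diff(rng) / sqrt(12) / sqrt(30)
  expect_lt(abs(mean(achieved) - midpoint), 3 * se)
})
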