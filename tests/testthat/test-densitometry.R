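test_that("the density-mask indices reproduce hand-counted values", {
  # IN-950: strict threshold, 2 of 8 voxels below -950
  f <- vol_from_values(c(-980, -960, -940, -900, -850, -800, -750, -700))
  expect_identical(compute_in950(f$vol, f$mask), 25)
  all_air <- vol_from_values(rep(-1000, 10))
  expect_identical(compute_in950(all_air$vol, all_air$mask), 100)
  none <- vol_from_values(rep(-940, 10))
  expect_identical(compute_in950(none$vol, none$mask), 0)

  # EXP-856: the threshold value itself is excluded
  g <- vol_from_values(c(-900, -870, -856, -850))
  expect_identical(compute_exp856(g$vol, g$mask), 50)
  expect_identical(compute_exp856(all_air$vol, all_air$mask), 100)
  high <- vol_from_values(c(-800, -700))
  expect_identical(compute_exp856(high$vol, high$mask), 0)
})

test_that("Perc15 follows linear interpolation between order statistics", {
  h <- vol_from_values(rep(-900, 7))
  expect_identical(compute_perc15(h$vol, h$mask), -900)
  # 20 values -1000 ... -810 by 10: position (n-1)*0.15 = 2.85
  f <- vol_from_values(seq(-1000, -810, by = 10))
  expect_equal(compute_perc15(f$vol, f$mask), -971.5, tolerance = 1e-12)
  # translation equivariance: +11 HU everywhere moves Perc15 by exactly 11
  shifted <- vol_from_values(seq(-1000, -810, by = 10) + 11)
  expect_equal(compute_perc15(shifted$vol, shifted$mask), -971.5 + 11,
               tolerance = 1e-12)
})

test_that("RVC subtracts inspiratory from expiratory band shares", {
  f <- vol_from_values(rep(-900, 10))
  expect_identical(compute_rvc(f$vol, f$mask, f$vol, f$mask), 0)
  # insp 40 % in the [-950, -860] band, exp 20 %
  insp <- vol_from_values(c(-940, -900, -880, -870, -700, -700, -600, -500, -400, -300))
  exp_ <- vol_from_values(c(-940, -900, -700, -700, -600, -500, -400, -300, -200, -100))
  expect_equal(compute_rvc(insp$vol, insp$mask, exp_$vol, exp_$mask), -20)
  # extremes: exp fully in band, insp fully out
  lo <- vol_from_values(rep(-700, 5))
  inb <- vol_from_values(rep(-900, 5))
  expect_identical(compute_rvc(lo$vol, lo$mask, inb$vol, inb$mask), 100)
  # band edges inclusive; below -950 is outside the band
  edges <- vol_from_values(c(-950, -860, -951, -859))
  expect_identical(lungqct:::band_share_pct(c(-950, -860, -951, -859)), 50)
})

test_that("the E/I ratio is a plain MLD ratio and scale-invariant", {
  i <- vol_from_values(rep(-850, 4))
  e <- vol_from_values(rep(-750, 4))
  expect_equal(compute_ei_ratio(i$vol, i$mask, e$vol, e$mask),
               100 * (-750) / (-850), tolerance = 1e-12)
  expect_identical(compute_ei_ratio(i$vol, i$mask, i$vol, i$mask), 100)
  # common HU scaling leaves the ratio unchanged, exactly
  i2 <- vol_from_values(rep(-850, 4) * 4)
  e2 <- vol_from_values(rep(-750, 4) * 4)
  expect_identical(compute_ei_ratio(i$vol, i$mask, e$vol, e$mask),
                   compute_ei_ratio(i2$vol, i2$mask, e2$vol, e2$mask))
})

test_that("compute_densitometry agrees with the single-index functions", {
  set.seed(1)
  insp <- vol_from_values(runif(400, -1000, -600))
  exp_ <- vol_from_values(runif(400, -1000, -600))
  res <- compute_densitometry(insp$vol, exp_$vol, insp$mask, exp_$mask)
  expect_equal(res$in950_pct, compute_in950(insp$vol, insp$mask))
  expect_equal(res$perc15_hu, compute_perc15(insp$vol, insp$mask))
  expect_equal(res$exp856_pct, compute_exp856(exp_$vol, exp_$mask))
  expect_equal(res$rvc_pct,
               compute_rvc(insp$vol, insp$mask, exp_$vol, exp_$mask))
  expect_equal(res$ei_ratio_pct,
               compute_ei_ratio(insp$vol, insp$mask, exp_$vol, exp_$mask))
  # bounded outputs, percentile inside the masked range
  expect_true(res$in950_pct >= 0 && res$in950_pct <= 100)
  expect_true(res$exp856_pct >= 0 && res$exp856_pct <= 100)
  expect_true(res$rvc_pct >= -100 && res$rvc_pct <= 100)
  expect_true(res$perc15_hu >= min(insp$vol$values) &&
                res$perc15_hu <= max(insp$vol$values))
})

test_that("densitometry rejects empty masks", {
  f <- vol_from_values(rep(-900, 4))
  empty <- as_lung_mask(array(FALSE, dim(f$vol$values)), f$vol$spacing_mm)
  expect_error(compute_in950(f$vol, empty), class = "lungqct_parameter_error")
  expect_error(compute_perc15(f$vol, empty), class = "lungqct_parameter_error")
})
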