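test_that("concordance correlation matches hand and oracle evaluations", {
  x <- c(1, 2, 3)
  expect_identical(concordance_correlation(x, x), 1)
  z <- c(-1, 0, 1)
  expect_identical(concordance_correlation(z, -z), -1)
  expect_equal(concordance_correlation(c(1, 2, 3), c(2, 2, 4)), 2 / 3,
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    a <- rnorm(n, sd = runif(1, 0.5, 5))
    b <- a * runif(1, 0.5, 1.5) + rnorm(n)
    expect_equal(concordance_correlation(a, b), lin_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("concordance is symmetric, shift-invariant and bounded by Pearson r", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    a <- rnorm(n)
    b <- a + rnorm(n, sd = 0.5)
    pc <- concordance_correlation(a, b)
    expect_equal(pc, concordance_correlation(b, a), tolerance = 1e-12)
    expect_equal(pc, concordance_correlation(a + 3.7, b + 3.7),
                 tolerance = 1e-9)
    expect_lte(abs(pc), abs(cor(a, b)) + 1e-12)
  }
})

test_that("concordance input validation", {
  expect_error(concordance_correlation(1:2, 1:2),
               class = "lungqct_parameter_error")
  expect_error(concordance_correlation(1:4, 1:5),
               class = "lungqct_parameter_error")
  expect_error(concordance_correlation(rep(2, 5), rep(2, 5)),
               class = "lungqct_parameter_error")
})

test_that("the descriptive agreement scale honours its printed boundaries", {
  expect_identical(classify_agreement(0.89), "poor")
  expect_identical(classify_agreement(0.90), "moderate")
  expect_identical(classify_agreement(0.95), "moderate")
  expect_identical(classify_agreement(0.9500001), "substantial")
  expect_identical(classify_agreement(0.99), "substantial")
  expect_identical(classify_agreement(0.998), "almost perfect")
  expect_identical(classify_agreement(-0.5), "poor")
  expect_error(classify_agreement(1.2), class = "lungqct_parameter_error")
})

test_that("signed-rank p equals the exact enumeration for a pure shift", {
  res <- wilcoxon_signed_rank(1:8, 1:8 + 2)
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 2 / 256)
  expect_identical(res$method, "exact")
})

test_that("identical series give the degenerate flag with p = 1", {
  res <- wilcoxon_signed_rank(1:6, 1:6)
  expect_true(res$degenerate)
  expect_identical(res$p_value, 1)
})

test_that("exact signed-rank p matches brute-force enumeration, ties included", {
  set.seed(10)
  for (i in 1:12) {
    n <- sample(5:12, 1)
    x <- round(rnorm(n), 1)
    y <- round(x + rnorm(n, 0.3, 0.7), 1)
    if (sum(x != y) < 5) next
    expect_identical(wilcoxon_signed_rank(x, y)$p_value,
                     signed_rank_brute_force(x, y))
  }
})

test_that("exact p agrees with the tie-free closed form in stats", {
  set.seed(11)
  x <- rnorm(18)
  y <- x + rnorm(18, 0.3)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("the normal approximation converges to the exact null by n = 25", {
  set.seed(12)
  x <- rnorm(25)
  y <- x + rnorm(25, 0.2)
  p_exact <- wilcoxon_signed_rank(x, y, exact_max_n = 25)$p_value
  p_normal <- wilcoxon_signed_rank(x, y, exact_max_n = 10)$p_value
  expect_identical(wilcoxon_signed_rank(x, y, exact_max_n = 10)$method, "normal")
  expect_lt(abs(p_exact - p_normal), 0.01)
})

test_that("median_iqr uses linear interpolation and handles edge cases", {
  expect_equal(median_iqr(1:5), c(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(rep(7, 4)), c(median = 7, q1 = 7, q3 = 7))
  expect_equal(median_iqr(4.2), c(median = 4.2, q1 = 4.2, q3 = 4.2))
  expect_error(median_iqr(numeric(0)), class = "lungqct_parameter_error")
})

test_that("compare_algorithms produces one internally consistent row per measure", {
  set.seed(13)
  measures <- c("in950", "perc15", "exp856", "rvc", "ei_ratio",
                "la", "wa", "wa_pct", "pi")
  subj <- sprintf("S%02d", 1:10)
  long <- do.call(rbind, lapply(measures, function(m) {
    base <- rnorm(10, 10, 3)
    data.frame(
      subject = rep(subj, 2),
      measure = m,
      algorithm = rep(c("FBP", "IR"), each = 10),
      value = c(base, base + rnorm(10, 0.5))
    )
  }))
  tab <- compare_algorithms(long)
  expect_identical(nrow(tab), 9L)
  expect_identical(as.character(tab$measure), measures)
  g <- subset(long, measure == "rvc")
  direct <- concordance_correlation(g$value[g$algorithm == "FBP"],
                                    g$value[g$algorithm == "IR"])
  expect_equal(tab$pc[tab$measure == "rvc"], direct, tolerance = 1e-12)
  expect_identical(tab$agreement_class[tab$measure == "rvc"],
                   classify_agreement(direct))
})

test_that("duplicating one cohort as both algorithms gives perfect degenerate agreement", {
  long <- data.frame(
    subject = rep(sprintf("S%d", 1:6), 2),
    measure = "la",
    algorithm = rep(c("FBP", "IR"), each = 6),
    value = rep(c(9.1, 10.4, 11.8, 8.7, 12.2, 10.0), 2)
  )
  tab <- compare_algorithms(long)
  expect_equal(tab$pc, 1, tolerance = 1e-15)
  expect_true(tab$degenerate)
  expect_identical(tab$wilcoxon_p, 1)
})

test_that("subjects missing one algorithm are dropped with a message", {
  long <- data.frame(
    subject = c(rep(sprintf("S%d", 1:5), 2), "S6"),
    measure = "wa",
    algorithm = c(rep(c("FBP", "IR"), each = 5), "FBP"),
    value = c(rnorm(11, 30))
  )
  expect_message(tab <- compare_algorithms(long), "Dropping 1")
  expect_identical(tab$n, 5L)
})
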