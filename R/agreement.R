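#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two paired series as the correlation with the
#' line of identity:
#' `pc = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`,
#' penalizing both scatter and systematic departure from `y = x`. Moments
#' use the denominator `n` (the original moment form); with an `n - 1`
#' convention pc shifts slightly at small n.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 3).
#' @return The concordance correlation coefficient in \[-1, 1\].
#' @export
#' @examples
#' concordance_correlation(c(1, 2, 3), c(2, 2, 4)) # 2/3
concordance_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "lungqct_parameter_error")
  }
  n <- length(x)
  if (n < 3) {
    abort("At least 3 pairs are required.", class = "lungqct_parameter_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Inputs must be finite.", class = "lungqct_parameter_error")
  }
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    abort("Concordance undefined: both series constant with equal means.",
          class = "lungqct_parameter_error")
  }
  2 * sxy / denom
}

#' Descriptive agreement class for a concordance coefficient
#'
#' Classifies pc on the descriptive scale for continuous variables:
#' poor (pc < 0.90), moderate (0.90 <= pc <= 0.95), substantial
#' (0.95 < pc <= 0.99), almost perfect (pc > 0.99).
#'
#' @param pc Concordance correlation in \[-1, 1\].
#' @return One of `"poor"`, `"moderate"`, `"substantial"`,
#'   `"almost perfect"`.
#' @export
#' @examples
#' classify_agreement(0.95) # boundary: still "moderate"
classify_agreement <- function(pc) {
  if (length(pc) != 1L || !is.finite(pc) || pc < -1 || pc > 1) {
    abort("`pc` must be a single value in [-1, 1].",
          class = "lungqct_parameter_error")
  }
  if (pc < 0.90) "poor"
  else if (pc <= 0.95) "moderate"
  else if (pc <= 0.99) "substantial"
  else "almost perfect"
}

#' Wilcoxon signed-rank test with an exact small-sample null
#'
#' Two-sided paired signed-rank test. Zero differences are discarded before
#' ranking (classic treatment; their count is reported). For `n <=
#' exact_max_n` non-zero differences the p-value is computed from the exact
#' permutation null over all `2^n` sign assignments — including tied
#' midranks, via dynamic programming over the doubled ranks — and equals
#' brute-force sign-flip enumeration exactly. Larger samples use the normal
#' approximation with tie correction and a 0.5 continuity correction.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_max_n Largest n for the exact null; default 25.
#' @return A list with `statistic` (the smaller of the positive/negative
#'   rank sums), `p_value`, `n` (non-zero pairs), `n_zero` (discarded
#'   pairs), `method` (`"exact"`, `"normal"` or `"degenerate"`) and
#'   `degenerate` (`TRUE` when all differences are zero, reported as
#'   p = 1).
#' @export
#' @examples
#' wilcoxon_signed_rank(1:8, 1:8 + 2)$p_value # 2/256
wilcoxon_signed_rank <- function(x, y, exact_max_n = 25) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "lungqct_parameter_error")
  }
  d <- x - y
  if (any(!is.finite(d))) {
    abort("Inputs must be finite.", class = "lungqct_parameter_error")
  }
  nz <- d[d != 0]
  n_zero <- sum(d == 0)
  n <- length(nz)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n = 0L, n_zero = n_zero,
                method = "degenerate", degenerate = TRUE))
  }
  if (n < 5L) {
    abort("Fewer than 5 non-zero differences; signed-rank test not run.",
          class = "lungqct_parameter_error")
  }
  rk <- rank(abs(nz))
  w_pos <- sum(rk[nz > 0])
  w_neg <- sum(rk) - w_pos
  statistic <- min(w_pos, w_neg)

  if (n <= exact_max_n) {
    p <- exact_signed_rank_p(rk, w_pos)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (statistic - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z))
    method <- "normal"
  }
  list(statistic = statistic, p_value = p, n = n, n_zero = n_zero,
       method = method, degenerate = FALSE)
}

# Exact two-sided p via the permutation distribution of W+ over all sign
# assignments. Works on doubled (mid)ranks so tied ranks stay integral; the
# two-sided p sums the probability of |W+ - mean| at least as large as
# observed, which for this symmetric null equals twice the one-sided tail.
exact_signed_rank_p <- function(rk, w_pos) {
  dr <- as.integer(round(2 * rk))
  total <- sum(dr)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (g in dr) {
    shifted <- c(numeric(g), counts[seq_len(total + 1 - g)])
    counts <- counts + shifted
  }
  support <- 0:total
  # compare |2*W2 - total| as exact integers (W2 = doubled observed W+)
  dev_obs <- abs(as.integer(round(2 * 2 * w_pos)) - total)
  dev <- abs(2L * support - total)
  sum(counts[dev >= dev_obs]) / 2^length(rk)
}

#' Median and interquartile range
#'
#' Median with 25th and 75th percentiles, using linear interpolation between
#' order statistics at position `(n - 1) * p` (the same convention as the
#' attenuation percentile Perc15).
#'
#' @param values Numeric vector (n >= 1).
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
#' @examples
#' median_iqr(1:5)
median_iqr <- function(values) {
  if (length(values) == 0L || any(!is.finite(values))) {
    abort("`values` must be a non-empty finite vector.",
          class = "lungqct_parameter_error")
  }
  q <- quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Paired agreement analysis of one measure under two algorithms
#'
#' Bundles the agreement statistics for one paired measure: Lin's
#' concordance with its descriptive class, the signed-rank test, and
#' median/IQR summaries of both series and of the absolute within-subject
#' differences.
#'
#' @param x,y Paired per-subject values under algorithms A and B.
#' @param measure Optional measure name carried into the output.
#' @return An object of class `agreement_result`; see [tidy()] and
#'   [glance()] methods.
#' @export
agreement_test <- function(x, y, measure = NA_character_) {
  pc <- concordance_correlation(x, y)
  wt <- tryCatch(
    wilcoxon_signed_rank(x, y),
    lungqct_parameter_error = function(e) {
      list(statistic = NA_real_, p_value = NA_real_, n = length(x),
           n_zero = sum(x == y), method = "not run", degenerate = FALSE)
    }
  )
  structure(
    list(
      measure = measure,
      n = length(x),
      pc = pc,
      agreement_class = classify_agreement(pc),
      wilcoxon_stat = wt$statistic,
      wilcoxon_p = wt$p_value,
      wilcoxon_method = wt$method,
      degenerate = wt$degenerate,
      median_iqr_A = median_iqr(x),
      median_iqr_B = median_iqr(y),
      abs_diff_median_iqr = median_iqr(abs(x - y))
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result>%s n = %d\n",
              if (is.na(x$measure)) "" else paste0(" ", x$measure), x$n))
  cat(sprintf("  pc = %.4f (%s), Wilcoxon p = %.4g (%s)\n",
              x$pc, x$agreement_class, x$wilcoxon_p, x$wilcoxon_method))
  invisible(x)
}

#' Compare two reconstruction algorithms across all measures
#'
#' Takes a long table of per-subject quantitative CT measures under two
#' algorithms and produces one agreement row per measure: Lin's concordance
#' with its descriptive class, the Wilcoxon signed-rank p-value, and
#' median/IQR summaries for both algorithms and for the absolute
#' within-subject differences. Subjects missing either algorithm for a
#' measure are dropped from that row (with a message).
#'
#' @param data A data frame with columns `subject`, `measure`, `algorithm`
#'   and `value` (long format).
#' @param algorithm_a,algorithm_b Labels of the two algorithms in
#'   `data$algorithm`; A is the reference (e.g. `"FBP"`).
#' @return A tibble with one row per measure: `measure`, `n`, `pc`,
#'   `agreement_class`, `wilcoxon_stat`, `wilcoxon_p`, `degenerate`, the
#'   median/q1/q3 of each algorithm (`_a` / `_b` suffixes) and of the
#'   absolute differences (`abs_diff_` prefix). Classed
#'   `agreement_table` for [autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(
#'   subject = rep(sprintf("S%d", 1:6), each = 2),
#'   measure = "in950",
#'   algorithm = rep(c("FBP", "IR"), 6),
#'   value = c(3.1, 1.0, 4.0, 1.6, 5.2, 2.4, 2.2, 0.7, 7.9, 3.9, 6.0, 2.8)
#' )
#' compare_algorithms(d)
compare_algorithms <- function(data, algorithm_a = "FBP", algorithm_b = "IR") {
  req <- c("subject", "measure", "algorithm", "value")
  if (!all(req %in% names(data))) {
    abort(paste0("`data` needs columns: ", paste(req, collapse = ", ")),
          class = "lungqct_parameter_error")
  }
  data <- dplyr::filter(data, .data$algorithm %in% c(algorithm_a, algorithm_b))
  wide <- tidyr::pivot_wider(
    dplyr::select(data, "subject", "measure", "algorithm", "value"),
    names_from = "algorithm", values_from = "value"
  )
  complete <- !is.na(wide[[algorithm_a]]) & !is.na(wide[[algorithm_b]])
  if (any(!complete)) {
    inform(sprintf("Dropping %d subject-measure pairs missing one algorithm.",
                   sum(!complete)))
    wide <- wide[complete, ]
  }
  rows <- lapply(split(wide, factor(wide$measure, unique(wide$measure))),
                 function(g) {
    if (nrow(g) < 3) {
      warn(sprintf("Measure '%s': fewer than 3 complete pairs; skipped.",
                   g$measure[1]))
      return(NULL)
    }
    res <- agreement_test(g[[algorithm_a]], g[[algorithm_b]],
                          measure = g$measure[1])
    tidy(res)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("agreement_table", class(out))
  attr(out, "algorithms") <- c(a = algorithm_a, b = algorithm_b)
  out
}
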