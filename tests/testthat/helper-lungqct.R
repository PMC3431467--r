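# Shared fixtures and independent oracles, built in code.

# Small, fast phantom for unit tests.
small_params <- function(seed = 11, ...) {
  phantom_params(grid_shape = c(48, 48, 48), seed = seed, ...)
}

# A volume whose masked voxels are exactly `values` (stacked into a column),
# with an all-TRUE mask — for hand-computed densitometry cases.
vol_from_values <- function(values, spacing = c(1, 1, 1)) {
  v <- array(values, c(length(values), 1, 1))
  list(vol = ct_volume(v, spacing),
       mask = as_lung_mask(array(TRUE, dim(v)), spacing))
}

# Direct evaluation of Lin's moment formula (denominator n) — independent of
# the package implementation.
lin_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Brute-force signed-rank p by enumerating all 2^n sign assignments; the
# two-sided tail counts |W - E(W)| at least as extreme as observed
# (integer-exact via doubled ranks).
signed_rank_brute_force <- function(x, y) {
  d <- x - y
  nz <- d[d != 0]
  n <- length(nz)
  stopifnot(n >= 1, n <= 14)
  rk2 <- as.integer(round(2 * rank(abs(nz))))
  total <- sum(rk2)
  w_obs2 <- sum(rk2[nz > 0])
  dev_obs <- abs(2L * w_obs2 - total)
  hits <- 0L
  for (b in 0:(2^n - 1)) {
    s <- bitwAnd(b, bitwShiftL(1L, 0:(n - 1))) > 0
    w2 <- sum(rk2[s])
    if (abs(2L * w2 - total) >= dev_obs) hits <- hits + 1L
  }
  hits / 2^n
}

# Rotate a slice about its centre by `angle_deg` using bilinear resampling,
# for rotation-invariance checks.
rotate_slice <- function(slice, angle_deg) {
  d <- dim(slice$values)
  sp <- slice$spacing_mm
  ctr <- (d - 1) / 2 * sp
  th <- angle_deg * pi / 180
  x <- (seq_len(d[1]) - 1) * sp[1] - ctr[1]
  y <- (seq_len(d[2]) - 1) * sp[2] - ctr[2]
  gx <- outer(x, rep(1, d[2]))
  gy <- outer(rep(1, d[1]), y)
  sx <- cos(th) * gx - sin(th) * gy + ctr[1]
  sy <- sin(th) * gx + cos(th) * gy + ctr[2]
  out <- slice
  out$values <- matrix(
    lungqct:::interp_bilinear(slice, as.vector(sx), as.vector(sy)),
    d[1], d[2]
  )
  out
}
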