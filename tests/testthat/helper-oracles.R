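# Independent oracles. Each deliberately re-derives its quantity by a
# different route than the implementation under test.

# Per-voxel least-squares unmixing via lm.fit, one voxel at a time.
oracle_lsq_unmix <- function(cube, design) {
  nw <- dim(cube$intensities)[4]
  V <- matrix(cube$intensities, ncol = nw)
  out <- t(apply(V, 1, function(s) stats::lm.fit(design, s)$coefficients))
  colnames(out) <- c("hb", "hbo2")
  out
}

# Brute-force moment-preserving fraction: for a candidate fraction p,
# solve the two levels that preserve m1 and m2 exactly; the signed m3
# mismatch is strictly decreasing in p (two-point skewness is monotone at
# fixed mean/variance), so its unique root is Tsai's p0. Found by
# bisection via uniroot, independently of the closed-form cubic.
oracle_tsai_p0 <- function(hist) {
  p <- hist$counts / hist$total
  z <- hist$mids
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  v <- m2 - m1^2
  f <- function(q) {
    za <- m1 - sqrt((1 - q) / q * v)
    zb <- m1 + sqrt(q / (1 - q) * v)
    q * za^3 + (1 - q) * zb^3 - m3
  }
  stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

# Oracle threshold: brute-forced p0 pushed through the documented
# left-continuous ECDF inversion (smallest bin with CDF >= p0).
oracle_tsai_threshold <- function(hist) {
  p0 <- oracle_tsai_p0(hist)
  cdf <- cumsum(hist$counts) / hist$total
  k <- which(cdf >= p0 - 1e-9)[1]
  hist$bin_edges[k + 1L]
}

# Exact Mann-Whitney by full enumeration of rank assignments (tie-free).
oracle_mwu_exact <- function(a, b) {
  m <- length(a); N <- m + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(N, m)
  Us <- colSums(matrix(seq_len(N)[sets], nrow = m)) - m * (m + 1) / 2
  lower <- mean(Us <= U_obs); upper <- mean(Us >= U_obs)
  list(U = U_obs, p = min(1, 2 * min(lower, upper)))
}

# Brute-force normalised cross-correlation scan for the frame offset.
oracle_offset_scan <- function(a, b, max_shift) {
  W <- ncol(a)
  best <- c(offset = NA, score = -Inf)
  for (s in 0:max_shift) {
    x <- c(a[, (s + 1):W]); y <- c(b[, 1:(W - s)])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    if (r > best["score"]) best <- c(offset = s, score = r)
  }
  best
}

# Manual type-7 (linear interpolation) quantile from sorted values.
oracle_quantile7 <- function(x, probs) {
  x <- sort(x); n <- length(x)
  vapply(probs, function(p) {
    h <- (n - 1) * p
    lo <- floor(h) + 1
    if (lo >= n) return(x[n])
    x[lo] + (h - floor(h)) * (x[lo + 1] - x[lo])
  }, numeric(1))
}

# Small standard phantom used across tests: one axial vessel on a coarse
# grid, noiseless unless asked otherwise.
test_phantom <- function(so2 = 0.373, noise_sigma = 0, seed = 1,
                         fluence = 0, background = 0,
                         geometry = voxel_geometry(c(30, 30, 20), 500, 400),
                         radius = 1) {
  v <- vessel_spec(c(0, 7, 4), c(geometry$extent_mm[1], 7, 4), radius,
                   hb = 1 - so2, hbo2 = so2)
  make_finger_phantom(phantom_spec(
    geometry, list(v), fluence_decay_constant = fluence,
    background_level = background, noise_sigma = noise_sigma, seed = seed))
}

# Peak in-vessel forward signal for a given sO2 (fluence 1), used to set
# noise as a fraction of peak signal.
peak_signal <- function(so2, wavelengths = c(700, 730, 760, 800, 850)) {
  A <- build_design_matrix(wavelengths)
  max(log(10) * (A[, "eps_hb"] * (1 - so2) + A[, "eps_hbo2"] * so2))
}
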