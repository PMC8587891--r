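# Orthonormal discrete wavelet transform (Daubechies-6) with periodic
# extension, plus the soft-threshold / BayesShrink pieces used by the
# denoiser. Implemented here because the transform is small and no wavelet
# package ships with the target R stack.

# db6 decomposition low-pass filter (12 taps, standard published constants).
.DB6_LO <- c(-0.0010773010853084796, 0.0047772575109455108,
             0.00055384220116149613, -0.03158203931748603,
             0.027522865530305727, 0.097501605587323043,
             -0.12976686756726194, -0.22626469396543983,
             0.31525035170919763, 0.75113390802109536,
             0.49462389039845306, 0.11154074335010947)

# Quadrature mirror high-pass: g[k] = (-1)^k h[L-1-k] (0-based k)
.DB6_HI <- rev(.DB6_LO) * (-1)^(seq_along(.DB6_LO) - 1)

# One analysis step with periodic extension: row i of the analysis operator
# holds the filter at circular offset 2(i-1). The operator is orthogonal
# (QMF conditions), so the synthesis step below is its transpose.
dwt_step <- function(x, lo = .DB6_LO, hi = .DB6_HI) {
  n <- length(x)
  m <- n %/% 2
  L <- length(lo)
  a <- d <- numeric(m)
  base <- 2 * (seq_len(m) - 1)          # 0-based row offsets
  for (k in seq_len(L)) {
    p <- (base + k - 1) %% n + 1
    a <- a + lo[k] * x[p]
    d <- d + hi[k] * x[p]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, lo = .DB6_LO, hi = .DB6_HI) {
  m <- length(a)
  n <- 2 * m
  L <- length(lo)
  x <- numeric(n)
  base <- 2 * (seq_len(m) - 1)
  for (k in seq_len(L)) {
    p <- (base + k - 1) %% n + 1
    contrib <- a * lo[k] + d * hi[k]
    # scatter-add; p has no duplicates for fixed k (offsets differ by 2)
    x[p] <- x[p] + contrib
  }
  x
}

# Multi-level periodized DWT. Pads x (by repeating the last sample) so each
# level has even length; returns coefficients plus bookkeeping to invert.
dwt_forward <- function(x, level) {
  n0 <- length(x)
  need <- 2^level
  pad <- (need - n0 %% need) %% need
  if (pad) x <- c(x, rep(x[n0], pad))
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, n0 = n0, level = level)
}

dwt_inverse <- function(w) {
  a <- w$approx
  for (j in rev(seq_len(w$level))) a <- idwt_step(a, w$details[[j]])
  a[seq_len(w$n0)]
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# BayesShrink per-level threshold: sigma_hat^2 / sigma_signal_j, with the
# noise level estimated from the finest detail by MAD/0.6745 and
# sigma_signal_j = sqrt(max(var(d_j) - sigma_hat^2, 0)). A level whose
# signal variance estimate collapses to zero is fully suppressed.
bayes_threshold <- function(d, sigma_hat) {
  s2 <- mean(d^2) - sigma_hat^2
  if (s2 <= 0) return(Inf)
  sigma_hat^2 / sqrt(s2)
}
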