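# Periodic discrete wavelet transform with the 8-tap Daubechies
# extremal-phase filter, plus universal soft-threshold denoising.
# Implemented as a plain filter bank; the transform is orthogonal on
# even-length inputs, and odd lengths are handled by symmetric padding.

# 8-tap Daubechies scaling filter (orthonormal, sum = sqrt(2)).
.db8_h <- c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)
.db8_g <- rev(.db8_h) * c(1, -1, 1, -1, 1, -1, 1, -1)

# One periodic analysis step: x (even length) -> list(approx, detail).
.dwtStep <- function(x) {
  n <- length(x)
  n2 <- n %/% 2L
  idx0 <- 2L * (seq_len(n2) - 1L)          # 0-based positions of outputs
  a <- numeric(n2); d <- numeric(n2)
  for (k in seq_along(.db8_h)) {
    xi <- x[((idx0 + k - 1L) %% n) + 1L]
    a <- a + .db8_h[k] * xi
    d <- d + .db8_g[k] * xi
  }
  list(a = a, d = d)
}

# One periodic synthesis step: approx + detail -> signal of doubled length.
.idwtStep <- function(a, d) {
  n2 <- length(a)
  n <- 2L * n2
  up <- function(c) { z <- numeric(n); z[seq(1, n, by = 2)] <- c; z }
  ua <- up(a); ud <- up(d)
  x <- numeric(n)
  m0 <- seq_len(n) - 1L
  for (k in seq_along(.db8_h)) {
    j <- ((m0 - (k - 1L)) %% n) + 1L
    x <- x + .db8_h[k] * ua[j] + .db8_g[k] * ud[j]
  }
  x
}

# Multi-level periodic DWT. Pads symmetrically to a multiple of 2^level and
# records the original length for reconstruction.
dwt <- function(x, level) {
  n0 <- length(x)
  mult <- 2L^level
  if (n0 %% mult) {
    padLen <- mult - n0 %% mult
    x <- c(x, x[n0 - seq_len(padLen) + 1L])   # symmetric tail extension
  }
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- .dwtStep(a)
    a <- s$a
    details[[l]] <- s$d
  }
  list(approx = a, details = details, n = n0, level = level)
}

idwt <- function(w) {
  a <- w$approx
  for (l in rev(seq_len(w$level))) a <- .idwtStep(a, w$details[[l]])
  a[seq_len(w$n)]
}
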