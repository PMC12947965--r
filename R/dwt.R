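# Periodized orthogonal discrete wavelet transform (Daubechies-4, 8 taps).
#
# No wavelet package ships with the target R stack, so the small filter
# bank needed by the ECG denoiser is implemented here. Analysis is by
# correlation with the scaling/wavelet filters followed by dyadic
# downsampling on a circularly extended signal; synthesis is the adjoint,
# which for an orthonormal filter bank is the exact inverse. Filter taps
# follow the standard db4 scaling filter (four vanishing moments).

DB4_H <- c(0.230377813308855230, 0.714846570552541500,
           0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)
# quadrature mirror: g[m] = (-1)^m h[L-1-m]
DB4_G <- rev(DB4_H) * (-1)^(seq_along(DB4_H) - 1)

dwt_step <- function(x, flt) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  k <- seq(1L, n, by = 2L)  # output positions 2k (0-based)
  out <- numeric(n / 2L)
  for (m in seq_along(flt)) {
    idx <- ((k - 1L + m - 1L) %% n) + 1L
    out <- out + flt[m] * x[idx]
  }
  out
}

idwt_step <- function(ca, cd) {
  n <- 2L * length(ca)
  y <- numeric(n)
  k <- seq(1L, n, by = 2L)
  for (m in seq_along(DB4_H)) {
    idx <- ((k - 1L + m - 1L) %% n) + 1L
    contrib <- DB4_H[m] * ca + DB4_G[m] * cd
    y[idx] <- y[idx] + contrib
  }
  y
}

# Multi-level periodized decomposition. Returns list(a = approximation,
# d = list of detail vectors, level 1 first, n_orig for unpadding).
dwt_periodized <- function(x, levels = 4L) {
  n_orig <- length(x)
  block <- 2L^levels
  pad <- (block - n_orig %% block) %% block
  if (pad > 0L) {
    # reflect the tail to keep the periodic wrap mild
    ext <- rev(x)[seq_len(pad)]
    x <- c(x, ext)
  }
  d <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    d[[j]] <- dwt_step(a, DB4_G)
    a <- dwt_step(a, DB4_H)
  }
  list(a = a, d = d, n_orig = n_orig)
}

idwt_periodized <- function(dec) {
  a <- dec$a
  for (j in rev(seq_along(dec$d))) {
    a <- idwt_step(a, dec$d[[j]])
  }
  a[seq_len(dec$n_orig)]
}
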