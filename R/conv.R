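# FFT-based 2-D convolution helpers shared by the bathymetry generator and
# the terrain derivatives. Kernels here are small relative to typical grids,
# but the BPI annulus at 10 km outer radius on a 100 m grid spans 201x201
# cells, which rules out direct looping in R.

# "same"-size linear convolution of matrix a with kernel k (odd dimensions).
conv2_same <- function(a, k) {
  na <- nrow(a); ma <- ncol(a)
  nk <- nrow(k); mk <- ncol(k)
  stopifnot(nk %% 2L == 1L, mk %% 2L == 1L)
  nr <- na + nk - 1L; nc <- ma + mk - 1L
  pa <- matrix(0, nr, nc); pa[seq_len(na), seq_len(ma)] <- a
  pk <- matrix(0, nr, nc); pk[seq_len(nk), seq_len(mk)] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    (nr * nc)
  r0 <- (nk - 1L) %/% 2L
  c0 <- (mk - 1L) %/% 2L
  full[r0 + seq_len(na), c0 + seq_len(ma)]
}

# Neighbourhood mean with NA-awareness: mean of `m` over the footprint given
# by logical/0-1 kernel `k`, using only available (finite) cells.
neighbourhood_mean <- function(m, k) {
  ok <- is.finite(m)
  mz <- m
  mz[!ok] <- 0
  s <- conv2_same(mz, k)
  n <- conv2_same(ok + 0, k)
  out <- s / n
  out[n < 0.5] <- NA_real_  # no contributing cell at all
  out[!ok] <- NA_real_
  out
}

# 0/1 disc (or annulus) kernel in cell units; membership by centre distance.
disc_kernel <- function(radius_cells, inner_cells = -1, drop_centre = FALSE) {
  r <- ceiling(radius_cells)
  ix <- -r:r
  d <- sqrt(outer(ix^2, ix^2, "+"))
  k <- (d <= radius_cells & d > inner_cells) + 0
  if (drop_centre) k[r + 1L, r + 1L] <- 0
  k
}

# Gaussian smoothing with edge renormalisation (used for correlated noise).
gauss_smooth <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_cells))
  ix <- -r:r
  k1 <- exp(-ix^2 / (2 * sigma_cells^2))
  k <- outer(k1, k1)
  conv2_same(m, k) / conv2_same(matrix(1, nrow(m), ncol(m)), k)
}
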