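# Undecimated (MODWT / a-trous) discrete wavelet transform with the db6 basis.
#
# The beat detector consumes only the low-frequency approximation
# reconstruction, for which the undecimated transform is the right tool: it
# shares the db6 analysis filter pair with the decimated pyramid but is
# shift-invariant and, because synthesis is the exact adjoint of analysis,
# the approximation reconstruction is a symmetric (zero-phase) operator --
# beat peak positions are not displaced.

# db6 scaling (low-pass) filter, orthonormal, sum = sqrt(2)
.DB6_LO <- c(-1.07730108499558e-03,  4.77725751094551e-03,  5.53842200993802e-04,
             -3.15820393180312e-02,  2.75228655300163e-02,  9.75016055870794e-02,
             -1.29766867567096e-01, -2.26264693965169e-01,  3.15250351709243e-01,
              7.51133908021578e-01,  4.94623890398385e-01,  1.11540743350080e-01)

# quadrature-mirror high-pass
.db6_hi <- function() rev(.DB6_LO) * (-1)^(seq_along(.DB6_LO))

# circular filtering with filter upsampled by `stride`:
#   y[t] = sum_k f[k] x[(t - stride*(k-1)) mod N]
.circ_filt <- function(x, f, stride) {
  N <- length(x); y <- numeric(N); tt <- seq_len(N)
  for (k in seq_along(f))
    y <- y + f[k] * x[((tt - 1L - stride * (k - 1L)) %% N) + 1L]
  y
}

# adjoint of .circ_filt
.circ_filt_t <- function(x, f, stride) {
  N <- length(x); y <- numeric(N); tt <- seq_len(N)
  for (k in seq_along(f))
    y <- y + f[k] * x[((tt - 1L + stride * (k - 1L)) %% N) + 1L]
  y
}

# one analysis level of the undecimated transform (filters pre-scaled by 1/sqrt(2))
.modwt_level <- function(a, lo, hi, level) {
  stride <- 2L^(level - 1L)
  list(a = .circ_filt(a, lo, stride), d = .circ_filt(a, hi, stride))
}

.reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  c(rev(x[2:(p + 1L)]), x, rev(x[(n - p):(n - 1L)]))
}

# Multiresolution components of x at `level`: the smooth (approximation
# reconstruction with all details zeroed) and, optionally, the detail.
# `pad` reflection samples on each side suppress circular wrap-around.
.modwt_mra <- function(x, level, pad = 512L, what = c("smooth", "detail")) {
  what <- match.arg(what)
  lo <- .DB6_LO / sqrt(2)
  hi <- .db6_hi() / sqrt(2)
  xp <- .reflect_pad(x, pad)
  a <- xp
  if (what == "smooth") {
    for (j in seq_len(level)) a <- .circ_filt(a, lo, 2L^(j - 1L))
    for (j in rev(seq_len(level))) a <- .circ_filt_t(a, lo, 2L^(j - 1L))
  } else {
    if (level > 1L)
      for (j in seq_len(level - 1L)) a <- .circ_filt(a, lo, 2L^(j - 1L))
    a <- .circ_filt(a, hi, 2L^(level - 1L))
    a <- .circ_filt_t(a, hi, 2L^(level - 1L))
    if (level > 1L)
      for (j in rev(seq_len(level - 1L))) a <- .circ_filt_t(a, lo, 2L^(j - 1L))
  }
  p <- min(pad, length(x) - 1L)
  a[(p + 1L):(p + length(x))]
}
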