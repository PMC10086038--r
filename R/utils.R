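# Internal numerical helpers shared across modules.

# Derive a child seed from a master seed and an index; stays below 2^31.
.childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * as.numeric(index)) %%
               2147483647)
}

# 1/f ("pink") noise, n samples x m columns, unit sd per column.
# White Gaussian noise shaped to a ~1/f amplitude spectrum with a 3-pole /
# 3-zero IIR approximation (accurate over the band relevant here).
.pinkNoise <- function(n, m) {
  if (n < 8L) return(matrix(stats::rnorm(n * m), n, m))
  .pinkShape(matrix(stats::rnorm(n * m), n, m))
}

# Zero-phase FIR low-pass applied down the columns of a matrix via FFT
# convolution with reflection padding; b must be a linear-phase (symmetric)
# FIR kernel of odd length.
.firFilterMat <- function(mat, b) {
  L <- length(b)
  half <- (L - 1L) %/% 2L
  n <- nrow(mat)
  pad <- min(L, n - 1L)
  top <- mat[pad:1, , drop = FALSE]
  bot <- mat[n:(n - pad + 1L), , drop = FALSE]
  xp <- rbind(top, mat, bot)
  np <- nrow(xp)
  nf <- stats::nextn(np + L - 1L, 2)
  B <- stats::fft(c(b, rep(0, nf - L)))
  X <- stats::mvfft(rbind(xp, matrix(0, nf - np, ncol(mat))))
  Y <- Re(stats::mvfft(X * B, inverse = TRUE)) / nf
  Y[(pad + half) + seq_len(n), , drop = FALSE]
}

# Row-wise medians of a matrix.
.rowMedians <- function(x) {
  n <- ncol(x)
  if (n == 1L) return(x[, 1L])
  if (n == 2L) return((x[, 1L] + x[, 2L]) / 2)
  .rowMediansC(x)
}

# Runs of TRUE in a logical vector: matrix with columns start, length.
.trueRuns <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], length = r$lengths[r$values])
}

.assertScalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar", name), call. = FALSE)
  invisible(x)
}
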