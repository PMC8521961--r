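# Zero-phase band filtering on a matrix of equal-length segments.
# Implemented in the frequency domain with a Butterworth magnitude
# response and reflected borders: applying a real, symmetric |H(f)| via
# FFT is zero-phase by construction (no forward-backward pass needed),
# and a whole night of 30 s segments is filtered in one mvfft call.

butter_mag <- function(f, flo, fhi, order) {
  h <- rep(1, length(f))
  if (!is.null(flo) && flo > 0) {
    r <- (f / flo)^order
    h <- h * r / sqrt(1 + r^2)
  }
  if (!is.null(fhi)) h <- h / sqrt(1 + (f / fhi)^(2 * order))
  h
}

# X: one segment per column; returns filtered matrix of the same shape
fft_bandpass <- function(X, rate, flo, fhi, order, pad_s = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  npad <- min(n - 1L, round(pad_s * rate))
  if (npad > 0L)
    X <- rbind(X[npad:1L, , drop = FALSE], X,
               X[n:(n - npad + 1L), , drop = FALSE])
  N <- nrow(X)
  f <- (seq_len(N) - 1L) / N * rate
  f <- pmin(f, rate - f)                    # fold to two-sided symmetry
  H <- butter_mag(f, flo, fhi, order)
  Y <- Re(stats::mvfft(stats::mvfft(X) * H, inverse = TRUE)) / N
  Y[npad + seq_len(n), , drop = FALSE]
}

# centered moving average of width w (cumsum based; edges renormalized)
moving_avg <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  hw1 <- (w - 1L) %/% 2L
  hw2 <- w - 1L - hw1
  lo <- pmax(seq_len(n) - hw1, 1L)
  hi <- pmin(seq_len(n) + hw2, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
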