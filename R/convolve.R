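# Small dense 2D cross-correlation, "valid" region only.  Kernels here are
# at most 4x4, so shifting the image once per tap and accumulating is both
# simple and fast; boundaries are never padded (padding artifacts would
# dominate the sharpness sums).
conv2_valid <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (H < kh || W < kw)
    stop("frame smaller than the convolution kernel", call. = FALSE)
  out <- matrix(0, H - kh + 1L, W - kw + 1L)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      k <- kernel[a, b]
      if (k == 0) next
      out <- out + k * img[a:(a + H - kh), b:(b + W - kw), drop = FALSE]
    }
  }
  out
}

# Periodic Gaussian low-pass via the FFT.  Exact for the periodic band-pass
# scenes generated by the synthetic module and free of edge artifacts.
gaussian_blur_periodic <- function(img, sigma) {
  if (sigma <= 0) return(img)
  H <- nrow(img); W <- ncol(img)
  fr <- fft_freqs(H); fc <- fft_freqs(W)
  transfer <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, "+"))
  Re(stats::fft(stats::fft(img) * transfer, inverse = TRUE)) / (H * W)
}

# DFT sample frequencies in cycles/pixel, matching R's fft ordering.
fft_freqs <- function(n) {
  k <- c(seq.int(0L, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1L), -1L))
  k / n
}
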