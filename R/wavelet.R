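# One-level 2D discrete wavelet transform with the Daubechies-6 filter
# pair and periodic (circular) signal extension.  Periodization keeps the
# transform orthonormal on even-length signals, so detail bands vanish
# exactly on constant input and coefficient energy is preserved.
# Filter taps are the standard published db6 decomposition coefficients.

db6_dec_lo <- c(-1.0773010853084796e-03, 4.7772575109455108e-03,
                5.5384220116149613e-04, -3.1582039317486030e-02,
                2.7522865530305727e-02, 9.7501605587323043e-02,
                -1.2976686756726194e-01, -2.2626469396543983e-01,
                3.1525035170919763e-01, 7.5113390802109536e-01,
                4.9462389039845306e-01, 1.1154074335010947e-01)

db6_dec_hi <- c(-1.1154074335010947e-01, 4.9462389039845306e-01,
                -7.5113390802109536e-01, 3.1525035170919763e-01,
                2.2626469396543983e-01, -1.2976686756726194e-01,
                -9.7501605587323043e-02, 2.7522865530305727e-02,
                3.1582039317486030e-02, 5.5384220116149613e-04,
                -4.7772575109455108e-03, -1.0773010853084796e-03)

# Downsampled circular correlation along columns: Y[m, ] = sum_t f[t] *
# X[(2(m-1) + t - 1) mod n + 1, ].  Vectorized over the filter taps.
dwt_step_cols <- function(X, f) {
  n <- nrow(X)
  m <- n %/% 2L
  base <- 2L * (seq_len(m) - 1L)
  Y <- matrix(0, m, ncol(X))
  for (t in seq_along(f)) {
    idx <- (base + t - 1L) %% n + 1L
    Y <- Y + f[t] * X[idx, , drop = FALSE]
  }
  Y
}

#' One-level 2D Daubechies-6 wavelet decomposition
#'
#' Periodic extension; both frame dimensions must be even and at least
#' the filter length (12).
#'
#' @param x numeric matrix.
#' @return list with approximation `ll` and detail bands `hl` (rows
#'   high-pass), `lh` (columns high-pass) and `hh`.
#' @export
dwt2_db6 <- function(x) {
  if (nrow(x) < 12L || ncol(x) < 12L)
    stop("frame too small for the Daubechies-6 filter (needs >= 12x12)",
         call. = FALSE)
  if (nrow(x) %% 2L || ncol(x) %% 2L)
    stop("frame dimensions must be even for the periodized DWT", call. = FALSE)
  lo_r <- dwt_step_cols(x, db6_dec_lo)
  hi_r <- dwt_step_cols(x, db6_dec_hi)
  list(ll = t(dwt_step_cols(t(lo_r), db6_dec_lo)),
       lh = t(dwt_step_cols(t(lo_r), db6_dec_hi)),
       hl = t(dwt_step_cols(t(hi_r), db6_dec_lo)),
       hh = t(dwt_step_cols(t(hi_r), db6_dec_hi)))
}
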