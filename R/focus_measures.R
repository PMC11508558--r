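# The 22 focus-measure operators.  Each maps one frame to a scalar
# sharpness value that is maximal (in magnitude, for the signed LOG/VOL5)
# at best focus.  Conventions shared by every operator:
#   * "valid" convolution region only -- boundaries are never padded;
#   * direction-selective operators (ABG, SAG, BRE, BOD, ACF, VOL5)
#     difference along the FIRST (row) index, the spatial axis of a
#     pushbroom hyperspectral frame; `axis = 2` flips this;
#   * histogram operators (ENT, LOG, WHS) work on integer gray levels up
#     to 2^bit_depth; non-integer frames are binned to 256 levels.

#' Focus-measure options
#'
#' @param threshold gradient threshold theta in intensity units, applied
#'   by TEN1/TEN2 (to the gradient magnitude) and ABG/SAG/BRE (to the
#'   absolute difference).  `"auto"` estimates 2x the robust detector
#'   noise sd from the dark frame when available, otherwise from a
#'   median-absolute-difference estimate on the frame itself.
#' @param histogram_bins number of gray levels for ENT/LOG/WHS; `NULL`
#'   uses the native `2^bit_depth` levels.
#' @param whs_power,whs_root exponent on the gray level and root on the
#'   histogram count in the weighted-histogram measure.
#' @param dct_block block size K of the blockwise discrete cosine
#'   transform.
#' @param axis differencing axis for the direction-selective operators:
#'   1 = rows (spatial axis of a hyperspectral frame), 2 = columns.
#' @return a list of class `fm_options`.
#' @export
fm_options <- function(threshold = 0, histogram_bins = NULL,
                       whs_power = 5, whs_root = 5,
                       dct_block = 8L, axis = 1L) {
  stopifnot(identical(threshold, "auto") || threshold >= 0,
            is.null(histogram_bins) || histogram_bins >= 2,
            axis %in% c(1L, 2L))
  structure(list(threshold = threshold, histogram_bins = histogram_bins,
                 whs_power = whs_power, whs_root = whs_root,
                 dct_block = as.integer(dct_block), axis = as.integer(axis)),
            class = "fm_options")
}

oriented_pixels <- function(frame, axis = 1L) {
  p <- as_pixel_matrix(frame)
  if (axis == 2L) t(p) else p
}

#' Robust detector-noise estimate
#'
#' Median-absolute-deviation estimate of the per-pixel noise standard
#' deviation from first differences along rows (texture inflates it, so
#' it is an upper bound on quiet frames).
#'
#' @param frame an [image_frame] or matrix.
#' @return estimated noise sd in intensity units.
#' @export
estimate_noise_sd <- function(frame) {
  p <- as_pixel_matrix(frame)
  d <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  stats::mad(as.numeric(d)) / sqrt(2)
}

resolve_threshold <- function(threshold, frame, dark = NULL) {
  if (!identical(threshold, "auto")) return(threshold)
  if (!is.null(dark)) 2 * stats::mad(as.numeric(as_pixel_matrix(dark)))
  else 2 * estimate_noise_sd(frame)
}

# -- gradient family ---------------------------------------------------------

sobel_kernel <- function(a) rbind(c(-1, 0, 1), c(-a, 0, a), c(-1, 0, 1))

#' Tenengrad focus measure
#'
#' Convolves the frame with a pair of edge-detection kernels (Sobel for
#' `a = 2`, the TEN1 variant; Prewitt for `a = 1`, TEN2) and sums the
#' squared gradient components over pixels whose gradient magnitude
#' exceeds `threshold`.
#'
#' @param frame an [image_frame] or numeric matrix.
#' @param a kernel centre weight: 2 = Sobel (TEN1), 1 = Prewitt (TEN2).
#' @param threshold gradient-magnitude threshold theta.
#' @return scalar sharpness value.
#' @export
fm_tenengrad <- function(frame, a = 2, threshold = 0) {
  p <- as_pixel_matrix(frame)
  k <- sobel_kernel(a)
  gx <- conv2_valid(p, k)
  gy <- conv2_valid(p, t(k))
  g2 <- gx^2 + gy^2
  sum(g2[g2 > threshold^2])
}

#' Laplacian-energy focus measures (EOL, SML, DLF)
#'
#' Second-derivative operators built on the 1D Laplacian `[-1, 2, -1]`:
#' `EOL` sums the squared total Laplacian, `SML` sums absolute horizontal
#' and vertical responses separately (so opposite signs cannot cancel),
#' and `DLF` extends SML with two diagonal Laplacian masks weighted
#' `1/sqrt(2)`.  All responses are accumulated over the common interior.
#'
#' @inheritParams fm_tenengrad
#' @param variant `"EOL"`, `"SML"` or `"DLF"`.
#' @return scalar sharpness value.
#' @export
fm_laplacian_energy <- function(frame, variant = c("EOL", "SML", "DLF")) {
  variant <- match.arg(variant)
  p <- as_pixel_matrix(frame)
  if (nrow(p) < 3L || ncol(p) < 3L)
    stop("frame smaller than the convolution kernel", call. = FALSE)
  H <- nrow(p); W <- ncol(p)
  lx <- conv2_valid(p, matrix(c(-1, 2, -1), 1L))[2:(H - 1L), , drop = FALSE]
  ly <- conv2_valid(p, matrix(c(-1, 2, -1), 3L))[, 2:(W - 1L), drop = FALSE]
  if (variant == "EOL") return(sum((lx + ly)^2))
  s <- sum(abs(lx)) + sum(abs(ly))
  if (variant == "SML") return(s)
  d1 <- matrix(c(0, 0, 1, 0, -2, 0, 1, 0, 0), 3L, byrow = TRUE) / sqrt(2)
  d2 <- matrix(c(1, 0, 0, 0, -2, 0, 0, 0, 1), 3L, byrow = TRUE) / sqrt(2)
  s + sum(abs(conv2_valid(p, d1))) + sum(abs(conv2_valid(p, d2)))
}

#' Thresholded derivative focus measures (ABG, SAG, BRE)
#'
#' Accumulates `|I(i, j) - I(i + k, j)|^p` along the spatial axis over
#' pixels where the absolute difference exceeds `threshold`.
#' `k = 1, p = 1` is the thresholded absolute gradient (ABG),
#' `k = 1, p = 2` the squared absolute gradient (SAG) and
#' `k = 2, p = 2` the Brenner function (BRE).
#'
#' @inheritParams fm_tenengrad
#' @param k pixel lag of the difference.
#' @param p exponent on the absolute difference.
#' @param axis differencing axis (1 = rows).
#' @return scalar sharpness value.
#' @export
fm_derivative <- function(frame, k = 1L, p = 1, threshold = 0, axis = 1L) {
  m <- oriented_pixels(frame, axis)
  n <- nrow(m)
  if (k >= n) stop("difference lag k must be smaller than the frame extent",
                   call. = FALSE)
  d <- abs(m[seq_len(n - k), , drop = FALSE] -
             m[seq_len(n - k) + k, , drop = FALSE])
  sum(d[d > threshold]^p)
}

#' Energy of image gradient (EIG)
#'
#' Sum of squared forward differences in both directions.
#'
#' @inheritParams fm_tenengrad
#' @return scalar sharpness value.
#' @export
fm_energy_of_gradient <- function(frame) {
  p <- as_pixel_matrix(frame)
  if (nrow(p) < 2L || ncol(p) < 2L) stop("frame must be at least 2x2",
                                         call. = FALSE)
  ix <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  iy <- p[, -1L, drop = FALSE] - p[, -ncol(p), drop = FALSE]
  sum(ix^2) + sum(iy^2)
}

#' Boddeke's focus measure (BOD)
#'
#' Squared central differences `(I(i+1, j) - I(i-1, j))^2` along a single
#' direction -- the spatial axis of a hyperspectral frame.
#'
#' @inheritParams fm_derivative
#' @return scalar sharpness value.
#' @export
fm_boddeke <- function(frame, axis = 1L) {
  m <- oriented_pixels(frame, axis)
  n <- nrow(m)
  if (n < 3L) stop("frame extent must be at least 3 along the differencing axis",
                   call. = FALSE)
  sum((m[3:n, , drop = FALSE] - m[seq_len(n - 2L), , drop = FALSE])^2)
}

# -- statistics family -------------------------------------------------------

#' Normalized variance (NVR)
#'
#' Population variance of the gray levels divided by the mean intensity.
#'
#' @inheritParams fm_tenengrad
#' @return scalar sharpness value.
#' @export
fm_normalized_variance <- function(frame) {
  p <- as_pixel_matrix(frame)
  mu <- mean(p)
  if (mu <= 0) stop("normalized variance undefined for zero-mean frame",
                    call. = FALSE)
  sum((p - mu)^2) / (mu * length(p))
}

#' Vollath's F4 autocorrelation measure (ACF)
#'
#' Difference between the lag-1 and lag-2 autocorrelation products along
#' the spatial axis.
#'
#' @inheritParams fm_derivative
#' @return scalar sharpness value.
#' @export
fm_vollath_f4 <- function(frame, axis = 1L) {
  m <- oriented_pixels(frame, axis)
  n <- nrow(m)
  if (n < 3L) stop("frame extent must be at least 3 along the lag axis",
                   call. = FALSE)
  sum(m[seq_len(n - 1L), , drop = FALSE] * m[2:n, , drop = FALSE]) -
    sum(m[seq_len(n - 2L), , drop = FALSE] * m[3:n, , drop = FALSE])
}

#' Vollath's F5 measure (VOL5)
#'
#' Lag-1 autocorrelation product minus `H * W * mu^2`; can be negative.
#'
#' @inheritParams fm_derivative
#' @return scalar value (signed).
#' @export
fm_vollath_f5 <- function(frame, axis = 1L) {
  m <- oriented_pixels(frame, axis)
  n <- nrow(m)
  if (n < 2L) stop("frame extent must be at least 2 along the lag axis",
                   call. = FALSE)
  sum(m[seq_len(n - 1L), , drop = FALSE] * m[2:n, , drop = FALSE]) -
    length(m) * mean(m)^2
}

# Histogram of gray levels: exact integer levels when the data are
# integer counts, otherwise equal-width binning to `bins` levels.
gray_histogram <- function(frame, bins = NULL) {
  p <- as_pixel_matrix(frame)
  bd <- if (inherits(frame, "image_frame")) frame$bit_depth else 16L
  native <- is.null(bins)
  if (native) bins <- 2L^bd
  v <- as.numeric(p)
  if (all(v == round(v)) && max(v) < bins) {
    h <- tabulate(as.integer(v) + 1L, nbins = bins)
    levels <- seq.int(0L, bins - 1L)
  } else {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      h <- c(length(v), integer(bins - 1L))
      levels <- seq.int(0L, bins - 1L)
    } else {
      idx <- pmin(floor((v - rng[1]) / diff(rng) * bins), bins - 1L)
      h <- tabulate(as.integer(idx) + 1L, nbins = bins)
      levels <- seq.int(0L, bins - 1L)
    }
  }
  list(h = h, levels = levels, n = length(v))
}

#' Histogram entropy (ENT)
#'
#' Shannon entropy in bits of the gray-level histogram; a focused image
#' carries more information than a defocused one.
#'
#' @inheritParams fm_tenengrad
#' @param bins number of gray levels (`NULL` = native `2^bit_depth`).
#' @return entropy in bits.
#' @export
fm_entropy <- function(frame, bins = NULL) {
  g <- gray_histogram(frame, bins)
  p <- g$h[g$h > 0] / g$n
  -sum(p * log2(p))
}

#' Variance of the log-histogram (LOG)
#'
#' Evaluated exactly as printed in its source:
#' `sum((l - E)^2 * log(p_l))` with `E = sum(l * log(p_l))` over occupied
#' levels.  Since `log(p_l) <= 0` the value is non-positive; focus curves
#' use its magnitude (see [normalize_curve()]).  Also known under the
#' alias `VAR`.
#'
#' @inheritParams fm_entropy
#' @return scalar value (non-positive).
#' @export
fm_log_histogram <- function(frame, bins = NULL) {
  g <- gray_histogram(frame, bins)
  occ <- g$h > 0
  p <- g$h[occ] / g$n
  l <- g$levels[occ]
  lp <- log(p)
  e <- sum(l * lp)
  sum((l - e)^2 * lp)
}

#' Weighted histogram (WHS)
#'
#' `sum(1e-15 * l^power * h(l)^(1/root))`: a focused image has more
#' bright pixels than a defocused one, so high gray levels are weighted
#' heavily.  The default exponents are the empirically determined 5/5.
#'
#' @inheritParams fm_entropy
#' @param power exponent on the gray level.
#' @param root root applied to the histogram count.
#' @return scalar sharpness value.
#' @export
fm_weighted_histogram <- function(frame, bins = NULL, power = 5, root = 5) {
  g <- gray_histogram(frame, bins)
  occ <- g$h > 0
  sum(1e-15 * g$levels[occ]^power * g$h[occ]^(1 / root))
}

# -- frequency family --------------------------------------------------------

next_pow2 <- function(n) 2L^ceiling(log2(n))

#' Fourier-domain focus measure (FFT)
#'
#' Zero-pads the frame to the next power of two per axis, takes the 2D
#' FFT, shifts DC to the spectrum centre and sums the magnitudes weighted
#' by radial frequency `sqrt(u^2 + v^2)`; the DC term gets weight 0.
#'
#' @inheritParams fm_tenengrad
#' @return scalar sharpness value.
#' @export
fm_fourier <- function(frame) {
  p <- as_pixel_matrix(frame)
  H <- next_pow2(nrow(p)); W <- next_pow2(ncol(p))
  padded <- matrix(0, H, W)
  padded[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  g <- abs(stats::fft(padded))
  # fftshift: DC moves to index floor(N/2)+1
  g <- g[c((H / 2 + 1):H, 1:(H / 2)), c((W / 2 + 1):W, 1:(W / 2))]
  u <- seq_len(H) - (H / 2 + 1L)
  v <- seq_len(W) - (W / 2 + 1L)
  w <- sqrt(outer(u^2, v^2, "+"))
  sum(w * g)
}

dct_matrix <- function(K) {
  Tm <- matrix(0, K, K)
  for (u in 0:(K - 1L)) {
    cu <- if (u == 0L) sqrt(1 / K) else sqrt(2 / K)
    Tm[u + 1L, ] <- cu * cos(pi * (2 * (0:(K - 1L)) + 1) * u / (2 * K))
  }
  Tm
}

#' Blockwise DCT focus measure (DCT)
#'
#' Orthonormal 2D DCT-II on K x K blocks (frame cropped to whole blocks);
#' the sharpness value is the total squared AC energy -- all squared
#' coefficients minus the DC term of each block.  By Parseval the AC
#' energy equals the pixel variance energy within each block, so the
#' value is invariant to a constant intensity offset.
#'
#' @inheritParams fm_tenengrad
#' @param block block size K.
#' @return scalar sharpness value.
#' @export
fm_dct <- function(frame, block = 8L) {
  p <- as_pixel_matrix(frame)
  K <- as.integer(block)
  nb_r <- nrow(p) %/% K; nb_c <- ncol(p) %/% K
  if (nb_r < 1L || nb_c < 1L)
    stop("frame smaller than one DCT block", call. = FALSE)
  Tm <- dct_matrix(K)
  total <- 0
  for (br in seq_len(nb_r)) {
    rows <- (br - 1L) * K + seq_len(K)
    for (bc in seq_len(nb_c)) {
      cols <- (bc - 1L) * K + seq_len(K)
      S <- Tm %*% p[rows, cols] %*% t(Tm)
      total <- total + sum(S^2) - S[1L, 1L]^2
    }
  }
  total
}

mdct_operator <- function() {
  matrix(c(1, 1, -1, -1,
           1, 1, -1, -1,
           -1, -1, 1, 1,
           -1, -1, 1, 1), 4L, 4L, byrow = TRUE)
}

#' Mid-frequency DCT focus measure (MFDCT)
#'
#' Convolves the frame with the 4x4 mid-frequency DCT operator (a +-1
#' checkerboard of 2x2 blocks) and sums the squared responses.
#'
#' @inheritParams fm_tenengrad
#' @return scalar sharpness value.
#' @export
fm_midfreq_dct <- function(frame) {
  p <- as_pixel_matrix(frame)
  if (nrow(p) < 4L || ncol(p) < 4L)
    stop("frame must be at least 4x4", call. = FALSE)
  sum(conv2_valid(p, mdct_operator())^2)
}

#' Wavelet focus measures (WL1, WL2, WL3)
#'
#' One-level 2D Daubechies-6 wavelet transform with periodic extension.
#' `WL1` sums the absolute detail coefficients of the hl, lh and hh
#' sub-bands; `WL2` sums, normalized by the frame area, the squared
#' deviations of the absolute coefficients around each band's mean
#' absolute value; `WL3` does the same on the signed coefficients.
#'
#' @inheritParams fm_tenengrad
#' @param variant `"WL1"`, `"WL2"` or `"WL3"`.
#' @return scalar sharpness value.
#' @export
fm_wavelet <- function(frame, variant = c("WL1", "WL2", "WL3")) {
  variant <- match.arg(variant)
  p <- as_pixel_matrix(frame)
  bands <- dwt2_db6(p)
  det <- list(bands$hl, bands$lh, bands$hh)
  if (variant == "WL1") return(sum(vapply(det, function(b) sum(abs(b)), 0)))
  n <- length(p)
  if (variant == "WL2") {
    s <- vapply(det, function(b) {
      ab <- abs(b); sum((ab - mean(ab))^2)
    }, 0)
  } else {
    s <- vapply(det, function(b) sum((b - mean(b))^2), 0)
  }
  sum(s) / n
}

# -- registry ----------------------------------------------------------------

fm_families <- c(
  TEN1 = "gradient", TEN2 = "gradient", EOL = "gradient", SML = "gradient",
  DLF = "gradient", ABG = "gradient", SAG = "gradient", BRE = "gradient",
  EIG = "gradient", BOD = "gradient",
  NVR = "statistics", ACF = "statistics", VOL5 = "statistics",
  ENT = "statistics", LOG = "statistics", WHS = "statistics",
  FFT = "frequency", DCT = "frequency", MFDCT = "frequency",
  WL1 = "frequency", WL2 = "frequency", WL3 = "frequency")

#' Focus-measure registry
#'
#' The 22 operators with their family assignment, in the fixed order used
#' throughout the package.  `LOG` also answers to the alias `VAR` used in
#' some published tables.
#'
#' @return data frame with columns `fm_id`, `family`, `signed`.
#' @export
fm_registry <- function() {
  data.frame(fm_id = names(fm_families),
             family = unname(fm_families),
             signed = names(fm_families) %in% c("LOG", "VOL5"),
             stringsAsFactors = FALSE)
}

resolve_fm_ids <- function(fms) {
  if (identical(fms, "all") || is.null(fms)) return(names(fm_families))
  fms <- toupper(fms)
  fms[fms == "VAR"] <- "LOG"
  bad <- setdiff(fms, names(fm_families))
  if (length(bad)) stop("unknown focus measure(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  fms
}

fm_evaluators <- function(opts) {
  th <- opts$threshold
  list(
    TEN1 = function(f) fm_tenengrad(f, a = 2, threshold = th),
    TEN2 = function(f) fm_tenengrad(f, a = 1, threshold = th),
    EOL = function(f) fm_laplacian_energy(f, "EOL"),
    SML = function(f) fm_laplacian_energy(f, "SML"),
    DLF = function(f) fm_laplacian_energy(f, "DLF"),
    ABG = function(f) fm_derivative(f, 1L, 1, th, opts$axis),
    SAG = function(f) fm_derivative(f, 1L, 2, th, opts$axis),
    BRE = function(f) fm_derivative(f, 2L, 2, th, opts$axis),
    EIG = function(f) fm_energy_of_gradient(f),
    BOD = function(f) fm_boddeke(f, opts$axis),
    NVR = function(f) fm_normalized_variance(f),
    ACF = function(f) fm_vollath_f4(f, opts$axis),
    VOL5 = function(f) fm_vollath_f5(f, opts$axis),
    ENT = function(f) fm_entropy(f, opts$histogram_bins),
    LOG = function(f) fm_log_histogram(f, opts$histogram_bins),
    WHS = function(f) fm_weighted_histogram(f, opts$histogram_bins,
                                            opts$whs_power, opts$whs_root),
    FFT = function(f) fm_fourier(f),
    DCT = function(f) fm_dct(f, opts$dct_block),
    MFDCT = function(f) fm_midfreq_dct(f),
    WL1 = function(f) fm_wavelet(f, "WL1"),
    WL2 = function(f) fm_wavelet(f, "WL2"),
    WL3 = function(f) fm_wavelet(f, "WL3"))
}

#' Evaluate all (or selected) focus measures on one frame
#'
#' Individual operator failures are recorded per entry (value `NA`,
#' message in `error`) and do not abort the evaluation.
#'
#' @param frame an [image_frame] or numeric matrix.
#' @param options an [fm_options] list.
#' @param fms `"all"` or a character vector of registry ids.
#' @param dark optional dark frame used by the `"auto"` threshold rule.
#' @return data frame with columns `fm_id`, `family`, `value`, `error`,
#'   in fixed registry order.
#' @export
compute_all_fms <- function(frame, options = fm_options(), fms = "all",
                            dark = NULL) {
  ids <- resolve_fm_ids(fms)
  opts <- options
  opts$threshold <- resolve_threshold(options$threshold, frame, dark)
  ev <- fm_evaluators(opts)
  vals <- numeric(length(ids))
  errs <- character(length(ids))
  for (i in seq_along(ids)) {
    r <- tryCatch(ev[[ids[i]]](frame),
                  error = function(e) structure(NA_real_, msg = conditionMessage(e)))
    vals[i] <- as.numeric(r)
    errs[i] <- if (is.null(attr(r, "msg"))) NA_character_ else attr(r, "msg")
  }
  data.frame(fm_id = ids, family = unname(fm_families[ids]),
             value = vals, error = errs, stringsAsFactors = FALSE)
}
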