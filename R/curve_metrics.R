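# Focus-curve metrics: the five per-curve ranking criteria.  All criteria
# are distances from the ideal (0 is best for accuracy and unimodality; a
# narrow width and a total variation of exactly 2 are the noiseless
# references for the remaining three).

#' Focus curve
#'
#' Per-position scalar values of one focus measure over a through-focus
#' stack.
#'
#' @param values numeric vector, one value per focal position.
#' @param z_um focal positions (defaults to step indices).
#' @param fm_id identifier of the measure that produced the curve.
#' @param normalized whether the values are already normalized.
#' @return object of class `focus_curve`.
#' @export
focus_curve <- function(values, z_um = seq_along(values), fm_id = NA_character_,
                        normalized = FALSE) {
  stopifnot(length(values) == length(z_um))
  structure(list(values = as.numeric(values), z_um = as.numeric(z_um),
                 fm_id = fm_id, normalized = isTRUE(normalized)),
            class = "focus_curve")
}

#' @export
print.focus_curve <- function(x, ...) {
  cat(sprintf("<focus_curve> %s: %d positions%s, peak at index %d\n",
              x$fm_id, length(x$values),
              if (x$normalized) " (normalized)" else "",
              peak_index(x$values)))
  invisible(x)
}

curve_values <- function(curve) {
  if (inherits(curve, "focus_curve")) curve$values else as.numeric(curve)
}

#' Normalize a focus curve to [0, 1] with peak 1
#'
#' Signed measures whose values are entirely non-positive (LOG) are first
#' replaced by their magnitude, so "maximum at best focus" semantics hold
#' for all 22 operators; the curve is then shifted so its minimum is 0
#' and scaled by its maximum.  Idempotent; a flat curve is an error.
#'
#' @param curve a [focus_curve] or numeric vector.
#' @return normalized [focus_curve] (or vector, matching the input type).
#' @export
normalize_curve <- function(curve) {
  v <- curve_values(curve)
  if (any(!is.finite(v))) stop("curve contains non-finite values", call. = FALSE)
  if (max(v) == min(v)) stop("cannot normalize a flat focus curve", call. = FALSE)
  if (max(v) <= 0) v <- -v
  v <- (v - min(v)) / (max(v) - min(v))
  if (inherits(curve, "focus_curve")) {
    curve$values <- v
    curve$normalized <- TRUE
    curve
  } else v
}

# Global peak index.  A plateau of equal maxima resolves to its midpoint;
# when the midpoint is ambiguous (even plateau) or maxima are scattered,
# the candidate nearest `reference` (if given, else the plateau centre,
# then the lower index) wins.
peak_index <- function(values, reference = NULL) {
  v <- curve_values(values)
  cand <- which(v == max(v))
  if (length(cand) == 1L) return(cand)
  target <- if (!is.null(reference)) reference
  else (min(cand) + max(cand)) / 2
  cand[order(abs(cand - target), cand)][1L]
}

#' Accuracy distance d_acc
#'
#' Absolute difference, in focus steps, between the curve's peak position
#' and the reference ("ideal") focus index from the PCA analysis.
#'
#' @param curve a normalized [focus_curve] or numeric vector.
#' @param reference_index reference focus index (e.g.
#'   `pca_focus_curve(stack)$best_focus_index`).
#' @return non-negative step distance.
#' @export
accuracy_distance <- function(curve, reference_index) {
  abs(peak_index(curve, reference = reference_index) - reference_index)
}

# Local maxima (plateau-aware) of a vector: returns the representative
# index and height of each interior peak.
local_maxima <- function(v) {
  n <- length(v)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) idx <- c(idx, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

# Topographic prominence of the peak at index p: height minus the higher
# of the two lowest points separating it from higher ground (or the
# signal end) on each side.
peak_prominence <- function(v, p) {
  h <- v[p]
  left <- if (p == 1L) h else {
    seg <- v[seq_len(p - 1L)]
    higher <- which(seg > h)
    min(v[(if (length(higher)) max(higher) else 1L):(p - 1L)])
  }
  right <- if (p == length(v)) h else {
    seg <- v[(p + 1L):length(v)]
    higher <- which(seg > h)
    hi <- if (length(higher)) p + min(higher) else length(v)
    min(v[(p + 1L):hi])
  }
  h - max(left, right)
}

#' Unimodality count d_uni
#'
#' Number of secondary local maxima with topographic prominence at least
#' `prominence`, excluding the global peak.  False local maxima hinder a
#' focus search; the optimal value is 0.
#'
#' @param curve a normalized [focus_curve] or numeric vector.
#' @param prominence prominence threshold as a fraction of the normalized
#'   height (default 0.05).
#' @return integer count of spurious peaks.
#' @export
unimodality_count <- function(curve, prominence = 0.05) {
  v <- curve_values(curve)
  peaks <- local_maxima(v)
  gp <- peak_index(v)
  peaks <- setdiff(peaks, gp)   # the chosen global peak is never spurious
  if (!length(peaks)) return(0L)
  sum(vapply(peaks, function(p) peak_prominence(v, p), 0) >= prominence)
}

#' Curve width at a fraction of the maximum
#'
#' Length in steps (linear interpolation between samples) of the
#' contiguous interval around the global peak where the normalized value
#' stays at or above `fraction`; `fraction = 0.5` is the FWHM (d_50) and
#' `0.9` the near-peak width (d_90).  If the curve never drops below the
#' level on one side, the width is clipped at the scanned span and
#' flagged.
#'
#' @param curve a normalized [focus_curve] or numeric vector.
#' @param fraction level in (0, 1).
#' @return list with `width` (steps), `left`, `right` (interpolated
#'   positions) and `clipped`.
#' @export
width_at_fraction <- function(curve, fraction = 0.5) {
  v <- curve_values(curve)
  stopifnot(fraction > 0, fraction < 1)
  n <- length(v)
  p <- peak_index(v)
  clipped <- FALSE
  i <- p
  while (i > 1L && v[i - 1L] >= fraction) i <- i - 1L
  left <- if (i == 1L) {
    if (v[1L] >= fraction) clipped <- TRUE
    1
  } else i - (v[i] - fraction) / (v[i] - v[i - 1L])
  j <- p
  while (j < n && v[j + 1L] >= fraction) j <- j + 1L
  right <- if (j == n) {
    if (v[n] >= fraction) clipped <- TRUE
    n
  } else j + (v[j] - fraction) / (v[j] - v[j + 1L])
  list(width = right - left, left = left, right = right, clipped = clipped)
}

#' Smoothness index d_smo
#'
#' Total variation (sum of absolute first differences) of the normalized
#' curve.  A noiseless unimodal normalized curve rises by 1 and falls by
#' 1, so 2 is the ideal anchor; zero-mean jitter strictly increases the
#' index.
#'
#' @param curve a normalized [focus_curve] or numeric vector.
#' @return non-negative total variation.
#' @export
smoothness_index <- function(curve) {
  v <- curve_values(curve)
  sum(abs(diff(v)))
}

#' Assemble the five ranking criteria for one focus curve
#'
#' Normalizes the curve (see [normalize_curve()]) and computes d_acc,
#' d_uni, d_50, d_90 and d_smo against the PCA reference index.  Widths
#' are reported as fractions of the scanned span so stacks of different
#' lengths are comparable before cross-FM normalization.
#'
#' @param curve a [focus_curve] or numeric vector (raw or normalized).
#' @param reference_index reference focus index.
#' @param prominence unimodality prominence threshold.
#' @return one-row data frame: `fm_id`, `d_acc`, `d_uni`, `d_50`, `d_90`,
#'   `d_smo`, `width_clipped`.
#' @export
criterion_vector <- function(curve, reference_index, prominence = 0.05) {
  fm_id <- if (inherits(curve, "focus_curve")) curve$fm_id else NA_character_
  nc <- normalize_curve(curve)
  v <- curve_values(nc)
  n <- length(v)
  w50 <- width_at_fraction(v, 0.5)
  w90 <- width_at_fraction(v, 0.9)
  data.frame(fm_id = fm_id,
             d_acc = accuracy_distance(v, reference_index),
             d_uni = unimodality_count(v, prominence),
             d_50 = w50$width / (n - 1L),
             d_90 = w90$width / (n - 1L),
             d_smo = smoothness_index(v),
             width_clipped = w50$clipped || w90$clipped,
             stringsAsFactors = FALSE)
}
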