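# PCA focus reference.  In hyperspectral stacks the instantaneous frames
# often carry no human-comprehensible visual anchor, so the "ideal" focus
# position is defined statistically: for each frame, count how many
# principal components of the standardized frame are needed to retain a
# fixed variance fraction (98-99%).  Out-of-focus frames are blur- and
# noise-dominated, spreading variance over many components; the count
# curve attains its global minimum at best focus.

#' Standardize a frame to zero mean and unit standard deviation
#'
#' Global scalar mean and (population) standard deviation.
#'
#' @param frame an [image_frame] or numeric matrix.
#' @return standardized numeric matrix.
#' @export
standardize_frame <- function(frame) {
  p <- as_pixel_matrix(frame)
  mu <- mean(p)
  s <- sqrt(mean((p - mu)^2))
  if (s == 0) stop("cannot standardize a constant frame", call. = FALSE)
  (p - mu) / s
}

#' Column covariance matrix of a standardized frame
#'
#' `C = (1 / (W * H)) * t(Im) %*% Im`; when the frame is wider than tall
#' the covariance is taken over the smaller axis (the spectrum of
#' `Im' Im` and `Im Im'` is identical up to zero padding, so the
#' component count is unaffected while the eigenproblem stays small).
#'
#' @param im standardized matrix (see [standardize_frame()]).
#' @return symmetric positive semi-definite covariance matrix.
#' @export
covariance_matrix <- function(im) {
  if (ncol(im) > nrow(im)) im <- t(im)
  C <- crossprod(im) / length(im)
  (C + t(C)) / 2
}

#' Number of principal components for a variance fraction
#'
#' Smallest k such that the k largest eigenvalues hold at least
#' `fraction` of the total variance.  Eigenvalues below
#' `1e-10 * lambda_max` are clamped to zero.
#'
#' @param C covariance matrix (or a precomputed eigenvalue vector).
#' @param fraction target variance fraction in (0, 1].
#' @return integer component count.
#' @export
components_for_fraction <- function(C, fraction = 0.99) {
  stopifnot(fraction > 0, fraction <= 1)
  ev <- if (is.matrix(C))
    eigen(C, symmetric = TRUE, only.values = TRUE)$values
  else sort(as.numeric(C), decreasing = TRUE)
  ev[ev < 1e-10 * max(ev, 0)] <- 0
  tot <- sum(ev)
  if (tot <= 0) stop("all-zero eigenvalue spectrum", call. = FALSE)
  cf <- cumsum(ev) / tot
  as.integer(which(cf >= fraction - 1e-12)[1L])
}

pca_component_count <- function(frame, fraction = 0.99) {
  components_for_fraction(covariance_matrix(standardize_frame(frame)), fraction)
}

#' PCA component-count focus curve
#'
#' One component count per frame; the reference ("ideal") focus is the
#' global minimum of the curve.  Degenerate (constant) frames are flagged
#' `NA` and excluded from the argmin.  Ties for the minimum are broken to
#' the index closest to the stack centre (deterministic and unbiased for
#' symmetric curves).
#'
#' @param stack a [focus_stack].
#' @param fraction variance fraction to preserve (default 0.99).
#' @return object of class `pca_focus_curve`: list with `z_um`, integer
#'   `counts`, `fraction` and `best_focus_index`.
#' @export
pca_focus_curve <- function(stack, fraction = 0.99) {
  stopifnot(inherits(stack, "focus_stack"))
  counts <- vapply(stack$frames, function(f)
    tryCatch(pca_component_count(f, fraction),
             error = function(e) NA_integer_), integer(1))
  if (all(is.na(counts)))
    stop("every frame in the stack is degenerate", call. = FALSE)
  best <- argmin_center_tie(counts, length(counts))
  structure(list(z_um = stack$z_um, counts = counts, fraction = fraction,
                 best_focus_index = best),
            class = "pca_focus_curve")
}

# Global argmin with ties resolved to the index nearest the stack centre
# (then to the lower index).  NA entries are excluded.
argmin_center_tie <- function(x, n) {
  m <- min(x, na.rm = TRUE)
  cand <- which(!is.na(x) & x == m)
  center <- (n + 1) / 2
  cand[order(abs(cand - center), cand)][1L]
}

#' @export
print.pca_focus_curve <- function(x, ...) {
  cat(sprintf("<pca_focus_curve> %d positions, fraction %.3g, best focus index %d (z = %g um)\n",
              length(x$counts), x$fraction, x$best_focus_index,
              x$z_um[x$best_focus_index]))
  invisible(x)
}
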