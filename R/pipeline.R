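# End-to-end orchestration: FM curves -> PCA reference -> criteria ->
# ranking tables.  All randomness is confined to the synthetic module;
# evaluation itself is deterministic, so a run is reproducible from its
# inputs and options alone.

#' Focus curves of selected measures over a stack
#'
#' @param stack a [focus_stack].
#' @param fms `"all"` or a character vector of registry ids.
#' @param options an [fm_options] list.
#' @return named list of raw (un-normalized) [focus_curve] objects.
#' @export
fm_curves <- function(stack, fms = "all", options = fm_options()) {
  stopifnot(inherits(stack, "focus_stack"))
  ids <- resolve_fm_ids(fms)
  vals <- lapply(stack$frames, compute_all_fms, options = options,
                 fms = ids, dark = stack$dark_frame)
  out <- lapply(seq_along(ids), function(i) {
    focus_curve(vapply(vals, function(v) v$value[i], 0),
                z_um = stack$z_um, fm_id = ids[i])
  })
  names(out) <- ids
  out
}

#' Evaluate one stack end to end
#'
#' Computes the focus curve of every selected measure, the PCA reference
#' curve, and the five-criterion vector of each measure against the PCA
#' best-focus index.  Individual measure failures (e.g. a flat curve)
#' are recorded and skipped, not fatal.
#'
#' @param stack a [focus_stack].
#' @param fms `"all"` or a character vector of registry ids.
#' @param options an [fm_options] list.
#' @param fraction PCA variance fraction for the reference.
#' @param roi optional [roi_spec] applied to every frame first.
#' @param prominence unimodality prominence threshold.
#' @param reference_index override the PCA reference index (used by the
#'   robustness protocol, where the reference comes from the clean
#'   parent stack).
#' @return list with `curves` (raw focus curves), `pca` (the
#'   [pca_focus_curve]), `reference_index` and `criteria` (one row per
#'   measure).
#' @export
evaluate_stack <- function(stack, fms = "all", options = fm_options(),
                           fraction = 0.99, roi = NULL, prominence = 0.05,
                           reference_index = NULL) {
  stopifnot(inherits(stack, "focus_stack"))
  if (!is.null(roi)) stack <- crop_roi(stack, roi)
  curves <- fm_curves(stack, fms, options)
  pca <- pca_focus_curve(stack, fraction)
  ref <- if (is.null(reference_index)) pca$best_focus_index else reference_index
  crit <- do.call(rbind, lapply(curves, function(cv) {
    tryCatch(criterion_vector(cv, ref, prominence),
             error = function(e) {
               warning("criterion vector failed for ", cv$fm_id, ": ",
                       conditionMessage(e))
               NULL
             })
  }))
  rownames(crit) <- NULL
  list(curves = curves, pca = pca, reference_index = ref, criteria = crit)
}

#' Benchmark a set of stacks and build ranking tables
#'
#' Evaluates every stack, averages the criterion vectors per measure,
#' normalizes each criterion to its per-family maximum and ranks by the
#' Euclidean overall score.  Optionally writes the per-stack criteria,
#' the aggregated table (CSV) and a Markdown report to `out_dir`.
#'
#' @param stacks list of [focus_stack] objects (at least one).
#' @param fms,options,fraction,roi,prominence passed to
#'   [evaluate_stack()].
#' @param out_dir optional output directory.
#' @return list with `per_stack` criteria, aggregated `means` and the
#'   `table` (a `ranking_table`).
#' @export
run_benchmark <- function(stacks, fms = "all", options = fm_options(),
                          fraction = 0.99, roi = NULL, prominence = 0.05,
                          out_dir = NULL) {
  if (inherits(stacks, "focus_stack")) stacks <- list(stacks)
  if (!length(stacks)) stop("run_benchmark needs at least one stack",
                            call. = FALSE)
  per_stack <- lapply(seq_along(stacks), function(i) {
    ev <- evaluate_stack(stacks[[i]], fms, options, fraction, roi, prominence)
    cbind(stack = i, ev$criteria)
  })
  all_crit <- do.call(rbind, per_stack)
  means <- aggregate_over_stacks(all_crit)
  table <- rank_table(normalize_distances(means))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(all_crit, file.path(out_dir, "criteria_per_stack.csv"),
                     row.names = FALSE)
    utils::write.csv(table, file.path(out_dir, "ranking.csv"),
                     row.names = FALSE)
    write_ranking_markdown(table, file.path(out_dir, "ranking.md"))
  }
  list(per_stack = all_crit, means = means, table = table)
}

#' Export a PCA focus curve as CSV
#'
#' @param pca a [pca_focus_curve].
#' @param path output CSV path (columns `z_um`, `n_components`).
#' @return `path`, invisibly.
#' @export
write_pca_curve <- function(pca, path) {
  utils::write.csv(data.frame(z_um = pca$z_um, n_components = pca$counts),
                   path, row.names = FALSE)
  invisible(path)
}
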