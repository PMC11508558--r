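# Ranking: average criterion vectors over stacks, normalize each
# criterion to its per-family maximum (so each distance carries equal
# weight in the overall score), take the Euclidean overall score D and
# rank ascending within family.

criterion_cols <- c("d_acc", "d_uni", "d_50", "d_90", "d_smo")

# Family lookup tolerant of ids outside the registry (grouped as "other").
fm_family_of <- function(ids) {
  fam <- unname(fm_families[ids])
  fam[is.na(fam)] <- "other"
  fam
}

#' Average criterion vectors across stacks
#'
#' Arithmetic mean per focus measure and criterion.  A measure absent
#' from every stack is dropped with a warning; per-stack failures simply
#' reduce that measure's `n_stacks`.
#'
#' @param vectors data frame of per-stack criterion vectors (rows as
#'   returned by [criterion_vector()], any number of stacks), or a list
#'   of such data frames.
#' @return data frame with one row per `fm_id`: mean criteria plus
#'   `n_stacks`.
#' @export
aggregate_over_stacks <- function(vectors) {
  if (is.list(vectors) && !is.data.frame(vectors))
    vectors <- do.call(rbind, vectors)
  ok <- stats::complete.cases(vectors[criterion_cols])
  if (!all(ok)) {
    warning(sum(!ok), " criterion vector(s) with missing values excluded")
    vectors <- vectors[ok, , drop = FALSE]
  }
  if (!nrow(vectors)) stop("no complete criterion vectors to aggregate",
                           call. = FALSE)
  ids <- unique(vectors$fm_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- vectors[vectors$fm_id == id, , drop = FALSE]
    cbind(data.frame(fm_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(sub[criterion_cols]))),
          data.frame(n_stacks = nrow(sub)))
  }))
  rownames(out) <- NULL
  out
}

#' Normalize mean distances to their per-family maxima
#'
#' Within each focus-measure family, every criterion column is divided by
#' its maximum over the family, so the worst measure scores 1.00 on that
#' criterion and all criteria carry equal weight in the overall score.
#' An all-zero column is left at zero.  Set `scope = "global"` to
#' normalize across all families instead.
#'
#' @param means data frame from [aggregate_over_stacks()] (must contain
#'   `fm_id` and the five criterion columns).
#' @param scope `"family"` (default) or `"global"`.
#' @return the data frame with criteria normalized and a `family` column
#'   attached.
#' @export
normalize_distances <- function(means, scope = c("family", "global")) {
  scope <- match.arg(scope)
  means$family <- fm_family_of(means$fm_id)
  groups <- if (scope == "family") split(means, means$family) else list(means)
  out <- do.call(rbind, lapply(groups, function(g) {
    for (cc in criterion_cols) {
      mx <- max(g[[cc]])
      if (mx > 0) g[[cc]] <- g[[cc]] / mx
    }
    g
  }))
  rownames(out) <- NULL
  out
}

#' Euclidean overall score D
#'
#' `D = sqrt(d_acc^2 + d_uni^2 + d_50^2 + d_90^2 + d_smo^2)` on the
#' normalized distances; the best focus measure has the lowest score.
#' Vectorized over rows.
#'
#' @param d_acc,d_uni,d_50,d_90,d_smo normalized criterion distances, or
#'   pass a data frame with those columns as the single first argument.
#' @return numeric score(s).
#' @export
overall_score <- function(d_acc, d_uni = NULL, d_50 = NULL, d_90 = NULL,
                          d_smo = NULL) {
  if (is.data.frame(d_acc)) {
    df <- d_acc
    return(sqrt(df$d_acc^2 + df$d_uni^2 + df$d_50^2 + df$d_90^2 + df$d_smo^2))
  }
  sqrt(d_acc^2 + d_uni^2 + d_50^2 + d_90^2 + d_smo^2)
}

#' Build a per-family ranking table
#'
#' Attaches the overall score and ranks measures 1..n ascending by score
#' within each family; exact ties share their order lexicographically by
#' `fm_id`.
#'
#' @param normalized data frame from [normalize_distances()].
#' @param digits rounding (half-up) applied to the reported columns; the
#'   ranking itself uses the unrounded scores.  `NULL` leaves values
#'   unrounded.
#' @return data frame of class `ranking_table`, ordered by family and
#'   rank.
#' @export
rank_table <- function(normalized, digits = 2L) {
  if (is.null(normalized$family))
    normalized$family <- fm_family_of(normalized$fm_id)
  normalized$overall <- overall_score(normalized)
  parts <- split(normalized, normalized$family)
  out <- do.call(rbind, lapply(parts, function(g) {
    ord <- order(g$overall, g$fm_id)
    g <- g[ord, , drop = FALSE]
    g$rank <- seq_len(nrow(g))
    g
  }))
  rownames(out) <- NULL
  if (!is.null(digits)) {
    for (cc in c(criterion_cols, "overall"))
      out[[cc]] <- round_half_up(out[[cc]], digits)
  }
  fam_order <- c("gradient", "frequency", "statistics")
  out <- out[order(match(out$family, fam_order), out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranking_table", class(out))
  out
}

# Round half away from zero, matching how the reference tables print.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a ranking table as Markdown
#'
#' Columns mirror the published layout: FM, Accuracy, Unimodality,
#' Width at 50%, Width at 90%, Smoothness, Overall Score, Ranking.
#'
#' @param table a `ranking_table`.
#' @param path output file; `NULL` returns the lines invisibly.
#' @return the Markdown lines, invisibly.
#' @export
write_ranking_markdown <- function(table, path = NULL) {
  fmt <- function(x) sprintf("%.2f", x)
  lines <- c("| FM | Accuracy | Unimodality | Width at 50% | Width at 90% | Smoothness | Overall Score | Ranking |",
             "|---|---|---|---|---|---|---|---|")
  for (fam in unique(table$family)) {
    g <- table[table$family == fam, , drop = FALSE]
    for (i in seq_len(nrow(g)))
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s | %s | %d |",
                                g$fm_id[i], fmt(g$d_acc[i]), fmt(g$d_uni[i]),
                                fmt(g$d_50[i]), fmt(g$d_90[i]), fmt(g$d_smo[i]),
                                fmt(g$overall[i]), g$rank[i]))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
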