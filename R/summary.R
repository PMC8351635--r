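# Per-taxon prevalence summaries: the survey's table-shaped output.

# Half-up integer rounding, the convention behind every printed percentage
# (95.4 -> 95, 76.8 -> 77, 18.5 -> 19). R's round() rounds half to even,
# which would disagree at .5 boundaries.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Prevalence as a whole-number percent
#'
#' @param k Count of positive genomes (0 <= k <= n).
#' @param n Total genomes (> 0).
#' @return `round(100 * k / n)` with half-up rounding.
#' @examples
#' prevalence(311, 326)  # 95
#' @export
prevalence <- function(k, n) {
  if (n <= 0) stop("prevalence undefined for n = 0")
  stopifnot(k >= 0, k <= n)
  round_half_up(100 * k / n)
}

#' Pooled prevalence over several groups
#'
#' Prevalence of a feature over the union of the selected groups:
#' `round(100 * sum(k) / sum(n))`. Lies between the minimum and maximum
#' of the constituent group prevalences.
#'
#' @param summaries List of `TaxonSummary` objects from
#'   [summarize_groups()].
#' @param feature Feature (matrix column) name.
#' @param groups Character vector of group names to pool (non-empty).
#' @return Whole-number percent.
#' @export
pooled_prevalence <- function(summaries, feature, groups) {
  stopifnot(length(groups) >= 1L)
  sel <- Filter(function(s) s$group_name %in% groups, summaries)
  if (length(sel) == 0L) stop("no summaries match the requested groups")
  k <- sum(vapply(sel, function(s) as.numeric(s$counts[[feature]]), 0))
  n <- sum(vapply(sel, function(s) as.numeric(s$n_genomes), 0))
  prevalence(k, n)
}

#' Conditional prevalence of one feature given another
#'
#' The prevalence of `feature` among genomes positive for
#' `condition_feature`, optionally restricted to a set of taxon groups.
#'
#' @param matrix A `PresenceAbsenceMatrix`.
#' @param feature,condition_feature Column names.
#' @param taxon_map Named character vector genome -> group (required when
#'   `group_filter` is given).
#' @param group_filter Optional character vector of group names.
#' @return Whole-number percent.
#' @export
conditional_prevalence <- function(matrix, feature, condition_feature,
                                   taxon_map = NULL, group_filter = NULL) {
  rows <- rownames(matrix)
  if (!is.null(group_filter)) {
    if (is.null(taxon_map)) stop("group_filter requires a taxon_map")
    rows <- rows[taxon_map[rows] %in% group_filter]
  }
  cond <- rows[matrix[rows, condition_feature] == 1L]
  if (length(cond) == 0L) stop("empty condition subset")
  prevalence(sum(matrix[cond, feature] == 1L), length(cond))
}

#' Summarize a cohort per taxon group
#'
#' Produces the table-shaped per-group summary: genome counts (split by
#' completeness when available), per-feature positive counts, and the
#' group mean [Fe-S]-motif proteome fraction as a percent at two
#' decimals. The mean weights genomes equally, not by proteome size.
#'
#' @param matrix A `PresenceAbsenceMatrix` (genomes x features).
#' @param fractions Named numeric vector genome -> [Fe-S] proteome
#'   fraction in \[0,1\] (may be `NULL`; the mean is then `NA`).
#' @param taxon_map Named character vector genome -> group label; every
#'   genome in the matrix must be labeled.
#' @param completeness Optional named character vector genome ->
#'   `"complete"`/`"draft"`.
#' @return A list of `TaxonSummary` objects (one per group, in label
#'   first-seen order): fields `group_name`, `n_genomes`, `n_complete`,
#'   `n_draft`, `counts` (named numeric per feature),
#'   `mean_fes_fraction_pct`.
#' @export
summarize_groups <- function(matrix, fractions = NULL, taxon_map,
                             completeness = NULL) {
  ids <- rownames(matrix)
  unlabeled <- ids[!ids %in% names(taxon_map)]
  if (length(unlabeled))
    stop("genomes without taxon label: ", paste(unlabeled, collapse = ", "))
  groups <- unique(unname(taxon_map[ids]))
  lapply(groups, function(g) {
    sel <- ids[taxon_map[ids] == g]
    sub <- matrix[sel, , drop = FALSE]
    counts <- colSums(sub == 1L)
    n_complete <- if (is.null(completeness)) NA_integer_ else
      sum(completeness[sel] == "complete")
    mean_fes <- if (is.null(fractions)) NA_real_ else
      round_half_up(100 * mean(fractions[sel]), 2)
    structure(list(group_name = g, n_genomes = length(sel),
                   n_complete = n_complete,
                   n_draft = if (is.na(n_complete)) NA_integer_ else
                     length(sel) - n_complete,
                   counts = counts,
                   mean_fes_fraction_pct = mean_fes),
              class = "TaxonSummary")
  })
}

#' @export
print.TaxonSummary <- function(x, ...) {
  cat(sprintf("TaxonSummary '%s': %d genomes", x$group_name, x$n_genomes))
  if (!is.na(x$mean_fes_fraction_pct))
    cat(sprintf(", mean [Fe-S] fraction %.2f%%", x$mean_fes_fraction_pct))
  cat("\n")
  invisible(x)
}

#' Write group summaries as a table-layout TSV
#'
#' One row per taxon group: genome counts, per-feature positive counts,
#' and the mean [Fe-S] fraction, in a fixed column layout.
#'
#' @param summaries List of `TaxonSummary`.
#' @param path TSV path.
#' @param features Feature columns to include (defaults to all).
#' @export
write_summary_table <- function(summaries, path, features = NULL) {
  if (is.null(features)) features <- names(summaries[[1L]]$counts)
  rows <- lapply(summaries, function(s) {
    data.frame(group = s$group_name, n_genomes = s$n_genomes,
               n_complete = s$n_complete, n_draft = s$n_draft,
               as.list(s$counts[features]),
               mean_fes_fraction_pct = s$mean_fes_fraction_pct,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
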