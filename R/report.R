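# Headline summaries: counts and percentages of ROIs with significant
# findings, direction tallies, and a plain-text report.

#' Count ROIs participating in significant edges
#'
#' An ROI counts as significant if it is an endpoint of at least one
#' significant edge in the comparison result. The percentage uses
#' half-up rounding to two decimals, i.e. it is exactly
#' `round_half_up(10000 * n_sig / n_total) / 100`.
#'
#' @param edge_results an `edge_comparison` from [compare_edges()].
#' @param n_total total number of ROIs in the universe being summarized.
#' @return list with `contrast`, `n_significant_rois`, `n_total_rois`,
#'   `percent`.
#' @export
summarize_significant_rois <- function(edge_results, n_total) {
  if (n_total <= 0) {
    hemifc_stop("hemifc_error_stat_input", "n_total must be positive")
  }
  sig <- edge_results[edge_results$significant, , drop = FALSE]
  rois <- unique(c(sig$seed_roi, sig$target_roi))
  n_sig <- length(rois)
  if (n_sig > n_total) {
    hemifc_stop("hemifc_error_stat_input",
                "more significant ROIs than n_total")
  }
  list(contrast = if (nrow(edge_results) > 0) edge_results$contrast[1] else NA,
       n_significant_rois = n_sig, n_total_rois = n_total,
       percent = round_half_up(10000 * n_sig / n_total) / 100,
       significant_rois = rois)
}

#' Tally lateralization directions in one group
#'
#' Counts ROIs whose paired rFC-vs-lFC test survives FDR at `alpha`,
#' split by the sign of the mean difference (rightward: mean rFC > mean
#' lFC).
#'
#' @param lateralization a `lateralization_table`.
#' @param group group label to tally.
#' @param alpha FDR significance level (default 0.05).
#' @return list with `n_rightward`, `n_leftward`, `n_asymmetric`.
#' @export
tally_directions <- function(lateralization, group, alpha = 0.05) {
  sub <- lateralization[lateralization$group == group, , drop = FALSE]
  sig <- !is.na(sub$q_fdr) & sub$q_fdr < alpha
  right <- sum(sig & sub$mean_rFC > sub$mean_lFC)
  left <- sum(sig & sub$mean_rFC < sub$mean_lFC)
  list(n_rightward = right, n_leftward = left, n_asymmetric = right + left)
}

#' Write a tidy result table with threshold metadata
#'
#' Tab-separated, with analysis thresholds recorded as `# key=value`
#' comment lines above the header so every output is self-describing.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param params named list of thresholds/settings to log.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, params = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(params)) {
    writeLines(sprintf("# %s=%s", k, format(params[[k]])), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Render a Markdown summary report
#'
#' Combines edge-comparison summaries and lateralization tallies into a
#' short human-readable report mirroring the headline statements a study
#' would print (counts and percentages of affected ROIs per contrast,
#' asymmetric-ROI tallies per group).
#'
#' @param edge_summaries named list of outputs of
#'   [summarize_significant_rois()] (names used as contrast labels).
#' @param lateralization a `lateralization_table`, or `NULL`.
#' @param path file to write; `NULL` returns the text invisibly instead.
#' @param alpha significance level reported for tallies.
#' @return the report lines, invisibly.
#' @export
render_report <- function(edge_summaries = list(), lateralization = NULL,
                          path = NULL, alpha = 0.05) {
  lines <- c("# Hemispheric connectivity asymmetry report", "")
  if (length(edge_summaries) > 0) {
    lines <- c(lines, "## Edge-wise group differences", "")
    for (nm in names(edge_summaries)) {
      s <- edge_summaries[[nm]]
      lines <- c(lines, sprintf(
        "- %s: %d of %d ROIs (%.2f%%) participate in significant edges",
        nm, s$n_significant_rois, s$n_total_rois, s$percent))
    }
    lines <- c(lines, "")
  }
  if (!is.null(lateralization)) {
    lines <- c(lines, sprintf("## Lateralized ROIs (FDR q < %.2f)", alpha), "")
    for (g in unique(lateralization$group)) {
      tl <- tally_directions(lateralization, g, alpha)
      lines <- c(lines, sprintf(
        "- %s: %d asymmetric ROIs (%d rightward, %d leftward)",
        g, tl$n_asymmetric, tl$n_rightward, tl$n_leftward))
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
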