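#' Overlap between two candidate lists
#'
#' Counts the genes shared by two top-candidate lists (e.g. the top-100
#' dropped-out genes of two screens run with different drugs); the
#' fraction is reported relative to the first list's size.
#'
#' @param list_a,list_b `candidate_list` objects or character vectors of
#'   gene ids.
#' @return List of class `overlap_result`: `overlap_count`,
#'   `overlap_fraction` (relative to `list_a`), `genes` (the shared ids).
#' @export
top_list_overlap <- function(list_a, list_b) {
  a <- if (is.character(list_a)) list_a else list_a$gene
  b <- if (is.character(list_b)) list_b else list_b$gene
  if (!length(a) || !length(b)) stop("both lists must be non-empty")
  shared <- intersect(a, b)
  structure(list(overlap_count = length(shared),
                 overlap_fraction = length(shared) / length(unique(a)),
                 genes = shared),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Top-list overlap: %d genes (%.1f%% of the reference list)\n",
              x$overlap_count, 100 * x$overlap_fraction))
  invisible(x)
}

#' Align a gene panel across two screens
#'
#' Builds the two-column comparison used for oncogene-panel heat maps:
#' the panel genes ordered by their score in screen A (descending, i.e.
#' most enriched first), with the matched score from screen B alongside.
#' Genes missing a score in either screen are dropped with a warning.
#' Equal scores keep the input panel order (stable sort).
#'
#' @param panel_genes character vector of panel genes.
#' @param summaries_a,summaries_b `gene_summary` (or `draco_table`)
#'   objects for the two screens at one timepoint.
#' @param value score column to compare: `"mean_lfc"` (default) or
#'   `"selected_lfc"`.
#' @return Data frame of class `oncogene_panel` with `gene`, `value_a`,
#'   `value_b`, ordered descending by `value_a`.
#' @export
align_panel <- function(panel_genes, summaries_a, summaries_b,
                        value = "mean_lfc") {
  if (!length(panel_genes)) stop("panel_genes must be non-empty")
  a <- as.data.frame(summaries_a)
  b <- as.data.frame(summaries_b)
  if (!value %in% names(a) || !value %in% names(b))
    stop("score column '", value, "' not present in both summaries")
  va <- a[[value]][match(panel_genes, a$gene)]
  vb <- b[[value]][match(panel_genes, b$gene)]
  ok <- !is.na(va) & !is.na(vb)
  if (any(!ok))
    warning(sum(!ok), " panel gene(s) missing from one of the screens ",
            "and dropped")
  out <- data.frame(gene = panel_genes[ok], value_a = va[ok],
                    value_b = vb[ok], stringsAsFactors = FALSE)
  out <- out[order(-out$value_a), , drop = FALSE]  # stable: ties keep order
  rownames(out) <- NULL
  structure(out, value = value,
            class = c("oncogene_panel", "data.frame"))
}

#' Rank correlations between the two screens of an aligned panel
#'
#' @param panel an `oncogene_panel` from [align_panel()].
#' @return List of class `comparison_result` with `pearson`, `kendall`
#'   (tau-b, tie-corrected) and `spearman` coefficients.
#' @export
panel_correlations <- function(panel) {
  df <- as.data.frame(panel)
  if (nrow(df) < 3) stop("need at least 3 genes")
  if (stats::sd(df$value_a) == 0 || stats::sd(df$value_b) == 0)
    stop("correlation undefined: zero variance in one screen's values")
  structure(list(
    pearson = stats::cor(df$value_a, df$value_b, method = "pearson"),
    kendall = stats::cor(df$value_a, df$value_b, method = "kendall"),
    spearman = stats::cor(df$value_a, df$value_b, method = "spearman")),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Screen comparison: Pearson %.3f / Kendall %.3f / Spearman %.3f\n",
              x$pearson, x$kendall, x$spearman))
  invisible(x)
}
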