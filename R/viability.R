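#' Compute relative viability from a 96-well absorbance plate
#'
#' Standard MTS-style processing: the mean media-only (blank) absorbance
#' is subtracted from every well, and viability is expressed as a
#' percentage of the mean vehicle-treated signal. Negative signals are
#' clamped to 0% and flagged.
#'
#' @param reads data frame with columns `well` and `absorbance`.
#' @param layout data frame with columns `well` and `condition`;
#'   conditions `"blank"` and `"vehicle"` are reserved and required.
#' @return List of class `viability_table`: `wells` (per-well signal,
#'   viability %, killing %, `clamped` flag) and `conditions` (per
#'   condition: n, mean/sd viability, mean killing = 100 - viability).
#' @export
compute_viability <- function(reads, layout) {
  need <- function(df, cols, what)
    if (!all(cols %in% names(df)))
      stop(what, " must have columns: ", paste(cols, collapse = ", "))
  need(reads, c("well", "absorbance"), "reads")
  need(layout, c("well", "condition"), "layout")
  df <- merge(reads, layout, by = "well")
  if (!any(df$condition == "blank")) stop("no blank wells in layout")
  if (!any(df$condition == "vehicle")) stop("no vehicle wells in layout")
  blank <- mean(df$absorbance[df$condition == "blank"])
  df$signal <- df$absorbance - blank
  vehicle <- mean(df$signal[df$condition == "vehicle"])
  if (vehicle <= 0)
    stop("plate invalid: mean vehicle signal is not positive")
  df$viability <- 100 * df$signal / vehicle
  df$clamped <- df$viability < 0
  df$viability[df$clamped] <- 0
  df$killing <- 100 - df$viability
  wells <- df[df$condition != "blank",
              c("well", "condition", "signal", "viability", "killing",
                "clamped")]
  rownames(wells) <- NULL
  agg <- do.call(rbind, lapply(split(wells, wells$condition), function(d)
    data.frame(condition = d$condition[1], n = nrow(d),
               viability = mean(d$viability),
               sd_viability = stats::sd(d$viability),
               killing = mean(d$killing), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(list(wells = wells, conditions = agg),
            class = "viability_table")
}

#' @export
print.viability_table <- function(x, ...) {
  cat("Viability (% of vehicle):\n")
  print(transform(x$conditions, viability = round(viability, 1),
                  sd_viability = round(sd_viability, 2),
                  killing = round(killing, 1)))
  invisible(x)
}

#' Map an additive-killing gap to an efficacy level
#'
#' Five hierarchical levels summarize how much extra killing a drug
#' combination adds over its most potent single agent: a gap below 20
#' percentage points is the low band (levels 1-2) and a gap of at least
#' 30 points is the maximal level 5. The internal cutoffs splitting the
#' bands default to 10 (level 1 vs 2) and 25 (level 3 vs 4).
#'
#' @param gap additive-killing gap in percentage points (vectorized).
#' @param cutoffs increasing level boundaries; `cutoffs[2] = 20` and
#'   `cutoffs[4] = 30` are the two fixed band edges.
#' @return Integer level(s) in 1-5.
#' @export
efficacy_level <- function(gap, cutoffs = c(10, 20, 25, 30)) {
  if (length(cutoffs) != 4 || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be 4 strictly increasing numbers")
  as.integer(findInterval(gap, cutoffs) + 1L)
}

#' Assess a drug combination's additive killing effect
#'
#' The gap is killing(combo) minus the killing of the most potent single
#' agent, in percentage points; it is mapped to an efficacy level (1-5)
#' by [efficacy_level()]. The combination is "effective" only when its
#' killing is significantly higher than the best single agent's
#' (two-tailed t-test on replicate killing values, p < `alpha`, Welch by
#' default). A negative gap is reported as a rescue.
#'
#' @param v a [compute_viability()] result.
#' @param combo,single_a,single_b condition labels in `v`.
#' @param alpha significance level (default 0.05).
#' @param var_equal `TRUE` for the pooled-variance Student test.
#' @param cutoffs passed to [efficacy_level()].
#' @return List of class `combo_assessment` with the killing means,
#'   `best_single`, `gap`, `level`, `p_value`, `effective`, `rescue`.
#'   With fewer than 2 replicates (or zero variance) the p-value and
#'   `effective` are `NA`; the level is still computed.
#' @export
assess_combo <- function(v, combo, single_a, single_b, alpha = 0.05,
                         var_equal = FALSE, cutoffs = c(10, 20, 25, 30)) {
  stopifnot(inherits(v, "viability_table"))
  killing_of <- function(cond) {
    k <- v$wells$killing[v$wells$condition == cond]
    if (!length(k)) stop("condition not found on plate: ", cond)
    k
  }
  kc <- killing_of(combo)
  ka <- killing_of(single_a)
  kb <- killing_of(single_b)
  best <- if (mean(ka) >= mean(kb)) single_a else single_b
  kbest <- killing_of(best)
  gap <- mean(kc) - mean(kbest)
  p <- tryCatch({
    if (length(kc) < 2 || length(kbest) < 2) NA_real_
    else stats::t.test(kc, kbest, var.equal = var_equal)$p.value
  }, error = function(e) NA_real_)
  structure(list(combo = combo, single_a = single_a, single_b = single_b,
                 killing_combo = mean(kc), killing_a = mean(ka),
                 killing_b = mean(kb), best_single = best,
                 gap = gap, level = efficacy_level(gap, cutoffs),
                 p_value = p,
                 effective = if (is.na(p)) NA else (p < alpha && gap > 0),
                 rescue = gap < 0),
            class = "combo_assessment")
}

#' @export
print.combo_assessment <- function(x, ...) {
  cat(sprintf(
    "Combo %s vs best single %s: gap %.1f pp -> level %d%s\n",
    x$combo, x$best_single, x$gap, x$level,
    if (isTRUE(x$rescue)) " (rescue)" else ""))
  cat(sprintf("  killing: combo %.1f%%, %s %.1f%%, %s %.1f%%; p = %s; effective: %s\n",
              x$killing_combo, x$single_a, x$killing_a, x$single_b,
              x$killing_b, format(x$p_value, digits = 3), x$effective))
  invisible(x)
}

#' Efficacy-level heat-map matrix
#'
#' @param assessments data frame with columns `compound`, `cell_line`,
#'   `level` (e.g. rows built from [assess_combo()] results).
#' @return Integer matrix compounds x cell lines; combinations that were
#'   not tested are `NA`, never 0.
#' @export
efficacy_heatmap <- function(assessments) {
  need <- c("compound", "cell_line", "level")
  if (!all(need %in% names(assessments)))
    stop("assessments must have columns: ", paste(need, collapse = ", "))
  if (!nrow(assessments)) stop("no assessments given")
  key <- paste(assessments$compound, assessments$cell_line, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (compound, cell line) pair: ",
         gsub("\r", " / ", key[duplicated(key)][1]))
  compounds <- unique(assessments$compound)
  lines <- unique(assessments$cell_line)
  m <- matrix(NA_integer_, length(compounds), length(lines),
              dimnames = list(compounds, lines))
  m[cbind(match(assessments$compound, compounds),
          match(assessments$cell_line, lines))] <-
    as.integer(assessments$level)
  m
}
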