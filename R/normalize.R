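#' Depth-normalize a count table
#'
#' Each count is divided by its sample's total read count and rescaled by
#' 1e7, so every sample column sums to the same fixed library size and
#' abundances are comparable across sequencing depths:
#' N = count / total * 1e7.
#'
#' @param x a [screen_counts()] object or a non-negative count matrix.
#' @return Numeric matrix of normalized abundances with the same dimnames
#'   as the counts and attribute `scale = 1e7`.
#' @export
normalize_counts <- function(x) {
  counts <- if (inherits(x, "screen_counts")) x$counts else as.matrix(x)
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero))
    stop("normalization undefined for all-zero sample(s): ",
         paste(zero, collapse = ", "))
  norm <- sweep(counts, 2, totals, "/") * 1e7
  attr(norm, "scale") <- 1e7
  norm
}

#' Flag noisy guides from baseline counts
#'
#' Guides whose baseline (T0) representation is too low to report a
#' reliable fold change are flagged and removed from all downstream
#' arms and timepoints. The default follows the screen's rule of thumb:
#' raw T0 counts strictly below 50 reads (about 10% of the expected
#' per-guide count at 500x coverage) are noisy.
#'
#' @param x a [screen_counts()] object.
#' @param t0_samples sample ids to use as baseline; defaults to all
#'   samples at timepoint `"T0"`.
#' @param threshold raw-count threshold; a guide is flagged when its T0
#'   statistic is strictly below it. `NULL` derives the threshold as
#'   `fraction_expected` of the mean expected count per guide
#'   (mean column total / number of guides).
#' @param combine how to combine several T0 replicates into one per-guide
#'   statistic: `"mean"` (default), `"min"`, or `"all_below"` (flag only
#'   when every replicate is below threshold).
#' @param fraction_expected used only when `threshold = NULL` (default 0.1).
#' @return Named logical vector of class `noise_mask` (`TRUE` = noisy),
#'   with attributes `threshold`, `basis` (sample ids used) and `combine`.
#' @export
flag_noisy_guides <- function(x, t0_samples = NULL, threshold = 50,
                              combine = c("mean", "min", "all_below"),
                              fraction_expected = 0.1) {
  stopifnot(inherits(x, "screen_counts"))
  combine <- match.arg(combine)
  if (is.null(t0_samples))
    t0_samples <- x$samples$sample_id[x$samples$timepoint %in% "T0"]
  if (!length(t0_samples))
    stop("no T0 samples found; supply t0_samples explicitly")
  t0 <- x$counts[, sample_index(x, t0_samples), drop = FALSE]
  if (is.null(threshold))
    threshold <- fraction_expected * mean(colSums(t0)) / nrow(t0)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("threshold must be a single non-negative number")
  flagged <- switch(combine,
    mean = rowMeans(t0) < threshold,
    min = apply(t0, 1, min) < threshold,
    all_below = apply(t0 < threshold, 1, all))
  names(flagged) <- rownames(t0)
  structure(flagged, threshold = threshold, basis = t0_samples,
            combine = combine, class = "noise_mask")
}

#' @export
print.noise_mask <- function(x, ...) {
  cat(sprintf(
    "Noise mask: %d/%d guides flagged (%.1f%%), threshold < %g (%s of %s)\n",
    sum(x), length(x), 100 * mean(x), attr(x, "threshold"),
    attr(x, "combine"), paste(attr(x, "basis"), collapse = ", ")))
  invisible(x)
}

#' Pearson correlation between two samples
#'
#' Replicate-to-replicate correlation is the screen's basic
#' reproducibility check (computed on normalized abundances by default).
#'
#' @param x a [screen_counts()] object.
#' @param a,b sample ids.
#' @param on `"normalized"` (default), `"raw"`, or `"log"`
#'   (log1p of normalized abundances).
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
replicate_correlation <- function(x, a, b,
                                  on = c("normalized", "raw", "log")) {
  stopifnot(inherits(x, "screen_counts"))
  on <- match.arg(on)
  mat <- switch(on,
    raw = x$counts,
    normalized = normalize_counts(x),
    log = log1p(normalize_counts(x)))
  u <- mat[, sample_index(x, a)]
  v <- mat[, sample_index(x, b)]
  if (length(u) < 2) stop("need at least 2 guides")
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("correlation undefined: zero variance in sample ",
         if (stats::sd(u) == 0) a else b)
  stats::cor(u, v)
}

#' Check sequencing coverage per sample
#'
#' Coverage is total reads divided by the number of library guides; the
#' screen design targets at least 500 reads per guide.
#'
#' @param x a [screen_counts()] object.
#' @param min_reads_per_guide pass threshold (default 500).
#' @return Data frame with `sample_id`, `total_reads`, `coverage`, `pass`.
#' @export
coverage_check <- function(x, min_reads_per_guide = 500) {
  stopifnot(inherits(x, "screen_counts"))
  cov <- x$total_reads / nrow(x$counts)
  data.frame(sample_id = colnames(x$counts),
             total_reads = unname(x$total_reads),
             coverage = unname(cov),
             pass = unname(cov >= min_reads_per_guide),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Essential-gene CDF separation (editing-efficiency QC)
#'
#' Compares the abundance distribution of guides targeting a designated
#' essential-gene set (typically ribosomal genes) against all other
#' targeting guides in one sample. Under effective editing, essential-set
#' guides drop out, so their cumulative distribution shifts left and the
#' maximum vertical distance between the two empirical CDFs (the
#' two-sample Kolmogorov-Smirnov statistic) grows at later timepoints.
#'
#' @param x a [screen_counts()] object.
#' @param essential_genes character vector of gene symbols; must be a
#'   non-empty strict subset of the library's targeting genes.
#' @param sample sample id to evaluate.
#' @param on `"normalized"` (default) or `"raw"` abundances.
#' @return List of class `cdf_comparison`: `gap` (KS statistic),
#'   `essential`/`other` (sorted abundance vectors), `n_essential`,
#'   `n_other`, `sample`.
#' @export
editing_efficiency_cdf <- function(x, essential_genes, sample,
                                   on = c("normalized", "raw")) {
  stopifnot(inherits(x, "screen_counts"))
  on <- match.arg(on)
  if (!length(essential_genes)) stop("essential_genes must be non-empty")
  lib <- x$library
  genes <- unique(lib$gene[!lib$is_control])
  ess <- intersect(essential_genes, genes)
  if (!length(ess)) stop("no essential gene present in the library")
  if (length(ess) == length(genes))
    stop("essential set must be a strict subset of library genes")
  mat <- if (on == "raw") x$counts else normalize_counts(x)
  v <- mat[, sample_index(x, sample)]
  in_ess <- !lib$is_control & lib$gene %in% ess
  in_oth <- !lib$is_control & !lib$gene %in% ess
  a <- sort(v[in_ess])
  b <- sort(v[in_oth])
  structure(list(gap = ks_statistic(a, b), essential = a, other = b,
                 n_essential = length(a), n_other = length(b),
                 sample = sample),
            class = "cdf_comparison")
}

#' @export
print.cdf_comparison <- function(x, ...) {
  cat(sprintf(
    "CDF comparison (%s): KS gap %.4f (%d essential vs %d other guides)\n",
    x$sample, x$gap, x$n_essential, x$n_other))
  invisible(x)
}

# two-sample KS statistic: max |ECDF_a - ECDF_b| over pooled values
ks_statistic <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  fa <- findInterval(pooled, sort(a)) / length(a)
  fb <- findInterval(pooled, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' Assemble a screen quality-control report
#'
#' @param x a [screen_counts()] object.
#' @param essential_genes optional essential-gene set for the CDF check.
#' @param min_reads_per_guide coverage threshold (default 500).
#' @param correlation_pairs optional list of `c(a, b)` sample-id pairs;
#'   defaults to all pairs of T0 samples.
#' @return List of class `qc_report` with `coverage`, `correlations`,
#'   and (when `essential_genes` is given) per-sample `cdf_gaps`.
#' @export
qc_report <- function(x, essential_genes = NULL, min_reads_per_guide = 500,
                      correlation_pairs = NULL) {
  stopifnot(inherits(x, "screen_counts"))
  cov <- coverage_check(x, min_reads_per_guide)
  if (is.null(correlation_pairs)) {
    t0 <- x$samples$sample_id[x$samples$timepoint %in% "T0"]
    correlation_pairs <- if (length(t0) >= 2)
      utils::combn(t0, 2, simplify = FALSE) else list()
  }
  cors <- lapply(correlation_pairs, function(p)
    data.frame(sample_a = p[1], sample_b = p[2],
               pearson = replicate_correlation(x, p[1], p[2]),
               stringsAsFactors = FALSE))
  cors <- if (length(cors)) do.call(rbind, cors) else
    data.frame(sample_a = character(), sample_b = character(),
               pearson = numeric())
  gaps <- NULL
  if (!is.null(essential_genes)) {
    gaps <- vapply(colnames(x$counts), function(s)
      editing_efficiency_cdf(x, essential_genes, s)$gap, numeric(1))
  }
  structure(list(coverage = cov, correlations = cors, cdf_gaps = gaps),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Screen QC report\n----------------\nCoverage:\n")
  print(x$coverage)
  if (nrow(x$correlations)) {
    cat("Replicate correlations (normalized):\n")
    print(x$correlations)
  }
  if (!is.null(x$cdf_gaps)) {
    cat("Essential-gene CDF gap per sample:\n")
    print(round(x$cdf_gaps, 4))
  }
  invisible(x)
}
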