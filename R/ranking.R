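#' Per-guide log2 fold changes between a drug and a control sample
#'
#' For every non-noisy guide, computes
#' LFC = log2((N_drug + 1) / (N_control + 1)) on depth-normalized
#' abundances; the +1 pseudocount keeps the ratio finite when either arm
#' drops to zero. The control should be the vehicle arm of the same
#' timepoint, so the fold change isolates the drug-gene interaction from
#' ordinary growth effects.
#'
#' @param x a [screen_counts()] object.
#' @param drug,control sample ids of the drug and matched control arm.
#' @param mask optional [flag_noisy_guides()] mask; flagged guides are
#'   dropped before any fold change is computed.
#' @return Data frame of class `lfc_table` with columns `guide_id`,
#'   `gene`, `is_control`, `norm_drug`, `norm_control`, `lfc`, and
#'   attributes `drug`, `control`, `timepoint`.
#' @export
compute_lfc <- function(x, drug, control, mask = NULL) {
  stopifnot(inherits(x, "screen_counts"))
  if (identical(drug, control))
    stop("drug and control must be different samples")
  norm <- normalize_counts(x)
  nd <- norm[, sample_index(x, drug)]
  nc <- norm[, sample_index(x, control)]
  keep <- rep(TRUE, nrow(norm))
  if (!is.null(mask)) {
    if (length(mask) != nrow(norm))
      stop("mask length does not match the number of guides")
    keep <- !as.logical(mask)
  }
  out <- data.frame(guide_id = x$library$guide_id,
                    gene = x$library$gene,
                    is_control = x$library$is_control,
                    norm_drug = unname(nd),
                    norm_control = unname(nc),
                    lfc = unname(log2((nd + 1) / (nc + 1))),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  tp <- x$samples$timepoint[match(drug, x$samples$sample_id)]
  structure(out, drug = drug, control = control, timepoint = tp,
            all_genes = unique(x$library$gene[!x$library$is_control]),
            class = c("lfc_table", "data.frame"))
}

#' Summarize guide fold changes per gene
#'
#' For each gene with at least one usable guide, computes the mean fold
#' change and the sign-concordance count k: the number of individual
#' guide LFC values sharing the sign (+ or -) of the gene's mean. The
#' terrace rank equals k (1-6 for a full six-guide set); a gene whose
#' mean is exactly zero has no sign to agree with and gets rank 0. An
#' exactly-zero guide LFC matches neither sign.
#'
#' @param records an `lfc_table` from [compute_lfc()].
#' @param mean_mode `"mean_of_logs"` (default): mean of per-guide LFC
#'   values; `"log_of_means"`: log2 ratio of the mean normalized
#'   abundances (pseudocounted), an alternative reading of the gene-level
#'   reference sign.
#' @param exclude_controls drop non-targeting control guides (default).
#' @return Data frame of class `gene_summary`: `gene`, `n_guides`,
#'   `mean_lfc`, `concordance_k`, `terrace_rank`, ordered by gene.
#' @export
summarize_genes <- function(records,
                            mean_mode = c("mean_of_logs", "log_of_means"),
                            exclude_controls = TRUE) {
  mean_mode <- match.arg(mean_mode)
  df <- as.data.frame(records)
  if (exclude_controls && "is_control" %in% names(df))
    df <- df[!df$is_control, , drop = FALSE]
  if (!nrow(df)) stop("no usable guide records")
  split_idx <- split(seq_len(nrow(df)), df$gene)
  res <- lapply(names(split_idx), function(g) {
    i <- split_idx[[g]]
    lfc <- df$lfc[i]
    mu <- if (mean_mode == "mean_of_logs") mean(lfc) else
      log2((mean(df$norm_drug[i]) + 1) / (mean(df$norm_control[i]) + 1))
    k <- if (mu == 0) 0L else sum(sign(lfc) == sign(mu))
    data.frame(gene = g, n_guides = length(i), mean_lfc = mu,
               concordance_k = as.integer(k),
               terrace_rank = if (mu == 0) 0L else as.integer(k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  lost <- setdiff(attr(records, "all_genes"), out$gene)
  if (length(lost))
    warning(length(lost), " gene(s) have no usable guides and were omitted")
  structure(out, mean_mode = mean_mode, timepoint = attr(records, "timepoint"),
            class = c("gene_summary", "data.frame"))
}

#' Plot-ready terrace table
#'
#' Genes are grouped on terraces by their concordance rank (6 = all
#' guides agree with the mean sign, down to 1) and ordered within each
#' terrace by mean fold change (most depleted first). Rank-0 genes
#' (exactly zero mean) are excluded.
#'
#' @param summaries a `gene_summary` from [summarize_genes()].
#' @return Data frame with `gene`, `mean_lfc`, `terrace_rank`, ordered by
#'   decreasing rank then increasing mean LFC.
#' @export
terrace_table <- function(summaries) {
  df <- as.data.frame(summaries)
  if (!nrow(df)) stop("empty gene summary")
  df <- df[df$terrace_rank >= 1L, c("gene", "mean_lfc", "terrace_rank")]
  df <- df[order(-df$terrace_rank, df$mean_lfc, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Terrace view restricted to a gene subset
#'
#' Used to display a panel of interest (e.g. olfactory-receptor genes or
#' an oncogene list) on its own terraced plot; values are identical to
#' the full table for the retained genes.
#'
#' @param summaries a `gene_summary`.
#' @param genes character vector of genes to keep.
#' @return Terrace table restricted to `genes` (empty, with a warning,
#'   when none are present).
#' @export
gene_subset_view <- function(summaries, genes) {
  if (!length(genes)) stop("gene subset must be non-empty")
  full <- terrace_table(summaries)
  out <- full[full$gene %in% genes, , drop = FALSE]
  if (!nrow(out))
    warning("none of the subset genes are present in the summaries")
  rownames(out) <- NULL
  out
}

#' DRACO candidate selection
#'
#' DRACO ranks each gene by its single most efficient guide — the one
#' with the largest absolute LFC — but only after the four-of-six
#' concordance filter: a gene is a candidate only if at least
#' `min_concordant` of its guide LFC values share the sign of the gene's
#' mean. The filter is what prevents a lone extreme guide (off-target or
#' hyper-efficient) from promoting a gene on its own.
#'
#' @param records an `lfc_table` from [compute_lfc()].
#' @param min_concordant concordance threshold k (default 4, the
#'   four-of-six rule).
#' @param proportional if `TRUE`, genes with fewer than six usable guides
#'   pass when k/n >= 2/3 and n >= 3 instead of the literal k >= 4.
#' @param keep_all return failing genes too, with `passed = FALSE`.
#' @param mean_mode passed to [summarize_genes()].
#' @return Data frame of class `draco_table`: `gene`, `n_guides`,
#'   `concordance_k`, `mean_lfc`, `selected_guide`, `selected_lfc`
#'   (signed value of the max-|LFC| guide; ties broken by guide id),
#'   `passed`.
#' @export
draco_select <- function(records, min_concordant = 4, proportional = FALSE,
                         keep_all = FALSE,
                         mean_mode = c("mean_of_logs", "log_of_means")) {
  if (min_concordant < 1) stop("min_concordant must be >= 1")
  summ <- summarize_genes(records, mean_mode = match.arg(mean_mode))
  df <- as.data.frame(records)
  if ("is_control" %in% names(df)) df <- df[!df$is_control, , drop = FALSE]
  df <- df[order(df$guide_id), , drop = FALSE]  # deterministic tie-break
  pick <- vapply(split(seq_len(nrow(df)), df$gene), function(i)
    i[which.max(abs(df$lfc[i]))], integer(1))
  sel <- df[pick[summ$gene], , drop = FALSE]
  passed <- if (proportional)
    summ$n_guides >= 3 & summ$concordance_k / summ$n_guides >= 2 / 3
  else summ$concordance_k >= min_concordant
  passed <- passed & summ$terrace_rank > 0L
  out <- data.frame(gene = summ$gene, n_guides = summ$n_guides,
                    concordance_k = summ$concordance_k,
                    mean_lfc = summ$mean_lfc,
                    selected_guide = sel$guide_id,
                    selected_lfc = sel$lfc,
                    passed = passed, stringsAsFactors = FALSE)
  if (!keep_all) out <- out[out$passed, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, min_concordant = min_concordant,
            timepoint = attr(records, "timepoint"),
            class = c("draco_table", "data.frame"))
}

#' Select the top depleted or enriched candidate genes
#'
#' Terrace method: restrict to genes at terrace rank >= `min_concordant`
#' and order by rank (most concordant first), then by mean LFC (ascending
#' for depleted genes, descending for enriched). DRACO method: order the
#' passed genes by their selected guide's signed LFC. Ties are broken by
#' gene id for determinism.
#'
#' @param x a `gene_summary` (terrace method) or `draco_table` (DRACO).
#' @param direction `"depleted"` (dropout, default) or `"enriched"`.
#' @param n list size (default 25).
#' @param min_concordant terrace-rank cutoff for the terrace method.
#' @param label provenance label recorded on the list, e.g.
#'   `"draco:T3"`; defaults to `"<method>:<timepoint>"` when the
#'   timepoint is known.
#' @return Data frame of class `candidate_list` with `gene`, `score`
#'   (mean or selected LFC), `rank`, and attributes `method`,
#'   `direction`, `label`. Shorter than `n`, with a warning, when fewer
#'   genes are eligible.
#' @export
select_top <- function(x, direction = c("depleted", "enriched"), n = 25,
                       min_concordant = 4, label = NULL) {
  direction <- match.arg(direction)
  if (n < 1) stop("n must be >= 1")
  if (inherits(x, "draco_table")) {
    method <- "draco"
    df <- as.data.frame(x)[as.data.frame(x)$passed, , drop = FALSE]
    score <- df$selected_lfc
  } else if (inherits(x, "gene_summary")) {
    method <- "terrace"
    df <- as.data.frame(x)
    df <- df[df$terrace_rank >= min_concordant, , drop = FALSE]
    score <- df$mean_lfc
  } else stop("x must be a gene_summary or draco_table")
  df$score <- score
  keep <- if (direction == "depleted") df$score < 0 else df$score > 0
  df <- df[keep, , drop = FALSE]
  ord <- if (method == "terrace") {
    if (direction == "depleted")
      order(-df$terrace_rank, df$score, df$gene)
    else order(-df$terrace_rank, -df$score, df$gene)
  } else {
    if (direction == "depleted") order(df$score, df$gene)
    else order(-df$score, df$gene)
  }
  df <- df[ord, , drop = FALSE]
  if (nrow(df) < n)
    warning(sprintf("only %d eligible genes for a top-%d %s list",
                    nrow(df), n, direction))
  df <- utils::head(df, n)
  out <- data.frame(gene = df$gene, score = df$score,
                    rank = seq_len(nrow(df)), stringsAsFactors = FALSE)
  if (is.null(label)) {
    tp <- attr(x, "timepoint")
    label <- if (is.null(tp) || is.na(tp)) method else paste0(method, ":", tp)
  }
  structure(out, method = method, direction = direction, label = label,
            class = c("candidate_list", "data.frame"))
}

#' Merge candidate lists with provenance
#'
#' Takes the union of several candidate lists (e.g. top-25 terrace and
#' DRACO lists from T2 and T3) and records, per gene, which lists it
#' appeared in — genes recurring across methods/timepoints are the most
#' robust candidates.
#'
#' @param ... `candidate_list` objects (or one list of them).
#' @return Data frame with `gene`, `n_groups`, `groups` (comma-separated
#'   provenance labels), `best_score` (most extreme score across lists),
#'   ordered by decreasing `n_groups` then best score.
#' @export
merge_candidates <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && !inherits(lists[[1]], "candidate_list"))
    lists <- lists[[1]]
  if (!length(lists)) stop("need at least one candidate list")
  labs <- vapply(seq_along(lists), function(i) {
    l <- attr(lists[[i]], "label")
    if (is.null(l)) paste0("list", i) else l
  }, character(1))
  long <- do.call(rbind, lapply(seq_along(lists), function(i)
    data.frame(gene = lists[[i]]$gene, score = lists[[i]]$score,
               group = labs[i], stringsAsFactors = FALSE)))
  by_gene <- split(long, long$gene)
  out <- do.call(rbind, lapply(by_gene, function(d)
    data.frame(gene = d$gene[1], n_groups = length(unique(d$group)),
               groups = paste(unique(d$group), collapse = ","),
               best_score = d$score[which.max(abs(d$score))],
               stringsAsFactors = FALSE)))
  out <- out[order(-out$n_groups, -abs(out$best_score), out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Draw a terrace plot
#'
#' Base-graphics rendering of [terrace_table()]: one column of points per
#' concordance rank, vertical position = mean LFC.
#'
#' @param summaries a `gene_summary`.
#' @param highlight optional genes to label in red.
#' @param ... passed to [plot()].
#' @export
plot_terrace <- function(summaries, highlight = NULL, ...) {
  tt <- terrace_table(summaries)
  plot(jitter(tt$terrace_rank, amount = 0.15), tt$mean_lfc,
       xlab = "concordance rank (guides agreeing with mean sign)",
       ylab = expression(mean ~ log[2] ~ "(drug/control)"),
       pch = 16, col = "grey40", xaxt = "n", ...)
  graphics::axis(1, at = sort(unique(tt$terrace_rank)))
  graphics::abline(h = 0, lty = 2)
  if (!is.null(highlight)) {
    hi <- tt[tt$gene %in% highlight, , drop = FALSE]
    graphics::points(hi$terrace_rank, hi$mean_lfc, col = "red", pch = 16)
    graphics::text(hi$terrace_rank, hi$mean_lfc, hi$gene, pos = 4,
                   col = "red", cex = 0.7)
  }
  invisible(tt)
}
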