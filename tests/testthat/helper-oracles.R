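# Independent brute-force oracles and tiny fixture builders.
# Oracles deliberately use naive loops, not the package's vectorized code.

# deterministic unique fixed-length spacers: base-4 encoding of the index
make_spacers <- function(n, len = 20) {
  alpha <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(len)
    for (p in seq_len(len)) { digits[p] <- i %% 4L; i <- i %/% 4L }
    paste(alpha[digits + 1L], collapse = "")
  }, character(1))
}

make_library <- function(n_genes = 3, gpg = 6, n_ctrl = 0) {
  genes <- rep(sprintf("G%02d", seq_len(n_genes)), each = gpg)
  ids <- paste0(genes, "_sg", seq_len(gpg))
  if (n_ctrl > 0) {
    ids <- c(ids, sprintf("CTRL%02d", seq_len(n_ctrl)))
    genes <- c(genes, rep("non-targeting", n_ctrl))
  }
  guide_library(ids, make_spacers(length(ids)), genes,
                is_control = grepl("^CTRL", ids), guides_per_gene = gpg)
}

make_counts <- function(library, counts_mat, arms = NULL, tps = NULL) {
  samples <- if (is.null(arms)) NULL else
    sample_info(colnames(counts_mat), arms, tps,
                ave(seq_len(ncol(counts_mat)),
                    paste(arms, tps), FUN = seq_along))
  screen_counts(counts_mat, library, samples)
}

# build an lfc_table directly from per-guide lfc values (bypasses counts)
make_lfc_records <- function(lfc_by_gene) {
  rows <- do.call(rbind, lapply(names(lfc_by_gene), function(g) {
    v <- lfc_by_gene[[g]]
    data.frame(guide_id = paste0(g, "_sg", seq_along(v)), gene = g,
               is_control = FALSE, norm_drug = NA_real_,
               norm_control = NA_real_, lfc = v, stringsAsFactors = FALSE)
  }))
  structure(rows, class = c("lfc_table", "data.frame"))
}

# naive per-gene summary: mean, strict sign concordance, terrace rank
oracle_gene_summary <- function(lfc) {
  mu <- sum(lfc) / length(lfc)
  k <- 0L
  for (v in lfc) {
    if (mu > 0 && v > 0) k <- k + 1L
    if (mu < 0 && v < 0) k <- k + 1L
  }
  list(mean_lfc = mu, concordance_k = if (mu == 0) 0L else k,
       terrace_rank = if (mu == 0) 0L else k)
}

# naive DRACO: four-of-six filter + argmax |lfc|, guide-id tie-break
oracle_draco <- function(lfc, guide_ids, min_concordant = 4) {
  s <- oracle_gene_summary(lfc)
  best <- 1L
  for (i in seq_along(lfc)) {
    if (abs(lfc[i]) > abs(lfc[best]) ||
        (abs(lfc[i]) == abs(lfc[best]) && guide_ids[i] < guide_ids[best]))
      best <- i
  }
  list(passed = s$terrace_rank > 0 && s$concordance_k >= min_concordant,
       selected_guide = guide_ids[best], selected_lfc = lfc[best])
}

# quadratic two-sample KS statistic
oracle_ks <- function(a, b) {
  gap <- 0
  for (x in c(a, b)) {
    fa <- sum(a <= x) / length(a)
    fb <- sum(b <= x) / length(b)
    gap <- max(gap, abs(fa - fb))
  }
  gap
}

# naive O(n^2) Kendall tau-b with tie correction
oracle_kendall <- function(x, y) {
  n <- length(x); conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# naive Spearman: Pearson on mid-ranks computed by counting
oracle_spearman <- function(x, y) {
  midrank <- function(v) vapply(v, function(a)
    sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
  stats::cor(midrank(x), midrank(y))
}
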