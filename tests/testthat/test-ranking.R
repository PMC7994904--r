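test_that("log2 fold changes use the +1 pseudocount on normalized values", {
  lib <- make_library(n_genes = 1, gpg = 4)
  # choose counts so normalized values are easy: equal totals
  m <- cbind(DRUG_T3 = c(0, 3, 1, 4), VEH_T3 = c(0, 1, 7, 0))
  rownames(m) <- lib$guide_id
  x <- make_counts(lib, m, arms = c("drug", "vehicle"),
                   tps = c("T3", "T3"))
  # force equal normalized scale by testing via the formula directly
  norm <- normalize_counts(x)
  rec <- compute_lfc(x, "DRUG_T3", "VEH_T3")
  expect_equal(rec$lfc,
               log2((norm[, 1] + 1) / (norm[, 2] + 1)),
               ignore_attr = TRUE)
  expect_equal(rec$lfc[1], 0)  # 0 vs 0 -> log2(1/1)
  expect_equal(attr(rec, "timepoint"), "T3")
  expect_error(compute_lfc(x, "DRUG_T3", "DRUG_T3"), "different")

  # masked guides are dropped before any fold change is computed
  mask <- structure(c(TRUE, FALSE, FALSE, FALSE), class = "noise_mask")
  expect_equal(nrow(compute_lfc(x, "DRUG_T3", "VEH_T3", mask)), 3)
})

test_that("gene summaries reproduce the hand-worked concordance example", {
  rec <- make_lfc_records(list(A = c(-1, -2, -0.5, -3, 0.2, 0.1),
                               B = rep(-1, 6),
                               C = c(1, -1)))
  s <- summarize_genes(rec)
  a <- s[s$gene == "A", ]
  expect_equal(a$mean_lfc, mean(c(-1, -2, -0.5, -3, 0.2, 0.1)))
  expect_equal(a$concordance_k, 4L)
  expect_equal(a$terrace_rank, 4L)
  expect_equal(s$terrace_rank[s$gene == "B"], 6L)
  # exact-zero mean: no sign to agree with -> rank 0, excluded from terraces
  expect_equal(s$terrace_rank[s$gene == "C"], 0L)
  expect_false("C" %in% terrace_table(s)$gene)
})

test_that("terrace and DRACO match the enumeration oracle on random sets", {
  set.seed(202)
  for (i in 1:400) {
    n_guides <- sample(1:6, 1)
    lfc <- round(rnorm(n_guides, sd = 2), 3)
    rec <- make_lfc_records(list(GX = lfc))
    s <- summarize_genes(rec)
    d <- draco_select(rec, keep_all = TRUE)
    o_s <- oracle_gene_summary(lfc)
    o_d <- oracle_draco(lfc, rec$guide_id)
    expect_equal(s$mean_lfc, o_s$mean_lfc)
    expect_equal(s$concordance_k, o_s$concordance_k)
    expect_equal(s$terrace_rank, o_s$terrace_rank)
    expect_equal(d$selected_guide, o_d$selected_guide)
    expect_equal(d$selected_lfc, o_d$selected_lfc)
    expect_equal(d$passed, o_d$passed)
  }
})

test_that("the four-of-six filter blocks lone extreme guides", {
  rec <- make_lfc_records(list(
    PASS = c(-1, -2, -0.5, -3, 0.2, 0.1),     # k = 4 -> candidate
    SPLIT = c(-1, -1, -1, 1, 1, 1),           # mean exactly 0 -> out
    LONE = c(-5, 0.1, 0.2, 0.3, 0.4, 0.5)))   # extreme guide, k = 1 -> out
  d <- draco_select(rec)
  expect_equal(d$gene, "PASS")
  expect_equal(d$selected_lfc, -3)
  all3 <- draco_select(rec, keep_all = TRUE)
  expect_equal(all3$passed[all3$gene == "LONE"], FALSE)
  expect_equal(all3$selected_lfc[all3$gene == "LONE"], -5)
  expect_error(draco_select(rec, min_concordant = 0), "min_concordant")

  # |lfc| ties resolve to the lexicographically first guide id
  tie <- make_lfc_records(list(T1 = c(-2, 2, -2, -1, -1, -1)))
  expect_equal(draco_select(tie)$selected_guide, "T1_sg1")
})

test_that("sign symmetry: negating lfc flips scores, keeps concordance", {
  set.seed(77)
  for (i in 1:50) {
    lfc <- rnorm(6)
    rec <- make_lfc_records(list(G = lfc))
    neg <- make_lfc_records(list(G = -lfc))
    s1 <- summarize_genes(rec); s2 <- summarize_genes(neg)
    d1 <- draco_select(rec, keep_all = TRUE)
    d2 <- draco_select(neg, keep_all = TRUE)
    expect_equal(s2$mean_lfc, -s1$mean_lfc)
    expect_equal(s2$concordance_k, s1$concordance_k)
    expect_equal(d2$selected_lfc, -d1$selected_lfc)
    expect_equal(d2$passed, d1$passed)
  }
})

test_that("top-candidate selection orders, truncates and reverses", {
  rec <- make_lfc_records(stats::setNames(
    lapply(c(-3, -2, -1, 1, 2), function(m) rep(m, 6)),
    paste0("G", 1:5)))
  s <- summarize_genes(rec)
  top <- select_top(s, "depleted", n = 2)
  expect_equal(top$gene, c("G1", "G2"))
  expect_equal(top$score, c(-3, -2))
  up <- select_top(s, "enriched", n = 2)
  expect_equal(up$gene, c("G5", "G4"))
  expect_warning(short <- select_top(s, "depleted", n = 10), "eligible")
  expect_equal(nrow(short), 3)

  d <- draco_select(rec)
  dtop <- select_top(d, "depleted", n = 2)
  expect_equal(dtop$gene, c("G1", "G2"))
  expect_equal(attr(dtop, "method"), "draco")

  # terrace ordering is rank-first: a rank-6 gene precedes a deeper rank-4
  rec2 <- make_lfc_records(list(R6 = rep(-1, 6),
                                R4 = c(-9, -9, -9, -9, 1, 1)))
  s2 <- summarize_genes(rec2)
  expect_equal(select_top(s2, "depleted", n = 2)$gene, c("R6", "R4"))
})

test_that("candidate-list merging tracks provenance", {
  mk <- function(genes, label) structure(
    data.frame(gene = genes, score = -seq_along(genes),
               rank = seq_along(genes), stringsAsFactors = FALSE),
    label = label, class = c("candidate_list", "data.frame"))
  a <- mk(paste0("G", 1:25), "draco:T2")
  b <- mk(paste0("G", 26:50), "draco:T3")
  m1 <- merge_candidates(a, b)
  expect_equal(nrow(m1), 50)
  expect_true(all(m1$n_groups == 1))
  m2 <- merge_candidates(a, a)
  expect_equal(nrow(m2), 25)
  m3 <- merge_candidates(a, mk(c(paste0("G", 23:25), paste0("H", 1:22)),
                              "terrace:T3"))
  expect_equal(nrow(m3), 47)
  expect_equal(sum(m3$n_groups == 2), 3)
  expect_equal(m3$groups[m3$gene == "G23"], "draco:T2,terrace:T3")
})

test_that("gene-subset terrace views restrict without altering values", {
  rec <- make_lfc_records(stats::setNames(
    lapply(c(-2, -1, 0.5), function(m) rep(m, 6)), c("A", "B", "C")))
  s <- summarize_genes(rec)
  sub <- gene_subset_view(s, c("B", "C"))
  full <- terrace_table(s)
  expect_equal(sub, full[full$gene %in% c("B", "C"), ],
               ignore_attr = TRUE)
  expect_equal(nrow(gene_subset_view(s, "A")), 1)
  expect_warning(empty <- gene_subset_view(s, "ZZZ"), "none")
  expect_equal(nrow(empty), 0)
  expect_error(gene_subset_view(s, character(0)), "non-empty")
})

test_that("null screens pass k >= 4 at the sign-symmetric Monte-Carlo rate", {
  # product of the pipeline on exchangeable drug/control counts vs a
  # direct Monte-Carlo over 6 iid sign-symmetric values
  set.seed(5150)
  n_mc <- 20000
  mc <- matrix(rnorm(6 * n_mc), n_mc, 6)
  mu <- rowMeans(mc)
  k <- rowSums(sign(mc) == sign(mu))
  p_mc <- mean(k >= 4)

  cfg <- sim_config(n_genes = 500, n_control_guides = 0,
                    n_strong_dropout = 0, n_single_efficient = 0,
                    coverage = 500, seed = 99)
  sim <- simulate_library(cfg)
  x <- simulate_screen(sim$library, sim$truth, cfg)
  rec <- compute_lfc(x, "DRUG_T3_R1", "VEH_T3_R1")
  s <- summarize_genes(rec)
  p_screen <- mean(s$concordance_k >= 4)
  ci <- 2.576 * sqrt(p_mc * (1 - p_mc) / nrow(s))
  expect_lt(abs(p_screen - p_mc), ci + 0.01)
})
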