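test_that("normalization follows count/total * 1e7 and conserves columns", {
  lib <- make_library(n_genes = 1, gpg = 2)
  m <- matrix(c(2, 3), 2, 1, dimnames = list(lib$guide_id, "s1"))
  x <- screen_counts(m, lib)
  norm <- normalize_counts(x)
  expect_equal(unname(norm[, 1]), c(4e6, 6e6))

  set.seed(42)
  lib2 <- make_library(n_genes = 10, gpg = 6)
  m2 <- matrix(rpois(60 * 4, 40), 60, 4,
               dimnames = list(lib2$guide_id, paste0("s", 1:4)))
  m2[5, 2] <- 0
  n2 <- normalize_counts(screen_counts(m2, lib2))
  expect_equal(unname(colSums(n2)), rep(1e7, 4))
  expect_equal(n2[5, 2], 0)  # zero counts stay zero

  # scale invariance: integer rescaling of a raw column changes nothing
  m3 <- m2
  m3[, 3] <- m3[, 3] * 17L
  expect_equal(normalize_counts(screen_counts(m3, lib2)), n2)

  # all-zero column is undefined and names the sample
  m2[, 2] <- 0
  expect_error(normalize_counts(screen_counts(m2, lib2)), "s2")
})

test_that("noise flagging is strict, combines replicates, and is monotone", {
  lib <- make_library(n_genes = 1, gpg = 4)
  m <- matrix(c(49, 50, 49, 1000,
                49, 50, 60, 1000), 4, 2,
              dimnames = list(lib$guide_id, c("t0a", "t0b")))
  x <- make_counts(lib, m, arms = c("baseline", "baseline"),
                   tps = c("T0", "T0"))
  # guide1: both 49 -> flagged; guide2: both 50 -> strict '<' keeps it;
  # guide3: mean(49, 60) = 54.5 -> not flagged under combine = mean
  mask <- flag_noisy_guides(x)
  expect_equal(as.logical(mask), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(flag_noisy_guides(x, combine = "min")[3])
  expect_false(flag_noisy_guides(x, combine = "all_below")[3])

  # monotone in threshold: raising it never unflags a guide
  set.seed(1)
  mr <- matrix(rpois(40, 60), 20, 2)
  dimnames(mr) <- list(make_library(5, 4)$guide_id, c("a", "b"))
  xr <- make_counts(make_library(5, 4), mr, c("baseline", "baseline"),
                    c("T0", "T0"))
  prev <- flag_noisy_guides(xr, threshold = 0)
  for (th in c(10, 30, 50, 80, 200)) {
    cur <- flag_noisy_guides(xr, threshold = th)
    expect_true(all(cur[prev]))
    prev <- cur
  }
  expect_error(flag_noisy_guides(x, threshold = -1), "non-negative")

  # threshold = NULL derives 10% of expected per-guide counts
  auto <- flag_noisy_guides(x, threshold = NULL)
  expect_equal(attr(auto, "threshold"), 0.1 * mean(colSums(m)) / 4)
})

test_that("replicate correlation is Pearson with explicit failure modes", {
  lib <- make_library(n_genes = 1, gpg = 3)
  m <- matrix(c(1, 2, 3, 6, 4, 2), 3, 2,
              dimnames = list(lib$guide_id, c("a", "b")))
  x <- screen_counts(m, lib)
  expect_equal(replicate_correlation(x, "a", "a", on = "raw"), 1)
  expect_equal(replicate_correlation(x, "a", "b", on = "raw"), -1)
  # depth-normalization leaves perfectly proportional columns at r = 1
  m2 <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  rownames(m2) <- lib$guide_id
  expect_equal(replicate_correlation(screen_counts(m2, lib), "a", "b"), 1)
  m3 <- cbind(a = c(5, 5, 5), b = c(1, 2, 3))
  rownames(m3) <- lib$guide_id
  expect_error(replicate_correlation(screen_counts(m3, lib), "a", "b",
                                     on = "raw"), "zero variance")
})

test_that("coverage check compares reads-per-guide to the design depth", {
  lib <- make_library(n_genes = 5, gpg = 4)
  m <- matrix(500, 20, 1, dimnames = list(lib$guide_id, "s"))
  x <- screen_counts(m, lib)
  cc <- coverage_check(x)
  expect_equal(cc$coverage, 500)
  expect_true(cc$pass)
  m2 <- matrix(100, 20, 1, dimnames = list(lib$guide_id, "s"))
  expect_false(coverage_check(screen_counts(m2, lib))$pass)
  expect_true(coverage_check(screen_counts(m2, lib),
                             min_reads_per_guide = 0)$pass)
})

test_that("essential-gene CDF gap equals the brute-force KS oracle", {
  set.seed(11)
  lib <- make_library(n_genes = 30, gpg = 6)
  ess <- sprintf("G%02d", 1:8)
  in_ess <- lib$gene %in% ess
  # essential guides at half the abundance of the rest
  mu <- ifelse(in_ess, 100, 200)
  m <- matrix(rpois(nrow(lib), mu), ncol = 1,
              dimnames = list(lib$guide_id, "s"))
  x <- screen_counts(m, lib)
  res <- editing_efficiency_cdf(x, ess, "s")
  norm <- normalize_counts(x)[, 1]
  expect_equal(res$gap, oracle_ks(norm[in_ess], norm[!in_ess]))
  expect_gt(res$gap, 0.3)

  # identically drawn sets: small gap; oracle agreement on random draws
  for (i in 1:5) {
    a <- rpois(40, 120); b <- rpois(150, 120)
    expect_equal(dracoscreen:::ks_statistic(a, b), oracle_ks(a, b))
  }
  expect_error(editing_efficiency_cdf(x, unique(lib$gene), "s"), "strict")
  expect_error(editing_efficiency_cdf(x, "NOPE", "s"), "no essential")
})

test_that("qc_report assembles coverage, correlations and CDF gaps", {
  cfg <- sim_config(n_genes = 40, n_control_guides = 10,
                    n_strong_dropout = 8, n_single_efficient = 0,
                    dropout_effect = -1, seed = 3)
  sim <- simulate_library(cfg)
  x <- simulate_screen(sim$library, sim$truth, cfg)
  ess <- sim$truth$genes$gene[sim$truth$genes$label == "strong_dropout"]
  rep <- qc_report(x, essential_genes = ess)
  expect_true(all(rep$coverage$coverage > 0))
  expect_equal(nrow(rep$correlations), 1)  # one T0 pair
  expect_gt(rep$correlations$pearson, 0.8)
  # dropout of the "essential" set opens the CDF gap under drug pressure
  expect_gt(rep$cdf_gaps[["DRUG_T3_R1"]], rep$cdf_gaps[["T0_R1"]])
})
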