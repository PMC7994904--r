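#' Configuration for the synthetic screen generator
#'
#' Defines a screen with the statistical structure the analysis assumes:
#' a GeCKOv2-like library (six guides per gene plus non-targeting
#' controls), log-normal baseline representation, negative-binomial
#' (Gamma-Poisson) count noise, heterogeneous per-guide editing
#' efficiency, and gene fitness effects that scale with an escalating
#' drug-pressure schedule over timepoints T1-T3 (vehicle arm: no
#' pressure). Ground-truth labels allow recovery benchmarking.
#'
#' Guide abundance evolves multiplicatively between timepoints:
#' `a_i(t) = a_i(0) * exp(e_i * (f_g * t + d_g * P(t)))`, where `e_i` is
#' the guide's editing efficiency, `f_g` the gene's basal fitness effect,
#' `d_g` its drug-interaction effect (natural-log scale per pressure
#' unit) and `P(t)` the cumulative pressure. Counts are drawn
#' negative-binomially around depth-scaled relative abundances.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene guides per gene (default 6).
#' @param n_control_guides non-targeting control guides.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline per-guide representation.
#' @param coverage expected reads per guide per sample (default 500,
#'   the screen's design coverage).
#' @param dispersion negative-binomial size parameter (`Inf` = Poisson);
#'   default 100, i.e. ~10% extra coefficient of variation.
#' @param inactive_fraction fraction of guides with no editing activity
#'   among ordinary genes.
#' @param efficiency_shape Beta(shape1, shape2) for active-guide
#'   efficiencies of ordinary genes.
#' @param strong_efficiency_shape Beta parameters for guides of
#'   strong-effect genes (default Beta(5, 1): mostly efficient, so at
#'   least four of six guides carry the phenotype).
#' @param n_strong_dropout,n_strong_enrichment,n_single_efficient counts
#'   of labeled effect genes; single-efficient genes have exactly one
#'   fully active guide (the DRACO filter's false-positive model).
#' @param dropout_effect,enrichment_effect,single_effect drug-interaction
#'   effects `d_g` (ln scale per pressure unit) for the labeled classes.
#' @param basal_fitness_sd sd of per-gene basal fitness `f_g` (default 0).
#' @param pressure named drug-pressure increments for T1-T3 (escalating
#'   by default).
#' @param n_reps_t0 baseline replicates (default 2).
#' @param n_reps_arm replicates per arm and timepoint (default 1).
#' @param spacer_length spacer length for simulated libraries.
#' @param seed base random seed used by the generators.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, guides_per_gene = 6,
                       n_control_guides = 60,
                       baseline_meanlog = 0, baseline_sdlog = 0.25,
                       coverage = 500, dispersion = 100,
                       inactive_fraction = 0.2,
                       efficiency_shape = c(2, 2),
                       strong_efficiency_shape = c(5, 1),
                       n_strong_dropout = 30, n_strong_enrichment = 0,
                       n_single_efficient = 10,
                       dropout_effect = -0.5, enrichment_effect = 0.5,
                       single_effect = -0.75,
                       basal_fitness_sd = 0,
                       pressure = c(T1 = 1, T2 = 2, T3 = 4),
                       n_reps_t0 = 2, n_reps_arm = 1,
                       spacer_length = 20, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$guides_per_gene < 1) stop("guides_per_gene must be >= 1")
  if (cfg$coverage <= 0) stop("coverage must be positive")
  if (cfg$inactive_fraction < 0 || cfg$inactive_fraction > 1)
    stop("inactive_fraction must be in [0, 1]")
  if (cfg$n_strong_dropout + cfg$n_strong_enrichment +
      cfg$n_single_efficient > cfg$n_genes)
    stop("more labeled effect genes than genes")
  if (is.null(names(cfg$pressure)))
    names(cfg$pressure) <- paste0("T", seq_along(cfg$pressure))
  structure(cfg, class = "sim_config")
}

# unique random fixed-length spacers
random_spacers <- function(n, len) {
  repeat {
    sp <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
    if (!anyDuplicated(sp)) return(sp)
  }
}

#' Simulate a guide library with ground-truth effect labels
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return List with `library` (a [guide_library()]) and `truth`
#'   (`genes`: gene, label, `d` drug effect, `f` basal fitness;
#'   `guides`: guide_id, gene, `efficiency`).
#' @export
simulate_library <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  g <- config$n_genes
  gpg <- config$guides_per_gene
  genes <- sprintf("GENE%04d", seq_len(g))

  label <- rep("null", g)
  pool <- sample(g)
  i <- 0
  take <- function(k) { out <- pool[i + seq_len(k)]; i <<- i + k; out }
  strong_dn <- take(config$n_strong_dropout)
  strong_up <- take(config$n_strong_enrichment)
  single <- take(config$n_single_efficient)
  label[strong_dn] <- "strong_dropout"
  label[strong_up] <- "strong_enrichment"
  label[single] <- "single_efficient_guide"

  d <- rep(0, g)
  d[strong_dn] <- config$dropout_effect
  d[strong_up] <- config$enrichment_effect
  d[single] <- config$single_effect
  f <- if (config$basal_fitness_sd > 0)
    stats::rnorm(g, 0, config$basal_fitness_sd) else rep(0, g)

  guide_gene <- rep(genes, each = gpg)
  guide_id <- paste0(guide_gene, "_sg", seq_len(gpg))
  eff <- numeric(length(guide_id))
  for (j in seq_len(g)) {
    idx <- (j - 1) * gpg + seq_len(gpg)
    eff[idx] <- switch(label[j],
      strong_dropout = ,
      strong_enrichment = stats::rbeta(gpg,
        config$strong_efficiency_shape[1], config$strong_efficiency_shape[2]),
      single_efficient_guide = c(1, rep(0, gpg - 1)),
      # null genes: inactive/active mixture (phenotypically moot at d = 0)
      ifelse(stats::runif(gpg) < config$inactive_fraction, 0,
             stats::rbeta(gpg, config$efficiency_shape[1],
                          config$efficiency_shape[2])))
  }

  nc <- config$n_control_guides
  all_ids <- c(guide_id, if (nc) sprintf("CTRL_sg%03d", seq_len(nc)))
  all_genes <- c(guide_gene, rep("non-targeting", nc))
  lib <- guide_library(all_ids,
                       random_spacers(length(all_ids), config$spacer_length),
                       all_genes,
                       is_control = c(rep(FALSE, length(guide_id)),
                                      rep(TRUE, nc)),
                       guides_per_gene = gpg,
                       spacer_length = config$spacer_length)
  truth <- list(
    genes = data.frame(gene = genes, label = label, d = d, f = f,
                       stringsAsFactors = FALSE),
    guides = data.frame(guide_id = all_ids, gene = all_genes,
                        efficiency = c(eff, rep(0, nc)),
                        stringsAsFactors = FALSE))
  list(library = lib, truth = truth)
}

#' Simulate screen counts over the arm/timepoint layout
#'
#' Produces baseline (T0) replicates plus paired vehicle/drug arms at
#' T1-T3, with counts drawn around depth-scaled relative abundances so
#' compositional effects (mass lost by dropouts inflating the rest) are
#' reproduced.
#'
#' @param library,truth from [simulate_library()].
#' @param config the same [sim_config()].
#' @param seed overrides `config$seed + 1`.
#' @return A [screen_counts()] object with samples `T0_R*`, `VEH_T*_R*`,
#'   `DRUG_T*_R*`.
#' @export
simulate_screen <- function(library, truth, config,
                            seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- nrow(library)
  depth <- config$coverage * n
  a0 <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)

  gi <- match(library$gene, truth$genes$gene)  # NA for controls
  d <- ifelse(is.na(gi), 0, truth$genes$d[gi])
  f <- ifelse(is.na(gi), 0, truth$genes$f[gi])
  e <- truth$guides$efficiency[match(library$guide_id,
                                     truth$guides$guide_id)]
  p_cum <- cumsum(config$pressure)
  tps <- names(config$pressure)

  draw <- function(mu) {
    if (is.infinite(config$dispersion)) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
  }
  cols <- list(); meta <- list()
  add <- function(id, arm, tp, rep_, logmult) {
    w <- a0 * exp(logmult)
    cols[[id]] <<- draw(depth * w / sum(w))
    meta[[id]] <<- data.frame(sample_id = id, arm = arm, timepoint = tp,
                              replicate = rep_, stringsAsFactors = FALSE)
  }
  for (r in seq_len(config$n_reps_t0))
    add(paste0("T0_R", r), "baseline", "T0", r, 0)
  for (t in seq_along(tps)) for (r in seq_len(config$n_reps_arm)) {
    add(paste0("VEH_", tps[t], "_R", r), "vehicle", tps[t], r,
        e * f * t)
    add(paste0("DRUG_", tps[t], "_R", r), "drug", tps[t], r,
        e * (f * t + d * p_cum[t]))
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- library$guide_id
  samples <- do.call(rbind, meta)
  class(samples) <- c("sample_info", "data.frame")
  screen_counts(counts, library, samples)
}

#' Simulate a viability plate with known killing effects
#'
#' @param true_killing named numeric vector of true killing percentages
#'   per non-vehicle condition (in [0, 100]); vehicle (0% killing) and
#'   blank wells are added automatically.
#' @param cv multiplicative noise coefficient of variation on well
#'   signals (0 = noiseless).
#' @param n_replicates wells per condition (default 4, as in the assays).
#' @param blank,vehicle_signal blank absorbance and vehicle signal above
#'   blank.
#' @param seed random seed.
#' @return List with `reads` (well, absorbance) and `layout`
#'   (well, condition), ready for [compute_viability()].
#' @export
simulate_plate <- function(true_killing, cv = 0.05, n_replicates = 4,
                           blank = 0.1, vehicle_signal = 1, seed = 1L) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (any(true_killing < 0 | true_killing > 100))
    stop("true killing must be in [0, 100]")
  if (is.null(names(true_killing)) || any(!nzchar(names(true_killing))))
    stop("true_killing must be a named vector of conditions")
  set.seed(seed)
  conds <- c(blank = NA, vehicle = 0, true_killing)
  names(conds)[1:2] <- c("blank", "vehicle")
  rows <- list()
  w <- 0
  for (j in seq_along(conds)) {
    for (r in seq_len(n_replicates)) {
      w <- w + 1
      well <- sprintf("%s%02d", LETTERS[(w - 1) %/% 12 + 1],
                      (w - 1) %% 12 + 1)
      ab <- if (is.na(conds[j])) blank else
        blank + vehicle_signal * (1 - conds[j] / 100) *
          (1 + if (cv > 0) stats::rnorm(1, 0, cv) else 0)
      rows[[w]] <- data.frame(well = well, condition = names(conds)[j],
                              absorbance = ab, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  list(reads = df[, c("well", "absorbance")],
       layout = df[, c("well", "condition")])
}

#' Write a synthetic FASTQ realizing a known count vector
#'
#' Emits, for each guide, `counts[guide]` reads of the form
#' prefix + anchor + spacer + tail, plus optional anchor-less and
#' unmapped (anchor + non-library 20-mer) reads — the exact-recovery
#' oracle for [count_spacers()].
#'
#' @param counts named integer vector (names = guide ids).
#' @param library the [guide_library()] supplying spacers.
#' @param path output FASTQ path (`.gz` supported).
#' @param anchor anchor sequence placed before each spacer.
#' @param n_anchorless,n_unmapped extra reads without the anchor / with
#'   an alien spacer.
#' @param seed random seed for prefixes/tails and read shuffling.
#' @return `path`, invisibly.
#' @export
simulate_fastq <- function(counts, library, path, anchor = "CACCG",
                           n_anchorless = 0, n_unmapped = 0, seed = 1L) {
  stopifnot(inherits(library, "guide_library"))
  set.seed(seed)
  len <- attr(library, "spacer_length")
  bad <- setdiff(names(counts), library$guide_id)
  if (length(bad)) stop("unknown guide(s): ", paste(bad, collapse = ", "))
  sp <- library$spacer[match(names(counts), library$guide_id)]
  rand_dna <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = ""),
    character(1))
  # prefixes must not create a spurious earlier anchor occurrence
  # (including across the prefix-anchor junction), or the synthesized
  # read would not realize the requested count vector
  clean_prefix <- function(n) {
    p <- rand_dna(n)
    repeat {
      bad <- regexpr(anchor, paste0(p, anchor), fixed = TRUE) != nchar(p) + 1L
      if (!any(bad)) return(p)
      p[bad] <- rand_dna(sum(bad))
    }
  }
  seqs <- rep(sp, counts)
  seqs <- paste0(clean_prefix(length(seqs)), anchor, seqs,
                 rand_dna(length(seqs)))
  if (n_anchorless > 0)
    seqs <- c(seqs, vapply(seq_len(n_anchorless), function(i)
      paste(sample(c("A", "C", "T"), 40, replace = TRUE), collapse = ""),
      character(1)))
  if (n_unmapped > 0) {
    alien <- random_spacers(n_unmapped, len)
    alien <- alien[!alien %in% library$spacer]
    seqs <- c(seqs, paste0(clean_prefix(length(alien)), anchor, alien,
                           rand_dna(length(alien))))
  }
  seqs <- sample(seqs)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0("@read", i), seqs[i], "+",
                 strrep("I", nchar(seqs[i]))), con)
  invisible(path)
}
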