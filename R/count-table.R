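#' Describe the samples of a screen
#'
#' Sample metadata ties each sequencing sample to a screen arm and
#' timepoint. `T0` is the baseline collected before the arms split;
#' `T1`-`T3` follow under escalating drug pressure.
#'
#' @param sample_id unique sample identifiers.
#' @param arm arm label per sample, e.g. `"baseline"`, `"vehicle"` or a
#'   drug name. Baseline samples must be at timepoint `T0`.
#' @param timepoint one of `"T0"`, `"T1"`, `"T2"`, `"T3"` per sample.
#' @param replicate integer replicate index (>= 1).
#' @return A data frame of class `sample_info`.
#' @export
sample_info <- function(sample_id, arm, timepoint, replicate = 1L) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  arm <- rep_len(as.character(arm), n)
  timepoint <- rep_len(as.character(timepoint), n)
  replicate <- rep_len(as.integer(replicate), n)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad_tp <- setdiff(unique(timepoint), c("T0", "T1", "T2", "T3"))
  if (length(bad_tp))
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "))
  if (any(replicate < 1L)) stop("replicate indices must be >= 1")
  key <- paste(arm, timepoint, replicate)
  if (anyDuplicated(key))
    stop("duplicate (arm, timepoint, replicate) combination: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (any(arm == "baseline" & timepoint != "T0"))
    stop("baseline samples must carry timepoint T0")
  out <- data.frame(sample_id = sample_id, arm = arm, timepoint = timepoint,
                    replicate = replicate, stringsAsFactors = FALSE)
  class(out) <- c("sample_info", "data.frame")
  out
}

#' Construct a screen count table
#'
#' Bundles the guides x samples matrix of read counts with the guide
#' library and per-sample metadata, mirroring the list design of count
#' containers in the differential-abundance world.
#'
#' @param counts integer matrix, guides in rows (rownames = guide ids),
#'   samples in columns (colnames = sample ids). Non-negative.
#' @param library the [guide_library()] the rows belong to. Guides present
#'   in the library but absent from `counts` are zero-filled with a
#'   warning (dropout screens legitimately drive counts to zero).
#' @param samples a [sample_info()] covering every column, or `NULL` to
#'   derive a minimal one from the column names.
#' @return A list of class `screen_counts` with elements `counts`,
#'   `samples`, `library` and `total_reads` (column sums).
#' @export
screen_counts <- function(counts, library, samples = NULL) {
  stopifnot(inherits(library, "guide_library"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have guide rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"

  unknown <- setdiff(rownames(counts), library$guide_id)
  if (length(unknown))
    stop("guide(s) not present in the library: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  absent <- setdiff(library$guide_id, rownames(counts))
  if (length(absent)) {
    warning(length(absent), " library guide(s) absent from counts; ",
            "filled with zeros")
    zeros <- matrix(0, length(absent), ncol(counts),
                    dimnames = list(absent, colnames(counts)))
    counts <- rbind(counts, zeros)
  }
  counts <- counts[library$guide_id, , drop = FALSE]

  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(counts),
                          arm = NA_character_, timepoint = NA_character_,
                          replicate = NA_integer_, stringsAsFactors = FALSE)
    class(samples) <- c("sample_info", "data.frame")
  }
  missing_meta <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_meta))
    stop("sample(s) missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL

  structure(list(counts = counts, samples = samples, library = library,
                 total_reads = colSums(counts)),
            class = "screen_counts")
}

#' Read a count table from a delimited text file
#'
#' @param path TSV/CSV (optionally gzipped); first column `guide_id`,
#'   remaining columns one per sample.
#' @param library the [guide_library()] the counts were made against.
#' @param samples optional [sample_info()] for the sample columns.
#' @return A [screen_counts()] object.
#' @export
read_counts <- function(path, library, samples = NULL) {
  df <- read_delim_auto(path)
  if (names(df)[1] != "guide_id")
    stop("first column of a count file must be 'guide_id'")
  if (ncol(df) < 2) stop("count file has no sample columns")
  mat <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(mat))) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("non-integer or negative count at row %d, column '%s'",
                   bad[1], colnames(mat)[j]))
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df$guide_id)
  if (nrow(mat) == 0) {
    warning("count file has no data rows; all counts set to zero")
    mat <- matrix(0, length(library$guide_id), ncol(mat),
                  dimnames = list(library$guide_id, colnames(mat)))
  }
  screen_counts(mat, library, samples)
}

#' Write a count table to a delimited text file
#'
#' Columns follow the sample order of the object; zero counts are kept so
#' the file round-trips exactly through [read_counts()].
#'
#' @param x a [screen_counts()].
#' @param path output TSV/CSV path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "screen_counts"))
  df <- data.frame(guide_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_delim_auto(df, path)
  invisible(path)
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("Screen counts: %d guides x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("Samples:\n")
  print(as.data.frame(x$samples))
  invisible(x)
}

# resolve sample ids to column indices with a clear error
sample_index <- function(x, ids) {
  idx <- match(ids, colnames(x$counts))
  if (anyNA(idx))
    stop("unknown sample(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}
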