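#' Construct a validated guide library
#'
#' A guide library maps each sgRNA (identified by its 20-nt spacer) to the
#' gene it targets. The library is the unit against which sequencing reads
#' are counted and per-gene guide sets (default six guides per gene, as in
#' GeCKOv2-style libraries) are summarized.
#'
#' @param guide_id character, unique guide identifiers.
#' @param spacer character, fixed-length DNA spacers over A/C/G/T.
#' @param gene character, target gene symbol (or a control label).
#' @param is_control logical, `TRUE` for non-targeting control guides.
#' @param guides_per_gene expected guide-set size per gene (default 6).
#' @param spacer_length required spacer length (default 20).
#' @return A data frame of class `guide_library` with columns `guide_id`,
#'   `spacer`, `gene`, `is_control` and attributes `guides_per_gene` and
#'   `spacer_length`.
#' @examples
#' lib <- guide_library(c("g1", "g2"),
#'                      c(strrep("A", 20), strrep("C", 20)),
#'                      c("TP53", "TP53"))
#' @export
guide_library <- function(guide_id, spacer, gene, is_control = FALSE,
                          guides_per_gene = 6L, spacer_length = 20L) {
  guide_id <- as.character(guide_id)
  spacer <- toupper(as.character(spacer))
  gene <- as.character(gene)
  n <- length(guide_id)
  if (length(spacer) != n || length(gene) != n)
    stop("guide_id, spacer and gene must have equal length")
  is_control <- rep_len(as.logical(is_control), n)

  dup <- unique(guide_id[duplicated(guide_id)])
  if (length(dup))
    stop("duplicate guide_id: ", paste(dup, collapse = ", "))
  bad_len <- guide_id[nchar(spacer) != spacer_length]
  if (length(bad_len))
    stop("spacer length != ", spacer_length, " for guide(s): ",
         paste(utils::head(bad_len, 5), collapse = ", "))
  bad_alpha <- guide_id[grepl("[^ACGT]", spacer)]
  if (length(bad_alpha))
    stop("spacer contains non-ACGT characters for guide(s): ",
         paste(utils::head(bad_alpha, 5), collapse = ", "))
  dup_sp <- unique(spacer[duplicated(spacer)])
  if (length(dup_sp))
    stop("duplicate spacer sequence(s): ",
         paste(utils::head(dup_sp, 3), collapse = ", "))
  if (any(!nzchar(gene)))
    stop("empty gene label for guide(s): ",
         paste(utils::head(guide_id[!nzchar(gene)], 5), collapse = ", "))

  out <- data.frame(guide_id = guide_id, spacer = spacer, gene = gene,
                    is_control = is_control, stringsAsFactors = FALSE)
  attr(out, "guides_per_gene") <- as.integer(guides_per_gene)
  attr(out, "spacer_length") <- as.integer(spacer_length)
  class(out) <- c("guide_library", "data.frame")
  out
}

#' Read a guide library from a delimited text file
#'
#' @param path TSV/CSV file (optionally gzipped) with a header row.
#' @param guide_col,spacer_col,gene_col,control_col column names; the
#'   control column is optional in the file.
#' @param ... passed to [guide_library()] (e.g. `spacer_length`).
#' @return A [guide_library()].
#' @export
read_library <- function(path, guide_col = "guide_id", spacer_col = "spacer",
                         gene_col = "gene", control_col = "is_control", ...) {
  df <- read_delim_auto(path)
  need <- c(guide_col, spacer_col, gene_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("library file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  is_control <- if (control_col %in% names(df))
    as.logical(df[[control_col]]) else FALSE
  guide_library(df[[guide_col]], df[[spacer_col]], df[[gene_col]],
                is_control = is_control, ...)
}

#' Write a guide library to a delimited text file
#'
#' @param library a [guide_library()].
#' @param path output path; `.csv` extension selects comma separation,
#'   anything else tab.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "guide_library"))
  write_delim_auto(as.data.frame(library), path)
  invisible(path)
}

#' @export
print.guide_library <- function(x, ...) {
  cat(sprintf("Guide library: %d guides, %d genes (%d control guides)\n",
              nrow(x), length(unique(x$gene[!x$is_control])),
              sum(x$is_control)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# shared delimited-text helpers; gz handled transparently by file()
read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

write_delim_auto <- function(df, path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}
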