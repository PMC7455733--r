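#' @title Input/output for sorted-screen tables
#' @description Readers, validators and writers for the three tabular inputs
#'   of a FACS-sorted CRISPR screen: the sgRNA library table, the sample
#'   sheet, and the sgRNA x sample read-count matrix. All files are
#'   tab-separated with a header line; lines starting with '#' are comments.
#' @name screen_io
NULL

#' Default gene label marking nontargeting control guides
#' @export
NT_LABEL <- "NONTARGETING"

read_tsv_ <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Construct and validate an sgRNA library table
#'
#' The library table maps every sgRNA to its target gene (or marks it as a
#' nontargeting control) and records the sublibrary it belongs to.
#' Nontargeting guides define both the normalization denominator and the
#' null distribution for hit calling, so a library without them is rejected.
#'
#' @param sgrna_id character vector of unique guide identifiers.
#' @param gene_id character vector; `NA`, `""` or `nt_label` marks a
#'   nontargeting guide.
#' @param sublibrary_id character vector of sublibrary labels (recycled).
#' @param nt_label sentinel gene label treated as nontargeting.
#' @return A `library_table`: a data.frame with columns `sgrna_id`,
#'   `gene_id` (`NA` for nontargeting) and `sublibrary_id`.
#' @export
library_table <- function(sgrna_id, gene_id, sublibrary_id = "lib1",
                          nt_label = NT_LABEL) {
  sgrna_id <- as.character(sgrna_id)
  gene_id <- as.character(gene_id)
  if (length(gene_id) != length(sgrna_id))
    stop("sgrna_id and gene_id must have equal length")
  dup <- duplicated(sgrna_id)
  if (any(dup))
    stop("duplicate sgrna_id in library: ",
         paste(utils::head(unique(sgrna_id[dup]), 5L), collapse = ", "))
  gene_id[is.na(gene_id) | gene_id == "" | gene_id == nt_label] <- NA_character_
  if (!any(is.na(gene_id)))
    stop("library contains no nontargeting guides; ",
         "normalization and null construction are impossible")
  out <- data.frame(sgrna_id = sgrna_id, gene_id = gene_id,
                    sublibrary_id = rep_len(as.character(sublibrary_id),
                                            length(sgrna_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("library_table", "data.frame")
  attr(out, "nt_label") <- nt_label
  out
}

#' Test which guides of a library are nontargeting
#' @param library a `library_table`.
#' @return logical vector aligned with the library rows.
#' @export
is_nontargeting <- function(library) is.na(library$gene_id)

#' Read an sgRNA library table from a TSV file
#'
#' @param path file with header columns `sgrna_id`, `gene_id`,
#'   `sublibrary_id`; an empty `gene_id` or the `nt_label` sentinel marks a
#'   nontargeting guide.
#' @param nt_label sentinel gene label treated as nontargeting.
#' @return a validated [library_table()].
#' @export
read_library <- function(path, nt_label = NT_LABEL) {
  df <- read_tsv_(path, colClasses = "character")
  need <- c("sgrna_id", "gene_id", "sublibrary_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("library file missing columns: ", paste(miss, collapse = ", "))
  lib <- library_table(df$sgrna_id, df$gene_id, df$sublibrary_id, nt_label)
  nt <- is_nontargeting(lib)
  message(sprintf("library: %d genes, %d targeting guides, %d nontargeting guides",
                  length(unique(lib$gene_id[!nt])), sum(!nt), sum(nt)))
  lib
}

SENSOR_LEVELS <- c("live", "dead")
CONDITION_LEVELS <- c("respiratory", "glycolytic", "basal")
FRACTION_LEVELS <- c("high", "low", "pre", "post")
ASSAY_LEVELS <- c("atp", "mito", "consumption", "growth")

#' Construct and validate a sample sheet
#'
#' Each row describes one sequenced sample (one sorted fraction of one
#' replicate of one sensor channel). Within every (condition, replicate,
#' sensor, assay) group the two fractions must pair up: exactly one `high`
#' with one `low`, or one `pre` with one `post`.
#'
#' @param sample_id,condition,fraction,replicate,sensor,assay vectors of
#'   equal length (condition/fraction/sensor/assay validated against their
#'   allowed levels; replicate a positive integer).
#' @return a `sample_sheet` data.frame.
#' @export
sample_sheet <- function(sample_id, condition, fraction, replicate,
                         sensor = "live", assay = "atp") {
  n <- length(sample_id)
  df <- data.frame(sample_id = as.character(sample_id),
                   condition = rep_len(as.character(condition), n),
                   fraction = rep_len(as.character(fraction), n),
                   replicate = rep_len(as.integer(replicate), n),
                   sensor = rep_len(as.character(sensor), n),
                   assay = rep_len(as.character(assay), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet")
  chk <- function(col, levels) {
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s", col, paste(bad, collapse = ", ")))
  }
  chk("condition", CONDITION_LEVELS)
  chk("fraction", FRACTION_LEVELS)
  chk("sensor", SENSOR_LEVELS)
  chk("assay", ASSAY_LEVELS)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop("replicate must be a positive integer")
  key <- interaction(df$condition, df$replicate, df$sensor, df$assay,
                     drop = TRUE)
  for (g in levels(key)) {
    fr <- sort(df$fraction[key == g])
    ok <- identical(fr, c("high", "low")) || identical(fr, c("post", "pre"))
    if (!ok)
      stop("incomplete fraction pairing for group ", g,
           ": found {", paste(fr, collapse = ", "),
           "}, need one high+low or one pre+post")
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from a TSV file
#' @param path file with header columns `sample_id`, `condition`,
#'   `fraction`, `replicate`, `sensor`, `assay`.
#' @return a validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_(path)
  need <- c("sample_id", "condition", "fraction", "replicate", "sensor", "assay")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  sample_sheet(df$sample_id, df$condition, df$fraction, df$replicate,
               df$sensor, df$assay)
}

#' Construct and validate a sorted count set
#'
#' Bundles the integer read-count matrix with its library and sample sheet.
#' Counts must be nonnegative integers; every row must be a known library
#' guide (unknown guides suggest mis-joined files and are rejected); guides
#' missing from the matrix are added as zero rows with a warning; every
#' sample column must contain at least one read.
#'
#' @param counts numeric matrix, rows sgRNAs (rownames required), columns
#'   samples (colnames required).
#' @param library a [library_table()].
#' @param samples a [sample_sheet()].
#' @return a `sorted_count_set`: list with elements `counts`, `library`,
#'   `samples`.
#' @export
sorted_count_set <- function(counts, library, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at sgRNA '%s', sample '%s': %s",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
                 counts[bad[1L, , drop = FALSE]]))
  unknown <- setdiff(rownames(counts), library$sgrna_id)
  if (length(unknown))
    stop("count matrix contains guides absent from the library: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  missing <- setdiff(library$sgrna_id, rownames(counts))
  if (length(missing)) {
    warning(length(missing), " library guides absent from counts; added as zeros")
    zero <- matrix(0, nrow = length(missing), ncol = ncol(counts),
                   dimnames = list(missing, colnames(counts)))
    counts <- rbind(counts, zero)
  }
  counts <- counts[library$sgrna_id, , drop = FALSE]
  extra <- setdiff(colnames(counts), samples$sample_id)
  if (length(extra))
    stop("count matrix samples missing from sample sheet: ",
         paste(extra, collapse = ", "))
  counts <- counts[, samples$sample_id, drop = FALSE]
  allzero <- colSums(counts) == 0
  if (any(allzero))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[allzero], collapse = ", "))
  storage.mode(counts) <- "double"
  structure(list(counts = counts, library = library, samples = samples),
            class = "sorted_count_set")
}

#' Read a sorted count set from TSV files
#'
#' @param count_path TSV matrix: first column `sgrna_id`, remaining columns
#'   one per sample.
#' @param sheet_path sample sheet TSV (see [read_sample_sheet()]).
#' @param library a [library_table()].
#' @return a validated [sorted_count_set()].
#' @export
read_counts <- function(count_path, sheet_path, library) {
  df <- read_tsv_(count_path)
  if (names(df)[1L] != "sgrna_id")
    stop("count file must have 'sgrna_id' as its first column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sgrna_id
  samples <- read_sample_sheet(sheet_path)
  sorted_count_set(m, library, samples)
}

#' @export
print.sorted_count_set <- function(x, ...) {
  cat(sprintf("sorted_count_set: %d guides x %d samples (%d nontargeting)\n",
              nrow(x$counts), ncol(x$counts), sum(is_nontargeting(x$library))))
  invisible(x)
}

#' Write a result table as deterministic TSV
#'
#' Numeric columns are serialized with 17 significant digits so a reread
#' reproduces the doubles exactly; identical inputs yield byte-identical
#' files.
#'
#' @param table nonempty data.frame.
#' @param path output file path.
#' @param comments optional character vector written as leading '#' lines
#'   (e.g. the RNG seed for provenance).
#' @export
write_results <- function(table, path, comments = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("refusing to write an empty table")
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
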