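# Readers and writers for the plain-text formats the pipeline consumes:
# FASTQ/FASTA via Biostrings, tab-delimited count matrices, term->gene
# annotation tables, Ct tables and the truth-set JSON.

#' Read a small-RNA FASTQ file
#'
#' Reads a (possibly gzipped) FASTQ file into a
#' [Biostrings::QualityScaledDNAStringSet] with Phred+33 qualities.
#' Records whose sequence and quality strings differ in length are
#' rejected by the underlying parser.
#'
#' @param path path to a FASTQ file.
#' @return a `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path,
                                              quality.scoring = "phred"),
    warning = function(w) {
      # qualities are re-attached as PhredQuality; the metadata-column
      # bookkeeping notice is irrelevant here
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  Biostrings::writeXStringSet(as(reads, "DNAStringSet"), path,
                              format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#'
#' @param sequences named character vector (DNA or RNA alphabet).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a tab-delimited count matrix
#'
#' First column feature id, remaining columns one integer count per sample.
#'
#' @param path path to a TSV file.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a count matrix as TSV
#'
#' @param counts matrix with feature rownames and sample colnames.
#' @param path output path.
#' @param feature_col name for the leading id column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, feature_col = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a term-to-gene annotation table
#'
#' Two tab-separated columns (term id, gene id) with an optional third
#' namespace column; a missing namespace defaults to `"GO"`.
#'
#' @param path path to a TSV file (no header required; a header line whose
#'   first field is `"term"` is skipped).
#' @return data.frame with columns `term`, `gene`, `namespace`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) > 0 && identical(tolower(df[1, 1]), "term")) {
    df <- df[-1, , drop = FALSE]
  }
  if (ncol(df) < 2) stop("annotation table needs at least two columns")
  out <- data.frame(term = df[[1]], gene = df[[2]],
                    stringsAsFactors = FALSE)
  out$namespace <- if (ncol(df) >= 3) df[[3]] else "GO"
  out
}

#' Write a term-to-gene annotation table
#'
#' @param annotation data.frame with columns `term`, `gene` and optionally
#'   `namespace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  cols <- intersect(c("term", "gene", "namespace"), colnames(annotation))
  utils::write.table(annotation[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Expects tab-separated columns `sample`, `stage`, `gene`, `replicate`,
#' `ct` (with header).
#'
#' @param path path to a TSV file.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "stage", "gene", "replicate", "ct")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("Ct table is missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a qPCR Ct table
#' @param ct data.frame as returned by [generate_qpcr()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a truth set to JSON
#'
#' @param truth a `truth_set` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  x <- unclass(truth)
  # named atomic vectors serialize as JSON objects, keeping the names
  x$de_direction <- lapply(x$de_direction, as.list)
  x$read_category <- as.list(x$read_category)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a truth set written by [write_truth()]
#'
#' @param path path to the JSON file.
#' @return a `truth_set` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$de_direction <- lapply(x$de_direction, function(v) unlist(v))
  x$read_category <- unlist(x$read_category)
  x$true_pairs <- as.data.frame(x$true_pairs,
                                stringsAsFactors = FALSE)
  x$planted_sites <- as.data.frame(x$planted_sites,
                                   stringsAsFactors = FALSE)
  structure(x, class = "truth_set")
}

#' Collapse reads to distinct sequences
#'
#' Collapses a set of (trimmed) reads to distinct sequences with
#' multiplicities, using the `seq_<n>_x<count>` FASTA header dialect common
#' in small-RNA pipelines.
#'
#' @param reads a `DNAStringSet`, `QualityScaledDNAStringSet` or character
#'   vector of sequences.
#' @return named character vector, names `seq_<n>_x<count>`, ordered by
#'   decreasing count then sequence.
#' @export
collapse_reads <- function(reads) {
  s <- as.character(reads)
  tab <- table(s)
  tab <- tab[order(-as.integer(tab), names(tab))]
  stats::setNames(names(tab),
                  sprintf("seq_%d_x%d", seq_along(tab), as.integer(tab)))
}

#' Expand collapsed reads back to a sequence multiset
#'
#' Inverse of [collapse_reads()]: parses the `_x<count>` suffix and
#' replicates each distinct sequence `count` times.
#'
#' @param collapsed named character vector in the `seq_<n>_x<count>` dialect.
#' @return unnamed character vector of sequences.
#' @export
expand_collapsed_reads <- function(collapsed) {
  counts <- sub("^.*_x(\\d+)$", "\\1", names(collapsed))
  if (any(!grepl("^\\d+$", counts))) {
    stop("headers do not follow the seq_<n>_x<count> dialect")
  }
  rep(unname(collapsed), as.integer(counts))
}
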