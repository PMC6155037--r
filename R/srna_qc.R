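# Small-RNA read QC: the six-category filter cascade with per-sample
# accounting, read length distributions, per-position base composition,
# and known/unknown classification against a mature miRNA reference.
#
# The cascade order follows the per-sample accounting tables of small-RNA
# pipelines top to bottom; each read is counted once, in the FIRST failing
# category, so the categories partition the input:
#   low_quality -> adaptor3_null -> insert_null -> adaptor5_contaminant
#   -> size_lt_18 -> polyA -> high_quality.

qc_categories <- .artifact_categories

#' QC configuration for the small-RNA filter cascade
#'
#' "Low quality" is defined as mean Phred below `quality_threshold` or more
#' than `max_n_fraction` ambiguous base calls; "adaptor3 null" as no match
#' of the first `adaptor_prefix_length` nt of the 3' adaptor anywhere in
#' the read allowing `adaptor_mismatch` mismatches; "insert null" as that
#' match sitting at position 1 (empty insert); "5' adaptor contaminant" as
#' the 5' adaptor prefix found starting within the first 8 nt; "polyA" as a
#' post-trim insert with at least `polya_threshold` adenines. All
#' thresholds are configurable.
#'
#' @param adaptor3,adaptor5 adaptor sequences (defaults: Illumina small-RNA
#'   adaptors).
#' @param min_insert_length minimum trimmed insert length (nt).
#' @param quality_threshold mean Phred threshold for the low-quality class.
#' @param max_n_fraction maximum tolerated fraction of N calls.
#' @param polya_threshold adenine fraction at and above which a trimmed
#'   insert is classed polyA.
#' @param adaptor_prefix_length prefix length used for adaptor matching.
#' @param adaptor_mismatch mismatches tolerated in adaptor matching.
#' @param adaptor3_required if `TRUE` (the default, for raw reads) a read
#'   without a 3' adaptor hit is classed `adaptor3_null`; set `FALSE` for
#'   input that is already adaptor-trimmed, in which case the full read is
#'   taken as the insert.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(adaptor3 = "TGGAATTCTCGGGTGCCAAGG",
                      adaptor5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                      min_insert_length = 18L,
                      quality_threshold = 20,
                      max_n_fraction = 0.1,
                      polya_threshold = 0.8,
                      adaptor_prefix_length = 8L,
                      adaptor_mismatch = 1L,
                      adaptor3_required = TRUE) {
  stopifnot(nzchar(adaptor3), nzchar(adaptor5), min_insert_length >= 1)
  structure(list(adaptor3 = adaptor3, adaptor5 = adaptor5,
                 min_insert_length = as.integer(min_insert_length),
                 quality_threshold = quality_threshold,
                 max_n_fraction = max_n_fraction,
                 polya_threshold = polya_threshold,
                 adaptor_prefix_length = as.integer(adaptor_prefix_length),
                 adaptor_mismatch = as.integer(adaptor_mismatch),
                 adaptor3_required = isTRUE(adaptor3_required)),
            class = "qc_config")
}

#' Build a per-sample filter accounting report
#'
#' The surviving high-quality count is derived from the accounting
#' identity `total = high_quality + sum(category counts)`, and every
#' percentage is `round(100 * count / total, 2)`.
#'
#' @param sample_id sample label.
#' @param total_reads total raw reads.
#' @param category_counts named numeric vector over the six filter
#'   categories (missing categories count 0).
#' @return an object of class `filter_report`.
#' @export
filter_report <- function(sample_id, total_reads, category_counts) {
  counts <- stats::setNames(numeric(length(qc_categories)), qc_categories)
  bad <- setdiff(names(category_counts), qc_categories)
  if (length(bad)) {
    stop("unknown filter categories: ", paste(bad, collapse = ", "))
  }
  counts[names(category_counts)] <- category_counts
  high_quality <- total_reads - sum(counts)
  if (high_quality < 0) {
    stop("category counts exceed total_reads for sample ", sample_id)
  }
  all_counts <- c(counts, high_quality = high_quality)
  pct <- if (total_reads > 0) round(100 * all_counts / total_reads, 2)
         else all_counts * 0
  structure(list(sample_id = sample_id, total_reads = total_reads,
                 counts = counts, high_quality = high_quality,
                 percentages = pct),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Small-RNA filter report --", x$sample_id, "\n")
  cat(sprintf("  %-22s %12s %8s\n", "class", "reads", "%"))
  cat(sprintf("  %-22s %12s %8.2f\n", "total", format(x$total_reads,
                                                      big.mark = ","), 100))
  for (cat_i in names(x$counts)) {
    cat(sprintf("  %-22s %12s %8.2f\n", cat_i,
                format(x$counts[[cat_i]], big.mark = ","),
                x$percentages[[cat_i]]))
  }
  cat(sprintf("  %-22s %12s %8.2f\n", "high_quality",
              format(x$high_quality, big.mark = ","),
              x$percentages[["high_quality"]]))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(sample = x$sample_id, total_reads = x$total_reads,
             t(x$counts), high_quality = x$high_quality,
             stringsAsFactors = FALSE)
}

first_hits <- function(seqs, pattern, max_mismatch) {
  if (length(seqs) == 0) return(integer(0))
  m <- Biostrings::vmatchPattern(pattern, seqs, max.mismatch = max_mismatch)
  starts <- Biostrings::startIndex(m)
  vapply(starts, function(v) if (length(v)) min(v) else NA_integer_,
         integer(1))
}

#' Filter small-RNA reads through the six-category cascade
#'
#' Assigns every read to exactly one category (see [qc_config()] for the
#' cascade order and the per-category definitions), trims surviving reads
#' to their insert, and returns the trimmed clean reads together with a
#' [filter_report()].
#'
#' @param reads a `QualityScaledDNAStringSet` (see [read_fastq()]).
#' @param config a [qc_config()].
#' @param sample_id label used in the report.
#' @return list with `clean` (trimmed `QualityScaledDNAStringSet`),
#'   `report` (a `filter_report`) and `category` (named per-read category
#'   vector).
#' @export
filter_reads <- function(reads, config = qc_config(), sample_id = "sample") {
  stopifnot(is(reads, "QualityScaledDNAStringSet"),
            inherits(config, "qc_config"))
  n <- length(reads)
  if (n == 0) {
    return(list(clean = reads,
                report = filter_report(sample_id, 0, numeric(0)),
                category = character(0)))
  }
  seqs <- as(reads, "DNAStringSet")
  widths <- Biostrings::width(seqs)

  qual <- as(Biostrings::quality(reads), "IntegerList")
  mean_q <- sum(qual) / widths
  n_frac <- as.vector(Biostrings::letterFrequency(seqs, "N")) / widths

  a3p <- substr(config$adaptor3, 1, config$adaptor_prefix_length)
  a5p <- substr(config$adaptor5, 1, config$adaptor_prefix_length)
  a3_first <- first_hits(seqs, a3p, config$adaptor_mismatch)

  m5 <- Biostrings::vmatchPattern(a5p, seqs,
                                  max.mismatch = config$adaptor_mismatch)
  has_a5 <- vapply(Biostrings::startIndex(m5),
                   function(v) any(v <= 8), logical(1))

  insert_len <- ifelse(is.na(a3_first), widths, a3_first - 1L)
  a_frac <- rep(0, n)
  pos_len <- insert_len > 0
  if (any(pos_len)) {
    ins <- Biostrings::subseq(seqs[pos_len], 1L, insert_len[pos_len])
    a_frac[pos_len] <- as.vector(Biostrings::letterFrequency(ins, "A")) /
      insert_len[pos_len]
  }

  category <- rep("high_quality", n)
  unassigned <- rep(TRUE, n)
  assign_cat <- function(mask, label) {
    hit <- unassigned & mask
    category[hit] <<- label
    unassigned[hit] <<- FALSE
  }
  assign_cat(mean_q < config$quality_threshold |
               n_frac > config$max_n_fraction, "low_quality")
  if (config$adaptor3_required) {
    assign_cat(is.na(a3_first), "adaptor3_null")
  }
  assign_cat(!is.na(a3_first) & a3_first == 1L, "insert_null")
  assign_cat(has_a5, "adaptor5_contaminant")
  assign_cat(insert_len < config$min_insert_length, "size_lt_18")
  assign_cat(a_frac >= config$polya_threshold, "polyA")

  keep <- category == "high_quality"
  clean <- Biostrings::subseq(reads[keep], 1L, insert_len[keep])
  tallies <- table(factor(category, levels = qc_categories))
  report <- filter_report(sample_id, n, stats::setNames(as.numeric(tallies),
                                                        names(tallies)))
  list(clean = clean, report = report,
       category = stats::setNames(category, names(reads)))
}

#' Read length distribution of filtered reads
#'
#' Tallies read lengths over all reads ("total" view) and over distinct
#' sequences ("distinct" view); fractions are normalized within each view.
#'
#' @param reads `DNAStringSet`, `QualityScaledDNAStringSet` or character
#'   vector of (already filtered) reads.
#' @return data.frame with columns `length`, `count`, `fraction`, `view`.
#' @export
length_distribution <- function(reads) {
  s <- as.character(reads)
  one_view <- function(x, view) {
    if (length(x) == 0) {
      return(data.frame(length = integer(0), count = integer(0),
                        fraction = numeric(0), view = character(0),
                        stringsAsFactors = FALSE))
    }
    tab <- table(nchar(x))
    data.frame(length = as.integer(names(tab)),
               count = as.integer(tab),
               fraction = as.integer(tab) / length(x),
               view = view, stringsAsFactors = FALSE)
  }
  rbind(one_view(s, "total"), one_view(unique(s), "distinct"))
}

#' Per-position base composition
#'
#' Fraction of A, C, G, T and N calls at every read position with non-zero
#' coverage. Positions are 0-based from the read start; at every covered
#' position the five fractions sum to one.
#'
#' @param reads `DNAStringSet`, `QualityScaledDNAStringSet` or character
#'   vector.
#' @return data.frame with columns `position`, `A`, `C`, `G`, `T`, `N`,
#'   `coverage`.
#' @export
base_composition <- function(reads) {
  s <- toupper(as.character(reads))
  cols <- c("A", "C", "G", "T", "N")
  if (length(s) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), 5), cols))
    return(cbind(data.frame(position = integer(0)), out,
                 data.frame(coverage = integer(0))))
  }
  maxw <- max(nchar(s))
  rows <- vector("list", maxw)
  for (p in seq_len(maxw)) {
    covered <- s[nchar(s) >= p]
    b <- substr(covered, p, p)
    b[!b %in% cols] <- "N"
    tab <- table(factor(b, levels = cols))
    rows[[p]] <- c(position = p - 1L, tab / length(covered),
                   coverage = length(covered))
  }
  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- c("position", cols, "coverage")
  out
}

#' Classify distinct clean sequences as known or unknown miRNAs
#'
#' A sequence is "known" iff it equals a reference mature sequence exactly
#' or differs from one only by up to `trim_3p` bases added or removed at
#' the 3' end; everything else -- degradation products, other small RNA
#' classes, candidate novel miRNAs -- is "unknown". T/U are equivalent.
#'
#' @param sequences character vector (or `XStringSet`) of distinct clean
#'   sequences.
#' @param reference named character vector (or `XStringSet`) of mature
#'   miRNA sequences.
#' @param trim_3p tolerated 3'-end length difference (nt).
#' @return named character vector of labels (`"known"`/`"unknown"`), one
#'   per input sequence, with a `summary` attribute (counts + fractions).
#' @export
annotate_known_mirnas <- function(sequences, reference, trim_3p = 2L) {
  norm <- function(x) toupper(chartr("uU", "TT", as.character(x)))
  s <- norm(sequences)
  ref <- norm(reference)
  if (length(ref) == 0) {
    warning("empty miRNA reference: labelling every sequence unknown")
    labels <- rep("unknown", length(s))
  } else {
    ref_trimmed <- unique(unlist(lapply(0:trim_3p, function(k) {
      r <- ref[nchar(ref) > k]
      substr(r, 1, nchar(r) - k)
    })))
    known <- s %in% ref_trimmed   # exact or reference trimmed at the 3' end
    for (k in seq_len(trim_3p)) { # sequence carries extra 3' bases
      known <- known | substr(s, 1, nchar(s) - k) %in% ref
    }
    labels <- ifelse(known, "known", "unknown")
  }
  out <- stats::setNames(labels, as.character(sequences))
  attr(out, "summary") <- data.frame(
    status = c("known", "unknown"),
    count = c(sum(labels == "known"), sum(labels == "unknown")),
    fraction = if (length(labels)) {
      c(mean(labels == "known"), mean(labels == "unknown"))
    } else c(NA_real_, NA_real_))
  out
}
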