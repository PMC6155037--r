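# Fold-change quadrant integration of differential miRNAs, differential
# mRNAs and predicted target pairs. The plane is (x = mRNA log2FC,
# y = miRNA log2FC); demarcation lines sit at 1.5-fold on both axes
# (t = log2 1.5), boundaries included. Quadrants II and IV (opposite
# signs) are the negative-regulation pairs.

#' Assign a fold-change quadrant
#'
#' Quadrants require both coordinates beyond the demarcation `t`
#' (inclusive): I = (x >= t, y >= t), II = (x <= -t, y >= t),
#' III = (x <= -t, y <= -t), IV = (x >= t, y <= -t); anything else is
#' `"none"`.
#'
#' @param x mRNA log2 fold change(s).
#' @param y miRNA log2 fold change(s).
#' @param t demarcation threshold, default `log2(1.5)`.
#' @return character vector of quadrant labels.
#' @export
assign_quadrant <- function(x, y, t = log2(1.5)) {
  if (t <= 0) stop("t must be positive")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite fold change supplied to assign_quadrant")
  }
  out <- rep("none", length(x))
  out[x >= t & y >= t] <- "I"
  out[x <= -t & y >= t] <- "II"
  out[x <= -t & y <= -t] <- "III"
  out[x >= t & y <= -t] <- "IV"
  out
}

#' Correlate target pairs with fold changes and classify quadrants
#'
#' Joins predicted target pairs with the miRNA and mRNA differential
#' results, retains pairs whose BOTH members are called differential, and
#' classifies each retained pair into a fold-change quadrant. Pairs in
#' quadrants II and IV are flagged as negative regulation.
#'
#' @param target_pairs data.frame with columns `mirna`, `transcript` (a
#'   `target_prediction$pairs` works directly); when a `passes` column is
#'   present only passing pairs are used unless `passing_only = FALSE`.
#' @param mirna_fc,mrna_fc differential results from
#'   [call_differential()] (columns `feature_id`, `log2fc`, `call`).
#' @param t demarcation threshold, default `log2(1.5)`.
#' @param passing_only honour the `passes` flag of the target table.
#' @return data.frame with columns `mirna`, `mrna`, `x` (mRNA log2fc),
#'   `y` (miRNA log2fc), `quadrant`, `negative_regulation`, ordered by
#'   (miRNA, mRNA).
#' @export
correlate_pairs <- function(target_pairs, mirna_fc, mrna_fc,
                            t = log2(1.5), passing_only = TRUE) {
  pairs <- as.data.frame(target_pairs)
  if (passing_only && "passes" %in% colnames(pairs)) {
    pairs <- pairs[pairs$passes, , drop = FALSE]
  }
  empty <- data.frame(mirna = character(0), mrna = character(0),
                      x = numeric(0), y = numeric(0),
                      quadrant = character(0),
                      negative_regulation = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(empty)
  missing_mir <- setdiff(pairs$mirna, mirna_fc$feature_id)
  missing_gene <- setdiff(pairs$transcript, mrna_fc$feature_id)
  if (length(missing_mir) || length(missing_gene)) {
    stop("missing fold-change records for: ",
         paste(c(missing_mir, missing_gene), collapse = ", "))
  }
  mir_idx <- match(pairs$mirna, mirna_fc$feature_id)
  gene_idx <- match(pairs$transcript, mrna_fc$feature_id)
  keep <- mirna_fc$call[mir_idx] != "ns" & mrna_fc$call[gene_idx] != "ns"
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)
  x <- mrna_fc$log2fc[gene_idx[keep]]
  y <- mirna_fc$log2fc[mir_idx[keep]]
  quadrant <- assign_quadrant(x, y, t)
  out <- data.frame(mirna = pairs$mirna, mrna = pairs$transcript,
                    x = x, y = y, quadrant = quadrant,
                    negative_regulation = quadrant %in% c("II", "IV"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$mrna), ]
  rownames(out) <- NULL
  out
}

#' Summarize miRNA-mRNA pair statistics
#'
#' Degree statistics in the style of a correlation-analysis summary table:
#' per-miRNA target counts and per-transcript miRNA counts (min, max,
#' mean to 2 dp), total and negative pair counts, and quadrant counts.
#'
#' @param pairs data.frame from [correlate_pairs()] (columns `mirna`,
#'   `mrna`, optionally `quadrant`, `negative_regulation`).
#' @return list of class `pair_summary`.
#' @export
summarize_pairs <- function(pairs) {
  degree_stats <- function(ids) {
    if (length(ids) == 0) return(c(min = 0, max = 0, mean = 0))
    d <- table(ids)
    c(min = min(d), max = max(d), mean = round(mean(d), 2))
  }
  quadrants <- if ("quadrant" %in% colnames(pairs)) {
    table(factor(pairs$quadrant, levels = c("I", "II", "III", "IV", "none")))
  } else {
    table(factor(character(0), levels = c("I", "II", "III", "IV", "none")))
  }
  structure(list(
    n_pairs = nrow(pairs),
    n_negative = if ("negative_regulation" %in% colnames(pairs)) {
      sum(pairs$negative_regulation)
    } else 0L,
    quadrant_counts = quadrants,
    targets_per_mirna = degree_stats(pairs$mirna),
    mirnas_per_transcript = degree_stats(pairs$mrna)),
    class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  cat("Pair summary:", x$n_pairs, "pairs,", x$n_negative,
      "negative-regulation\n")
  cat("  quadrants:", paste(names(x$quadrant_counts), x$quadrant_counts,
                            sep = "=", collapse = " "), "\n")
  cat("  targets per miRNA: min", x$targets_per_mirna[["min"]],
      "max", x$targets_per_mirna[["max"]],
      "mean", x$targets_per_mirna[["mean"]], "\n")
  cat("  miRNAs per transcript: min", x$mirnas_per_transcript[["min"]],
      "max", x$mirnas_per_transcript[["max"]],
      "mean", x$mirnas_per_transcript[["mean"]], "\n")
  invisible(x)
}
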