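# Differential expression between telogen and anagen: counts-per-million
# normalization, log2 fold changes on condition means, and an exact
# conditional binomial test on pooled per-condition counts.
#
# The test conditions on each feature's total pooled count and the two
# conditions' library-size ratio, in the style of exact tests for SAGE/
# RNA-seq pools. It is exact under its own (Poisson) sampling model; with
# strong biological overdispersion it is anticonservative, which is why
# the planted-truth fixtures are the primary validation surface.

check_condition <- function(counts, condition) {
  condition <- as.factor(condition)
  if (length(condition) != ncol(counts)) {
    stop("condition must have one label per sample column")
  }
  if (nlevels(droplevels(condition)) != 2) {
    stop("exactly two conditions are required; got levels: ",
         paste(levels(droplevels(condition)), collapse = ", "))
  }
  droplevels(condition)
}

#' Counts-per-million normalization
#'
#' Scales every sample column to a library size of one million.
#'
#' @param counts numeric matrix, features x samples, non-negative.
#' @return numeric matrix of CPM values; every column sums to 1e6.
#' @export
normalize_cpm <- function(counts) {
  cs <- colSums(counts)
  zero <- cs == 0
  if (any(zero)) {
    stop("zero-sum sample column(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  t(t(counts) / cs) * 1e6
}

#' Per-feature log2 fold change between two conditions
#'
#' `log2fc = log2((mean CPM treatment + pseudocount) /
#' (mean CPM reference + pseudocount))`, where the reference is the first
#' condition level (telogen) and the treatment the second (anagen).
#' Swapping the two condition labels negates every fold change exactly.
#'
#' @param counts integer count matrix, features x samples.
#' @param condition factor (or character) of length `ncol(counts)` with
#'   two levels; the first level is the reference.
#' @param pseudocount added to both CPM means; must be > 0 for finite fold
#'   changes at zero counts.
#' @return data.frame with columns `feature_id`, `mean_reference`,
#'   `mean_treatment` (CPM), `log2fc`.
#' @export
log2_fold_change <- function(counts, condition, pseudocount = 0.5) {
  condition <- check_condition(counts, condition)
  cpm <- normalize_cpm(counts)
  ref <- levels(condition)[1]
  trt <- levels(condition)[2]
  mean_ref <- rowMeans(cpm[, condition == ref, drop = FALSE])
  mean_trt <- rowMeans(cpm[, condition == trt, drop = FALSE])
  data.frame(feature_id = rownames(counts),
             mean_reference = mean_ref,
             mean_treatment = mean_trt,
             log2fc = log2((mean_trt + pseudocount) /
                             (mean_ref + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differential features with a pooled exact binomial test
#'
#' For each feature the counts are pooled within each condition and the
#' treatment pool is tested against a binomial with success probability
#' equal to the treatment share of the total library size (a two-sided
#' exact conditional test given the feature total). Calls combine the
#' (optionally BH-adjusted) p-value at `alpha` with the fold-change sign.
#'
#' @inheritParams log2_fold_change
#' @param alpha significance threshold on the (adjusted) p-value.
#' @param adjust `"none"` (raw p-values, the default) or `"BH"`.
#' @return data.frame as [log2_fold_change()] plus `p_value`,
#'   `adjusted_p` and `call` (`"up"`, `"down"` or `"ns"`).
#' @export
call_differential <- function(counts, condition, alpha = 0.05,
                              adjust = c("none", "BH"), pseudocount = 0.5) {
  adjust <- match.arg(adjust)
  condition <- check_condition(counts, condition)
  fc <- log2_fold_change(counts, condition, pseudocount)
  ref <- levels(condition)[1]
  trt <- levels(condition)[2]
  pooled_ref <- rowSums(counts[, condition == ref, drop = FALSE])
  pooled_trt <- rowSums(counts[, condition == trt, drop = FALSE])
  lib_ref <- sum(pooled_ref)
  lib_trt <- sum(pooled_trt)
  prob <- lib_trt / (lib_ref + lib_trt)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    total <- pooled_ref[i] + pooled_trt[i]
    if (total == 0) return(1)
    binom.test(pooled_trt[i], total, p = prob)$p.value
  }, numeric(1))
  padj <- if (adjust == "BH") p.adjust(p, "BH") else p
  call <- rep("ns", nrow(counts))
  call[padj <= alpha & fc$log2fc > 0] <- "up"
  call[padj <= alpha & fc$log2fc < 0] <- "down"
  cbind(fc, data.frame(p_value = p, adjusted_p = padj, call = call,
                       stringsAsFactors = FALSE))
}
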