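# Relative qPCR quantitation by the 2^-ddCt method with a reference gene
# and a calibrator stage, plus pairwise stage comparisons by one-way
# ANOVA with Fisher's LSD. Amplification efficiency is fixed at 2 (the
# method's doubling-per-cycle assumption).

#' Relative expression by the 2^-ddCt method
#'
#' Per biological sample and gene: `dCt = mean Ct(gene) - mean
#' Ct(reference)` over technical replicates; `ddCt = dCt - mean dCt` over
#' the calibrator-stage samples of that gene; `RQ = 2^-ddCt`. Stage-level
#' relative quantities aggregate per-sample RQs by geometric mean (the
#' natural mean for a multiplicative quantity); the calibrator stage
#' therefore has stage RQ exactly 1.
#'
#' @param ct data.frame with columns `sample`, `stage`, `gene`,
#'   `replicate`, `ct` (see [read_ct_table()]); Ct values must lie in
#'   (0, 45).
#' @param reference_gene the reference (housekeeping) gene id.
#' @param calibrator_stage the stage every RQ is expressed against;
#'   defaults to the first stage in the table.
#' @param aggregate `"geometric"` (default) or `"arithmetic"` stage mean.
#' @return list of class `relative_expression` with `samples` (per-sample
#'   table: `sample`, `stage`, `gene`, `delta_ct`, `delta_delta_ct`, `rq`)
#'   and `stages` (per-stage table: `gene`, `stage`, `rq`, `sd`, `n`; `sd`
#'   over biological-sample RQs).
#' @export
delta_delta_ct <- function(ct, reference_gene, calibrator_stage = NULL,
                           aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  need <- c("sample", "stage", "gene", "replicate", "ct")
  if (!all(need %in% colnames(ct))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(ct$ct <= 0 | ct$ct >= 45)) {
    stop("Ct values must lie in (0, 45)")
  }
  if (!reference_gene %in% ct$gene) {
    stop("reference gene ", reference_gene, " absent from the table")
  }
  if (is.null(calibrator_stage)) calibrator_stage <- ct$stage[1]
  if (!calibrator_stage %in% ct$stage) {
    stop("calibrator stage ", calibrator_stage, " absent from the table")
  }
  # technical-replicate means per (sample, gene)
  mean_ct <- stats::aggregate(ct ~ sample + stage + gene, data = ct,
                              FUN = mean)
  ref <- mean_ct[mean_ct$gene == reference_gene, ]
  no_ref <- setdiff(unique(mean_ct$sample), ref$sample)
  if (length(no_ref)) {
    stop("no reference-gene measurement for sample(s): ",
         paste(no_ref, collapse = ", "))
  }
  genes <- mean_ct[mean_ct$gene != reference_gene, , drop = FALSE]
  if (nrow(genes) == 0) genes <- mean_ct  # degenerate: reference only
  genes$delta_ct <- genes$ct - ref$ct[match(genes$sample, ref$sample)]
  cal_mean <- stats::aggregate(
    delta_ct ~ gene, FUN = mean,
    data = genes[genes$stage == calibrator_stage, , drop = FALSE])
  idx <- match(genes$gene, cal_mean$gene)
  if (any(is.na(idx))) {
    stop("gene(s) missing from the calibrator stage: ",
         paste(unique(genes$gene[is.na(idx)]), collapse = ", "))
  }
  genes$delta_delta_ct <- genes$delta_ct - cal_mean$delta_ct[idx]
  genes$rq <- 2^(-genes$delta_delta_ct)
  samples <- genes[, c("sample", "stage", "gene", "delta_ct",
                       "delta_delta_ct", "rq")]
  samples <- samples[order(samples$gene, samples$stage, samples$sample), ]
  rownames(samples) <- NULL

  agg_fun <- if (aggregate == "geometric") {
    function(v) exp(mean(log(v)))
  } else mean
  stages <- do.call(rbind, lapply(
    split(samples, list(samples$gene, samples$stage), drop = TRUE),
    function(sub) {
      data.frame(gene = sub$gene[1], stage = sub$stage[1],
                 rq = agg_fun(sub$rq), sd = stats::sd(sub$rq),
                 n = nrow(sub), stringsAsFactors = FALSE)
    }))
  stages <- stages[order(stages$gene, stages$stage), ]
  rownames(stages) <- NULL
  structure(list(samples = samples, stages = stages,
                 reference_gene = reference_gene,
                 calibrator_stage = calibrator_stage),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat("2^-ddCt relative expression (reference ", x$reference_gene,
      ", calibrator ", x$calibrator_stage, ")\n", sep = "")
  print(x$stages)
  invisible(x)
}

#' Pairwise stage comparisons by ANOVA + Fisher's LSD
#'
#' Per gene: one-way ANOVA on log2 RQ across stages, then Fisher's
#' least-significant-difference pairwise t statistics using the pooled
#' error mean square, `t = (m1 - m2) / sqrt(MSE (1/n1 + 1/n2))` on the
#' residual degrees of freedom; p-values two-sided. Stages with a single
#' biological sample are excluded with a warning. With zero within-stage
#' variance the comparison is degenerate: p is reported as 0 for unequal
#' means (1 for equal) and flagged.
#'
#' @param rq a `relative_expression` (or its `samples` data.frame).
#' @param method only `"LSD"` is implemented.
#' @return data.frame with columns `gene`, `stage1`, `stage2`,
#'   `diff_log2rq`, `t`, `df`, `p_value`, `zero_variance`.
#' @export
compare_stages <- function(rq, method = "LSD") {
  if (!identical(method, "LSD")) {
    stop("only the LSD method is implemented")
  }
  samples <- if (inherits(rq, "relative_expression")) rq$samples else rq
  out <- list()
  for (g in unique(samples$gene)) {
    sub <- samples[samples$gene == g, , drop = FALSE]
    sizes <- table(sub$stage)
    small <- names(sizes)[sizes < 2]
    if (length(small)) {
      warning("gene ", g, ": excluding stage(s) with one sample: ",
              paste(small, collapse = ", "))
      sub <- sub[!sub$stage %in% small, , drop = FALSE]
    }
    stages <- unique(sub$stage)
    if (length(stages) < 2) next
    y <- log2(sub$rq)
    grp <- factor(sub$stage)
    fit <- stats::aov(y ~ grp)
    mse <- sum(fit$residuals^2) / fit$df.residual
    means <- tapply(y, grp, mean)
    ns <- tapply(y, grp, length)
    combos <- utils::combn(levels(grp), 2)
    for (ci in seq_len(ncol(combos))) {
      s1 <- combos[1, ci]
      s2 <- combos[2, ci]
      diff <- means[[s1]] - means[[s2]]
      zero_var <- mse <= .Machine$double.eps
      if (zero_var) {
        tt <- if (diff == 0) 0 else sign(diff) * Inf
        p <- if (diff == 0) 1 else 0
      } else {
        se <- sqrt(mse * (1 / ns[[s1]] + 1 / ns[[s2]]))
        tt <- diff / se
        p <- 2 * stats::pt(-abs(tt), fit$df.residual)
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = g, stage1 = s1, stage2 = s2, diff_log2rq = diff,
        t = tt, df = fit$df.residual, p_value = p,
        zero_variance = zero_var, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), stage1 = character(0),
                      stage2 = character(0), diff_log2rq = numeric(0),
                      t = numeric(0), df = integer(0), p_value = numeric(0),
                      zero_variance = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
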