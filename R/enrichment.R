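# Hypergeometric GO/KEGG enrichment of differential-miRNA target sets.
#
# Notation (as in the enrichment report columns): TB is the number of
# annotated background mRNAs, TS the number of annotated target-set mRNAs,
# B the mRNAs annotated to one term, S the target-set mRNAs annotated to
# that term. The p-value is the exact upper tail
# P(X >= S) = 1 - sum_{i=0}^{S-1} C(B,i) C(TB-B, TS-i) / C(TB, TS),
# evaluated by summing the upper tail in log space.

#' Exact hypergeometric enrichment p-value
#'
#' Upper-tail probability that at least `S` of `TS` genes drawn without
#' replacement from a background of `TB` genes fall into a term of `B`
#' genes. Computed term-by-term via log binomial coefficients, so it is
#' exact in log space for large arguments; `C(n, k) = 0` whenever `k > n`
#' or `k < 0`.
#'
#' @param TB annotated background size.
#' @param TS annotated target-set size (`TS <= TB`).
#' @param B genes annotated to the term (`B <= TB`).
#' @param S target-set genes annotated to the term
#'   (`0 <= S <= min(B, TS)`).
#' @return the p-value `P(X >= S)`; `S = 0` gives 1 by the empty-sum
#'   convention.
#' @export
hypergeom_p <- function(TB, TS, B, S) {
  if (S < 0 || S > min(B, TS)) {
    stop("invariant violated: 0 <= S <= min(B, TS)")
  }
  if (B > TB) stop("invariant violated: B <= TB")
  if (TS > TB) stop("invariant violated: TS <= TB")
  if (S == 0) return(1)
  i <- S:min(B, TS)
  log_terms <- lchoose(B, i) + lchoose(TB - B, TS - i) - lchoose(TB, TS)
  log_terms <- log_terms[is.finite(log_terms)]
  if (!length(log_terms)) return(0)
  m <- max(log_terms)
  exp(m) * sum(exp(log_terms - m))
}

#' Hypergeometric enrichment over an annotation table
#'
#' Tests every annotated term for over-representation of `target_genes`
#' against the annotated background. `TB` and `TS` are computed per
#' namespace (a gene counts as background if it carries at least one
#' annotation in that namespace); terms with `S = 0` are suppressed.
#' Results are ordered by (p-value, term id), with ties broken by term id,
#' and ranked within each namespace.
#'
#' @param target_genes character vector of target-set gene ids.
#' @param annotation data.frame with columns `term`, `gene` and optionally
#'   `namespace` (default namespace `"GO"`).
#' @param background optional gene universe to intersect the annotation
#'   with; defaults to all annotated genes.
#' @return data.frame with columns `term`, `namespace`, `TB`, `TS`, `B`,
#'   `S`, `p_value`, `rich_factor` (`S/B`), `rank`.
#' @export
enrich <- function(target_genes, annotation, background = NULL) {
  ann <- as.data.frame(annotation)
  if (!all(c("term", "gene") %in% colnames(ann))) {
    stop("annotation needs columns 'term' and 'gene'")
  }
  if (!"namespace" %in% colnames(ann)) ann$namespace <- "GO"
  if (!is.null(background)) {
    if (length(background) == 0) stop("empty background")
    ann <- ann[ann$gene %in% background, , drop = FALSE]
    extra <- setdiff(target_genes, background)
    if (length(extra)) {
      stop("target genes outside the background: ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  if (nrow(ann) == 0) stop("empty background: no annotated genes")
  target_genes <- unique(target_genes)

  out <- lapply(split(ann, ann$namespace), function(sub) {
    sub <- unique(sub[, c("term", "gene", "namespace")])
    TB <- length(unique(sub$gene))
    annotated_targets <- intersect(target_genes, sub$gene)
    TS <- length(annotated_targets)
    per_term <- split(sub$gene, sub$term)
    res <- lapply(names(per_term), function(tm) {
      genes <- per_term[[tm]]
      S <- length(intersect(genes, annotated_targets))
      if (S == 0) return(NULL)
      B <- length(genes)
      data.frame(term = tm, namespace = sub$namespace[1],
                 TB = TB, TS = TS, B = B, S = S,
                 p_value = hypergeom_p(TB, TS, B, S),
                 rich_factor = S / B, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(term = character(0), namespace = character(0),
                      TB = integer(0), TS = integer(0), B = integer(0),
                      S = integer(0), p_value = numeric(0),
                      rich_factor = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$p_value, out$term), ]
  out$rank <- stats::ave(seq_len(nrow(out)), out$namespace,
                         FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Top-k enriched terms per namespace
#'
#' The `k` terms with the smallest p-values in each namespace (ties broken
#' by term id); fewer than `k` returns all.
#'
#' @param results data.frame from [enrich()].
#' @param k number of terms per namespace (default 8).
#' @return the ranked sublist, ascending p within namespace.
#' @export
top_k <- function(results, k = 8L) {
  if (k < 1) stop("k must be >= 1")
  out <- do.call(rbind, lapply(split(results, results$namespace),
                               function(sub) {
    sub <- sub[order(sub$p_value, sub$term), ]
    utils::head(sub, k)
  }))
  rownames(out) <- NULL
  out
}
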