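# Shared fixture builders: everything is generated in code at test time.

# A small, fast configuration for structural tests.
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_mirna = 8L, n_mrna = 40L,
         n_de_mirna_up = 2L, n_de_mirna_down = 2L,
         n_de_mrna_up = 6L, n_de_mrna_down = 6L,
         n_true_pairs = 6L,
         n_terms = 10L, genes_per_term = 8L,
         n_enriched_terms = 2L, enriched_overlap = 5L,
         n_reads = 150L),
    list(...))
  do.call(generator_config, args)
}

# The default study conditions used by the recovery checks: 50 planted
# negative-regulation pairs, |log2FC| = 2, NB dispersion 0.1, n = 3.
recovery_config <- function(seed = 1L) {
  generator_config(seed = seed)
}

# Run the de -> targets -> integrate pipeline on one generated study and
# compare flagged negative pairs against the planted truth.
run_recovery_pipeline <- function(config) {
  study <- generate_study(config)
  de_mir <- call_differential(study$mirna_counts, study$condition)
  de_gene <- call_differential(study$mrna_counts, study$condition)
  pred <- predict_targets(study$mirna_seqs, study$utrs)
  quad <- correlate_pairs(pred$pairs, de_mir, de_gene)
  flagged <- quad[quad$negative_regulation, c("mirna", "mrna")]
  truth_key <- paste(study$truth$true_pairs$mirna,
                     study$truth$true_pairs$mrna)
  flagged_key <- paste(flagged$mirna, flagged$mrna)
  list(study = study, de_mir = de_mir, de_gene = de_gene, pred = pred,
       quad = quad,
       n_true = length(truth_key),
       n_recovered = sum(truth_key %in% flagged_key),
       n_false = sum(!flagged_key %in% truth_key),
       n_flagged = length(flagged_key))
}

# Minimal QualityScaledDNAStringSet from plain sequences.
make_reads <- function(seqs, phred = 38L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  quals <- vapply(nchar(seqs), function(n) {
    rawToChar(as.raw(rep(phred + 33L, n)))
  }, character(1))
  Biostrings::QualityScaledDNAStringSet(
    stats::setNames(Biostrings::DNAStringSet(seqs), ids),
    Biostrings::PhredQuality(quals))
}
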