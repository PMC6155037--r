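# Synthetic study generator: negative-binomial count matrices with planted
# differential features, 3'UTRs with planted miRNA binding sites, small-RNA
# reads with planted filter artifacts, annotation sets with planted enriched
# terms, and qPCR Ct tables with planted fold changes. Every planted
# structure is recorded in a truth set before any file is written, so each
# downstream stage has a recovery-testable fixture.
#
# One RNG stream per generator operation, derived from the master seed by a
# fixed offset, so individual fixtures regenerate independently.

.seed_offsets <- c(counts = 101L, mirnas = 202L, utrs = 303L, reads = 404L,
                   annotations = 505L, qpcr = 606L)

.artifact_categories <- c("low_quality", "adaptor3_null", "insert_null",
                          "adaptor5_contaminant", "size_lt_18", "polyA")

#' Configuration for the synthetic two-stage study generator
#'
#' Bundles and validates every tunable of the generator. The defaults
#' emulate a two-condition (telogen vs anagen) small-RNA + mRNA study with
#' three biological replicates per condition, negative-binomial counts,
#' planted four-fold (|log2FC| = 2) differential features, and planted
#' negatively regulated miRNA-target pairs carrying exact 7mer-m8 seed
#' sites with 3' supplementary pairing.
#'
#' @param seed master integer RNG seed; every generator operation derives
#'   its own stream from it by a fixed offset.
#' @param n_mirna,n_mrna number of miRNA / mRNA features.
#' @param n_reps_per_condition biological replicates per condition.
#' @param nb_mean_log_range natural-log bounds for baseline expression
#'   means (counts); baselines are drawn log-uniformly.
#' @param nb_dispersion negative-binomial dispersion (edgeR
#'   parameterization; variance = mu + dispersion * mu^2).
#' @param n_de_mirna_up,n_de_mirna_down,n_de_mrna_up,n_de_mrna_down
#'   planted differential feature counts ("up" = higher in the second
#'   condition, anagen).
#' @param de_log2fc_magnitude absolute planted log2 fold change.
#' @param n_true_pairs planted negative-regulation miRNA-mRNA pairs; each
#'   pair joins an up-feature to a down-feature of the other class.
#' @param utr_length_range integer bounds on generated 3'UTR lengths (nt).
#' @param n_terms,genes_per_term,n_enriched_terms annotation structure.
#' @param enriched_overlap planted target-set genes per enriched term.
#' @param read_artifact_fractions named fractions for the six filter
#'   categories of FASTQ generation; must be non-negative and sum to < 1.
#' @param n_reads reads to generate.
#' @param adaptor3,adaptor5 library adaptor sequences.
#' @param qpcr_genes,qpcr_planted_rq,qpcr_reference_gene,qpcr_stages,
#'   qpcr_noise_sd,qpcr_n_bio,qpcr_n_tech qPCR plate layout: validation
#'   genes, planted relative quantities (second stage vs the calibrator
#'   first stage), reference gene, stage labels, Ct noise SD (cycles),
#'   biological samples per stage and technical replicates.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_mirna = 40L,
                             n_mrna = 400L,
                             n_reps_per_condition = 3L,
                             nb_mean_log_range = log(c(50, 2000)),
                             nb_dispersion = 0.1,
                             n_de_mirna_up = 10L,
                             n_de_mirna_down = 10L,
                             n_de_mrna_up = 40L,
                             n_de_mrna_down = 40L,
                             de_log2fc_magnitude = 2,
                             n_true_pairs = 50L,
                             utr_length_range = c(400L, 700L),
                             n_terms = 50L,
                             genes_per_term = 20L,
                             n_enriched_terms = 5L,
                             enriched_overlap = 15L,
                             read_artifact_fractions = c(
                               low_quality = 0.01, adaptor3_null = 0.01,
                               insert_null = 0.01,
                               adaptor5_contaminant = 0.002,
                               size_lt_18 = 0.01, polyA = 0.002),
                             n_reads = 2000L,
                             adaptor3 = "TGGAATTCTCGGGTGCCAAGG",
                             adaptor5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                             qpcr_genes = c("CHP1", "FZD6", "SIAH1", "SMAD2"),
                             qpcr_planted_rq = c(CHP1 = 4, FZD6 = 2,
                                                 SIAH1 = 0.5, SMAD2 = 1),
                             qpcr_reference_gene = "ACTB",
                             qpcr_stages = c("telogen", "anagen"),
                             qpcr_noise_sd = 0.2,
                             qpcr_n_bio = 3L,
                             qpcr_n_tech = 3L) {
  config <- list(seed = as.integer(seed), n_mirna = as.integer(n_mirna),
                 n_mrna = as.integer(n_mrna),
                 n_reps_per_condition = as.integer(n_reps_per_condition),
                 nb_mean_log_range = as.numeric(nb_mean_log_range),
                 nb_dispersion = nb_dispersion,
                 n_de_mirna_up = as.integer(n_de_mirna_up),
                 n_de_mirna_down = as.integer(n_de_mirna_down),
                 n_de_mrna_up = as.integer(n_de_mrna_up),
                 n_de_mrna_down = as.integer(n_de_mrna_down),
                 de_log2fc_magnitude = de_log2fc_magnitude,
                 n_true_pairs = as.integer(n_true_pairs),
                 utr_length_range = as.integer(utr_length_range),
                 n_terms = as.integer(n_terms),
                 genes_per_term = as.integer(genes_per_term),
                 n_enriched_terms = as.integer(n_enriched_terms),
                 enriched_overlap = as.integer(enriched_overlap),
                 read_artifact_fractions = read_artifact_fractions,
                 n_reads = as.integer(n_reads),
                 adaptor3 = adaptor3, adaptor5 = adaptor5,
                 qpcr_genes = qpcr_genes,
                 qpcr_planted_rq = qpcr_planted_rq,
                 qpcr_reference_gene = qpcr_reference_gene,
                 qpcr_stages = qpcr_stages,
                 qpcr_noise_sd = qpcr_noise_sd,
                 qpcr_n_bio = as.integer(qpcr_n_bio),
                 qpcr_n_tech = as.integer(qpcr_n_tech))
  class(config) <- "generator_config"
  validate_generator_config(config)
  config
}

validate_generator_config <- function(config) {
  fail <- function(field, why) {
    stop("invalid generator_config field '", field, "': ", why, call. = FALSE)
  }
  with(config, {
    if (length(seed) != 1 || is.na(seed)) fail("seed", "must be one integer")
    if (n_mirna < 1) fail("n_mirna", "must be >= 1")
    if (n_mrna < 1) fail("n_mrna", "must be >= 1")
    if (n_reps_per_condition < 1) {
      fail("n_reps_per_condition", "must be >= 1")
    }
    if (length(nb_mean_log_range) != 2 ||
        nb_mean_log_range[1] > nb_mean_log_range[2]) {
      fail("nb_mean_log_range", "must be an increasing pair")
    }
    if (nb_dispersion <= 0) fail("nb_dispersion", "must be positive")
    if (n_de_mirna_up < 0 || n_de_mirna_down < 0 ||
        n_de_mirna_up + n_de_mirna_down > n_mirna) {
      fail("n_de_mirna_up/n_de_mirna_down",
           "planted miRNA DE counts must be >= 0 and sum to <= n_mirna")
    }
    if (n_de_mrna_up < 0 || n_de_mrna_down < 0 ||
        n_de_mrna_up + n_de_mrna_down > n_mrna) {
      fail("n_de_mrna_up/n_de_mrna_down",
           "planted mRNA DE counts must be >= 0 and sum to <= n_mrna")
    }
    if (de_log2fc_magnitude <= 0) {
      fail("de_log2fc_magnitude", "must be positive")
    }
    max_pairs <- n_de_mirna_down * n_de_mrna_up +
      n_de_mirna_up * n_de_mrna_down
    if (n_true_pairs < 0 || n_true_pairs > max_pairs) {
      fail("n_true_pairs",
           sprintf("must be between 0 and %d (opposite-direction combinations)",
                   max_pairs))
    }
    if (length(utr_length_range) != 2 ||
        utr_length_range[1] > utr_length_range[2]) {
      fail("utr_length_range", "must be an increasing integer pair")
    }
    if (n_enriched_terms > n_terms) {
      fail("n_enriched_terms", "must be <= n_terms")
    }
    if (enriched_overlap > genes_per_term) {
      fail("enriched_overlap", "must be <= genes_per_term")
    }
    bad <- setdiff(names(read_artifact_fractions), .artifact_categories)
    if (length(bad)) {
      fail("read_artifact_fractions",
           paste("unknown categories:", paste(bad, collapse = ", ")))
    }
    if (any(read_artifact_fractions < 0) ||
        sum(read_artifact_fractions) >= 1) {
      fail("read_artifact_fractions",
           "fractions must be >= 0 and sum to < 1")
    }
    if (n_reads < 0) fail("n_reads", "must be >= 0")
    if (!nzchar(adaptor3)) fail("adaptor3", "adaptor sequence is empty")
    if (!nzchar(adaptor5)) fail("adaptor5", "adaptor sequence is empty")
    if (length(qpcr_planted_rq) != length(qpcr_genes)) {
      fail("qpcr_planted_rq", "needs one relative quantity per gene")
    }
    if (any(qpcr_planted_rq <= 0)) fail("qpcr_planted_rq", "must be > 0")
    if (qpcr_noise_sd < 0) fail("qpcr_noise_sd", "must be >= 0")
    if (length(qpcr_stages) < 2) fail("qpcr_stages", "needs >= 2 stages")
  })
  invisible(config)
}

mirna_ids <- function(config) sprintf("miR-%03d", seq_len(config$n_mirna))
gene_ids <- function(config) sprintf("gene%04d", seq_len(config$n_mrna))

new_truth_set <- function() {
  structure(list(de_direction = list(mirna = character(), mrna = character()),
                 true_pairs = data.frame(mirna = character(),
                                         mrna = character(),
                                         stringsAsFactors = FALSE),
                 enriched_terms = character(),
                 read_category = character(),
                 planted_sites = data.frame(mirna = character(),
                                            mrna = character(),
                                            start = integer(),
                                            stringsAsFactors = FALSE)),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Truth set:\n")
  cat("  miRNA directions:",
      paste(names(table(x$de_direction$mirna)),
            table(x$de_direction$mirna), collapse = ", "), "\n")
  cat("  mRNA directions:",
      paste(names(table(x$de_direction$mrna)),
            table(x$de_direction$mrna), collapse = ", "), "\n")
  cat("  true pairs:", nrow(x$true_pairs), "\n")
  cat("  planted sites:", nrow(x$planted_sites), "\n")
  cat("  enriched terms:", length(x$enriched_terms), "\n")
  cat("  categorized reads:", length(x$read_category), "\n")
  invisible(x)
}

#' Generate miRNA and mRNA count matrices with planted differential features
#'
#' Draws negative-binomial counts for two conditions (telogen, anagen) with
#' `n_reps_per_condition` replicates each. Planted "up" features have an
#' expected log2 fold change of `+de_log2fc_magnitude` in anagen relative
#' to telogen ("down": negative). Also plants the set of negatively
#' regulated miRNA-mRNA pairs (up miRNA with down mRNA, and vice versa),
#' preferring distinct mRNAs so the target-gene set is as large as the pair
#' set allows.
#'
#' @param config a [generator_config()].
#' @return list with elements `mirna` and `mrna` (integer count matrices,
#'   samples `T1..Tn, A1..An`), `condition` (factor, levels
#'   `telogen`/`anagen`), and `truth` (a `truth_set`).
#' @export
generate_counts <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed + .seed_offsets[["counts"]])
  nrep <- config$n_reps_per_condition
  samples <- c(paste0("T", seq_len(nrep)), paste0("A", seq_len(nrep)))
  condition <- factor(rep(c("telogen", "anagen"), each = nrep),
                      levels = c("telogen", "anagen"))

  plant <- function(n, n_up, n_down) {
    dir <- rep("null", n)
    idx <- sample.int(n, n_up + n_down)
    dir[idx[seq_len(n_up)]] <- "up"
    if (n_down > 0) dir[idx[n_up + seq_len(n_down)]] <- "down"
    dir
  }
  draw <- function(ids, dir) {
    n <- length(ids)
    mu0 <- exp(runif(n, config$nb_mean_log_range[1],
                     config$nb_mean_log_range[2]))
    lfc <- ifelse(dir == "up", config$de_log2fc_magnitude,
                  ifelse(dir == "down", -config$de_log2fc_magnitude, 0))
    mu <- cbind(matrix(mu0, n, nrep),
                matrix(mu0 * 2^lfc, n, nrep))
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / config$nb_dispersion),
                     nrow = n, dimnames = list(ids, samples))
    storage.mode(counts) <- "integer"
    counts
  }

  mirna_dir <- plant(config$n_mirna, config$n_de_mirna_up,
                     config$n_de_mirna_down)
  mrna_dir <- plant(config$n_mrna, config$n_de_mrna_up,
                    config$n_de_mrna_down)
  mirna <- draw(mirna_ids(config), mirna_dir)
  mrna <- draw(gene_ids(config), mrna_dir)

  truth <- new_truth_set()
  truth$de_direction$mirna <- stats::setNames(mirna_dir, mirna_ids(config))
  truth$de_direction$mrna <- stats::setNames(mrna_dir, gene_ids(config))
  truth$true_pairs <- plant_pairs(config, truth)
  list(mirna = mirna, mrna = mrna, condition = condition, truth = truth)
}

# Opposite-direction pairs; greedy pass prefers unused mRNAs so the planted
# target-gene set is as large as possible, then fills from the remainder.
plant_pairs <- function(config, truth) {
  if (config$n_true_pairs == 0) {
    return(data.frame(mirna = character(), mrna = character(),
                      stringsAsFactors = FALSE))
  }
  mir_dir <- truth$de_direction$mirna
  gene_dir <- truth$de_direction$mrna
  cross <- rbind(
    expand.grid(mirna = names(mir_dir)[mir_dir == "down"],
                mrna = names(gene_dir)[gene_dir == "up"],
                stringsAsFactors = FALSE),
    expand.grid(mirna = names(mir_dir)[mir_dir == "up"],
                mrna = names(gene_dir)[gene_dir == "down"],
                stringsAsFactors = FALSE))
  cross <- cross[sample.int(nrow(cross)), , drop = FALSE]
  fresh <- !duplicated(cross$mrna)
  cross <- rbind(cross[fresh, ], cross[!fresh, ])
  pairs <- cross[seq_len(config$n_true_pairs), , drop = FALSE]
  pairs <- pairs[order(pairs$mirna, pairs$mrna), ]
  data.frame(mirna = pairs$mirna, mrna = pairs$mrna,
             stringsAsFactors = FALSE)
}

#' Generate mature miRNA sequences
#'
#' Random 22-nt mature sequences (RNA alphabet) with GC content constrained
#' to 0.4-0.65 and pairwise-distinct seed regions (positions 2-8), so
#' planted seed sites are unambiguous and planted duplexes are stable.
#'
#' @param config a [generator_config()].
#' @return named character vector of RNA sequences.
#' @export
generate_mirna_seqs <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed + .seed_offsets[["mirnas"]])
  ids <- mirna_ids(config)
  seqs <- character(length(ids))
  seeds_seen <- character(0)
  cores_seen <- character(0)     # 7mer-m8 site cores, DNA
  elements_seen <- character(0)  # 18-nt planted elements, DNA
  for (i in seq_along(ids)) {
    for (attempt in seq_len(5000)) {
      s <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                 collapse = "")
      gc <- (nchar(gsub("[^GC]", "", s))) / 22
      seed <- substr(s, 2, 8)
      core <- revcomp_dna(seed)
      element <- revcomp_dna(substr(s, 2, 19))
      # elements are fixed content once planted, so no element may contain
      # any other miRNA's seed core (in either direction), or screening in
      # generate_utrs could never converge
      clash <- any(vapply(cores_seen, function(cc) {
        grepl(cc, element, fixed = TRUE)
      }, logical(1))) ||
        any(vapply(elements_seen, function(el) {
          grepl(core, el, fixed = TRUE)
        }, logical(1)))
      if (gc >= 0.4 && gc <= 0.65 && !(seed %in% seeds_seen) && !clash) {
        break
      }
      if (attempt == 5000) stop("could not draw compatible miRNA seeds")
    }
    seqs[i] <- s
    seeds_seen <- c(seeds_seen, seed)
    cores_seen <- c(cores_seen, core)
    elements_seen <- c(elements_seen, element)
  }
  stats::setNames(seqs, ids)
}

# Reverse complement into the DNA alphabet, accepting RNA input.
revcomp_dna <- function(x) {
  x <- chartr("uU", "tT", x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate 3'UTR sequences with planted miRNA binding sites
#'
#' For every planted pair the transcript UTR receives an 18-nt element that
#' is the exact reverse complement of miRNA positions 2-19: positions 2-8
#' form an exact 7mer-m8 seed site and positions 9-19 supply 3'
#' supplementary pairing, so the planted duplex free energy clears the
#' default -20 kcal/mol threshold. The 30 nt flanking the element are drawn
#' AU-rich (90% A/U), emulating the AU-rich context of functional sites.
#' The base opposite miRNA position 1 is forced to a non-A so the planted
#' site type is exactly 7mer-m8. Every UTR is screened (rejection
#' resampling, up to 100 attempts) so that no truth miRNA has a 7mer-m8
#' seed match anywhere it was not planted.
#'
#' @param config a [generator_config()].
#' @param truth `truth_set` from [generate_counts()].
#' @param mirna_seqs named mature miRNA sequences covering every miRNA in
#'   `truth$true_pairs` (each of length >= 19 nt).
#' @return list with `utrs` (named character, DNA alphabet) and the updated
#'   `truth` whose `planted_sites` records 0-based site starts.
#' @export
generate_utrs <- function(config, truth, mirna_seqs) {
  validate_generator_config(config)
  stopifnot(inherits(truth, "truth_set"))
  if (config$utr_length_range[1] < 120) {
    stop("utr_length_range too short to host a planted site ",
         "(minimum length 120 nt)")
  }
  pair_mirnas <- unique(truth$true_pairs$mirna)
  missing <- setdiff(pair_mirnas, names(mirna_seqs))
  if (length(missing)) {
    stop("no sequence provided for paired miRNAs: ",
         paste(missing, collapse = ", "))
  }
  if (any(nchar(mirna_seqs[pair_mirnas]) < 19)) {
    stop("every paired miRNA sequence must be >= 19 nt")
  }
  set.seed(config$seed + .seed_offsets[["utrs"]])

  truth_cores <- vapply(mirna_seqs[pair_mirnas], function(s) {
    revcomp_dna(substr(s, 2, 8))
  }, character(1))
  elements <- vapply(mirna_seqs[pair_mirnas], function(s) {
    revcomp_dna(substr(s, 2, 19))
  }, character(1))

  genes <- gene_ids(config)
  pair_by_gene <- split(truth$true_pairs$mirna, truth$true_pairs$mrna)
  utrs <- stats::setNames(character(length(genes)), genes)
  sites <- list()
  bases <- c("A", "C", "G", "T")
  au_bases <- c("A", "T")

  for (g in genes) {
    partners <- pair_by_gene[[g]]
    expected <- table(factor(partners, levels = pair_mirnas))
    ok <- FALSE
    for (attempt in seq_len(100)) {
      len <- sample(seq(config$utr_length_range[1],
                        config$utr_length_range[2]), 1)
      chars <- sample(bases, len, replace = TRUE)
      g_sites <- integer(0)
      if (length(partners)) {
        width <- (len - 40) %/% length(partners)
        if (width < 80) stop("utr_length_range too short to host ",
                             length(partners), " planted sites")
        for (k in seq_along(partners)) {
          m <- partners[k]
          lo <- 21 + (k - 1) * width
          p <- lo + sample.int(width - 60, 1)   # element start, 1-based
          el <- strsplit(elements[[m]], "")[[1]]
          chars[p:(p + 17)] <- el
          # AU-rich context around the site, non-A opposite miRNA pos 1
          left <- max(1, p - 19):(p - 1)
          right <- (p + 19):min(len, p + 48)
          chars[c(left, right)] <- sample(
            c(au_bases, bases), length(left) + length(right),
            replace = TRUE, prob = c(0.45, 0.45, 0.025, 0.025, 0.025, 0.025))
          chars[p + 18] <- "T"
          g_sites[m] <- p + 10L              # 0-based start of 7mer-m8 site
        }
      }
      utr <- paste(chars, collapse = "")
      # screening: every truth miRNA core occurs exactly as often as planted
      n_core <- vapply(truth_cores, function(core) {
        length(gregexpr(core, utr, fixed = TRUE)[[1]]) -
          (gregexpr(core, utr, fixed = TRUE)[[1]][1] == -1)
      }, numeric(1))
      if (all(n_core == as.numeric(expected))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not generate a collision-free UTR for ", g,
           " in 100 attempts")
    }
    utrs[g] <- utr
    if (length(partners)) {
      sites[[g]] <- data.frame(mirna = names(g_sites), mrna = g,
                               start = unname(g_sites),
                               stringsAsFactors = FALSE)
    }
  }
  truth$planted_sites <- if (length(sites)) {
    out <- do.call(rbind, sites)
    rownames(out) <- NULL
    out
  } else {
    new_truth_set()$planted_sites
  }
  list(utrs = utrs, truth = truth)
}

# 1-mismatch occurrence check used both by the generator's rejection
# screens and (through qc) consistent with the filter's matching rule.
first_adaptor_hit <- function(seq, prefix, max_mismatch = 1L) {
  m <- Biostrings::matchPattern(prefix, Biostrings::DNAString(seq),
                                max.mismatch = max_mismatch)
  if (length(m) == 0) NA_integer_ else Biostrings::start(m)[1]
}

#' Generate small-RNA reads with planted filter artifacts
#'
#' Each read is assigned exactly one category drawn from a multinomial over
#' the configured artifact fractions (remainder: clean). Clean reads are
#' 18-30 nt inserts, mode 22 nt, followed by the 3' adaptor, with high
#' Phred+33 qualities; artifact reads are constructed so the QC cascade of
#' [filter_reads()] assigns them to exactly their planted category.
#'
#' @param config a [generator_config()].
#' @param truth optional `truth_set` to update (a fresh one is created
#'   otherwise).
#' @return list with `reads` (a `QualityScaledDNAStringSet`) and `truth`
#'   whose `read_category` maps read id to planted category or `"clean"`.
#' @export
generate_reads <- function(config, truth = new_truth_set()) {
  validate_generator_config(config)
  stopifnot(inherits(truth, "truth_set"))
  if (config$n_reads == 0) {
    truth$read_category <- character(0)
    return(list(reads = Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0))),
      truth = truth))
  }
  set.seed(config$seed + .seed_offsets[["reads"]])
  a3 <- config$adaptor3
  a5 <- config$adaptor5
  a3p <- substr(a3, 1, 8)
  a5p <- substr(a5, 1, 8)
  bases <- c("A", "C", "G", "T")

  fr <- config$read_artifact_fractions
  fr <- fr[fr > 0]
  cats <- sample(c(names(fr), "clean"), config$n_reads, replace = TRUE,
                 prob = c(fr, 1 - sum(fr)))

  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE),
                                collapse = "")
  # insert acceptable for a clean/high-quality read? the final read is
  # validated with the same matching rule the filter applies, so the first
  # (1-mismatch) 3' adaptor hit sits exactly at the insert/adaptor junction
  insert_ok <- function(ins) {
    read <- paste0(ins, a3)
    if (identical(first_adaptor_hit(read, a3p), nchar(ins) + 1L)) {
      afrac <- nchar(gsub("[^A]", "", ins)) / nchar(ins)
      h5 <- first_adaptor_hit(ins, a5p)
      afrac < 0.8 && (is.na(h5) || h5 > 8)
    } else FALSE
  }
  clean_insert <- function() {
    lens <- 18:30
    w <- stats::dnorm(lens, mean = 22, sd = 2)
    repeat {
      ins <- rand_seq(sample(lens, 1, prob = w))
      if (insert_ok(ins)) return(ins)
    }
  }

  seqs <- character(config$n_reads)
  low_qual <- logical(config$n_reads)
  for (i in seq_len(config$n_reads)) {
    seqs[i] <- switch(
      cats[i],
      clean = paste0(clean_insert(), a3),
      low_quality = {
        low_qual[i] <- TRUE
        paste0(clean_insert(), a3)
      },
      adaptor3_null = {
        repeat {
          s <- rand_seq(sample(30:45, 1))
          if (is.na(first_adaptor_hit(s, a3p))) break
        }
        s
      },
      insert_null = paste0(a3, rand_seq(sample(0:5, 1))),
      adaptor5_contaminant = {
        # needs the 3' adaptor present at the junction and no earlier
        # spurious hit; the 5' adaptor at the start is the planted artifact
        repeat {
          ins <- rand_seq(sample(18:30, 1))
          contaminated <- paste0(a5, ins)
          read <- paste0(contaminated, a3)
          if (identical(first_adaptor_hit(read, a3p),
                        nchar(contaminated) + 1L)) break
        }
        read
      },
      size_lt_18 = {
        repeat {
          ins <- rand_seq(sample(5:17, 1))
          read <- paste0(ins, a3)
          h5 <- first_adaptor_hit(ins, a5p)
          if (identical(first_adaptor_hit(read, a3p), nchar(ins) + 1L) &&
              (is.na(h5) || h5 > 8)) break
        }
        read
      },
      polyA = {
        repeat {
          ins <- strrep("A", sample(18:25, 1))
          read <- paste0(ins, a3)
          if (identical(first_adaptor_hit(read, a3p), nchar(ins) + 1L)) break
        }
        read
      })
  }
  quals <- vapply(seq_len(config$n_reads), function(i) {
    n <- nchar(seqs[i])
    q <- if (low_qual[i]) sample(5:15, n, replace = TRUE)
         else sample(30:40, n, replace = TRUE)
    rawToChar(as.raw(q + 33L))
  }, character(1))

  ids <- sprintf("read%06d", seq_len(config$n_reads))
  reads <- Biostrings::QualityScaledDNAStringSet(
    stats::setNames(Biostrings::DNAStringSet(seqs), ids),
    Biostrings::PhredQuality(quals))
  truth$read_category <- stats::setNames(cats, ids)
  list(reads = reads, truth = truth)
}

#' Generate a term-to-gene annotation table with planted enriched terms
#'
#' Terms alternate between the GO and KEGG namespaces. Enriched terms
#' receive `enriched_overlap` genes from the planted target set (the mRNAs
#' of the true pairs) plus uniformly drawn background genes up to
#' `genes_per_term`; background terms draw genes uniformly. Every gene is
#' then guaranteed at least one annotation per namespace (unannotated genes
#' are appended to a random background term), so the annotated background
#' equals the full gene universe in both namespaces.
#'
#' @param config a [generator_config()].
#' @param truth `truth_set` carrying the planted pairs.
#' @return list with `annotation` (data.frame `term`, `gene`, `namespace`)
#'   and the updated `truth` with `enriched_terms` filled in.
#' @export
generate_annotations <- function(config, truth) {
  validate_generator_config(config)
  stopifnot(inherits(truth, "truth_set"))
  if (config$genes_per_term > config$n_mrna) {
    stop("genes_per_term exceeds the number of mRNAs (n_mrna)")
  }
  set.seed(config$seed + .seed_offsets[["annotations"]])
  genes <- gene_ids(config)
  ns <- rep(c("GO", "KEGG"), length.out = config$n_terms)
  ids <- ifelse(ns == "GO",
                sprintf("GO:%07d", seq_len(config$n_terms)),
                sprintf("ko%05d", seq_len(config$n_terms)))
  target_set <- unique(truth$true_pairs$mrna)
  enriched_idx <- integer(0)
  if (config$n_enriched_terms > 0) {
    if (length(target_set) < config$enriched_overlap) {
      stop("planted target set (", length(target_set),
           " genes) smaller than enriched_overlap")
    }
    enriched_idx <- sort(sample.int(config$n_terms,
                                    config$n_enriched_terms))
  }
  term_genes <- vector("list", config$n_terms)
  for (i in seq_len(config$n_terms)) {
    if (i %in% enriched_idx) {
      hits <- sample(target_set, config$enriched_overlap)
      rest <- sample(setdiff(genes, hits),
                     config$genes_per_term - config$enriched_overlap)
      term_genes[[i]] <- c(hits, rest)
    } else {
      term_genes[[i]] <- sample(genes, config$genes_per_term)
    }
  }
  # guarantee full per-namespace coverage of the gene universe
  for (space in unique(ns)) {
    in_ns <- which(ns == space)
    background <- setdiff(in_ns, enriched_idx)
    if (!length(background)) background <- in_ns
    annotated <- unique(unlist(term_genes[in_ns]))
    for (g in setdiff(genes, annotated)) {
      i <- background[sample.int(length(background), 1)]
      term_genes[[i]] <- c(term_genes[[i]], g)
    }
  }
  annotation <- data.frame(
    term = rep(ids, lengths(term_genes)),
    gene = unlist(term_genes),
    namespace = rep(ns, lengths(term_genes)),
    stringsAsFactors = FALSE)
  rownames(annotation) <- NULL
  truth$enriched_terms <- ids[enriched_idx]
  list(annotation = annotation, truth = truth)
}

#' Generate a qPCR Ct table with planted relative quantities
#'
#' Emulates a validation plate: `qpcr_n_bio` biological samples per stage,
#' `qpcr_n_tech` technical replicates per sample x gene, a reference gene
#' at a constant baseline Ct, and planted fold changes encoded as delta-Ct
#' shifts (`Ct = 24 - log2(RQ)` in non-calibrator stages). Gaussian Ct
#' noise of SD `noise_sd` cycles is added per well.
#'
#' @param config a [generator_config()].
#' @param noise_sd per-well Ct noise SD in cycles; defaults to the
#'   configured `qpcr_noise_sd`. `0` gives a noiseless plate whose
#'   recovered relative quantities equal the planted ones exactly.
#' @return data.frame with columns `sample`, `stage`, `gene`, `replicate`,
#'   `ct`.
#' @export
generate_qpcr <- function(config, noise_sd = config$qpcr_noise_sd) {
  validate_generator_config(config)
  set.seed(config$seed + .seed_offsets[["qpcr"]])
  stages <- config$qpcr_stages
  genes <- c(config$qpcr_reference_gene, config$qpcr_genes)
  rq <- stats::setNames(as.numeric(config$qpcr_planted_rq),
                        config$qpcr_genes)
  rows <- list()
  for (s_i in seq_along(stages)) {
    stage <- stages[s_i]
    for (b in seq_len(config$qpcr_n_bio)) {
      sample_id <- paste0(toupper(substr(stage, 1, 1)), "-", b)
      for (g in genes) {
        base <- if (g == config$qpcr_reference_gene) {
          20
        } else if (s_i == 1) {
          24
        } else {
          24 - log2(rq[[g]])
        }
        ct <- base + rnorm(config$qpcr_n_tech, sd = noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_id, stage = stage, gene = g,
          replicate = seq_len(config$qpcr_n_tech), ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the full synthetic study
#'
#' Convenience wrapper running every generator stage in order and returning
#' all fixtures plus the consolidated truth set.
#'
#' @param config a [generator_config()].
#' @param with_reads also generate FASTQ reads (slower; off for pipelines
#'   that start from count matrices).
#' @return list with `mirna_counts`, `mrna_counts`, `condition`,
#'   `mirna_seqs`, `utrs`, `annotation`, `qpcr`, optionally `reads`, and
#'   `truth`.
#' @export
generate_study <- function(config, with_reads = FALSE) {
  counts <- generate_counts(config)
  mirna_seqs <- generate_mirna_seqs(config)
  utrs <- generate_utrs(config, counts$truth, mirna_seqs)
  ann <- generate_annotations(config, utrs$truth)
  truth <- ann$truth
  out <- list(mirna_counts = counts$mirna, mrna_counts = counts$mrna,
              condition = counts$condition, mirna_seqs = mirna_seqs,
              utrs = utrs$utrs, annotation = ann$annotation,
              qpcr = generate_qpcr(config))
  if (with_reads) {
    reads <- generate_reads(config, truth)
    out$reads <- reads$reads
    truth <- reads$truth
  }
  out$truth <- truth
  out
}
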