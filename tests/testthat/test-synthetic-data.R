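# Synthetic study generator: determinism, validation, planted structure.

test_that("invalid configurations are rejected with the field named", {
  expect_error(generator_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(generator_config(n_de_mrna_up = 300, n_de_mrna_down = 200),
               "n_de_mrna")
  expect_error(generator_config(n_true_pairs = 1e6), "n_true_pairs")
  expect_error(generator_config(read_artifact_fractions =
                                  c(polyA = 0.6, size_lt_18 = 0.5)),
               "read_artifact_fractions")
  expect_error(generator_config(read_artifact_fractions =
                                  c(bogus = 0.1)),
               "read_artifact_fractions")
  expect_error(generator_config(adaptor3 = ""), "adaptor3")
  expect_error(generator_config(n_enriched_terms = 99, n_terms = 10),
               "n_enriched_terms")
})

test_that("count generation is deterministic and respects planted nulls", {
  cfg <- small_config(seed = 11L)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(a$mirna, b$mirna)
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$truth$true_pairs, b$truth$true_pairs)
  expect_true(all(a$mirna >= 0L), all(a$mrna >= 0L))
  expect_identical(dim(a$mrna), c(40L, 6L))

  cfg0 <- small_config(seed = 3L, n_de_mrna_up = 0L, n_de_mrna_down = 0L,
                       n_true_pairs = 0L)
  z <- generate_counts(cfg0)
  expect_true(all(z$truth$de_direction$mrna == "null"))
})

test_that("planted fold changes are recovered on average", {
  cfg <- generator_config(seed = 1L, n_mirna = 5L, n_mrna = 200L,
                          n_de_mrna_up = 50L, n_de_mrna_down = 0L,
                          n_de_mirna_up = 0L, n_de_mirna_down = 0L,
                          n_true_pairs = 0L, de_log2fc_magnitude = 2,
                          nb_dispersion = 0.1)
  x <- generate_counts(cfg)
  up <- names(x$truth$de_direction$mrna)[x$truth$de_direction$mrna == "up"]
  # raw count means: the generator's contract is on expected counts
  m_tel <- rowMeans(x$mrna[up, x$condition == "telogen"])
  m_ana <- rowMeans(x$mrna[up, x$condition == "anagen"])
  emp <- log2(m_ana / m_tel)
  expect_equal(mean(emp), 2, tolerance = 0.5 / 2)
})

test_that("true pairs join opposite directions and prefer distinct genes", {
  cfg <- recovery_config(seed = 5L)
  x <- generate_counts(cfg)
  tp <- x$truth$true_pairs
  expect_equal(nrow(tp), 50L)
  dm <- x$truth$de_direction$mirna[tp$mirna]
  dg <- x$truth$de_direction$mrna[tp$mrna]
  expect_true(all((dm == "up" & dg == "down") |
                    (dm == "down" & dg == "up")))
  # 80 planted DE genes available for 50 pairs: all genes distinct
  expect_equal(anyDuplicated(tp$mrna), 0L)
})

test_that("UTR generation plants recoverable seed sites and screens the rest", {
  cfg <- small_config(seed = 7L)
  counts <- generate_counts(cfg)
  seqs <- generate_mirna_seqs(cfg)
  gu <- generate_utrs(cfg, counts$truth, seqs)
  ps <- gu$truth$planted_sites
  expect_equal(nrow(ps), nrow(counts$truth$true_pairs))
  for (k in seq_len(nrow(ps))) {
    sites <- find_seed_sites(seqs[[ps$mirna[k]]], gu$utrs[[ps$mrna[k]]],
                             ps$mirna[k], ps$mrna[k])
    expect_true(ps$start[k] %in% sites$start)
    expect_equal(sites$site_type[sites$start == ps$start[k]], "7mer-m8")
  }
  # no unplanted 7mer-m8 (or larger) match for any truth miRNA anywhere
  truth_mirnas <- unique(counts$truth$true_pairs$mirna)
  for (m in truth_mirnas) {
    for (g in names(gu$utrs)) {
      sites <- find_seed_sites(seqs[[m]], gu$utrs[[g]], m, g)
      strong <- sites[sites$site_type %in% c("7mer-m8", "8mer"), ]
      planted_here <- ps$start[ps$mirna == m & ps$mrna == g]
      expect_setequal(strong$start, planted_here)
    }
  }
})

test_that("UTR generation with no pairs leaves no truth-miRNA seed match", {
  cfg <- small_config(seed = 2L, n_true_pairs = 0L)
  counts <- generate_counts(cfg)
  seqs <- generate_mirna_seqs(cfg)
  gu <- generate_utrs(cfg, counts$truth, seqs)
  expect_equal(nrow(gu$truth$planted_sites), 0L)
  expect_error(generate_utrs(generator_config(utr_length_range = c(30, 50)),
                             counts$truth, seqs),
               "too short")
})

test_that("read generation is deterministic and matches planted categories", {
  cfg <- small_config(seed = 9L)
  r1 <- generate_reads(cfg)
  r2 <- generate_reads(cfg)
  expect_identical(as.character(r1$reads), as.character(r2$reads))
  expect_identical(as.character(Biostrings::quality(r1$reads)),
                   as.character(Biostrings::quality(r2$reads)))
  expect_identical(r1$truth$read_category, r2$truth$read_category)
  expect_equal(length(r1$truth$read_category), 150L)

  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(r1$reads, f1)
  write_fastq(r2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  zero <- small_config(seed = 4L, read_artifact_fractions =
                         stats::setNames(numeric(0), character(0)))
  rz <- generate_reads(zero)
  expect_true(all(rz$truth$read_category == "clean"))
})

test_that("annotation generation plants enriched terms over the target set", {
  cfg <- small_config(seed = 13L)
  counts <- generate_counts(cfg)
  ga <- generate_annotations(cfg, counts$truth)
  expect_equal(length(ga$truth$enriched_terms), 2L)
  target <- unique(counts$truth$true_pairs$mrna)
  for (tm in ga$truth$enriched_terms) {
    genes <- ga$annotation$gene[ga$annotation$term == tm]
    expect_gte(length(intersect(genes, target)), 5L)
  }
  # full per-namespace coverage of the gene universe
  for (space in c("GO", "KEGG")) {
    covered <- unique(ga$annotation$gene[ga$annotation$namespace == space])
    expect_setequal(covered, rownames(counts$mrna))
  }
  expect_error(generate_annotations(small_config(genes_per_term = 999L),
                                    counts$truth),
               "genes_per_term")
})

test_that("qPCR generation encodes planted fold changes as dCt shifts", {
  cfg <- small_config(seed = 21L)
  noiseless <- generate_qpcr(cfg, noise_sd = 0)
  rq <- delta_delta_ct(noiseless, reference_gene = "ACTB",
                       calibrator_stage = "telogen")
  anagen <- rq$stages[rq$stages$stage == "anagen", ]
  expect_equal(stats::setNames(anagen$rq, anagen$gene),
               c(CHP1 = 4, FZD6 = 2, SIAH1 = 0.5, SMAD2 = 1))
  telogen <- rq$stages[rq$stages$stage == "telogen", ]
  expect_true(all(telogen$rq == 1))

  noisy <- generate_qpcr(cfg, noise_sd = 0.2)
  rq2 <- delta_delta_ct(noisy, "ACTB", "telogen")
  chp1 <- rq2$stages$rq[rq2$stages$gene == "CHP1" &
                          rq2$stages$stage == "anagen"]
  expect_gt(chp1, 2.5)
  expect_lt(chp1, 6.5)
})
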