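# Seed-site detection, nearest-neighbor duplex energy, context scores and
# the full target-prediction surface.

mir195 <- "TGGTAGCAGCACAGAAATGTTGG"   # mature sequence, DNA alphabet

test_that("seed sites are typed and placed canonically", {
  utr <- "NNNNNNNNNNTGCTACCNNN"
  sites <- find_seed_sites(mir195, utr)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 10L)
  expect_equal(sites$end, 17L)
  expect_equal(sites$site_type, "7mer-m8")

  expect_equal(nrow(find_seed_sites(mir195, "ACGTAA")), 0L)

  # constructed 8mer: revcomp of positions 2-8 plus an A opposite position 1
  site8 <- paste0("TGCTACC", "A")
  utr8 <- paste0("CCGG", site8, "GGC")
  s8 <- find_seed_sites(mir195, utr8)
  expect_equal(s8$site_type, "8mer")
  expect_equal(s8$start, 4L)
  expect_equal(s8$end, 12L)

  # 7mer-A1: seed 2-7 match, A opposite position 1, mismatch at m8
  utr_a1 <- paste0("CCGG", "GCTACC", "A", "GGC")
  sa1 <- find_seed_sites(mir195, utr_a1)
  expect_equal(sa1$site_type, "7mer-A1")
  # 6mer: no m8 match, no A1 adenine
  utr6 <- paste0("CCGG", "GCTACC", "GGGC")
  s6 <- find_seed_sites(mir195, utr6)
  expect_equal(s6$site_type, "6mer")
  expect_equal(s6$end - s6$start, 6L)

  expect_error(find_seed_sites(mir195, "ACGTXZACGTAC"), "X")
  expect_error(find_seed_sites("ACGU", "ACGUACGU"), ">= 19")
})

test_that("every reported site substring is the demanded reverse complement", {
  cfg <- small_config(seed = 41L)
  counts <- generate_counts(cfg)
  seqs <- generate_mirna_seqs(cfg)
  gu <- generate_utrs(cfg, counts$truth, seqs)
  pred <- predict_targets(seqs, gu$utrs)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(chartr("U", "T", x))))
  for (k in seq_len(nrow(pred$sites))) {
    s <- pred$sites[k, ]
    m <- chartr("uU", "TT", toupper(seqs[[s$mirna_id]]))
    utr <- gu$utrs[[s$transcript_id]]
    frag <- substr(utr, s$start + 1, s$end)
    expected <- switch(s$site_type,
      "6mer" = rc(substr(m, 2, 7)),
      "7mer-m8" = rc(substr(m, 2, 8)),
      "7mer-A1" = paste0(rc(substr(m, 2, 7)), "A"),
      "8mer" = paste0(rc(substr(m, 2, 8)), "A"))
    expect_identical(frag, expected)
  }
})

test_that("duplex energy follows the nearest-neighbor stack sum", {
  # degenerate: no complementarity at all -> initiation penalty only
  mir_a <- paste(rep("A", 22), collapse = "")
  utr_a <- paste(rep("A", 30), collapse = "")
  site <- list(start = 10L, end = 17L, site_type = "7mer-m8")
  expect_equal(duplex_energy(mir_a, utr_a, site), 4.09)

  # eight consecutive G:C pairs = seven GG/CC stacks of -3.26 each
  mir_g <- paste0("A", strrep("G", 8), strrep("A", 13))
  utr_g <- paste0("A", strrep("C", 8), "G", "AAAA")
  site_g <- list(start = 2L, end = 9L, site_type = "7mer-m8")
  expect_equal(duplex_energy(mir_g, utr_g, site_g), 4.09 + 7 * (-3.26))

  # removing an internal pair never lowers the energy
  utr_nick <- paste0("A", "CCC", "T", "CCCC", "G", "AAAA")  # breaks one pair
  expect_gte(duplex_energy(mir_g, utr_nick, site_g),
             duplex_energy(mir_g, utr_g, site_g))
  expect_error(duplex_energy(mir_g, utr_g, site_g, flank = -1), "flank")
})

test_that("duplex energy is invariant under site translation", {
  cfg <- small_config(seed = 43L)
  seqs <- generate_mirna_seqs(cfg)
  m <- seqs[[1]]
  el <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", substr(m, 2, 19)))))
  pad1 <- strrep("A", 25)
  pad2 <- strrep("A", 60)
  utr1 <- paste0(pad1, el, "C", strrep("A", 10))
  utr2 <- paste0(pad2, el, "C", strrep("A", 10))
  s1 <- find_seed_sites(m, utr1)
  s2 <- find_seed_sites(m, utr2)
  s1 <- s1[s1$site_type == "7mer-m8", ][1, ]
  s2 <- s2[s2$site_type == "7mer-m8", ][1, ]
  expect_equal(duplex_energy(m, utr1, s1), duplex_energy(m, utr2, s2))
})

test_that("context scores order by site type and percentiles by rank", {
  utr <- paste0(strrep("G", 40), "NNNNNNNN", strrep("G", 40))
  s_8mer <- list(start = 40L, end = 48L, site_type = "8mer")
  s_6mer <- list(start = 40L, end = 46L, site_type = "6mer")
  expect_gt(context_score(s_8mer, utr), context_score(s_6mer, utr))

  expect_equal(score_percentile(3.7), 100)
  p <- score_percentile(1:10)
  expect_equal(p[10], 100)
  expect_equal(p[1], 10)
  expect_equal(score_percentile(c(2, 2, 1)), c(100, 100, 100 / 3))
})

test_that("planted pairs are recovered and impossible thresholds reject all", {
  # default study conditions: 50 planted 7mer-m8 pairs; the percentile
  # filter needs the full-size site universe, so this runs at scale
  cfg <- recovery_config(seed = 47L)
  counts <- generate_counts(cfg)
  seqs <- generate_mirna_seqs(cfg)
  gu <- generate_utrs(cfg, counts$truth, seqs)
  pred <- predict_targets(seqs, gu$utrs)
  truth_key <- paste(counts$truth$true_pairs$mirna,
                     counts$truth$true_pairs$mrna)
  pass_key <- paste(pred$pairs$mirna[pred$pairs$passes],
                    pred$pairs$transcript[pred$pairs$passes])
  expect_equal(length(truth_key), 50L)
  expect_true(all(truth_key %in% pass_key))

  none <- predict_targets(seqs, gu$utrs, energy_threshold = 0,
                          percentile_threshold = 101)
  expect_false(any(none$pairs$passes))
  expect_error(predict_targets(seqs, gu$utrs[c(1, 1)]), "duplicate")
})

test_that("prediction is order-independent and shuffling destroys sites", {
  cfg <- small_config(seed = 53L)
  counts <- generate_counts(cfg)
  seqs <- generate_mirna_seqs(cfg)
  gu <- generate_utrs(cfg, counts$truth, seqs)
  a <- predict_targets(seqs, gu$utrs)
  b <- predict_targets(rev(seqs), gu$utrs[sample(length(gu$utrs))])
  expect_equal(a$pairs, b$pairs)

  shuffled <- dinucleotide_shuffle(gu$utrs, seed = 99L)
  pred_s <- predict_targets(seqs, shuffled)
  truth_key <- paste(counts$truth$true_pairs$mirna,
                     counts$truth$true_pairs$mrna)
  pass_key <- paste(pred_s$pairs$mirna[pred_s$pairs$passes],
                    pred_s$pairs$transcript[pred_s$pairs$passes])
  expect_lte(mean(truth_key %in% pass_key), 0.05)
})
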