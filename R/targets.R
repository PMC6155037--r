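# miRNA target prediction from mature sequences and 3'UTRs: canonical
# seed-site detection (6mer / 7mer-A1 / 7mer-m8 / 8mer), duplex free
# energy from a nearest-neighbor stack sum, a context score with an
# empirical percentile, and the two literal thresholds used for the
# pass/fail call: best duplex energy <= -20 kcal/mol and context-score
# percentile >= 90.

#' Nearest-neighbor RNA stacking free energies
#'
#' Stacking free-energy increments (Delta-G37, kcal/mol) for adjacent base
#' pairs in an RNA duplex. Entry `[p1, p2]` is the increment for the stack
#' whose 5' pair (reading the top strand 5'->3') is `p1` and whose 3' pair
#' is `p2`, each pair written top-strand base first. Watson-Crick entries
#' are the unrounded Xia et al. values retained by the Turner 2004 set;
#' G:U wobble entries are the Turner 2004 values (published to 0.1
#' kcal/mol). The duplex initiation penalty is +4.09 kcal/mol.
#'
#' @return 6x6 numeric matrix over pairs `AU, UA, CG, GC, GU, UG`.
#' @export
rna_stack_energies <- function() {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  matrix(c(
    # AU     UA     CG     GC     GU     UG       (3' pair ->)
    -0.93, -1.10, -2.24, -2.08, -0.60, -1.40,  # AU
    -1.33, -0.93, -2.35, -2.11, -1.00, -1.30,  # UA
    -2.11, -2.08, -3.26, -2.36, -1.40, -2.10,  # CG
    -2.35, -2.24, -3.42, -3.26, -1.50, -2.50,  # GC
    -1.30, -1.40, -2.50, -2.10, -0.50,  1.30,  # GU
    -1.00, -0.60, -1.50, -1.40,  0.30, -0.50), # UG
    nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
}

.duplex_initiation <- 4.09

as_rna_chars <- function(x, what = "sequence") {
  chars <- strsplit(toupper(chartr("tT", "uU", x)), "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "U", "N"))
  if (length(bad)) {
    stop("non-nucleotide characters in ", what, ": ",
         paste(bad, collapse = ", "))
  }
  chars
}

.rna_complement <- c(A = "U", C = "G", G = "C", U = "A", N = "N")
.wc_or_wobble <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Find canonical seed-match sites for one miRNA on one UTR
#'
#' Scans the UTR sense strand for matches to the miRNA seed (positions 2-8,
#' 1-based) and types each site by the canonical TargetScan nomenclature:
#' `6mer` (match to positions 2-7), `7mer-m8` (2-8), `7mer-A1` (2-7 plus an
#' adenine opposite position 1), `8mer` (2-8 plus the A1 adenine).
#' Overlapping matches of different extent collapse to the longest type.
#' Coordinates are 0-based half-open on the UTR as supplied (T/U both
#' accepted; N never matches).
#'
#' @param mirna mature miRNA sequence, 5'->3', length >= 19 nt.
#' @param utr 3'UTR sense-strand sequence.
#' @param mirna_id,transcript_id ids carried into the result.
#' @return data.frame with columns `transcript_id`, `mirna_id`, `start`,
#'   `end`, `site_type` (zero rows when no site exists).
#' @export
find_seed_sites <- function(mirna, utr, mirna_id = "miRNA",
                            transcript_id = "transcript") {
  m <- as_rna_chars(mirna, "miRNA sequence")
  if (length(m) < 19) stop("mature miRNA must be >= 19 nt")
  u <- as_rna_chars(utr, "UTR sequence")
  empty <- data.frame(transcript_id = character(0), mirna_id = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  if (length(u) < 6) return(empty)
  core <- rev(unname(.rna_complement[m[2:7]]))  # revcomp of positions 2-7
  hits <- integer(0)
  for (i in seq_len(length(u) - 5L)) {
    if (all(u[i:(i + 5L)] == core)) hits <- c(hits, i)
  }
  if (!length(hits)) return(empty)
  comp_m8 <- .rna_complement[[m[8]]]
  site <- lapply(hits, function(i) {
    has_m8 <- i > 1L && u[i - 1L] == comp_m8
    has_a1 <- (i + 6L) <= length(u) && u[i + 6L] == "A"
    if (has_m8 && has_a1) {
      c(i - 2L, i + 6L, "8mer")
    } else if (has_m8) {
      c(i - 2L, i + 5L, "7mer-m8")
    } else if (has_a1) {
      c(i - 1L, i + 6L, "7mer-A1")
    } else {
      c(i - 1L, i + 5L, "6mer")
    }
  })
  data.frame(transcript_id = transcript_id, mirna_id = mirna_id,
             start = vapply(site, function(s) as.integer(s[1]), 1L),
             end = vapply(site, function(s) as.integer(s[2]), 1L),
             site_type = vapply(site, function(s) s[3], ""),
             stringsAsFactors = FALSE)
}

# 1-based UTR start of the 6mer core for a typed site
core_start_1b <- function(start, site_type) {
  start + ifelse(site_type %in% c("7mer-m8", "8mer"), 2L, 1L)
}

#' Duplex free energy of a target site
#'
#' Extends the seed duplex over up to `flank` UTR bases 5' of the site,
#' pairing each successive miRNA 3'-region base with the UTR base opposite
#' it (banded, gap-free). Watson-Crick and G:U wobble pairs count as
#' paired; the free energy is the sum of nearest-neighbor stacking
#' increments over consecutive paired positions plus the +4.09 kcal/mol
#' duplex initiation penalty. Unpaired positions contribute nothing, and
#' destabilizing (positive) stack entries are truncated to zero, so adding
#' paired stacks never increases the energy. No loop or bulge terms are
#' modelled.
#'
#' @param mirna mature miRNA sequence, 5'->3'.
#' @param utr UTR sense-strand sequence the site lives on.
#' @param site one-row data.frame (or list) with `start`, `end`,
#'   `site_type` as produced by [find_seed_sites()].
#' @param flank UTR bases 5' of the site considered for 3' supplementary
#'   pairing.
#' @return duplex Delta-G in kcal/mol (initiation included).
#' @export
duplex_energy <- function(mirna, utr, site, flank = 15L) {
  if (flank < 0) stop("flank must be >= 0")
  m <- as_rna_chars(mirna, "miRNA sequence")
  u <- as_rna_chars(utr, "UTR sequence")
  start0 <- as.integer(site$start)
  if (start0 < 0 || as.integer(site$end) > length(u)) {
    stop("site does not fit on the UTR")
  }
  i <- core_start_1b(start0, as.character(site$site_type))
  # UTR position opposite miRNA position j (antiparallel band)
  opposite <- i + 7L - seq_along(m)
  lo <- max(1L, start0 + 1L - flank)
  paired <- logical(length(m))
  partner <- character(length(m))
  for (j in seq_along(m)) {
    up <- opposite[j]
    if (up >= lo && up <= length(u)) {
      partner[j] <- u[up]
      paired[j] <- paste0(m[j], u[up]) %in% .wc_or_wobble
    }
  }
  nn <- rna_stack_energies()
  dg <- .duplex_initiation
  for (j in seq_len(length(m) - 1L)) {
    if (paired[j] && paired[j + 1L]) {
      stack <- nn[paste0(m[j], partner[j]), paste0(m[j + 1L], partner[j + 1L])]
      dg <- dg + min(stack, 0)
    }
  }
  dg
}

.context_type_points <- c("8mer" = 3, "7mer-m8" = 2, "7mer-A1" = 1.5,
                          "6mer" = 1)

#' Context score of a target site
#'
#' `score = w_type * type_points + w_au * local AU fraction (30 nt each
#' side of the site) + w_pos * min(distance to the nearer UTR end, 1500) /
#' 1500`, with type points 8mer = 3, 7mer-m8 = 2, 7mer-A1 = 1.5, 6mer = 1
#' and default weights (1, 1, 0.5).
#'
#' @param site one-row data.frame (or list) with `start`, `end`,
#'   `site_type`.
#' @param utr UTR sequence the site lives on.
#' @param weights numeric vector with elements `type`, `au`, `pos`.
#' @return the numeric context score.
#' @export
context_score <- function(site, utr, weights = c(type = 1, au = 1,
                                                 pos = 0.5)) {
  u <- as_rna_chars(utr, "UTR sequence")
  start0 <- as.integer(site$start)
  end0 <- as.integer(site$end)
  type <- as.character(site$site_type)
  win <- c(seq(max(1L, start0 - 29L), start0),         # 1-based left window
           seq(end0 + 1L, min(length(u), end0 + 30L)))
  win <- win[win >= 1 & win <= length(u)]
  au <- if (length(win)) mean(u[win] %in% c("A", "U")) else 0
  dist_end <- min(start0, length(u) - end0)
  unname(weights[["type"]] * .context_type_points[[type]] +
           weights[["au"]] * au +
           weights[["pos"]] * min(dist_end, 1500) / 1500)
}

#' Empirical percentiles of context scores
#'
#' Percentile of each score against the whole site universe of the current
#' run: `100 * (number of scores <= s) / n`; tied scores share a
#' percentile and a singleton universe scores 100.
#'
#' @param scores numeric vector of context scores.
#' @return numeric vector of percentiles in (0, 100].
#' @export
score_percentile <- function(scores) {
  n <- length(scores)
  if (n == 0) return(numeric(0))
  vapply(scores, function(s) 100 * sum(scores <= s) / n, numeric(1))
}

site_type_rank <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L,
                    "6mer" = 1L)

#' Predict miRNA-target relations over a set of UTRs
#'
#' Runs [find_seed_sites()] for every miRNA x transcript combination,
#' scores every site ([duplex_energy()], [context_score()]), computes
#' context-score percentiles against all sites of the run, and aggregates
#' per (miRNA, transcript) pair. A pair passes when its best (lowest)
#' duplex energy is at most `energy_threshold` and its best (highest)
#' percentile is at least `percentile_threshold`.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param utrs named character vector of 3'UTR sequences; names must be
#'   unique transcript ids.
#' @param energy_threshold duplex-energy cutoff (kcal/mol, default -20).
#' @param percentile_threshold context-score percentile cutoff (default
#'   90).
#' @param flank see [duplex_energy()].
#' @param weights see [context_score()].
#' @return list of class `target_prediction` with `pairs` (one row per
#'   miRNA-transcript pair with >= 1 site, sorted by miRNA then
#'   transcript: `mirna`, `transcript`, `n_sites`, `best_site_type`,
#'   `best_start`, `best_end`, `best_delta_g`, `best_context_percentile`,
#'   `passes`) and `sites` (every typed, scored site).
#' @export
predict_targets <- function(mirnas, utrs,
                            energy_threshold = -20,
                            percentile_threshold = 90,
                            flank = 15L,
                            weights = c(type = 1, au = 1, pos = 0.5)) {
  mirnas <- stats::setNames(as.character(mirnas), names(mirnas))
  utrs <- stats::setNames(as.character(utrs), names(utrs))
  if (length(mirnas) == 0 || length(utrs) == 0) {
    stop("mirnas and utrs must both be non-empty")
  }
  if (anyDuplicated(names(utrs))) {
    stop("duplicate transcript ids: ",
         paste(unique(names(utrs)[duplicated(names(utrs))]), collapse = ", "))
  }
  if (is.null(names(mirnas)) || is.null(names(utrs))) {
    stop("mirnas and utrs must be named")
  }

  utr_dna <- Biostrings::DNAStringSet(chartr("uU", "tT", utrs))
  all_sites <- list()
  for (mid in names(mirnas)) {
    m <- as_rna_chars(mirnas[[mid]], paste0("miRNA ", mid))
    if (length(m) < 19) stop("mature miRNA ", mid, " must be >= 19 nt")
    core6 <- chartr("uU", "tT",
                    paste(rev(unname(.rna_complement[m[2:7]])), collapse = ""))
    comp_m8 <- chartr("U", "T", .rna_complement[[m[8]]])
    hits <- Biostrings::vmatchPattern(core6, utr_dna)
    starts <- Biostrings::startIndex(hits)
    for (t_i in seq_along(utrs)) {
      st <- starts[[t_i]]
      if (is.null(st) || length(st) == 0) next
      useq <- strsplit(toupper(chartr("uU", "tT", utrs[[t_i]])), "")[[1]]
      for (i in st) {
        has_m8 <- i > 1L && useq[i - 1L] == comp_m8
        has_a1 <- (i + 6L) <= length(useq) && useq[i + 6L] == "A"
        type <- if (has_m8 && has_a1) "8mer"
                else if (has_m8) "7mer-m8"
                else if (has_a1) "7mer-A1"
                else "6mer"
        start0 <- i - 1L - (has_m8) * 1L
        end0 <- i + 5L + (has_a1) * 1L
        all_sites[[length(all_sites) + 1L]] <- data.frame(
          transcript_id = names(utrs)[t_i], mirna_id = mid,
          start = start0, end = end0, site_type = type,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(all_sites)) {
    sites <- data.frame(transcript_id = character(0), mirna_id = character(0),
                        start = integer(0), end = integer(0),
                        site_type = character(0), delta_g = numeric(0),
                        context_score = numeric(0), percentile = numeric(0),
                        stringsAsFactors = FALSE)
    pairs <- data.frame(mirna = character(0), transcript = character(0),
                        n_sites = integer(0), best_site_type = character(0),
                        best_start = integer(0), best_end = integer(0),
                        best_delta_g = numeric(0),
                        best_context_percentile = numeric(0),
                        passes = logical(0), stringsAsFactors = FALSE)
    return(structure(list(pairs = pairs, sites = sites),
                     class = "target_prediction"))
  }
  sites <- do.call(rbind, all_sites)
  sites$delta_g <- vapply(seq_len(nrow(sites)), function(k) {
    duplex_energy(mirnas[[sites$mirna_id[k]]], utrs[[sites$transcript_id[k]]],
                  sites[k, ], flank = flank)
  }, numeric(1))
  sites$context_score <- vapply(seq_len(nrow(sites)), function(k) {
    context_score(sites[k, ], utrs[[sites$transcript_id[k]]],
                  weights = weights)
  }, numeric(1))
  sites$percentile <- score_percentile(sites$context_score)

  key <- paste(sites$mirna_id, sites$transcript_id, sep = "\r")
  agg <- split(seq_len(nrow(sites)), key)
  pairs <- do.call(rbind, lapply(agg, function(idx) {
    sub <- sites[idx, ]
    best_site <- sub[order(-site_type_rank[sub$site_type], sub$start), ][1, ]
    data.frame(mirna = sub$mirna_id[1], transcript = sub$transcript_id[1],
               n_sites = nrow(sub), best_site_type = best_site$site_type,
               best_start = best_site$start, best_end = best_site$end,
               best_delta_g = min(sub$delta_g),
               best_context_percentile = max(sub$percentile),
               stringsAsFactors = FALSE)
  }))
  pairs$passes <- pairs$best_delta_g <= energy_threshold &
    pairs$best_context_percentile >= percentile_threshold
  pairs <- pairs[order(pairs$mirna, pairs$transcript), ]
  rownames(pairs) <- NULL
  rownames(sites) <- NULL
  structure(list(pairs = pairs, sites = sites),
            class = "target_prediction")
}

#' @export
print.target_prediction <- function(x, ...) {
  cat("Target prediction:", nrow(x$sites), "sites,",
      nrow(x$pairs), "miRNA-transcript pairs,",
      sum(x$pairs$passes), "passing\n")
  invisible(x)
}

#' Dinucleotide shuffle of sequences
#'
#' Shuffles each sequence while approximately preserving its dinucleotide
#' composition (random Eulerian-walk style reshuffle of the transition
#' lists), the standard negative control for motif and target-site
#' analyses.
#'
#' @param sequences named character vector.
#' @param seed integer seed for reproducibility.
#' @return named character vector of shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequences, seed = 1L) {
  set.seed(seed)
  walk_once <- function(chars) {
    n <- length(chars)
    succ <- lapply(split(chars[-1], chars[-n]), sample)
    used <- stats::setNames(integer(length(succ)), names(succ))
    res <- character(n)
    res[1] <- chars[1]
    for (k in 2:n) {
      prev <- res[k - 1]
      bag <- succ[[prev]]
      if (is.null(bag) || used[prev] >= length(bag)) return(NULL)
      used[prev] <- used[prev] + 1L
      res[k] <- bag[used[prev]]
    }
    res
  }
  out <- vapply(sequences, function(s) {
    chars <- strsplit(s, "")[[1]]
    if (length(chars) < 3) return(s)
    res <- NULL
    for (attempt in seq_len(20)) {
      res <- walk_once(chars)
      if (!is.null(res)) break
    }
    if (is.null(res)) res <- sample(chars)  # rare: plain permutation
    paste(res, collapse = "")
  }, character(1))
  stats::setNames(out, names(sequences))
}
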