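---
title: "Methods: integrative miRNA-mRNA analysis of the hair-follicle cycle"
author: "mirpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative miRNA-mRNA analysis of the hair-follicle cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpair)
```

## The problem

During the hair-follicle cycle, skin transitions between a resting phase
(telogen) and a growth phase (anagen). In wool- and cashmere-producing
species the transition is seasonal, and its initiation is under combined
transcriptional and post-transcriptional control: microRNAs repress their
target mRNAs by binding seed-complementary sites in 3'UTRs, so a miRNA
that drops in anagen releases targets that rise, and vice versa. `mirpair`
implements the full desk-scale analysis that connects the two expression
layers: small-RNA read QC, differential expression of both feature
classes, sequence-based target prediction, fold-change quadrant
integration, hypergeometric functional enrichment of the target set,
regulatory-network assembly, and qPCR validation arithmetic.

Every stage can be driven by the package's synthetic-data generator,
which plants known structure (differential features, negatively regulated
miRNA-target pairs, enriched annotation terms, read artifacts) and
records it in a truth set, so the whole pipeline is testable without any
study's raw data.

## Small-RNA read filtering

`filter_reads()` sends every read through a fixed cascade of six
categories, counting each read once in the first category it fails:

1. `low_quality` — mean Phred below 20, or more than 10% `N` calls;
2. `adaptor3_null` — the first 8 nt of the 3' adaptor are not found
   anywhere in the read (one mismatch allowed);
3. `insert_null` — the 3' adaptor starts at position 1 (empty insert);
4. `adaptor5_contaminant` — the 5' adaptor prefix starts within the
   first 8 nt;
5. `size_lt_18` — the trimmed insert is shorter than 18 nt;
6. `polyA` — the trimmed insert is at least 80% adenine.

Reads surviving all six are "high quality" and are trimmed to their
insert. Published per-sample accounting tables of this kind report
disjoint counts that sum to the total, which implies a cascade; the order
above follows such tables top to bottom. The quantitative definitions of
"low quality" and "polyA" are not standardized anywhere, so the
thresholds above are this package's defaults and every one of them is
configurable through `qc_config()`. Qualities are interpreted as
Phred+33 throughout.

Because surviving reads are adaptor-trimmed, re-filtering them with the
raw-read configuration would classify every read as `adaptor3_null`.
The `adaptor3_required` flag exists for exactly this situation: with
`adaptor3_required = FALSE` the full read is taken as the insert, and
re-filtering clean output removes nothing (this is the configuration the
idempotence test exercises).

`annotate_known_mirnas()` classifies distinct clean sequences against a
mature miRNA reference by exact match with a ±2 nt tolerance at the 3'
end — the end where mature miRNAs genuinely vary. This is a deliberately
database-free substitute for genome mapping followed by miRBase lookup;
it cannot recognize a known miRNA whose 5' end shifted, and it does not
attempt novel-miRNA prediction.

## Differential expression

Counts are normalized to counts-per-million (`normalize_cpm()`), and
per-feature fold changes are
`log2((CPM_anagen + c) / (CPM_telogen + c))` with pseudocount
`c = 0.5` (configurable) so zero counts stay finite.

Significance is assessed by an exact conditional binomial test on pooled
per-condition counts (`call_differential()`): conditioned on a feature's
total pooled count, the anagen pool is binomial with success probability
equal to anagen's share of the total library size; the two-sided p-value
is exact. The default is raw p-values at `alpha = 0.05`, with
Benjamini-Hochberg adjustment behind a flag.

Two properties and one caveat matter here:

* condition relabelling negates every fold change and preserves every
  p-value exactly;
* under the test's own sampling model (independent Poisson-like counts)
  the test holds its nominal size — the package's null-rate check runs
  the generator at near-zero negative-binomial dispersion for exactly
  this reason;
* with strong biological overdispersion across replicates the pooled
  test is anticonservative, a known property of exact pooled-count
  tests. The planted-truth recovery checks are therefore the primary
  validation surface, and effect sizes there (four-fold) dwarf the
  dispersion (0.1).

## Target prediction

`find_seed_sites()` reports canonical seed sites with TargetScan-style
typing: `6mer` (complement of miRNA positions 2-7), `7mer-m8` (2-8),
`7mer-A1` (2-7 plus an adenine opposite position 1), and `8mer` (both).
Overlapping extents collapse to the longest type, coordinates are
0-based half-open on the input strand, and `T`/`U` are interchangeable.

`duplex_energy()` scores each site by a nearest-neighbor stack sum: the
seed duplex is extended over up to `flank = 15` UTR bases 5' of the site,
pairing successive miRNA 3'-region bases with the bases opposite them
(banded, gap-free); Watson-Crick and G:U wobble pairs count. The free
energy is the +4.09 kcal/mol duplex initiation penalty plus the Delta-G37
stacking increment of every adjacent paired pair. Watson-Crick increments
are the unrounded Xia et al. values retained in the Turner 2004 set;
wobble increments are the Turner 2004 values. Two wobble-on-wobble
stacks are destabilizing (positive); they are truncated to zero so that
extending a duplex never raises its predicted stability — without a
loop/bulge model (deliberately out of scope; the stack-sum stays
hand-checkable) a destabilizing extension would otherwise make the score
depend non-monotonically on match length.

`context_score()` combines three terms:
`w_type * type_points + w_au * AU + w_pos * min(d, 1500)/1500`,
with type points 8mer = 3, 7mer-m8 = 2, 7mer-A1 = 1.5, 6mer = 1, `AU`
the A/U fraction of the 30 nt on each side of the site (functional sites
sit in AU-rich, structurally accessible context), and `d` the distance
to the nearer UTR end. The weights (1, 1, 0.5) are package choices. The
score is converted to an empirical percentile against every site found
in the current run (`100 * #{scores <= s} / n`; ties share a value; a
singleton universe scores 100).

A miRNA-transcript pair passes (`predict_targets()`) when its best site
reaches both literal thresholds: duplex energy at most −20 kcal/mol and
context-score percentile at least 90. Because the percentile is
empirical, the filter is only meaningful against a realistically sized
site universe — at toy scale (a handful of sites) the 90th percentile
rejects almost everything, which is why the recovery tests run at the
generator's default study size. Conservation scoring is not implemented:
it would require multi-species alignments, which are out of scope.

## Quadrant integration

`correlate_pairs()` joins predicted pairs with both differential tables,
keeps pairs whose *both* members are called differential, and places each
on the plane x = mRNA log2FC, y = miRNA log2FC. The demarcation lines sit
at 1.5-fold on both axes, `t = log2(1.5) ≈ 0.585`, with boundaries
included: quadrant I (x ≥ t, y ≥ t), II (x ≤ −t, y ≥ t), III (both
≤ −t), IV (x ≥ t, y ≤ −t), everything else `none`. Quadrants II and IV —
opposite signs — are the negative-regulation pairs that matter for miRNA
repression. The x = mRNA / y = miRNA axis convention is fixed by the
package and stated here because published verbal descriptions of such
plots are easy to transpose; the geometry (sign-flip maps I↔III and
II↔IV and preserves the negative-pair count) does not depend on it.

## Enrichment

For a target set of `TS` annotated genes drawn from `TB` annotated
background genes, a term with `B` genes of which `S` are in the target
set is scored with the exact hypergeometric upper tail

P = 1 − Σ_{i=0}^{S−1} C(B,i) · C(TB−B, TS−i) / C(TB, TS),

implemented in `hypergeom_p()` by summing the upper tail directly with
log binomial coefficients — algebraically identical to the
one-minus-sum form but numerically stable when P is tiny. `S = 0` takes
the empty-sum convention P = 1. `TB` and `TS` are computed per namespace
(GO and KEGG separately), background defaults to all annotated genes,
terms with `S = 0` are suppressed, ties order by term id, and
`top_k()` returns the 8 smallest p-values per namespace by default.
Raw p-values are reported; the rich factor is `S/B`. GO-graph ancestor
propagation is out of scope.

## Network

`build_network()` assembles the bipartite-plus-terms graph: miRNA nodes,
gene nodes (with up/down direction from fold-change sign), and the top-8
enriched terms per namespace; edges are typed `targets` (miRNA→gene) and
`annotated` (gene→term). `merge_interactions()` folds in external
gene-gene edge tables (BioGRID-style exports read as plain two-column
TSV — no API client, no network access), adding `interacts` edges only
between existing gene nodes unless `expand = TRUE`; self-loops are
dropped and unordered duplicates deduplicated, with malformed rows
skipped (aborting above 10%). Exports speak the Cytoscape SIF dialect
(ids with whitespace double-quoted) and GraphML via igraph; GraphML
round-trips the network exactly, SIF round-trips the typed edge set.
`hub_genes()` ranks genes by total degree — the "connected to many
genes" notion of a key node — with ties broken by id; other centralities
are out of scope.

## qPCR quantitation

`delta_delta_ct()` implements 2^−ΔΔCt with amplification efficiency
fixed at 2: technical replicates are averaged per (sample, gene); ΔCt
subtracts the reference gene; ΔΔCt subtracts the calibrator-stage mean
ΔCt of the same gene; RQ = 2^−ΔΔCt. Stage-level RQs aggregate biological
samples by geometric mean — the natural mean of a multiplicative
quantity, and the choice that pins the calibrator stage at exactly 1 —
with an arithmetic-mean flag. Adding any constant to every Ct leaves all
RQs unchanged, and duplicated rows do not change results (means are
idempotent).

`compare_stages()` runs one-way ANOVA on log2 RQ per gene and Fisher's
LSD pairwise t-statistics on the pooled error mean square. Zero
within-stage variance is a degenerate case: p is reported as 0 for
unequal means (1 for equal) and flagged in a `zero_variance` column.
Duncan's multiple range test is deliberately not implemented; LSD covers
the pairwise-contrast use case from its closed form.

## The synthetic generator: what it emulates, and what it does not

`generator_config()` fixes the study conditions; the defaults are the
conditions under which the recovery guarantees are stated:

* two conditions × 3 biological replicates; negative-binomial counts
  (mean-dispersion parameterization, dispersion 0.1 — a typical
  well-controlled bulk RNA-seq value) with baseline means log-uniform on
  [50, 2000];
* 40 miRNAs / 400 mRNAs; planted differential features at |log2FC| = 2,
  balanced up/down (10+10 miRNAs, 40+40 mRNAs) so library-composition
  bias stays negligible;
* 50 planted negative-regulation pairs joining opposite-direction
  features, preferring distinct mRNAs;
* 3'UTRs of 400-700 nt; each planted pair receives an 18-nt element that
  is the exact reverse complement of miRNA positions 2-19 — an exact
  7mer-m8 seed plus 3' supplementary pairing, so the planted duplex
  clears −20 kcal/mol with margin — in AU-rich (~90% A/U) flanking
  context, emulating the context of genuine functional sites; the base
  opposite miRNA position 1 is forced non-A so the planted type is
  exactly 7mer-m8;
* rejection screening (up to 100 attempts per UTR) guarantees no truth
  miRNA has an unplanted 7mer-m8 match anywhere; miRNA sequences are
  drawn with distinct seeds, 40-65% GC, and mutually non-colliding
  planted elements, since element content is fixed once planted;
* incidental 6mer/7mer-A1 matches are deliberately left in place: they
  populate the context-score percentile universe, exactly as weak sites
  do in real UTR scans;
* annotation: 50 terms alternating GO/KEGG namespaces, 20 genes each,
  full per-namespace coverage of the gene universe; enriched terms carry
  15 target-set genes;
* reads: insert lengths 18-30 nt with a 22-nt mode, Illumina small-RNA
  adaptors, and one planted artifact category per read drawn from the
  configured fractions; artifact reads are constructed to land in
  exactly their category under the filter cascade, validated with the
  same 1-mismatch adaptor matching the filter uses;
* qPCR plates: 3 biological × 3 technical replicates, reference gene at
  Ct 20, planted fold changes encoded as ΔCt shifts around Ct 24,
  optional Gaussian well noise (default SD 0.2 cycles).

Each generator operation draws from its own RNG stream derived from the
master seed by a fixed offset, so fixtures regenerate independently and
identical configurations are bit-identical.

What the generator does *not* emulate: sequencing error models beyond a
single low-quality class, GC or length biases in counting, dependence
between features, UTR secondary structure, imperfect (wobble or
bulged) seed sites, or annotation noise. Passing the recovery checks
therefore demonstrates that the pipeline's logic is correct under clean,
known-truth conditions; it does not certify performance on real data,
where dispersion estimation (edgeR/DESeq2-class modelling) and
conservation-aware target prediction would outperform the simplified
components here.

## Problem sizes and numerical conventions

The bundled checks run at: the full default study (40 miRNAs × 400
mRNAs × 6 samples, ~1,800 scanned sites) for pair recovery, averaged
over 10 seeds; 1,000-gene universes for enrichment recovery (10 seeds);
the exhaustive hypergeometric grid TB ≤ 30 (~87,000 cases) against
`phyper` and literal draw enumeration at TB ≤ 10; and a 7 × 7 quadrant
grid spanning both demarcation boundaries. Key conventions: percentile
ties share the maximal value; quadrant boundaries are inclusive;
enrichment ties break by term id; zero-total features get p = 1 without
error; zero-sum library columns are an error naming the sample; the
exact binomial two-sided p-value follows the minimum-likelihood
convention of `binom.test`.

## Known limitations

* The pooled exact test ignores replicate-level dispersion (see above).
* The duplex model has no loops, bulges, or dangling-end terms; energies
  are comparable within this package, not with full folding algorithms.
* The context-score percentile depends on the composition of the site
  universe in the run, so pass/fail decisions are corpus-relative.
* known/unknown miRNA classification tolerates only 3'-end length
  variation.
* SIF carries no node attributes; only GraphML round-trips them.
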