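# mirpair

Integrative miRNA–mRNA analysis of the telogen→anagen hair-follicle
transition, as an installable, fully tested R pipeline.

Skin switches seasonally between a resting (telogen) and a growth
(anagen) phase of the hair-follicle cycle, and the switch is controlled
in part post-transcriptionally: microRNAs bind seed-complementary sites
in 3'UTRs and repress their targets, so regulatory miRNA–mRNA pairs show
*opposite* expression changes across the transition. `mirpair` is for
researchers who have (or want to simulate) small-RNA and mRNA expression
data for two such conditions and need the standard integration analysis
end to end:

- **Small-RNA QC** — a six-category filter cascade (low quality / 3'
  adaptor missing / null insert / 5' adaptor contamination / <18 nt /
  polyA) with per-sample accounting where
  `total = high_quality + Σ categories`, length distributions, and
  per-position base composition.
- **Differential expression** — CPM normalization,
  `log2FC = log2((CPM_anagen + c)/(CPM_telogen + c))`, and a two-sided
  exact conditional binomial test on pooled per-condition counts at
  P = 0.05.
- **Target prediction** — canonical seed sites (6mer, 7mer-A1, 7mer-m8,
  8mer), duplex free energy as a Turner-2004 nearest-neighbor stack sum
  with a +4.09 kcal/mol initiation penalty, and a context score with an
  empirical percentile; a pair passes at ΔG ≤ −20 kcal/mol and
  percentile ≥ 90.
- **Quadrant integration** — pairs where both members are differential,
  placed on the (mRNA log2FC, miRNA log2FC) plane with demarcation
  lines at t = log2(1.5); quadrants II and IV are the
  negative-regulation pairs.
- **Enrichment** — the exact hypergeometric upper tail
  `P = 1 − Σ_{i<S} C(B,i)·C(TB−B,TS−i)/C(TB,TS)` per GO/KEGG namespace,
  with rich factor S/B and a top-8 ranking.
- **Network** — miRNA→gene→term graphs with merged external gene–gene
  interaction tables, SIF/GraphML export, and degree-ranked hub genes.
- **qPCR** — 2^−ΔΔCt relative quantitation against a reference gene and
  calibrator stage, with ANOVA + Fisher's LSD stage comparisons.
- **Synthetic data** — a generator that plants differential features,
  negatively regulated target pairs, enriched terms and read artifacts,
  and records every planted structure in a truth set, so each stage is
  verifiable without raw data.

## Worked example

Generate a synthetic study at the default conditions (2 × 3 replicates,
NB dispersion 0.1, 50 planted negative-regulation pairs at |log2FC| = 2)
and run the pipeline:

```r
library(mirpair)

study   <- generate_study(generator_config(seed = 1))
de_mir  <- call_differential(study$mirna_counts, study$condition)
de_gene <- call_differential(study$mrna_counts, study$condition)
pred    <- predict_targets(study$mirna_seqs, study$utrs)
pred
#> Target prediction: 1803 sites, 1695 miRNA-transcript pairs, 53 passing

quad <- correlate_pairs(pred$pairs, de_mir, de_gene)
summarize_pairs(quad)
#> Pair summary: 52 pairs, 50 negative-regulation
#>   quadrants: I=0 II=21 III=0 IV=29 none=2
#>   targets per miRNA: min 1 max 5 mean 2.6
#>   miRNAs per transcript: min 1 max 2 mean 1.04
```

Of 1,695 scanned miRNA–transcript combinations, 53 pass both thresholds;
52 survive the both-members-differential filter, and the 50 in quadrants
II and IV are exactly the 50 planted negative-regulation pairs. Enrich
the negative-pair target genes and build the network:

```r
neg <- quad[quad$negative_regulation, ]
enr <- enrich(unique(neg$mrna), study$annotation)
head(top_k(enr, 3), 4)
#>         term namespace  TB TS  B  S      p_value rich_factor
#> 1 GO:0000027        GO 400 50 20 17 2.541961e-14        0.85
#> 2 GO:0000001        GO 400 50 20 16 1.110677e-12        0.80
#> 3 GO:0000003        GO 400 50 20 15 3.544201e-11        0.75
#> 4    ko00048      KEGG 400 50 20 17 2.541961e-14        0.85

net <- build_network(neg, enr, study$annotation, de_gene)
net
#> Regulatory network: 84 nodes ( gene:50 miRNA:18 term:16 ), 187 edges ( annotated:137 targets:50 )
export_network(net, "network.sif", "sif")     # Cytoscape-ready
```

Here TB = 400 annotated background genes, TS = 50 annotated target
genes, and a term with B = 20 genes of which S = 17 are targets gets
P ≈ 2.5e-14 — the generator's planted enriched terms, recovered at the
top of the ranking. Finally, qPCR validation arithmetic on a noiseless
synthetic plate returns the planted relative quantities exactly:

```r
rq <- delta_delta_ct(generate_qpcr(generator_config(seed = 1), noise_sd = 0),
                     reference_gene = "ACTB", calibrator_stage = "telogen")
rq$stages[rq$stages$stage == "anagen", ]
#>    gene  stage  rq sd n
#> 1  CHP1 anagen 4.0  0 3
#> 3  FZD6 anagen 2.0  0 3
#> 5 SIAH1 anagen 0.5  0 3
#> 7 SMAD2 anagen 1.0  0 3
```

The package also ships the published per-category filter counts of six
goat skin small-RNA libraries (`goat_filter_counts()`); feeding them to
`filter_report()` reproduces the surviving high-quality read counts and
percentages through the accounting identity.

## Documentation

The methods vignette (`vignettes/mirna-mrna-integration.Rmd`) documents
the models, every tunable parameter with its default and rationale, the
numerical conventions, what the synthetic generator does and does not
emulate, and known limitations.
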