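# Network construction, interaction merging, export round-trips, hubs.

toy_network <- function() {
  pairs <- data.frame(mirna = c("m1", "m1", "m2"),
                      mrna = c("g1", "g2", "g1"),
                      x = c(2, 2, 2), y = c(-2, -2, -2),
                      quadrant = "IV", negative_regulation = TRUE,
                      stringsAsFactors = FALSE)
  enr <- data.frame(term = c("t1", "t2"), namespace = "GO",
                    TB = 10L, TS = 3L, B = 3L, S = 2L,
                    p_value = c(0.01, 0.2), rich_factor = 0.5,
                    rank = 1:2, stringsAsFactors = FALSE)
  ann <- data.frame(term = c("t1", "t1", "t2"),
                    gene = c("g1", "g2", "gX"),
                    stringsAsFactors = FALSE)
  fc <- data.frame(feature_id = c("g1", "g2"), log2fc = c(2, 2),
                   call = "up", stringsAsFactors = FALSE)
  build_network(pairs, enr, ann, fc)
}

test_that("build_network assembles typed nodes and edges", {
  net <- toy_network()
  expect_setequal(net$nodes$id, c("m1", "m2", "g1", "g2", "t1", "t2"))
  expect_equal(sum(net$edges$edge_type == "targets"), 3L)
  expect_equal(sum(net$edges$edge_type == "annotated"), 2L)  # gX not a node
  expect_equal(net$nodes$direction[net$nodes$id == "g1"], "up")
  expect_equal(net$nodes$direction[net$nodes$id == "m1"], "down")

  # one pair, one annotation: 3 nodes, 2 edges
  one <- build_network(
    data.frame(mirna = "m1", mrna = "g1", x = 2, y = -2,
               stringsAsFactors = FALSE),
    data.frame(term = "t1", namespace = "GO", p_value = 0.01,
               stringsAsFactors = FALSE),
    data.frame(term = "t1", gene = "g1", stringsAsFactors = FALSE),
    data.frame(feature_id = "g1", log2fc = 2, call = "up",
               stringsAsFactors = FALSE))
  expect_equal(nrow(one$nodes), 3L)
  expect_equal(nrow(one$edges), 2L)

  empty <- build_network(data.frame(mirna = character(0),
                                    mrna = character(0)),
                         NULL, NULL, NULL)
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)

  expect_error(build_network(
    data.frame(mirna = "m1", mrna = "gZ", x = 2, y = -2),
    NULL, data.frame(term = character(0), gene = character(0)),
    data.frame(feature_id = "g1", log2fc = 2, call = "up")), "gZ")
})

test_that("merge_interactions honours presence, expansion and dedup rules", {
  net <- toy_network()
  tab <- data.frame(a = c("g1", "g1", "g2", "g1"),
                    b = c("g2", "gX", "g1", "g1"),
                    stringsAsFactors = FALSE)
  merged <- merge_interactions(net, tab)
  inter <- merged$edges[merged$edges$edge_type == "interacts", ]
  expect_equal(nrow(inter), 1L)  # gX absent, self-loop dropped, dup dedup

  expanded <- merge_interactions(net, tab, expand = TRUE)
  expect_true("gX" %in% expanded$nodes$id)
  inter2 <- expanded$edges[expanded$edges$edge_type == "interacts", ]
  expect_equal(nrow(inter2), 2L)

  # synthetic table: qualifying rows added exactly once
  big <- data.frame(a = c(rep("g1", 40), rep("zz", 60)),
                    b = c(paste0("n", 1:40), paste0("q", 1:60)),
                    stringsAsFactors = FALSE)
  both_present <- merge_interactions(net, big)
  expect_equal(sum(both_present$edges$edge_type == "interacts"), 0L)

  bad <- data.frame(a = c("g1", "", ""), b = c("g2", "x", "y"),
                    stringsAsFactors = FALSE)
  expect_error(merge_interactions(net, bad), "10%")
  ok_bad <- data.frame(a = c(rep("g1", 20), ""),
                       b = c(paste0("g2"), paste0("n", 1:19), "x"),
                       stringsAsFactors = FALSE)
  expect_warning(merge_interactions(net, ok_bad), "malformed")
})

test_that("GraphML export/import is the identity", {
  net <- toy_network()
  net <- merge_interactions(net, data.frame(a = "g1", b = "g2"))
  path <- tempfile(fileext = ".graphml")
  export_network(net, path, format = "graphml")
  back <- import_network(path, format = "graphml")
  ord <- function(n) {
    list(nodes = n$nodes[order(n$nodes$id), ],
         edges = n$edges[order(n$edges$source, n$edges$target,
                               n$edges$edge_type), ])
  }
  a <- ord(net); b <- ord(back)
  rownames(a$nodes) <- rownames(b$nodes) <- NULL
  rownames(a$edges) <- rownames(b$edges) <- NULL
  expect_equal(a$nodes, b$nodes)
  expect_equal(a$edges, b$edges)
})

test_that("SIF export/import reproduces the typed edge set, quoting spaces", {
  net <- toy_network()
  net$nodes$id[net$nodes$id == "t1"] <- "wnt signalling"
  net$edges$target[net$edges$target == "t1"] <- "wnt signalling"
  path <- tempfile(fileext = ".sif")
  export_network(net, path, format = "sif")
  lines <- readLines(path)
  expect_equal(length(lines), nrow(net$edges))
  expect_true(any(grepl("\"wnt signalling\"", lines)))
  back <- import_network(path, format = "sif")
  key <- function(e) sort(paste(e$source, e$edge_type, e$target))
  expect_identical(key(back$edges), key(net$edges))
  expect_error(export_network(net, path, format = "dot"), "should be one of")
})

test_that("edge conservation holds on a generated study", {
  cfg <- small_config(seed = 83L)
  counts <- generate_counts(cfg)
  ga <- generate_annotations(cfg, counts$truth)
  tp <- counts$truth$true_pairs
  pairs <- data.frame(mirna = tp$mirna, mrna = tp$mrna,
                      x = ifelse(counts$truth$de_direction$mrna[tp$mrna] ==
                                   "up", 2, -2),
                      y = ifelse(counts$truth$de_direction$mirna[tp$mirna] ==
                                   "up", 2, -2),
                      stringsAsFactors = FALSE)
  fc <- data.frame(feature_id = rownames(counts$mrna),
                   log2fc = ifelse(counts$truth$de_direction$mrna == "up",
                                   2, -2),
                   call = "up", stringsAsFactors = FALSE)
  enr <- enrich(unique(tp$mrna), ga$annotation)
  net <- build_network(pairs, enr, ga$annotation, fc, top_terms = 8L)
  terms_in <- net$nodes$id[net$nodes$node_type == "term"]
  ann_links <- unique(ga$annotation[ga$annotation$gene %in% unique(tp$mrna) &
                                      ga$annotation$term %in% terms_in,
                                    c("term", "gene")])
  expect_equal(nrow(net$edges), nrow(tp) + nrow(ann_links))
})

test_that("hub ranking is degree-descending with id tie-breaks", {
  nodes <- data.frame(id = c("m1", "g1", "g2", "g3"),
                      node_type = c("miRNA", "gene", "gene", "gene"),
                      direction = "na", stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("m1", "m1", "m1", "g1", "g2"),
    target = c("g1", "g2", "g3", "g2", "g3"),
    edge_type = c("targets", "targets", "targets", "interacts", "interacts"),
    stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "regulatory_network")
  # degrees: g1 = 2 (m1, g1-g2), g2 = 3, g3 = 2; tie g1/g3 broken by id
  ranked <- hub_genes(net, 10)
  expect_equal(ranked$gene, c("g2", "g1", "g3"))
  expect_equal(ranked$degree, c(3L, 2L, 2L))

  # ranking invariant under node-insertion order
  net2 <- net
  net2$nodes <- net2$nodes[rev(seq_len(nrow(net2$nodes))), ]
  expect_equal(hub_genes(net2, 10), ranked)

  empty <- structure(list(nodes = nodes[0, ], edges = edges[0, ]),
                     class = "regulatory_network")
  expect_equal(nrow(hub_genes(empty, 3)), 0L)
})
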