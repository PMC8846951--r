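test_that("KGML parsing builds the bipartite graph and ignores map entries", {
  g <- parse_kgml(kgml_two_enzymes_one_compound())
  expect_equal(g$pathway_id, "ec99999")
  expect_equal(nrow(g$nodes), 3L)  # 2 enzymes + 1 shared compound; map dropped
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(g$nodes$label[g$nodes$kind == "enzyme"],
                  c("1.1.1.1", "2.2.2.2"))
  expect_equal(g$edges$role[g$edges$enzyme == "1.1.1.1"], "substrate")
  expect_true(g$edges$reversible[g$edges$enzyme == "2.2.2.2"])
})

test_that("multi-EC entries expand and dangling references are errors", {
  xml <- paste0(
    '<pathway name="path:ec00002" title="t">',
    '<entry id="1" name="ec:1.1.1.1 ec:1.2.1.3" type="enzyme"/>',
    '<entry id="2" name="cpd:C00002" type="compound"/>',
    '<reaction id="1" name="rn:R1" type="irreversible">',
    '<substrate id="2"/></reaction></pathway>')
  g <- parse_kgml(xml)
  expect_setequal(g$nodes$label[g$nodes$kind == "enzyme"],
                  c("1.1.1.1", "1.2.1.3"))
  expect_equal(nrow(g$edges), 2L)  # one per expanded enzyme

  bad <- sub('substrate id="2"', 'substrate id="9"', xml)
  expect_error(parse_kgml(bad), "unknown entry id")
  expect_error(parse_kgml("<notkgml/>"), "no <pathway> root")
})

test_that("generated KGML parses back to the generator's ground truth", {
  g <- generate_kgml(n_pathways = 5, ecs_per_pathway = 6,
                     shared_fraction = 0.5, seed = 41)
  net <- merge_networks(lapply(g$kgml, parse_kgml))
  expect_equal(sum(net$nodes$kind == "enzyme"), g$truth$n_ec_nodes)
  expect_equal(sum(net$nodes$kind == "compound"), g$truth$n_compound_nodes)
  expect_equal(nrow(net$edges), g$truth$n_edges)
  for (ec in names(g$truth$membership)) {
    expect_setequal(net$membership[[ec]], g$truth$membership[[ec]])
  }
})

test_that("merging unifies shared enzymes and is idempotent", {
  shared <- generate_kgml(2, 5, shared_fraction = 1, seed = 42)
  net <- merge_networks(lapply(shared$kgml, parse_kgml))
  expect_equal(sum(net$nodes$kind == "enzyme"), 5L)
  expect_true(all(lengths(net$membership) == 2L))

  disjoint <- generate_kgml(2, 5, shared_fraction = 0, seed = 42)
  net2 <- merge_networks(lapply(disjoint$kgml, parse_kgml))
  expect_equal(sum(net2$nodes$kind == "enzyme"), 10L)

  one <- parse_kgml(disjoint$kgml[1])
  twice <- merge_networks(list(one, one))
  once <- merge_networks(list(one))
  expect_equal(twice$nodes, once$nodes)
  expect_equal(twice$edges, once$edges)
})

test_that("the EZS filter removes depleted enzymes and orphaned compounds", {
  g <- parse_kgml(kgml_two_enzymes_one_compound())
  net <- merge_networks(list(g))

  # boundary: ezs exactly at the threshold is retained
  sc <- scores_from(c("1.1.1.1", "2.2.2.2"), c(-1.0, 0.5))
  kept <- filter_by_ezs(net, sc, min_z = -1)
  expect_setequal(kept$nodes$label, net$nodes$label)

  # a depleted enzyme goes, and with it its now-isolated compound
  xml <- paste0(
    '<pathway name="path:ec00003" title="t">',
    '<entry id="1" name="ec:1.1.1.1" type="enzyme"/>',
    '<entry id="2" name="ec:2.2.2.2" type="enzyme"/>',
    '<entry id="3" name="cpd:C00001" type="compound"/>',
    '<entry id="4" name="cpd:C00002" type="compound"/>',
    '<reaction id="1" name="rn:R1" type="irreversible">',
    '<substrate id="3"/></reaction>',
    '<reaction id="2" name="rn:R2" type="irreversible">',
    '<substrate id="4"/></reaction></pathway>')
  net2 <- merge_networks(list(parse_kgml(xml)))
  sc2 <- scores_from(c("1.1.1.1", "2.2.2.2"), c(-2.5, 0))
  cut <- filter_by_ezs(net2, sc2)
  expect_setequal(cut$nodes$label, c("2.2.2.2", "C00002"))
  expect_equal(names(cut$membership), "2.2.2.2")

  # unscored enzymes drop by default, stay on request
  sc3 <- scores_from("2.2.2.2", 0)
  expect_false("1.1.1.1" %in% filter_by_ezs(net2, sc3)$nodes$label)
  expect_true("1.1.1.1" %in%
              filter_by_ezs(net2, sc3, keep_unscored = TRUE)$nodes$label)

  # idempotence at a fixed threshold
  again <- filter_by_ezs(cut, sc2)
  expect_equal(again$nodes, cut$nodes)
  expect_equal(again$edges, cut$edges)
})

test_that("MCL recovers disjoint components and stays column-stochastic", {
  net <- biclique_network(n_enz = 4, n_cpd = 4, n_blocks = 2)
  cs <- mcl_cluster(net, keep_matrix = TRUE)
  expect_true(cs$converged)
  expect_equal(length(cs$clusters), 2L)
  expect_true(all(abs(colSums(cs$stochastic_matrix) - 1) < 1e-9))

  # the split must match the graph components (independent oracle)
  ig <- igraph::graph_from_data_frame(
    net$edges[, c("enzyme", "compound")], directed = FALSE)
  comp <- igraph::components(ig)$membership
  for (cl in cs$clusters) {
    expect_equal(length(unique(comp[cl])), 1L)
  }
  expect_equal(unname(cs$ec_counts), c(4L, 4L))
})

test_that("MCL handles singletons and is deterministic", {
  single <- structure(
    list(nodes = data.frame(label = "1.1.1.1", kind = "enzyme"),
         edges = data.frame(enzyme = character(0), compound = character(0),
                            role = character(0), reaction = character(0),
                            reversible = logical(0)),
         membership = list("1.1.1.1" = "p1"), pathway_ids = "p1"),
    class = "metabolic_network")
  cs <- mcl_cluster(single)
  expect_equal(length(cs$clusters), 1L)
  expect_equal(cs$clusters[[1]], "1.1.1.1")

  net <- biclique_network(3, 3, 3)
  expect_identical(mcl_cluster(net)$clusters, mcl_cluster(net)$clusters)
  expect_error(mcl_cluster(structure(
    list(nodes = data.frame(label = character(0), kind = character(0)),
         edges = single$edges, membership = list(), pathway_ids = character(0)),
    class = "metabolic_network")), "empty")
})

test_that("higher inflation never coarsens the clustering of a bridged graph", {
  # two dense bicliques joined by a single bridge compound
  b <- biclique_network(n_enz = 4, n_cpd = 4, n_blocks = 2)
  bridge <- data.frame(enzyme = c("1.1.1.1", "2.1.1.1"),
                       compound = "CBRIDGE", role = "substrate",
                       reaction = "RB", reversible = FALSE)
  b$edges <- rbind(b$edges, bridge)
  b$nodes <- rbind(b$nodes, data.frame(label = "CBRIDGE", kind = "compound"))
  n_low <- length(mcl_cluster(b, inflation = 1.5)$clusters)
  n_high <- length(mcl_cluster(b, inflation = 5)$clusters)
  expect_gte(n_high, n_low)
})

test_that("clusters never span components of a random synthetic network", {
  g <- generate_kgml(4, 5, shared_fraction = 0, seed = 43)
  net <- merge_networks(lapply(g$kgml, parse_kgml))
  cs <- mcl_cluster(net)
  ig <- igraph::graph_from_data_frame(
    net$edges[, c("enzyme", "compound")], directed = FALSE)
  comp <- igraph::components(ig)$membership
  for (cl in cs$clusters) {
    expect_equal(length(unique(comp[cl])), 1L)
  }
})

test_that("cluster size filtering keeps only clusters with enough enzymes", {
  mk_cs <- function(ec_counts) {
    clusters <- lapply(seq_along(ec_counts), function(i) {
      c(sprintf("%d.1.1.%d", i, seq_len(ec_counts[i])), sprintf("C%d", i))
    })
    names(clusters) <- paste0("cluster_", seq_along(clusters))
    kinds <- stats::setNames(
      unlist(lapply(clusters, function(cl) {
        ifelse(grepl("^C", cl), "compound", "enzyme")
      })), unlist(clusters))
    structure(list(clusters = clusters, kinds = kinds,
                   ec_counts = as.integer(ec_counts), intersections = NULL,
                   parameters = list(inflation = 1.5, prune = 1e-5,
                                     max_iter = 200L, min_ec = NA_integer_),
                   converged = TRUE, iterations = 1L,
                   stochastic_matrix = NULL),
              class = "mcl_clusters")
  }
  cs <- filter_clusters(mk_cs(c(5, 3, 4)), min_ec = 4)
  expect_equal(unname(cs$ec_counts), c(5L, 4L))

  none <- filter_clusters(mk_cs(c(1, 2)), min_ec = 4)
  expect_equal(length(none$clusters), 0L)

  ident <- filter_clusters(mk_cs(c(1, 0, 3)), min_ec = 0)
  expect_equal(length(ident$clusters), 3L)
})

test_that("pathway intersections count cluster enzymes per pathway", {
  g <- generate_kgml(3, 4, shared_fraction = 0.5, seed = 44)
  net <- merge_networks(lapply(g$kgml, parse_kgml))
  cs <- pathway_intersections(mcl_cluster(net), net)
  expect_equal(dim(cs$intersections),
               c(length(cs$clusters), length(net$pathway_ids)))
  # the matrix must agree with a direct recount from the truth membership
  for (ci in seq_along(cs$clusters)) {
    ecs <- cs$clusters[[ci]][cs$kinds[cs$clusters[[ci]]] == "enzyme"]
    for (p in colnames(cs$intersections)) {
      expected <- sum(vapply(ecs, function(ec) {
        p %in% g$truth$membership[[ec]]
      }, logical(1)))
      expect_equal(cs$intersections[ci, p], expected)
    }
    expect_lte(max(cs$intersections[ci, ]), length(ecs))
  }

  # hand-sized case: cluster {a, b}, pathway containing only a
  tiny <- structure(
    list(nodes = data.frame(label = c("1.1.1.1", "2.2.2.2"),
                            kind = "enzyme"),
         edges = data.frame(enzyme = character(0), compound = character(0),
                            role = character(0), reaction = character(0),
                            reversible = logical(0)),
         membership = list("1.1.1.1" = "pA", "2.2.2.2" = "pB"),
         pathway_ids = c("pA", "pB")),
    class = "metabolic_network")
  cs2 <- structure(
    list(clusters = list(cluster_1 = c("1.1.1.1", "2.2.2.2")),
         kinds = c("1.1.1.1" = "enzyme", "2.2.2.2" = "enzyme"),
         ec_counts = 2L, intersections = NULL,
         parameters = list(), converged = TRUE, iterations = 0L,
         stochastic_matrix = NULL),
    class = "mcl_clusters")
  m <- pathway_intersections(cs2, tiny)$intersections
  expect_equal(unname(m["cluster_1", "pA"]), 1L)
  expect_equal(unname(m["cluster_1", "pB"]), 1L)
})
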