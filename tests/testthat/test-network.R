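two_sample_fixture <- function() {
  ct <- make_clonotypes(
    cdr3a = c("CAVRDNYQLIW", "CAVRDNYQLIW", "CAVNTGGFKTIF"),
    cdr3b = c("CASSLGQAYEQYF", "CASSLGQAYEQFF", "CAWWPTSGGNEQFF"),
    sample_id = c("AD01", "MCI01", "AD01"),
    group = c("AD", "MCI", "AD")
  )
  list(ct = ct, m = pairwise_lsim(ct, "concat_ab"))
}

test_that("build_network creates hubs, leaves and thresholded edges", {
  fx <- two_sample_fixture()
  net <- build_network(fx$ct, fx$m, tau = 0.9)
  g <- net$graph
  expect_equal(sum(igraph::V(g)$kind == "hub"), 2L)
  expect_equal(sum(igraph::V(g)$kind == "leaf"), 3L)  # leaf count = clonotypes
  # one cross-sample pair above 0.9 (single beta substitution)
  sim <- igraph::E(g)[igraph::E(g)$kind == "similarity"]
  expect_equal(length(sim), 1L)
  expect_true(all(sim$lsim > 0.9))
  # attachment edge count = leaf count
  expect_equal(sum(igraph::E(g)$kind == "attachment"), 3L)

  # stricter threshold prunes all edges but keeps hubs and leaves
  strict <- build_network(fx$ct, fx$m, tau = 0.999)
  expect_equal(sum(igraph::E(strict$graph)$kind == "similarity"), 0L)
  expect_equal(igraph::vcount(strict$graph), 5L)
})

test_that("identical beta-only clonotypes across samples connect at lsim 1", {
  ct <- make_clonotypes(NULL, rep("CASSLGQAYEQYF", 3),
                        sample_id = c("HC01", "HC02", "HC03"), group = "HC")
  m <- pairwise_lsim(ct, "beta_only")
  net <- build_network(ct, m, tau = 0.999)
  ed <- igraph::E(net$graph)
  sim <- ed[ed$kind == "similarity"]
  expect_equal(length(sim), 3L)  # all three pairwise edges
  expect_true(all(sim$lsim == 1))
  counts <- group_sharing_counts(net)
  expect_equal(counts["HC", "HC"], 3L)
  expect_equal(sum(counts[upper.tri(counts, diag = TRUE)]), 3L)
})

test_that("group sharing counts edges between unique samples", {
  ct <- make_clonotypes(
    NULL,
    c("CASSLGQAYEQYF", "CASSLGQAYEQFF",   # AD01 - MCI01 edge
      "CAWWPTSGGNEQFF", "CAWWPTSGGNEQFA", # AD01 - AD02 edge
      "CGGGGGGGGGGGGF"),                  # isolated
    sample_id = c("AD01", "MCI01", "AD01", "AD02", "PD01"),
    group = c("AD", "MCI", "AD", "AD", "PD")
  )
  m <- pairwise_lsim(ct, "beta_only")
  net <- build_network(ct, m, tau = 0.8)
  counts <- group_sharing_counts(net)
  expect_equal(counts["AD", "MCI"], 1L)
  expect_equal(counts["MCI", "AD"], 1L)
  expect_equal(counts["AD", "AD"], 1L)
  expect_equal(counts["PD", "PD"], 0L)
  # total equals cross-sample similarity edges
  expect_equal(sum(counts[upper.tri(counts, diag = TRUE)]), 2L)

  # within-sample edges are excluded by default, included on request
  ct2 <- make_clonotypes(NULL, c("CASSLGQAYEQYF", "CASSLGQAYEQFF"),
                         sample_id = "AD01", group = "AD")
  net2 <- build_network(ct2, pairwise_lsim(ct2, "beta_only"), tau = 0.8)
  expect_equal(group_sharing_counts(net2)["AD", "AD"], 0L)
  expect_equal(group_sharing_counts(net2, include_within_sample = TRUE)["AD", "AD"], 1L)
})

test_that("empty edge set yields an all-zero matrix", {
  fx <- two_sample_fixture()
  net <- build_network(fx$ct, fx$m, tau = 0.999)
  expect_true(all(group_sharing_counts(net) == 0L))
})

test_that("networks round-trip through graphml and edge CSVs", {
  fx <- two_sample_fixture()
  net <- build_network(fx$ct, fx$m, tau = 0.8)
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_true(igraph::isomorphic(net$graph, back$graph))
  expect_equal(sort(igraph::V(back$graph)$name),
               sort(igraph::V(net$graph)$name))
  expect_equal(sort(igraph::E(back$graph)$kind),
               sort(igraph::E(net$graph)$kind))

  base <- tempfile()
  files <- export_network(net, base, "edge_csv")
  back2 <- import_network(base, "edge_csv")
  expect_true(igraph::isomorphic(net$graph, back2$graph))
  edges <- read.csv(paste0(base, "_edges.csv"))
  expect_equal(sum(edges$kind == "attachment"), 3L)
})

test_that("matrix/clonotype mismatch is an integrity error", {
  fx <- two_sample_fixture()
  expect_error(build_network(fx$ct[1:2, ], fx$m, 0.8), "mismatch")
})

test_that("the tau=0.9 network is an edge-subgraph of tau=0.8", {
  set.seed(505)
  ct <- make_clonotypes(NULL, vapply(sample(10:16, 30, TRUE),
                                     random_cdr3_string, ""),
                        sample_id = sample(c("S1", "S2", "S3"), 30, TRUE))
  m <- pairwise_lsim(ct, "beta_only")
  edge_set <- function(tau) {
    net <- build_network(ct, m, tau)
    ed <- igraph::E(net$graph)
    sim <- ed[ed$kind == "similarity"]
    if (!length(sim)) return(character())
    ends <- igraph::ends(net$graph, sim)
    paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
  }
  expect_true(all(edge_set(0.9) %in% edge_set(0.8)))
  # also at a low threshold where edges certainly exist
  expect_true(all(edge_set(0.5) %in% edge_set(0.3)))
  expect_gt(length(edge_set(0.3)), 0L)
})
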