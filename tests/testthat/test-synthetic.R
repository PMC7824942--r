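test_that("generation is deterministic and internally consistent", {
  cfg <- small_sim_config(seed = 11L)
  sim1 <- generate_repertoire(cfg)
  sim2 <- generate_repertoire(cfg)
  expect_identical(sim1$contigs, sim2$contigs)
  expect_identical(sim1$truth$cells, sim2$truth$cells)

  # written outputs are byte-identical under the same seed
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_sim_repertoire(sim1, d1)
  write_sim_repertoire(sim2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # every emitted CDR3 passes repertoire validation
  contigs <- read_cellranger_contigs(
    file.path(d1, "AD01_contig_annotations.csv"), "AD01")
  expect_true(all(contigs$usable))

  # clone sizes sum to the per-sample cell budget
  per_sample <- table(sim1$truth$cells$sample_id)
  expect_true(all(per_sample == cfg$cells_per_sample))
  expect_equal(nrow(sim1$metadata), 8L)
})

test_that("different seeds give different repertoires", {
  a <- generate_repertoire(small_sim_config(seed = 1L))
  b <- generate_repertoire(small_sim_config(seed = 2L))
  expect_false(identical(a$contigs$cdr3, b$contigs$cdr3))
})

test_that("planted structure is recovered by the analysis chain", {
  sim <- generate_repertoire(small_sim_config(seed = 33L))
  res <- suppressMessages(suppressWarnings(
    run_pipeline(sim$contigs, sim$metadata,
                 out_dir = file.path(tempdir(), "simrun33"),
                 motif_length = 9)))
  rec <- score_recovery(sim, res$clonal, res$clusters, res$motifs)
  expect_equal(rec$clusters$recall, rep(1, 3))
  expect_equal(rec$clusters$contamination, rep(0L, 3))
  expect_equal(rec$clusters$n_planted, c(4L, 5L, 6L))
  expect_equal(rec$motifs$observed_frequency, 5L)
  expect_equal(rec$motifs$rank, 1L)

  # planted members sit in AD/MCI samples only
  expect_true(all(sim$truth$clusters$sample_id %in%
                    sim$metadata$sample_id[sim$metadata$diagnosis_group %in%
                                             c("AD", "MCI")]))
})

test_that("a structure-free repertoire yields no high-similarity clusters", {
  cfg <- sim_config(groups = c(HC = 1L), cells_per_sample = 300L,
                    clone_size_floor = 2L, clone_geom_prob = 1,
                    planted_clusters = list(), planted_motifs = list(),
                    ambiguous_rate = 0, nonproductive_rate = 0, seed = 44L)
  sim <- generate_repertoire(cfg)
  res <- suppressMessages(run_pipeline(sim$contigs, sim$metadata,
                                       out_dir = file.path(tempdir(), "flat44")))
  expect_equal(nrow(res$clonal), 150L)  # 300 cells in clones of exactly two
  expect_true(all(res$clonal$size == 2L))
  expect_equal(nrow(res$clusters), 0L)
})

test_that("infeasible configurations are rejected", {
  expect_error(
    sim_config(planted_motifs = list(list(motif = strrep("A", 30),
                                          carriers = 2L, clone_size = 2L,
                                          groups = "AD"))),
    "infeasible motif")
  expect_error(
    sim_config(planted_clusters = list(list(n_variants = 3L, radius = 6L,
                                            clone_size = 2L, groups = "AD",
                                            alpha_len = 14L, beta_len = 12L))),
    "infeasible cluster")
})

test_that("score_recovery flags id mismatches and partial recovery", {
  sim <- generate_repertoire(small_sim_config(seed = 55L))
  res <- suppressMessages(suppressWarnings(
    run_pipeline(sim$contigs, sim$metadata,
                 out_dir = file.path(tempdir(), "simrun55"))))
  # mangle: drop one planted member from the clonotype table
  planted_key <- paste(sim$truth$clusters$sample_id[1],
                       sim$truth$clusters$cdr3a[1],
                       sim$truth$clusters$cdr3b[1], sep = "\r")
  ct_key <- paste(res$clonal$sample_id, res$clonal$cdr3a, res$clonal$cdr3b,
                  sep = "\r")
  broken <- res$clonal[ct_key != planted_key, , drop = FALSE]
  expect_error(score_recovery(sim, broken, res$clusters), "mismatch")

  # removing a member from the detected clusters lowers recall to (k-1)/k
  victim_ct <- res$clonal$clonotype_id[ct_key == planted_key]
  pruned <- res$clusters[res$clusters$clonotype_id != victim_ct, , drop = FALSE]
  rec <- score_recovery(sim, res$clonal, pruned)
  k <- rec$clusters$n_planted[rec$clusters$cluster == "cluster1"]
  expect_equal(rec$clusters$recall[rec$clusters$cluster == "cluster1"],
               (k - 1) / k)
  expect_equal(rec$clusters$contamination, rep(0L, 3))
})
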