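test_that("edit distance and L-sim match frozen worked values", {
  expect_identical(levenshtein_distance("kitten", "sitting"), 3L)
  expect_identical(levenshtein_distance("", "ABC"), 3L)
  expect_identical(levenshtein_distance("ABC", ""), 3L)
  expect_identical(lsim("CASSLGQAYEQYF", "CASSLGQAYEQYF"), 1)
  expect_identical(lsim("A", "B"), 0)
  expect_equal(lsim("CASSF", "CASTF"), 0.8)
  expect_identical(lsim("AB", "ABCD"), 0.5)
  expect_error(lsim("", ""), "undefined")
})

test_that("optimized distance agrees with the naive DP oracle", {
  set.seed(101)
  for (rep in 1:200) {
    a <- random_aa_string(sample(0:30, 1))
    b <- random_aa_string(sample(0:30, 1))
    expect_identical(levenshtein_distance(a, b), oracle_lev(a, b))
  }
})

test_that("distance is a metric and lsim is a bounded similarity", {
  set.seed(202)
  strs <- vapply(sample(1:25, 60, replace = TRUE), random_aa_string, "")
  d <- function(x, y) levenshtein_distance(x, y)
  for (rep in 1:200) {
    t <- sample(strs, 3)
    expect_identical(d(t[1], t[2]), d(t[2], t[1]))           # symmetry
    expect_lte(d(t[1], t[3]), d(t[1], t[2]) + d(t[2], t[3])) # triangle
    s <- lsim(t[1], t[2])
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_identical(s == 1, t[1] == t[2])                   # 1 iff equal
  }
})

test_that("pairwise_lsim computes all pairs in every pairing mode", {
  ct <- make_clonotypes(
    cdr3a = c("CAVRDNYQLIW", "CAVRDNYQLIW", "CAVNTGGFKTIF"),
    cdr3b = c("CASSLGQAYEQYF", "CASSLGQAYEQFF", "CASSLGQAYEQYF")
  )
  for (mode in c("concat_ab", "per_chain_mean", "beta_only")) {
    m <- pairwise_lsim(ct, mode)
    expect_equal(length(m$scores), 3L)  # n(n-1)/2
    full <- as.matrix(m)
    expect_identical(full, t(full))
    expect_true(all(diag(full) == 1))
  }
  # hand computation: identical alpha, one beta substitution
  m <- pairwise_lsim(ct[1:2, ], "per_chain_mean")
  expect_equal(m$scores, (1 + oracle_lsim("CASSLGQAYEQYF", "CASSLGQAYEQFF")) / 2)
  m2 <- pairwise_lsim(ct[1:2, ], "concat_ab")
  expect_equal(m2$scores,
               oracle_lsim("CAVRDNYQLIWCASSLGQAYEQYF", "CAVRDNYQLIWCASSLGQAYEQFF"))
  # identical clonotypes in different samples score exactly 1
  twin <- make_clonotypes(cdr3a = rep("CAVRDNYQLIW", 2),
                          cdr3b = rep("CASSLGQAYEQYF", 2),
                          sample_id = c("A", "B"))
  expect_identical(pairwise_lsim(twin, "concat_ab")$scores, 1)
  # missing alpha chains are a config error outside beta_only
  beta_only_ct <- make_clonotypes(NULL, c("CASSF", "CASTF"))
  expect_error(pairwise_lsim(beta_only_ct, "concat_ab"), "both chains")
  expect_equal(pairwise_lsim(beta_only_ct, "beta_only")$scores, 0.8)
})

test_that("lsim_distribution summarises off-diagonal scores", {
  same <- make_clonotypes(cdr3a = rep("CAVRDNYQLIW", 4),
                          cdr3b = rep("CASSLGQAYEQYF", 4))
  d <- lsim_distribution(pairwise_lsim(same))
  expect_equal(d$n_pairs, 6L)
  expect_equal(d$mean, 1)
  expect_equal(sum(d$counts), 6L)
  expect_equal(d$counts[length(d$counts)], 6L)  # point mass at 1

  # two planted near-duplicate families give a bimodal histogram
  fam1 <- c("CASSLGQAYEQYF", "CASSLGQAYEQFF", "CASSLGQAYEQYA")
  fam2 <- c("CAWWPTSGGNEQFF", "CAWWPTSGGNEQFA", "CAWWPTSGGNEQAF")
  ct <- make_clonotypes(NULL, c(fam1, fam2))
  db <- lsim_distribution(pairwise_lsim(ct, "beta_only"), binwidth = 0.1)
  hi <- sum(db$counts[db$mids > 0.8])
  lo <- sum(db$counts[db$mids < 0.6])
  expect_equal(hi, 6L)  # within-family pairs
  expect_equal(lo, 9L)  # cross-family pairs
})

test_that("threshold clustering uses strict inequality and connected components", {
  # pair at exactly 0.8 does not connect at tau = 0.8
  ct <- make_clonotypes(NULL, c("CASSF", "CASTF"))
  m <- pairwise_lsim(ct, "beta_only")
  expect_equal(nrow(threshold_clusters(m, 0.8)), 0L)
  cl <- threshold_clusters(m, 0.79)
  expect_equal(nrow(cl), 2L)
  expect_equal(unique(cl$cluster_id), "C1")

  # chained pairs form one component even when the far pair is dissimilar
  chain <- lsim_matrix_from_pairs(
    c("A", "B", "C"),
    data.frame(id_i = c("A", "A", "B"), id_j = c("B", "C", "C"),
               lsim = c(0.85, 0.40, 0.82)))
  cl <- threshold_clusters(chain, 0.8)
  expect_equal(sort(cl$clonotype_id), c("A", "B", "C"))
  expect_equal(unique(cl$cluster_id), "C1")
  summ <- attr(cl, "summary")
  expect_equal(summ$n_members, 3L)
  expect_equal(summ$min_lsim, 0.40)  # within-component range includes far pair
  expect_equal(summ$max_lsim, 0.85)
})

test_that("clusters match brute-force components on random matrices", {
  set.seed(303)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    ids <- sprintf("CT%05d", seq_len(n))
    npair <- n * (n - 1) / 2
    scores <- round(runif(npair), 2)
    m <- structure(list(ids = ids, scores = scores, n = n,
                        pairing_mode = "beta_only"), class = "lsim_matrix")
    tau <- 0.7
    cl <- threshold_clusters(m, tau)
    # oracle: brute-force merge over the explicit edge list
    full <- as.matrix(m)
    edges <- which(upper.tri(full) & full > tau, arr.ind = TRUE)
    if (nrow(edges) == 0) {
      expect_equal(nrow(cl), 0L)
      next
    }
    comp <- oracle_components(n, edges)
    keep <- comp %in% which(tabulate(comp) >= 2)
    expected_sets <- unname(split(ids[keep], comp[keep]))
    got_sets <- unname(split(cl$clonotype_id, cl$cluster_id))
    canon <- function(sets) sort(vapply(sets, function(s)
      paste(sort(s), collapse = ","), ""))
    expect_equal(canon(got_sets), canon(expected_sets))
  }
})

test_that("raising tau refines clusters", {
  set.seed(404)
  ct <- make_clonotypes(NULL, vapply(sample(10:16, 40, TRUE),
                                     random_cdr3_string, ""))
  m <- pairwise_lsim(ct, "beta_only")
  lo <- threshold_clusters(m, 0.5)
  hi <- threshold_clusters(m, 0.7)
  # every high-tau cluster sits inside a single low-tau cluster
  if (nrow(hi) > 0) {
    lo_of <- setNames(lo$cluster_id, lo$clonotype_id)
    for (cid in unique(hi$cluster_id)) {
      members <- hi$clonotype_id[hi$cluster_id == cid]
      expect_equal(length(unique(lo_of[members])), 1L)
    }
  }
  succeed()
})
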