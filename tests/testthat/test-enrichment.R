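test_that("contingency tables follow the (q, m-q; Q-q, N-Q-m+q) layout", {
  universe <- sprintf("g%04d", 1:9000)
  cluster <- universe[1:11]
  target <- c(universe[1:8], universe[1000:2491]) # Q = 1500, q = 8
  tab <- build_contingency(cluster, target, universe)
  expect_equal(unname(as.vector(t(tab))), c(8, 3, 1492, 7497))

  # empty cluster and out-of-universe targets
  tab0 <- build_contingency(character(0), c("g0001", "NOT_IN_UNIVERSE"),
                            universe)
  expect_equal(unname(as.vector(t(tab0))), c(0, 0, 1, 8999))
  expect_error(build_contingency("alien", "g0001", universe), "universe")
})

test_that("right-tailed Fisher equals hypergeometric enumeration", {
  # q = 0 always gives p = 1 (right tail includes the observed value)
  expect_equal(fisher_right_tail(matrix(c(0, 3, 2, 5), 2, byrow = TRUE)), 1)
  # N = 4, Q = 2, m = 2, q = 2 -> 1/6 by direct enumeration
  expect_equal(fisher_right_tail(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
               1 / 6, tolerance = 1e-12)
  # N = 10, Q = 4, m = 5, q = 3 -> P(X=3) + P(X=4)
  tab <- matrix(c(3, 2, 1, 4), 2, byrow = TRUE)
  expect_equal(fisher_right_tail(tab), hyper_tail_oracle(3, 4, 5, 10),
               tolerance = 1e-12)
  # spot equivalence with stats::fisher.test on a larger table
  tab2 <- matrix(c(8, 3, 32, 157), 2, byrow = TRUE)
  expect_equal(fisher_right_tail(tab2),
               stats::fisher.test(tab2, alternative = "greater")$p.value,
               tolerance = 1e-9)
  expect_error(fisher_right_tail(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Fisher p is non-increasing in q at fixed margins", {
  n_all <- 60; big_q <- 20; m <- 15
  ps <- vapply(0:15, function(q) {
    fisher_right_tail(matrix(c(q, m - q, big_q - q, n_all - big_q - m + q),
                             2, byrow = TRUE))
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("robust FDR reproduces the pinned pi0 and monotonised values", {
  all_ones <- robust_fdr(rep(1, 7))
  expect_equal(all_ones$pi0, 1)
  expect_equal(all_ones$fdr, rep(1, 7))

  single <- robust_fdr(0.05)
  expect_equal(single$pi0, 0.1)
  expect_equal(single$fdr, 0.005)

  # monotonisation: FDR non-decreasing in p
  r <- robust_fdr(c(0.01, 0.5, 0.9))
  expect_true(all(diff(r$fdr[order(c(0.01, 0.5, 0.9))]) >= 0))

  # tied p-values share one FDR value
  r2 <- robust_fdr(c(0.2, 0.2, 0.8))
  expect_equal(r2$fdr[1], r2$fdr[2])

  expect_error(robust_fdr(numeric(0)), "empty")
  expect_error(robust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("FDR is monotone in p on random vectors and pluggable pi0 works", {
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(5:50, 1))
    r <- robust_fdr(p)
    ord <- order(p)
    expect_true(all(diff(r$fdr[ord]) >= -1e-15))
    expect_true(all(r$fdr >= 0 & r$fdr <= 1))
  }
  fixed <- robust_fdr(c(0.1, 0.2), pi0_estimator = function(p) 0.5)
  expect_equal(fixed$pi0, 0.5)
})

make_gene_sets <- function(pathogenic, aa, ca) {
  structure(list(pathogenic = pathogenic, cnv_aa_genes = aa,
                 cnv_ca_genes = ca), class = "gene_sets")
}

test_that("cluster scoring keeps Table-style count invariants", {
  set.seed(9)
  a <- random_planted_adj(36, c(10, 10), 0.8, 0.05)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  cl <- suppressWarnings(mcl_cluster(build_transition_matrix(g), 1.8))
  universe <- rownames(a)
  sets <- make_gene_sets(sample(universe, 12), sample(universe, 5),
                         sample(universe, 4))
  sc <- score_clusters(cl, sets, universe)
  expect_true(all(sc$q <= sc$m))
  expect_true(all(sc$q <= length(sets$pathogenic)))
  expect_true(all(sc$p_path >= 0 & sc$p_path <= 1))
  expect_true(all(sc$fdr_path >= 0 & sc$fdr_path <= 1))
  expect_equal(sc$joint_score, sc$fdr_path * sc$fdr_cnv)
  # one row per cluster and population
  expect_equal(nrow(sc), 2 * length(cl$clusters))
  aa <- sc[sc$population == "AA", ]
  ca <- sc[sc$population == "CA", ]
  expect_equal(aa$p_path, ca$p_path) # pathogenic test shared across populations
})

test_that("ranking applies strict gates and the documented tie-breaks", {
  base <- data.frame(
    run = "I1.5", population = "AA",
    cluster_id = sprintf("C%03d", 1:5),
    m = c(10, 8, 12, 9, 7), q = 3, s = 2,
    p_path = c(0.05, 0.15, 0.02, 0.02, 0.05),
    p_cnv = c(0.05, 0.01, 0.02, 0.02, 0.05),
    fdr_path = c(0.10, 0.05, 0.10, 0.10, 0.25),
    fdr_cnv = c(0.10, 0.10, 0.10, 0.10, 0.10),
    anchor_gene = c("B", "A", "A", "C", "D"),
    stringsAsFactors = FALSE
  )
  base$joint_score <- base$fdr_path * base$fdr_cnv
  ranked <- rank_clusters(base, "AA")
  # C002 excluded by p_path >= 0.10; C005 by fdr_path >= 0.20
  expect_false("C002" %in% ranked$cluster_id)
  expect_false("C005" %in% ranked$cluster_id)
  # equal joint scores: ascending p product, then larger m, then anchor
  expect_equal(ranked$cluster_id, c("C003", "C004", "C001"))
  expect_equal(ranked$rank, 1:3)

  # boundary values fail the strict gates
  boundary <- base[1, ]
  boundary$p_path <- 0.10
  expect_equal(nrow(rank_clusters(boundary, "AA")), 0)

  none <- base; none$fdr_cnv <- 0.5
  none$joint_score <- none$fdr_path * none$fdr_cnv
  expect_equal(nrow(rank_clusters(none, "AA")), 0)
})
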