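small_config <- function(seed = 1, ...) {
  scenario_config(n_genes = 120, n_modules = 4, module_size_range = c(6, 10),
                  p_within = 0.7, p_between = 0.02, n_pathogenic = 15,
                  pathogenic_enriched_modules = c(1, 2),
                  pathogenic_module_fraction = 0.75, n_cnvs = 8,
                  genes_per_chrom = 30, seed = seed, ...)
}

test_that("configuration validation rejects infeasible scenarios", {
  expect_error(scenario_config(p_within = 0.2, p_between = 0.5), "p_between")
  expect_error(scenario_config(n_genes = 40, n_modules = 8,
                               module_size_range = c(10, 14)), "fit")
  expect_error(scenario_config(pathogenic_module_fraction = 1.5), "\\[0, 1\\]")
  expect_error(scenario_config(aa_skew = 0.4), "exceed 0.5")
  expect_error(scenario_config(pathogenic_enriched_modules = 99),
               "out of range")
})

test_that("network generation is a pure function of the seed", {
  cfg <- small_config(seed = 7)
  g1 <- generate_network(cfg)
  g2 <- generate_network(cfg)
  expect_identical(igraph::as_edgelist(g1$network),
                   igraph::as_edgelist(g2$network))
  expect_identical(g1$truth$modules, g2$truth$modules)
  g3 <- generate_network(small_config(seed = 8))
  expect_false(identical(igraph::as_edgelist(g1$network),
                         igraph::as_edgelist(g3$network)))
})

test_that("extreme edge probabilities produce clean planted components", {
  cfg <- scenario_config(n_genes = 20, n_modules = 2,
                         module_size_range = c(5, 5), p_within = 1,
                         p_between = 0, n_pathogenic = 4,
                         pathogenic_enriched_modules = 1,
                         pathogenic_module_fraction = 0.6,
                         n_cnvs = 2, genes_per_chrom = 20, seed = 3)
  net <- generate_network(cfg)$network
  comp <- igraph::components(net)
  sizes <- sort(comp$csize, decreasing = TRUE)
  expect_equal(sizes[1:2], c(5, 5)) # two K5 components
  expect_true(all(sizes[-(1:2)] == 1)) # isolated background genes
  expect_equal(igraph::gsize(net), 2 * choose(5, 2))
})

test_that("within-module density exceeds background density across seeds", {
  dens <- vapply(1:20, function(s) {
    cfg <- small_config(seed = s)
    out <- generate_network(cfg)
    a <- igraph::as_adjacency_matrix(out$network, sparse = FALSE)
    mem <- out$truth$modules[rownames(a)]
    same <- outer(mem, mem, "==") & outer(mem, mem, function(x, y) x > 0)
    diag(same) <- FALSE
    c(within = mean(a[same]), between = mean(a[!same & upper.tri(a) |
                                                 !same & lower.tri(a)]))
  }, numeric(2))
  expect_true(mean(dens["within", ]) > mean(dens["between", ]))
})

test_that("the synthetic genome tiles sorted non-overlapping genes", {
  cfg <- small_config(seed = 5)
  genes <- igraph::V(generate_network(cfg)$network)$name
  genome <- generate_genome(cfg, genes)
  expect_equal(nrow(genome), length(genes))
  expect_true(all(genome$start >= 1))
  expect_true(all(genome$end >= genome$start))
  for (chr in unique(genome$chrom)) {
    blk <- genome[genome$chrom == chr, ]
    expect_true(all(diff(blk$start) > 0))
    expect_true(all(blk$start[-1] > blk$end[-nrow(blk)]))
  }
  expect_identical(genome, generate_genome(cfg, genes))
  expect_equal(length(unique(genome$chrom)), ceiling(120 / 30))
})

test_that("variants plant the advertised population structure", {
  cfg <- small_config(seed = 11)
  net <- generate_network(cfg)
  genome <- generate_genome(cfg, igraph::V(net$network)$name)
  out <- generate_variants(cfg, genome, net$truth)
  truth <- out$truth

  expect_equal(length(truth$pathogenic), cfg$n_pathogenic)
  # every pathogenic gene carries at least one SNP inside its span
  hit <- pathogenic_genes_from_snps(out$snp, genome)
  expect_setequal(hit, truth$pathogenic)

  # targeted AA CNV: exact skew and full containment of its target gene
  parts <- repartition_cnvs(out$cnv)
  aa_frac <- parts$cnv_aa$count_AA /
    (parts$cnv_aa$count_AA + parts$cnv_aa$count_CA)
  expect_true(all(aa_frac > 0.5))
  expect_equal(out$cnv$count_AA[1] /
                 (out$cnv$count_AA[1] + out$cnv$count_CA[1]), cfg$aa_skew)
  contained <- map_intervals_to_genes(out$cnv[1, ], genome, "containment")
  disp_genes <- names(truth$modules)[truth$modules == truth$disparity_module]
  expect_true(any(contained %in% disp_genes))

  # disparity module pathogenic fraction beats the global rate
  frac_disp <- mean(disp_genes %in% truth$pathogenic)
  expect_gt(frac_disp, length(truth$pathogenic) / length(truth$modules))
  # and it contains at least one AA CNV gene
  expect_true(any(truth$cnv_aa_genes %in% disp_genes))
})

test_that("scenario bundles are byte-identical per seed and round-trip", {
  cfg <- small_config(seed = 2)
  d1 <- tempfile(); d2 <- tempfile()
  out1 <- generate_scenario(cfg, d1)
  out2 <- generate_scenario(cfg, d2)
  expect_length(out1$paths, 6)
  for (nm in names(out1$paths)) {
    expect_identical(readLines(out1$paths[[nm]]),
                     readLines(out2$paths[[nm]]))
  }
  # round trip through the readers reproduces the in-memory objects
  net <- suppressWarnings(read_network(out1$paths[["network"]]))
  genome <- read_gene_annotation(out1$paths[["genes"]])
  var <- read_variant_tables(out1$paths[["cnvs"]], out1$paths[["snps"]])
  expect_equal(sort(igraph::V(net)$name),
               sort(names(out1$truth$modules)))
  expect_setequal(pathogenic_genes_from_snps(var$snp, genome),
                  out1$truth$pathogenic)
  truth_df <- read.delim(out1$paths[["truth"]], stringsAsFactors = FALSE)
  expect_equal(truth_df$gene[truth_df$pathogenic == 1],
               out1$truth$pathogenic)
})
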