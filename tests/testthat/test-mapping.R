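test_that("the majority-occurrence rule repartitions CNVs", {
  cnvs <- data.frame(
    name = sprintf("cnv_%04d", 1:4), chrom = "1",
    start = c(1, 100, 200, 300), end = c(50, 150, 250, 350),
    kind = "cnv", type = "duplication",
    count_AA = c(5, 3, 1, 2), count_CA = c(0, 1, 3, 2),
    stringsAsFactors = FALSE
  )
  parts <- repartition_cnvs(cnvs)
  expect_equal(parts$cnv_aa$name, c("cnv_0001", "cnv_0002"))
  expect_equal(parts$cnv_ca$name, "cnv_0003")
  expect_equal(parts$excluded$name, "cnv_0004")
  # the three sets partition the input
  expect_setequal(c(parts$cnv_aa$name, parts$cnv_ca$name,
                    parts$excluded$name), cnvs$name)
  expect_equal(nrow(parts$cnv_aa) + nrow(parts$cnv_ca) +
                 nrow(parts$excluded), nrow(cnvs))

  zero <- cnvs[1, ]; zero$count_AA <- 0; zero$count_CA <- 0
  expect_error(repartition_cnvs(zero), "> 0")
})

test_that("repartition always partitions random CNV tables", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    cnvs <- data.frame(name = sprintf("c%02d", 1:n), chrom = "1",
                       start = 1:n, end = 1:n + 10, kind = "cnv",
                       type = "duplication",
                       count_AA = sample(0:5, n, replace = TRUE),
                       count_CA = sample(0:5, n, replace = TRUE),
                       stringsAsFactors = FALSE)
    cnvs <- cnvs[cnvs$count_AA + cnvs$count_CA > 0, , drop = FALSE]
    if (nrow(cnvs) == 0) next
    parts <- repartition_cnvs(cnvs)
    got <- sort(c(parts$cnv_aa$name, parts$cnv_ca$name, parts$excluded$name))
    expect_equal(got, sort(cnvs$name))
  }
})

test_that("duplication exemplars contain their genes in both modes", {
  fx <- dup_fixture()
  for (mode in c("overlap", "containment")) {
    for (i in 1:3) { # the three chr7 regions each contain HSPB1
      expect_equal(map_intervals_to_genes(fx$cnvs[i, ], fx$genes, mode),
                   "HSPB1")
    }
    expect_equal(map_intervals_to_genes(fx$cnvs[4, ], fx$genes, mode),
                 "ATP2A1")
  }
  # chromosome mismatch yields nothing
  shifted <- fx$genes
  shifted$chrom <- c("16", "7")
  expect_length(map_intervals_to_genes(fx$cnvs[1, ], shifted, "overlap"), 0)
})

test_that("overlap needs one shared base; containment the whole gene", {
  genes <- data.frame(name = "G", chrom = "1", start = 100, end = 200,
                      kind = "gene", stringsAsFactors = FALSE)
  touch <- data.frame(name = "iv", chrom = "1", start = 200, end = 300,
                      kind = "cnv", stringsAsFactors = FALSE)
  expect_equal(map_intervals_to_genes(touch, genes, "overlap"), "G")
  expect_length(map_intervals_to_genes(touch, genes, "containment"), 0)
  past <- touch; past$start <- 201
  expect_length(map_intervals_to_genes(past, genes, "overlap"), 0)
})

test_that("interval mapping matches a brute-force per-base scan", {
  set.seed(13)
  for (i in 1:1000) {
    gs <- sample(1:400, 1); ge <- gs + sample(0:60, 1)
    is <- sample(1:400, 1); ie <- is + sample(0:120, 1)
    genes <- data.frame(name = "G", chrom = "1", start = gs, end = ge,
                        kind = "gene", stringsAsFactors = FALSE)
    iv <- data.frame(name = "iv", chrom = "1", start = is, end = ie,
                     kind = "cnv", stringsAsFactors = FALSE)
    for (mode in c("overlap", "containment")) {
      got <- length(map_intervals_to_genes(iv, genes, mode)) == 1
      want <- interval_scan_oracle(gs, ge, is, ie, mode)
      expect_identical(got, want)
    }
    # containment result is always a subset of the overlap result
    expect_true(all(map_intervals_to_genes(iv, genes, "containment") %in%
                      map_intervals_to_genes(iv, genes, "overlap")))
  }
})

test_that("SNP positions identify pathogenic genes inclusively", {
  genes <- dup_fixture()$genes
  expect_equal(pathogenic_genes_from_snps(snp_features("7", 75932000), genes),
               "HSPB1")
  # boundary bases count, one past the end does not
  expect_equal(pathogenic_genes_from_snps(snp_features("7", 75933614), genes),
               "HSPB1")
  expect_length(pathogenic_genes_from_snps(snp_features("7", 75933615), genes),
                0)
  # two SNPs in one gene report it once
  expect_equal(pathogenic_genes_from_snps(
    snp_features("7", c(75932000, 75932001)), genes), "HSPB1")
  bad <- data.frame(name = "x", chrom = "7", start = 1, end = 2,
                    kind = "snp", stringsAsFactors = FALSE)
  expect_error(pathogenic_genes_from_snps(bad, genes), "point")
})

test_that("derive_gene_sets assembles the three enrichment gene sets", {
  fx <- dup_fixture()
  sets <- derive_gene_sets(fx$genes, fx$cnvs, snp_features("7", 75932000))
  expect_equal(sets$pathogenic, "HSPB1")
  expect_equal(sets$cnv_aa_genes, "HSPB1")
  expect_equal(sets$cnv_ca_genes, "ATP2A1")
})
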