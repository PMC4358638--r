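# Small in-code fixtures shared across test files.

graph_from_pairs <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

# Published duplication exemplars: two genes and the four CNV regions that
# contain them (1-based inclusive hg coordinates).
dup_fixture <- function() {
  genes <- data.frame(
    name = c("HSPB1", "ATP2A1"),
    chrom = c("7", "16"),
    start = c(75931861, 28889726),
    end = c(75933614, 28915830),
    kind = "gene", stringsAsFactors = FALSE
  )
  cnvs <- data.frame(
    name = sprintf("cnv_%04d", 1:4),
    chrom = c("7", "7", "7", "16"),
    start = c(75867431, 75929740, 75929740, 28306730),
    end = c(76481102, 76481102, 76568388, 28936772),
    kind = "cnv",
    type = "duplication",
    count_AA = c(5, 4, 3, 0),
    count_CA = c(0, 0, 1, 5),
    stringsAsFactors = FALSE
  )
  list(genes = genes, cnvs = cnvs)
}

snp_features <- function(chrom, pos, id = sprintf("rs%03d", seq_along(pos))) {
  data.frame(name = id, chrom = chrom, start = pos, end = pos,
             kind = "snp", stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# annotation_map built directly from a named list of gene vectors
make_annotations <- function(sets) {
  structure(list(sets = sets,
                 labels = stats::setNames(names(sets), names(sets))),
            class = "annotation_map")
}

# planted-partition adjacency matrix with named nodes (test-local sampler,
# independent of the package's generator)
random_planted_adj <- function(n, modules, p_in, p_out) {
  membership <- rep(0L, n)
  idx <- 1L
  for (m in seq_along(modules)) {
    membership[idx:(idx + modules[m] - 1L)] <- m
    idx <- idx + modules[m]
  }
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (membership[i] == membership[j] && membership[i] > 0)
        p_in else p_out
      if (runif(1) < p) a[i, j] <- a[j, i] <- 1
    }
  }
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  a
}
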