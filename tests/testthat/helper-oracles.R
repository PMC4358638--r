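# Independent oracles used to cross-check the package's statistics and
# clustering. They share no code with the implementation paths they check.

# Upper-tail hypergeometric probability by direct enumeration over the
# support, from binomial coefficients only.
hyper_tail_oracle <- function(q, big_q, m, n_all) {
  ks <- max(0, m + big_q - n_all):min(m, big_q)
  probs <- choose(big_q, ks) * choose(n_all - big_q, m - ks) /
    choose(n_all, m)
  sum(probs[ks >= q])
}

# Brute-force per-base interval scan: does any query interval share a base
# with the gene (overlap), or contain every base of the gene (containment)?
# Only usable on small coordinate spaces.
interval_scan_oracle <- function(gene_start, gene_end, iv_start, iv_end,
                                 mode) {
  gene_bases <- gene_start:gene_end
  covered <- rep(FALSE, length(gene_bases))
  for (i in seq_along(iv_start)) {
    hit <- gene_bases >= iv_start[i] & gene_bases <= iv_end[i]
    if (mode == "overlap" && any(hit)) return(TRUE)
    covered <- covered | hit
    if (mode == "containment" && all(gene_bases >= iv_start[i] &
                                     gene_bases <= iv_end[i])) return(TRUE)
  }
  FALSE
}

# Minimal reference MCL: plain dense loops, clusters read as connected
# components of the symmetrised support of the converged matrix (a
# different extraction route than the package's attractor systems).
reference_mcl <- function(adj, inflation, self_loop = 1, prune = 1e-5,
                          tol = 1e-6, max_iter = 200) {
  a <- adj
  diag(a) <- diag(a) + self_loop
  m <- sweep(a, 2, colSums(a), "/")
  for (i in seq_len(max_iter)) {
    prev <- m
    m <- m %*% m
    m <- m^inflation
    m <- sweep(m, 2, colSums(m), "/")
    cmax <- apply(m, 2, max)
    m[m < prune & m < rep(cmax, each = nrow(m))] <- 0
    m <- sweep(m, 2, colSums(m), "/")
    if (max(abs(m - prev)) < tol) break
  }
  sup <- (m > 1e-8) | t(m > 1e-8)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(sup, mode = "undirected",
                                        diag = FALSE))$membership
  unname(split(rownames(adj), comp))
}

# canonical form of a partition: sorted clusters sorted by first member
canonical_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[[`, character(1), 1L))]
}

same_partition <- function(a, b) {
  identical(canonical_partition(a), canonical_partition(b))
}
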