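# Per-cluster enrichment scoring: 2x2 contingency tables, right-tailed
# Fisher's exact tests (upper-tail hypergeometric), robust pi0-based FDR,
# and joint FDR-product ranking under strict p/FDR gates.

#' Build the 2x2 contingency table for one cluster and one gene set
#'
#' With `N` genes in the network, `m` in the cluster, `Q` target genes in
#' the network and `q` of them in the cluster, returns the table
#' `(q, m - q; Q - q, N - Q - m + q)`. Target genes outside the universe
#' are ignored.
#'
#' @param cluster Character vector of cluster member genes.
#' @param target_set Character vector of target genes (pathogenic or CNV).
#' @param universe Character vector of all genes in the clustered network.
#' @return A 2x2 integer matrix with dimnames
#'   `in_cluster`/`out_cluster` x `in_target`/`out_target`.
#' @export
build_contingency <- function(cluster, target_set, universe) {
  if (!all(cluster %in% universe)) {
    stop("cluster contains genes outside the universe", call. = FALSE)
  }
  target <- intersect(target_set, universe)
  n_all <- length(unique(universe))
  m <- length(unique(cluster))
  big_q <- length(target)
  q <- length(intersect(cluster, target))
  tab <- matrix(c(q, big_q - q, m - q, n_all - big_q - m + q),
                nrow = 2, byrow = FALSE)
  dimnames(tab) <- list(c("in_cluster", "out_cluster"),
                        c("in_target", "out_target"))
  tab
}

#' Right-tailed Fisher's exact test
#'
#' Exact upper-tail probability `P(X >= q)` of the hypergeometric
#' distribution with the table's margins fixed, where `q` is the top-left
#' cell. Equivalent to `fisher.test(tab, alternative = "greater")$p.value`
#' but computed directly from the hypergeometric tail.
#'
#' @param tab 2x2 matrix of non-negative integer counts laid out as
#'   [build_contingency()] returns.
#' @return The exact right-tail p-value.
#' @export
fisher_right_tail <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != floor(tab))) {
    stop("need a 2x2 table of non-negative integers", call. = FALSE)
  }
  q <- tab[1, 1]
  m <- tab[1, 1] + tab[2, 1]
  big_q <- tab[1, 1] + tab[1, 2]
  n_all <- sum(tab)
  phyper(q - 1, big_q, n_all - big_q, m, lower.tail = FALSE)
}

#' Robust false discovery rate with a pi0 estimate
#'
#' Estimates the null proportion as `pi0 = min(1, 2 * mean(p))` and converts
#' each p-value to an FDR: the i-th smallest p gets the raw value
#' `pi0 * p_(i) * m / i` (`m` = number of tests), monotonised by a running
#' minimum from the largest p downwards, clamped to `[0, 1]`. Tied p-values
#' share one FDR value (the smallest among the tie).
#'
#' @param pvalues Non-empty numeric vector of p-values in `[0, 1]`.
#' @param pi0_estimator Optional function mapping the p-value vector to a
#'   pi0 estimate in `[0, 1]`; the default is the doubled-mean estimator.
#' @return A list with `pi0` and `fdr` (same order as the input).
#' @export
robust_fdr <- function(pvalues, pi0_estimator = NULL) {
  if (length(pvalues) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(pi0_estimator)) {
    pi0 <- min(1, 2 * mean(pvalues))
  } else {
    pi0 <- pi0_estimator(pvalues)
    stopifnot(is.numeric(pi0), length(pi0) == 1, pi0 >= 0, pi0 <= 1)
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  p_sorted <- pvalues[ord]
  raw <- pi0 * p_sorted * m / seq_len(m)
  fdr_sorted <- rev(cummin(rev(raw)))
  fdr_sorted <- pmin(1, pmax(0, fdr_sorted))
  # ties share the smallest FDR within the tie group
  for (p in unique(p_sorted[duplicated(p_sorted)])) {
    idx <- which(p_sorted == p)
    fdr_sorted[idx] <- min(fdr_sorted[idx])
  }
  fdr <- numeric(m)
  fdr[ord] <- fdr_sorted
  list(pi0 = pi0, fdr = fdr)
}

#' Score every cluster of one run for pathogenic and CNV-gene enrichment
#'
#' For each cluster of `clustering` and each population, builds the two
#' contingency tables against the network node set, computes right-tailed
#' Fisher p-values, and converts them to robust FDRs per test family within
#' the run (one p-value list across all clusters for the pathogenic test and
#' one per population for the CNV test). The joint score is the product
#' `fdr_path * fdr_cnv`; `passes_gates` applies the strict gates
#' `p < p_gate` and `FDR < fdr_gate` to both tests.
#'
#' @param clustering A `clustering` object from [mcl_cluster()].
#' @param gene_sets A `gene_sets` list (see [derive_gene_sets()]).
#' @param universe Character vector of network genes; defaults to the union
#'   of the clustering's clusters.
#' @param p_gate,fdr_gate Strict upper gates on p-values and FDRs.
#' @return A data frame with one row per cluster and population: `run`,
#'   `population`, `cluster_id`, `m`, `q`, `s`, `p_path`, `p_cnv`,
#'   `fdr_path`, `fdr_cnv`, `joint_score`, `passes_gates`, `anchor_gene`
#'   (lexicographically smallest member).
#' @export
score_clusters <- function(clustering, gene_sets, universe = NULL,
                           p_gate = 0.10, fdr_gate = 0.20) {
  stopifnot(inherits(clustering, "clustering"))
  clusters <- clustering$clusters
  if (is.null(universe)) {
    universe <- sort(unique(unlist(clusters, use.names = FALSE)))
  }
  n_cl <- length(clusters)
  if (n_cl == 0) return(empty_scores())
  pathogenic <- intersect(gene_sets$pathogenic, universe)
  m_sizes <- lengths(clusters)
  q_counts <- vapply(clusters, function(cl)
    length(intersect(cl, pathogenic)), integer(1))
  p_path <- vapply(seq_len(n_cl), function(i) {
    fisher_right_tail(build_contingency(clusters[[i]], pathogenic, universe))
  }, numeric(1))
  fdr_path <- robust_fdr(p_path)$fdr
  anchor <- vapply(clusters, function(cl) min(cl), character(1))
  out <- lapply(c(AA = "cnv_aa_genes", CA = "cnv_ca_genes"), function(field) {
    cnv_genes <- intersect(gene_sets[[field]], universe)
    s_counts <- vapply(clusters, function(cl)
      length(intersect(cl, cnv_genes)), integer(1))
    p_cnv <- vapply(seq_len(n_cl), function(i) {
      fisher_right_tail(build_contingency(clusters[[i]], cnv_genes, universe))
    }, numeric(1))
    fdr_cnv <- robust_fdr(p_cnv)$fdr
    data.frame(
      run = clustering$label,
      population = NA_character_,
      cluster_id = sprintf("C%03d", seq_len(n_cl)),
      m = m_sizes,
      q = q_counts,
      s = s_counts,
      p_path = p_path,
      p_cnv = p_cnv,
      fdr_path = fdr_path,
      fdr_cnv = fdr_cnv,
      joint_score = fdr_path * fdr_cnv,
      anchor_gene = anchor,
      stringsAsFactors = FALSE
    )
  })
  out$AA$population <- "AA"
  out$CA$population <- "CA"
  res <- rbind(out$AA, out$CA)
  res$passes_gates <- res$p_path < p_gate & res$p_cnv < p_gate &
    res$fdr_path < fdr_gate & res$fdr_cnv < fdr_gate
  rownames(res) <- NULL
  res
}

empty_scores <- function() {
  data.frame(run = character(), population = character(),
             cluster_id = character(), m = integer(), q = integer(),
             s = integer(), p_path = numeric(), p_cnv = numeric(),
             fdr_path = numeric(), fdr_cnv = numeric(),
             joint_score = numeric(), anchor_gene = character(),
             passes_gates = logical(), stringsAsFactors = FALSE)
}

#' Rank gate-passing clusters by the product of their FDRs
#'
#' Retains, within one run and population, the clusters satisfying all four
#' strict gates (`p_path < p_gate`, `p_cnv < p_gate`, `fdr_path < fdr_gate`,
#' `fdr_cnv < fdr_gate`) and orders them by ascending
#' `joint_score = fdr_path * fdr_cnv`. Ties break by ascending
#' `p_path * p_cnv`, then descending cluster size `m`, then the smallest
#' member symbol.
#'
#' @param scores Data frame from [score_clusters()], already restricted to
#'   one run; rows of other populations are filtered out via `population`.
#' @param population `"AA"` or `"CA"`.
#' @param p_gate,fdr_gate Strict gates (defaults 0.10 and 0.20).
#' @return The retained rows with a `rank` column, ordered by rank
#'   (possibly zero rows).
#' @export
rank_clusters <- function(scores, population = c("AA", "CA"),
                          p_gate = 0.10, fdr_gate = 0.20) {
  population <- match.arg(population)
  s <- scores[scores$population == population, , drop = FALSE]
  keep <- s$p_path < p_gate & s$p_cnv < p_gate &
    s$fdr_path < fdr_gate & s$fdr_cnv < fdr_gate
  s <- s[keep, , drop = FALSE]
  if (nrow(s) > 0) {
    s <- s[order(s$joint_score, s$p_path * s$p_cnv, -s$m, s$anchor_gene), ,
           drop = FALSE]
    s$rank <- seq_len(nrow(s))
  } else {
    s$rank <- integer(0)
  }
  rownames(s) <- NULL
  s
}
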