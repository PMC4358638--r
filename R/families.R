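# Cross-resolution consistency: clusters from different inflation runs are
# linked when their gene sets are similar (Jaccard index >= threshold) and
# families are the connected components of the link graph (single linkage).
# First-place tallies over the per-run ranked lists measure how consistently
# a family tops the ranking.

#' Group similar clusters across inflation runs into families
#'
#' Builds links between clusters of *different* runs whose gene-set Jaccard
#' index is at least `jaccard_threshold`, then takes connected components of
#' the link graph (single linkage). Every cluster belongs to exactly one
#' family; clusters without any link form singleton families.
#'
#' @param clusterings List of `clustering` objects (one per inflation run).
#' @param jaccard_threshold Similarity threshold in `(0, 1]`; default 0.5.
#' @return A list of class `cluster_families` with:
#'   `members` — data frame (`family_id`, `run`, `cluster_id`, `size`);
#'   `representative` — named list of gene-set unions per family;
#'   `runs_present` — named integer vector of distinct runs per family.
#' @export
match_cluster_families <- function(clusterings, jaccard_threshold = 0.5) {
  if (!(jaccard_threshold > 0 && jaccard_threshold <= 1)) {
    stop("jaccard_threshold must be in (0, 1]", call. = FALSE)
  }
  entries <- do.call(rbind, lapply(clusterings, function(cl) {
    if (length(cl$clusters) == 0) return(NULL)
    data.frame(run = cl$label,
               cluster_id = sprintf("C%03d", seq_along(cl$clusters)),
               size = lengths(cl$clusters),
               stringsAsFactors = FALSE)
  }))
  genes_by_entry <- unlist(lapply(clusterings, function(cl) cl$clusters),
                           recursive = FALSE)
  n_entry <- if (is.null(entries)) 0L else nrow(entries)
  if (n_entry == 0) {
    return(structure(list(
      members = data.frame(family_id = character(), run = character(),
                           cluster_id = character(), size = integer(),
                           stringsAsFactors = FALSE),
      representative = list(), runs_present = integer(0)
    ), class = "cluster_families"))
  }
  # candidate pairs via an inverted gene -> cluster index; only clusters
  # sharing at least one gene can have positive Jaccard
  gene_idx <- data.frame(
    gene = unlist(genes_by_entry, use.names = FALSE),
    entry = rep.int(seq_len(n_entry), lengths(genes_by_entry)),
    stringsAsFactors = FALSE
  )
  by_gene <- split(gene_idx$entry, gene_idx$gene)
  pairs <- unique(do.call(rbind, lapply(by_gene, function(e) {
    e <- sort(unique(e))
    if (length(e) < 2) return(NULL)
    t(utils::combn(e, 2))
  })))
  edges <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    same_run <- entries$run[pairs[, 1]] == entries$run[pairs[, 2]]
    pairs <- pairs[!same_run, , drop = FALSE]
    if (nrow(pairs) > 0) {
      inter <- mapply(function(a, b) {
        length(intersect(genes_by_entry[[a]], genes_by_entry[[b]]))
      }, pairs[, 1], pairs[, 2])
      uni <- entries$size[pairs[, 1]] + entries$size[pairs[, 2]] - inter
      jac <- inter / uni
      edges <- pairs[jac >= jaccard_threshold, , drop = FALSE]
    }
  }
  g <- igraph::make_empty_graph(n = n_entry, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership
  rep_sets <- lapply(split(seq_len(n_entry), comp), function(idx) {
    sort(unique(unlist(genes_by_entry[idx], use.names = FALSE)))
  })
  # deterministic family ids: order by representative smallest symbol
  first_gene <- vapply(rep_sets, `[[`, character(1), 1L)
  fam_order <- order(first_gene, as.integer(names(rep_sets)))
  id_map <- setNames(sprintf("F%03d", seq_along(fam_order)),
                     names(rep_sets)[fam_order])
  family_id <- unname(id_map[as.character(comp)])
  members <- cbind(data.frame(family_id = family_id,
                              stringsAsFactors = FALSE), entries)
  representative <- setNames(rep_sets, id_map[names(rep_sets)])
  representative <- representative[order(names(representative))]
  runs_present <- vapply(split(members$run, members$family_id),
                         function(r) length(unique(r)), integer(1))
  structure(list(members = members, representative = representative,
                 runs_present = runs_present),
            class = "cluster_families")
}

#' Tally how often each family ranks first across inflation runs
#'
#' For each population, walks the per-run ranked lists and increments the
#' family containing the rank-1 cluster of each non-empty list. Families are
#' then ordered per population by descending tally, ties broken by larger
#' `runs_present`, then by the smallest symbol of the representative set.
#'
#' @param ranked_lists Named list with elements `AA` and `CA`, each a list
#'   of ranked data frames (one per run) as returned by [rank_clusters()].
#' @param families A `cluster_families` object.
#' @return A data frame with `population`, `rank`, `family_id`,
#'   `first_place_count`, `runs_present`, `representative_size`,
#'   `representative_genes` (comma-separated); one block per population,
#'   ordered by the documented tie-break.
#' @export
count_first_place <- function(ranked_lists, families) {
  stopifnot(inherits(families, "cluster_families"))
  members <- families$members
  key <- paste(members$run, members$cluster_id, sep = "\r")
  fam_of <- setNames(members$family_id, key)
  fams <- names(families$representative)
  out <- lapply(names(ranked_lists), function(pop) {
    tally <- setNames(integer(length(fams)), fams)
    for (rl in ranked_lists[[pop]]) {
      if (is.null(rl) || nrow(rl) == 0) next
      top <- rl[rl$rank == 1, , drop = FALSE]
      k <- paste(top$run[1], top$cluster_id[1], sep = "\r")
      fid <- unname(fam_of[k])
      if (length(fid) != 1 || is.na(fid)) {
        stop("rank-1 cluster ", top$cluster_id[1], " of run ", top$run[1],
             " matches no family", call. = FALSE)
      }
      tally[fid] <- tally[fid] + 1L
    }
    smallest <- vapply(families$representative, `[[`, character(1), 1L)
    ord <- order(-tally, -families$runs_present[fams], smallest[fams])
    data.frame(
      population = pop,
      rank = seq_along(fams),
      family_id = fams[ord],
      first_place_count = unname(tally[ord]),
      runs_present = unname(families$runs_present[fams][ord]),
      representative_size = unname(lengths(families$representative)[ord]),
      representative_genes = vapply(families$representative[ord],
                                    paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
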