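# Target-vs-background functional-term enrichment: for each term the
# upper-tail hypergeometric probability of seeing at least k annotated
# genes among the n target genes, with the network node set as background.

#' Hypergeometric term enrichment of a target gene set
#'
#' For every term in `annotations`, computes `p = P(X >= k)` under the
#' hypergeometric distribution with population `B = |background|`, `b`
#' annotated background genes, and `n = |target|` draws, where `k` is the
#' number of annotated target genes. Genes without annotation never count
#' towards `b` or `k`. A Benjamini-Hochberg `q` is reported alongside, but
#' the `reported` flag follows the raw-p threshold (`p <= p_threshold`).
#'
#' @param target Character vector of target genes; must be a subset of
#'   `background`.
#' @param background Character vector of background genes (typically the
#'   network node set).
#' @param annotations An `annotation_map` (see [read_term_annotations()]).
#' @param p_threshold Raw-p reporting threshold in `(0, 1]`; default `1e-3`.
#' @return Data frame sorted by ascending `p` (ties by `term_id`):
#'   `term_id`, `label`, `b`, `n`, `k`, `B`, `p`, `q`, `reported`.
#' @export
enrich_terms <- function(target, background, annotations,
                         p_threshold = 1e-3) {
  stopifnot(inherits(annotations, "annotation_map"))
  if (!(p_threshold > 0 && p_threshold <= 1)) {
    stop("p_threshold must be in (0, 1]", call. = FALSE)
  }
  target <- unique(target)
  background <- unique(background)
  if (!all(target %in% background)) {
    stop("target genes must be a subset of the background", call. = FALSE)
  }
  big_b <- length(background)
  n <- length(target)
  terms <- names(annotations$sets)
  if (length(terms) == 0) {
    return(data.frame(term_id = character(), label = character(),
                      b = integer(), n = integer(), k = integer(),
                      B = integer(), p = numeric(), q = numeric(),
                      reported = logical(), stringsAsFactors = FALSE))
  }
  b <- vapply(annotations$sets, function(g)
    length(intersect(g, background)), integer(1))
  k <- vapply(annotations$sets, function(g)
    length(intersect(g, target)), integer(1))
  p <- phyper(k - 1, b, big_b - b, n, lower.tail = FALSE)
  res <- data.frame(
    term_id = terms,
    label = unname(annotations$labels[terms]),
    b = unname(b), n = n, k = unname(k), B = big_b,
    p = unname(p),
    q = p.adjust(unname(p), method = "BH"),
    reported = unname(p) <= p_threshold,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
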