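# CNV repartition by the majority-occurrence rule and coordinate-overlap
# mapping of CNV intervals / SNP positions onto genes. All interval
# arithmetic is 1-based inclusive, delegated to GenomicRanges.

#' Repartition CNVs into population-preferred sets
#'
#' Computes, for each CNV, the fraction of its occurrences observed in
#' African Americans, `f = count_AA / (count_AA + count_CA)`. CNVs with
#' `f > 0.5` (including AA-only CNVs) form the African-American-preferred
#' set `cnv_aa`; `f < 0.5` the Caucasian-preferred set `cnv_ca`; CNVs with
#' exactly balanced occurrence (`f == 0.5`) are excluded — the rule is a
#' strict "more than 50%".
#'
#' @param cnvs CNV feature data frame (see [read_variant_tables()]).
#' @return A list of class `population_cnv_sets` with data frames `cnv_aa`,
#'   `cnv_ca` and `excluded`; the three partition the input rows.
#' @export
repartition_cnvs <- function(cnvs) {
  stopifnot(is.data.frame(cnvs),
            all(c("count_AA", "count_CA") %in% names(cnvs)))
  total <- cnvs$count_AA + cnvs$count_CA
  if (any(total <= 0)) {
    stop("CNV row ", which(total <= 0)[1],
         ": count_AA + count_CA must be > 0", call. = FALSE)
  }
  f <- cnvs$count_AA / total
  structure(list(
    cnv_aa = cnvs[f > 0.5, , drop = FALSE],
    cnv_ca = cnvs[f < 0.5, , drop = FALSE],
    excluded = cnvs[f == 0.5, , drop = FALSE]
  ), class = "population_cnv_sets")
}

features_to_granges <- function(df, seqlevels = unique(df$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}

#' Map genomic intervals to the genes they cover
#'
#' Returns the gene symbols whose annotated span intersects at least one of
#' the query intervals on the same chromosome. With `mode = "overlap"`
#' (default) sharing a single base suffices; with `mode = "containment"`
#' the gene interval must lie fully inside a query interval. Coordinates
#' are 1-based inclusive on both sides.
#'
#' @param intervals Feature data frame of query intervals (CNVs, regions).
#' @param genes Gene annotation data frame (see [read_gene_annotation()]).
#' @param mode `"overlap"` or `"containment"`.
#' @return Sorted character vector of unique gene symbols (possibly empty).
#' @export
map_intervals_to_genes <- function(intervals, genes,
                                   mode = c("overlap", "containment")) {
  mode <- match.arg(mode)
  if (nrow(intervals) == 0 || nrow(genes) == 0) return(character(0))
  chroms <- unique(c(genes$chrom, intervals$chrom))
  gr_genes <- features_to_granges(genes, chroms)
  gr_iv <- features_to_granges(intervals, chroms)
  hits <- GenomicRanges::findOverlaps(
    gr_genes, gr_iv,
    type = if (mode == "containment") "within" else "any"
  )
  sort(unique(genes$name[S4Vectors::queryHits(hits)]))
}

#' Identify pathogenic genes from disease-associated SNP positions
#'
#' A gene is pathogenic if at least one SNP position falls within its
#' 1-based inclusive span on the same chromosome.
#'
#' @param snps SNP feature data frame (point intervals).
#' @param genes Gene annotation data frame.
#' @return Sorted character vector of unique gene symbols.
#' @export
pathogenic_genes_from_snps <- function(snps, genes) {
  if (nrow(snps) > 0 && any(snps$start != snps$end)) {
    stop("SNP features must be point intervals", call. = FALSE)
  }
  map_intervals_to_genes(snps, genes, mode = "overlap")
}

#' Derive the three gene sets driving cluster enrichment
#'
#' Convenience wrapper: repartitions CNVs, maps the AA- and CA-preferred
#' CNV sets and the SNPs onto genes.
#'
#' @param genes Gene annotation data frame.
#' @param cnvs CNV feature data frame.
#' @param snps SNP feature data frame.
#' @param mode Interval mapping mode, see [map_intervals_to_genes()].
#' @return A list of class `gene_sets` with character vectors `pathogenic`,
#'   `cnv_aa_genes`, `cnv_ca_genes` (sets may intersect).
#' @export
derive_gene_sets <- function(genes, cnvs, snps,
                             mode = c("overlap", "containment")) {
  mode <- match.arg(mode)
  parts <- repartition_cnvs(cnvs)
  structure(list(
    pathogenic = pathogenic_genes_from_snps(snps, genes),
    cnv_aa_genes = map_intervals_to_genes(parts$cnv_aa, genes, mode),
    cnv_ca_genes = map_intervals_to_genes(parts$cnv_ca, genes, mode)
  ), class = "gene_sets")
}
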