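#' Read an undirected gene network from an edge list
#'
#' Parses a whitespace- or tab-separated edge list into a simple undirected
#' [igraph][igraph::igraph-package] graph over gene symbols. Lines starting
#' with `#` are ignored. Duplicate edges (including reversed duplicates)
#' collapse to a single undirected edge; self-loop lines are dropped with a
#' warning. Extra columns beyond the first two are ignored.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple `igraph` graph whose vertex names are the
#'   gene symbols seen in the file (the union of all endpoints).
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "B\tC"), f)
#' g <- read_network(f)
#' igraph::gorder(g) # 3
#' igraph::gsize(g)  # 2
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read network file: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("edge list line ", idx[which(nf < 2)[1]],
         " has fewer than 2 fields", call. = FALSE)
  }
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), 2L)
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop line(s) dropped", call. = FALSE)
  }
  nodes <- sort(unique(c(from, to)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (any(!loops)) {
    el <- cbind(from[!loops], to[!loops])
    g <- igraph::add_edges(g, t(el))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  g
}

parse_coord <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(gsub(",", "", trimws(as.character(x)))))
  bad <- is.na(v) | v != floor(v) | v < 1
  if (any(bad)) {
    stop("invalid ", what, " coordinate in ", path, " at row ",
         which(bad)[1], call. = FALSE)
  }
  as.numeric(v)
}

#' Read a gene annotation table
#'
#' Reads a tab-separated table with header columns `name`, `chrom`, `start`,
#' `end` holding 1-based inclusive gene coordinates. Comma-grouped integers
#' (e.g. `75,931,861`) are accepted and stripped.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `name`, `chrom` (character), `start`,
#'   `end` (numeric, 1-based inclusive) and `kind = "gene"`.
#' @export
read_gene_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   check.names = FALSE)
  need <- c("name", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("gene annotation needs columns name/chrom/start/end", call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    name = df$name,
    chrom = df$chrom,
    start = parse_coord(df$start, "start", path),
    end = parse_coord(df$end, "end", path),
    kind = "gene",
    stringsAsFactors = FALSE
  )
  if (any(out$end < out$start)) {
    stop("gene annotation row ", which(out$end < out$start)[1],
         ": end < start", call. = FALSE)
  }
  dup <- duplicated(out[, c("name", "chrom")])
  if (any(dup)) {
    stop("duplicate gene name on one chromosome: ",
         out$name[dup][1], call. = FALSE)
  }
  out
}

#' Read CNV and SNP tables
#'
#' The CNV table is a TSV with header `chrom`, `start`, `end`, `type`
#' (duplication/deletion, case-insensitive), `count_AA`, `count_CA` — the
#' occurrence counts in African Americans and Caucasians. The SNP table is a
#' TSV with header `id`, `chrom`, `pos`; each SNP becomes a point feature
#' with `start == end == pos`.
#'
#' @param cnv_path,snp_path Paths to the two TSV files.
#' @return A list with elements `cnv` and `snp`, each a feature data frame
#'   (`name`, `chrom`, `start`, `end`, `kind`, plus `type`, `count_AA`,
#'   `count_CA` for CNVs).
#' @export
read_variant_tables <- function(cnv_path, snp_path) {
  cnv <- read.delim(cnv_path, header = TRUE, colClasses = "character",
                    check.names = FALSE)
  need <- c("chrom", "start", "end", "type", "count_AA", "count_CA")
  if (!all(need %in% names(cnv))) {
    stop("CNV table needs columns chrom/start/end/type/count_AA/count_CA",
         call. = FALSE)
  }
  type <- tolower(trimws(cnv$type))
  bad <- !type %in% c("duplication", "deletion")
  if (nrow(cnv) > 0 && any(bad)) {
    stop("CNV row ", which(bad)[1], ": type must be duplication or deletion, got '",
         cnv$type[bad][1], "'", call. = FALSE)
  }
  counts_aa <- suppressWarnings(as.numeric(cnv$count_AA))
  counts_ca <- suppressWarnings(as.numeric(cnv$count_CA))
  if (nrow(cnv) > 0 &&
      (anyNA(counts_aa) || anyNA(counts_ca) ||
       any(counts_aa < 0) || any(counts_ca < 0))) {
    stop("CNV occurrence counts must be non-negative numbers", call. = FALSE)
  }
  cnv_out <- data.frame(
    name = if (nrow(cnv) > 0) sprintf("cnv_%04d", seq_len(nrow(cnv))) else character(),
    chrom = cnv$chrom,
    start = if (nrow(cnv) > 0) parse_coord(cnv$start, "start", cnv_path) else numeric(),
    end = if (nrow(cnv) > 0) parse_coord(cnv$end, "end", cnv_path) else numeric(),
    kind = rep("cnv", nrow(cnv)),
    type = type,
    count_AA = counts_aa,
    count_CA = counts_ca,
    stringsAsFactors = FALSE
  )
  snp <- read.delim(snp_path, header = TRUE, colClasses = "character",
                    check.names = FALSE)
  if (!all(c("id", "chrom", "pos") %in% names(snp))) {
    stop("SNP table needs columns id/chrom/pos", call. = FALSE)
  }
  pos <- if (nrow(snp) > 0) parse_coord(snp$pos, "pos", snp_path) else numeric()
  snp_out <- data.frame(
    name = snp$id,
    chrom = snp$chrom,
    start = pos,
    end = pos,
    kind = rep("snp", nrow(snp)),
    stringsAsFactors = FALSE
  )
  list(cnv = cnv_out, snp = snp_out)
}

#' Read a flat term annotation table
#'
#' Two- or three-column TSV with header `term_id`, `gene` and optionally
#' `label`. Annotations are taken as given (no ontology propagation).
#'
#' @param path Path to the TSV file.
#' @return A list of class `annotation_map` with `sets` (named list of gene
#'   character vectors, one per term) and `labels` (named character vector).
#' @export
read_term_annotations <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   check.names = FALSE)
  if (!all(c("term_id", "gene") %in% names(df))) {
    stop("term annotation needs columns term_id/gene", call. = FALSE)
  }
  sets <- lapply(split(df$gene, df$term_id), function(g) sort(unique(g)))
  labels <- if ("label" %in% names(df)) {
    vapply(split(df$label, df$term_id), `[[`, character(1), 1L)
  } else {
    setNames(names(sets), names(sets))
  }
  structure(list(sets = sets, labels = labels[names(sets)]),
            class = "annotation_map")
}

# Documented deterministic sort keys per result table.
result_sort_keys <- list(
  clusters = c("run", "cluster_id", "gene"),
  cluster_scores = c("run", "population", "cluster_id"),
  ranked_AA = c("run", "rank"),
  ranked_CA = c("run", "rank"),
  families = c("population", "rank"),
  term_enrichment = c("population", "p", "term_id")
)

#' Write pipeline result tables as TSV files
#'
#' Writes each table in `tables` as `<name>.tsv` under `out_dir` with a
#' header row and a deterministic row order (each table is sorted on its
#' documented key columns; tables with unknown names are sorted on all
#' columns left to right). Writing the same tables twice yields
#' byte-identical files.
#'
#' @param tables Named list of data frames. Recognised names: `clusters`,
#'   `cluster_scores`, `ranked_AA`, `ranked_CA`, `families`,
#'   `term_enrichment`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the character vector of written file paths.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    keys <- result_sort_keys[[nm]]
    if (is.null(keys)) keys <- names(df)
    keys <- intersect(keys, names(df))
    if (nrow(df) > 0 && length(keys) > 0) {
      df <- df[do.call(order, df[keys]), , drop = FALSE]
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
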