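# Seeded synthetic input bundles with planted ground truth: a
# planted-partition network whose dense modules play the role of functional
# gene clusters, a synthetic genome laying the genes out on chromosomes,
# CNVs with population-skewed occurrence counts covering designated module
# genes, disease SNPs concentrated in designated modules, and per-module
# term annotations. Every quantity is a pure function of the scenario seed.

#' Build and validate a synthetic scenario configuration
#'
#' Defaults describe the reference scenario: a 400-gene network with 8
#' planted modules of 10-14 genes (`p_within = 0.6` inside modules,
#' `p_between = 0.01` background), 40 pathogenic genes of which 9 sit in
#' the 12-gene disparity module, an African-American-skewed duplication
#' covering the disparity module's central gene (and, being much longer
#' than a gene, its genomic neighbours), and a Caucasian-only duplication
#' covering module 2's central gene as the mirrored control.
#'
#' @param n_genes Total number of genes.
#' @param n_modules Number of planted modules.
#' @param module_size_range Length-2 integer vector, sizes drawn uniformly;
#'   modules listed in `pathogenic_enriched_modules` are pinned to the
#'   midpoint size so the planted signal is size-stable across seeds.
#' @param p_within,p_between Edge probabilities inside modules / elsewhere;
#'   requires `0 <= p_between < p_within <= 1`.
#' @param n_pathogenic Number of pathogenic genes network-wide.
#' @param pathogenic_enriched_modules Module indices receiving elevated
#'   pathogenic density; the first entry named by `cnv_target_modules["aa"]`
#'   is the designated disparity module.
#' @param pathogenic_module_fraction Fraction of each enriched module's
#'   genes made pathogenic.
#' @param n_cnvs Total number of CNVs (targeted ones included).
#' @param cnv_target_modules Named numeric vector; entry `aa` is the module
#'   whose central gene the AA-skewed CNV must cover, entry `ca` the module
#'   for the Caucasian-only CNV. Either may be `NA` to skip.
#' @param aa_skew Occurrence fraction `count_AA / (count_AA + count_CA)` of
#'   the AA-skewed CNV; must exceed 0.5 and be an exact ratio of small
#'   integer counts.
#' @param cnv_flank_bp Flank added on both sides of a targeted gene when
#'   placing its CNV; CNVs are much longer than genes, as empirical
#'   duplications are.
#' @param gene_length_bp,intergenic_gap_bp Mean synthetic gene length and
#'   intergenic gap (exponential, with small hard floors).
#' @param genes_per_chrom Genes tiled per synthetic chromosome.
#' @param seed Integer master seed; sub-stages use fixed offsets from it.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_genes = 400, n_modules = 8,
                            module_size_range = c(10, 14),
                            p_within = 0.6, p_between = 0.01,
                            n_pathogenic = 40,
                            pathogenic_enriched_modules = c(1, 2),
                            pathogenic_module_fraction = 0.75,
                            n_cnvs = 20,
                            cnv_target_modules = c(aa = 1, ca = 2),
                            aa_skew = 0.8, cnv_flank_bp = 8000,
                            gene_length_bp = 2000,
                            intergenic_gap_bp = 1000,
                            genes_per_chrom = 50, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              module_size_range = as.integer(module_size_range),
              p_within = p_within, p_between = p_between,
              n_pathogenic = as.integer(n_pathogenic),
              pathogenic_enriched_modules = as.integer(pathogenic_enriched_modules),
              pathogenic_module_fraction = pathogenic_module_fraction,
              n_cnvs = as.integer(n_cnvs),
              cnv_target_modules = cnv_target_modules,
              aa_skew = aa_skew, cnv_flank_bp = as.integer(cnv_flank_bp),
              gene_length_bp = as.integer(gene_length_bp),
              intergenic_gap_bp = as.integer(intergenic_gap_bp),
              genes_per_chrom = as.integer(genes_per_chrom),
              seed = as.integer(seed))
  if (!(cfg$p_between >= 0 && cfg$p_between < cfg$p_within &&
        cfg$p_within <= 1)) {
    stop("need 0 <= p_between < p_within <= 1", call. = FALSE)
  }
  if (length(cfg$module_size_range) != 2 ||
      cfg$module_size_range[1] > cfg$module_size_range[2] ||
      cfg$module_size_range[1] < 1) {
    stop("module_size_range must be an increasing pair of counts",
         call. = FALSE)
  }
  stride <- cfg$n_genes %/% cfg$n_modules
  if (cfg$module_size_range[2] > stride) {
    stop("modules of up to ", cfg$module_size_range[2],
         " genes do not fit ", cfg$n_genes, " genes in ",
         cfg$n_modules, " disjoint blocks", call. = FALSE)
  }
  if (!(cfg$pathogenic_module_fraction >= 0 &&
        cfg$pathogenic_module_fraction <= 1)) {
    stop("pathogenic_module_fraction must be in [0, 1]", call. = FALSE)
  }
  if (any(cfg$pathogenic_enriched_modules < 1) ||
      any(cfg$pathogenic_enriched_modules > cfg$n_modules)) {
    stop("pathogenic_enriched_modules out of range", call. = FALSE)
  }
  if (!is.na(cfg$aa_skew) && cfg$aa_skew <= 0.5) {
    stop("aa_skew must exceed 0.5", call. = FALSE)
  }
  if (is.null(skew_counts(cfg$aa_skew))) {
    stop("aa_skew must be an exact ratio with total count <= 20",
         call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

# smallest integer count pair (count_AA, count_CA), total <= 20, whose
# occurrence fraction equals `skew` exactly
skew_counts <- function(skew) {
  for (total in 2:20) {
    aa <- skew * total
    if (abs(aa - round(aa)) < 1e-9) {
      return(c(AA = round(aa), CA = total - round(aa)))
    }
  }
  NULL
}

gene_symbols <- function(n) sprintf("G%04d", seq_len(n))

# module membership per gene index: 0 = background, module i occupies a
# contiguous block starting at (i-1)*stride + 1
module_layout <- function(cfg, sizes) {
  stride <- cfg$n_genes %/% cfg$n_modules
  membership <- integer(cfg$n_genes)
  for (i in seq_len(cfg$n_modules)) {
    start <- (i - 1L) * stride + 1L
    membership[start:(start + sizes[i] - 1L)] <- i
  }
  membership
}

#' Generate a planted-partition gene network
#'
#' Disjoint module blocks are wired with independent edge probability
#' `p_within`; all remaining pairs with `p_between`. Pure function of
#' `config$seed`.
#'
#' @param config A `scenario_config`.
#' @return A list with `network` (named `igraph`, isolated genes kept) and
#'   `truth` (partial ground truth: `modules` named membership vector,
#'   `module_sizes`, `disparity_module`).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  rng <- config$module_size_range
  sizes <- rng[1] - 1L +
    sample.int(rng[2] - rng[1] + 1L, config$n_modules, replace = TRUE)
  pinned <- round(mean(rng))
  sizes[config$pathogenic_enriched_modules] <- pinned
  membership <- module_layout(config, sizes)
  genes <- gene_symbols(config$n_genes)
  pairs <- utils::combn(config$n_genes, 2)
  same_module <- membership[pairs[1, ]] == membership[pairs[2, ]] &
    membership[pairs[1, ]] > 0
  p <- ifelse(same_module, config$p_within, config$p_between)
  keep <- runif(ncol(pairs)) < p
  g <- igraph::make_empty_graph(n = config$n_genes, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  if (any(keep)) {
    g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
  }
  aa_target <- config$cnv_target_modules[["aa"]]
  disparity <- if (is.na(aa_target)) NA_integer_ else as.integer(aa_target)
  list(network = g,
       truth = list(modules = setNames(membership, genes),
                    module_sizes = sizes,
                    disparity_module = disparity))
}

#' Lay genes out on synthetic chromosomes
#'
#' Genes are tiled in symbol order, `genes_per_chrom` per chromosome, with
#' exponentially distributed lengths and intergenic gaps around the
#' configured means (hard floors of 200 bp and 100 bp). Intervals are
#' non-overlapping and sorted within each chromosome.
#'
#' @param config A `scenario_config`.
#' @param genes Character vector of gene symbols.
#' @return Gene feature data frame (`name`, `chrom`, `start`, `end`,
#'   `kind = "gene"`).
#' @export
generate_genome <- function(config, genes) {
  stopifnot(inherits(config, "scenario_config"), length(genes) > 0)
  set.seed(config$seed + 1L)
  n <- length(genes)
  lens <- 200L + round(rexp(n, 1 / config$gene_length_bp))
  gaps <- 100L + round(rexp(n, 1 / config$intergenic_gap_bp))
  chrom_idx <- ceiling(seq_len(n) / config$genes_per_chrom)
  start <- integer(n)
  end <- integer(n)
  pos <- 1L
  last_chrom <- 0L
  for (i in seq_len(n)) {
    if (chrom_idx[i] != last_chrom) {
      pos <- 1L
      last_chrom <- chrom_idx[i]
    }
    start[i] <- pos + gaps[i]
    end[i] <- start[i] + lens[i] - 1L
    pos <- end[i]
  }
  data.frame(name = genes, chrom = paste0("chr", chrom_idx),
             start = start, end = end, kind = "gene",
             stringsAsFactors = FALSE)
}

central_gene_of_module <- function(truth, genome, module) {
  members <- names(truth$modules)[truth$modules == module]
  members <- members[order(match(members, genome$name))]
  members[ceiling(length(members) / 2)]
}

#' Generate CNV and SNP tables with planted population structure
#'
#' Pathogenic genes are drawn so that each enriched module carries
#' `pathogenic_module_fraction` of its genes, the remainder scattered over
#' the other genes; every pathogenic gene receives 1-3 uniformly placed
#' SNPs. One AA-skewed duplication (occurrence fraction exactly `aa_skew`)
#' covers the disparity module's central gene plus `cnv_flank_bp` on each
#' side; one Caucasian-only duplication does the same for the `ca` target
#' module. Remaining CNVs are background: anchored on random module-free
#' genes with short flanks and random occurrence counts. The planted
#' enrichment is checked by bounded rejection sampling (at most 100
#' redraws); an infeasible configuration is an error, never silently
#' accepted.
#'
#' @param config A `scenario_config`.
#' @param genome Gene feature data frame from [generate_genome()].
#' @param truth Partial ground truth from [generate_network()].
#' @return A list with `cnv` and `snp` feature data frames and the
#'   completed `truth` (adds `pathogenic`, `cnv_aa_genes`, `cnv_ca_genes`).
#' @export
generate_variants <- function(config, genome, truth) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 2L)
  genes <- genome$name
  modules <- truth$modules[genes]
  enriched <- config$pathogenic_enriched_modules
  n_global <- config$n_pathogenic

  pathogenic <- NULL
  for (attempt in seq_len(100)) {
    path <- character(0)
    for (mod in enriched) {
      members <- genes[modules == mod]
      n_mod <- round(config$pathogenic_module_fraction * length(members))
      path <- c(path, sample(members, n_mod))
    }
    remaining <- n_global - length(path)
    if (remaining < 0) {
      stop("n_pathogenic smaller than the planted module load", call. = FALSE)
    }
    pool <- setdiff(genes[!modules %in% enriched], path)
    path <- c(path, sample(pool, remaining))
    disp <- truth$disparity_module
    if (is.na(disp)) break
    disp_members <- genes[modules == disp]
    frac_disp <- mean(disp_members %in% path)
    if (frac_disp > length(path) / length(genes)) break
    path <- NULL
  }
  pathogenic <- path
  if (is.null(pathogenic)) {
    stop("could not plant a disparity module with pathogenic fraction ",
         "above the global rate in 100 attempts", call. = FALSE)
  }
  pathogenic <- sort(pathogenic)

  # SNPs: 1-3 per pathogenic gene, uniform inside the gene span
  snp_rows <- lapply(pathogenic, function(g) {
    row <- genome[genome$name == g, ]
    k <- sample(1:3, 1)
    pos <- row$start + floor(runif(k) * (row$end - row$start + 1))
    data.frame(chrom = row$chrom, pos = as.integer(pos),
               stringsAsFactors = FALSE)
  })
  snp <- do.call(rbind, snp_rows)
  snp <- data.frame(name = sprintf("rs%06d", seq_len(nrow(snp))),
                    chrom = snp$chrom, start = snp$pos, end = snp$pos,
                    kind = "snp", stringsAsFactors = FALSE)

  # targeted CNVs
  cnv_rows <- list()
  add_cnv <- function(chrom, start, end, type, aa, ca) {
    cnv_rows[[length(cnv_rows) + 1]] <<- data.frame(
      chrom = chrom, start = as.integer(max(1, start)),
      end = as.integer(end), type = type,
      count_AA = aa, count_CA = ca, stringsAsFactors = FALSE)
  }
  targets <- config$cnv_target_modules
  if (!is.na(targets[["aa"]])) {
    g <- central_gene_of_module(truth, genome, targets[["aa"]])
    row <- genome[genome$name == g, ]
    counts <- skew_counts(config$aa_skew)
    add_cnv(row$chrom, row$start - config$cnv_flank_bp,
            row$end + config$cnv_flank_bp, "duplication",
            counts[["AA"]], counts[["CA"]])
  }
  if (!is.na(targets[["ca"]])) {
    g <- central_gene_of_module(truth, genome, targets[["ca"]])
    row <- genome[genome$name == g, ]
    add_cnv(row$chrom, row$start - config$cnv_flank_bp,
            row$end + config$cnv_flank_bp, "duplication", 0, 5)
  }
  # background CNVs on module-free genes, short flanks, random skew
  n_bg <- config$n_cnvs - length(cnv_rows)
  free <- genes[modules == 0]
  if (n_bg > 0 && length(free) > 0) {
    anchors <- sample(free, min(n_bg, length(free)))
    for (g in anchors) {
      row <- genome[genome$name == g, ]
      total <- sample(2:8, 1)
      aa <- sample(0:total, 1)
      add_cnv(row$chrom, row$start - 1500L, row$end + 1500L,
              sample(c("duplication", "deletion"), 1), aa, total - aa)
    }
  }
  cnv <- do.call(rbind, cnv_rows)
  cnv <- cbind(data.frame(name = sprintf("cnv_%04d", seq_len(nrow(cnv))),
                          stringsAsFactors = FALSE),
               cnv, kind = "cnv")
  cnv <- cnv[, c("name", "chrom", "start", "end", "kind", "type",
                 "count_AA", "count_CA")]

  sets <- derive_gene_sets(genome, cnv, snp, mode = "overlap")
  truth$pathogenic <- pathogenic
  truth$cnv_aa_genes <- sets$cnv_aa_genes
  truth$cnv_ca_genes <- sets$cnv_ca_genes
  list(cnv = cnv, snp = snp, truth = truth)
}

#' Generate per-module term annotations
#'
#' One term per planted module annotating its genes plus two random
#' background genes, and ten unrelated random terms of fifteen genes each.
#'
#' @param config A `scenario_config`.
#' @param truth Ground truth carrying the module membership.
#' @return Data frame with columns `term_id`, `gene`, `label`.
#' @export
generate_term_annotations <- function(config, truth) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 3L)
  genes <- names(truth$modules)
  rows <- list()
  for (mod in seq_len(config$n_modules)) {
    members <- genes[truth$modules == mod]
    extra <- sample(setdiff(genes, members), 2)
    rows[[length(rows) + 1]] <- data.frame(
      term_id = sprintf("TMOD%02d", mod),
      gene = c(members, extra),
      label = sprintf("module %d process", mod),
      stringsAsFactors = FALSE)
  }
  for (i in 1:10) {
    rows[[length(rows) + 1]] <- data.frame(
      term_id = sprintf("TRND%02d", i),
      gene = sample(genes, 15),
      label = sprintf("random process %d", i),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates the network, genome, variants and term annotations and writes
#' them in the package's input dialects (`network.tsv` edge list,
#' `genes.tsv`, `cnvs.tsv`, `snps.tsv`, `terms.tsv`) plus a plain-TSV
#' ground-truth sidecar `truth.tsv` with per-gene module membership and
#' pathogenic / CNV-gene / disparity-module flags. Re-running with the same
#' seed produces a byte-identical bundle.
#'
#' @param config A `scenario_config`.
#' @param out_dir Output directory, created if needed.
#' @return A list with `paths` (named character vector of the six files)
#'   and `truth` (the completed ground-truth list).
#' @export
generate_scenario <- function(config, out_dir) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_network(config)
  genome <- generate_genome(config, igraph::V(net$network)$name)
  var <- generate_variants(config, genome, net$truth)
  terms <- generate_term_annotations(config, var$truth)
  truth <- var$truth

  paths <- c(network = file.path(out_dir, "network.tsv"),
             genes = file.path(out_dir, "genes.tsv"),
             cnvs = file.path(out_dir, "cnvs.tsv"),
             snps = file.path(out_dir, "snps.tsv"),
             terms = file.path(out_dir, "terms.tsv"),
             truth = file.path(out_dir, "truth.tsv"))

  el <- igraph::as_edgelist(net$network)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  # isolated genes are written as self-loop lines: the reader drops the
  # loop but keeps the node, so the gene universe survives the round trip
  isolated <- igraph::V(net$network)$name[igraph::degree(net$network) == 0]
  writeLines(c("# synthetic gene network edge list",
               paste(el[, 1], el[, 2], sep = "\t"),
               paste(isolated, isolated, sep = "\t")), paths[["network"]])

  write_tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(genome[, c("name", "chrom", "start", "end")], paths[["genes"]])
  write_tsv(var$cnv[, c("chrom", "start", "end", "type",
                        "count_AA", "count_CA")], paths[["cnvs"]])
  snp_out <- data.frame(id = var$snp$name, chrom = var$snp$chrom,
                        pos = var$snp$start, stringsAsFactors = FALSE)
  write_tsv(snp_out, paths[["snps"]])
  write_tsv(terms, paths[["terms"]])

  genes <- names(truth$modules)
  truth_df <- data.frame(
    gene = genes,
    module = unname(truth$modules),
    pathogenic = as.integer(genes %in% truth$pathogenic),
    cnv_aa = as.integer(genes %in% truth$cnv_aa_genes),
    cnv_ca = as.integer(genes %in% truth$cnv_ca_genes),
    is_disparity_module = as.integer(!is.na(truth$disparity_module) &
                                       truth$modules == truth$disparity_module),
    stringsAsFactors = FALSE
  )
  write_tsv(truth_df, paths[["truth"]])
  list(paths = paths, truth = truth)
}
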