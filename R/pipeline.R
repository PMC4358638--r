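# One-command orchestration: read (or synthesize) inputs, sweep-cluster,
# map variants to genes, score and rank per run, group families, tally
# first places, and annotate the top families with term enrichment.

#' Build and validate a pipeline configuration
#'
#' Either supply paths to the five input files, or set `synthetic = TRUE`
#' to generate a seeded scenario first (its files are written under
#' `<out_dir>/inputs` and read back through the ordinary readers).
#'
#' @param network,genes,cnvs,snps,terms Input file paths (ignored in
#'   synthetic mode).
#' @param synthetic Generate inputs from `scenario` instead of reading them.
#' @param scenario A `scenario_config` for synthetic mode; defaults to
#'   `scenario_config(seed = seed)`.
#' @param inflations MCL inflation sweep; default 1.1 to 2.0 by 0.1.
#' @param mapping_mode `"overlap"` or `"containment"` for CNV-to-gene
#'   assignment.
#' @param p_gate,fdr_gate Strict enrichment gates (defaults 0.10, 0.20).
#' @param jaccard_threshold Cluster-family similarity threshold.
#' @param term_p_threshold Raw-p reporting threshold for term enrichment.
#' @param out_dir Output directory.
#' @param seed Integer seed (drives synthetic mode; the analysis itself is
#'   deterministic).
#' @param verbose Emit per-stage progress messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(network = NULL, genes = NULL, cnvs = NULL,
                            snps = NULL, terms = NULL, synthetic = FALSE,
                            scenario = NULL,
                            inflations = seq(1.1, 2.0, by = 0.1),
                            mapping_mode = c("overlap", "containment"),
                            p_gate = 0.10, fdr_gate = 0.20,
                            jaccard_threshold = 0.5,
                            term_p_threshold = 1e-3,
                            out_dir = tempfile("cnvclust_run_"),
                            seed = 1, verbose = TRUE) {
  mapping_mode <- match.arg(mapping_mode)
  if (!(p_gate > 0 && p_gate <= 1 && fdr_gate > 0 && fdr_gate <= 1)) {
    stop("gates must lie in (0, 1]", call. = FALSE)
  }
  if (any(inflations <= 1)) {
    stop("all inflation values must be > 1", call. = FALSE)
  }
  if (synthetic && is.null(scenario)) {
    scenario <- scenario_config(seed = seed)
  }
  if (!synthetic) {
    missing <- c(network = is.null(network), genes = is.null(genes),
                 cnvs = is.null(cnvs), snps = is.null(snps))
    if (any(missing)) {
      stop("missing input path(s): ",
           paste(names(missing)[missing], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(network = network, genes = genes, cnvs = cnvs,
                 snps = snps, terms = terms, synthetic = synthetic,
                 scenario = scenario, inflations = inflations,
                 mapping_mode = mapping_mode, p_gate = p_gate,
                 fdr_gate = fdr_gate, jaccard_threshold = jaccard_threshold,
                 term_p_threshold = term_p_threshold, out_dir = out_dir,
                 seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

pipeline_stage <- function(cfg, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (isTRUE(cfg$verbose)) {
    message(sprintf("[cnvclust] %-18s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  res
}

#' Run the full disparity-cluster pipeline
#'
#' Executes read (or synthesize) -> MCL inflation sweep -> CNV/SNP gene
#' mapping -> per-run enrichment scoring and gate-filtered ranking ->
#' cross-run family matching and first-place tallies -> term enrichment of
#' each population's top family. All result tables are written as TSV under
#' `config$out_dir` together with a reproducibility manifest; rerunning
#' with an identical configuration reproduces identical outputs.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list of class `pipeline_report`: `tables` (named
#'   list of the six result data frames), `families` (the
#'   `cluster_families` object), `universe`, `gene_sets`, `top_family`
#'   (named list per population), `truth` (synthetic mode only),
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (cfg$synthetic) {
    gen <- pipeline_stage(cfg, "simulate",
                          generate_scenario(cfg$scenario,
                                            file.path(cfg$out_dir, "inputs")))
    truth <- gen$truth
    cfg$network <- gen$paths[["network"]]
    cfg$genes <- gen$paths[["genes"]]
    cfg$cnvs <- gen$paths[["cnvs"]]
    cfg$snps <- gen$paths[["snps"]]
    cfg$terms <- gen$paths[["terms"]]
  }

  inputs <- pipeline_stage(cfg, "read", {
    # self-loop lines (homodimers; isolated-gene markers in synthetic
    # bundles) are expected input: log instead of warning
    net <- withCallingHandlers(
      read_network(cfg$network),
      warning = function(w) {
        if (grepl("self-loop", conditionMessage(w))) {
          if (isTRUE(cfg$verbose)) {
            message("[cnvclust] read: ", conditionMessage(w))
          }
          invokeRestart("muffleWarning")
        }
      })
    genes <- read_gene_annotation(cfg$genes)
    var <- read_variant_tables(cfg$cnvs, cfg$snps)
    ann <- if (!is.null(cfg$terms)) read_term_annotations(cfg$terms) else NULL
    list(net = net, genes = genes, cnv = var$cnv, snp = var$snp, ann = ann)
  })
  universe <- sort(igraph::V(inputs$net)$name)

  sweep <- pipeline_stage(cfg, "cluster",
                          inflation_sweep(inputs$net, cfg$inflations))

  sets <- pipeline_stage(cfg, "map",
                         derive_gene_sets(inputs$genes, inputs$cnv,
                                          inputs$snp, cfg$mapping_mode))

  scored <- pipeline_stage(cfg, "score", {
    lapply(sweep, function(cl)
      score_clusters(cl, sets, universe = universe,
                     p_gate = cfg$p_gate, fdr_gate = cfg$fdr_gate))
  })
  ranked <- list(
    AA = lapply(scored, rank_clusters, population = "AA",
                p_gate = cfg$p_gate, fdr_gate = cfg$fdr_gate),
    CA = lapply(scored, rank_clusters, population = "CA",
                p_gate = cfg$p_gate, fdr_gate = cfg$fdr_gate)
  )

  families <- pipeline_stage(cfg, "families",
                             match_cluster_families(sweep,
                                                    cfg$jaccard_threshold))
  tallies <- count_first_place(ranked, families)

  top_family <- lapply(c(AA = "AA", CA = "CA"), function(pop) {
    blk <- tallies[tallies$population == pop, , drop = FALSE]
    if (nrow(blk) == 0 || blk$first_place_count[1] == 0) return(NULL)
    list(family_id = blk$family_id[1],
         first_place_count = blk$first_place_count[1],
         genes = families$representative[[blk$family_id[1]]])
  })

  term_tab <- pipeline_stage(cfg, "terms", {
    if (is.null(inputs$ann)) {
      data.frame(population = character(), term_id = character(),
                 label = character(), b = integer(), n = integer(),
                 k = integer(), B = integer(), p = numeric(), q = numeric(),
                 reported = logical(), stringsAsFactors = FALSE)
    } else {
      blocks <- lapply(names(top_family), function(pop) {
        tf <- top_family[[pop]]
        if (is.null(tf)) return(NULL)
        target <- intersect(tf$genes, universe)
        res <- enrich_terms(target, universe, inputs$ann,
                            cfg$term_p_threshold)
        if (nrow(res) == 0) return(NULL)
        cbind(data.frame(population = pop, stringsAsFactors = FALSE), res)
      })
      blocks <- blocks[!vapply(blocks, is.null, logical(1))]
      if (length(blocks) == 0) {
        data.frame(population = character(), term_id = character(),
                   label = character(), b = integer(), n = integer(),
                   k = integer(), B = integer(), p = numeric(), q = numeric(),
                   reported = logical(), stringsAsFactors = FALSE)
      } else {
        do.call(rbind, blocks)
      }
    }
  })

  clusters_tab <- do.call(rbind, lapply(sweep, function(cl) {
    if (length(cl$clusters) == 0) return(NULL)
    data.frame(run = cl$label,
               cluster_id = rep(sprintf("C%03d", seq_along(cl$clusters)),
                                lengths(cl$clusters)),
               gene = unlist(cl$clusters, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(clusters_tab)) {
    clusters_tab <- data.frame(run = character(), cluster_id = character(),
                               gene = character(), stringsAsFactors = FALSE)
  }
  scores_tab <- do.call(rbind, scored)
  bind_ranked <- function(lst) {
    lst <- lst[vapply(lst, nrow, integer(1)) > 0]
    if (length(lst) == 0) {
      out <- empty_scores()
      out$rank <- integer(0)
      return(out)
    }
    do.call(rbind, lst)
  }
  tables <- list(
    clusters = clusters_tab,
    cluster_scores = scores_tab,
    ranked_AA = bind_ranked(ranked$AA),
    ranked_CA = bind_ranked(ranked$CA),
    families = tallies,
    term_enrichment = term_tab
  )
  paths <- pipeline_stage(cfg, "write", write_results(tables, cfg$out_dir))

  manifest <- data.frame(
    key = c("package_version", "seed", "synthetic", "mapping_mode",
            "inflations", "p_gate", "fdr_gate", "jaccard_threshold",
            "term_p_threshold",
            paste0("rows_", names(tables))),
    value = c(as.character(packageVersion("cnvclust")),
              as.character(cfg$seed), as.character(cfg$synthetic),
              cfg$mapping_mode, paste(cfg$inflations, collapse = ","),
              as.character(cfg$p_gate), as.character(cfg$fdr_gate),
              as.character(cfg$jaccard_threshold),
              as.character(cfg$term_p_threshold),
              as.character(vapply(tables, nrow, integer(1)))),
    stringsAsFactors = FALSE
  )
  write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(structure(list(tables = tables, families = families,
                           universe = universe, gene_sets = sets,
                           top_family = top_family, truth = truth,
                           manifest = manifest, out_dir = cfg$out_dir,
                           paths = paths),
                      class = "pipeline_report"))
}

#' Locate the family of the planted disparity module in a report
#'
#' Finds, among all clusters of all runs, the one with maximum Jaccard
#' similarity to the planted disparity-module gene set and returns its
#' family together with that family's AA tally rank — the end-to-end
#' recovery check for synthetic scenarios.
#'
#' @param report A `pipeline_report` from a synthetic run.
#' @return A list: `family_id`, `best_jaccard`, `aa_rank` (rank of that
#'   family in the AA tally ordering), `aa_tally`, `is_top_aa`.
#' @export
disparity_family <- function(report) {
  stopifnot(inherits(report, "pipeline_report"), !is.null(report$truth))
  truth <- report$truth
  module_genes <- names(truth$modules)[truth$modules ==
                                         truth$disparity_module]
  members <- report$families$members
  clusters_tab <- report$tables$clusters
  key <- paste(clusters_tab$run, clusters_tab$cluster_id, sep = "\r")
  genes_by_cluster <- split(clusters_tab$gene, key)
  jac <- vapply(genes_by_cluster, function(g) {
    length(intersect(g, module_genes)) / length(union(g, module_genes))
  }, numeric(1))
  best <- names(jac)[which.max(jac)]
  parts <- strsplit(best, "\r", fixed = TRUE)[[1]]
  fid <- members$family_id[members$run == parts[1] &
                             members$cluster_id == parts[2]]
  aa <- report$tables$families
  aa <- aa[aa$population == "AA", , drop = FALSE]
  row <- aa[aa$family_id == fid, , drop = FALSE]
  list(family_id = fid, best_jaccard = max(jac),
       aa_rank = if (nrow(row)) row$rank[1] else NA_integer_,
       aa_tally = if (nrow(row)) row$first_place_count[1] else 0L,
       is_top_aa = nrow(row) > 0 && row$rank[1] == 1 &&
         row$first_place_count[1] > 0)
}
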