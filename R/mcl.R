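# Markov Cluster (MCL) algorithm: alternating expansion (matrix
# self-multiplication) and inflation (entrywise power + column
# renormalisation) of a column-stochastic flow matrix, with pruning of small
# entries, until the flow stabilises. Clusters are read off the attractor
# structure of the converged matrix.

#' Build the column-stochastic transition matrix for MCL
#'
#' Adds `self_loop_weight` to every diagonal entry of the adjacency matrix
#' (standard MCL practice; it damps parity oscillation) and normalises each
#' column to sum to one. Isolated nodes get a pure self-loop column.
#'
#' @param network An undirected `igraph` graph with named vertices.
#' @param self_loop_weight Positive diagonal weight added to every node.
#' @param sparse Use a sparse (`Matrix`) representation. `NULL` (default)
#'   picks sparse for graphs with 100 or more nodes; results are identical
#'   either way.
#' @return A list of class `stochastic_matrix` with elements `matrix`
#'   (column-stochastic, dense or `dgCMatrix`) and `nodes` (vertex names in
#'   matrix order).
#' @export
build_transition_matrix <- function(network, self_loop_weight = 1,
                                    sparse = NULL) {
  stopifnot(igraph::is_igraph(network))
  if (self_loop_weight <= 0) {
    stop("self_loop_weight must be > 0", call. = FALSE)
  }
  n <- igraph::gorder(network)
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (is.null(sparse)) sparse <- n >= 100
  if (n == 0) {
    m <- if (sparse) Matrix::sparseMatrix(i = integer(), j = integer(),
                                          x = numeric(), dims = c(0, 0))
         else matrix(numeric(0), 0, 0)
    return(structure(list(matrix = m, nodes = character(0)),
                     class = "stochastic_matrix"))
  }
  a <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  a <- methods::as(a, "dMatrix")
  Matrix::diag(a) <- Matrix::diag(a) + self_loop_weight
  a <- normalize_columns(a)
  if (!sparse) a <- as.matrix(a)
  dimnames(a) <- list(nodes, nodes)
  structure(list(matrix = a, nodes = nodes), class = "stochastic_matrix")
}

normalize_columns <- function(m) {
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  if (inherits(m, "sparseMatrix")) {
    m %*% Matrix::Diagonal(x = 1 / cs)
  } else {
    sweep(m, 2, cs, "/")
  }
}

inflate_entries <- function(m, inflation) {
  if (inherits(m, "sparseMatrix")) {
    m <- methods::as(m, "CsparseMatrix")
    m@x <- m@x^inflation
    m
  } else {
    m^inflation
  }
}

# Zero out entries below `threshold`, but never a column's maximum, so no
# column can be emptied by pruning.
prune_entries <- function(m, threshold) {
  if (threshold <= 0) return(m)
  if (inherits(m, "sparseMatrix")) {
    m <- methods::as(m, "CsparseMatrix")
    colmax <- rep(0, ncol(m))
    j <- rep.int(seq_len(ncol(m)), diff(m@p))
    if (length(m@x)) {
      colmax <- vapply(split(m@x, factor(j, levels = seq_len(ncol(m)))),
                       function(x) if (length(x)) max(x) else 0, numeric(1))
      drop <- m@x < threshold & m@x < colmax[j]
      m@x[drop] <- 0
    }
    Matrix::drop0(m)
  } else {
    colmax <- apply(m, 2, max)
    drop <- m < threshold & m < rep(colmax, each = nrow(m))
    m[drop] <- 0
    m
  }
}

max_abs_diff <- function(a, b) {
  d <- a - b
  if (inherits(d, "sparseMatrix")) {
    if (length(d@x) == 0) 0 else max(abs(d@x))
  } else {
    if (length(d) == 0) 0 else max(abs(d))
  }
}

#' Run MCL on a transition matrix
#'
#' Alternates expansion (`M %*% M`) and inflation (entrywise power
#' `inflation`, then column renormalisation), pruning entries below
#' `prune_threshold` (the column maximum is never pruned) and renormalising,
#' until the largest absolute entry change across one full iteration drops
#' below `tol` or `max_iter` is reached. Clusters are the attractor systems
#' of the final matrix: nodes with positive diagonal mass are attractors;
#' attractors connected through shared flow form one system; every other
#' node joins the system(s) its column flows into. A node attracted to more
#' than one system is assigned to the largest one (ties broken towards the
#' cluster whose lexicographically smallest member is smallest), so the
#' result is always a strict partition.
#'
#' @param tm A `stochastic_matrix` from [build_transition_matrix()].
#' @param inflation Inflation parameter, must be > 1. Larger values give
#'   finer clusters.
#' @param max_iter Maximum number of expansion/inflation iterations.
#' @param tol Convergence tolerance on the maximum absolute entry change.
#' @param prune_threshold Entries below this value are set to zero after
#'   each inflation (with column renormalisation).
#' @param label Run label stored on the result; defaults to
#'   `sprintf("I%.1f", inflation)`.
#' @return A list of class `clustering`: `inflation`, `label`, `clusters`
#'   (list of disjoint character vectors covering all nodes, each sorted;
#'   clusters ordered by decreasing size then smallest member), `converged`,
#'   `iterations`.
#' @export
mcl_cluster <- function(tm, inflation, max_iter = 200, tol = 1e-6,
                        prune_threshold = 1e-5, label = NULL) {
  stopifnot(inherits(tm, "stochastic_matrix"))
  if (!is.numeric(inflation) || inflation <= 1.0) {
    stop("inflation must be > 1.0", call. = FALSE)
  }
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (is.null(label)) label <- sprintf("I%.1f", inflation)
  nodes <- tm$nodes
  n <- length(nodes)
  if (n == 0) {
    return(structure(list(inflation = inflation, label = label,
                          clusters = list(), converged = TRUE,
                          iterations = 0L),
                     class = "clustering"))
  }
  m <- tm$matrix
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    prev <- m
    m <- m %*% m                       # expansion
    m <- inflate_entries(m, inflation) # inflation
    m <- normalize_columns(m)
    m <- prune_entries(m, prune_threshold)
    m <- normalize_columns(m)
    if (max_abs_diff(m, prev) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations (inflation ", inflation, ")", call. = FALSE)
  }
  clusters <- extract_clusters(m, nodes)
  assert_partition(clusters, nodes)
  structure(list(inflation = inflation, label = label, clusters = clusters,
                 converged = converged, iterations = iter),
            class = "clustering")
}

# Read clusters off the attractor structure of a (near-)idempotent flow
# matrix. eps separates numerical zero from retained flow.
extract_clusters <- function(m, nodes, eps = 1e-8) {
  n <- length(nodes)
  md <- unname(as.matrix(m))
  diag_mass <- diag(md)
  attractors <- which(diag_mass > eps)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # attractor systems: connected components of shared-flow links among
  # attractors (direct flow either way, or flow from a common column)
  sup <- md > eps
  sub <- sup[attractors, attractors, drop = FALSE]
  link <- sub | t(sub)
  # attractors fed by the same column belong together
  cols_on_attr <- sup[attractors, , drop = FALSE]
  if (length(attractors) > 1) {
    shared <- cols_on_attr %*% t(cols_on_attr) > 0
    link <- link | shared
  }
  g <- igraph::graph_from_adjacency_matrix(link, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  nsys <- max(comp)
  members <- vector("list", nsys)
  assigned <- integer(n) # 0 = unassigned
  assigned[attractors] <- comp
  # non-attractor nodes: candidate systems from the attractors in their column
  pending <- list()
  for (j in setdiff(seq_len(n), attractors)) {
    hit <- attractors[sup[attractors, j]]
    systems <- unique(comp[match(hit, attractors)])
    if (length(systems) == 1) {
      assigned[j] <- systems
    } else if (length(systems) == 0) {
      assigned[j] <- NA_integer_ # singleton fallback
    } else {
      pending[[length(pending) + 1]] <- list(node = j, systems = systems)
    }
  }
  # overlap resolution: largest cluster wins, ties to smallest member symbol
  if (length(pending)) {
    sizes <- tabulate(assigned[!is.na(assigned)], nbins = nsys)
    smallest <- vapply(seq_len(nsys), function(s) {
      mem <- nodes[which(!is.na(assigned) & assigned == s)]
      if (length(mem)) min(mem) else "\uffff"
    }, character(1))
    for (p in pending) {
      cand <- p$systems
      best <- cand[order(-sizes[cand], smallest[cand])][1]
      assigned[p$node] <- best
      sizes[best] <- sizes[best] + 1
    }
  }
  out <- split(nodes[!is.na(assigned)], assigned[!is.na(assigned)])
  out <- c(out, as.list(nodes[is.na(assigned)]))
  out <- lapply(out, function(x) sort(unname(x)))
  first <- vapply(out, `[[`, character(1), 1L)
  out <- out[order(-lengths(out), first)]
  names(out) <- NULL
  out
}

assert_partition <- function(clusters, nodes) {
  all_members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_members) || !setequal(all_members, nodes) ||
      length(all_members) != length(nodes)) {
    stop("internal error: clusters do not partition the node set",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Cluster a network across a sweep of inflation values
#'
#' Runs [mcl_cluster()] once per inflation value. The default sweep is 1.1
#' to 2.0 in steps of 0.1, the standard granularity scan for MCL on
#' interaction networks.
#'
#' @param network An undirected `igraph` graph with named vertices.
#' @param inflations Numeric vector of inflation values, all > 1.
#' @param self_loop_weight,max_iter,tol,prune_threshold Passed through to
#'   [build_transition_matrix()] and [mcl_cluster()].
#' @param sparse Matrix backend selector, see [build_transition_matrix()].
#' @return A list of `clustering` objects, one per inflation value, labeled
#'   `I1.1`, `I1.2`, ...
#' @export
inflation_sweep <- function(network,
                            inflations = seq(1.1, 2.0, by = 0.1),
                            self_loop_weight = 1, max_iter = 200,
                            tol = 1e-6, prune_threshold = 1e-5,
                            sparse = NULL) {
  if (length(inflations) == 0) {
    stop("inflation sweep must contain at least one value", call. = FALSE)
  }
  if (any(inflations <= 1.0)) {
    stop("all inflation values must be > 1.0", call. = FALSE)
  }
  tm <- build_transition_matrix(network, self_loop_weight, sparse = sparse)
  lapply(inflations, function(i) {
    suppressWarnings(
      mcl_cluster(tm, inflation = i, max_iter = max_iter, tol = tol,
                  prune_threshold = prune_threshold)
    )
  })
}

#' @export
print.clustering <- function(x, ...) {
  cat("MCL clustering", x$label, "-", length(x$clusters), "clusters over",
      sum(lengths(x$clusters)), "genes;",
      if (x$converged) paste0("converged in ", x$iterations, " iterations")
      else paste0("not converged after ", x$iterations, " iterations"),
      "\n")
  invisible(x)
}
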