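#' Build the weighted protein-family similarity graph
#'
#' Edges connect rHMM pairs whose strict-context comparison reaches
#' probability p >= `min_p` and pairwise coverage
#' `cov = min(qcov, scov)` >= `min_cov`; the edge weight is the score
#' `p * cov`. rHMMs without any qualifying edge remain as isolated nodes so
#' that they later form singleton families.
#'
#' @param pairs strict-context pair table.
#' @param nodes universe of rHMM ids (defaults to the ids seen in `pairs`).
#' @param min_p,min_cov inclusive thresholds.
#' @return list of class `family_graph` with `nodes` (character) and
#'   `edges` (data frame `id_a`, `id_b`, `weight`).
#' @export
build_family_graph <- function(pairs, nodes = NULL, min_p = 0.95,
                               min_cov = 0.8) {
  keep <- filter_pairs(pairs, min_p = min_p, min_cov_mode = "min",
                       min_cov = min_cov)
  edges <- data.frame(id_a = keep$id_a, id_b = keep$id_b,
                      weight = keep$p * keep$cov_min,
                      stringsAsFactors = FALSE)
  edges <- edges[edges$id_a != edges$id_b, , drop = FALSE]
  nodes <- sort(unique(c(nodes, pairs$id_a, pairs$id_b,
                         edges$id_a, edges$id_b)))
  structure(list(nodes = nodes, edges = edges), class = "family_graph")
}

#' Markov clustering of a weighted similarity graph
#'
#' Standard MCL on the column-stochastic matrix of the graph: self-loops
#' are added with weight equal to the node's maximum incident edge weight
#' (1 for isolated nodes), columns are normalised, then expansion (matrix
#' power) and inflation (entrywise power followed by renormalisation)
#' alternate, with entries below `prune_eps` removed for sparsity, until
#' the matrix changes by less than `tol` or `max_iter` iterations have
#' run. Clusters are read from the attractor rows of the limit matrix;
#' a node reachable from several attractor systems is assigned to the one
#' holding the largest mass on it, ties to the lowest family id.
#'
#' @param graph `family_graph` from [build_family_graph()].
#' @param inflation inflation exponent (the clustering granularity knob;
#'   2 is the conventional default).
#' @param expansion expansion power.
#' @param max_iter iteration cap; non-convergence warns and clusters the
#'   current state.
#' @param prune_eps entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max absolute change.
#' @return data frame with `rhmm_id` and integer `family_id`; family ids
#'   are 1..k in order of each family's smallest member id.
#' @export
mcl <- function(graph, inflation = 2, expansion = 2, max_iter = 100,
                prune_eps = 1e-6, tol = 1e-8) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L)
    return(data.frame(rhmm_id = character(), family_id = integer(),
                      stringsAsFactors = FALSE))
  i <- match(graph$edges$id_a, nodes)
  j <- match(graph$edges$id_b, nodes)
  w <- graph$edges$weight
  if (any(w <= 0)) stop("edge weights must be positive")
  loop <- rep(1, n)
  if (length(i)) {
    inc <- tapply(c(w, w), c(i, j), max)
    loop[as.integer(names(inc))] <- inc
  }
  M <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)),
                            j = c(j, i, seq_len(n)),
                            x = c(w, w, loop), dims = c(n, n))
  M <- normalise_cols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M_new <- M
    for (e in seq_len(expansion - 1L)) M_new <- M_new %*% M
    M_new <- M_new^inflation
    M_new@x[M_new@x < prune_eps] <- 0
    M_new <- Matrix::drop0(M_new)
    M_new <- normalise_cols(M_new)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; clustering the current state")
  interpret_mcl(M, nodes)
}

normalise_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

# Read clusters from the (near-)limit matrix. Attractors are the nodes with
# positive diagonal mass; attractors reached from a common column form one
# attractor system (in the idempotent limit every attractor's column carries
# its whole system, so column co-occurrence identifies systems). Each node
# joins the system holding the largest mass in its column, ties to the
# lowest attractor index.
interpret_mcl <- function(M, nodes, eps = 1e-9) {
  n <- length(nodes)
  Mc <- methods::as(M, "CsparseMatrix")
  cols <- lapply(seq_len(n), function(col) {
    idx <- if (Mc@p[col] < Mc@p[col + 1L]) (Mc@p[col] + 1L):Mc@p[col + 1L] else integer()
    rows <- Mc@i[idx] + 1L
    vals <- Mc@x[idx]
    keep <- vals > eps
    list(rows = rows[keep], vals = vals[keep])
  })
  diag_mass <- vapply(seq_len(n), function(col) {
    k <- match(col, cols[[col]]$rows)
    if (is.na(k)) 0 else cols[[col]]$vals[k]
  }, numeric(1))
  attractors <- which(diag_mass > eps)
  if (length(attractors) == 0L) attractors <- seq_len(n)

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (col in seq_len(n)) {
    att <- cols[[col]]$rows[cols[[col]]$rows %in% attractors]
    if (length(att) > 1L)
      for (a in att[-1L]) union_(att[1L], a)
  }

  assign <- integer(n)
  for (col in seq_len(n)) {
    rows <- cols[[col]]$rows
    vals <- cols[[col]]$vals
    keep <- rows %in% attractors
    rows <- rows[keep]; vals <- vals[keep]
    if (length(rows) == 0L) {
      # no attractor mass (numerically); fall back to the node itself
      assign[col] <- find(col)
    } else {
      best <- which(vals >= max(vals) - eps)
      assign[col] <- min(vapply(rows[best], find, integer(1)))
    }
  }
  fam <- match(assign, sort(unique(assign)))
  data.frame(rhmm_id = nodes, family_id = fam, stringsAsFactors = FALSE)
}

#' Per-family mosaic status
#'
#' A family is mosaic under a basis if it contains any rHMM carrying that
#' basis' mosaic signal.
#'
#' @param partition data frame from [mcl()].
#' @param signals data frame from [mosaic_signal()].
#' @return data frame with `family_id`, logical `ecod_mosaic`,
#'   `sequence_mosaic`.
#' @export
family_mosaic_status <- function(partition, signals) {
  missing <- setdiff(signals$rhmm_id, partition$rhmm_id)
  if (length(missing))
    stop("mosaic signal on rHMMs absent from the partition: ",
         paste(missing, collapse = ", "))
  fam <- stats::setNames(partition$family_id, partition$rhmm_id)
  sig_fam <- fam[signals$rhmm_id]
  ids <- sort(unique(partition$family_id))
  data.frame(
    family_id = ids,
    ecod_mosaic = ids %in% sig_fam[signals$ecod],
    sequence_mosaic = ids %in% sig_fam[signals$sequence],
    stringsAsFactors = FALSE
  )
}
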