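# BDeu scoring.  The score of a (child, parent set) family is the log
# marginal likelihood of the child's CPT under symmetric Dirichlet priors
# with total prior weight `ess` (the equivalent sample size) spread
# uniformly over the CPT cells:
#
#   sum_j [ lgamma(a_j) - lgamma(a_j + n_j) ] +
#   sum_jk [ lgamma(a_jk + n_jk) - lgamma(a_jk) ]
#
# with a_j = ess / q, a_jk = ess / (q r), q parent configurations, r child
# levels and n_jk the cell counts.  BDeu is score equivalent: Markov
# equivalent DAGs receive identical network scores.

# Integer-coded dataset: values 1..r per column, plus the level counts.
encode_dataset <- function(data) {
  data <- check_dataset(data)
  nodes <- names(data)
  m <- matrix(0L, nrow = nrow(data), ncol = length(nodes),
              dimnames = list(NULL, nodes))
  nlev <- integer(length(nodes))
  levels_list <- vector("list", length(nodes))
  for (j in seq_along(nodes)) {
    f <- data[[j]]
    m[, j] <- as.integer(f)
    nlev[j] <- nlevels(f)
    levels_list[[j]] <- levels(f)
  }
  names(nlev) <- nodes
  names(levels_list) <- nodes
  list(m = m, nlev = nlev, levels = levels_list, nodes = nodes,
       n = nrow(data))
}

# Validate a dataset: complete, categorical, >= 1 column.  Character columns
# are converted to factors; factor columns keep their declared levels (so
# unobserved levels still shape the CPT counts).
check_dataset <- function(data) {
  if (!is.data.frame(data) || ncol(data) == 0L)
    stop("data must be a data frame with at least one column", call. = FALSE)
  if (anyNA(data))
    stop("data contain missing values; complete data are required",
         call. = FALSE)
  for (j in seq_along(data)) {
    if (is.character(data[[j]]))
      data[[j]] <- factor(data[[j]])
    else if (!is.factor(data[[j]]))
      stop(sprintf("column '%s' is not categorical", names(data)[j]),
           call. = FALSE)
    if (nlevels(data[[j]]) < 1L)
      stop(sprintf("column '%s' has no levels", names(data)[j]),
           call. = FALSE)
  }
  data
}

# Fast family score on an encoded dataset; ci / pa are column indices.
family_score_enc <- function(enc, ci, pa, ess) {
  r <- unname(enc$nlev[ci])
  if (length(pa) == 0L) {
    q <- 1L
    cell <- enc$m[, ci]
  } else {
    q <- prod(enc$nlev[pa])
    if (q * as.double(r) >= 2^31)
      stop("parent configuration space too large to score", call. = FALSE)
    cell <- enc$m[, pa[1L]]
    mult <- enc$nlev[pa[1L]]
    for (p in pa[-1L]) {
      cell <- cell + (enc$m[, p] - 1L) * mult
      mult <- mult * enc$nlev[p]
    }
    cell <- cell + (enc$m[, ci] - 1L) * as.integer(q)
  }
  njk <- tabulate(cell, q * r)
  nj <- if (q == 1L) sum(njk) else .rowSums(njk, q, r)
  ajk <- ess / (q * r)
  aj <- ess / q
  nzk <- njk > 0L
  nzj <- nj > 0
  sum(lgamma(ajk + njk[nzk])) - sum(nzk) * lgamma(ajk) +
    sum(nzj) * lgamma(aj) - sum(lgamma(aj + nj[nzj]))
}

#' BDeu log marginal likelihood of one family
#'
#' Scores a child variable against a candidate parent set under the
#' Bayesian Dirichlet equivalent uniform (BDeu) prior.  The total network
#' score is the sum of the family scores of every node given its parents
#' (the score is decomposable), which is what [network_score()] computes.
#'
#' @param child name of the child variable.
#' @param parents character vector of parent names (possibly empty).
#' @param data complete categorical data frame.
#' @param ess equivalent sample size, the total Dirichlet prior weight
#'   (default 10).
#' @return The family's log marginal likelihood (0 for an empty dataset).
#' @export
bdeu_family_score <- function(child, parents = character(0L), data, ess = 10) {
  if (!is.numeric(ess) || length(ess) != 1L || ess <= 0)
    stop("'ess' must be a positive number", call. = FALSE)
  enc <- encode_dataset(data)
  vars <- c(child, parents)
  if (!all(vars %in% enc$nodes))
    stop("unknown variable(s): ",
         paste(setdiff(vars, enc$nodes), collapse = ", "), call. = FALSE)
  if (child %in% parents)
    stop("a variable cannot be its own parent", call. = FALSE)
  family_score_enc(enc, match(child, enc$nodes),
                   match(parents, enc$nodes), ess)
}

#' Directed graph over named nodes
#'
#' Lightweight structure-learning output: a node set plus a set of directed
#' edges, with no distribution attached.
#'
#' @param nodes character vector of node names.
#' @param edges two-column matrix or data frame of (from, to) pairs, or
#'   `NULL` for no edges.
#' @return An object of class `bn_graph` with components `nodes` and
#'   `edges` (two-column character matrix).
#' @export
bn_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes))
    stop("duplicated node names", call. = FALSE)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0L), ncol = 2L,
                    dimnames = list(NULL, c("from", "to")))
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    colnames(edges) <- c("from", "to")
    if (!all(edges %in% nodes))
      stop("edge endpoints outside the node set", call. = FALSE)
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self loops are not allowed", call. = FALSE)
    edges <- unique(edges)
  }
  structure(list(nodes = nodes, edges = edges), class = "bn_graph")
}

#' @export
print.bn_graph <- function(x, ...) {
  cat(sprintf("Directed graph: %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  if (nrow(x$edges))
    cat(" ", paste(sprintf("%s -> %s", x$edges[, 1L], x$edges[, 2L]),
                   collapse = ", "), "\n")
  invisible(x)
}

graph_parents <- function(graph) {
  pa <- stats::setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (v in graph$nodes) pa[[v]] <- character(0L)
  if (nrow(graph$edges))
    for (i in seq_len(nrow(graph$edges)))
      pa[[graph$edges[i, 2L]]] <- c(pa[[graph$edges[i, 2L]]],
                                    graph$edges[i, 1L])
  pa
}

is_acyclic <- function(graph) {
  !is.null(topological_order(graph_parents(graph)))
}

#' BDeu score of a whole network structure
#'
#' Sums [bdeu_family_score()] over every node given its parents in `graph`.
#' Because the score decomposes over families, adding or removing an edge
#' changes only the child's family term.
#'
#' @param graph a `bn_graph` (must be acyclic).
#' @param data complete categorical data frame covering the graph's nodes.
#' @param ess equivalent sample size (default 10).
#' @return The network's log marginal likelihood.
#' @export
network_score <- function(graph, data, ess = 10) {
  if (!inherits(graph, "bn_graph"))
    stop("'graph' must be a bn_graph", call. = FALSE)
  if (!is_acyclic(graph))
    stop("'graph' is cyclic", call. = FALSE)
  enc <- encode_dataset(data)
  if (!all(graph$nodes %in% enc$nodes))
    stop("graph nodes missing from the data", call. = FALSE)
  pa <- graph_parents(graph)
  sum(vapply(graph$nodes, function(v)
    family_score_enc(enc, match(v, enc$nodes), match(pa[[v]], enc$nodes),
                     ess), numeric(1L)))
}
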