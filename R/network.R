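#' Discrete Bayesian networks
#'
#' A discrete Bayesian network is a directed acyclic graph over categorical
#' variables together with one conditional probability table (CPT) per node.
#' The network object stores, for every node, its levels, its parent set
#' (in a fixed order) and a CPT whose first dimension indexes the node's own
#' levels and whose remaining dimensions index the parents' levels, in the
#' parent order.
#'
#' @param variables named list; one entry per variable, each a character
#'   vector of at least two distinct level labels.
#' @param edges a two-column matrix or data frame of directed edges
#'   (parent, child), or `NULL` for an empty graph.
#' @param cpts named list of CPT arrays, one per node.  For a parentless
#'   node a plain probability vector over its levels is accepted.  If
#'   omitted, uniform CPTs are filled in.
#' @param check if `TRUE` (default) the constructed network is validated and
#'   construction fails on any violation.
#'
#' @return An object of class `dbn`: a list with one element per node,
#'   each a list with components `levels`, `parents` and `cpt`.
#' @seealso [validate_network()], [forward_sample()], [random_network()]
#' @examples
#' net <- discrete_bn(
#'   variables = list(A = c("no", "yes"), B = c("no", "yes")),
#'   edges = rbind(c("A", "B")),
#'   cpts = list(
#'     A = c(no = 0.7, yes = 0.3),
#'     B = matrix(c(0.9, 0.1, 0.2, 0.8), nrow = 2,
#'                dimnames = list(c("no", "yes"), c("no", "yes")))))
#' param_count(net)
#' @export
discrete_bn <- function(variables, edges = NULL, cpts = NULL, check = TRUE) {
  if (!is.list(variables) || is.null(names(variables)) ||
      any(names(variables) == ""))
    stop("'variables' must be a named list of level vectors", call. = FALSE)
  node_names <- names(variables)
  if (anyDuplicated(node_names))
    stop("duplicated variable names", call. = FALSE)

  if (is.null(edges)) {
    edges <- matrix(character(0L), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (length(edges) == 0L)
      edges <- matrix(character(0L), ncol = 2L)
    if (ncol(edges) != 2L)
      stop("'edges' must have two columns (parent, child)", call. = FALSE)
    storage.mode(edges) <- "character"
  }

  nodes <- vector("list", length(node_names))
  names(nodes) <- node_names
  for (v in node_names) {
    lv <- as.character(variables[[v]])
    pa <- edges[edges[, 2L] == v, 1L]
    # parents kept in node-declaration order so CPT dimensions are canonical
    pa <- node_names[node_names %in% pa]
    cpt <- if (!is.null(cpts) && v %in% names(cpts)) cpts[[v]] else NULL
    if (is.null(cpt)) {
      dims <- c(length(lv), vapply(pa, function(p)
        length(variables[[p]]), integer(1L)))
      cpt <- array(1 / length(lv), dim = dims,
                   dimnames = c(list(lv), lapply(pa, function(p)
                     as.character(variables[[p]]))))
    } else {
      if (is.null(dim(cpt)))
        cpt <- array(cpt, dim = length(cpt), dimnames = list(names(cpt) %||% lv))
      if (is.null(dimnames(cpt)))
        dimnames(cpt) <- c(list(lv), lapply(pa, function(p)
          as.character(variables[[p]])))
    }
    nodes[[v]] <- list(levels = lv, parents = pa, cpt = cpt)
  }
  net <- structure(nodes, class = "dbn")
  if (check) {
    bad <- validate_network(net)
    if (length(bad))
      stop("invalid network:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
  }
  net
}

#' @export
print.dbn <- function(x, ...) {
  e <- network_edges(x)
  cat(sprintf("Discrete Bayesian network: %d nodes, %d edges, %d parameters\n",
              length(x), nrow(e), param_count(x)))
  cat("  nodes:", paste(names(x), collapse = ", "), "\n")
  if (nrow(e))
    cat("  edges:", paste(sprintf("%s -> %s", e[, 1L], e[, 2L]),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Directed edges of a network
#'
#' @param net a `dbn` object.
#' @return A two-column character matrix with columns `from` and `to`.
#' @export
network_edges <- function(net) {
  out <- do.call(rbind, lapply(names(net), function(v) {
    pa <- net[[v]]$parents
    if (length(pa)) cbind(from = pa, to = rep(v, length(pa))) else NULL
  }))
  if (is.null(out))
    out <- matrix(character(0L), ncol = 2L, dimnames = list(NULL, c("from", "to")))
  out
}

# Topological order of node names given a parents list; NULL if cyclic.
topological_order <- function(parents) {
  nodes <- names(parents)
  indeg <- vapply(parents, length, integer(1L))
  order <- character(0L)
  avail <- nodes[indeg == 0L]
  remaining <- parents
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    remaining[[v]] <- NULL
    for (w in names(remaining)) {
      if (v %in% remaining[[w]]) {
        remaining[[w]] <- setdiff(remaining[[w]], v)
        if (length(remaining[[w]]) == 0L)
          avail <- c(avail, w)
      }
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

#' Validate a discrete Bayesian network
#'
#' Checks the structural invariants of a [discrete_bn()] object: at least two
#' distinct levels per variable, an acyclic edge set, CPT dimensions matching
#' the node's level count and the parents' level counts, and every CPT row
#' (one fixed parent configuration) summing to one within `1e-9`.
#'
#' @param net a `dbn` object.
#' @return A character vector of human-readable violation descriptions;
#'   empty when the network is valid.  This function reports rather than
#'   throws, so it can be used to accumulate all problems at once.
#' @export
validate_network <- function(net) {
  out <- character(0L)
  if (!inherits(net, "dbn"))
    return("not a 'dbn' object")
  nodes <- names(net)
  if (anyDuplicated(nodes))
    out <- c(out, "duplicated node names")
  for (v in nodes) {
    lv <- net[[v]]$levels
    if (length(lv) < 2L)
      out <- c(out, sprintf("node '%s': fewer than two levels", v))
    if (anyDuplicated(lv))
      out <- c(out, sprintf("node '%s': duplicated levels", v))
    if (!all(net[[v]]$parents %in% nodes))
      out <- c(out, sprintf("node '%s': undeclared parent(s) %s", v,
                            paste(setdiff(net[[v]]$parents, nodes),
                                  collapse = ", ")))
  }
  ord <- topological_order(lapply(net, function(x)
    intersect(x$parents, nodes)))
  if (is.null(ord))
    out <- c(out, "edge set is cyclic: no topological order exists")
  for (v in nodes) {
    lv <- net[[v]]$levels
    pa <- net[[v]]$parents
    if (!all(pa %in% nodes)) next
    cpt <- net[[v]]$cpt
    want <- c(length(lv), vapply(pa, function(p) length(net[[p]]$levels),
                                 integer(1L)))
    have <- if (is.null(dim(cpt))) length(cpt) else dim(cpt)
    if (length(have) != length(want) || any(have != want)) {
      out <- c(out, sprintf(
        "node '%s': CPT dimensions (%s) do not match levels/parents (%s)",
        v, paste(have, collapse = "x"), paste(want, collapse = "x")))
      next
    }
    m <- matrix(as.numeric(cpt), nrow = length(lv))
    sums <- colSums(m)
    bad <- which(abs(sums - 1) > 1e-9)
    for (j in bad)
      out <- c(out, sprintf(
        "node '%s': CPT row for parent configuration %d sums to %.10g", v,
        j, sums[j]))
    if (any(m < -1e-12))
      out <- c(out, sprintf("node '%s': negative CPT entries", v))
  }
  out
}

assert_valid_network <- function(net) {
  bad <- validate_network(net)
  if (length(bad))
    stop("invalid network:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(net)
}

#' Number of free parameters of a discrete Bayesian network
#'
#' Each node with `r` levels and parents with a joint level-configuration
#' count of `q` contributes `(r - 1) * q` free parameters (one probability
#' per CPT row is determined by the sum-to-one constraint).  The total is
#' the `p` used in the sample-size-to-parameters ratio `n/p` when gauging
#' the difficulty of structure learning.
#'
#' @param net a valid `dbn` object.
#' @return Integer count of free parameters.
#' @export
param_count <- function(net) {
  assert_valid_network(net)
  sum(vapply(names(net), function(v) {
    r <- length(net[[v]]$levels)
    q <- prod(vapply(net[[v]]$parents, function(p)
      length(net[[p]]$levels), integer(1L)))
    (r - 1L) * as.integer(q)
  }, integer(1L)))
}

#' Number of possible undirected edges
#'
#' For a graph over `N` nodes there are `k = N (N - 1) / 2` unordered node
#' pairs, each a candidate edge whose bootstrap confidence is estimated.
#'
#' @param num_nodes positive integer.
#' @return `num_nodes * (num_nodes - 1) / 2` as an integer.
#' @examples
#' possible_edge_count(37)  # 666
#' @export
possible_edge_count <- function(num_nodes) {
  num_nodes <- stopifnot_scalar_count(num_nodes, "num_nodes", min = 1L)
  as.integer(num_nodes * (num_nodes - 1L) / 2L)
}

#' True skeleton of a network
#'
#' @param net a `dbn` object or a `bn_graph`.
#' @return Canonical pair table (`node_a`, `node_b`) of the undirected
#'   edges obtained by dropping directions.
#' @export
skeleton <- function(net) {
  e <- if (inherits(net, "dbn")) network_edges(net) else net$edges
  canonicalise_pairs(as.data.frame(e, stringsAsFactors = FALSE))
}
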