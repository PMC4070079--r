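#' Nonparametric bootstrap resample of a dataset
#'
#' Draws `nrow(data)` rows with replacement from `data`.
#'
#' @param data data frame with at least one row.
#' @param seed optional integer seed.
#' @return A data frame of the same shape and column types.
#' @export
bootstrap_resample <- function(data, seed = NULL) {
  data <- check_dataset(data)
  if (nrow(data) < 1L)
    stop("cannot bootstrap an empty dataset", call. = FALSE)
  idx <- with_seed(seed, sample.int(nrow(data), nrow(data), replace = TRUE))
  out <- data[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_edge_strength <- function(pairs, count_ab, count_ba, m, nodes) {
  out <- data.frame(node_a = pairs$node_a, node_b = pairs$node_b,
                    confidence = (count_ab + count_ba) / m,
                    count_ab = count_ab, count_ba = count_ba,
                    stringsAsFactors = FALSE)
  attr(out, "m") <- m
  attr(out, "nodes") <- nodes
  class(out) <- c("edge_strength", "data.frame")
  out
}

#' @export
print.edge_strength <- function(x, ...) {
  m <- attr(x, "m")
  cat(sprintf("Edge confidences over %d node pairs (%s bootstrap replicates)\n",
              nrow(x), if (is.na(m)) "unknown" else m))
  print.data.frame(x, ...)
  invisible(x)
}

# count skeleton orientations of a learned graph into the pair table
tally_graph <- function(graph, lookup, count_ab, count_ba) {
  e <- graph$edges
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      a <- e[i, 1L]; b <- e[i, 2L]
      if (a < b) {
        j <- lookup[[pair_key(a, b)]]
        count_ab[j] <- count_ab[j] + 1L
      } else {
        j <- lookup[[pair_key(b, a)]]
        count_ba[j] <- count_ba[j] + 1L
      }
    }
  }
  list(ab = count_ab, ba = count_ba)
}

pair_lookup <- function(pairs) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (j in seq_len(nrow(pairs)))
    env[[pair_key(pairs$node_a[j], pairs$node_b[j])]] <- j
  env
}

check_learner_output <- function(graph, nodes) {
  if (!inherits(graph, "bn_graph") ||
      !setequal(graph$nodes, nodes))
    stop("learner contract violation: output is not a bn_graph over the data's columns",
         call. = FALSE)
  if (!is_acyclic(graph))
    stop("learner contract violation: output graph is cyclic", call. = FALSE)
  graph
}

#' Bootstrap edge confidences (arc strengths)
#'
#' Friedman-style bootstrap model averaging: learn one network structure on
#' each of `m` nonparametric bootstrap replicates of the data, and estimate
#' the confidence of every possible edge as the fraction of replicates in
#' which it appears (in either orientation).  The two orientations are also
#' counted separately; the direction counts are used later to orient the
#' significant edges of the averaged network by majority.
#'
#' Replicate seeds are derived deterministically from `seed`, so replicates
#' are independent and could be executed in any order (or concurrently)
#' with identical results.
#'
#' @param data complete categorical data frame (>= 2 columns, >= 1 row).
#' @param learner a function `(data, seed) -> bn_graph` over the data's
#'   columns, e.g. [hc_learner()].
#' @param m number of bootstrap replicates (default 500; 200 gives very
#'   similar results at half the cost).
#' @param seed optional integer master seed.
#' @return An `edge_strength` data frame with one row per unordered node
#'   pair in canonical order: `node_a`, `node_b`, `confidence`, `count_ab`,
#'   `count_ba`; attribute `m` records the replicate count.
#' @export
bootstrap_confidences <- function(data, learner, m = 500L, seed = NULL) {
  data <- check_dataset(data)
  m <- stopifnot_scalar_count(m, "m", min = 1L)
  if (nrow(data) < 1L)
    stop("cannot bootstrap an empty dataset", call. = FALSE)
  nodes <- sort(names(data))
  pairs <- canonical_pairs(nodes)
  lookup <- pair_lookup(pairs)
  count_ab <- integer(nrow(pairs))
  count_ba <- integer(nrow(pairs))
  seeds <- matrix(derive_seeds(seed, 2L * m), ncol = 2L)
  for (b in seq_len(m)) {
    repl <- bootstrap_resample(data, seeds[b, 1L])
    g <- check_learner_output(learner(repl, seeds[b, 2L]), nodes)
    counts <- tally_graph(g, lookup, count_ab, count_ba)
    count_ab <- counts$ab
    count_ba <- counts$ba
  }
  new_edge_strength(pairs, count_ab, count_ba, m, nodes)
}

#' Permutation noise floor of edge confidences
#'
#' Estimates how often each edge is learned from data with no dependence
#' structure at all: every column of the data is independently permuted
#' (destroying all associations while preserving each variable's marginal
#' distribution), one structure is learned per permutation replicate, and
#' each pair's floor is the fraction of replicates containing it.  The
#' maximum floor over all pairs serves as an alternative significance
#' cut-off: an edge is deemed significant when its bootstrap confidence
#' strictly exceeds it (see [select_by_noise_floor()]).
#'
#' @param data complete categorical data frame.
#' @param learner a function `(data, seed) -> bn_graph`, e.g. [hc_learner()].
#' @param permutations number of permutation replicates (default 100).
#' @param seed optional integer master seed.
#' @return A `noise_floor` data frame (`node_a`, `node_b`, `floor`) with
#'   attributes `max_floor` and `permutations`.
#' @export
noise_floor <- function(data, learner, permutations = 100L, seed = NULL) {
  data <- check_dataset(data)
  permutations <- stopifnot_scalar_count(permutations, "permutations",
                                         min = 1L)
  if (nrow(data) < 1L)
    stop("cannot permute an empty dataset", call. = FALSE)
  nodes <- sort(names(data))
  pairs <- canonical_pairs(nodes)
  lookup <- pair_lookup(pairs)
  count_ab <- integer(nrow(pairs))
  count_ba <- integer(nrow(pairs))
  seeds <- matrix(derive_seeds(seed, 2L * permutations), ncol = 2L)
  for (b in seq_len(permutations)) {
    perm <- with_seed(seeds[b, 1L], {
      out <- data
      for (j in seq_along(out))
        out[[j]] <- out[[j]][sample.int(nrow(out))]
      out
    })
    g <- check_learner_output(learner(perm, seeds[b, 2L]), nodes)
    counts <- tally_graph(g, lookup, count_ab, count_ba)
    count_ab <- counts$ab
    count_ba <- counts$ba
  }
  out <- data.frame(node_a = pairs$node_a, node_b = pairs$node_b,
                    floor = (count_ab + count_ba) / permutations,
                    stringsAsFactors = FALSE)
  attr(out, "max_floor") <- if (nrow(out)) max(out$floor) else 0
  attr(out, "permutations") <- permutations
  class(out) <- c("noise_floor", "data.frame")
  out
}

#' Select edges whose confidence exceeds the noise floor
#'
#' An edge is significant when its bootstrap confidence is strictly greater
#' than the maximum of the noise-floor distribution.
#'
#' @param conf an `edge_strength` table from [bootstrap_confidences()].
#' @param floor a `noise_floor` table from [noise_floor()] over the same
#'   node pairs.
#' @return Canonical pair table (`node_a`, `node_b`) of significant edges.
#' @export
select_by_noise_floor <- function(conf, floor) {
  if (!inherits(conf, "edge_strength") || !inherits(floor, "noise_floor"))
    stop("'conf' must be an edge_strength and 'floor' a noise_floor",
         call. = FALSE)
  if (!identical(paste(conf$node_a, conf$node_b),
                 paste(floor$node_a, floor$node_b)))
    stop("'conf' and 'floor' cover different node pairs", call. = FALSE)
  keep <- conf$confidence > attr(floor, "max_floor")
  data.frame(node_a = conf$node_a[keep], node_b = conf$node_b[keep],
             stringsAsFactors = FALSE)
}

#' Write / read an edge-confidence table
#'
#' The on-disk form is a tab-separated table with columns `node_a`,
#' `node_b`, `confidence` and (optionally) `count_ab`, `count_ba`, sorted
#' canonically.  Tables with only the first three columns are accepted on
#' input, so confidences produced by any external learner or averaging
#' scheme can be thresholded.
#'
#' @param conf an `edge_strength` data frame.
#' @param path file path.
#' @return `write_strength()` returns `path` invisibly; `read_strength()`
#'   returns an `edge_strength` data frame (direction counts `NA` when the
#'   file does not carry them).
#' @export
write_strength <- function(conf, path) {
  if (!inherits(conf, "edge_strength"))
    stop("'conf' must be an edge_strength", call. = FALSE)
  utils::write.table(as.data.frame(conf), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_strength
#' @export
read_strength <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_a", "node_b", "confidence")
  if (!all(need %in% names(tab)))
    stop("strength table must have columns node_a, node_b, confidence",
         call. = FALSE)
  if (any(tab$confidence < 0 | tab$confidence > 1))
    stop("confidences must lie in [0, 1]", call. = FALSE)
  ord <- order(tab$node_a, tab$node_b)
  tab <- tab[ord, , drop = FALSE]
  pairs <- data.frame(node_a = as.character(tab$node_a),
                      node_b = as.character(tab$node_b),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(pairs$node_a, pairs$node_b)))
  count_ab <- if ("count_ab" %in% names(tab)) tab$count_ab else
    rep(NA_integer_, nrow(tab))
  count_ba <- if ("count_ba" %in% names(tab)) tab$count_ba else
    rep(NA_integer_, nrow(tab))
  m <- if (all(!is.na(count_ab + count_ba)) && nrow(tab)) {
    tot <- count_ab + count_ba
    mm <- unique(round(tot[tab$confidence > 0] / tab$confidence[tab$confidence > 0]))
    if (length(mm) == 1L) as.integer(mm) else NA_integer_
  } else NA_integer_
  out <- data.frame(node_a = pairs$node_a, node_b = pairs$node_b,
                    confidence = tab$confidence,
                    count_ab = count_ab, count_ba = count_ba,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "nodes") <- nodes
  class(out) <- c("edge_strength", "data.frame")
  out
}
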