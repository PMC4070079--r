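# Greedy hill climbing in DAG space under the BDeu score.
#
# Search starts from the empty graph and repeatedly applies the single-edge
# addition, deletion or reversal with the largest strictly positive score
# improvement, subject to acyclicity (and an optional parent-count cap),
# stopping when no move improves the score.  Family scores are cached on
# (child, sorted parent set), so each candidate move costs two cache
# lookups once its families have been scored.  Ties in the score delta are
# broken by canonical move order: edges in lexicographic (from, to) order,
# and addition before deletion before reversal; together with the cache
# this makes the search fully deterministic.

hc_state_score <- function(enc, parents_idx, ess, cache) {
  total <- 0
  for (ci in seq_along(parents_idx))
    total <- total + hc_family(enc, ci, parents_idx[[ci]], ess, cache)
  total
}

hc_family <- function(enc, ci, pa, ess, cache) {
  key <- paste0(ci, "|", paste(sort(pa), collapse = ","))
  val <- cache[[key]]
  if (is.null(val)) {
    val <- family_score_enc(enc, ci, pa, ess)
    cache[[key]] <- val
  }
  val
}

# descendant reachability matrix (TRUE if row-node reaches col-node)
hc_reach <- function(parents_idx) {
  n <- length(parents_idx)
  adj <- matrix(FALSE, n, n)
  for (v in seq_len(n))
    adj[parents_idx[[v]], v] <- TRUE
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

#' Learn a network structure by hill climbing with the BDeu score
#'
#' @param data complete categorical data frame with at least two columns.
#' @param ess BDeu equivalent sample size (default 10).
#' @param max_parents cap on the number of parents per node (default
#'   unbounded).
#' @param max_iter cap on the number of applied moves (default unbounded);
#'   `max_iter = 0` returns the empty graph.
#' @param restarts number of additional greedy runs from random starting
#'   DAGs; the best-scoring final structure is kept (default 0, a single
#'   run from the empty graph).
#' @param seed optional integer seed; only consumed when `restarts > 0`,
#'   since the base search is deterministic.
#' @return A `bn_graph` over the data's columns; always acyclic.
#' @examples
#' net <- random_network(4, avg_neighbours = 1.5, seed = 7,
#'                       cpt_concentration = 0.4)
#' x <- forward_sample(net, 500, seed = 7)
#' hill_climb(x)
#' @export
hill_climb <- function(data, ess = 10, max_parents = Inf, max_iter = Inf,
                       restarts = 0L, seed = NULL) {
  enc <- encode_dataset(data)
  if (length(enc$nodes) < 2L)
    stop("structure learning needs at least two variables", call. = FALSE)
  if (!is.numeric(ess) || length(ess) != 1L || ess <= 0)
    stop("'ess' must be a positive number", call. = FALSE)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  nn <- length(enc$nodes)
  empty <- rep(list(integer(0L)), nn)

  runs <- list(empty)
  if (restarts > 0L) {
    seeds <- derive_seeds(seed, restarts)
    for (s in seeds)
      runs <- c(runs, list(with_seed(s, {
        ord <- sample.int(nn)
        st <- rep(list(integer(0L)), nn)
        idx <- utils::combn(nn, 2L)
        keep <- which(stats::runif(ncol(idx)) < 1 / (nn - 1L))
        for (j in keep) {
          child <- ord[idx[2L, j]]
          if (length(st[[child]]) < max_parents)
            st[[child]] <- c(st[[child]], ord[idx[1L, j]])
        }
        st
      })))
  }

  best <- NULL
  best_score <- -Inf
  for (start in runs) {
    res <- hc_run(enc, start, ess, max_parents, max_iter, cache)
    if (res$score > best_score + 1e-12) {
      best <- res$parents
      best_score <- res$score
    }
  }

  edges <- do.call(rbind, lapply(seq_len(nn), function(v)
    if (length(best[[v]]))
      cbind(enc$nodes[best[[v]]], enc$nodes[v])
    else NULL))
  bn_graph(enc$nodes, edges)
}

hc_run <- function(enc, parents_idx, ess, max_parents, max_iter, cache) {
  nn <- length(enc$nodes)
  # candidate ordered pairs in canonical lexicographic (from, to) name order
  ord <- order(enc$nodes)
  pairs <- do.call(rbind, lapply(ord, function(u)
    cbind(u, ord[ord != u])))
  score <- hc_state_score(enc, parents_idx, ess, cache)
  iter <- 0L
  while (iter < max_iter) {
    reach <- hc_reach(parents_idx)
    best_delta <- 0
    best_move <- NULL
    for (i in seq_len(nrow(pairs))) {
      u <- pairs[i, 1L]; v <- pairs[i, 2L]
      has_uv <- u %in% parents_idx[[v]]
      has_vu <- v %in% parents_idx[[u]]
      old_v <- hc_family(enc, v, parents_idx[[v]], ess, cache)
      if (!has_uv && !has_vu) {
        # addition u -> v: forbidden if v already reaches u
        if (length(parents_idx[[v]]) < max_parents && !reach[v, u]) {
          delta <- hc_family(enc, v, c(parents_idx[[v]], u), ess, cache) - old_v
          if (delta > best_delta) {
            best_delta <- delta
            best_move <- list(op = "add", u = u, v = v)
          }
        }
      } else if (has_uv) {
        drop_v <- hc_family(enc, v, setdiff(parents_idx[[v]], u), ess,
                            cache) - old_v
        if (drop_v > best_delta) {
          best_delta <- drop_v
          best_move <- list(op = "del", u = u, v = v)
        }
        # reversal u -> v  ==>  v -> u: forbidden if removing u -> v still
        # leaves a path u ~> v (then adding v -> u closes a cycle)
        if (length(parents_idx[[u]]) < max_parents) {
          tmp <- parents_idx
          tmp[[v]] <- setdiff(tmp[[v]], u)
          if (!hc_reach(tmp)[u, v]) {
            delta <- drop_v +
              hc_family(enc, u, c(parents_idx[[u]], v), ess, cache) -
              hc_family(enc, u, parents_idx[[u]], ess, cache)
            if (delta > best_delta) {
              best_delta <- delta
              best_move <- list(op = "rev", u = u, v = v)
            }
          }
        }
      }
    }
    if (is.null(best_move)) break
    u <- best_move$u; v <- best_move$v
    if (best_move$op == "add") {
      parents_idx[[v]] <- c(parents_idx[[v]], u)
    } else if (best_move$op == "del") {
      parents_idx[[v]] <- setdiff(parents_idx[[v]], u)
    } else {
      parents_idx[[v]] <- setdiff(parents_idx[[v]], u)
      parents_idx[[u]] <- c(parents_idx[[u]], v)
    }
    score <- score + best_delta
    iter <- iter + 1L
  }
  list(parents = parents_idx, score = score)
}

#' Hill-climbing learner factory
#'
#' Wraps [hill_climb()] into the learner interface used by
#' [bootstrap_confidences()] and [noise_floor()]: a function taking
#' `(data, seed)` and returning an acyclic `bn_graph` over the data's
#' columns.  Any function with this signature and contract can be used in
#' its place, so the averaging and thresholding machinery is agnostic to
#' the structure-learning algorithm.
#'
#' @param ess,max_parents,max_iter,restarts passed on to [hill_climb()].
#' @return A function `(data, seed) -> bn_graph`.
#' @export
hc_learner <- function(ess = 10, max_parents = Inf, max_iter = Inf,
                       restarts = 0L) {
  function(data, seed = NULL)
    hill_climb(data, ess = ess, max_parents = max_parents,
               max_iter = max_iter, restarts = restarts, seed = seed)
}
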