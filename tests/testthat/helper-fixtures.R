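# Shared fixtures: tiny networks, learner stubs and the worked-example
# confidence vector used across the threshold tests.

example1_confidences <- c(AB = 0.2242, AC = 0.0460, AD = 0.8935,
                          BC = 0.3921, BD = 0.7689, CD = 0.9439)

example1_strength <- function() {
  read_strength(system.file("extdata", "example1_strength.tsv",
                            package = "bnstrength"))
}

# two binary nodes A -> B; `dep` controls how strongly B follows A
ab_net <- function(p_a = 0.3, dep = 0.9) {
  discrete_bn(
    variables = list(A = c("a1", "a2"), B = c("b1", "b2")),
    edges = rbind(c("A", "B")),
    cpts = list(
      A = c(a1 = p_a, a2 = 1 - p_a),
      B = matrix(c(dep, 1 - dep, 1 - dep, dep), nrow = 2,
                 dimnames = list(c("b1", "b2"), c("a1", "a2")))))
}

# binary chain V1 -> V2 -> ... -> Vk
chain_net <- function(k, dep = 0.85) {
  vars <- stats::setNames(rep(list(c("l1", "l2")), k),
                          sprintf("V%02d", seq_len(k)))
  edges <- if (k > 1L)
    cbind(sprintf("V%02d", seq_len(k - 1L)), sprintf("V%02d", 2:k))
  else NULL
  cpts <- list(V01 = c(l1 = 0.5, l2 = 0.5))
  if (k > 1L)
    for (i in 2:k)
      cpts[[sprintf("V%02d", i)]] <-
        matrix(c(dep, 1 - dep, 1 - dep, dep), nrow = 2,
               dimnames = list(c("l1", "l2"), c("l1", "l2")))
  discrete_bn(vars, edges, cpts)
}

# learner stubs satisfying the (data, seed) -> bn_graph contract
fixed_graph_learner <- function(graph) function(data, seed = NULL) graph
empty_graph_learner <- function(data, seed = NULL) bn_graph(names(data))

# dataset of mutually independent uniform categorical columns
independent_data <- function(n, ncol = 2L, nlev = 2L, seed = 1L) {
  withr::with_seed(seed, {
    out <- lapply(seq_len(ncol), function(j)
      factor(sample(paste0("l", seq_len(nlev)), n, replace = TRUE),
             levels = paste0("l", seq_len(nlev))))
    names(out) <- sprintf("X%02d", seq_len(ncol))
    as.data.frame(out)
  })
}

# edge_strength table from a named confidence vector (names like "AB")
strength_from_vector <- function(conf, m = 10000L) {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(node_a = substr(names(conf), 1L, 1L),
                    node_b = substr(names(conf), 2L, 2L),
                    confidence = as.numeric(conf))
  tab <- tab[order(tab$node_a, tab$node_b), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_strength(path)
}

# all DAGs on `nodes` enumerated as {absent, a->b, b->a} per unordered pair
enumerate_dags <- function(nodes) {
  pairs <- utils::combn(nodes, 2L)
  np <- ncol(pairs)
  states <- expand.grid(rep(list(0:2), np))
  out <- list()
  for (i in seq_len(nrow(states))) {
    e <- NULL
    for (j in seq_len(np)) {
      s <- states[i, j]
      if (s == 1L) e <- rbind(e, c(pairs[1L, j], pairs[2L, j]))
      if (s == 2L) e <- rbind(e, c(pairs[2L, j], pairs[1L, j]))
    }
    g <- bn_graph(nodes, e)
    if (bnstrength:::is_acyclic(g))
      out[[length(out) + 1L]] <- g
  }
  out
}

# equivalence-class key: skeleton plus v-structures
cpdag_key <- function(graph) {
  sk <- skeleton(graph)
  sk_key <- paste(sk$node_a, sk$node_b, sep = "-", collapse = ";")
  adj <- paste(c(sk$node_a, sk$node_b), c(sk$node_b, sk$node_a))
  pa <- bnstrength:::graph_parents(graph)
  vs <- character(0L)
  for (v in graph$nodes) {
    ps <- sort(pa[[v]])
    if (length(ps) < 2L) next
    cmb <- utils::combn(ps, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      if (!paste(a, b) %in% adj)
        vs <- c(vs, paste(a, b, v, sep = ">"))
    }
  }
  paste(sk_key, paste(sort(vs), collapse = ";"), sep = "|")
}
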