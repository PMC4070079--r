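# Internal helpers: seeding, canonical node pairs, small validators.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  seed = NULL runs `code` on the
# current stream (still advancing it), so unseeded calls remain stochastic.
with_seed <- function(seed, code) {
  if (is.null(seed))
    return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic stream splitting: one master seed yields `n` replicate seeds
# (without replacement, so replicates never share a stream).  Replicates can
# then run in any order -- or concurrently -- with identical results.
derive_seeds <- function(seed, n) {
  if (n == 0L)
    return(integer(0L))
  with_seed(seed, sample.int(2147483646L, n))
}

# All unordered node pairs in canonical (lexicographic) order.
canonical_pairs <- function(nodes) {
  nodes <- sort(as.character(nodes))
  n <- length(nodes)
  if (n < 2L)
    return(data.frame(node_a = character(0L), node_b = character(0L),
                      stringsAsFactors = FALSE))
  idx <- utils::combn(n, 2L)
  data.frame(node_a = nodes[idx[1L, ]], node_b = nodes[idx[2L, ]],
             stringsAsFactors = FALSE)
}

# Canonicalise a two-column pair table: node_a < node_b, rows sorted, unique.
canonicalise_pairs <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L)
    stop("pair table must have two columns", call. = FALSE)
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- unique(data.frame(node_a = a, node_b = b, stringsAsFactors = FALSE))
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

pair_key <- function(a, b) paste(a, b, sep = "\r")

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != floor(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
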