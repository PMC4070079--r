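# Threshold estimation.
#
# With a consistent learner and unlimited data, every bootstrap replicate
# would learn the same structure, and the vector of sorted edge confidences
# would be the ideal configuration {0, ..., 0, 1, ..., 1}: its CDF is a
# one-step function equal to t on [0, 1) -- t being the fraction of
# non-significant edges.  At finite sample sizes the observed CDF is a
# staircase between those extremes.  The estimator picks the t whose
# one-step CDF is closest to the observed staircase in L1 distance; because
# both CDFs are piecewise constant the distance is a finite weighted sum of
# |F(x_i) - t| terms, convex piecewise-linear in t, and its exact minimiser
# is a weighted median of the staircase plateau values with weights equal
# to the plateau widths.  The estimated t is then converted into a
# confidence cut-off through the quantile function of the observed CDF, and
# an edge is significant when its confidence strictly exceeds the cut-off.

confidence_vector <- function(x) {
  if (inherits(x, "edge_strength"))
    x <- x$confidence
  x <- as.numeric(x)
  if (length(x) == 0L)
    stop("need at least one confidence value", call. = FALSE)
  if (anyNA(x) || any(x < 0 | x > 1))
    stop("confidences must lie in [0, 1]", call. = FALSE)
  x
}

#' Empirical CDF of edge confidences
#'
#' Sorts the confidences into their order statistic and summarises the
#' right-continuous empirical CDF as jump points (the distinct confidence
#' values) and plateau values (multiples of `1/k` ending at 1).
#'
#' @param confidences numeric vector of `k >= 1` values in `[0, 1]`, or an
#'   `edge_strength` table.
#' @return An object of class `confidence_cdf`: list with `jumps`,
#'   `plateaus` and `k`.
#' @examples
#' empirical_cdf(c(0.2242, 0.0460, 0.8935, 0.3921, 0.7689, 0.9439))
#' @export
empirical_cdf <- function(confidences) {
  x <- sort(confidence_vector(confidences))
  k <- length(x)
  jumps <- unique(x)
  counts <- tabulate(match(x, jumps), length(jumps))
  structure(list(jumps = jumps, plateaus = cumsum(counts) / k, k = k),
            class = "confidence_cdf")
}

#' @export
print.confidence_cdf <- function(x, ...) {
  cat(sprintf("Empirical CDF of %d edge confidences (%d jump points)\n",
              x$k, length(x$jumps)))
  print(data.frame(jump = x$jumps, F = x$plateaus), ...)
  invisible(x)
}

# step-function segments of the CDF on [0, 1]: values and widths
cdf_segments <- function(cdf) {
  xs <- c(0, cdf$jumps, 1)
  list(values = c(0, cdf$plateaus), widths = diff(xs))
}

#' Distance between the empirical CDF and the ideal one-step CDF
#'
#' `l1_distance()` evaluates the L1 distance between the empirical CDF of
#' the confidences and the ideal one-step CDF with non-significant fraction
#' `t`.  Both CDFs are step functions, so the integral reduces to a
#' weighted sum of `|F(x_i) - t|` over the constant segments of the
#' empirical CDF, computable in linear time.  `cdf_distance()` additionally
#' offers the L2 distance (integrated squared difference) and the
#' L-infinity distance (maximum absolute difference); L1 is the default
#' everywhere because it does not inflate large deviations.
#'
#' @param t numeric vector of candidate thresholds in `[0, 1]` (vectorised).
#' @param cdf a `confidence_cdf` from [empirical_cdf()].
#' @param norm one of `"L1"`, `"L2"`, `"Linf"`.
#' @return Numeric vector of distances, one per element of `t`.
#' @export
l1_distance <- function(t, cdf) cdf_distance(t, cdf, norm = "L1")

#' @rdname l1_distance
#' @export
cdf_distance <- function(t, cdf, norm = c("L1", "L2", "Linf")) {
  norm <- match.arg(norm)
  if (!inherits(cdf, "confidence_cdf"))
    stop("'cdf' must be a confidence_cdf", call. = FALSE)
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0 | t > 1))
    stop("'t' must lie in [0, 1]", call. = FALSE)
  seg <- cdf_segments(cdf)
  f <- seg$values
  w <- seg$widths
  if (norm == "L2")   # quadratic in t: sum w f^2 - 2 t sum w f + t^2
    return(sum(w * f^2) - 2 * t * sum(w * f) + t^2 * sum(w))
  if (norm == "Linf") {
    fv <- f[w > 0]
    return(pmax(t - min(fv), max(fv) - t))
  }
  # L1, vectorised over t: split the sum at the position of t among the
  # (sorted) segment values using cumulative weights
  cw <- cumsum(w)
  cwf <- cumsum(w * f)
  tot_w <- cw[length(cw)]
  tot_wf <- cwf[length(cwf)]
  idx <- findInterval(t, f)
  below_w <- c(0, cw)[idx + 1L]
  below_wf <- c(0, cwf)[idx + 1L]
  (t * below_w - below_wf) + (tot_wf - below_wf) - t * (tot_w - below_w)
}

#' Quantile function of a confidence CDF
#'
#' The generalised inverse `inf { x : F(x) >= t }` of the right-continuous
#' empirical CDF.  For `t = 0` every real satisfies the condition; 0 is
#' returned by convention (confidences live in `[0, 1]`).
#'
#' @param cdf a `confidence_cdf`.
#' @param t a probability in `[0, 1]`.
#' @return The smallest jump point whose plateau reaches `t`.
#' @export
cdf_quantile <- function(cdf, t) {
  if (!inherits(cdf, "confidence_cdf"))
    stop("'cdf' must be a confidence_cdf", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("'t' must be a single value in [0, 1]", call. = FALSE)
  if (t <= 0)
    return(0)
  cdf$jumps[which(cdf$plateaus >= t - 1e-12)[1L]]
}

#' Estimate the significance threshold for edge confidences
#'
#' Finds the fraction `t` of non-significant edges whose ideal one-step CDF
#' is closest to the empirical CDF of the observed confidences, then turns
#' it into a confidence cut-off via the quantile function.  Under the
#' default L1 norm the objective is convex piecewise-linear and the exact
#' minimiser is the weighted median of the empirical-CDF plateau values
#' weighted by plateau widths; when the minimum is attained on a flat
#' interval its midpoint is returned.  The L2 minimiser is the
#' width-weighted mean of the plateau values, and the L-infinity minimiser
#' the midrange; both are provided for comparison only.
#'
#' @param confidences numeric vector of confidences in `[0, 1]`, or an
#'   `edge_strength` table from [bootstrap_confidences()] /
#'   [read_strength()].
#' @param norm distance used, `"L1"` (default), `"L2"` or `"Linf"`.
#' @return An object of class `threshold_result`: list with `t_hat`, the
#'   confidence cut-off `cutoff` (edges with confidence strictly above it
#'   are significant), `min_significant` (smallest significant confidence,
#'   `NA` if none), `objective` (distance at the optimum), `norm`, `k` and
#'   the `confidence_cdf` used.
#' @examples
#' p_hat <- c(AB = 0.2242, AC = 0.0460, AD = 0.8935,
#'            BC = 0.3921, BD = 0.7689, CD = 0.9439)
#' estimate_threshold(p_hat)
#' @export
estimate_threshold <- function(confidences, norm = c("L1", "L2", "Linf")) {
  norm <- match.arg(norm)
  x <- confidence_vector(confidences)
  cdf <- empirical_cdf(x)
  seg <- cdf_segments(cdf)
  f <- seg$values
  w <- seg$widths
  if (norm == "L1") {
    # weighted median of f with weights w (total weight is exactly 1)
    cw <- cumsum(w)
    i <- which(cw >= 0.5 - 1e-12)[1L]
    t_hat <- if (abs(cw[i] - 0.5) <= 1e-12 && i < length(f))
      (f[i] + f[i + 1L]) / 2            # flat optimum: midpoint convention
    else
      f[i]
  } else if (norm == "L2") {
    t_hat <- sum(w * f)
  } else {
    fv <- f[w > 0]
    t_hat <- (min(fv) + max(fv)) / 2
  }
  t_hat <- min(max(t_hat, 0), 1)
  cutoff <- cdf_quantile(cdf, t_hat)
  sig <- x[x > cutoff]
  structure(list(t_hat = t_hat,
                 cutoff = cutoff,
                 min_significant = if (length(sig)) min(sig) else NA_real_,
                 objective = cdf_distance(t_hat, cdf, norm),
                 norm = norm,
                 k = cdf$k,
                 cdf = cdf),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Estimated significance threshold (%s norm, k = %d pairs)\n",
              x$norm, x$k))
  cat(sprintf("  t_hat   = %.7g  (estimated fraction of non-significant edges)\n",
              x$t_hat))
  cat(sprintf("  cutoff  = %.7g  (edges significant iff confidence > cutoff)\n",
              x$cutoff))
  if (!is.na(x$min_significant))
    cat(sprintf("  minimum significant confidence = %.7g\n", x$min_significant))
  else
    cat("  no significant edges\n")
  invisible(x)
}

#' Select the significant edges given an estimated threshold
#'
#' Applies the strict selection rule: a pair is significant exactly when
#' its confidence is strictly greater than the estimated cut-off
#' (equivalently, at least `min_significant`).
#'
#' @param conf an `edge_strength` table.
#' @param result a `threshold_result` computed from the same confidences.
#' @return Canonical pair table (`node_a`, `node_b`) of significant edges.
#' @export
select_significant <- function(conf, result) {
  if (!inherits(conf, "edge_strength"))
    stop("'conf' must be an edge_strength", call. = FALSE)
  if (!inherits(result, "threshold_result"))
    stop("'result' must be a threshold_result", call. = FALSE)
  if (nrow(conf) != result$k)
    stop("'result' was not computed from this confidence table", call. = FALSE)
  keep <- conf$confidence > result$cutoff
  data.frame(node_a = conf$node_a[keep], node_b = conf$node_b[keep],
             stringsAsFactors = FALSE)
}

#' Build the averaged network from the significant edges
#'
#' Each significant pair is oriented along the direction observed more
#' often among the bootstrap-learned structures; pairs whose two direction
#' counts tie (or are unavailable) are flagged undirected.
#'
#' @param conf an `edge_strength` table carrying direction counts.
#' @param significant pair table of significant edges, a subset of `conf`'s
#'   pairs (e.g. from [select_significant()]).
#' @return An object of class `averaged_network`: list with `nodes` and an
#'   `edges` data frame (`from`, `to`, `undirected`); undirected rows keep
#'   the canonical pair order.
#' @export
build_averaged_network <- function(conf, significant) {
  if (!inherits(conf, "edge_strength"))
    stop("'conf' must be an edge_strength", call. = FALSE)
  significant <- canonicalise_pairs(significant)
  key_all <- pair_key(conf$node_a, conf$node_b)
  key_sig <- pair_key(significant$node_a, significant$node_b)
  idx <- match(key_sig, key_all)
  if (anyNA(idx))
    stop("'significant' contains pairs outside the confidence table",
         call. = FALSE)
  from <- character(0L); to <- character(0L); undirected <- logical(0L)
  for (j in idx) {
    ab <- conf$count_ab[j]; ba <- conf$count_ba[j]
    if (is.na(ab) || is.na(ba) || ab == ba) {
      from <- c(from, conf$node_a[j]); to <- c(to, conf$node_b[j])
      undirected <- c(undirected, TRUE)
    } else if (ab > ba) {
      from <- c(from, conf$node_a[j]); to <- c(to, conf$node_b[j])
      undirected <- c(undirected, FALSE)
    } else {
      from <- c(from, conf$node_b[j]); to <- c(to, conf$node_a[j])
      undirected <- c(undirected, FALSE)
    }
  }
  structure(list(nodes = attr(conf, "nodes") %||%
                   sort(unique(c(conf$node_a, conf$node_b))),
                 edges = data.frame(from = from, to = to,
                                    undirected = undirected,
                                    stringsAsFactors = FALSE)),
            class = "averaged_network")
}

#' @export
print.averaged_network <- function(x, ...) {
  cat(sprintf("Averaged network: %d nodes, %d significant edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    arrow <- ifelse(x$edges$undirected, "--", "->")
    cat(" ", paste(sprintf("%s %s %s", x$edges$from, arrow, x$edges$to),
                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a JSON significance report
#'
#' Serialises a threshold estimate together with the selected edges and
#' their majority orientations.
#'
#' @param conf an `edge_strength` table.
#' @param result a `threshold_result` computed from it.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_threshold_report <- function(conf, result, path) {
  significant <- select_significant(conf, result)
  avg <- build_averaged_network(conf, significant)
  report <- list(
    t_hat = result$t_hat,
    cutoff = result$cutoff,
    min_significant = result$min_significant,
    objective = result$objective,
    norm = result$norm,
    k = result$k,
    m = attr(conf, "m"),
    significant_edges = unname(apply(significant, 1L, as.list)),
    directions = if (nrow(avg$edges))
      lapply(seq_len(nrow(avg$edges)), function(i)
        list(from = avg$edges$from[i], to = avg$edges$to[i],
             undirected = avg$edges$undirected[i]))
    else list())
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Export an averaged network to Graphviz DOT
#'
#' @param net an `averaged_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(net, path) {
  if (!inherits(net, "averaged_network"))
    stop("'net' must be an averaged_network", call. = FALSE)
  lines <- c("digraph averaged {",
             sprintf("  \"%s\";", net$nodes))
  if (nrow(net$edges)) {
    e <- net$edges
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;", e$from, e$to,
                              ifelse(e$undirected, " [dir=none]", "")))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
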