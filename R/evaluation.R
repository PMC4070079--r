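#' Structure-recovery metrics against a known skeleton
#'
#' Compares a set of selected (significant) pairs with the skeleton of the
#' true network, ignoring edge directions.  Over the `k = N(N-1)/2`
#' possible pairs: sensitivity is the proportion of true edges recovered,
#' specificity the proportion of true non-edges rejected, and accuracy the
#' proportion of correct decisions.
#'
#' @param true_net the generating `dbn` (or a `bn_graph`) whose skeleton is
#'   ground truth.
#' @param selected pair table (`node_a`, `node_b`) of edges deemed
#'   significant; any two-column form is accepted and canonicalised.
#' @return A list of class `skeleton_metrics` with counts `tp`, `fp`, `tn`,
#'   `fn`, the ratios `sensitivity`, `specificity`, `accuracy`, and `k`.
#' @examples
#' net <- random_network(5, avg_neighbours = 1.5, seed = 3)
#' skeleton_metrics(net, skeleton(net))  # perfect recovery
#' @export
skeleton_metrics <- function(true_net, selected) {
  nodes <- if (inherits(true_net, "dbn")) names(true_net) else true_net$nodes
  truth <- skeleton(true_net)
  selected <- canonicalise_pairs(selected)
  if (!all(c(selected$node_a, selected$node_b) %in% nodes))
    stop("selected pairs contain unknown node names", call. = FALSE)
  k <- possible_edge_count(length(nodes))
  key_true <- pair_key(truth$node_a, truth$node_b)
  key_sel <- pair_key(selected$node_a, selected$node_b)
  tp <- sum(key_sel %in% key_true)
  fp <- length(key_sel) - tp
  fn <- length(key_true) - tp
  tn <- k - tp - fp - fn
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, k = k,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else 1,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 1,
    accuracy = (tp + tn) / k), class = "skeleton_metrics")
}

#' @export
print.skeleton_metrics <- function(x, ...) {
  cat(sprintf(
    "Skeleton recovery over %d pairs: tp %d, fp %d, tn %d, fn %d\n",
    x$k, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

# one metrics row for the tidy simulation output (first formal deliberately
# not a prefix of any column name, to dodge partial matching from ...)
metrics_row <- function(counts, ...) {
  data.frame(..., t_hat = NA_real_, tp = counts$tp, fp = counts$fp,
             tn = counts$tn, fn = counts$fn, sensitivity = counts$sensitivity,
             specificity = counts$specificity, accuracy = counts$accuracy,
             stringsAsFactors = FALSE)
}

#' Simulation study: estimated versus ad hoc thresholds
#'
#' Replicates the structure-recovery protocol at desk scale: for each
#' sample size and replicate, forward-sample a dataset from the fixture
#' network, estimate bootstrap edge confidences with hill climbing + BDeu,
#' apply both the estimated threshold and a set of ad hoc confidence
#' thresholds, and score each selection against the fixture's skeleton.
#' Ad hoc policies select pairs with confidence strictly greater than the
#' stated value; the estimated policy thresholds through the quantile rule.
#'
#' @param fixture a valid `dbn`, the generating network.
#' @param sizes vector of sample sizes to draw.
#' @param m bootstrap replicates per dataset (default 100).
#' @param reps independent repetitions per sample size (default 10).
#' @param ad_hoc ad hoc confidence thresholds to compare against
#'   (default `c(0.70, 0.80, 0.90, 0.95)`).
#' @param ess BDeu equivalent sample size (default 10).
#' @param seed optional integer master seed; every cell records the derived
#'   seeds it used, so any row is reproducible in isolation.
#' @return A tidy data frame with one row per (size, replicate, policy):
#'   columns `n`, `n_over_p`, `m`, `rep`, `seed_data`, `seed_boot`,
#'   `policy`, `t_hat`, the four counts and the three ratios.
#' @seealso [summarise_simulation()] for per-cell means and normal 95%
#'   confidence intervals.
#' @export
run_simulation <- function(fixture, sizes, m = 100L, reps = 10L,
                           ad_hoc = c(0.70, 0.80, 0.90, 0.95),
                           ess = 10, seed = NULL) {
  assert_valid_network(fixture)
  if (length(sizes) == 0L)
    stop("'sizes' must be non-empty", call. = FALSE)
  m <- stopifnot_scalar_count(m, "m", min = 1L)
  reps <- stopifnot_scalar_count(reps, "reps", min = 1L)
  p <- param_count(fixture)
  learner <- hc_learner(ess = ess)
  cells <- expand.grid(rep = seq_len(reps), n = as.integer(sizes))
  seeds <- matrix(derive_seeds(seed, 2L * nrow(cells)), ncol = 2L)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    n <- cells$n[i]
    x <- forward_sample(fixture, n, seed = seeds[i, 1L])
    conf <- bootstrap_confidences(x, learner, m = m, seed = seeds[i, 2L])
    thr <- estimate_threshold(conf)
    rows <- list(metrics_row(
      skeleton_metrics(fixture, select_significant(conf, thr)),
      n = n, n_over_p = n / p, m = m, rep = cells$rep[i],
      seed_data = seeds[i, 1L], seed_boot = seeds[i, 2L],
      policy = "estimated"))
    rows[[1L]]$t_hat <- thr$t_hat
    for (t0 in ad_hoc) {
      sel <- conf[conf$confidence > t0, c("node_a", "node_b"), drop = FALSE]
      rows <- c(rows, list(metrics_row(
        skeleton_metrics(fixture, sel),
        n = n, n_over_p = n / p, m = m, rep = cells$rep[i],
        seed_data = seeds[i, 1L], seed_boot = seeds[i, 2L],
        policy = sprintf("t=%.2f", t0))))
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate a simulation into per-cell means and 95% intervals
#'
#' @param results the tidy data frame from [run_simulation()].
#' @return One row per (n, policy) with the mean and a normal-approximation
#'   95% confidence interval for sensitivity, specificity and accuracy, and
#'   the mean `t_hat` where the policy estimates one.
#' @export
summarise_simulation <- function(results) {
  cells <- unique(results[, c("n", "policy")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- results[results$n == cells$n[i] & results$policy == cells$policy[i], ]
    ci <- function(v) {
      mu <- mean(v)
      half <- stats::qnorm(0.975) * stats::sd(v) / sqrt(length(v))
      c(mu, mu - half, mu + half)
    }
    se <- ci(sub$sensitivity); sp <- ci(sub$specificity); ac <- ci(sub$accuracy)
    data.frame(n = cells$n[i], n_over_p = sub$n_over_p[1L],
               policy = cells$policy[i], reps = nrow(sub),
               sensitivity = se[1L], sensitivity_lo = se[2L],
               sensitivity_hi = se[3L],
               specificity = sp[1L], specificity_lo = sp[2L],
               specificity_hi = sp[3L],
               accuracy = ac[1L], accuracy_lo = ac[2L], accuracy_hi = ac[3L],
               t_hat = mean(sub$t_hat), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot recovery metrics against log(n/p)
#'
#' Draws mean sensitivity, specificity and accuracy (with their intervals)
#' per threshold policy against the log of the sample-to-parameter ratio.
#' Requires ggplot2.
#'
#' @param summary the data frame from [summarise_simulation()].
#' @return A ggplot object.
#' @export
plot_simulation <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_simulation() requires the ggplot2 package", call. = FALSE)
  long <- do.call(rbind, lapply(c("sensitivity", "specificity", "accuracy"),
    function(metric) data.frame(
      n_over_p = summary$n_over_p, policy = summary$policy, metric = metric,
      value = summary[[metric]], lo = summary[[paste0(metric, "_lo")]],
      hi = summary[[paste0(metric, "_hi")]], stringsAsFactors = FALSE)))
  ggplot2::ggplot(long, ggplot2::aes(x = log(n_over_p), y = value,
                                     colour = policy)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = lo, ymax = hi),
                             size = 0.3) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "log(n/p)", y = NULL, colour = "threshold") +
    ggplot2::theme_minimal()
}
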