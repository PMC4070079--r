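test_that("empirical_cdf reproduces the worked-example staircase", {
  cdf <- empirical_cdf(example1_confidences)
  expect_identical(cdf$jumps,
                   c(0.0460, 0.2242, 0.3921, 0.7689, 0.8935, 0.9439))
  expect_equal(cdf$plateaus, (1:6) / 6)
  expect_identical(cdf$k, 6L)

  same <- empirical_cdf(rep(0.4, 5))
  expect_identical(same$jumps, 0.4)
  expect_identical(same$plateaus, 1)
  expect_identical(same$k, 5L)

  binary <- empirical_cdf(c(0, 1))
  expect_identical(binary$jumps, c(0, 1))
  expect_equal(binary$plateaus, c(0.5, 1))

  expect_error(empirical_cdf(c(0.2, 1.2)), "\\[0, 1\\]")
  expect_error(empirical_cdf(numeric(0)), "at least one")
})

test_that("l1_distance matches the segment sum and a numerical integration oracle", {
  cdf <- empirical_cdf(example1_confidences)
  expect_equal(l1_distance(0, cdf), 1 - mean(example1_confidences),
               tolerance = 1e-12)
  expect_equal(l1_distance(0.5, cdf), 0.1760, tolerance = 1e-4)

  # midpoint-rule integration of the |F - F_ideal| area
  riemann <- function(t, cdf, cells = 1e6) {
    xm <- (seq_len(cells) - 0.5) / cells
    f <- c(0, cdf$plateaus)[findInterval(xm, cdf$jumps) + 1L]
    mean(abs(f - t))
  }
  withr::with_seed(101, {
    for (i in 1:20) {
      k <- sample(3:200, 1)
      x <- round(runif(k), sample(c(1, 2, 6), 1))
      cdf_i <- empirical_cdf(x)
      t <- runif(1)
      expect_equal(l1_distance(t, cdf_i), riemann(t, cdf_i), tolerance = 1e-6)
      expect_equal(l1_distance(1, cdf_i), riemann(1, cdf_i), tolerance = 1e-6)
    }
  })
})

test_that("the L1 minimiser is a weighted median beating any grid value", {
  grid <- seq(0, 1, by = 1e-4)
  withr::with_seed(33, {
    for (i in 1:50) {
      k <- sample(3:300, 1)
      x <- runif(k)
      if (i %% 3 == 0) x <- round(x, 1)        # heavy ties
      res <- estimate_threshold(x)
      cdf <- empirical_cdf(x)
      expect_lte(res$objective, min(l1_distance(grid, cdf)) + 1e-12)
      # convexity of the piecewise-linear objective along the grid
      d2 <- diff(diff(l1_distance(grid, cdf)))
      expect_gt(min(d2), -1e-9)
    }
  })
})

test_that("L2 and Linf minimisers beat their own grid oracles", {
  grid <- seq(0, 1, by = 1e-4)
  withr::with_seed(34, {
    for (i in 1:25) {
      x <- runif(sample(3:200, 1))
      cdf <- empirical_cdf(x)
      for (nrm in c("L2", "Linf")) {
        res <- estimate_threshold(x, norm = nrm)
        expect_lte(res$objective,
                   min(cdf_distance(grid, cdf, nrm)) + 1e-12)
      }
    }
  })
})

test_that("cdf_quantile follows the right-continuous generalised inverse", {
  cdf <- empirical_cdf(example1_confidences)
  expect_identical(cdf_quantile(cdf, 0.5), 0.3921)
  expect_identical(cdf_quantile(cdf, 0), 0)
  expect_identical(cdf_quantile(cdf, 1), 0.9439)
  expect_identical(cdf_quantile(cdf, 1 / 6), 0.0460)
  expect_identical(cdf_quantile(cdf, 0.17), 0.2242)
  expect_error(cdf_quantile(cdf, 1.5), "\\[0, 1\\]")
})

test_that("the worked example yields t_hat = 0.5, cutoff 0.3921 and three edges", {
  conf <- example1_strength()
  res <- estimate_threshold(conf)
  expect_equal(res$t_hat, 0.5, tolerance = 1e-12)
  expect_identical(res$cutoff, 0.3921)
  expect_identical(res$min_significant, 0.7689)
  sel <- select_significant(conf, res)
  expect_identical(sel, data.frame(node_a = c("A", "B", "C"),
                                   node_b = c("D", "D", "D")))
})

test_that("degenerate confidence vectors select all or nothing", {
  all_sig <- estimate_threshold(rep(1, 7))
  expect_identical(all_sig$t_hat, 0)
  expect_identical(all_sig$cutoff, 0)

  none_sig <- estimate_threshold(rep(0, 7))
  expect_identical(none_sig$t_hat, 1)
  expect_true(is.na(none_sig$min_significant))

  conf <- strength_from_vector(c(AB = 1, AC = 1, BC = 1))
  expect_identical(nrow(select_significant(conf, estimate_threshold(conf))), 3L)
  conf0 <- strength_from_vector(c(AB = 0, AC = 0, BC = 0))
  expect_identical(nrow(select_significant(conf0, estimate_threshold(conf0))), 0L)
})

test_that("thresholding the selection indicator is a fixed point", {
  withr::with_seed(55, {
    for (i in 1:20) {
      x <- runif(sample(4:100, 1))^sample(1:3, 1)
      res <- estimate_threshold(x)
      sel <- x > res$cutoff
      indicator <- as.numeric(sel)
      res2 <- estimate_threshold(indicator)
      expect_identical(indicator > res2$cutoff, sel)
    }
  })
})

test_that("raising a significant confidence never expels it (t_hat fixed)", {
  withr::with_seed(77, {
    for (i in 1:50) {
      x <- runif(sample(5:80, 1))
      res <- estimate_threshold(x)
      sig <- which(x > res$cutoff)
      if (length(sig) == 0) next
      j <- sample(sig, 1)
      y <- x
      y[j] <- x[j] + runif(1) * (1 - x[j])
      new_cut <- cdf_quantile(empirical_cdf(y), res$t_hat)
      expect_gt(y[j], new_cut)
    }
  })
})

test_that("the averaged network orients edges by majority and flags ties", {
  x <- independent_data(40, ncol = 4, seed = 1)
  g1 <- bn_graph(sort(names(x)), rbind(c("X01", "X02"), c("X03", "X04")))
  g2 <- bn_graph(sort(names(x)), rbind(c("X01", "X02"), c("X04", "X03")))
  alternating <- local({
    i <- 0L
    function(data, seed = NULL) {
      i <<- i + 1L
      if (i %% 2L == 0L) g1 else g2
    }
  })
  conf <- bootstrap_confidences(x, alternating, m = 4, seed = 2)
  sig <- conf[conf$confidence == 1, c("node_a", "node_b")]
  avg <- build_averaged_network(conf, sig)
  e <- avg$edges
  expect_identical(nrow(e), 2L)
  x12 <- e[e$from == "X01" & e$to == "X02", ]
  expect_false(x12$undirected)
  tie <- e[e$from == "X03", ]
  expect_true(tie$undirected)

  expect_identical(nrow(build_averaged_network(conf,
    conf[0, c("node_a", "node_b")])$edges), 0L)
  expect_error(build_averaged_network(conf,
    data.frame(node_a = "X01", node_b = "X99")), "outside")
})
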