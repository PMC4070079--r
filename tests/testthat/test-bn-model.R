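test_that("validate_network accepts well-formed networks and names each violation", {
  expect_identical(validate_network(ab_net()), character(0L))

  bad <- ab_net()
  bad$B$cpt[, "a2"] <- c(0.5, 0.4)   # row sums to 0.9
  v <- validate_network(bad)
  expect_length(v, 1L)
  expect_match(v, "node 'B'.*configuration 2.*0\\.9")

  cyc <- discrete_bn(
    variables = list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y")),
    edges = rbind(c("A", "B"), c("B", "C"), c("C", "A")), check = FALSE)
  expect_match(validate_network(cyc), "cyclic", all = FALSE)

  dim_bad <- ab_net()
  dim_bad$B$cpt <- matrix(0.5, nrow = 2, ncol = 3)
  expect_match(validate_network(dim_bad), "dimensions", all = FALSE)
})

test_that("param_count follows (r-1) * q per family and matches a brute-force cell count", {
  one <- discrete_bn(list(A = c("x", "y")))
  expect_identical(param_count(one), 1L)

  two_parents <- discrete_bn(
    variables = list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y")),
    edges = rbind(c("A", "C"), c("B", "C")))
  expect_identical(param_count(two_parents), 1L + 1L + 4L)

  expect_identical(param_count(chain_net(10)), 19L)

  # brute force: every CPT cell minus one per row
  net <- random_network(7, avg_neighbours = 2, levels_per_node = 3, seed = 5)
  brute <- sum(vapply(names(net), function(v) {
    cells <- length(net[[v]]$cpt)
    rows <- cells / length(net[[v]]$levels)
    cells - rows
  }, numeric(1L)))
  expect_identical(param_count(net), as.integer(brute))
})

test_that("possible_edge_count equals the number of enumerated unordered pairs", {
  expect_identical(possible_edge_count(1), 0L)
  for (n in c(2L, 3L, 10L, 57L, 100L))
    expect_identical(possible_edge_count(n), ncol(utils::combn(n, 2L)))
  expect_error(possible_edge_count(0), "integer >= 1")
})

test_that("forward_sample is deterministic, honours degenerate CPTs and empty draws", {
  net <- ab_net()
  empty <- forward_sample(net, 0)
  expect_identical(nrow(empty), 0L)
  expect_named(empty, c("A", "B"))
  expect_identical(levels(empty$A), c("a1", "a2"))

  sure <- ab_net(p_a = 1)
  x <- forward_sample(sure, 50, seed = 1)
  expect_true(all(x$A == "a1"))

  expect_identical(forward_sample(net, 200, seed = 9),
                   forward_sample(net, 200, seed = 9))
})

test_that("forward_sample marginals match the CPTs", {
  net <- ab_net(p_a = 0.3)
  n <- 100000L
  x <- forward_sample(net, n, seed = 4)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(x$A == "a1") - 0.3), 3 * se)

  # per-family conditional frequencies: chi-square goodness of fit
  # (moderate CPT rows, so expected counts stay in chi-square territory)
  fix <- random_network(5, avg_neighbours = 1.6, seed = 8,
                        cpt_concentration = 1)
  y <- forward_sample(fix, 50000, seed = 8)
  for (v in names(fix)) {
    pa <- fix[[v]]$parents
    r <- length(fix[[v]]$levels)
    pm <- matrix(as.numeric(fix[[v]]$cpt), nrow = r)
    if (length(pa) == 0L) {
      obs <- table(y[[v]])
      stat <- sum((obs - 50000 * pm[, 1])^2 / (50000 * pm[, 1]))
      df <- r - 1
    } else {
      conf <- interaction(y[pa], drop = FALSE, lex.order = FALSE)
      obs <- table(y[[v]], conf)
      nj <- colSums(obs)
      stat <- 0; df <- 0
      for (j in which(nj > 0)) {
        exp_j <- nj[j] * pm[, j]
        if (min(exp_j) < 5) next
        stat <- stat + sum((obs[, j] - exp_j)^2 / exp_j)
        df <- df + (r - 1)
      }
    }
    if (df > 0)
      expect_lt(stat, stats::qchisq(0.99, df))
  }
})

test_that("random_network hits the requested density on average and is always valid", {
  zero <- random_network(10, avg_neighbours = 0, seed = 1)
  expect_identical(nrow(network_edges(zero)), 0L)

  counts <- vapply(1:50, function(s)
    nrow(network_edges(random_network(10, avg_neighbours = 1.2, seed = s))),
    numeric(1L))
  p <- 1.2 / 9
  se <- sqrt(45 * p * (1 - p) / 50)
  expect_lt(abs(mean(counts) - 6), 3 * se)

  for (s in 1:10)
    expect_identical(validate_network(
      random_network(6, avg_neighbours = 2, levels_per_node = 3, seed = s,
                     cpt_concentration = 0.3)), character(0L))

  expect_error(random_network(5, avg_neighbours = 4), "avg_neighbours")
})

test_that("network files round-trip exactly and parse errors are specific", {
  net <- random_network(4, avg_neighbours = 1.5, levels_per_node = 3,
                        seed = 3)
  path <- withr::local_tempfile(fileext = ".bif")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(names(back), names(net))
  expect_identical(network_edges(back), network_edges(net))
  for (v in names(net)) {
    expect_identical(back[[v]]$levels, net[[v]]$levels)
    expect_identical(back[[v]]$parents, net[[v]]$parents)
    expect_lt(max(abs(back[[v]]$cpt - net[[v]]$cpt)), 1e-9)
  }

  # parser accepts comments and ragged whitespace
  mangled <- withr::local_tempfile(fileext = ".bif")
  txt <- readLines(path)
  txt <- c("// a comment", gsub(") ", ")   \t", txt))
  writeLines(txt, mangled)
  expect_identical(network_edges(read_network(mangled)), network_edges(net))

  empty <- withr::local_tempfile(fileext = ".bif")
  writeLines(character(0L), empty)
  expect_error(read_network(empty), class = "bnstrength_parse_error")

  undeclared <- withr::local_tempfile(fileext = ".bif")
  writeLines(c("network n { }",
               "variable A { type discrete [ 2 ] { x, y }; }",
               "probability ( A | Z ) { ( x ) 0.5, 0.5; }"), undeclared)
  expect_error(read_network(undeclared), class = "bnstrength_undeclared_error")

  arity <- withr::local_tempfile(fileext = ".bif")
  writeLines(c("network n { }",
               "variable A { type discrete [ 2 ] { x, y }; }",
               "probability ( A ) { table 0.2, 0.3, 0.5; }"), arity)
  expect_error(read_network(arity), class = "bnstrength_arity_error")
  expect_error(read_network(arity), "line 3")
})
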