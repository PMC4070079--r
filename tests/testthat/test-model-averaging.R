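test_that("bootstrap_resample draws with replacement, deterministically under a seed", {
  one <- data.frame(A = factor("x", levels = c("x", "y")))
  expect_identical(bootstrap_resample(one, seed = 1), one)

  x <- independent_data(1000, ncol = 2, seed = 1)
  expect_identical(bootstrap_resample(x, seed = 42),
                   bootstrap_resample(x, seed = 42))

  # fraction of original rows absent from a replicate ~ (1 - 1/n)^n -> 1/e
  x$id <- factor(seq_len(nrow(x)))
  absent <- vapply(1:30, function(s) {
    r <- bootstrap_resample(x, seed = s)
    mean(!x$id %in% r$id)
  }, numeric(1L))
  expect_lt(abs(mean(absent) - exp(-1)), 0.01)

  expect_error(bootstrap_resample(independent_data(0)), "empty")
})

test_that("bootstrap confidences are counting ratios with exact seed determinism", {
  x <- independent_data(60, ncol = 4, seed = 2)
  nodes <- sort(names(x))
  g <- bn_graph(nodes, rbind(c("X02", "X01"), c("X03", "X04")))

  conf <- bootstrap_confidences(x, fixed_graph_learner(g), m = 7, seed = 1)
  expect_identical(nrow(conf), possible_edge_count(4))
  on_g <- paste(conf$node_a, conf$node_b) %in% c("X01 X02", "X03 X04")
  expect_true(all(conf$confidence[on_g] == 1))
  expect_true(all(conf$confidence[!on_g] == 0))
  # direction accounting: X02 -> X01 is a count_ba for canonical pair (X01, X02)
  expect_identical(conf$count_ba[conf$node_a == "X01" & conf$node_b == "X02"], 7L)

  zero <- bootstrap_confidences(x, empty_graph_learner, m = 3, seed = 1)
  expect_true(all(zero$confidence == 0))

  hc <- bootstrap_confidences(x, hc_learner(), m = 20, seed = 5)
  expect_true(all(abs(hc$confidence * 20 - round(hc$confidence * 20)) < 1e-12))
  expect_identical(hc$confidence * 20, as.numeric(hc$count_ab + hc$count_ba))
  expect_identical(hc, bootstrap_confidences(x, hc_learner(), m = 20, seed = 5))

  bad_learner <- function(data, seed = NULL) bn_graph(c("foo", "bar"))
  expect_error(bootstrap_confidences(x, bad_learner, m = 2, seed = 1),
               "contract")
})

test_that("replicates can be tallied in any order with the same result", {
  x <- independent_data(80, ncol = 3, seed = 4)
  x$X02 <- x$X01
  m <- 12L
  seeds <- matrix(bnstrength:::derive_seeds(9L, 2L * m), ncol = 2L)
  learner <- hc_learner()
  tally_one <- function(b) {
    g <- learner(bootstrap_resample(x, seeds[b, 1L]), seeds[b, 2L])
    skeleton(g)
  }
  sequential <- lapply(seq_len(m), tally_one)
  shuffled <- lapply(rev(seq_len(m)), tally_one)[m:1]
  expect_identical(sequential, shuffled)

  conf <- bootstrap_confidences(x, learner, m = m, seed = 9)
  counts <- table(unlist(lapply(sequential, function(s)
    paste(s$node_a, s$node_b))))
  for (nm in names(counts)) {
    row <- paste(conf$node_a, conf$node_b) == nm
    expect_identical(conf$confidence[row], as.numeric(counts[[nm]]) / m)
  }
})

test_that("column permutation preserves marginals and the noise floor tracks pure noise", {
  x <- independent_data(200, ncol = 4, seed = 6)
  fl0 <- noise_floor(x, empty_graph_learner, permutations = 5, seed = 1)
  expect_true(all(fl0$floor == 0))
  expect_identical(attr(fl0, "max_floor"), 0)

  marg_learner <- function(data, seed = NULL) {
    # records that permutation left each column's level frequencies intact
    for (v in names(data))
      expect_identical(table(data[[v]]), table(x[[v]]))
    bn_graph(names(data))
  }
  invisible(noise_floor(x, marg_learner, permutations = 3, seed = 2))

  # on independent data, bootstrap confidences and the noise floor see the
  # same thing: noise-only edges.  The bootstrap runs a touch hotter (row
  # duplication mildly inflates apparent dependence), so the comparison is
  # coarse: both low, and close to each other.
  conf <- bootstrap_confidences(x, hc_learner(), m = 30, seed = 3)
  fl <- noise_floor(x, hc_learner(), permutations = 30, seed = 3)
  expect_lt(mean(conf$confidence), 0.4)
  expect_lt(mean(fl$floor), 0.4)
  expect_lt(abs(mean(conf$confidence) - mean(fl$floor)), 0.15)
})

test_that("noise-floor selection uses a strict cut at the maximum floor", {
  conf <- strength_from_vector(c(AB = 0.2, AC = 0.9, BC = 0.0))
  fl <- data.frame(node_a = conf$node_a, node_b = conf$node_b, floor = 0)
  class(fl) <- c("noise_floor", "data.frame")
  attr(fl, "max_floor") <- 0.2
  attr(fl, "permutations") <- 10L
  sel <- select_by_noise_floor(conf, fl)
  expect_identical(sel, data.frame(node_a = "A", node_b = "C"))

  attr(fl, "max_floor") <- 1
  expect_identical(nrow(select_by_noise_floor(conf, fl)), 0L)

  attr(fl, "max_floor") <- 0
  expect_identical(nrow(select_by_noise_floor(conf, fl)), 2L)

  other <- strength_from_vector(c(AB = 0.2, AD = 0.9, BD = 0.0))
  expect_error(select_by_noise_floor(other, fl), "different node pairs")
})

test_that("strength tables round-trip through TSV, with or without counts", {
  x <- independent_data(50, ncol = 3, seed = 8)
  x$X03 <- x$X01
  conf <- bootstrap_confidences(x, hc_learner(), m = 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_strength(conf, path)
  back <- read_strength(path)
  expect_identical(back, conf)

  bare <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(conf)[, 1:3], bare, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  partial <- read_strength(bare)
  expect_identical(partial$confidence, conf$confidence)
  expect_true(all(is.na(partial$count_ab)))
})

test_that("edge confidences sharpen towards 0/1 as the sample grows", {
  fix <- random_network(8, avg_neighbours = 2, seed = 13,
                        cpt_concentration = 0.5)
  sizes <- c(100L, 1000L, 10000L)
  seeds <- bnstrength:::derive_seeds(17L, 20L)
  sharp <- sapply(seq_along(sizes), function(i) {
    mean(vapply(1:10, function(r) {
      x <- forward_sample(fix, sizes[i], seed = seeds[r])
      conf <- bootstrap_confidences(x, hc_learner(), m = 15,
                                    seed = seeds[10 + r])
      mean(pmax(conf$confidence, 1 - conf$confidence))
    }, numeric(1L)))
  })
  expect_true(all(diff(sharp) >= 0))
})
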