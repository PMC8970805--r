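# ID3: entropy, information gain, discretization, tree induction.

test_that("entropy follows the closed forms", {
  expect_equal(entropy(rep("a", 5)), 0)
  expect_equal(entropy(c(0, 0, 1, 1)), 1)
  expect_equal(entropy(rep(c("a", "b"), c(9, 5))), 0.9403, tolerance = 1e-4)
  expect_equal(entropy(rep(c("a", "b"), c(9, 5))),
               -(9 / 14) * log2(9 / 14) - (5 / 14) * log2(5 / 14),
               tolerance = 1e-12)
  expect_miclass_error(entropy(character(0)), "domain")
})

test_that("expected entropy and information gain follow their definitions", {
  d <- data.frame(A = c(0, 0, 1, 1), B = c(1, 1, 1, 1))
  y <- c(0, 1, 1, 1)
  expect_equal(expected_entropy(d, y, "A"), 0.5)
  expect_equal(info_gain(d, y, "A"), entropy(y) - 0.5, tolerance = 1e-12)
  expect_equal(info_gain(d, y, "A"), 0.8113 - 0.5, tolerance = 1e-4)
  # constant attribute: single subset, no gain
  expect_equal(expected_entropy(d, y, "B"), entropy(y))
  expect_equal(info_gain(d, y, "B"), 0)
  # perfect separator on balanced labels gains the full bit
  d2 <- data.frame(A = c(0, 0, 1, 1))
  y2 <- c(0, 0, 1, 1)
  expect_equal(expected_entropy(d2, y2, "A"), 0)
  expect_equal(info_gain(d2, y2, "A"), 1)
  expect_miclass_error(expected_entropy(d, y, "nope"), "key")
})

test_that("entropy and gain match brute-force enumeration on random tiny datasets", {
  brute_entropy <- function(labels) {
    tot <- 0
    for (cl in unique(labels)) {
      p <- sum(labels == cl) / length(labels)
      tot <- tot - p * log2(p)
    }
    tot
  }
  brute_expected <- function(df, labels, a) {
    tot <- 0
    for (v in unique(df[[a]])) {
      sel <- df[[a]] == v
      tot <- tot + sum(sel) / length(labels) * brute_entropy(labels[sel])
    }
    tot
  }
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    df <- as.data.frame(lapply(1:3, function(j) sample(1:3, n, replace = TRUE)))
    names(df) <- c("a1", "a2", "a3")
    y <- sample(0:2, n, replace = TRUE)
    expect_equal(entropy(y), brute_entropy(y), tolerance = 1e-12)
    for (a in names(df)) {
      expect_equal(expected_entropy(df, y, a), brute_expected(df, y, a),
                   tolerance = 1e-12)
      g <- info_gain(df, y, a)
      expect_gte(g, -1e-12)
      expect_lte(g, entropy(y) + 1e-12)
    }
  }
})

test_that("the equal-frequency discretizer bins at training quantiles", {
  set.seed(3)
  x <- rnorm(101)
  F <- cbind(x, exp(x))   # monotone transform of the same ranks
  m2 <- fit_discretizer(F, n_bins = 2)
  expect_equal(m2$edges[[1]], median(x), tolerance = 1e-12)
  nd <- apply_discretizer(m2, F)
  # rank invariance: monotone transforms bin identically
  expect_equal(as.integer(nd$data$f1), as.integer(nd$data$f2))
  # near-balanced occupancy
  expect_lte(abs(diff(table(nd$data$f1))), 1)
  # determinism and out-of-range mapping to outer bins
  expect_identical(apply_discretizer(m2, F)$data, nd$data)
  ext <- apply_discretizer(m2, matrix(c(-100, 100), 2, 2))
  expect_equal(as.integer(ext$data$f1), c(1L, 2L))
  expect_warning(fit_discretizer(cbind(rep(1, 5)), 3),
                 class = "miclass_warning_degenerate")
  expect_miclass_error(fit_discretizer(cbind(c(1, NA)), 2), "config")
})

test_that("tree induction memorizes, solves XOR at depth 2, handles purity", {
  pure <- data.frame(A = c(1, 2, 1))
  t0 <- build_tree(pure, labels = c("x", "x", "x"))
  expect_true(t0$root$leaf)
  expect_equal(t0$depth, 0)

  xor <- data.frame(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  yx <- c(0, 1, 1, 0)
  tx <- build_tree(xor, labels = yx)
  expect_equal(tx$depth, 2)
  expect_equal(predict(tx, xor), as.character(yx))

  set.seed(6)
  df <- data.frame(a = sample(1:4, 30, TRUE), b = sample(1:3, 30, TRUE),
                   c = sample(1:2, 30, TRUE))
  key <- paste(df$a, df$b, df$c)
  y <- as.integer(as.factor(key)) %% 2   # consistent labels per feature combo
  tm <- build_tree(df, labels = y)
  expect_equal(predict(tm, df), as.character(y))

  expect_miclass_error(build_tree(df[0, ], labels = integer(0)), "domain")
})

test_that("prediction falls back to node majorities on unseen values", {
  df <- data.frame(a = c(1, 1, 2, 2, 2))
  y <- c(0, 0, 1, 1, 0)
  tr <- build_tree(df, labels = y)
  expect_equal(predict(tr, data.frame(a = 99)), "0")  # overall majority
  # batch equals per-sample mapping
  nd <- data.frame(a = c(1, 2, 99))
  expect_equal(predict(tr, nd),
               vapply(1:3, function(i) predict(tr, nd[i, , drop = FALSE]), ""))
})

test_that("trees are invariant to attribute column order up to tie-breaking", {
  set.seed(8)
  df <- data.frame(a = sample(1:2, 40, TRUE), b = sample(1:3, 40, TRUE))
  y <- ifelse(df$b == 2, 1, df$a - 1)
  t1 <- build_tree(df, labels = y)
  t2 <- build_tree(df[, c("b", "a")], labels = y)
  nd <- expand.grid(a = 1:2, b = 1:3)
  expect_equal(predict(t1, nd), predict(t2, nd))
})

test_that("json serialization round-trips a working tree", {
  xor <- data.frame(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  tx <- build_tree(xor, labels = c(0, 1, 1, 0))
  path <- tempfile(fileext = ".json")
  write_tree_json(tx, path)
  back <- read_tree_json(path)
  expect_equal(predict(back, xor), predict(tx, xor))
  expect_equal(back$depth, tx$depth)
})
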