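# Arithmetic Optimization Algorithm: schedules, operators, optimizer, tuner.

test_that("MOA is the stated linear schedule and MOP its power-law decay", {
  cfg <- aoa_config(Mt = 100)
  expect_equal(moa(0, cfg), 0.2)
  expect_equal(moa(100, cfg), 0.9)
  expect_equal(moa(50, cfg), 0.55)
  expect_equal(mop(0, cfg), 1)
  expect_equal(mop(100, cfg), 0)
  # 32^(1/5) = 2 exactly: MOP = 1 - 2 / 100^(1/5)
  expect_equal(mop(32, cfg), 1 - 2 / 100^0.2, tolerance = 1e-12)
  expect_equal(mop(32, cfg), 0.203786, tolerance = 1e-5)

  tgrid <- 0:100
  expect_true(all(diff(moa(tgrid, cfg)) >= 0))
  expect_true(all(diff(mop(tgrid, cfg)) <= 0))
  expect_true(all(moa(tgrid, cfg) >= 0.2 & moa(tgrid, cfg) <= 0.9))
  expect_true(all(mop(tgrid, cfg) >= 0 & mop(tgrid, cfg) <= 1))
  expect_miclass_error(moa(101, cfg), "domain")
  expect_miclass_error(mop(-1, cfg), "domain")
})

test_that("population initialization respects bounds, seeds and degeneracies", {
  sp <- search_space(c(0, -1, 5), c(2, 1, 5))
  cfg <- aoa_config(N = 10, Mt = 5, seed = 3)
  st <- init_population(function(x) sum(x^2), sp, cfg)
  expect_true(all(st$X >= matrix(sp$lb, 10, 3, byrow = TRUE)))
  expect_true(all(st$X <= matrix(sp$ub, 10, 3, byrow = TRUE)))
  expect_true(all(st$X[, 3] == 5))   # lb == ub pins the dimension
  st2 <- init_population(function(x) sum(x^2), sp, cfg)
  expect_identical(st$X, st2$X)
  expect_equal(st$best_f, min(st$fitness))
  expect_miclass_error(aoa_config(N = 1), "config")
})

test_that("explore and exploit operators evaluate to their closed forms", {
  sp <- search_space(0, 2)
  cfg <- aoa_config(N = 2, Mt = 2, mu = 0.5, epsilon = 1e-300)
  # division branch, mop = 1: X_b / (1 + eps) * ((2 - 0) * 0.5 + 0) = 1
  expect_equal(explore_step(0.3, best_x = 1, mop_val = 1, sp, cfg, r = 0.2), 1)
  # multiplication branch with mop = 0 annihilates, then clips to lb
  expect_equal(explore_step(0.3, best_x = 1, mop_val = 0, sp, cfg, r = 0.9), 0)
  # addition branch, mop = 1: 1 + (2 * 0.5 + 0) = 2
  expect_equal(exploit_step(0.3, best_x = 1, mop_val = 1, sp, cfg, r = 0.9), 2)
  # subtraction mirrors addition about X_b when lb = 0
  up <- exploit_step(0.3, 1, 0.4, sp, cfg, r = 0.9)
  dn <- exploit_step(0.3, 1, 0.4, sp, cfg, r = 0.1)
  expect_equal(up - 1, 1 - dn)
  # mop = 0 is a fixed point of both exploitation branches
  expect_equal(exploit_step(0.3, 1, 0, sp, cfg, r = 0.1), 1)
  expect_equal(exploit_step(0.3, 1, 0, sp, cfg, r = 0.9), 1)

  # bound feasibility under random draws
  set.seed(1)
  sp2 <- search_space(c(-1, 0), c(1, 3))
  for (rep in 1:200) {
    mv <- runif(1)
    out <- rbind(explore_step(runif(2), runif(2), mv, sp2, cfg),
                 exploit_step(runif(2), runif(2), mv, sp2, cfg))
    expect_true(all(out >= matrix(sp2$lb, 2, 2, byrow = TRUE) - 1e-12))
    expect_true(all(out <= matrix(sp2$ub, 2, 2, byrow = TRUE) + 1e-12))
  }
})

test_that("a tiny optimization run matches a hand-stepped trace", {
  sp <- search_space(c(0, -1), c(2, 1))
  cfg <- aoa_config(N = 2, Mt = 2, seed = 42)
  obj <- function(x) sum((x - 0.5)^2)
  res <- aoa_optimize(obj, sp, cfg)

  # independent re-derivation with the same rng stream
  set.seed(42)
  X <- matrix(runif(4), 2, 2)
  X <- sweep(sweep(X, 2, sp$ub - sp$lb, "*"), 2, sp$lb, "+")
  fit <- apply(X, 1, obj)
  b <- which.min(fit); best_x <- X[b, ]; best_f <- fit[b]
  scl <- (sp$ub - sp$lb) * cfg$mu + sp$lb
  for (t in 1:2) {
    moa_t <- cfg$min_moa + t * (cfg$max_moa - cfg$min_moa) / cfg$Mt
    mop_t <- 1 - t^(1 / cfg$alpha) / cfg$Mt^(1 / cfg$alpha)
    for (i in 1:2) {
      r1 <- runif(2); r23 <- runif(2)
      cand <- numeric(2)
      for (j in 1:2) {
        cand[j] <- if (r1[j] > moa_t) {
          if (r23[j] < 0.5) best_x[j] / (mop_t + cfg$epsilon) * scl[j]
          else best_x[j] * mop_t * scl[j]
        } else {
          if (r23[j] < 0.5) best_x[j] - mop_t * scl[j]
          else best_x[j] + mop_t * scl[j]
        }
      }
      cand <- pmin(pmax(cand, sp$lb), sp$ub)
      f <- obj(cand)
      if (f < fit[i]) {
        X[i, ] <- cand; fit[i] <- f
        if (f < best_f) { best_f <- f; best_x <- cand }
      }
    }
  }
  expect_equal(res$best_f, best_f, tolerance = 1e-12)
  expect_equal(res$best_x, best_x, tolerance = 1e-12)
  expect_equal(res$state$X, X, tolerance = 1e-12)
})

test_that("the optimizer solves convex benchmarks and keeps a monotone trace", {
  sp <- search_space(c(-10, -10), c(10, 10))
  best <- vapply(1:10, function(s) {
    r <- aoa_optimize(function(x) sum(x^2), sp,
                      aoa_config(N = 20, Mt = 200, seed = s))
    expect_true(all(diff(r$trace$best_f) <= 0))
    r$best_f
  }, 0)
  expect_lt(median(best), 1e-2)

  # shifted sphere on an asymmetric box
  sp2 <- search_space(c(-4, -4), c(12, 12))
  best2 <- vapply(1:5, function(s)
    aoa_optimize(function(x) sum((x - 3)^2), sp2,
                 aoa_config(N = 20, Mt = 200, seed = s))$best_f, 0)
  expect_lt(median(best2), 1e-2)

  # degenerate box: only solution is the pinned point
  sp3 <- search_space(2, 2)
  r3 <- aoa_optimize(function(x) (x - 5)^2, sp3, aoa_config(N = 3, Mt = 2))
  expect_equal(as.numeric(r3$best_x), 2)
  expect_equal(r3$best_f, 9)
})

test_that("non-finite objectives are skipped with a warning, all-bad errors", {
  sp <- search_space(-1, 1)
  cfg <- aoa_config(N = 4, Mt = 3, seed = 2)
  w <- testthat::capture_warnings(
    res <- aoa_optimize(function(x) if (abs(x) < 0.2) NaN else x^2, sp, cfg))
  expect_true(any(grepl("non-finite fitness", w)))
  expect_true(is.finite(res$best_f))
  expect_miclass_error(
    suppressWarnings(aoa_optimize(function(x) NaN, sp, cfg)),
    "optimization")
})

test_that("hyperparameter tuning obeys its evaluation budget and bookkeeping", {
  calls <- new.env(); calls$n <- 0L
  res <- tune_hyperparameters(function(hp) {
    calls$n <- calls$n + 1L
    1 - (log10(hp$learning_rate) + 2)^2 / 9
  }, cfg = aoa_config(N = 3, Mt = 2, seed = 1))
  expect_lte(calls$n, 3 * (2 + 1))
  expect_equal(res$accuracy, max(res$log$accuracy), tolerance = 1e-12)
  expect_equal(nrow(res$log), res$n_evals)

  # known optimum at lr = 1e-2: recovered within half a decade
  hits <- vapply(1:10, function(s) {
    r <- tune_hyperparameters(function(hp)
      1 - (log10(hp$learning_rate) + 2)^2 / 9,
      cfg = aoa_config(N = 6, Mt = 12, seed = s))
    abs(log10(r$best$learning_rate) + 2)
  }, 0)
  expect_lt(median(hits), 0.5)

  # failures are penalized, not fatal
  r2 <- tune_hyperparameters(function(hp) stop("boom"),
                             cfg = aoa_config(N = 2, Mt = 1, seed = 3))
  expect_equal(r2$accuracy, 0)
})
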