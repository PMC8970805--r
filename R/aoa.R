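# Arithmetic Optimization Algorithm: a population metaheuristic whose
# exploration moves use division/multiplication and whose exploitation moves
# use subtraction/addition, gated by the Math Optimizer Accelerated (MOA)
# schedule and scaled by the Math Optimizer Probability (MOP) schedule.

#' Define a box search space
#'
#' @param lb,ub Numeric lower/upper bounds per dimension (`lb <= ub`).
#' @param names Optional per-dimension labels.
#' @param scale Per-dimension scale, `"linear"` or `"log10"`; log-scaled
#'   dimensions are searched in log10 units and exponentiated on decode.
#' @return An object of class `search_space`.
#' @export
search_space <- function(lb, ub, names = NULL, scale = NULL) {
  if (length(lb) != length(ub)) mi_stop("config", "lb and ub lengths differ")
  if (any(lb > ub)) mi_stop("config", "every lb must be <= ub")
  n <- length(lb)
  scale <- scale %||% rep("linear", n)
  if (!all(scale %in% c("linear", "log10")))
    mi_stop("config", "scale entries must be 'linear' or 'log10'")
  structure(list(lb = as.numeric(lb), ub = as.numeric(ub),
                 names = names %||% paste0("x", seq_len(n)),
                 scale = scale, n = n),
            class = "search_space")
}

#' AOA configuration
#'
#' @param N Population size (>= 2).
#' @param Mt Maximum iterations (>= 1).
#' @param min_moa,max_moa Range of the linear MOA schedule.
#' @param mu Control parameter scaling the search step (default 0.5).
#' @param alpha Exploitation-sensitivity exponent of the MOP schedule
#'   (default 5).
#' @param epsilon Small positive guard against division by zero.
#' @param seed Integer seed.
#' @return A validated list of class `aoa_config`.
#' @export
aoa_config <- function(N = 20, Mt = 100, min_moa = 0.2, max_moa = 0.9,
                       mu = 0.5, alpha = 5, epsilon = 2.2e-16, seed = 1) {
  check_number(N, "N", lower = 2, integer = TRUE)
  check_number(Mt, "Mt", lower = 1, integer = TRUE)
  check_number(min_moa, "min_moa", lower = 0, upper = 1)
  check_number(max_moa, "max_moa", lower = 0, upper = 1)
  if (min_moa >= max_moa) mi_stop("config", "min_moa must be < max_moa")
  check_number(mu, "mu", lower = 1e-12)
  check_number(alpha, "alpha", lower = 1e-12)
  check_number(epsilon, "epsilon", lower = .Machine$double.xmin)
  check_number(seed, "seed", integer = TRUE)
  structure(list(N = as.integer(N), Mt = as.integer(Mt), min_moa = min_moa,
                 max_moa = max_moa, mu = mu, alpha = alpha, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "aoa_config")
}

#' Math Optimizer Accelerated schedule
#'
#' `MOA(t) = min_moa + t * (max_moa - min_moa) / Mt`: linear from `min_moa`
#' at t = 0 to `max_moa` at t = Mt. Agents exploit when a uniform draw falls
#' below MOA(t), so exploitation becomes more likely as iterations pass.
#'
#' @param t Iteration in `[0, Mt]`.
#' @param cfg An [aoa_config()].
#' @return Value in `[min_moa, max_moa]`.
#' @export
moa <- function(t, cfg = aoa_config()) {
  if (any(t < 0 | t > cfg$Mt)) mi_stop("domain", "t must lie in [0, Mt]")
  cfg$min_moa + t * (cfg$max_moa - cfg$min_moa) / cfg$Mt
}

#' Math Optimizer Probability schedule
#'
#' `MOP(t) = 1 - t^(1/alpha) / Mt^(1/alpha)`: strictly decreasing from 1 at
#' t = 0 to 0 at t = Mt; scales the magnitude of every arithmetic move.
#'
#' @inheritParams moa
#' @return Value in `[0, 1]`.
#' @export
mop <- function(t, cfg = aoa_config()) {
  if (any(t < 0 | t > cfg$Mt)) mi_stop("domain", "t must lie in [0, Mt]")
  1 - t^(1 / cfg$alpha) / cfg$Mt^(1 / cfg$alpha)
}

#' Initialize the AOA population
#'
#' Positions uniform within the bounds; fitness evaluated; best solution set.
#'
#' @param objective Function mapping an n-vector to a scalar (minimized).
#' @param space A [search_space()].
#' @param cfg An [aoa_config()].
#' @return An object of class `aoa_state` with fields `X` (N x n), `fitness`,
#'   `best_x`, `best_f`, `t`.
#' @export
init_population <- function(objective, space, cfg = aoa_config()) {
  set.seed(cfg$seed)
  X <- matrix(stats::runif(cfg$N * space$n), cfg$N, space$n)
  X <- sweep(sweep(X, 2, space$ub - space$lb, "*"), 2, space$lb, "+")
  fitness <- apply(X, 1, function(x) as.numeric(objective(x)))
  if (all(!is.finite(fitness)))
    mi_stop("optimization", "objective non-finite over the whole population")
  if (any(!is.finite(fitness))) {
    mi_warn("objective", "%d agents returned non-finite fitness at init",
            sum(!is.finite(fitness)))
    fitness[!is.finite(fitness)] <- Inf
  }
  b <- which.min(fitness)
  structure(list(X = X, fitness = fitness, best_x = X[b, ], best_f = fitness[b],
                 t = 0L, space = space, cfg = cfg),
            class = "aoa_state")
}

#' AOA exploration move (division / multiplication)
#'
#' Per dimension j, with a uniform draw r2: if `r2 < 0.5` the division
#' operator `X_b[j] / (MOP + eps) * ((ub - lb) * mu + lb)`, otherwise the
#' multiplication operator `X_b[j] * MOP * ((ub - lb) * mu + lb)`; clipped to
#' the bounds.
#'
#' @param x_i Current position (unused by the canonical operators; kept for
#'   the operator signature).
#' @param best_x Best-so-far position X_b.
#' @param mop_val Current MOP value in `[0, 1]`.
#' @param space A [search_space()].
#' @param cfg An [aoa_config()].
#' @param r Optional vector of uniform draws (length n), for reproducible
#'   hand-stepped traces; defaults to fresh draws.
#' @return New position, clipped to `[lb, ub]`.
#' @export
explore_step <- function(x_i, best_x, mop_val, space, cfg = aoa_config(),
                         r = stats::runif(space$n)) {
  scl <- (space$ub - space$lb) * cfg$mu + space$lb
  new <- ifelse(r < 0.5,
                best_x / (mop_val + cfg$epsilon) * scl,
                best_x * mop_val * scl)
  pmin(pmax(new, space$lb), space$ub)
}

#' AOA exploitation move (subtraction / addition)
#'
#' Per dimension j, with a uniform draw r3: if `r3 < 0.5` the subtraction
#' operator `X_b[j] - MOP * ((ub - lb) * mu + lb)`, otherwise the addition
#' operator `X_b[j] + MOP * ((ub - lb) * mu + lb)`; clipped to the bounds.
#'
#' @inheritParams explore_step
#' @return New position, clipped to `[lb, ub]`.
#' @export
exploit_step <- function(x_i, best_x, mop_val, space, cfg = aoa_config(),
                         r = stats::runif(space$n)) {
  scl <- (space$ub - space$lb) * cfg$mu + space$lb
  new <- ifelse(r < 0.5, best_x - mop_val * scl, best_x + mop_val * scl)
  pmin(pmax(new, space$lb), space$ub)
}

#' Run the Arithmetic Optimization Algorithm
#'
#' For t = 1..Mt: compute MOA(t) and MOP(t); per agent and per dimension draw
#' r1 and explore (division/multiplication) when `r1 > MOA(t)`, exploit
#' (subtraction/addition) otherwise; a candidate replaces its agent only when
#' its fitness improves (greedy elitism), so the best-so-far trace is
#' monotonically non-increasing.
#'
#' @param objective Function n-vector -> scalar, minimized over the box.
#' @param space A [search_space()].
#' @param cfg An [aoa_config()].
#' @return List with `best_x`, `best_f`, `trace` (data.frame: iteration,
#'   best_f), `state` (final `aoa_state`), and `n_evals`.
#' @export
aoa_optimize <- function(objective, space, cfg = aoa_config()) {
  st <- init_population(objective, space, cfg)
  n_evals <- cfg$N
  trace <- numeric(cfg$Mt)
  for (t in seq_len(cfg$Mt)) {
    moa_t <- moa(t, cfg)
    mop_t <- mop(t, cfg)
    for (i in seq_len(cfg$N)) {
      r1 <- stats::runif(space$n)
      r23 <- stats::runif(space$n)
      explore <- r1 > moa_t
      cand <- ifelse(explore,
                     explore_step(st$X[i, ], st$best_x, mop_t, space, cfg, r23),
                     exploit_step(st$X[i, ], st$best_x, mop_t, space, cfg, r23))
      f <- as.numeric(objective(cand))
      n_evals <- n_evals + 1L
      if (!is.finite(f)) {
        mi_warn("objective", "non-finite fitness at iteration %d, agent %d; skipped",
                t, i)
        next
      }
      if (f < st$fitness[i]) {
        st$X[i, ] <- cand
        st$fitness[i] <- f
        if (f < st$best_f) {
          st$best_f <- f
          st$best_x <- cand
        }
      }
    }
    st$t <- t
    trace[t] <- st$best_f
  }
  list(best_x = st$best_x, best_f = st$best_f,
       trace = data.frame(iteration = seq_len(cfg$Mt), best_f = trace),
       state = st, n_evals = n_evals)
}

#' Tune training hyperparameters with the AOA
#'
#' Maximizes a validation-accuracy function by minimizing `1 - accuracy`
#' through [aoa_optimize()]. The default space covers the learning rate
#' (log10 scale), the focal-loss gamma and alpha, and the epoch count.
#'
#' @param train_eval Function taking a named list of hyperparameters
#'   (`learning_rate`, `gamma`, `alpha`, `epochs`) and returning a validation
#'   accuracy in `[0, 1]`. Failures are penalized with fitness 1.
#' @param space A [search_space()]; dimensions are decoded by name, log10
#'   dimensions are exponentiated, and an `epochs` dimension is rounded.
#' @param cfg An [aoa_config()]; keep `N * (Mt + 1)` small, every evaluation
#'   is a training run.
#' @return List with `best` (named hyperparameter list), `accuracy`, `log`
#'   (data.frame of every evaluation), `n_evals`.
#' @export
tune_hyperparameters <- function(train_eval,
                                 space = default_hyper_space(),
                                 cfg = aoa_config(N = 3, Mt = 2)) {
  log_env <- new.env()
  log_env$rows <- list()
  decode <- function(x) {
    vals <- as.list(x)
    names(vals) <- space$names
    for (j in seq_len(space$n)) {
      if (space$scale[j] == "log10") vals[[j]] <- 10^vals[[j]]
      if (space$names[j] == "epochs") vals[[j]] <- max(1L, as.integer(round(vals[[j]])))
    }
    vals
  }
  objective <- function(x) {
    hp <- decode(x)
    acc <- tryCatch(as.numeric(train_eval(hp)), error = function(e) NA_real_)
    if (!is.finite(acc)) acc <- 0
    log_env$rows[[length(log_env$rows) + 1L]] <-
      data.frame(as.data.frame(hp), accuracy = acc)
    1 - acc
  }
  res <- aoa_optimize(objective, space, cfg)
  log <- do.call(rbind, log_env$rows)
  log$evaluation <- seq_len(nrow(log))
  list(best = decode(res$best_x), accuracy = 1 - res$best_f, log = log,
       n_evals = res$n_evals)
}

#' Default hyperparameter search space for the feature network
#'
#' Learning rate 1e-4..1e-1 (log10), focal gamma 0..5, focal alpha 0.05..0.95,
#' epochs 5..40.
#'
#' @return A [search_space()].
#' @export
default_hyper_space <- function() {
  search_space(lb = c(-4, 0, 0.05, 5), ub = c(-1, 5, 0.95, 40),
               names = c("learning_rate", "gamma", "alpha", "epochs"),
               scale = c("log10", "linear", "linear", "linear"))
}
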