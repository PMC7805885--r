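#' Discrete-time replicator dynamics
#'
#' One replicator update of a population state. Each strategy's fitness is its
#' expected payoff against the current population, `f_i = sum_j (A_ij + shift)
#' x_j`, and shares are reweighted proportionally to fitness:
#' `x'_i = x_i f_i / sum_k x_k f_k`. The uniform `shift` keeps all payoffs
#' positive (required for the discrete map); it is fixed per experiment
#' because discrete-time trajectories, unlike rest points, depend on it.
#'
#' @param x Population state: non-negative frequencies summing to 1, ordered
#'   as the rows of `matrix`.
#' @param matrix A [build_payoff_matrix()] result (or plain matrix).
#' @param shift Uniform payoff shift; defaults to [default_shift()] of the
#'   matrix. All shifted payoffs must be positive.
#' @return The updated population state (a valid frequency vector).
#' @examples
#' pm <- build_payoff_matrix(c("C", "D"), model_params(n = 0, a = 0))
#' replicator_step(c(0.5, 0.5), pm) # defectors gain
#' @export
replicator_step <- function(x, matrix, shift = default_shift(matrix)) {
  A <- if (inherits(matrix, "payoff_matrix")) {
    unclass_payoff_matrix(matrix)
  } else {
    as.matrix(matrix)
  }
  .check_population(x, nrow(A))
  f <- as.vector((A + shift) %*% x)
  xf <- x * f
  total <- sum(xf)
  if (!is.finite(total) || total <= 0) {
    stop("non-positive mean fitness: increase the payoff shift", call. = FALSE)
  }
  xf / total
}

#' @rdname replicator_step
#' @return `default_shift()` returns `max(0, -min(matrix) + 1)`, making every
#'   shifted payoff at least 1 whenever any payoff is non-positive.
#' @export
default_shift <- function(matrix) {
  A <- if (inherits(matrix, "payoff_matrix")) {
    unclass_payoff_matrix(matrix)
  } else {
    as.matrix(matrix)
  }
  max(0, -min(A) + 1)
}

.check_population <- function(x, k) {
  if (!is.numeric(x) || length(x) != k) {
    stop("population state must be a numeric vector matching the strategy set",
         call. = FALSE)
  }
  if (any(x < 0) || abs(sum(x) - 1) > 1e-12) {
    stop("population state must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(x)
}

# Advance a batch of population states (rows of X) until, in each row, some
# strategy's share exceeds `threshold`, or `max_iter` is hit. Converged rows
# are dropped from the iteration, so cost scales with the rows still moving.
.replicator_batch <- function(X, A, shift, threshold, max_iter) {
  W <- A + shift
  if (min(W) <= 0) {
    stop("non-positive shifted payoffs: increase the payoff shift",
         call. = FALSE)
  }
  nrows <- nrow(X)
  attractor <- rep(NA_integer_, nrows)
  iterations <- rep(NA_integer_, nrows)
  active <- seq_len(nrows)

  k <- ncol(X)
  iter <- 0L
  repeat {
    mx <- X[active, 1L]
    for (j in seq_len(k)[-1L]) mx <- pmax(mx, X[active, j])
    hit <- mx > threshold
    if (any(hit)) {
      rows <- active[hit]
      attractor[rows] <- max.col(X[rows, , drop = FALSE], ties.method = "first")
      iterations[rows] <- iter
      active <- active[!hit]
      X[rows, ] <- NA_real_
    }
    if (length(active) == 0L || iter >= max_iter) break
    iter <- iter + 1L
    Xa <- X[active, , drop = FALSE]
    Fit <- Xa %*% t(W)
    XF <- Xa * Fit
    X[active, ] <- XF / rowSums(XF)
  }
  iterations[is.na(attractor)] <- iter
  list(attractor = attractor, iterations = iterations)
}

#' Run replicator dynamics to convergence
#'
#' Iterates [replicator_step()] from an initial state until one strategy's
#' share exceeds `threshold` (the population is then classified as converging
#' to that strategy's vertex) or `max_iter` updates have been taken, in which
#' case the run is classified `"UNRESOLVED"` — a valid outcome, always counted
#' separately, never dropped.
#'
#' @param x0 Initial population state.
#' @param matrix A [build_payoff_matrix()] result (or plain matrix with
#'   dimnames).
#' @param threshold Dominant-share convergence threshold.
#' @param max_iter Iteration cap.
#' @param shift Uniform payoff shift (see [replicator_step()]).
#' @return A list with `attractor` (strategy name or `"UNRESOLVED"`),
#'   `iterations`, and `x_final`.
#' @examples
#' pm <- build_payoff_matrix(c("C", "D", "GP", "F"), model_params())
#' run_replicator(c(0, 1, 0, 0), pm)$attractor # a vertex is a rest point
#' @export
run_replicator <- function(x0, matrix, threshold = 0.999, max_iter = 1e6,
                           shift = default_shift(matrix)) {
  A <- if (inherits(matrix, "payoff_matrix")) {
    unclass_payoff_matrix(matrix)
  } else {
    as.matrix(matrix)
  }
  .check_population(x0, nrow(A))
  labels <- rownames(A)
  x <- x0
  iter <- 0L
  repeat {
    if (max(x) > threshold) {
      return(list(attractor = labels[which.max(x)], iterations = iter,
                  x_final = stats::setNames(x, labels)))
    }
    if (iter >= max_iter) {
      return(list(attractor = "UNRESOLVED", iterations = iter,
                  x_final = stats::setNames(x, labels)))
    }
    x <- replicator_step(x, A, shift)
    iter <- iter + 1L
  }
}

#' Estimate basins of attraction by uniform simplex sampling
#'
#' Draws `samples` initial populations uniformly from the simplex (symmetric
#' Dirichlet with concentration 1, via normalized exponentials), runs the
#' discrete-time replicator dynamics on each until one strategy's share
#' exceeds `threshold`, and tallies the fraction of starts absorbed by each
#' strategy's vertex. Runs hitting the iteration cap are reported as
#' `unresolved`, so the attractor fractions plus the unresolved fraction
#' always sum to 1.
#'
#' @param params A [model_params()] object.
#' @param strategies Ordered strategy set for the population.
#' @param samples Number of initial states to draw.
#' @param seed Integer seed (the estimate is fully reproducible from it).
#' @param threshold Dominant-share convergence threshold.
#' @param max_iter Iteration cap per run.
#' @return An object of class `basin_estimate`: list with `fractions` (named,
#'   one per strategy), `unresolved`, `ci` (95 percent normal-approximation
#'   binomial intervals per strategy), `samples`, `seed`, `shift`,
#'   `strategies`, `params` and `matrix`.
#' @examples
#' est <- estimate_basin(model_params(p = 0.5, c = 0.1, d = 0.1),
#'                       samples = 50, seed = 1)
#' est$fractions
#' @export
estimate_basin <- function(params, strategies = c("C", "D", "GP", "F"),
                           samples = 1000, seed = 1, threshold = 0.999,
                           max_iter = 1e6) {
  stopifnot(inherits(params, "model_params"), samples >= 1)
  pm <- build_payoff_matrix(strategies, params)
  A <- unclass_payoff_matrix(pm)
  shift <- default_shift(A)
  k <- length(strategies)

  set.seed(seed)
  E <- matrix(stats::rexp(samples * k), samples, k)
  X <- E / rowSums(E)

  res <- .replicator_batch(X, A, shift, threshold, max_iter)
  counts <- tabulate(res$attractor, nbins = k)
  fractions <- stats::setNames(counts / samples, strategies)
  unresolved <- sum(is.na(res$attractor)) / samples
  half <- 1.96 * sqrt(fractions * (1 - fractions) / samples)
  ci <- cbind(low = pmax(0, fractions - half),
              high = pmin(1, fractions + half))
  rownames(ci) <- strategies

  structure(
    list(fractions = fractions, unresolved = unresolved, ci = ci,
         samples = samples, seed = seed, shift = shift,
         strategies = strategies, params = params, matrix = pm,
         iterations = res$iterations),
    class = "basin_estimate"
  )
}

#' @export
print.basin_estimate <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Basin-of-attraction estimate | n=%g a=%g p=%g c=%g d=%g | %d starts, seed %d\n",
    p$n, p$a, p$p, p$c, p$d, x$samples, x$seed))
  df <- data.frame(strategy = x$strategies,
                   fraction = unname(x$fractions),
                   ci_low = unname(x$ci[, "low"]),
                   ci_high = unname(x$ci[, "high"]))
  print(df, row.names = FALSE)
  if (x$unresolved > 0) {
    cat(sprintf("unresolved: %.4f\n", x$unresolved))
  }
  invisible(x)
}

#' Apology cost maximizing the basin of attraction of guilt-proneness
#'
#' Sweeps a grid of apology costs (applied with `c = d`), estimates the
#' guilt-prone basin of attraction at each cost with
#' strategies C, D, GP and F, and returns the grid cost with the largest GP
#' basin fraction. Ties are broken toward the smaller cost (the conservative
#' claim), with a message.
#'
#' @param p Fakeability.
#' @param cost_grid Grid of costs to explore, sorted ascending internally.
#' @param params_base A [model_params()] whose `n`, `a` and policy are reused
#'   at every grid point (its `p`, `c`, `d` are overridden).
#' @param samples Simplex starts per grid point.
#' @param seed Base seed; grid point `i` uses `seed + i - 1`.
#' @param strategies Population strategy set.
#' @return An object of class `cost_sweep`: list with `optimal_cost`, a
#'   `table` data frame (cost, GP fraction, CI, unresolved), and the sweep
#'   settings.
#' @examples
#' \donttest{
#' sweep <- optimal_cost(p = 0.9, samples = 200, seed = 1)
#' sweep$optimal_cost
#' }
#' @export
optimal_cost <- function(p,
                         cost_grid = c(0.005, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0),
                         params_base = model_params(n = 0.95, a = 0.01),
                         samples = 1000, seed = 1,
                         strategies = c("C", "D", "GP", "F")) {
  stopifnot(length(cost_grid) >= 1, "GP" %in% strategies)
  cost_grid <- sort(cost_grid)
  rows <- vector("list", length(cost_grid))
  for (i in seq_along(cost_grid)) {
    cc <- cost_grid[i]
    params <- model_params(n = params_base$n, a = params_base$a, p = p,
                           c = cc, d = cc,
                           faker_apology_policy =
                             params_base$faker_apology_policy)
    est <- estimate_basin(params, strategies = strategies,
                          samples = samples, seed = seed + i - 1L)
    rows[[i]] <- data.frame(
      cost = cc,
      gp_fraction = unname(est$fractions["GP"]),
      ci_low = unname(est$ci["GP", "low"]),
      ci_high = unname(est$ci["GP", "high"]),
      unresolved = est$unresolved,
      seed = seed + i - 1L
    )
  }
  table <- do.call(rbind, rows)
  best <- which(table$gp_fraction == max(table$gp_fraction))
  if (length(best) > 1) {
    message("tie in GP basin fraction at costs ",
            paste(table$cost[best], collapse = ", "),
            "; taking the smaller cost")
  }
  structure(
    list(optimal_cost = table$cost[best[1]], table = table, p = p,
         params_base = params_base, samples = samples, seed = seed,
         strategies = strategies),
    class = "cost_sweep"
  )
}

#' @export
print.cost_sweep <- function(x, ...) {
  cat(sprintf(
    "Apology-cost sweep (c = d), p = %g, n = %g, a = %g, %d starts per cost\n",
    x$p, x$params_base$n, x$params_base$a, x$samples))
  print(x$table, row.names = FALSE)
  cat(sprintf("GP-basin-maximizing cost: %g\n", x$optimal_cost))
  invisible(x)
}
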