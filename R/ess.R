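#' Certify an evolutionarily stable strategy
#'
#' Applies the Maynard-Smith conditions to the expected-payoff matrix: a
#' resident strategy S is stable against an invader T when E(S,S) > E(T,S), or
#' E(S,S) = E(T,S) (within `tolerance`) and E(S,T) > E(T,T). An ESS resists
#' every listed invader.
#'
#' @param strategy The candidate resident strategy.
#' @param invaders Character vector of invading strategies (the resident
#'   itself is dropped if present).
#' @param matrix A [build_payoff_matrix()] result containing the resident and
#'   all invaders.
#' @param tolerance Numeric tie tolerance for payoff equality.
#' @return An object of class `ess_report`: list with `strategy`, `invaders`,
#'   `is_ess`, and a `margins` data frame with per-invader resident margins
#'   `E(S,S) - E(T,S)` and tie-breaker margins `E(S,T) - E(T,T)`.
#' @examples
#' pm <- build_payoff_matrix(params = model_params())
#' is_ess("D", c("C", "GT", "GP", "F"), pm) # defection is always an ESS
#' @export
is_ess <- function(strategy, invaders, matrix, tolerance = 1e-9) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  m <- unclass_payoff_matrix(matrix)
  present <- rownames(m)
  missing <- setdiff(c(strategy, invaders), present)
  if (length(missing) > 0) {
    stop("strategies not in payoff matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invaders <- setdiff(invaders, strategy)
  margins <- data.frame(
    invader = invaders,
    margin_resident = NA_real_,   # E(S,S) - E(T,S)
    margin_tiebreak = NA_real_,   # E(S,T) - E(T,T)
    holds = NA
  )
  for (i in seq_along(invaders)) {
    t <- invaders[i]
    m_res <- m[strategy, strategy] - m[t, strategy]
    m_tie <- m[strategy, t] - m[t, t]
    margins$margin_resident[i] <- m_res
    margins$margin_tiebreak[i] <- m_tie
    margins$holds[i] <- (m_res > tolerance) ||
      (abs(m_res) <= tolerance && m_tie > tolerance)
  }
  structure(
    list(strategy = strategy, invaders = invaders,
         is_ess = all(margins$holds), margins = margins,
         tolerance = tolerance),
    class = "ess_report"
  )
}

#' @export
print.ess_report <- function(x, ...) {
  cat(sprintf("ESS report for %s vs {%s}: %s\n", x$strategy,
              paste(x$invaders, collapse = ", "),
              if (x$is_ess) "ESS" else "not an ESS"))
  print(x$margins, row.names = FALSE)
  invisible(x)
}

# Scan-then-bisect threshold search shared by the two boundary finders.
# ess_at(v) must be a cheap boolean; the scan verifies the crossing is
# monotone (FALSE...FALSE TRUE...TRUE); otherwise falls back to a fine grid.
.threshold_search <- function(ess_at, range, tol, scan_points = 25L) {
  grid <- seq(range[1], range[2], length.out = scan_points)
  ok <- vapply(grid, ess_at, logical(1))
  if (ok[1]) return(range[1])
  if (!any(ok)) return(structure(NA_real_, not_found = TRUE))
  first <- which(ok)[1]
  if (!all(ok[first:length(ok)])) {
    message("non-monotone ESS margin on coarse scan; falling back to grid search")
    fine <- seq(range[1], range[2], by = tol)
    ok_fine <- vapply(fine, ess_at, logical(1))
    if (!any(ok_fine)) return(structure(NA_real_, not_found = TRUE))
    return(fine[which(ok_fine)[1]])
  }
  lo <- grid[first - 1]  # ESS fails here
  hi <- grid[first]      # ESS holds here
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ess_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Minimum apology cost for guilt-prone to be stable against fakers
#'
#' With equal costs (`c = d`), finds the smallest apology cost at which the
#' guilt-prone grim trigger is an ESS against the faker, by bisection after a
#' coarse scan verifies that ESS status is monotone in the cost (a
#' non-monotone scan falls back to a fine grid search, with a message).
#' Higher costs deter fakers, so a minimum stabilizing cost exists whenever
#' any cost in the search range works.
#'
#' @param p Fakeability.
#' @param n Continuation probability.
#' @param a Execution-error probability.
#' @param range Search interval for the cost.
#' @param tol Bisection tolerance on the cost.
#' @return The minimal stabilizing cost, or `NA` (with attribute `not_found`)
#'   when no cost in `range` makes guilt-prone stable.
#' @examples
#' min_cost_for_ess_vs_faker(p = 0.9, n = 0.95)
#' @export
min_cost_for_ess_vs_faker <- function(p, n, a = 0.01, range = c(0, 5),
                                      tol = 1e-4) {
  ess_at <- function(cost) {
    pm <- build_payoff_matrix(
      c("GP", "F"), model_params(n = n, a = a, p = p, c = cost, d = cost))
    is_ess("GP", "F", pm)$is_ess
  }
  .threshold_search(ess_at, range, tol)
}

#' Minimum interaction length for guilt-prone to be stable
#'
#' Finds the smallest continuation probability `n` at which the guilt-prone
#' grim trigger is an ESS against a single invader (unconditional cooperation,
#' unconditional defection, or the plain grim trigger), at a given apology
#' cost. Longer interactions reward apology-and-forgive, so stability sets in
#' above a threshold in `n`; the search is the same scan-verified bisection
#' used for the cost boundary.
#'
#' @param invader One of `"C"`, `"D"`, `"GT"`.
#' @param cost Apology cost `c` (the faker cost `d` is set equal to it).
#' @param a Execution-error probability.
#' @param p Fakeability (irrelevant against non-faker invaders; kept for a
#'   complete parameter set).
#' @param range Search interval for `n`.
#' @param tol Bisection tolerance on `n`.
#' @return The minimal stabilizing `n`, or `NA` (attribute `not_found`).
#' @examples
#' min_continuation_for_ess("C", cost = 0.2)
#' @export
min_continuation_for_ess <- function(invader, cost, a = 0.01, p = 0.95,
                                     range = c(0, 0.9999), tol = 1e-4) {
  if (!invader %in% c("C", "D", "GT")) {
    stop("`invader` must be one of C, D, GT", call. = FALSE)
  }
  ess_at <- function(n) {
    pm <- build_payoff_matrix(
      c("GP", invader), model_params(n = n, a = a, p = p, c = cost, d = cost))
    is_ess("GP", invader, pm)$is_ess
  }
  .threshold_search(ess_at, range, tol)
}
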