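#' Markov chain of one encounter between two strategies
#'
#' An encounter between two strategies is a time-homogeneous Markov chain on
#' the joint modes of the two players (at most 2 x 2 states; strategies
#' without an internal mode contribute a single state). For each state the
#' builder enumerates the four realized-action combinations (error probability
#' `a` per player, independent), the resulting apology events and their costs,
#' and the belief outcomes (probability 1 for guilt-prone apologies, `p` for
#' faker apologies), then applies the mode-update rules to obtain the
#' transition distribution and the expected per-round reward of each player
#' (stage payoff minus expected apology cost).
#'
#' @param s1,s2 Strategy identifiers for player 1 and player 2.
#' @param params A [model_params()] object.
#'
#' @return An object of class `pair_process`: a list with elements
#'   `strategies` (the ordered pair), `params`, `states` (a data frame of
#'   joint modes), `rewards` (a states x 2 matrix of expected per-round
#'   rewards), `transition` (the row-stochastic transition matrix) and
#'   `initial` (index of the both-cooperative starting state; all conditional
#'   strategies begin in cooperative mode).
#'
#' @examples
#' pr <- build_pair_process("GP", "F", model_params(p = 0.95, c = 0.4))
#' pr$transition
#' expected_pair_payoffs(pr)
#' @export
build_pair_process <- function(s1, s2, params) {
  .check_strategy(s1)
  .check_strategy(s2)
  stopifnot(inherits(params, "model_params"))
  a <- params$a

  modes1 <- if (has_mode(s1)) player_modes() else "cooperative"
  modes2 <- if (has_mode(s2)) player_modes() else "cooperative"
  states <- expand.grid(mode1 = modes1, mode2 = modes2,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ns <- nrow(states)
  labels <- paste(states$mode1, states$mode2, sep = "|")

  state_index <- function(m1, m2) {
    which(states$mode1 == m1 & states$mode2 == m2)
  }

  transition <- matrix(0, ns, ns, dimnames = list(labels, labels))
  rewards <- matrix(0, ns, 2, dimnames = list(labels, c(s1, s2)))

  belief_branches <- function(strategy, issued) {
    # branches of (believed, probability) for one player's apology event
    if (!issued) return(list(list(believed = FALSE, prob = 1)))
    if (strategy == "GP") return(list(list(believed = TRUE, prob = 1)))
    list(list(believed = TRUE, prob = params$p),
         list(believed = FALSE, prob = 1 - params$p))
  }

  for (s in seq_len(ns)) {
    m1 <- states$mode1[s]
    m2 <- states$mode2[s]
    i1 <- intended_action(s1, m1)
    i2 <- intended_action(s2, m2)
    for (r1 in actions()) {
      for (r2 in actions()) {
        prob_act <- (if (r1 == i1) 1 - a else a) *
                    (if (r2 == i2) 1 - a else a)
        if (prob_act == 0) next
        ap1 <- apology_issued(s1, m1, r1, r2, params)
        ap2 <- apology_issued(s2, m2, r2, r1, params)
        rewards[s, 1] <- rewards[s, 1] +
          prob_act * (stage_payoff(r1, r2) - ap1$cost)
        rewards[s, 2] <- rewards[s, 2] +
          prob_act * (stage_payoff(r2, r1) - ap2$cost)
        for (b1 in belief_branches(s1, ap1$issued)) {
          for (b2 in belief_branches(s2, ap2$issued)) {
            nm1 <- update_mode(s1, m1, r2, ap2$issued && b2$believed)
            nm2 <- update_mode(s2, m2, r1, ap1$issued && b1$believed)
            j <- state_index(nm1, nm2)
            transition[s, j] <- transition[s, j] +
              prob_act * b1$prob * b2$prob
          }
        }
      }
    }
  }

  row_err <- abs(rowSums(transition) - 1)
  if (any(row_err > 1e-12)) {
    stop("internal error: transition rows do not sum to 1", call. = FALSE)
  }

  structure(
    list(strategies = c(s1, s2), params = params, states = states,
         rewards = rewards, transition = transition,
         initial = state_index("cooperative", "cooperative")),
    class = "pair_process"
  )
}

#' @export
print.pair_process <- function(x, ...) {
  cat(sprintf("Encounter Markov chain: %s vs %s (%d state%s)\n",
              x$strategies[1], x$strategies[2], nrow(x$states),
              if (nrow(x$states) == 1) "" else "s"))
  cat("Per-round expected rewards:\n")
  print(round(x$rewards, 6))
  cat("Transition matrix:\n")
  print(round(x$transition, 6))
  invisible(x)
}

#' Expected whole-encounter payoffs from an encounter chain
#'
#' The encounter lasts a geometric number of rounds (continue with probability
#' `n` after each round), so each player's expected total payoff from state
#' `s` satisfies `v = r + n P v`, where `r` is that player's per-round
#' expected reward vector and `P` the transition matrix. The linear system is
#' solved exactly and evaluated at the initial (all-cooperative) state. This
#' is identical to the expectation of the summed per-round payoffs over the
#' geometric encounter length.
#'
#' @param process A [build_pair_process()] result.
#' @param n Continuation probability; defaults to the one in the process's
#'   parameters.
#' @return A named numeric vector of length 2: the expected total payoff to
#'   each player.
#' @export
expected_pair_payoffs <- function(process, n = process$params$n) {
  stopifnot(inherits(process, "pair_process"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n >= 1) {
    stop("`n` must lie in [0, 1)", call. = FALSE)
  }
  ns <- nrow(process$transition)
  A <- diag(ns) - n * process$transition
  v <- solve(A, process$rewards)
  out <- v[process$initial, ]
  names(out) <- process$strategies
  out
}
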