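#' Model parameters for the noisy iterated prisoner's dilemma with apology
#'
#' Bundles the five scalar parameters of the model together with the faker
#' apology policy, and validates their ranges.
#'
#' @param n Continuation probability: after each round the encounter continues
#'   with probability `n`, so the expected number of rounds is `1 / (1 - n)`.
#'   Must lie in `[0, 1)`.
#' @param a Execution-error probability: each round, each player's realized
#'   action is the opposite of its intended action with probability `a`.
#'   Must lie in `[0, 0.5)`.
#' @param p Fakeability: the probability that a faker's apology is believed.
#'   Guilt-prone apologies are always believed. Must lie in `(0, 1]`.
#' @param c Apology cost paid by the guilt-prone type each time it apologizes.
#'   Non-negative.
#' @param d Apology cost paid by the faker each time it apologizes.
#'   Non-negative. In the costly-fake-apology regime `d >= c`; a warning (not
#'   an error) is raised when `d < c`.
#' @param faker_apology_policy When the faker apologizes for a realized
#'   defection: `"always"` (default) after every own defection, or
#'   `"if_partner_cooperated"` only when the partner's realized action that
#'   round was cooperate (an economical faker that never wastes an apology on
#'   a fellow defector).
#' @param gp_apology_policy When the guilt-prone type apologizes for its own
#'   realized defection: `"always"` (default) after every defection, including
#'   intended punitive ones — guilt does not switch off while punishing — or
#'   `"cooperative_mode_only"` for accidental defections committed while still
#'   in cooperative mode. The defaults make apology an unconditional
#'   consequence of defecting, which is what lets moderate costs discriminate
#'   honest from fake apologizers at the population level.
#'
#' @return An object of class `model_params`: a list with elements `n`, `a`,
#'   `p`, `c`, `d` and `faker_apology_policy`.
#'
#' @examples
#' params <- model_params(n = 0.95, a = 0.01, p = 0.95, c = 0.4, d = 0.4)
#' expected_rounds(params$n)
#' @export
model_params <- function(n = 0.95, a = 0.01, p = 0.95, c = 0.4, d = c,
                         faker_apology_policy = "always",
                         gp_apology_policy = "always") {
  # NB: `c` is an argument here, shadowing base::c inside this body
  faker_apology_policy <- match.arg(faker_apology_policy,
                                    base::c("always", "if_partner_cooperated"))
  gp_apology_policy <- match.arg(gp_apology_policy,
                                 base::c("always", "cooperative_mode_only"))
  for (nm in base::c("n", "a", "p", "c", "d")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (n < 0 || n >= 1) {
    stop("`n` must lie in [0, 1): encounters must be finite in expectation",
         call. = FALSE)
  }
  if (a < 0 || a >= 0.5) {
    stop("`a` must lie in [0, 0.5)", call. = FALSE)
  }
  if (p <= 0 || p > 1) {
    stop("`p` must lie in (0, 1]", call. = FALSE)
  }
  if (c < 0) stop("`c` must be non-negative", call. = FALSE)
  if (d < 0) stop("`d` must be non-negative", call. = FALSE)
  if (d < c) {
    warning("d < c: fakers pay a lower apology cost than guilt-prone types; ",
            "the costly-fake-apology regime assumes d >= c", call. = FALSE)
  }
  structure(
    list(n = n, a = a, p = p, c = c, d = d,
         faker_apology_policy = faker_apology_policy,
         gp_apology_policy = gp_apology_policy),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (noisy iterated prisoner's dilemma with apology)\n")
  cat(sprintf("  n = %-6g continuation probability (expected rounds %.4g)\n",
              x$n, expected_rounds(x$n)))
  cat(sprintf("  a = %-6g execution-error probability\n", x$a))
  cat(sprintf("  p = %-6g fakeability (faker apology believed)\n", x$p))
  cat(sprintf("  c = %-6g apology cost, guilt-prone\n", x$c))
  cat(sprintf("  d = %-6g apology cost, faker\n", x$d))
  cat(sprintf("  faker apology policy: %s\n", x$faker_apology_policy))
  cat(sprintf("  guilt-prone apology policy: %s\n", x$gp_apology_policy))
  invisible(x)
}

#' Expected number of rounds in an encounter
#'
#' An encounter continues after each round with probability `n`, so its length
#' is geometric and the expected number of rounds is `1 / (1 - n)`; for
#' example `n = 0.95` gives 20 expected rounds.
#'
#' @param n Continuation probability in `[0, 1)`.
#' @return The expected encounter length `1 / (1 - n)`.
#' @examples
#' expected_rounds(0.95) # 20
#' @export
expected_rounds <- function(n) {
  if (!is.numeric(n) || any(n < 0) || any(n >= 1)) {
    stop("`n` must lie in [0, 1)", call. = FALSE)
  }
  1 / (1 - n)
}
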