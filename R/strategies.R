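#' Strategy, action and mode vocabularies
#'
#' The model's strategy set is fixed: unconditional cooperation (`"C"`),
#' unconditional defection (`"D"`), grim trigger (`"GT"`), guilt-prone grim
#' trigger (`"GP"`, apologizes after its own defections and forgives believed
#' apologies), and faker (`"F"`, always defects but apologizes).
#'
#' @return `strategy_ids()` returns the five strategy identifiers in canonical
#'   order; `actions()` the two stage-game actions; `player_modes()` the two
#'   within-encounter modes of the conditional strategies.
#' @examples
#' strategy_ids()
#' @export
strategy_ids <- function() c("C", "D", "GT", "GP", "F")

#' @rdname strategy_ids
#' @export
actions <- function() c("cooperate", "defect")

#' @rdname strategy_ids
#' @export
player_modes <- function() c("cooperative", "punishing")

.check_strategy <- function(strategy) {
  if (length(strategy) != 1L || !strategy %in% strategy_ids()) {
    stop("unknown strategy: ", paste(strategy, collapse = ", "),
         " (must be one of ", paste(strategy_ids(), collapse = ", "), ")",
         call. = FALSE)
  }
  strategy
}

.check_action <- function(action) {
  if (length(action) != 1L || !action %in% actions()) {
    stop("unknown action: ", paste(action, collapse = ", "), call. = FALSE)
  }
  action
}

.check_mode <- function(mode) {
  if (length(mode) != 1L || !mode %in% player_modes()) {
    stop("unknown mode: ", paste(mode, collapse = ", "), call. = FALSE)
  }
  mode
}

#' Does a strategy condition its play on an internal mode?
#'
#' Only the grim trigger and the guilt-prone grim trigger switch between a
#' cooperative and a punishing mode; C, D and F behave identically in both.
#'
#' @param strategy A strategy identifier.
#' @return `TRUE` for `"GT"` and `"GP"`, else `FALSE`.
#' @export
has_mode <- function(strategy) {
  .check_strategy(strategy) %in% c("GT", "GP")
}

#' Flip a stage-game action
#'
#' @param action `"cooperate"` or `"defect"`.
#' @return The opposite action.
#' @export
flip_action <- function(action) {
  .check_action(action)
  if (action == "cooperate") "defect" else "cooperate"
}

#' Stage-game payoff of the prisoner's dilemma
#'
#' The one-shot game uses the payoff constants T = 3 (defect against a
#' cooperator), R = 2 (mutual cooperation), P = 1 (mutual defection) and
#' S = 0 (cooperate against a defector), satisfying T > R > P > S.
#'
#' @param own,other Realized actions of the focal player and the partner.
#' @return The focal player's stage payoff.
#' @examples
#' stage_payoff("cooperate", "cooperate") # 2
#' stage_payoff("defect", "cooperate")    # 3
#' @export
stage_payoff <- function(own, other) {
  .check_action(own)
  .check_action(other)
  stage_payoffs()[own, other]
}

#' @rdname stage_payoff
#' @return `stage_payoffs()` returns the full 2x2 payoff table for the row
#'   player, with actions as dimnames.
#' @export
stage_payoffs <- function() {
  matrix(c(2, 0, 3, 1), nrow = 2, byrow = TRUE,
         dimnames = list(actions(), actions()))
}

#' Intended action of a strategy in a given mode
#'
#' C always intends to cooperate; D and F always intend to defect; GT and GP
#' intend to cooperate while in cooperative mode and to defect while punishing.
#'
#' @param strategy A strategy identifier.
#' @param mode A player mode; ignored by C, D and F.
#' @return `"cooperate"` or `"defect"`.
#' @export
intended_action <- function(strategy, mode = "cooperative") {
  .check_strategy(strategy)
  .check_mode(mode)
  switch(strategy,
    C = "cooperate",
    D = "defect",
    F = "defect",
    GT = ,
    GP = if (mode == "cooperative") "cooperate" else "defect"
  )
}

#' Realize an intended action under execution noise
#'
#' With probability `a` the realized action is the opposite of the intended
#' one; errors apply only to cooperate/defect actions, never to apology
#' issuance or belief.
#'
#' @param intended The intended action.
#' @param a Error probability in `[0, 0.5)`.
#' @param draw A uniform(0, 1) random draw; supplied explicitly so that the
#'   rule itself is deterministic and testable. Defaults to a fresh draw.
#' @return The realized action: flipped when `draw < a`.
#' @export
realize_action <- function(intended, a, draw = stats::runif(1)) {
  .check_action(intended)
  if (!is.numeric(a) || length(a) != 1L || a < 0 || a >= 0.5) {
    stop("`a` must lie in [0, 0.5)", call. = FALSE)
  }
  if (draw < a) flip_action(intended) else intended
}

#' Apology issuance after a resolved round
#'
#' GP apologizes, paying cost `c`, after its own realized defection — under
#' the default policy after every defection, accidental or punitive (guilt
#' does not switch off while punishing), under `"cooperative_mode_only"` only
#' for accidental defections committed while still cooperative. The apology is
#' issued regardless of the partner's type: strategies observe history, not
#' types. F apologizes, paying cost `d`, after its own realized defection —
#' under the default policy after every one, under `"if_partner_cooperated"`
#' only when the partner's realized action that round was cooperate. C, D and
#' GT never apologize.
#'
#' @param strategy The apologizer's strategy.
#' @param mode The apologizer's mode at the start of the round.
#' @param own_realized,partner_realized The realized actions of the round.
#' @param params A [model_params()] object (supplies `c`, `d` and the faker
#'   apology policy).
#' @return A list with `issued` (logical) and `cost` (the cost paid; 0 when no
#'   apology is issued).
#' @export
apology_issued <- function(strategy, mode, own_realized, partner_realized,
                           params) {
  .check_strategy(strategy)
  .check_mode(mode)
  .check_action(own_realized)
  .check_action(partner_realized)
  stopifnot(inherits(params, "model_params"))
  issued <- FALSE
  cost <- 0
  if (strategy == "GP" && own_realized == "defect" &&
      (params$gp_apology_policy == "always" || mode == "cooperative")) {
    issued <- TRUE
    cost <- params$c
  } else if (strategy == "F" && own_realized == "defect") {
    if (params$faker_apology_policy == "always" ||
        partner_realized == "cooperate") {
      issued <- TRUE
      cost <- params$d
    }
  }
  list(issued = issued, cost = cost)
}

#' Is an issued apology believed?
#'
#' Guilt-prone apologies are always believed (guilt is an honest signal); a
#' faker's apology is believed with probability `p`, independently per apology
#' event.
#'
#' @param apologizer Strategy of the player who issued the apology.
#' @param p Fakeability in `(0, 1]`.
#' @param draw A uniform(0, 1) random draw (explicit for testability).
#' @return Logical: `TRUE` if the apology is believed.
#' @export
apology_believed <- function(apologizer, p, draw = stats::runif(1)) {
  .check_strategy(apologizer)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("`p` must lie in (0, 1]", call. = FALSE)
  }
  if (apologizer == "GP") TRUE else draw < p
}

#' Mode update at the end of a round
#'
#' C, D and F never change mode. GT enters (and never leaves) punishing mode
#' once its partner's realized action is a defection; apologies do not sway
#' it. GP behaves like GT except that a believed apology received in the same
#' round as the partner's defection prevents the switch; once punishing, GP
#' never forgives again within the encounter.
#'
#' @param strategy The updating player's strategy.
#' @param mode The player's mode at the start of the round.
#' @param partner_realized The partner's realized action this round.
#' @param believed_apology_received Logical: did the partner issue an apology
#'   this round that this player believed?
#' @return The mode for the next round. Monotone: never `punishing` back to
#'   `cooperative`.
#' @export
update_mode <- function(strategy, mode, partner_realized,
                        believed_apology_received = FALSE) {
  .check_strategy(strategy)
  .check_mode(mode)
  .check_action(partner_realized)
  if (!has_mode(strategy)) return(mode)
  if (mode == "punishing") return("punishing")
  punish <- switch(strategy,
    GT = partner_realized == "defect",
    GP = partner_realized == "defect" && !isTRUE(believed_apology_received)
  )
  if (punish) "punishing" else "cooperative"
}
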