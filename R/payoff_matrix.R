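#' Expected payoff matrix over a strategy set
#'
#' Builds the expected whole-encounter payoff for every ordered pair of
#' strategies: entry (X, Y) is the expected total payoff to a player using X
#' in an encounter with a player using Y, computed exactly from the encounter
#' Markov chain. This matrix is the game on which ESS certification and the
#' replicator dynamics operate.
#'
#' @param strategies Ordered subset of [strategy_ids()], no duplicates.
#' @param params A [model_params()] object.
#' @return An object of class `payoff_matrix`: a numeric matrix with strategy
#'   dimnames and the parameters attached as attribute `"params"`.
#' @examples
#' pm <- build_payoff_matrix(c("C", "D"), model_params(n = 0, a = 0))
#' pm # the one-shot prisoner's dilemma table
#' @export
build_payoff_matrix <- function(strategies = strategy_ids(), params) {
  if (anyDuplicated(strategies)) {
    stop("duplicate strategies in `strategies`", call. = FALSE)
  }
  for (s in strategies) .check_strategy(s)
  stopifnot(inherits(params, "model_params"))
  k <- length(strategies)
  m <- matrix(NA_real_, k, k, dimnames = list(strategies, strategies))
  for (x in strategies) {
    for (y in strategies) {
      pr <- build_pair_process(x, y, params)
      m[x, y] <- expected_pair_payoffs(pr)[[1L]]
    }
  }
  structure(m, params = params, class = c("payoff_matrix", "matrix"))
}

#' @export
print.payoff_matrix <- function(x, digits = 4, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Expected encounter payoffs (row player) | n=%g a=%g p=%g c=%g d=%g\n",
    p$n, p$a, p$p, p$c, p$d))
  print(round(unclass_payoff_matrix(x), digits))
  invisible(x)
}

#' @export
as.matrix.payoff_matrix <- function(x, ...) unclass_payoff_matrix(x)

unclass_payoff_matrix <- function(x) {
  attr(x, "params") <- NULL
  class(x) <- "matrix"
  x
}

#' Export a payoff matrix to CSV or JSON
#'
#' CSV carries the row/column strategy labels; JSON additionally embeds the
#' full parameter set for provenance.
#'
#' @param x A [build_payoff_matrix()] result.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
export_payoff_matrix <- function(x, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(x, "payoff_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  m <- unclass_payoff_matrix(x)
  if (format == "csv") {
    df <- data.frame(strategy = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    p <- attr(x, "params")
    jsonlite::write_json(
      list(parameters = p[c("n", "a", "p", "c", "d",
                            "faker_apology_policy")],
           strategies = rownames(m),
           payoffs = m),
      path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(path)
}
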