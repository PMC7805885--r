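params_default <- model_params(n = 0.95, a = 0.01, p = 0.95, c = 0.4, d = 0.4)

test_that("every pair chain is a valid Markov process with bounded rewards", {
  pairs <- default_pairs()
  for (ps in list(params_default,
                  model_params(n = 0.5, a = 0.05, p = 0.5, c = 1, d = 1))) {
    bound <- max(ps$c, ps$d)
    for (i in seq_len(nrow(pairs))) {
      pr <- build_pair_process(pairs$s1[i], pairs$s2[i], ps)
      expect_lte(nrow(pr$states), 4L)
      expect_true(all(abs(rowSums(pr$transition) - 1) < 1e-12))
      expect_true(all(pr$rewards >= -bound - 1e-12))
      expect_true(all(pr$rewards <= 3 + 1e-12))
    }
  }
})

test_that("mutual defection chain matches the enumeration closed form", {
  for (a in c(0, 0.05)) {
    pr <- build_pair_process("D", "D", model_params(a = a))
    expect_identical(nrow(pr$states), 1L)
    expect_equal(unname(pr$rewards[1, ]), rep(dd_round_reward(a), 2),
                 tolerance = 1e-12)
  }
})

test_that("GP-GP per-round reward matches the closed form (1.988 at a=0.01, c=0.2)", {
  pr <- build_pair_process("GP", "GP", model_params(a = 0.01, c = 0.2, d = 0.2))
  i <- pr$initial
  expect_equal(unname(pr$rewards[i, 1]), 1.988, tolerance = 1e-12)
  expect_equal(unname(pr$rewards[i, 1]), gp_gp_round_reward(0.01, 0.2),
               tolerance = 1e-12)
  # the punishing states are unreachable: GP apologies are always believed
  expect_equal(unname(pr$transition[i, i]), 1, tolerance = 1e-12)
})

test_that("GP-F breakdown probability per round is exactly as enumerated", {
  a <- 0.01
  p <- 0.95
  # default policy: F apologizes after every realized defection, so GP starts
  # punishing iff F's action stands (1 - a) and the apology is disbelieved
  pr <- build_pair_process("GP", "F", model_params(a = a, p = p))
  coop <- pr$initial
  pun <- which(pr$states$mode1 == "punishing")
  expect_equal(unname(pr$transition[coop, pun]), (1 - a) * (1 - p),
               tolerance = 1e-12)
  # economical faker: no apology when GP's realized action was also a
  # defection, which adds an unapologized-defection route a(1 - a)
  pr2 <- build_pair_process(
    "GP", "F",
    model_params(a = a, p = p, faker_apology_policy = "if_partner_cooperated"))
  expect_equal(unname(pr2$transition[coop, pun]),
               (1 - a)^2 * (1 - p) + a * (1 - a), tolerance = 1e-12)
})

test_that("expected encounter payoffs solve the geometric-length expectation", {
  # error-free cooperators: R per round times expected rounds
  pr_cc <- build_pair_process("C", "C", model_params(n = 0.95, a = 0))
  expect_equal(unname(expected_pair_payoffs(pr_cc)), c(40, 40),
               tolerance = 1e-9)
  # GP-GP from the per-round closed form
  pr_gp <- build_pair_process("GP", "GP",
                              model_params(n = 0.95, a = 0.01, c = 0.2, d = 0.2))
  expect_equal(unname(expected_pair_payoffs(pr_gp)), rep(39.76, 2),
               tolerance = 1e-9)
  # n = 0 reduces to the single-round expected payoff, for every pair
  pairs <- default_pairs()
  for (i in seq_len(nrow(pairs))) {
    pr <- build_pair_process(pairs$s1[i], pairs$s2[i], params_default)
    expect_equal(unname(expected_pair_payoffs(pr, n = 0)),
                 unname(pr$rewards[pr$initial, ]), tolerance = 1e-12)
  }
  expect_error(expected_pair_payoffs(pr_cc, n = 1), "n")
})

test_that("role symmetry: payoff to X vs Y equals the column payoff of (Y, X)", {
  pairs <- default_pairs()
  for (i in seq_len(nrow(pairs))) {
    v_xy <- expected_pair_payoffs(
      build_pair_process(pairs$s1[i], pairs$s2[i], params_default))
    v_yx <- expected_pair_payoffs(
      build_pair_process(pairs$s2[i], pairs$s1[i], params_default))
    expect_equal(unname(v_xy[1]), unname(v_yx[2]), tolerance = 1e-9)
  }
})

test_that("without errors all cooperative pairings earn R per round exactly", {
  ps <- model_params(n = 0.9, a = 0, c = 0.7, d = 0.7)
  vals <- vapply(c("C", "GT", "GP"), function(s) {
    unname(expected_pair_payoffs(build_pair_process(s, s, ps))[1])
  }, numeric(1))
  expect_equal(unname(vals), rep(2 / (1 - 0.9), 3), tolerance = 1e-9)
})

test_that("GP-GP value falls with apology cost and rises with encounter length", {
  value_gp <- function(n, cost) {
    unname(expected_pair_payoffs(build_pair_process(
      "GP", "GP", model_params(n = n, a = 0.01, c = cost, d = cost)))[1])
  }
  costs <- c(0, 0.2, 0.5, 1)
  v_by_cost <- vapply(costs, function(cc) value_gp(0.95, cc), numeric(1))
  expect_true(all(diff(v_by_cost) <= 0))
  ns <- c(0.5, 0.9, 0.95, 0.99)
  v_by_n <- vapply(ns, function(nn) value_gp(nn, 0.2), numeric(1))
  expect_true(all(diff(v_by_n) > 0))
})

test_that("marginal cost of apology equals the expected apology count", {
  # d value(GP,GP) / d c = -(expected apologies per encounter); for GP-GP the
  # chain stays cooperative so apologies occur at rate a per round
  a <- 0.01
  n <- 0.95
  h <- 1e-6
  value_gp <- function(cost) {
    unname(expected_pair_payoffs(build_pair_process(
      "GP", "GP", model_params(n = n, a = a, c = cost, d = cost)))[1])
  }
  fd <- (value_gp(0.2 + h) - value_gp(0.2)) / h
  expect_equal(fd, -a / (1 - n), tolerance = 1e-6)
})

test_that("the payoff matrix reproduces the one-shot game and validates input", {
  pm <- build_payoff_matrix(c("C", "D"), model_params(n = 0, a = 0))
  m <- as.matrix(pm)
  expect_equal(m["C", "C"], 2)
  expect_equal(m["C", "D"], 0)
  expect_equal(m["D", "C"], 3)
  expect_equal(m["D", "D"], 1)
  expect_error(build_payoff_matrix(c("C", "C"), model_params()), "duplicate")
  expect_error(build_payoff_matrix(c("C", "Z"), model_params()),
               "unknown strategy")
})

test_that("payoff matrices export to CSV and JSON with provenance", {
  pm <- build_payoff_matrix(c("C", "D", "GP"), params_default)
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  export_payoff_matrix(pm, csv)
  export_payoff_matrix(pm, json)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_identical(back$strategy, c("C", "D", "GP"))
  expect_equal(back$GP, unname(as.matrix(pm)[, "GP"]), tolerance = 1e-12)
  meta <- jsonlite::read_json(json)
  expect_equal(meta$parameters$n, 0.95)
  expect_identical(unlist(meta$strategies), c("C", "D", "GP"))
})
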