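test_that("intended actions follow the strategy definitions", {
  expect_identical(intended_action("C", "cooperative"), "cooperate")
  expect_identical(intended_action("C", "punishing"), "cooperate")
  expect_identical(intended_action("D", "cooperative"), "defect")
  expect_identical(intended_action("F", "cooperative"), "defect")
  for (s in c("GT", "GP")) {
    expect_identical(intended_action(s, "cooperative"), "cooperate")
    expect_identical(intended_action(s, "punishing"), "defect")
  }
  expect_error(intended_action("X", "cooperative"), "unknown strategy")
})

test_that("execution noise flips the intended action with probability a", {
  expect_identical(realize_action("cooperate", a = 0, draw = 0.5), "cooperate")
  expect_identical(realize_action("defect", a = 0.01, draw = 0.005),
                   "cooperate")
  expect_identical(realize_action("defect", a = 0.01, draw = 0.5), "defect")
  expect_error(realize_action("cooperate", a = 0.6), "a")
  expect_error(realize_action("cooperate", a = -0.1), "a")

  set.seed(42)
  a <- 0.01
  ndraw <- 1e5
  flips <- vapply(stats::runif(ndraw), function(u) {
    realize_action("cooperate", a, u) == "defect"
  }, logical(1))
  se <- sqrt(a * (1 - a) / ndraw)
  expect_lt(abs(mean(flips) - a), 3 * se)
})

test_that("stage game has the prisoner's-dilemma ordering T > R > P > S", {
  tbl <- stage_payoffs()
  expect_identical(dim(tbl), c(2L, 2L))
  expect_true(stage_payoff("defect", "cooperate") >
                stage_payoff("cooperate", "cooperate"))
  expect_true(stage_payoff("cooperate", "cooperate") >
                stage_payoff("defect", "defect"))
  expect_true(stage_payoff("defect", "defect") >
                stage_payoff("cooperate", "defect"))
})

test_that("apology issuance: GP and F apologize after defecting, others never", {
  params <- model_params(c = 0.3, d = 0.7)

  gp <- apology_issued("GP", "cooperative", "defect", "cooperate", params)
  expect_true(gp$issued)
  expect_equal(gp$cost, 0.3)
  # under the default policy guilt does not switch off while punishing
  gp_pun <- apology_issued("GP", "punishing", "defect", "defect", params)
  expect_true(gp_pun$issued)
  # under the restricted policy punitive defections are not apologized for
  params_restricted <- model_params(c = 0.3, d = 0.7,
                                    gp_apology_policy = "cooperative_mode_only")
  expect_false(apology_issued("GP", "punishing", "defect", "defect",
                              params_restricted)$issued)
  expect_true(apology_issued("GP", "cooperative", "defect", "cooperate",
                             params_restricted)$issued)

  f <- apology_issued("F", "cooperative", "defect", "defect", params)
  expect_true(f$issued)
  expect_equal(f$cost, 0.7)
  params_econ <- model_params(c = 0.3, d = 0.7,
                              faker_apology_policy = "if_partner_cooperated")
  expect_false(apology_issued("F", "cooperative", "defect", "defect",
                              params_econ)$issued)
  expect_true(apology_issued("F", "cooperative", "defect", "cooperate",
                             params_econ)$issued)

  # nothing to apologize for without an own defection
  expect_false(apology_issued("F", "cooperative", "cooperate", "cooperate",
                              params)$issued)
  expect_false(apology_issued("GP", "cooperative", "cooperate", "defect",
                              params)$issued)

  # C, D, GT never apologize, in any reachable rule input
  for (s in c("C", "D", "GT")) {
    for (m in player_modes()) {
      for (own in actions()) {
        for (other in actions()) {
          res <- apology_issued(s, m, own, other, params)
          expect_false(res$issued)
          expect_identical(res$cost, 0)
        }
      }
    }
  }
})

test_that("guilt-prone apologies are always believed, faker ones with probability p", {
  expect_true(apology_believed("GP", p = 0.5, draw = 0.99))
  expect_true(apology_believed("F", p = 1.0, draw = 0.999999))
  expect_false(apology_believed("F", p = 0.5, draw = 0.7))

  set.seed(7)
  p <- 0.95
  ndraw <- 1e5
  believed <- vapply(stats::runif(ndraw), function(u) {
    apology_believed("F", p, draw = u)
  }, logical(1))
  se <- sqrt(p * (1 - p) / ndraw)
  expect_lt(abs(mean(believed) - p), 3 * se)
})

test_that("mode updates: grim punishment is absorbing, belief gates GP only", {
  expect_identical(update_mode("GP", "cooperative", "defect", TRUE),
                   "cooperative") # forgive and forget
  expect_identical(update_mode("GP", "cooperative", "defect", FALSE),
                   "punishing")
  expect_identical(update_mode("GT", "cooperative", "defect", TRUE),
                   "punishing") # GT ignores apologies
  expect_identical(update_mode("GP", "punishing", "cooperate", FALSE),
                   "punishing") # absorbing
  for (s in c("C", "D", "F")) {
    expect_identical(update_mode(s, "cooperative", "defect", FALSE),
                     "cooperative")
  }
})

test_that("no mode update ever leaves the punishing state (monotonicity)", {
  for (s in strategy_ids()) {
    for (partner in actions()) {
      for (bel in c(TRUE, FALSE)) {
        expect_identical(update_mode(s, "punishing", partner, bel),
                         "punishing")
      }
    }
  }
})
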