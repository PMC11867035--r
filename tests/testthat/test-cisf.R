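# CIS compartment dynamics: term assembly, normalization contract,
# growth condition, clamped integration.

# independent term-by-term evaluation of the compartment derivatives
oracle_derivative <- function(lv, roles, w) {
  E <- roles[["E"]]; C <- roles[["C"]]; P <- roles[["P"]]
  Rbar <- mean(lv)
  terms_R <- list(
    growth = w[["u0a"]] * lv,
    settings = w[["u7b"]] * lv,
    externalities = -w[["u7a"]] * lv,
    support = w[["u4a"]] * lv * C,
    flow = -(w[["u1b"]] * lv * E) * (w[["u5b"]] * C),
    management = (w[["u1a"]] * E * lv) * (w[["u5a"]] * C)
  )
  terms_E <- c(w[["u0b"]] * E, w[["u7d"]] * E, -w[["u7c"]] * E,
               (w[["u1b"]] * Rbar * E) * (w[["u5b"]] * C),
               w[["u6b_prime"]] * E * C, w[["u2b"]] * E * P)
  terms_C <- c(w[["u0d"]] * C, w[["u7h"]] * C, -w[["u7g"]] * C,
               (w[["u1b"]] * Rbar * E) * (w[["u5b_prime"]] * C),
               (w[["u1a"]] * Rbar * E) * (w[["u5a_prime"]] * C),
               (w[["u6a"]] - w[["u6b"]]) * E * C, w[["u3a"]] * P * C)
  terms_P <- c(w[["u0c"]] * P, w[["u7f"]] * C, -w[["u7e"]] * C,
               w[["u2a"]] * E * P, w[["u3b"]] * C * P)
  list(dR = Reduce(`+`, terms_R), dE = sum(terms_E), dC = sum(terms_C),
       dP = sum(terms_P))
}

test_that("an empty system and a single growth term evaluate exactly", {
  roles <- c(E = 0.4, C = 0.6, P = 0.3)
  d0 <- cisf_derivative(c(food = 0.3, wood = 0.8), roles, action_weights())
  expect_equal(unname(d0$dR), c(0, 0))
  expect_equal(d0$dE, 0)
  expect_equal(d0$dC, 0)
  expect_equal(d0$dP, 0)

  d1 <- cisf_derivative(c(food = 0.5), roles, action_weights(u0a = 0.1))
  expect_equal(unname(d1$dR), 0.05)
  expect_equal(d1$dE, 0)
  expect_equal(d1$dC, 0)
  expect_equal(d1$dP, 0)
})

test_that("derivatives equal the sum of independently evaluated terms", {
  set.seed(101)
  for (i in seq_len(1000)) {
    w <- random_weights()
    lv <- stats::setNames(runif(3), c("a", "b", "c"))
    roles <- c(E = runif(1), C = runif(1), P = runif(1))
    got <- cisf_derivative(lv, roles, w)
    want <- oracle_derivative(lv, roles, w)
    expect_equal(unname(got$dR), unname(want$dR), tolerance = 1e-12)
    expect_equal(got$dE, want$dE, tolerance = 1e-12)
    expect_equal(got$dC, want$dC, tolerance = 1e-12)
    expect_equal(got$dP, want$dP, tolerance = 1e-12)
  }
})

test_that("out-of-range weights are rejected before evaluation", {
  w <- action_weights(u1a = -0.5)  # u1a must be non-negative
  expect_error(cisf_derivative(c(a = 0.5), c(E = 0, C = 0, P = 0), w),
               "admissible range")
  expect_error(cisf_derivative(c(a = 0.5), c(E = 0, C = 0, P = 0),
                               action_weights(u7b = 0.5)),
               "u7b")
})

test_that("normalization check reports per-compartment sums", {
  w <- action_weights(u0b = 0.2, u1b = 0.2, u2b = 0.2, u6b = 0.2, u7d = 0.2,
                      u0c = 0.4, u2a = 0.3, u3b = 0.2, u7f = 0.1,
                      u0d = 0.2, u3a = 0.2, u4a = 0.2, u6a = 0.2, u7h = 0.2)
  chk <- check_normalization(w)
  expect_true(chk$pass)
  expect_equal(unname(chk$sums), c(1, 1, 1))

  bad <- action_weights(u0b = 0.5,
                        u0c = 0.4, u2a = 0.3, u3b = 0.2, u7f = 0.1,
                        u0d = 0.2, u3a = 0.2, u4a = 0.2, u6a = 0.2, u7h = 0.2)
  chk2 <- check_normalization(bad, allow_absent = FALSE)
  expect_false(chk2$pass)
  expect_equal(unname(chk2$sums[["E"]]), 0.5)
})

test_that("growth condition variants behave on pure growth and decline", {
  grow <- resource_growth_condition(action_weights(u0a = 0.2), c_capacity = 0.5)
  expect_true(grow[["printed"]])
  expect_true(grow[["derived"]])
  decline <- resource_growth_condition(action_weights(u7b = -0.3),
                                       c_capacity = 0.5)
  expect_false(decline[["printed"]])
  expect_false(decline[["derived"]])
})

test_that("derived growth condition agrees with the sign of dR/dt", {
  set.seed(202)
  for (i in seq_len(200)) {
    w <- random_weights()
    roles <- c(E = runif(1), C = runif(1), P = runif(1))
    cond <- resource_growth_condition(w, c_capacity = roles[["C"]],
                                      e_capacity = roles[["E"]])
    d <- cisf_derivative(c(a = 1), roles, w)  # per-unit rate at R = 1
    expect_equal(unname(cond[["derived"]]), unname(d$dR) >= 0)
  }
})

test_that("integration keeps ES levels and role capacities in [0, 1]", {
  set.seed(303)
  for (i in seq_len(25)) {
    w <- random_weights()
    tr <- cisf_simulate(w, stats::setNames(runif(2), c("a", "b")),
                        c(E = runif(1), C = runif(1), P = runif(1)),
                        years = 20)
    expect_true(all(tr$es >= 0 & tr$es <= 1))
    expect_true(all(tr$roles >= 0 & tr$roles <= 1))
  }
})
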