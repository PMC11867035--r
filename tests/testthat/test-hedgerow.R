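# Synthetic hedgerow fixture: determinism, constraint-set nesting, climate
# ordering, simplex conservation, ES ranges and the Shannon aesthetics index.

test_that("the fixture is deterministic given the seed", {
  a <- default_fixture("rural", 1, seed = 42)
  b <- default_fixture("rural", 1, seed = 42)
  expect_identical(a$base_weights, b$base_weights)
  expect_identical(a$weights, b$weights)
  expect_identical(a$model$effective, b$model$effective)
  c <- default_fixture("rural", 1, seed = 43)
  expect_false(identical(a$base_weights, c$base_weights))
  expect_error(default_fixture("rural", 5, 1), "climate level")
  expect_error(default_fixture("urban", 1, 1))
})

test_that("the rural satisfactory box is a strict subset of the peri-urban
           one", {
  r <- default_fixture("rural", 0, 1)$domain
  p <- default_fixture("peri_urban", 0, 1)$domain
  m <- merge(r, p, by = c("name", "sign"))
  svc <- m$sign == "service"
  expect_true(all(m$bound.x[svc] >= m$bound.y[svc]))    # rural minima higher
  expect_true(all(m$bound.x[!svc] <= m$bound.y[!svc]))  # rural maxima lower
  expect_true(any(m$bound.x != m$bound.y))
})

test_that("stronger climate stress strictly increases decay of tall and
           rich classes", {
  f0 <- default_fixture("rural", 0, 1)
  f2 <- default_fixture("rural", 2, 1)
  for (cls in c("TR", "SR")) {
    off0 <- f0$model$climate[cls, setdiff(colnames(f0$model$climate), cls)]
    off2 <- f2$model$climate[cls, setdiff(colnames(f2$model$climate), cls)]
    expect_true(all(off2 >= off0))
    expect_gt(sum(off2), sum(off0))
  }
  # and the climate stress maps onto the external stress weight u7b
  expect_lt(f2$base_weights[["u7b"]], f0$base_weights[["u7b"]])
})

test_that("annual steps conserve the simplex under arbitrary sequences", {
  fx <- default_fixture("peri_urban", 2, 9)
  set.seed(99)
  for (i in seq_len(20)) {
    s <- random_simplex_state()
    for (y in seq_len(40)) {
      s <- hedgerow_step(s, sample(9, 1), fx$model)
      expect_true(all(s >= -1e-12))
      expect_equal(sum(s), 1, tolerance = 1e-9)
    }
  }
})

test_that("three steps match hand iteration of the transition matrix", {
  fx <- default_fixture("rural", 1, 4)
  Teff <- fx$model$effective[[3]]
  s <- fx$initial_state
  manual <- as.numeric(s)
  for (k in 1:3) {
    manual <- as.numeric(manual %*% Teff)
    s <- hedgerow_step(s, 3, fx$model)
    expect_equal(as.numeric(s), manual, tolerance = 1e-12)
  }
  # identity operator leaves the state unchanged
  fx_id <- fx
  fx_id$model$effective[[1]] <- diag(5)
  expect_equal(as.numeric(hedgerow_step(s, 1, fx_id$model)), as.numeric(s))
})

test_that("ES outputs stay in [0, 1] over the simplex and respond to
           composition as designed", {
  set.seed(7)
  states <- t(vapply(seq_len(1000), function(i) as.numeric(random_simplex_state()),
                     numeric(5)))
  fx <- default_fixture("rural", 0, 1)
  for (i in c(1, 50, 500, 1000)) {
    es <- compute_es(states[i, ])
    expect_true(all(es$level >= 0 & es$level <= 1))
  }
  lv <- dappmap:::hedgerow_es_matrix(states)
  expect_true(all(lv >= 0 & lv <= 1))

  # bare landscape: linear ES at their intercepts, aesthetics zero
  bare <- compute_es(c(TR = 0, TP = 0, SR = 0, SP = 0, NO = 1))
  expect_equal(bare$level[bare$name == "pollinator_resources"], 0.05)
  expect_equal(bare$level[bare$name == "landscape_aesthetics"], 0)

  # more species-rich tall hedges means more pollinator resources
  s0 <- c(TR = 0.1, TP = 0.2, SR = 0.1, SP = 0.3, NO = 0.3)
  s1 <- c(TR = 0.2, TP = 0.2, SR = 0.1, SP = 0.3, NO = 0.2)
  e0 <- compute_es(s0); e1 <- compute_es(s1)
  expect_gt(e1$level[e1$name == "pollinator_resources"],
            e0$level[e0$name == "pollinator_resources"])
})

test_that("Shannon aesthetics matches its analytic values and is invariant
           under class permutations", {
  expect_equal(shannon_aesthetics(c(0.25, 0.25, 0.25, 0.25)), 1)
  expect_equal(shannon_aesthetics(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_aesthetics(c(0.5, 0.5, 0, 0)), 0.5)
  expect_equal(shannon_aesthetics(c(0, 0, 0, 0)), 0)
  # scale invariance: only relative proportions of present hedgerows matter
  expect_equal(shannon_aesthetics(c(0.1, 0.1, 0.2, 0)),
               shannon_aesthetics(c(0.25, 0.25, 0.5, 0)))
  set.seed(5)
  for (i in seq_len(100)) {
    p <- runif(4)
    for (j in seq_len(3)) {
      expect_equal(shannon_aesthetics(p), shannon_aesthetics(sample(p)))
    }
  }
})

test_that("the pathway-model wrapper round-trips grid and state spaces", {
  fx <- default_fixture("rural", 0, 1)
  m <- as_pathway_model(fx)
  g <- matrix(c(0.1, 0.2, 0.3, 0.1), 1)
  s <- m$grid_to_state(g)
  expect_equal(unname(s[1, 5]), 0.3)
  expect_equal(unname(m$state_to_grid(s)), unname(g))
  expect_true(m$valid_grid(g))
  expect_false(m$valid_grid(matrix(c(0.5, 0.5, 0.3, 0.1), 1)))
})
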