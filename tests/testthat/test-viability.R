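# Satisfactory-domain margins and the backward-induction viability kernel,
# checked against exhaustive enumeration of control sequences on a toy model.

test_that("margins behave at the boundary and at maximal satisfaction", {
  d <- satisfactory_domain(es_min = c(s1 = 0.3), es_max = c(d1 = 0.6))
  m <- margin(d, c(s1 = 0.3, d1 = 0.6))
  expect_equal(m$margin, c(0, 0))
  expect_true(attr(m, "member"))

  m2 <- margin(d, c(s1 = 1, d1 = 0))    # maximally inside both bounds
  expect_equal(attr(m2, "normalized_sum"), 1)
  expect_equal(m2$normalized, c(1, 1))
})

test_that("membership agrees with a direct per-constraint check", {
  set.seed(31)
  for (i in seq_len(300)) {
    d <- satisfactory_domain(es_min = c(a = runif(1), b = runif(1)),
                             es_max = c(c = runif(1)))
    lv <- c(a = runif(1), b = runif(1), c = runif(1))
    m <- margin(d, lv)
    expect_equal(attr(m, "member"),
                 oracle_in_domain(d, as.list(lv)))
  }
})

test_that("vacuous constraints fill the grid and infeasible ones empty it", {
  model <- toy_model()
  sched <- decision_schedule(0, 3, 1)
  vac <- satisfactory_domain(es_min = c(es_x = 0, es_y = 0))
  k <- compute_kernel(model, vac, sched, grid = 5)
  expect_true(all(k$membership))

  # ES delivery capped below the requested threshold: nothing is attainable
  capped <- model
  capped$es <- function(states) {
    out <- 0.9 * states
    colnames(out) <- c("es_x", "es_y")
    out
  }
  k2 <- compute_kernel(capped, satisfactory_domain(es_min = c(es_x = 0.95)),
                       sched, grid = 5)
  expect_false(any(k2$membership))
})

test_that("kernel membership and regulation map equal exhaustive enumeration", {
  model <- toy_model()
  n_grid <- 5
  sched <- decision_schedule(0, 2, 1)      # 3 epochs, 2 governed intervals
  dom <- toy_domain(0.25, 0.2)
  k <- compute_kernel(model, dom, sched, grid = n_grid)
  nodes <- expand.grid(x = seq(0, 1, length.out = n_grid),
                       y = seq(0, 1, length.out = n_grid))
  L <- sched$epochs
  for (r in seq_len(nrow(nodes))) {
    s0 <- as.numeric(nodes[r, ])
    for (ep in seq_len(L)) {
      want <- if (ep == L) {
        list(viable = oracle_toy_in_domain(dom, s0), first_controls = integer(0))
      } else {
        oracle_node_controls(model, dom, s0, n_grid,
                             n_intervals = L - ep, n_sub = sched$step)
      }
      expect_equal(k$membership[r, ep], want$viable,
                   info = sprintf("node %d epoch %d", r, ep))
      if (ep < L) {
        expect_equal(unname(regulation_map(k, s0, ep)), want$first_controls,
                     info = sprintf("controls node %d epoch %d", r, ep))
      }
    }
  }
})

test_that("regulation map is empty outside the kernel and errors off-grid", {
  model <- toy_model()
  sched <- decision_schedule(0, 2, 1)
  dom <- toy_domain(0.25, 0.2)
  k <- compute_kernel(model, dom, sched, grid = 5)
  expect_length(regulation_map(k, c(0, 0), 1), 0)   # outside K_R
  expect_error(regulation_map(k, c(2, 0.5), 1), "outside the grid")
  expect_error(regulation_map(k, c(0.5, 0.5), sched$epochs), "epoch")
})

test_that("kernel slices match direct membership lookup", {
  model <- toy_model()
  sched <- decision_schedule(0, 2, 1)
  vac <- satisfactory_domain(es_min = c(es_x = 0, es_y = 0))
  k_full <- compute_kernel(model, vac, sched, grid = 5)
  expect_true(all(kernel_slice(k_full, c("x", "y"))))

  imp <- satisfactory_domain(es_min = c(es_x = 0.999, es_y = 0.999))
  k_empty <- compute_kernel(model, imp, sched, grid = 5)
  expect_false(any(kernel_slice(k_empty, c("x", "y"))))

  dom <- toy_domain(0.25, 0.2)
  k <- compute_kernel(model, dom, sched, grid = 5)
  sl <- kernel_slice(k, c("x", "y"), epoch = 1)
  g <- seq(0, 1, length.out = 5)
  for (i in 1:5) for (j in 1:5) {
    node <- which(abs(k$nodes[, 1] - g[i]) < 1e-9 &
                    abs(k$nodes[, 2] - g[j]) < 1e-9)
    expect_equal(sl[i, j], k$membership[node, 1])
  }
})

test_that("relaxing every bound grows the kernel node-wise", {
  model <- toy_model()
  sched <- decision_schedule(0, 3, 1)
  tight <- toy_domain(0.35, 0.3)
  loose <- toy_domain(0.2, 0.15)
  kt <- compute_kernel(model, tight, sched, grid = 7)
  kl <- compute_kernel(model, loose, sched, grid = 7)
  expect_true(all(kl$membership | !kt$membership))
})

test_that("extending the horizon can only shrink the epoch-0 kernel", {
  model <- toy_model()
  dom <- toy_domain(0.3, 0.25)
  k_short <- compute_kernel(model, dom, decision_schedule(0, 3, 1), grid = 7)
  k_long <- compute_kernel(model, dom, decision_schedule(0, 4, 1), grid = 7)
  expect_true(all(!k_long$membership[, 1] | k_short$membership[, 1]))
})

test_that("a fixed point strictly inside the domain stays in the kernel at
           every horizon", {
  # third arrangement: the identity map; its fixed points are all states
  maps <- list(
    list(A = matrix(c(0.5, 0, 0, 0.5), 2), b = c(0.1, 0.05)),
    list(A = matrix(c(0.8, 0.1, 0.0, 0.7), 2), b = c(0, 0)),
    list(A = diag(2), b = c(0, 0))
  )
  model <- toy_model(maps)
  dom <- toy_domain(0.2, 0.2)
  for (h in 1:4) {
    k <- compute_kernel(model, dom, decision_schedule(0, h, 1), grid = 5)
    inside <- which(k$nodes[, 1] >= 0.25 & k$nodes[, 2] >= 0.25)
    expect_true(all(k$membership[inside, 1]))
  }
})
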