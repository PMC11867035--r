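# Pathway counting, simulation, enumeration against brute force, and the
# selection of secured / per-ES optimal subsets.

test_that("pathway counts match the closed form", {
  expect_equal(count_pathways(9, decision_schedule(2020, 30, 5)), 4782969)
  expect_equal(count_pathways(10, 10), 1e10)
  expect_equal(count_pathways(1, decision_schedule(0, 20, 4)), 1)
})

test_that("a pathway under vacuous constraints is viable; an initial state
           outside the domain fails at year zero", {
  model <- toy_model()
  sched <- decision_schedule(0, 4, 2)
  vac <- satisfactory_domain(es_min = c(es_x = 0, es_y = 0))
  r <- simulate_pathway(model, c(0.5, 0.5), c(1, 2, 3), sched, vac)
  expect_true(r$viable)
  expect_true(is.na(r$first_violation))

  dom <- toy_domain(0.4, 0.4)
  r2 <- simulate_pathway(model, c(0.1, 0.1), c(1, 2, 3), sched, dom)
  expect_false(r2$viable)
  expect_equal(r2$first_violation, 0L)
})

test_that("trajectories equal step-by-step hand iteration", {
  model <- toy_model()
  sched <- decision_schedule(0, 3, 1)
  dom <- toy_domain(0, 0)
  r <- simulate_pathway(model, c(0.3, 0.6), c(2, 1, 3, 1), sched, dom)
  s <- c(0.3, 0.6)
  for (k in 1:3) {
    s <- oracle_toy_step(model, s, c(2, 1, 3)[k])
    expect_equal(unname(r$states[k + 1, ]), unname(s), tolerance = 1e-12)
  }
  tab <- es_trajectories(r)
  expect_equal(nrow(tab), sched$horizon + 1)
  expect_equal(tab$es_x, unname(r$states[, 1]))
})

test_that("pathway security matches the margin aggregation", {
  model <- toy_model()
  sched <- decision_schedule(0, 2, 1)
  dom <- toy_domain(0.1, 0.1)
  r <- simulate_pathway(model, c(0.8, 0.8), c(1, 1, 1), sched, dom)
  # analytic recomputation: mean over years of mean normalized margin
  nm <- sapply(seq_len(3), function(i) {
    mean(c((r$states[i, 1] - 0.1) / 0.9, (r$states[i, 2] - 0.1) / 0.9))
  })
  expect_equal(r$security, mean(nm), tolerance = 1e-12)
  r_min <- simulate_pathway(model, c(0.8, 0.8), c(1, 1, 1), sched, dom,
                            aggregate = "min")
  expect_equal(r_min$security, min(nm), tolerance = 1e-12)
})

test_that("enumeration equals brute force on a 3-arrangement, 4-epoch toy", {
  model <- toy_model()
  sched <- decision_schedule(0, 3, 1)      # 4 epochs, 3 governed intervals
  dom <- toy_domain(0.45, 0.3)             # prunes some but not all pathways
  g <- enumerate_viable(model, c(0.6, 0.55), sched, dom)
  bf <- oracle_enumerate(model, c(0.6, 0.55), sched, dom)
  expect_gt(bf$total, 0)
  expect_lt(bf$total, count_pathways(3, sched))
  expect_equal(g$total_viable, bf$total)
  expect_equal(edges_as_array(g), bf$edges)

  g_plain <- enumerate_viable(model, c(0.6, 0.55), sched, dom,
                              memoize = FALSE)
  expect_equal(g_plain$total_viable, g$total_viable)
  expect_equal(edges_as_array(g_plain), edges_as_array(g))
})

test_that("zero viable pathways give an all-zero graph", {
  model <- toy_model()
  sched <- decision_schedule(0, 3, 1)
  dom <- toy_domain(0.9, 0.9)
  g <- enumerate_viable(model, c(0.1, 0.1), sched, dom)
  expect_equal(g$total_viable, 0)
  expect_true(all(g$edges$traversals == 0))
})

test_that("vacuous constraints force the fully symmetric edge counts", {
  fx <- default_fixture("rural", 0, seed = 1)
  model <- as_pathway_model(fx)
  vac <- satisfactory_domain(
    es_min = stats::setNames(rep(0, 5), fx$domain$name[fx$domain$sign == "service"]),
    es_max = stats::setNames(rep(1, 2), fx$domain$name[fx$domain$sign == "disservice"])
  )
  g <- enumerate_viable(model, fx$initial_state, fx$schedule, vac)
  expect_equal(g$total_viable, 9^7)
  expect_true(all(g$edges$traversals == 9^5))
  # per-node throughput: the 9 outgoing edges of any node sum to 9^6
  e1 <- g$edges[g$edges$layer == 1 & g$edges$arr_from == 1, ]
  expect_equal(sum(e1$traversals), 9^6)
})

test_that("layer conservation holds and matches the viable total", {
  model <- toy_model()
  sched <- decision_schedule(0, 4, 1)
  dom <- toy_domain(0.25, 0.2)
  g <- enumerate_viable(model, c(0.6, 0.5), sched, dom)
  for (l in unique(g$edges$layer)) {
    expect_equal(sum(g$edges$traversals[g$edges$layer == l]), g$total_viable)
  }
})

test_that("collected pathways carry the same security as re-simulation", {
  model <- toy_model()
  sched <- decision_schedule(0, 3, 1)
  dom <- toy_domain(0.28, 0.22)
  g <- enumerate_viable(model, c(0.6, 0.55), sched, dom)
  ps <- collect_pathways(g)
  expect_equal(nrow(ps$paths), g$total_viable)
  for (i in seq_len(min(nrow(ps$paths), 12))) {
    r <- simulate_pathway(model, c(0.6, 0.55), ps$paths[i, ], sched, dom)
    expect_true(r$viable)
    expect_equal(ps$security[i], r$security, tolerance = 1e-12)
    expect_equal(unname(ps$es_mean[i, ]),
                 unname(colMeans(r$es)), tolerance = 1e-12)
  }
})

test_that("top_secured keeps the requested fraction with documented
           tie-breaking, and fraction 1 returns everything", {
  sched <- decision_schedule(0, 3, 1)
  fake <- structure(list(
    paths = as.matrix(expand.grid(a = 1:2, b = 1:2, c = 1:2, d = 1:2)),
    security = rep(0.5, 16),
    es_mean = matrix(0.5, 16, 1, dimnames = list(NULL, "es_x")),
    per_es_margin = matrix(0.5, 16, 1, dimnames = list(NULL, "es_x")),
    arrangement_ids = c("A1", "A2"), schedule = sched
  ), class = "pathway_set")
  top <- top_secured(fake, 0.25)
  expect_equal(nrow(top$paths), 4)
  # all securities equal: lexicographically smallest sequences win
  expect_equal(top$paths[1, ], c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(top$paths[2, ], c(a = 1, b = 1, c = 1, d = 2))

  expect_equal(nrow(top_secured(fake, 1)$paths), 16)

  # graded securities: matches an independent sort-then-cut
  fake$security <- seq(0, 1, length.out = 16)
  top2 <- top_secured(fake, 0.5)
  want <- order(fake$security, decreasing = TRUE)[1:8]
  expect_equal(sort(top2$security), sort(fake$security[want]))
})

test_that("optimal_for_es returns the argmax set of the aggregate", {
  model <- toy_model()
  sched <- decision_schedule(0, 3, 1)
  dom <- toy_domain(0.28, 0.22)
  g <- enumerate_viable(model, c(0.6, 0.55), sched, dom)
  ps <- collect_pathways(g)
  opt <- optimal_for_es(ps, "es_x", "maximize")
  best <- max(ps$es_mean[, "es_x"])
  expect_true(all(abs(opt$es_mean[, "es_x"] - best) <= 1e-9))
  expect_equal(nrow(opt$paths), sum(abs(ps$es_mean[, "es_x"] - best) <= 1e-9))

  opt_min <- optimal_for_es(ps, "es_y", "minimize")
  expect_equal(min(ps$es_mean[, "es_y"]), unname(opt_min$es_mean[1, "es_y"]))
  expect_error(optimal_for_es(ps, "nope"), "unknown ES")
})

test_that("pathway_graph tabulates segment traversals of an explicit set", {
  sched <- decision_schedule(0, 2, 1)
  fake <- structure(list(
    paths = rbind(c(1, 2, 1), c(1, 2, 2), c(2, 2, 1)),
    security = c(0.3, 0.2, 0.1),
    es_mean = matrix(0, 3, 1, dimnames = list(NULL, "es_x")),
    per_es_margin = matrix(0, 3, 1, dimnames = list(NULL, "es_x")),
    arrangement_ids = c("A1", "A2"), schedule = sched
  ), class = "pathway_set")
  g <- pathway_graph(fake, n_arrangements = 2)
  a <- edges_as_array(g)
  expect_equal(a[1, 1, 2], 2)   # two pathways cross 1 -> 2 in layer 1
  expect_equal(a[1, 2, 2], 1)
  expect_equal(a[2, 2, 1], 2)
  expect_equal(a[2, 2, 2], 1)
  expect_equal(sum(a[1, , ]), 3)
})
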