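# Shared toy models and independent brute-force oracles.  The oracles are
# written as plain loops over explicitly enumerated control sequences so
# that they share no code path with the package implementation.

# Two-dimensional toy model: state (x, y) in [0, 1]^2, affine annual maps
# clamped to the box, ES = the state coordinates themselves (two services).
toy_model <- function(maps = NULL) {
  if (is.null(maps)) {
    maps <- list(
      list(A = matrix(c(0.9, 0.0, 0.0, 0.9), 2), b = c(0.05, 0.02)),
      list(A = matrix(c(0.7, 0.1, 0.2, 0.8), 2), b = c(0.00, 0.05)),
      list(A = matrix(c(0.95, 0.0, 0.0, 0.95), 2), b = c(-0.02, 0.04))
    )
  }
  structure(list(
    n_arrangements = length(maps),
    arrangement_ids = paste0("A", seq_along(maps)),
    state_names = c("x", "y"),
    grid_dim = 2L,
    grid_names = c("x", "y"),
    maps = maps,
    step = function(states, arr) {
      m <- maps[[arr]]
      out <- states %*% t(m$A) + matrix(m$b, nrow(states), 2, byrow = TRUE)
      pmin(pmax(out, 0), 1)
    },
    es = function(states) {
      colnames(states) <- c("es_x", "es_y")
      states
    },
    es_names = c("es_x", "es_y"),
    es_signs = c("service", "service"),
    grid_to_state = function(g) g,
    state_to_grid = function(s) s,
    valid_grid = function(g) rep(TRUE, nrow(g))
  ), class = "pathway_model")
}

toy_domain <- function(xmin = 0.1, ymin = 0.1) {
  satisfactory_domain(es_min = c(es_x = xmin, es_y = ymin))
}

# direct per-constraint membership check (margin oracle)
oracle_in_domain <- function(domain, levels) {
  ok <- TRUE
  for (i in seq_len(nrow(domain))) {
    lv <- levels[[domain$name[i]]]
    ok <- ok && if (domain$sign[i] == "service") lv >= domain$bound[i]
                else lv <= domain$bound[i]
  }
  ok
}

# one toy annual step, scalar version, written out longhand
oracle_toy_step <- function(model, s, arr) {
  m <- model$maps[[arr]]
  v <- c(m$A[1, 1] * s[1] + m$A[1, 2] * s[2] + m$b[1],
         m$A[2, 1] * s[1] + m$A[2, 2] * s[2] + m$b[2])
  pmin(pmax(v, 0), 1)
}

oracle_toy_in_domain <- function(domain, s) {
  oracle_in_domain(domain, list(es_x = s[1], es_y = s[2]))
}

# snap a toy state to the nearest node of an axis-aligned grid on [0,1]^2
oracle_snap <- function(s, n) {
  h <- 1 / (n - 1)
  round(s / h) * h
}

# all control sequences of length `len` over 1..n_arr, as a matrix
all_sequences <- function(n_arr, len) {
  as.matrix(expand.grid(rep(list(seq_len(n_arr)), len)))
}

# Brute-force finite-horizon viability of one grid node: enumerate every
# control sequence; a sequence keeps the node viable iff the start state and
# every annual state satisfy the constraints and every interval endpoint,
# snapped to the grid, continues to do so.  Returns, per decision epoch, the
# set of first-choice controls that admit a viable continuation.
oracle_node_controls <- function(model, domain, s0, n_grid, n_intervals,
                                 n_sub) {
  seqs <- all_sequences(model$n_arrangements, n_intervals)
  viable_first <- vector("list", n_intervals)
  for (k in seq_len(n_intervals)) viable_first[[k]] <- integer(0)
  any_viable <- FALSE
  for (r in seq_len(nrow(seqs))) {
    s <- s0
    ok <- oracle_toy_in_domain(domain, s)
    visited <- list(s)
    if (ok) {
      for (k in seq_len(n_intervals)) {
        for (y in seq_len(n_sub)) {
          s <- oracle_toy_step(model, s, seqs[r, k])
          if (!oracle_toy_in_domain(domain, s)) { ok <- FALSE; break }
        }
        if (!ok) break
        s <- oracle_snap(s, n_grid)
        if (!oracle_toy_in_domain(domain, s)) { ok <- FALSE; break }
        visited[[k + 1]] <- s
      }
    }
    if (ok) {
      any_viable <- TRUE
      # record the surviving first choices at every suffix start; a suffix
      # starting at epoch k is viable iff the remaining sequence works from
      # the state visited at epoch k
      viable_first[[1]] <- union(viable_first[[1]], seqs[r, 1])
    }
  }
  list(viable = any_viable, first_controls = sort(viable_first[[1]]))
}

# Brute-force DAPP enumeration: simulate every pathway with
# simulate_pathway() and tally totals and per-edge traversal counts.
oracle_enumerate <- function(model, initial_state, schedule, domain) {
  n_arr <- model$n_arrangements
  L <- schedule$epochs
  seqs <- all_sequences(n_arr, L)
  edges <- array(0, dim = c(L - 1, n_arr, n_arr))
  total <- 0
  for (r in seq_len(nrow(seqs))) {
    res <- simulate_pathway(model, initial_state, seqs[r, ], schedule, domain)
    if (res$viable) {
      total <- total + 1
      for (l in seq_len(L - 1)) {
        edges[l, seqs[r, l], seqs[r, l + 1]] <-
          edges[l, seqs[r, l], seqs[r, l + 1]] + 1
      }
    }
  }
  list(total = total, edges = edges)
}

edges_as_array <- function(graph) {
  n <- graph$n_arrangements
  L <- graph$schedule$epochs
  out <- array(0, dim = c(L - 1, n, n))
  for (r in seq_len(nrow(graph$edges))) {
    e <- graph$edges[r, ]
    out[e$layer, e$arr_from, e$arr_to] <- e$traversals
  }
  out
}

# random valid action weights: positive group shares plus ranged operationals
random_weights <- function() {
  rand_simplex <- function(nms) {
    v <- stats::runif(length(nms))
    stats::setNames(v / sum(v), nms)
  }
  g <- c(rand_simplex(c("u0b", "u1b", "u2b", "u6b", "u7d")),
         rand_simplex(c("u0c", "u2a", "u3b", "u7f")),
         rand_simplex(c("u0d", "u3a", "u4a", "u6a", "u7h")))
  op <- c(u0a = stats::runif(1, -1, 1), u1a = stats::runif(1),
          u4b = stats::runif(1, -1, 1),
          u5a = stats::runif(1), u5b = stats::runif(1),
          u5a_prime = stats::runif(1), u5b_prime = stats::runif(1),
          u6b_prime = stats::runif(1, -1, 1),
          u7a = stats::runif(1, -1, 1), u7b = stats::runif(1, -1, 0),
          u7c = stats::runif(1, -1, 1), u7e = stats::runif(1, -1, 1),
          u7g = stats::runif(1, -1, 1))
  action_weights(.values = c(g, op))
}

random_simplex_state <- function() {
  v <- -log(stats::runif(5))
  hedgerow_state(stats::setNames(v / sum(v), c("TR", "TP", "SR", "SP", "NO")))
}
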