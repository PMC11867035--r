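# DAPP maps: enumeration of governance pathways over decision epochs,
# per-segment viable-traversal counts, security scoring, and selection of
# most-secured / per-ES optimal pathway subsets.
#
# A pathway assigns one arrangement per decision epoch.  The arrangement
# chosen at epoch k governs the interval [t_k, t_{k+1}); the final epoch's
# arrangement labels the end state but governs no interval, so with U
# arrangements and T/step + 1 epochs there are U^(T/step + 1) pathways.

#' Decision schedule
#'
#' @param start First decision year (label only).
#' @param horizon Planning horizon in years.
#' @param step Years between decisions; must divide the horizon.
#' @return A list of class `"decision_schedule"` with `start`, `horizon`,
#'   `step` and `epochs = horizon/step + 1`.
#' @examples
#' decision_schedule(2020, 30, 5)$epochs  # 7
#' @export
decision_schedule <- function(start = 2020, horizon = 30, step = 5) {
  stopifnot(horizon > 0, step > 0)
  if (horizon %% step != 0) stop("step must divide the horizon")
  structure(list(start = start, horizon = as.integer(horizon),
                 step = as.integer(step),
                 epochs = as.integer(horizon / step + 1)),
            class = "decision_schedule")
}

#' Number of possible governance pathways
#'
#' With `n_arrangements` choices at each of the schedule's decision epochs
#' the pathway space has `n_arrangements ^ epochs` elements (the upper bound
#' on the size of a DAPP graph).
#'
#' @param n_arrangements Number of arrangements (>= 1).
#' @param schedule A [decision_schedule()], or an integer number of epochs.
#' @return A numeric count (exact for counts below 2^53).
#' @examples
#' count_pathways(9, decision_schedule(2020, 30, 5))  # 4782969
#' @export
count_pathways <- function(n_arrangements, schedule) {
  stopifnot(n_arrangements >= 1)
  epochs <- if (inherits(schedule, "decision_schedule")) schedule$epochs
            else as.integer(schedule)
  as.numeric(n_arrangements)^epochs
}

# resolve arrangement identifiers to indices
resolve_pathway <- function(pathway, model) {
  if (is.character(pathway)) {
    idx <- match(pathway, model$arrangement_ids)
    if (anyNA(idx)) stop("unknown arrangement id in pathway")
    idx
  } else as.integer(pathway)
}

#' Simulate one governance pathway
#'
#' Runs the model at annual resolution under the pathway's arrangement
#' sequence, evaluates the ES levels and their constraint margins at every
#' annual state, and scores the pathway: it is viable iff every annual state
#' lies in the satisfactory domain, and its security is the time-aggregated
#' normalized margin sum (mean over annual steps by default, worst year with
#' `aggregate = "min"`).
#'
#' @param model A `"pathway_model"` (see [as_pathway_model()]).
#' @param initial_state Full model state vector at the first epoch.
#' @param pathway Vector of arrangement indices (or identifiers), one per
#'   epoch; the last entry labels the end state only.
#' @param schedule A [decision_schedule()].
#' @param domain A [satisfactory_domain()].
#' @param aggregate Security aggregation over annual steps.
#' @return A list of class `"pathway_result"`: `years`, `states`, `es`
#'   (annual level matrix), `viable`, `security`, `first_violation` (year of
#'   the first constraint violation, or `NA`), `per_es_margin` (time-mean
#'   normalized margin per ES), `pathway`, `arrangement_ids`.
#' @export
simulate_pathway <- function(model, initial_state, pathway, schedule, domain,
                             aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  pathway <- resolve_pathway(pathway, model)
  stopifnot(length(pathway) == schedule$epochs)
  n_years <- schedule$horizon
  states <- matrix(NA_real_, n_years + 1, length(initial_state))
  colnames(states) <- model$state_names
  states[1, ] <- as.numeric(initial_state)
  s <- matrix(as.numeric(initial_state), nrow = 1)
  row <- 1
  for (k in seq_len(schedule$epochs - 1)) {
    for (y in seq_len(schedule$step)) {
      s <- model$step(s, pathway[k])
      row <- row + 1
      states[row, ] <- s
    }
  }
  es <- model$es(states)
  es <- es[, domain$name, drop = FALSE]
  mm <- margin_matrix(domain, es)
  ok_row <- rowSums(mm$margin < 0) == 0
  viable <- all(ok_row)
  nm_sum <- rowMeans(mm$normalized)
  security <- if (aggregate == "mean") mean(nm_sum) else min(nm_sum)
  structure(
    list(years = schedule$start + 0:n_years, states = states,
         es = model$es(states), viable = viable, security = security,
         first_violation = if (viable) NA_integer_ else which(!ok_row)[1] - 1L,
         per_es_margin = colMeans(mm$normalized),
         pathway = pathway,
         arrangement_ids = model$arrangement_ids[pathway],
         schedule = schedule),
    class = "pathway_result"
  )
}

#' @export
print.pathway_result <- function(x, ...) {
  cat("pathway:", paste(x$arrangement_ids, collapse = " -> "), "\n")
  if (x$viable) {
    cat(sprintf("viable; security %.4f\n", x$security))
  } else {
    cat(sprintf("non-viable (first violation at year %d); security %.4f\n",
                x$first_violation, x$security))
  }
  invisible(x)
}

#' Annual ES trajectory table of a pathway
#'
#' @param pathway A [simulate_pathway()] result, or a vector of arrangement
#'   indices (then `model`, `initial_state`, `schedule` and `domain` must be
#'   supplied).
#' @param model,initial_state,schedule,domain Used when `pathway` is a raw
#'   sequence.
#' @return A data frame with `year` and one column per ES; `horizon + 1`
#'   rows.
#' @export
es_trajectories <- function(pathway, model = NULL, initial_state = NULL,
                            schedule = NULL, domain = NULL) {
  if (!inherits(pathway, "pathway_result")) {
    pathway <- simulate_pathway(model, initial_state, pathway, schedule, domain)
  }
  data.frame(year = pathway$years, pathway$es, check.names = FALSE)
}

# viability of one interval: step `n_sub` annual sub-steps from a state
# matrix, checking the domain at every sub-step; returns endpoint states and
# a per-row all-clear flag plus per-row margin/ES accumulators
step_interval <- function(model, states, arr, n_sub, domain,
                          check_every_step = TRUE) {
  ok <- rep(TRUE, nrow(states))
  nm_total <- rep(0, nrow(states))
  es_total <- matrix(0, nrow(states), length(domain$name))
  per_es_nm <- matrix(0, nrow(states), length(domain$name))
  s <- states
  for (y in seq_len(n_sub)) {
    s <- model$step(s, arr)
    lv <- model$es(s)[, domain$name, drop = FALSE]
    mm <- margin_matrix(domain, lv)
    if (check_every_step || y == n_sub) {
      ok <- ok & rowSums(mm$margin < 0) == 0
    }
    nm_total <- nm_total + rowMeans(mm$normalized)
    es_total <- es_total + lv
    per_es_nm <- per_es_nm + mm$normalized
  }
  list(states = s, ok = ok, nm_total = nm_total, es_total = es_total,
       per_es_nm = per_es_nm)
}

state_keys <- function(states) {
  do.call(paste, c(as.data.frame(states), list(sep = "|")))
}

#' Enumerate viable pathways into a DAPP graph
#'
#' Explores the arrangement-choice tree epoch by epoch from the initial
#' state, pruning prefixes that leave the satisfactory domain.  Because the
#' dynamics are deterministic, states reached by different prefixes that
#' coincide exactly are merged (memoization on the exact floating-point
#' state; disable with `memoize = FALSE`), and viable-suffix counts are
#' shared.  Per-edge traversal counts are the number of unique full-horizon
#' viable pathways crossing each 5-year segment between two decision nodes:
#' (viable prefixes reaching the edge) x (viable suffixes from its head).
#' The grayscale `shade` of an edge is its count divided by the maximum edge
#' count in the map.
#'
#' @inheritParams simulate_pathway
#' @param check_every_step Check the domain at every annual sub-step (the
#'   default) or only at decision nodes.
#' @param memoize Merge identical states reached by different prefixes.
#' @return A list of class `"dapp_graph"`: `edges` (data frame with `layer`,
#'   `arr_from`, `arr_to`, `traversals`, `shade`), `total_viable`,
#'   `total_pathways`, `n_arrangements`, `schedule`, `arrangement_ids`, and
#'   the layered state DAG in `dag` (used by [collect_pathways()]).
#' @export
enumerate_viable <- function(model, initial_state, schedule, domain,
                             check_every_step = TRUE, memoize = TRUE) {
  n_arr <- model$n_arrangements
  L <- schedule$epochs                 # epoch times t_0 .. t_{L-1}
  n_es <- length(domain$name)

  s0 <- matrix(as.numeric(initial_state), nrow = 1)
  lv0 <- model$es(s0)[, domain$name, drop = FALSE]
  mm0 <- margin_matrix(domain, lv0)
  init_ok <- all(mm0$margin[1, ] >= 0)

  empty_graph <- function() {
    edges <- expand.grid(arr_from = seq_len(n_arr), arr_to = seq_len(n_arr),
                         layer = seq_len(L - 1))[, c("layer", "arr_from", "arr_to")]
    edges$traversals <- 0
    edges$shade <- 0
    structure(list(edges = edges, total_viable = 0,
                   total_pathways = count_pathways(n_arr, schedule),
                   n_arrangements = n_arr, schedule = schedule,
                   arrangement_ids = model$arrangement_ids,
                   dag = NULL, initial_margin = mm0$normalized[1, ]),
              class = "dapp_graph")
  }
  if (!init_ok) return(empty_graph())

  layers <- vector("list", L)
  layers[[1]] <- s0
  trans <- vector("list", L - 1)       # viable interval transitions
  for (l in seq_len(L - 1)) {
    st <- layers[[l]]
    n_l <- nrow(st)
    res_l <- vector("list", n_arr)
    for (a in seq_len(n_arr)) {
      r <- step_interval(model, st, a, schedule$step, domain, check_every_step)
      keep <- which(r$ok)
      res_l[[a]] <- if (length(keep)) {
        list(from = keep, arr = rep(a, length(keep)),
             states = r$states[keep, , drop = FALSE],
             nm_total = r$nm_total[keep],
             es_total = r$es_total[keep, , drop = FALSE],
             per_es_nm = r$per_es_nm[keep, , drop = FALSE])
      } else NULL
    }
    res_l <- res_l[!vapply(res_l, is.null, logical(1))]
    if (!length(res_l)) return(empty_graph())
    from <- unlist(lapply(res_l, `[[`, "from"))
    arr <- unlist(lapply(res_l, `[[`, "arr"))
    new_states <- do.call(rbind, lapply(res_l, `[[`, "states"))
    nm_total <- unlist(lapply(res_l, `[[`, "nm_total"))
    es_total <- do.call(rbind, lapply(res_l, `[[`, "es_total"))
    per_es_nm <- do.call(rbind, lapply(res_l, `[[`, "per_es_nm"))
    if (memoize) {
      keys <- state_keys(new_states)
      uk <- !duplicated(keys)
      to <- match(keys, keys[uk])
      layers[[l + 1]] <- new_states[uk, , drop = FALSE]
    } else {
      to <- seq_along(from)
      layers[[l + 1]] <- new_states
    }
    trans[[l]] <- list(from = from, arr = arr, to = to, nm_total = nm_total,
                       es_total = es_total, per_es_nm = per_es_nm)
  }

  # backward viable-suffix counts sv[[l]][state, first choice at epoch l]
  sv <- vector("list", L)
  sv[[L]] <- matrix(1, nrow(layers[[L]]), n_arr)
  for (l in rev(seq_len(L - 1))) {
    S_next <- rowSums(sv[[l + 1]])
    m <- matrix(0, nrow(layers[[l]]), n_arr)
    tr <- trans[[l]]
    m[cbind(tr$from, tr$arr)] <- S_next[tr$to]
    sv[[l]] <- m
  }
  total_viable <- sum(sv[[1]][1, ])

  # forward viable-prefix counts
  p <- vector("list", L)
  p[[1]] <- 1
  for (l in seq_len(L - 1)) {
    tr <- trans[[l]]
    pv <- rep(0, nrow(layers[[l + 1]]))
    # only transitions whose head still admits viable suffixes carry prefixes
    w <- p[[l]][tr$from]
    acc <- rowsum(w, group = tr$to)
    pv[as.integer(rownames(acc))] <- acc[, 1]
    p[[l + 1]] <- pv
  }

  # per-edge traversal counts between epoch layers
  edge_list <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    tr <- trans[[l]]
    w <- p[[l]][tr$from]
    m <- sv[[l + 1]][tr$to, , drop = FALSE] * w
    em <- matrix(0, n_arr, n_arr)
    acc <- rowsum(m, group = tr$arr)
    em[as.integer(rownames(acc)), ] <- acc
    edge_list[[l]] <- data.frame(
      layer = l,
      arr_from = rep(seq_len(n_arr), times = n_arr),
      arr_to = rep(seq_len(n_arr), each = n_arr),
      traversals = as.vector(em)
    )
  }
  edges <- do.call(rbind, edge_list)
  max_e <- max(edges$traversals)
  edges$shade <- if (max_e > 0) edges$traversals / max_e else 0

  structure(
    list(edges = edges, total_viable = total_viable,
         total_pathways = count_pathways(n_arr, schedule),
         n_arrangements = n_arr, schedule = schedule,
         arrangement_ids = model$arrangement_ids,
         dag = list(layers = layers, trans = trans, sv = sv, p = p,
                    init_nm = mean(mm0$normalized[1, ]),
                    init_es = lv0[1, ],
                    init_per_es_nm = mm0$normalized[1, ],
                    n_es = n_es, es_names = domain$name),
         initial_margin = mm0$normalized[1, ]),
    class = "dapp_graph"
  )
}

#' @export
print.dapp_graph <- function(x, ...) {
  cat(sprintf("DAPP graph: %d arrangements x %d epochs\n",
              x$n_arrangements, x$schedule$epochs))
  cat(sprintf("viable pathways: %s of %s (%.3f%%)\n",
              format(x$total_viable, big.mark = ","),
              format(x$total_pathways, big.mark = ","),
              100 * x$total_viable / x$total_pathways))
  invisible(x)
}

#' @export
summary.dapp_graph <- function(object, ...) {
  by_layer <- tapply(object$edges$traversals, object$edges$layer, sum)
  out <- list(total_viable = object$total_viable,
              total_pathways = object$total_pathways,
              viable_fraction = object$total_viable / object$total_pathways,
              traversals_by_layer = by_layer)
  class(out) <- "summary.dapp_graph"
  out
}

#' @export
print.summary.dapp_graph <- function(x, ...) {
  cat(sprintf("viable: %s / %s (%.4f%%)\n",
              format(x$total_viable, big.mark = ","),
              format(x$total_pathways, big.mark = ","),
              100 * x$viable_fraction))
  cat("edge traversals per layer:",
      paste(format(x$traversals_by_layer, big.mark = ","), collapse = ", "),
      "\n")
  invisible(x)
}

#' Plot a DAPP map
#'
#' Draws the epoch-layered graph with one horizontal lane per arrangement
#' and one segment per inter-epoch edge, shaded by its viable-traversal
#' count (darker = more unique viable pathways crossing the segment).
#'
#' @param x A `"dapp_graph"`.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dapp_graph <- function(x, main = "DAPP map", ...) {
  ep <- x$schedule$epochs
  years <- x$schedule$start + (seq_len(ep) - 1) * x$schedule$step
  graphics::plot(NA, xlim = range(years), ylim = c(0.5, x$n_arrangements + 0.5),
                 xlab = "year", ylab = "", yaxt = "n", main = main, ...)
  graphics::axis(2, at = seq_len(x$n_arrangements),
                 labels = x$arrangement_ids, las = 2, cex.axis = 0.7)
  e <- x$edges[x$edges$traversals > 0, ]
  if (nrow(e)) {
    graphics::segments(years[e$layer], e$arr_from, years[e$layer + 1], e$arr_to,
                       col = grDevices::gray(1 - 0.9 * e$shade), lwd = 2)
  }
  invisible(x)
}

#' Expand the viable pathways stored in a DAPP graph
#'
#' Walks the layered state DAG of [enumerate_viable()] and materializes every
#' viable pathway with its security score and per-ES aggregates.  The number
#' of viable pathways can be astronomically large; the expansion refuses to
#' materialize more than `max_pathways`.
#'
#' @param graph A `"dapp_graph"` with a stored DAG.
#' @param max_pathways Upper bound on the number of pathways to expand.
#' @return A list of class `"pathway_set"`: `paths` (integer matrix, one row
#'   per pathway, one column per epoch), `security`, `es_mean` (matrix of
#'   time-mean annual ES levels), `per_es_margin` (matrix of time-mean
#'   normalized margins), `arrangement_ids`, `schedule`.
#' @export
collect_pathways <- function(graph, max_pathways = 2e5) {
  stopifnot(inherits(graph, "dapp_graph"))
  if (graph$total_viable == 0) {
    return(structure(list(paths = matrix(integer(), 0, graph$schedule$epochs),
                          security = numeric(), es_mean = NULL,
                          per_es_margin = NULL,
                          arrangement_ids = graph$arrangement_ids,
                          schedule = graph$schedule),
                     class = "pathway_set"))
  }
  if (graph$total_viable > max_pathways) {
    stop("refusing to expand ", format(graph$total_viable, big.mark = ","),
         " viable pathways (max_pathways = ",
         format(max_pathways, big.mark = ","), ")")
  }
  dag <- graph$dag
  L <- graph$schedule$epochs
  n_year <- graph$schedule$horizon + 1
  n_es <- dag$n_es
  # partial prefixes: state index, choices so far, accumulated sums
  pref <- list(state = 1L, choice = integer(0),
               nm = dag$init_nm, es = dag$init_es,
               pm = dag$init_per_es_nm)
  stack <- list(pref)
  paths <- vector("list", 0)
  for (l in seq_len(L - 1)) {
    tr <- dag$trans[[l]]
    alive <- rowSums(dag$sv[[l + 1]]) > 0
    by_state <- split(seq_along(tr$from), tr$from)
    nxt <- list()
    for (pf in stack) {
      sel <- by_state[[as.character(pf$state)]]
      for (i in sel) {
        if (!alive[tr$to[i]]) next
        nxt[[length(nxt) + 1]] <- list(
          state = tr$to[i], choice = c(pf$choice, tr$arr[i]),
          nm = pf$nm + tr$nm_total[i],
          es = pf$es + tr$es_total[i, ],
          pm = pf$pm + tr$per_es_nm[i, ])
      }
    }
    stack <- nxt
  }
  n_core <- length(stack)
  n_arr <- graph$n_arrangements
  paths <- matrix(0L, n_core * n_arr, L)
  security <- numeric(n_core * n_arr)
  es_mean <- matrix(0, n_core * n_arr, n_es,
                    dimnames = list(NULL, dag$es_names))
  per_es <- matrix(0, n_core * n_arr, n_es,
                   dimnames = list(NULL, dag$es_names))
  r <- 0
  for (pf in stack) {
    for (lab in seq_len(n_arr)) {   # terminal label governs no interval
      r <- r + 1
      paths[r, ] <- c(pf$choice, lab)
      security[r] <- pf$nm / n_year
      es_mean[r, ] <- pf$es / n_year
      per_es[r, ] <- pf$pm / n_year
    }
  }
  structure(list(paths = paths, security = security, es_mean = es_mean,
                 per_es_margin = per_es,
                 arrangement_ids = graph$arrangement_ids,
                 schedule = graph$schedule),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("pathway set: %d pathways x %d epochs\n",
              nrow(x$paths), ncol(x$paths)))
  if (nrow(x$paths)) {
    cat(sprintf("security range: [%.4f, %.4f]\n",
                min(x$security), max(x$security)))
  }
  invisible(x)
}

subset_pathway_set <- function(ps, idx) {
  structure(list(paths = ps$paths[idx, , drop = FALSE],
                 security = ps$security[idx],
                 es_mean = ps$es_mean[idx, , drop = FALSE],
                 per_es_margin = ps$per_es_margin[idx, , drop = FALSE],
                 arrangement_ids = ps$arrangement_ids,
                 schedule = ps$schedule),
            class = "pathway_set")
}

#' Most-secured pathway subset
#'
#' Selects the `ceiling(fraction * n)` viable pathways with the highest
#' security; ties are broken by lexicographic order of the arrangement
#' sequence (lower indices first).
#'
#' @param pathways A [collect_pathways()] pathway set (viable pathways).
#' @param fraction Fraction in `(0, 1]` of pathways to keep.
#' @return A `"pathway_set"` with the selected pathways, ordered from most
#'   to least secured.
#' @export
top_secured <- function(pathways, fraction = 0.10) {
  stopifnot(inherits(pathways, "pathway_set"),
            fraction > 0, fraction <= 1)
  n <- nrow(pathways$paths)
  if (n == 0) return(pathways)
  ord <- do.call(order, c(list(-pathways$security),
                          as.data.frame(pathways$paths)))
  keep <- ord[seq_len(ceiling(fraction * n))]
  subset_pathway_set(pathways, keep)
}

#' Pathways optimal for one ecosystem service
#'
#' Among the given viable pathways, returns all pathways achieving the best
#' time-aggregated level of the named ES: the highest mean annual level for
#' `sense = "maximize"` (services) or the lowest for `sense = "minimize"`
#' (disservices).  Co-optimal pathways (aggregate within `tol` of the best)
#' are all returned.
#'
#' @param pathways A [collect_pathways()] pathway set.
#' @param es_name Name of the ES.
#' @param sense `"maximize"` or `"minimize"`.
#' @param tol Tie tolerance on the aggregate.
#' @return A `"pathway_set"` of co-optimal pathways.
#' @export
optimal_for_es <- function(pathways, es_name, sense = c("maximize", "minimize"),
                           tol = 1e-9) {
  sense <- match.arg(sense)
  stopifnot(inherits(pathways, "pathway_set"))
  if (!es_name %in% colnames(pathways$es_mean)) {
    stop("unknown ES name: ", es_name)
  }
  v <- pathways$es_mean[, es_name]
  if (!length(v)) return(pathways)
  best <- if (sense == "maximize") max(v) else min(v)
  subset_pathway_set(pathways, which(abs(v - best) <= tol))
}

#' Build a DAPP graph from an explicit pathway set
#'
#' Tabulates per-segment traversal counts of the given pathways (used for
#' the most-secured and per-ES optimal maps).
#'
#' @param pathways A `"pathway_set"`.
#' @param n_arrangements Total number of arrangements (defaults to the
#'   number of arrangement ids in the set).
#' @return A `"dapp_graph"` without a stored DAG.
#' @export
pathway_graph <- function(pathways,
                          n_arrangements = length(pathways$arrangement_ids)) {
  L <- pathways$schedule$epochs
  edge_list <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    em <- matrix(0, n_arrangements, n_arrangements)
    if (nrow(pathways$paths)) {
      tab <- table(factor(pathways$paths[, l], levels = seq_len(n_arrangements)),
                   factor(pathways$paths[, l + 1], levels = seq_len(n_arrangements)))
      em <- em + unclass(tab)
    }
    edge_list[[l]] <- data.frame(
      layer = l,
      arr_from = rep(seq_len(n_arrangements), times = n_arrangements),
      arr_to = rep(seq_len(n_arrangements), each = n_arrangements),
      traversals = as.vector(em)
    )
  }
  edges <- do.call(rbind, edge_list)
  max_e <- max(edges$traversals, 1)
  edges$shade <- edges$traversals / max_e
  structure(list(edges = edges, total_viable = nrow(pathways$paths),
                 total_pathways = count_pathways(n_arrangements,
                                                 pathways$schedule),
                 n_arrangements = n_arrangements,
                 schedule = pathways$schedule,
                 arrangement_ids = pathways$arrangement_ids, dag = NULL),
            class = "dapp_graph")
}
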