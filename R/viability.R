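# Finite-horizon viability kernel on a discrete state grid, computed by
# backward induction (the discrete approximation of the backward viability
# algorithm): a grid node is viable at epoch k iff its ES image satisfies
# every constraint and at least one arrangement steers it -- checking the
# constraints at every annual sub-step -- to a node viable at epoch k+1.
# The set of such arrangements per node and epoch is the regulation map.

#' Specify a regular state grid
#'
#' @param lower,upper Numeric vectors of per-dimension bounds.
#' @param n Integer vector (or scalar, recycled) of grid points per
#'   dimension; default 21.
#' @param names Optional dimension names.
#' @return A list of class `"grid_spec"`.
#' @examples
#' grid_spec(c(0, 0), c(1, 1), n = 5)
#' @export
grid_spec <- function(lower, upper, n = 21, names = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  n <- rep_len(as.integer(n), d)
  stopifnot(all(n >= 2))
  if (is.null(names)) names <- paste0("x", seq_len(d))
  structure(list(lower = lower, upper = upper, n = n, names = names,
                 h = (upper - lower) / (n - 1)),
            class = "grid_spec")
}

grid_nodes <- function(spec) {
  axes <- lapply(seq_along(spec$n), function(d) {
    seq(spec$lower[d], spec$upper[d], length.out = spec$n[d])
  })
  g <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- spec$names
  g
}

# node index (expand.grid order, first dimension fastest) from per-dim
# 0-based indices
node_index <- function(idx0, n) {
  mult <- cumprod(c(1, n[-length(n)]))
  as.integer(1 + idx0 %*% mult)
}

# snap grid-space coordinates to nodes; coordinates outside the bounds give
# NA (trajectory left the grid).  If a `valid` predicate is given, a snapped
# node violating it is repaired by stepping down, one grid step at a time,
# the coordinate with the largest upward rounding residual (deterministic);
# unrepairable rows give NA.
snap_to_grid <- function(coords, spec, valid = NULL) {
  d <- length(spec$n)
  rel <- sweep(sweep(coords, 2, spec$lower, "-"), 2, spec$h, "/")
  idx0 <- round(rel)
  oob <- rowSums(idx0 < -1e-9 | sweep(idx0, 2, spec$n - 1, ">")) > 0
  idx0 <- pmin(pmax(idx0, 0), matrix(spec$n - 1, nrow(coords), d, byrow = TRUE))
  if (!is.null(valid)) {
    node_coords <- sweep(sweep(idx0, 2, spec$h, "*"), 2, spec$lower, "+")
    bad <- which(!valid(node_coords) & !oob)
    for (r in bad) {
      repaired <- FALSE
      for (it in seq_len(sum(spec$n))) {
        resid <- idx0[r, ] - rel[r, ]   # upward rounding per coordinate
        cand <- which(idx0[r, ] > 0)
        if (!length(cand)) break
        j <- cand[which.max(resid[cand])]
        idx0[r, j] <- idx0[r, j] - 1
        nc <- spec$lower + idx0[r, ] * spec$h
        if (valid(matrix(nc, 1))) { repaired <- TRUE; break }
      }
      if (!repaired) oob[r] <- TRUE
    }
  }
  out <- node_index(idx0, spec$n)
  out[oob] <- NA_integer_
  out
}

#' Compute the finite-horizon viability kernel
#'
#' Backward induction over the decision epochs on a regular grid of the
#' model's state space.  At the final epoch a node is viable iff its ES
#' image lies in the satisfactory domain.  At every earlier epoch a node is
#' viable iff it lies in the domain and at least one arrangement maps it --
#' simulating one decision interval at annual resolution and checking the
#' domain at every sub-step unless `check_every_step = FALSE` -- to a grid
#' cell viable at the next epoch (interval endpoints are snapped to the
#' nearest node).  Trajectories leaving the grid bounds are treated as
#' non-viable and counted in `n_out_of_bounds`.
#'
#' @inheritParams enumerate_viable
#' @param grid A [grid_spec()] over the model's gridded dimensions, or an
#'   integer number of points per dimension (bounds then default to
#'   `[0, 1]`).
#' @return A list of class `"viability_kernel"`: `membership` (logical
#'   matrix, nodes x epochs), `controls` (logical array, nodes x
#'   arrangements x (epochs - 1): the regulation map), `nodes` (grid
#'   coordinates), `grid`, `schedule`, `domain`, `arrangement_ids`,
#'   `n_out_of_bounds`.
#' @export
compute_kernel <- function(model, domain, schedule, grid = 21,
                           check_every_step = TRUE) {
  if (!inherits(grid, "grid_spec")) {
    grid <- grid_spec(rep(0, model$grid_dim), rep(1, model$grid_dim),
                      n = grid, names = model$grid_names)
  }
  G <- grid_nodes(grid)
  n_nodes <- nrow(G)
  n_arr <- model$n_arrangements
  L <- schedule$epochs
  valid <- model$valid_grid(G)
  states <- model$grid_to_state(G)

  lv <- model$es(states)[, domain$name, drop = FALSE]
  kr <- rowSums(margin_matrix(domain, lv)$margin < 0) == 0
  kr <- kr & valid

  membership <- matrix(FALSE, n_nodes, L)
  controls <- array(FALSE, dim = c(n_nodes, n_arr, L - 1))
  membership[, L] <- kr
  n_oob <- 0

  act <- which(valid)
  # endpoint node of one interval per (active node, arrangement), plus the
  # along-the-way constraint check; dynamics do not depend on the epoch, so
  # this is computed once and reused across the backward sweep
  ok_mat <- matrix(FALSE, n_nodes, n_arr)
  to_mat <- matrix(NA_integer_, n_nodes, n_arr)
  for (a in seq_len(n_arr)) {
    r <- step_interval(model, states[act, , drop = FALSE], a, schedule$step,
                       domain, check_every_step)
    to <- snap_to_grid(model$state_to_grid(r$states), grid,
                       valid = model$valid_grid)
    n_oob <- n_oob + sum(is.na(to) & r$ok)
    ok_mat[act, a] <- r$ok & !is.na(to)
    to_mat[act, a] <- to
  }

  for (k in rev(seq_len(L - 1))) {
    nxt <- membership[, k + 1]
    via <- ok_mat
    via[] <- via & matrix(nxt[ifelse(is.na(to_mat), 1L, to_mat)] &
                            !is.na(to_mat), n_nodes, n_arr)
    via <- via & kr
    controls[, , k] <- via
    membership[, k] <- rowSums(via) > 0
  }

  structure(list(membership = membership, controls = controls, nodes = G,
                 grid = grid, schedule = schedule, domain = domain,
                 arrangement_ids = model$arrangement_ids,
                 n_out_of_bounds = n_oob),
            class = "viability_kernel")
}

#' @export
print.viability_kernel <- function(x, ...) {
  L <- ncol(x$membership)
  cat(sprintf("viability kernel: %d grid nodes x %d epochs\n",
              nrow(x$membership), L))
  cat(sprintf("viable at epoch 1: %d nodes (%.1f%%); at final epoch: %d\n",
              sum(x$membership[, 1]),
              100 * mean(x$membership[, 1]),
              sum(x$membership[, L])))
  if (x$n_out_of_bounds > 0) {
    cat(sprintf("%d interval endpoints left the grid (treated non-viable)\n",
                x$n_out_of_bounds))
  }
  invisible(x)
}

#' Regulation map at a state and epoch
#'
#' Returns the arrangements under which the grid cell containing `state` can
#' continue viably from the given epoch: the stored viable-control set of
#' the backward induction.  Empty exactly when the cell is outside the
#' kernel at that epoch.
#'
#' @param kernel A [compute_kernel()] result.
#' @param state Full model state vector (or grid coordinates of length
#'   `grid` dimension).
#' @param epoch Epoch index (1-based, before the final epoch).
#' @return Integer vector of viable arrangement indices, named with the
#'   arrangement identifiers when available.
#' @export
regulation_map <- function(kernel, state, epoch = 1) {
  L <- ncol(kernel$membership)
  if (epoch < 1 || epoch >= L) stop("epoch must be in 1..", L - 1)
  d <- length(kernel$grid$n)
  coords <- if (length(state) == d) matrix(as.numeric(state), 1)
            else matrix(as.numeric(state)[seq_len(d)], 1)
  node <- snap_to_grid(coords, kernel$grid)
  if (is.na(node)) stop("state outside the grid bounds")
  idx <- which(kernel$controls[node, , epoch])
  if (!is.null(kernel$arrangement_ids)) {
    names(idx) <- kernel$arrangement_ids[idx]
  }
  idx
}

#' Two-dimensional cut of a viability kernel
#'
#' Membership map over two chosen grid dimensions with the remaining
#' dimensions fixed (snapped to their nearest grid values), at a given
#' epoch.
#'
#' @param kernel A [compute_kernel()] result.
#' @param dims Pair of dimension names or indices to keep.
#' @param fixed_values Named values for the remaining dimensions (defaults
#'   to their lower bounds).
#' @param epoch Epoch index (default 1, the start of the horizon).
#' @return A logical matrix with the first dimension on rows; dimnames carry
#'   the grid coordinates.
#' @export
kernel_slice <- function(kernel, dims, fixed_values = NULL, epoch = 1) {
  spec <- kernel$grid
  d <- length(spec$n)
  if (is.character(dims)) dims <- match(dims, spec$names)
  stopifnot(length(dims) == 2, !anyNA(dims))
  rest <- setdiff(seq_len(d), dims)
  fixed <- stats::setNames(spec$lower[rest], spec$names[rest])
  if (!is.null(fixed_values)) {
    fixed[names(fixed_values)] <- unlist(fixed_values)
  }
  # nearest grid index of each fixed dimension
  fix_idx <- round((fixed - spec$lower[rest]) / spec$h[rest])
  fix_idx <- pmin(pmax(fix_idx, 0), spec$n[rest] - 1)
  axes_i <- vector("list", d)
  for (j in seq_along(rest)) axes_i[[rest[j]]] <- fix_idx[j]
  axes_i[[dims[1]]] <- 0:(spec$n[dims[1]] - 1)
  axes_i[[dims[2]]] <- 0:(spec$n[dims[2]] - 1)
  idx_grid <- as.matrix(expand.grid(axes_i, KEEP.OUT.ATTRS = FALSE))
  nodes <- node_index(idx_grid, spec$n)
  m <- matrix(kernel$membership[nodes, epoch],
              spec$n[dims[1]], spec$n[dims[2]])
  dimnames(m) <- list(
    format(seq(spec$lower[dims[1]], spec$upper[dims[1]],
               length.out = spec$n[dims[1]]), digits = 3),
    format(seq(spec$lower[dims[2]], spec$upper[dims[2]],
               length.out = spec$n[dims[2]]), digits = 3)
  )
  names(dimnames(m)) <- spec$names[dims]
  m
}

#' Plot a kernel slice
#'
#' @param x A `"viability_kernel"`.
#' @param dims,fixed_values,epoch Passed to [kernel_slice()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.viability_kernel <- function(x, dims = c(1, 2), fixed_values = NULL,
                                  epoch = 1, ...) {
  m <- kernel_slice(x, dims, fixed_values, epoch)
  spec <- x$grid
  if (is.character(dims)) dims <- match(dims, spec$names)
  graphics::image(
    seq(spec$lower[dims[1]], spec$upper[dims[1]], length.out = spec$n[dims[1]]),
    seq(spec$lower[dims[2]], spec$upper[dims[2]], length.out = spec$n[dims[2]]),
    m * 1, col = c("white", "steelblue"),
    xlab = spec$names[dims[1]], ylab = spec$names[dims[2]], ...
  )
  invisible(x)
}
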