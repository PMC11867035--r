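# Coupled-infrastructure-system (CIS) compartment model: a resource R (a vector
# of ecosystem-service potentials) coupled to three social role compartments --
# exploitation (E), conservation (C) and policy-making (P) -- through numbered
# action-rate weights u0a..u7h.

.cisf_weight_names <- c(
  "u0a", "u0b", "u0c", "u0d",
  "u1a", "u1b", "u2a", "u2b", "u3a", "u3b", "u4a", "u4b",
  "u5a", "u5b", "u5a_prime", "u5b_prime",
  "u6a", "u6b", "u6b_prime",
  "u7a", "u7b", "u7c", "u7d", "u7e", "u7f", "u7g", "u7h"
)

# admissible interval per weight (dimensionless rates per year)
.cisf_weight_ranges <- local({
  lo <- stats::setNames(rep(-1, length(.cisf_weight_names)), .cisf_weight_names)
  hi <- stats::setNames(rep(+1, length(.cisf_weight_names)), .cisf_weight_names)
  nonneg <- c("u1a", "u2a", "u4a", "u5a", "u5b", "u5a_prime", "u5b_prime")
  lo[nonneg] <- 0
  lo["u7b"] <- -1; hi["u7b"] <- 0
  list(lower = lo, upper = hi)
})

# incoming-weight groups whose total must equal 1 per social compartment
.cisf_sum_groups <- list(
  E = c("u0b", "u1b", "u2b", "u6b", "u7d"),
  P = c("u0c", "u2a", "u3b", "u7f"),
  C = c("u0d", "u3a", "u4a", "u6a", "u7h")
)

#' Construct a set of CIS action-rate weights
#'
#' Creates the full vector of action-rate parameters of the compartment model:
#' self-loops (`u0a`..`u0d`), inter-compartment links (`u1a`..`u6b_prime`) and
#' couplings with the external settings (`u7a`..`u7h`).  Unspecified weights
#' default to zero.
#'
#' Each weight has a declared admissible interval: `[0, 1]` for `u1a`, `u2a`,
#' `u4a`, `u5a`, `u5b`, `u5a_prime`, `u5b_prime`; `[-1, 0]` for the external
#' stress rate `u7b`; `[-1, 1]` for all others.  The incoming weights of each
#' social compartment are expected to sum to one (see
#' [check_normalization()]).
#'
#' @param ... Named weights, e.g. `u0a = 0.1`.  Unknown names are an error.
#' @param .values Optionally, a named numeric vector or list of weights
#'   (merged after `...`).
#' @return A named numeric vector of class `"action_weights"`.
#' @examples
#' w <- action_weights(u0a = 0.1, u0b = 0.5, u1b = 0.5)
#' w["u0a"]
#' @export
action_weights <- function(..., .values = NULL) {
  w <- stats::setNames(rep(0, length(.cisf_weight_names)), .cisf_weight_names)
  vals <- c(list(...), as.list(.values))
  if (length(vals)) {
    nm <- names(vals)
    if (is.null(nm) || any(nm == "")) {
      stop("all action weights must be named")
    }
    unknown <- setdiff(nm, .cisf_weight_names)
    if (length(unknown)) {
      stop("unknown action weight(s): ", paste(unknown, collapse = ", "))
    }
    w[nm] <- vapply(vals, function(v) as.numeric(v)[1], numeric(1))
  }
  structure(w, class = "action_weights")
}

#' @export
print.action_weights <- function(x, ...) {
  cat("CIS action-rate weights (per year)\n")
  nz <- x[x != 0]
  if (!length(nz)) {
    cat("  all weights zero\n")
  } else {
    print(unclass(nz), ...)
  }
  chk <- check_normalization(x)
  cat(if (chk$pass) "normalization: pass\n" else "normalization: FAIL\n")
  invisible(x)
}

as_action_weights <- function(x) {
  if (inherits(x, "action_weights")) return(x)
  action_weights(.values = x)
}

# stops on any weight outside its admissible interval
validate_weight_ranges <- function(weights, tol = 1e-9) {
  w <- as_action_weights(weights)
  lo <- .cisf_weight_ranges$lower
  hi <- .cisf_weight_ranges$upper
  bad <- names(w)[w < lo - tol | w > hi + tol]
  if (length(bad)) {
    stop("action weight(s) outside admissible range: ",
         paste(bad, collapse = ", "))
  }
  invisible(w)
}

#' Check the sum-to-one normalization of incoming action weights
#'
#' The total weight of all linking actions (self-loops included) directed
#' toward each social compartment must add up to one:
#' `u0b + u1b + u2b + u6b + u7d = 1` (E), `u0c + u2a + u3b + u7f = 1` (P) and
#' `u0d + u3a + u4a + u6a + u7h = 1` (C).  A compartment whose incoming
#' weights are all zero is treated as absent (its role switched off by a
#' governance arrangement) and passes trivially unless `allow_absent = FALSE`.
#'
#' Failure is reported in the result, not signalled as an error.
#'
#' @param weights An [action_weights()] vector.
#' @param tol Numeric tolerance on each sum.
#' @param allow_absent Treat an all-zero compartment as trivially normalized.
#' @return A list of class `"cisf_normalization"` with elements `sums` (named
#'   numeric, compartment sums), `in_range` (logical, all weights inside their
#'   admissible intervals), `compartment_pass` (named logical) and `pass`.
#' @examples
#' w <- action_weights(u0b = 0.2, u1b = 0.2, u2b = 0.2, u6b = 0.2, u7d = 0.2,
#'                     u0c = 0.4, u2a = 0.3, u3b = 0.2, u7f = 0.1,
#'                     u0d = 0.2, u3a = 0.2, u4a = 0.2, u6a = 0.2, u7h = 0.2)
#' check_normalization(w)$pass
#' @export
check_normalization <- function(weights, tol = 1e-9, allow_absent = TRUE) {
  w <- as_action_weights(weights)
  lo <- .cisf_weight_ranges$lower
  hi <- .cisf_weight_ranges$upper
  in_range <- all(w >= lo - tol & w <= hi + tol)
  sums <- vapply(.cisf_sum_groups, function(g) sum(w[g]), numeric(1))
  absent <- vapply(.cisf_sum_groups, function(g) all(w[g] == 0), logical(1))
  cp <- abs(sums - 1) <= tol
  if (allow_absent) cp <- cp | absent
  structure(
    list(sums = sums, in_range = in_range, compartment_pass = cp,
         absent = absent, pass = in_range && all(cp)),
    class = "cisf_normalization"
  )
}

#' @export
print.cisf_normalization <- function(x, ...) {
  cat("incoming-weight sums:",
      paste(sprintf("%s = %.6g", names(x$sums), x$sums), collapse = ", "), "\n")
  if (!x$in_range) cat("some weights are outside their admissible range\n")
  cat(if (x$pass) "PASS\n" else "FAIL\n")
  invisible(x)
}

#' Evaluate the CIS compartment derivatives
#'
#' Assembles the right-hand side of the compartment dynamics: for each
#' ecosystem-service component of the resource,
#' `dR_i/dt = u0a R_i + u7b R_i - u7a R_i + u4a R_i C - (u1b R_i E)(u5b C) +
#' (u1a E R_i)(u5a C)` (natural growth, impact of the external settings,
#' externalities, support by C, regulated access & flow, regulated access &
#' management); and analogous bilinear forms for the role capacities E, C and
#' P.  Signed weights carry their own sign (e.g. `u7b <= 0` for stress).
#'
#' In the scalar role equations the resource enters through the mean of the
#' ES component levels.
#'
#' @param es Named numeric vector of ES levels in `[0, 1]` (the resource
#'   state), or an [es_vector()].
#' @param roles Named numeric vector with elements `E`, `C`, `P` in `[0, 1]`.
#' @param weights An [action_weights()] vector; ranges are validated before
#'   evaluation.
#' @return A list with components `dR` (named per-ES rates), `dE`, `dC`, `dP`.
#' @examples
#' w <- action_weights(u0a = 0.1)
#' cisf_derivative(c(food = 0.5), c(E = 0, C = 0, P = 0), w)$dR
#' @export
cisf_derivative <- function(es, roles, weights) {
  w <- validate_weight_ranges(weights)
  lv <- es_levels(es)
  E <- roles[["E"]]; C <- roles[["C"]]; P <- roles[["P"]]
  Rbar <- mean(lv)

  dR <- w[["u0a"]] * lv +
    w[["u7b"]] * lv -
    w[["u7a"]] * lv +
    w[["u4a"]] * lv * C -
    (w[["u1b"]] * lv * E) * (w[["u5b"]] * C) +
    (w[["u1a"]] * E * lv) * (w[["u5a"]] * C)

  dE <- w[["u0b"]] * E +
    w[["u7d"]] * E -
    w[["u7c"]] * E +
    (w[["u1b"]] * Rbar * E) * (w[["u5b"]] * C) +
    w[["u6b_prime"]] * E * C +
    w[["u2b"]] * E * P

  dC <- w[["u0d"]] * C +
    w[["u7h"]] * C -
    w[["u7g"]] * C +
    (w[["u1b"]] * Rbar * E) * (w[["u5b_prime"]] * C) +
    (w[["u1a"]] * Rbar * E) * (w[["u5a_prime"]] * C) +
    (w[["u6a"]] - w[["u6b"]]) * E * C +
    w[["u3a"]] * P * C

  dP <- w[["u0c"]] * P +
    w[["u7f"]] * C -
    w[["u7e"]] * C +
    w[["u2a"]] * E * P +
    w[["u3b"]] * C * P

  list(dR = dR, dE = unname(dE), dC = unname(dC), dP = unname(dP))
}

#' Resource growth condition
#'
#' Evaluates whether the potential resource turn-over rate is non-negative,
#' in two variants.  The `printed` variant evaluates the closed-form
#' inequality `u0a + (u1a u5a_prime + u4b) C >= |u7b| + u1b u5a`, with the
#' stress rate `u7b` entering through its magnitude since it sits on the loss
#' side.  The `derived` variant evaluates the sign of the per-unit-resource
#' rate taken directly from the dR/dt equation,
#' `u0a + u7b - u7a + u4a C - u1b E u5b C + u1a E u5a C >= 0`.
#' The two deliberately differ: the closed form mixes the regulation and
#' monitoring rates (`u5a` vs `u5a_prime`) and uses the support weight `u4b`
#' where the dynamics use `u4a`; both are returned rather than guessing the
#' intended one.
#'
#' @param weights An [action_weights()] vector.
#' @param c_capacity Conservation role capacity in `[0, 1]`.
#' @param e_capacity Exploitation role capacity in `[0, 1]` (used by the
#'   `derived` variant only).
#' @return A named logical vector with elements `printed` and `derived`.
#' @examples
#' resource_growth_condition(action_weights(u0a = 0.2), c_capacity = 0.5)
#' @export
resource_growth_condition <- function(weights, c_capacity, e_capacity = 1) {
  w <- validate_weight_ranges(weights)
  stopifnot(c_capacity >= 0, c_capacity <= 1,
            e_capacity >= 0, e_capacity <= 1)
  C <- c_capacity; E <- e_capacity
  printed <- w[["u0a"]] + (w[["u1a"]] * w[["u5a_prime"]] + w[["u4b"]]) * C >=
    abs(w[["u7b"]]) + w[["u1b"]] * w[["u5a"]]
  derived <- w[["u0a"]] + w[["u7b"]] - w[["u7a"]] + w[["u4a"]] * C -
    w[["u1b"]] * E * w[["u5b"]] * C + w[["u1a"]] * E * w[["u5a"]] * C >= 0
  c(printed = unname(printed), derived = unname(derived))
}

#' Integrate the CIS compartment model
#'
#' Fixed-step explicit Euler integration of [cisf_derivative()].  After every
#' step the ES levels and the role capacities are clamped to `[0, 1]`
#' (dynamics first, then clamp).
#'
#' @param weights An [action_weights()] vector.
#' @param es0 Named numeric vector of initial ES levels in `[0, 1]`.
#' @param roles0 Named numeric vector `c(E=, C=, P=)` of initial capacities.
#' @param years Integration horizon in years.
#' @param dt Step size in years (default 1).
#' @return A list with `time` (vector), `es` (matrix, one row per time point)
#'   and `roles` (matrix with columns E, C, P).
#' @examples
#' w <- action_weights(u0a = 0.05, u0b = 1, u0c = 1, u0d = 1)
#' tr <- cisf_simulate(w, c(food = 0.5), c(E = 0.2, C = 0.2, P = 0.2), years = 5)
#' tail(tr$es, 1)
#' @export
cisf_simulate <- function(weights, es0, roles0, years, dt = 1) {
  w <- validate_weight_ranges(weights)
  lv <- es_levels(es0)
  roles <- c(E = roles0[["E"]], C = roles0[["C"]], P = roles0[["P"]])
  n_steps <- round(years / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1)
  es_out <- matrix(NA_real_, n_steps + 1, length(lv),
                   dimnames = list(NULL, names(lv)))
  role_out <- matrix(NA_real_, n_steps + 1, 3,
                     dimnames = list(NULL, c("E", "C", "P")))
  es_out[1, ] <- lv
  role_out[1, ] <- roles
  for (k in seq_len(n_steps)) {
    d <- cisf_derivative(lv, roles, w)
    lv <- pmin(pmax(lv + dt * d$dR, 0), 1)
    roles <- pmin(pmax(roles + dt * c(E = d$dE, C = d$dC, P = d$dP), 0), 1)
    es_out[k + 1, ] <- lv
    role_out[k + 1, ] <- roles
  }
  list(time = times, es = es_out, roles = role_out)
}
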