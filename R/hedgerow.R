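# Synthetic hedgerow / ecosystem-services case generator.
#
# Emulates a hedgerow-network management problem: the landscape state is the
# composition over five classes -- tall species-rich (TR), tall species-poor
# (TP), short species-rich (SR), short species-poor (SP) and absent (NO) --
# evolving under an annual transition operator composed of baseline
# degradation, arrangement-specific management and climate stress.  Seven ES
# are produced from the composition (five services, two disservices);
# landscape aesthetics is the normalized Shannon diversity of the four
# hedgerow classes.  All rates and coefficients are documented synthetic
# constants, not estimates of any real site.

.hedgerow_classes <- c("TR", "TP", "SR", "SP", "NO")

.hedgerow_es_names <- c("pollinator_resources", "fruit_production",
                        "wood_biomass", "sunlight_protection",
                        "landscape_aesthetics",
                        "maintenance_costs", "environmental_hazards")
.hedgerow_es_signs <- c("service", "service", "service", "service", "service",
                        "disservice", "disservice")

# clipped-linear ES coefficients: intercept + per-class weights (NO weighs 0)
.hedgerow_es_coef <- local({
  m <- rbind(
    pollinator_resources  = c(0.05, 0.90, 0.35, 0.75, 0.25),
    fruit_production      = c(0.05, 0.85, 0.45, 0.60, 0.30),
    wood_biomass          = c(0.00, 0.90, 0.80, 0.35, 0.25),
    sunlight_protection   = c(0.00, 0.95, 0.90, 0.30, 0.25),
    landscape_aesthetics  = c(NA, NA, NA, NA, NA),  # Shannon, not linear
    maintenance_costs     = c(0.05, 0.50, 0.70, 0.35, 0.50),
    environmental_hazards = c(0.02, 0.25, 0.60, 0.15, 0.50)
  )
  colnames(m) <- c("intercept", "TR", "TP", "SR", "SP")
  m
})

# annual baseline degradation (no management, no extra climate stress)
.hedgerow_baseline <- local({
  B <- diag(5)
  dimnames(B) <- list(.hedgerow_classes, .hedgerow_classes)
  B["TR", c("TP", "SR", "NO")] <- c(0.02, 0.03, 0.02)
  B["TP", c("SP", "NO")] <- c(0.04, 0.03)
  B["SR", c("SP", "NO")] <- c(0.04, 0.02)
  B["SP", "NO"] <- 0.05
  diag(B) <- 1 - (rowSums(B) - diag(B))
  B
})

# per-arrangement management rates (annual fractions of a class converted)
.hedgerow_management_rates <- list(
  "CCA1|KCA1" = c(plant_s = 0.002, plant_r = 0.000, enrich = 0.000,
                  grow = 0.005, trim = 0.040, remove = 0.010),
  "CCA2|KCA2" = c(plant_s = 0.030, plant_r = 0.010, enrich = 0.020,
                  grow = 0.020, trim = 0.015, remove = 0.002),
  "CCA2|KCA3" = c(plant_s = 0.010, plant_r = 0.030, enrich = 0.050,
                  grow = 0.020, trim = 0.010, remove = 0.002),
  "CCA2|KCA4" = c(plant_s = 0.050, plant_r = 0.010, enrich = 0.010,
                  grow = 0.010, trim = 0.020, remove = 0.002),
  "CCA3|KCA5" = c(plant_s = 0.010, plant_r = 0.030, enrich = 0.050,
                  grow = 0.040, trim = 0.005, remove = 0.001),
  "CCA3|KCA6" = c(plant_s = 0.020, plant_r = 0.010, enrich = 0.020,
                  grow = 0.060, trim = 0.002, remove = 0.001),
  "CCA3|KCA7" = c(plant_s = 0.010, plant_r = 0.040, enrich = 0.060,
                  grow = 0.030, trim = 0.005, remove = 0.001),
  "CCA4|KCA8" = c(plant_s = 0.030, plant_r = 0.040, enrich = 0.070,
                  grow = 0.050, trim = 0.005, remove = 0.001),
  "CCA4|KCA9" = c(plant_s = 0.010, plant_r = 0.000, enrich = 0.005,
                  grow = 0.005, trim = 0.050, remove = 0.020)
)

# role/link composition of the nine nested arrangements (synthetic emulation)
.hedgerow_arrangement_spec <- list(
  "CCA1|KCA1" = list(cca = 1, kca = 1, roles = c(E = TRUE, C = FALSE, P = FALSE),
                     links_off = character()),
  "CCA2|KCA2" = list(cca = 2, kca = 2, roles = c(E = TRUE, C = FALSE, P = TRUE),
                     links_off = character()),
  "CCA2|KCA3" = list(cca = 2, kca = 3, roles = c(E = TRUE, C = FALSE, P = TRUE),
                     links_off = "u2a"),
  "CCA2|KCA4" = list(cca = 2, kca = 4, roles = c(E = TRUE, C = FALSE, P = TRUE),
                     links_off = "u2b"),
  "CCA3|KCA5" = list(cca = 3, kca = 5, roles = c(E = TRUE, C = TRUE, P = FALSE),
                     links_off = character()),
  "CCA3|KCA6" = list(cca = 3, kca = 6, roles = c(E = TRUE, C = TRUE, P = FALSE),
                     links_off = c("u6a", "u6b")),
  "CCA3|KCA7" = list(cca = 3, kca = 7, roles = c(E = TRUE, C = TRUE, P = FALSE),
                     links_off = c("u5b", "u5b_prime")),
  "CCA4|KCA8" = list(cca = 4, kca = 8, roles = c(E = TRUE, C = TRUE, P = TRUE),
                     links_off = character()),
  "CCA4|KCA9" = list(cca = 4, kca = 9, roles = c(E = TRUE, C = TRUE, P = TRUE),
                     links_off = c("u3a", "u3b"))
)

# climate stress operator: extra annual decay of tall and species-rich
# classes, scaled by the stress level (0 = none, 1 = moderate, 2 = strong)
hedgerow_climate_operator <- function(level) {
  stopifnot(level %in% 0:2)
  CL <- diag(5)
  dimnames(CL) <- list(.hedgerow_classes, .hedgerow_classes)
  if (level > 0) {
    CL["TR", c("TP", "SR", "NO")] <- level * c(0.030, 0.020, 0.010)
    CL["SR", c("SP", "NO")] <- level * c(0.035, 0.010)
    CL["TP", "NO"] <- level * 0.015
    CL["SP", "NO"] <- level * 0.010
    diag(CL) <- 1 - (rowSums(CL) - diag(CL))
  }
  CL
}

hedgerow_management_operator <- function(rates) {
  r <- function(nm) if (nm %in% names(rates)) rates[[nm]] else 0
  M <- diag(5)
  dimnames(M) <- list(.hedgerow_classes, .hedgerow_classes)
  M["TR", c("SR", "NO")] <- c(r("trim"), r("remove"))
  M["TP", c("TR", "SP", "NO")] <- c(r("enrich"), r("trim"), r("remove"))
  M["SR", c("TR", "NO")] <- c(r("grow"), r("remove"))
  M["SP", c("SR", "TP", "NO")] <- c(r("enrich"), r("grow"), r("remove"))
  M["NO", c("SP", "SR")] <- c(r("plant_s"), r("plant_r"))
  diag(M) <- 1 - (rowSums(M) - diag(M))
  if (any(diag(M) < 0)) stop("management rates exceed row budget")
  M
}

#' Construct a hedgerow composition state
#'
#' @param p Numeric vector of five landscape fractions named (or ordered)
#'   `TR`, `TP`, `SR`, `SP`, `NO`; must be non-negative and sum to one.
#' @return A named numeric vector of class `"hedgerow_state"`.
#' @examples
#' hedgerow_state(c(TR = 0.05, TP = 0.15, SR = 0.08, SP = 0.42, NO = 0.30))
#' @export
hedgerow_state <- function(p) {
  if (!is.null(names(p))) p <- p[.hedgerow_classes]
  if (length(p) != 5 || anyNA(p)) stop("a hedgerow state has five fractions")
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1")
  }
  structure(stats::setNames(as.numeric(p), .hedgerow_classes),
            class = "hedgerow_state")
}

#' Normalized Shannon diversity of the hedgerow classes
#'
#' Computes the Shannon index `H = -sum(q_i log q_i)` over the four hedgerow
#' classes (the absent class is excluded and the proportions renormalized
#' over the hedgerows present), normalized by `log(4)` so that four equally
#' frequent classes score 1.  A landscape with a single hedgerow class, or no
#' hedgerows at all, scores 0.  The index is invariant under any permutation
#' of the four class proportions.
#'
#' @param p Non-negative proportions of the four hedgerow classes (a vector
#'   of length 4, or a 5-element state whose `NO` fraction is dropped).
#' @return A value in `[0, 1]`.
#' @examples
#' shannon_aesthetics(c(0.25, 0.25, 0.25, 0.25))  # 1
#' shannon_aesthetics(c(1, 0, 0, 0))              # 0
#' shannon_aesthetics(c(0.5, 0.5, 0, 0))          # 0.5
#' @export
shannon_aesthetics <- function(p) {
  if (length(p) == 5) p <- p[seq_len(4)]
  stopifnot(length(p) == 4, all(p >= -1e-12))
  tot <- sum(p)
  if (tot <= 0) return(0)
  q <- p / tot
  q <- q[q > 0]
  h <- -sum(q * log(q))
  h / log(4)
}

# vectorized over rows of a composition matrix (columns TR TP SR SP [NO])
shannon_aesthetics_matrix <- function(states) {
  q <- states[, seq_len(4), drop = FALSE]
  tot <- rowSums(q)
  qn <- q / ifelse(tot > 0, tot, 1)
  lq <- ifelse(qn > 0, log(qn), 0)
  h <- -rowSums(qn * lq) / log(4)
  ifelse(tot > 0, h, 0)
}

# ES level matrix (rows = states) from a composition matrix
hedgerow_es_matrix <- function(states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  coef <- .hedgerow_es_coef
  lin <- rownames(coef)[!is.na(coef[, 1])]
  out <- matrix(NA_real_, nrow(states), length(.hedgerow_es_names),
                dimnames = list(NULL, .hedgerow_es_names))
  for (es in lin) {
    v <- coef[es, "intercept"] +
      states[, 1] * coef[es, "TR"] + states[, 2] * coef[es, "TP"] +
      states[, 3] * coef[es, "SR"] + states[, 4] * coef[es, "SP"]
    out[, es] <- pmin(pmax(v, 0), 1)
  }
  out[, "landscape_aesthetics"] <- shannon_aesthetics_matrix(states)
  out
}

#' Ecosystem services produced by a hedgerow composition
#'
#' Five services (pollinator resources, fruit production, wood biomass,
#' sunlight protection, landscape aesthetics) and two disservices
#' (maintenance costs, environmental hazards).  All but aesthetics are
#' clipped linear functions of the class proportions; aesthetics is
#' [shannon_aesthetics()].
#'
#' @param state A [hedgerow_state()] (or 5-vector of fractions).
#' @param model Optional [default_fixture()] model (reserved for alternative
#'   coefficient tables; the shipped coefficients are package constants).
#' @return An [es_vector()] with seven entries.
#' @export
compute_es <- function(state, model = NULL) {
  lv <- hedgerow_es_matrix(matrix(as.numeric(state), nrow = 1))[1, ]
  es_vector(lv, .hedgerow_es_signs)
}

#' Advance a hedgerow composition by one year
#'
#' Applies the effective annual transition operator: baseline degradation,
#' then the arrangement's management conversions, then climate stress.  Each
#' operator is row-stochastic, so the composition stays on the simplex.
#'
#' @param state A [hedgerow_state()] or 5-vector of fractions.
#' @param arrangement Arrangement index (1..9) or identifier.
#' @param model A fixture returned by [default_fixture()].
#' @param climate_level Optional override of the fixture's climate level.
#' @return A [hedgerow_state()].
#' @export
hedgerow_step <- function(state, arrangement, model,
                          climate_level = model$climate_level) {
  if (is.character(arrangement)) {
    arrangement <- match(arrangement, model$arrangement_ids)
  }
  Teff <- if (climate_level == model$climate_level) {
    model$effective[[arrangement]]
  } else {
    model$baseline %*% model$management[[arrangement]] %*%
      hedgerow_climate_operator(climate_level)
  }
  hedgerow_state(drop(as.numeric(state) %*% Teff))
}

#' Generate the synthetic hedgerow study fixture
#'
#' Builds the complete synthetic case: the hedgerow transition model with the
#' requested climate stress level, the nine nested governance arrangements
#' (CCA1|KCA1 .. CCA4|KCA9) with role/link masks and derived action weights,
#' the SES-type satisfactory domain, and the initial 2020 composition
#' (short/species-poor dominated).  The rural constraint set is strictly
#' tighter than the peri-urban one; higher climate levels strictly increase
#' the degradation rates of the tall and species-rich classes.  The output
#' is deterministic given the seed; the seed jitters the base action weights
#' (renormalized so the sum-to-one contracts always hold).
#'
#' The two SES types share identical dynamics and differ only in their
#' constraint sets, mirroring a design in which the sites' visions of ES
#' needs differ while management options do not.
#'
#' @param ses_type `"rural"` or `"peri_urban"`.
#' @param climate_level Climate stress level 0, 1 or 2.
#' @param seed Integer seed.
#' @return A list of class `"hedgerow_fixture"` with elements `model`
#'   (transition operators + ES table), `arrangements` (list of 9
#'   [arrangement()]s), `weights` (per-arrangement [action_weights()]),
#'   `base_weights`, `domain` ([satisfactory_domain()]), `initial_state`,
#'   `schedule` ([decision_schedule()]), `ses_type`, `climate_level`, `seed`.
#' @examples
#' fx <- default_fixture("rural", climate_level = 0, seed = 1)
#' fx$initial_state
#' @export
default_fixture <- function(ses_type = c("rural", "peri_urban"),
                            climate_level = 0, seed = 1) {
  ses_type <- match.arg(ses_type)
  if (!climate_level %in% 0:2) stop("unknown climate level ", climate_level)
  set.seed(as.integer(seed))

  # base action weights: positive group shares jittered then renormalized
  jit <- function(x) x * stats::runif(length(x), 0.95, 1.05)
  grp <- list(
    E = c(u0b = 0.35, u1b = 0.25, u2b = 0.10, u6b = 0.10, u7d = 0.20),
    P = c(u0c = 0.40, u2a = 0.25, u3b = 0.20, u7f = 0.15),
    C = c(u0d = 0.35, u3a = 0.15, u4a = 0.25, u6a = 0.10, u7h = 0.15)
  )
  grp <- lapply(grp, function(g) { g <- jit(g); g / sum(g) })
  op <- c(u0a = 0.05, u1a = 0.30, u4b = 0.10, u5a = 0.50, u5b = 0.50,
          u5a_prime = 0.30, u5b_prime = 0.30, u6b_prime = 0.05,
          u7a = 0.02, u7c = 0.02, u7e = 0.02, u7g = 0.02)
  op <- pmin(jit(op), 1)
  base <- action_weights(.values = c(grp$E, grp$P, grp$C, op,
                                     u7b = -0.1 * climate_level))

  mgmt_rates <- .hedgerow_management_rates
  arrangements <- lapply(names(.hedgerow_arrangement_spec), function(id) {
    sp <- .hedgerow_arrangement_spec[[id]]
    lm <- stats::setNames(rep(TRUE, length(.cisf_weight_names)),
                          .cisf_weight_names)
    lm[sp$links_off] <- FALSE
    oca <- data.frame(weight = "u1a", min = 0, max = 1,
                      value = round(min(1, 10 * mgmt_rates[[id]][["grow"]] +
                                           5 * mgmt_rates[[id]][["enrich"]]), 3))
    arrangement(sp$cca, sp$kca, role_mask = sp$roles, link_mask = lm,
                oca = oca, id = id)
  })
  names(arrangements) <- names(.hedgerow_arrangement_spec)
  weights <- lapply(arrangements, arrangement_weights, base = base)

  CL <- hedgerow_climate_operator(climate_level)
  management <- lapply(mgmt_rates, hedgerow_management_operator)
  effective <- lapply(management, function(M) .hedgerow_baseline %*% M %*% CL)

  model <- structure(
    list(classes = .hedgerow_classes, baseline = .hedgerow_baseline,
         climate = CL, management = management, effective = effective,
         es_coef = .hedgerow_es_coef, es_names = .hedgerow_es_names,
         es_signs = .hedgerow_es_signs,
         arrangement_ids = names(arrangements),
         climate_level = climate_level),
    class = "hedgerow_model"
  )

  domain <- if (ses_type == "rural") {
    satisfactory_domain(
      es_min = c(pollinator_resources = 0.25, fruit_production = 0.20,
                 wood_biomass = 0.20, sunlight_protection = 0.15,
                 landscape_aesthetics = 0.20),
      es_max = c(maintenance_costs = 0.50, environmental_hazards = 0.45)
    )
  } else {
    satisfactory_domain(
      es_min = c(pollinator_resources = 0.15, fruit_production = 0.10,
                 wood_biomass = 0.10, sunlight_protection = 0.10,
                 landscape_aesthetics = 0.15),
      es_max = c(maintenance_costs = 0.60, environmental_hazards = 0.55)
    )
  }

  structure(
    list(model = model, arrangements = arrangements, weights = weights,
         base_weights = base, domain = domain,
         initial_state = hedgerow_state(c(TR = 0.05, TP = 0.15, SR = 0.08,
                                          SP = 0.42, NO = 0.30)),
         schedule = decision_schedule(start = 2020, horizon = 30, step = 5),
         ses_type = ses_type, climate_level = climate_level,
         seed = as.integer(seed)),
    class = "hedgerow_fixture"
  )
}

#' @export
print.hedgerow_fixture <- function(x, ...) {
  cat(sprintf("hedgerow fixture: %s SES, climate stress level %d, seed %d\n",
              x$ses_type, x$climate_level, x$seed))
  cat(sprintf("  %d arrangements, %d ES constraints, horizon %d years\n",
              length(x$arrangements), nrow(x$domain), x$schedule$horizon))
  invisible(x)
}

#' Pathway-model view of a hedgerow fixture
#'
#' Wraps a fixture as the generic model interface consumed by
#' [compute_kernel()], [simulate_pathway()] and [enumerate_viable()]:
#' a vectorized annual `step(states, arrangement)` over row-matrices of
#' states, a vectorized `es(states)` level matrix, and the mapping between
#' the 4-dimensional grid (TR, TP, SR, SP; the absent fraction is implied)
#' and the full composition.
#'
#' @param fixture A [default_fixture()].
#' @return A list of class `"pathway_model"`.
#' @export
as_pathway_model <- function(fixture) {
  stopifnot(inherits(fixture, "hedgerow_fixture"))
  model <- fixture$model
  structure(
    list(
      n_arrangements = length(fixture$arrangements),
      arrangement_ids = model$arrangement_ids,
      state_names = model$classes,
      grid_dim = 4L,
      grid_names = model$classes[1:4],
      step = function(states, arr) states %*% model$effective[[arr]],
      es = function(states) hedgerow_es_matrix(states),
      es_names = model$es_names,
      es_signs = model$es_signs,
      grid_to_state = function(g) cbind(g, NO = pmax(1 - rowSums(g), 0)),
      state_to_grid = function(s) s[, 1:4, drop = FALSE],
      valid_grid = function(g) rowSums(g) <= 1 + 1e-9
    ),
    class = "pathway_model"
  )
}
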