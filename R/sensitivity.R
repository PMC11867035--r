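# Retrospective sensitivity of pathway security to the allocation of
# management effort between hedgerow types: for every pathway, the per-ES
# security margin is recomputed with effort shifted toward one side of a
# class contrast (species-rich vs species-poor, tall vs short) and toward
# the other, and the difference is summarized over all pathways and over
# the viable ones.

.contrast_classes <- list(
  RH_vs_PH = list(first = c("TR", "SR"), second = c("TP", "SP")),
  PH_vs_RH = list(first = c("TP", "SP"), second = c("TR", "SR")),
  TH_vs_SH = list(first = c("TR", "TP"), second = c("SR", "SP")),
  SH_vs_TH = list(first = c("SR", "SP"), second = c("TR", "TP"))
)

# per-class effort vector of one contrast variant, clipped to [0, 2]
effort_vector <- function(contrast, delta) {
  cc <- .contrast_classes[[contrast]]
  e <- stats::setNames(rep(1, 4), c("TR", "TP", "SR", "SP"))
  e[cc$first] <- e[cc$first] + delta
  e[cc$second] <- e[cc$second] - delta
  clipped <- e < 0 | e > 2
  if (any(clipped)) {
    warning("effort perturbation clipped to [0, 2] for: ",
            paste(names(e)[clipped], collapse = ", "))
    e <- pmin(pmax(e, 0), 2)
  }
  e
}

# ES level matrix under an effort-weighted delivery: maintenance effort on a
# class scales its service contribution by e and its disservice contribution
# by (2 - e); aesthetics depends only on the planted composition and is
# unaffected by effort allocation
hedgerow_es_matrix_effort <- function(states, effort) {
  coef <- .hedgerow_es_coef
  out <- matrix(NA_real_, nrow(states), length(.hedgerow_es_names),
                dimnames = list(NULL, .hedgerow_es_names))
  for (es in rownames(coef)) {
    if (es == "landscape_aesthetics") next
    w <- if (.hedgerow_es_signs[match(es, .hedgerow_es_names)] == "service") {
      effort
    } else {
      2 - effort
    }
    v <- coef[es, "intercept"] +
      states[, 1] * coef[es, "TR"] * w[["TR"]] +
      states[, 2] * coef[es, "TP"] * w[["TP"]] +
      states[, 3] * coef[es, "SR"] * w[["SR"]] +
      states[, 4] * coef[es, "SP"] * w[["SP"]]
    out[, es] <- pmin(pmax(v, 0), 1)
  }
  out[, "landscape_aesthetics"] <- shannon_aesthetics_matrix(states)
  out
}

# fixture with management rates shifted toward one side of a contrast
# (dynamics mode): rates producing first-side classes scaled by (1 + delta),
# rates producing second-side classes by (1 - delta), clipped to the row
# budget of the management operator
perturbed_fixture <- function(fixture, contrast, delta) {
  cc <- .contrast_classes[[contrast]]
  rate_targets <- list(plant_s = "SP", plant_r = "SR", enrich = c("TR", "SR"),
                       grow = c("TR", "TP"), trim = c("SR", "SP"),
                       remove = character())
  fx <- fixture
  fx$model$management <- lapply(.hedgerow_management_rates, function(rates) {
    for (nm in names(rates)) {
      tg <- rate_targets[[nm]]
      f <- 1
      if (all(tg %in% cc$first) && length(tg)) f <- 1 + delta
      if (all(tg %in% cc$second) && length(tg)) f <- 1 - delta
      rates[[nm]] <- max(rates[[nm]] * f, 0)
    }
    hedgerow_management_operator(rates)
  })
  fx$model$effective <- lapply(fx$model$management, function(M) {
    fx$model$baseline %*% M %*% fx$model$climate
  })
  fx
}

#' Security gains from switching hedgerow management targets
#'
#' For every pathway, computes the per-ES security margin (time-mean
#' normalized constraint margin) under management effort shifted by
#' `perturbation_size` toward the first class pair of the contrast, and
#' toward the second, and returns the difference (first minus second).  A
#' positive value means greater security gains when acting more on the
#' first pair (e.g. species-rich hedgerows for `RH_vs_PH`).
#'
#' Two perturbation modes are available.  The default, `"delivery"`, keeps
#' the pathway's hedgerow trajectory fixed and reweights the per-class ES
#' delivery coefficients by the effort vector (maintenance effort improves a
#' class's service delivery and reduces its disservices, but does not
#' replant the landscape); landscape aesthetics depends only on the planted
#' composition and is therefore exactly insensitive to effort swaps.  Mode
#' `"dynamics"` rescales the management transition rates producing each
#' class pair and re-simulates the pathway (exploratory; aesthetics is then
#' only approximately insensitive).
#'
#' @param fixture A [default_fixture()].
#' @param pathways Matrix of arrangement indices (one row per pathway, one
#'   column per epoch), or a `"pathway_set"`.
#' @param contrast `"RH_vs_PH"` (species-rich vs species-poor) or
#'   `"TH_vs_SH"` (tall vs short); the reversed forms `"PH_vs_RH"` and
#'   `"SH_vs_TH"` flip the sign of every delta.
#' @param perturbation_size Effort shift (fraction; default 0.1).
#' @param mode Perturbation mode, see Details.
#' @return A list of class `"delta_es_analysis"`: `delta` (matrix, pathways
#'   x ES), `viable` (logical per pathway), `distributions` (per ES, a list
#'   with `all` and `viable_only` [summarize_distribution()] summaries plus
#'   the raw samples), `contrast`, `perturbation_size`, `mode`.
#' @export
delta_security <- function(fixture, pathways,
                           contrast = c("RH_vs_PH", "PH_vs_RH",
                                        "TH_vs_SH", "SH_vs_TH"),
                           perturbation_size = 0.1,
                           mode = c("delivery", "dynamics")) {
  contrast <- match.arg(contrast)
  mode <- match.arg(mode)
  stopifnot(perturbation_size >= 0)
  if (inherits(pathways, "pathway_set")) pathways <- pathways$paths
  if (is.null(dim(pathways))) pathways <- matrix(pathways, nrow = 1)
  model <- as_pathway_model(fixture)
  schedule <- fixture$schedule
  domain <- fixture$domain
  n_path <- nrow(pathways)
  es_names <- .hedgerow_es_names
  delta <- matrix(0, n_path, length(es_names),
                  dimnames = list(NULL, es_names))
  viable <- logical(n_path)

  e_first <- effort_vector(contrast, perturbation_size)
  e_second <- effort_vector(contrast, -perturbation_size)
  if (mode == "dynamics") {
    fx_first <- perturbed_fixture(fixture, contrast, perturbation_size)
    fx_second <- perturbed_fixture(fixture, contrast, -perturbation_size)
    m_first <- as_pathway_model(fx_first)
    m_second <- as_pathway_model(fx_second)
  }

  margin_of <- function(states, effort) {
    lv <- hedgerow_es_matrix_effort(states, effort)[, domain$name, drop = FALSE]
    colMeans(margin_matrix(domain, lv)$normalized)
  }
  for (i in seq_len(n_path)) {
    base <- simulate_pathway(model, fixture$initial_state, pathways[i, ],
                             schedule, domain)
    viable[i] <- base$viable
    if (mode == "delivery") {
      d <- margin_of(base$states, e_first) - margin_of(base$states, e_second)
    } else {
      tr1 <- simulate_pathway(m_first, fixture$initial_state, pathways[i, ],
                              schedule, domain)
      tr2 <- simulate_pathway(m_second, fixture$initial_state, pathways[i, ],
                              schedule, domain)
      d <- tr1$per_es_margin - tr2$per_es_margin
    }
    delta[i, domain$name] <- d[domain$name]
  }

  distributions <- lapply(es_names, function(es) {
    s_all <- delta[, es]
    s_v <- delta[viable, es]
    list(es_name = es,
         all = c(list(sample = s_all), summarize_distribution(s_all)),
         viable_only = c(list(sample = s_v), summarize_distribution(s_v)))
  })
  names(distributions) <- es_names
  structure(list(delta = delta, viable = viable,
                 distributions = distributions, contrast = contrast,
                 perturbation_size = perturbation_size, mode = mode),
            class = "delta_es_analysis")
}

#' @export
print.delta_es_analysis <- function(x, ...) {
  cat(sprintf("delta-ES security analysis (%s, effort shift %.2f, %s mode)\n",
              x$contrast, x$perturbation_size, x$mode))
  med <- vapply(x$distributions, function(d) {
    if (isTRUE(d$viable_only$empty)) NA_real_ else d$viable_only$median
  }, numeric(1))
  cat(sprintf("%d pathways (%d viable); medians over viable pathways:\n",
              nrow(x$delta), sum(x$viable)))
  print(round(med, 4))
  invisible(x)
}

#' Summarize a sample of delta-ES values
#'
#' Exact sample median and quartiles (type-7 quantiles) plus fixed-width
#' histogram bins for density export.
#'
#' @param sample Numeric vector.
#' @param bins Number of histogram bins.
#' @return A list with `n`, `median`, `q25`, `q75`, `breaks`, `counts`; or
#'   `list(empty = TRUE, n = 0)` for an empty sample.
#' @examples
#' summarize_distribution(c(1, 2, 3))$median  # 2
#' @export
summarize_distribution <- function(sample, bins = 30) {
  sample <- sample[!is.na(sample)]
  if (!length(sample)) return(list(empty = TRUE, n = 0L))
  q <- stats::quantile(sample, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  rng <- range(sample)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1) * 1e-9
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(pmin(findInterval(sample, breaks,
                                       rightmost.closed = TRUE), bins),
                     nbins = bins)
  list(empty = FALSE, n = length(sample), median = q[2], q25 = q[1],
       q75 = q[3], breaks = breaks, counts = counts)
}
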