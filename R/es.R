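# Ecosystem-service vectors and the satisfactory domain K_R: per-ES
# constraints ES+_i >= min_i (services) and ES-_j <= max_j (disservices).

#' Construct an ecosystem-service vector
#'
#' An ordered set of named ES levels in `[0, 1]`, each tagged as a service
#' (`ES+`, to keep above a minimum) or a disservice (`ES-`, to keep below a
#' maximum).
#'
#' @param levels Named numeric vector of levels in `[0, 1]`.
#' @param sign Character vector (recycled) of `"service"` / `"disservice"`
#'   tags, one per ES.
#' @return A data frame of class `"es_vector"` with columns `name`, `sign`,
#'   `level`.
#' @examples
#' es_vector(c(fruit = 0.4, costs = 0.2), c("service", "disservice"))
#' @export
es_vector <- function(levels, sign = "service") {
  nm <- names(levels)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    stop("ES levels must have unique non-empty names")
  }
  sign <- rep_len(sign, length(levels))
  if (!all(sign %in% c("service", "disservice"))) {
    stop("sign must be 'service' or 'disservice'")
  }
  if (any(levels < -1e-12 | levels > 1 + 1e-12)) {
    stop("ES levels must lie in [0, 1]")
  }
  structure(
    data.frame(name = nm, sign = sign, level = pmin(pmax(as.numeric(levels), 0), 1),
               stringsAsFactors = FALSE),
    class = c("es_vector", "data.frame")
  )
}

# named numeric levels from an es_vector or a named numeric vector
es_levels <- function(es) {
  if (inherits(es, "es_vector")) {
    stats::setNames(es$level, es$name)
  } else {
    if (is.null(names(es))) stop("ES levels must be named")
    es
  }
}

#' Define the satisfactory domain of ecosystem services
#'
#' The satisfactory domain is the box of ES levels meeting every actor
#' constraint: each service must stay at or above its lower threshold, each
#' disservice at or below its upper threshold.
#'
#' @param es_min Named numeric vector of lower thresholds for services,
#'   each in `[0, 1]`.
#' @param es_max Named numeric vector of upper thresholds for disservices,
#'   each in `[0, 1]`.
#' @return A data frame of class `"satisfactory_domain"` with columns `name`,
#'   `sign`, `bound`.
#' @examples
#' satisfactory_domain(es_min = c(fruit = 0.2), es_max = c(costs = 0.6))
#' @export
satisfactory_domain <- function(es_min = numeric(), es_max = numeric()) {
  for (v in list(es_min, es_max)) {
    if (length(v) && (is.null(names(v)) || any(names(v) == ""))) {
      stop("thresholds must be named by ES")
    }
    if (any(v < 0 | v > 1)) stop("thresholds must lie in [0, 1]")
  }
  if (anyDuplicated(c(names(es_min), names(es_max)))) {
    stop("each ES must have exactly one bound")
  }
  d <- rbind(
    if (length(es_min)) data.frame(name = names(es_min), sign = "service",
                                   bound = as.numeric(es_min)),
    if (length(es_max)) data.frame(name = names(es_max), sign = "disservice",
                                   bound = as.numeric(es_max))
  )
  if (is.null(d)) d <- data.frame(name = character(), sign = character(),
                                  bound = numeric())
  structure(d, class = c("satisfactory_domain", "data.frame"))
}

# per-ES signed margins for a matrix of levels (rows = states, columns in
# domain order).  Returns list(margin, normalized) of matrices.
margin_matrix <- function(domain, levels) {
  stopifnot(ncol(levels) == nrow(domain))
  bound <- domain$bound
  service <- domain$sign == "service"
  m <- sweep(levels, 2, bound, "-")
  m[, !service] <- -m[, !service, drop = FALSE]
  width <- ifelse(service, 1 - bound, bound)
  width[width <= 0] <- 1e-12   # degenerate bound at the edge of the range
  nm <- sweep(m, 2, width, "/")
  list(margin = m, normalized = nm)
}

#' Signed constraint margins against the satisfactory domain
#'
#' For a service the margin is `level - es_min`; for a disservice it is
#' `es_max - level`.  The normalized margin divides by the feasible width of
#' the bound (`1 - es_min` for a service, `es_max` for a disservice), so a
#' level maximally inside its bound scores 1 and a level exactly at the
#' threshold scores 0.  The state is a member of the domain iff all margins
#' are non-negative; the normalized sum is the mean of the normalized
#' margins.
#'
#' @param domain A [satisfactory_domain()].
#' @param es An [es_vector()] or named numeric vector of levels covering
#'   every ES named in the domain.
#' @return A data frame of class `"es_margin"` with columns `name`, `sign`,
#'   `level`, `bound`, `margin`, `normalized`, and attributes `member`
#'   (logical) and `normalized_sum`.
#' @examples
#' d <- satisfactory_domain(es_min = c(fruit = 0.2), es_max = c(costs = 0.6))
#' m <- margin(d, c(fruit = 0.2, costs = 0.1))
#' attr(m, "member")
#' @export
margin <- function(domain, es) {
  lv <- es_levels(es)
  missing <- setdiff(domain$name, names(lv))
  if (length(missing)) {
    stop("ES named in domain but absent from state: ",
         paste(missing, collapse = ", "))
  }
  levels <- matrix(lv[domain$name], nrow = 1)
  mm <- margin_matrix(domain, levels)
  out <- data.frame(name = domain$name, sign = domain$sign,
                    level = lv[domain$name], bound = domain$bound,
                    margin = mm$margin[1, ], normalized = mm$normalized[1, ],
                    row.names = NULL)
  class(out) <- c("es_margin", "data.frame")
  attr(out, "member") <- all(mm$margin[1, ] >= 0)
  attr(out, "normalized_sum") <- mean(mm$normalized[1, ])
  out
}

#' @export
print.es_margin <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("member of satisfactory domain: %s; normalized sum: %.4f\n",
              attr(x, "member"), attr(x, "normalized_sum")))
  invisible(x)
}
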