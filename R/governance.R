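# SESF multi-tier action codes and nested CCA|KCA|OCA governance arrangements.
#
# An action code identifies an adaptation action by the SESF attribute it
# targets (tier-1 category + tier-2 index), the role that triggers it, the
# role (or the resource R) it targets, and optionally the institutional level
# (OCA/KCA/CCA/MCA) and arrangement transition that the action realizes.

.tier2_max <- c(S = 7, RS = 10, RU = 7, GS = 10, A = 9, I = 10, O = 3)
.trigger_roles <- c("E", "C", "P")
.target_roles <- c("E", "C", "P", "R")
.levels <- c("OCA", "KCA", "CCA", "MCA")

#' Construct an SESF action code
#'
#' @param tier1 Tier-1 category: one of `S`, `RS`, `RU`, `GS`, `A`, `I`, `O`.
#' @param tier2 Positive integer, bounded by the category's attribute count
#'   (S: 7, RS: 10, RU: 7, GS: 10, A: 9, I: 10, O: 3).
#' @param trigger Optional triggering role (`E`, `C` or `P`).
#' @param target Optional targeted role (`E`, `C`, `P` or `R`).
#' @param level Optional institutional level (`OCA`, `KCA`, `CCA`, `MCA`).
#' @param transition Optional ordered pair of arrangement identifiers (the
#'   adaptation from the first into the second); requires `level`.
#' @return A list of class `"action_code"`.
#' @examples
#' action_code("A", 2, trigger = "C", target = "E")
#' @export
action_code <- function(tier1, tier2, trigger = NULL, target = NULL,
                        level = NULL, transition = NULL) {
  if (!tier1 %in% names(.tier2_max)) {
    stop("unknown tier-1 category ", tier1)
  }
  tier2 <- as.integer(tier2)
  if (is.na(tier2) || tier2 < 1 || tier2 > .tier2_max[[tier1]]) {
    stop("tier-2 index out of range for category ", tier1,
         " (1..", .tier2_max[[tier1]], ")")
  }
  if (!is.null(trigger) && !trigger %in% .trigger_roles) {
    stop("unknown trigger role ", trigger)
  }
  if (!is.null(target) && !target %in% .target_roles) {
    stop("unknown target role ", target)
  }
  if (!is.null(level) && !level %in% .levels) {
    stop("unknown institutional level ", level)
  }
  if (!is.null(transition)) {
    if (is.null(level)) stop("a level transition requires a level")
    transition <- as.character(transition)
    if (length(transition) != 2) stop("transition must be an ordered pair")
    if (any(grepl("_|->", transition))) {
      stop("arrangement identifiers in a transition may not contain '_' or '->'")
    }
  }
  structure(list(tier1 = tier1, tier2 = tier2, trigger = trigger,
                 target = target, level = level, transition = transition),
            class = "action_code")
}

#' Format an action code as text
#'
#' Produces the text form
#' `U[_{level}[:{from}->{to}]]_[{trigger}->]{target}:{tier1}{tier2}`,
#' e.g. `U_C->E:A2` or `U_OCA:1->2_C->E:A2`.  [parse_action_code()] is its
#' inverse.
#'
#' @param code An [action_code()].
#' @return A character scalar.
#' @export
format_action_code <- function(code) {
  stopifnot(inherits(code, "action_code"))
  lvl <- if (!is.null(code$level)) {
    paste0("_", code$level,
           if (!is.null(code$transition)) {
             paste0(":", code$transition[1], "->", code$transition[2])
           })
  } else ""
  core <- paste0(
    if (!is.null(code$trigger)) paste0(code$trigger, "->"),
    if (!is.null(code$target)) code$target,
    if (!is.null(code$target)) ":",
    code$tier1, code$tier2
  )
  paste0("U", lvl, "_", core)
}

#' Parse the text form of an action code
#'
#' @param text A character scalar in the grammar documented in
#'   [format_action_code()].
#' @return An [action_code()]; parsing is the inverse of formatting.
#' @examples
#' parse_action_code("U_C->E:A2")
#' parse_action_code("U_OCA:1->2_C->E:A2")
#' @export
parse_action_code <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!startsWith(text, "U_")) {
    stop("action code must start with 'U_': ", text)
  }
  rest <- substring(text, 3)
  level <- NULL; transition <- NULL
  m <- regmatches(rest, regexec("^(OCA|KCA|CCA|MCA)(:([^_]+)->([^_]+))?_(.*)$", rest))[[1]]
  if (length(m)) {
    level <- m[2]
    if (nzchar(m[3])) transition <- c(m[4], m[5])
    rest <- m[6]
  }
  trigger <- NULL
  m <- regmatches(rest, regexec("^([^-:]+)->(.*)$", rest))[[1]]
  if (length(m)) {
    trigger <- m[2]
    if (!trigger %in% .trigger_roles) stop("unknown trigger role ", trigger)
    rest <- m[3]
  }
  target <- NULL
  m <- regmatches(rest, regexec("^([A-Z]+):([A-Z]+)([0-9]+)$", rest))[[1]]
  if (length(m)) {
    target <- m[2]
    if (!target %in% .target_roles) stop("unknown target role ", target)
    tier1 <- m[3]; tier2 <- m[4]
  } else {
    m <- regmatches(rest, regexec("^([A-Z]+?)([0-9]+)$", rest))[[1]]
    if (!length(m)) stop("malformed attribute part: ", rest)
    tier1 <- m[2]; tier2 <- m[3]
  }
  action_code(tier1, as.integer(tier2), trigger = trigger, target = target,
              level = level, transition = transition)
}

#' @export
print.action_code <- function(x, ...) {
  cat(format_action_code(x), "\n")
  invisible(x)
}

# Role incidence: the roles whose state appears in (or that receive) the
# Eq-type term carried by each weight.  A role switched off by an arrangement
# forces all its incident links off.
.weight_roles <- list(
  u0a = character(), u0b = "E", u0c = "P", u0d = "C",
  u1a = c("E", "C"), u1b = c("E", "C"),
  u2a = c("E", "P"), u2b = c("E", "P"),
  u3a = c("P", "C"), u3b = c("C", "P"),
  u4a = "C", u4b = "C",
  u5a = c("E", "C"), u5b = c("E", "C"),
  u5a_prime = c("E", "C"), u5b_prime = c("E", "C"),
  u6a = c("E", "C"), u6b = c("E", "C"), u6b_prime = c("E", "C"),
  u7a = character(), u7b = character(), u7c = "E", u7d = "E",
  u7e = c("C", "P"), u7f = c("C", "P"), u7g = "C", u7h = "C"
)

# default SESF coding of each CIS link, used by diff_arrangements()
.weight_code_defaults <- list(
  u0a = list(trigger = NULL, target = "R", tier1 = "RU", tier2 = 2),
  u0b = list(trigger = "E", target = "E", tier1 = "A", tier2 = 2),
  u0c = list(trigger = "P", target = "P", tier1 = "A", tier2 = 2),
  u0d = list(trigger = "C", target = "C", tier1 = "A", tier2 = 2),
  u1a = list(trigger = "E", target = "R", tier1 = "I", tier2 = 1),
  u1b = list(trigger = "E", target = "R", tier1 = "I", tier2 = 1),
  u2a = list(trigger = "E", target = "P", tier1 = "I", tier2 = 9),
  u2b = list(trigger = "P", target = "E", tier1 = "I", tier2 = 3),
  u3a = list(trigger = "P", target = "C", tier1 = "I", tier2 = 3),
  u3b = list(trigger = "C", target = "P", tier1 = "I", tier2 = 3),
  u4a = list(trigger = "C", target = "R", tier1 = "I", tier2 = 9),
  u4b = list(trigger = "C", target = "R", tier1 = "I", tier2 = 5),
  u5a = list(trigger = "C", target = "E", tier1 = "GS", tier2 = 6),
  u5b = list(trigger = "C", target = "E", tier1 = "GS", tier2 = 6),
  u5a_prime = list(trigger = "E", target = "C", tier1 = "I", tier2 = 9),
  u5b_prime = list(trigger = "E", target = "C", tier1 = "I", tier2 = 9),
  u6a = list(trigger = "E", target = "C", tier1 = "I", tier2 = 7),
  u6b = list(trigger = "C", target = "E", tier1 = "I", tier2 = 3),
  u6b_prime = list(trigger = "C", target = "E", tier1 = "I", tier2 = 8),
  u7a = list(trigger = NULL, target = "R", tier1 = "O", tier2 = 3),
  u7b = list(trigger = NULL, target = "R", tier1 = "S", tier2 = 3),
  u7c = list(trigger = NULL, target = "E", tier1 = "O", tier2 = 3),
  u7d = list(trigger = NULL, target = "E", tier1 = "S", tier2 = 7),
  u7e = list(trigger = NULL, target = "P", tier1 = "O", tier2 = 3),
  u7f = list(trigger = NULL, target = "P", tier1 = "S", tier2 = 7),
  u7g = list(trigger = NULL, target = "C", tier1 = "O", tier2 = 3),
  u7h = list(trigger = NULL, target = "C", tier1 = "S", tier2 = 7)
)

# weights not part of any sum-to-one group: the operational surface on which
# OCA intensity choices are allowed (management, regulation, support,
# externality and stress rates acting on R or across compartments)
.oca_weights <- setdiff(.cisf_weight_names, unlist(.cisf_sum_groups))

#' Construct a nested governance arrangement
#'
#' A CCA|KCA|OCA configuration: the constitutional level (CCA) switches
#' whole roles on or off, the collective level (KCA) switches individual CIS
#' links on or off, and the operational level (OCA) fixes the chosen
#' intensity of each operational action within its admissible range.
#'
#' A role switched off forces all links whose dynamics involve that role off
#' as well; this is applied automatically to `link_mask`.
#'
#' @param cca_index Constitutional arrangement index (1..4 in the shipped
#'   fixture, any positive integer in general).
#' @param kca_index Collective arrangement index.
#' @param role_mask Named logical vector `c(E=, C=, P=)` of active roles.
#' @param link_mask Optional named logical vector over the action-weight
#'   names; defaults to all links of the active roles on.
#' @param oca Optional data frame with columns `weight`, `min`, `max`,
#'   `value`: the chosen intensity (an absolute rate, within `[min, max]`)
#'   of each operational action.  Only weights outside the sum-to-one groups
#'   may appear.
#' @param id Arrangement identifier; defaults to `"CCA<i>|KCA<j>"`.
#' @return A list of class `"arrangement"`.
#' @examples
#' arrangement(1, 1, role_mask = c(E = TRUE, C = FALSE, P = FALSE))
#' @export
arrangement <- function(cca_index, kca_index,
                        role_mask = c(E = TRUE, C = TRUE, P = TRUE),
                        link_mask = NULL, oca = NULL, id = NULL) {
  stopifnot(cca_index >= 1, kca_index >= 1)
  role_mask <- as.logical(role_mask[c("E", "C", "P")])
  names(role_mask) <- c("E", "C", "P")
  if (anyNA(role_mask)) stop("role_mask must name E, C and P")
  if (is.null(link_mask)) {
    link_mask <- stats::setNames(rep(TRUE, length(.cisf_weight_names)),
                                 .cisf_weight_names)
  } else {
    if (!all(names(link_mask) %in% .cisf_weight_names)) {
      stop("unknown link name(s) in link_mask")
    }
    full <- stats::setNames(rep(TRUE, length(.cisf_weight_names)),
                            .cisf_weight_names)
    full[names(link_mask)] <- as.logical(link_mask)
    link_mask <- full
  }
  inactive <- names(role_mask)[!role_mask]
  for (w in .cisf_weight_names) {
    if (length(intersect(.weight_roles[[w]], inactive))) link_mask[[w]] <- FALSE
  }
  if (!is.null(oca)) {
    stopifnot(is.data.frame(oca),
              all(c("weight", "min", "max", "value") %in% names(oca)))
    bad <- setdiff(oca$weight, .oca_weights)
    if (length(bad)) {
      stop("OCA intensities are only allowed on operational weights, not: ",
           paste(bad, collapse = ", "))
    }
    out <- oca$value < oca$min - 1e-12 | oca$value > oca$max + 1e-12
    if (any(out)) {
      stop("chosen OCA intensity outside its admissible range for: ",
           paste(oca$weight[out], collapse = ", "))
    }
  }
  if (is.null(id)) id <- sprintf("CCA%d|KCA%d", cca_index, kca_index)
  structure(list(id = id, cca_index = as.integer(cca_index),
                 kca_index = as.integer(kca_index), role_mask = role_mask,
                 link_mask = link_mask, oca = oca),
            class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  cat(sprintf("arrangement %s: roles {%s} active, %d/%d links on",
              x$id, paste(names(x$role_mask)[x$role_mask], collapse = ", "),
              sum(x$link_mask), length(x$link_mask)))
  if (!is.null(x$oca)) cat(sprintf(", %d OCA intensities", nrow(x$oca)))
  cat("\n")
  invisible(x)
}

#' Derive concrete action weights from an arrangement
#'
#' Applies the arrangement to a base weight set: weights of masked-off links
#' are set to zero, chosen OCA intensities replace the corresponding
#' operational weights, and each active compartment's remaining incoming
#' weights are rescaled proportionally so the sum-to-one constraints still
#' hold.  A compartment whose role is switched off ends with all incoming
#' weights zero (and passes [check_normalization()] as an absent role).
#'
#' The operation is idempotent: applying the same arrangement to its own
#' output returns the output unchanged.
#'
#' @param arr An [arrangement()].
#' @param base An [action_weights()] vector passing [check_normalization()].
#' @return An [action_weights()] vector.
#' @export
arrangement_weights <- function(arr, base) {
  stopifnot(inherits(arr, "arrangement"))
  base <- as_action_weights(base)
  if (!check_normalization(base)$pass) {
    stop("base weights do not satisfy the sum-to-one constraints")
  }
  w <- base
  w[!arr$link_mask] <- 0
  if (!is.null(arr$oca)) {
    on <- arr$link_mask[arr$oca$weight]
    w[arr$oca$weight[on]] <- arr$oca$value[on]
  }
  for (comp in names(.cisf_sum_groups)) {
    g <- .cisf_sum_groups[[comp]]
    role_active <- arr$role_mask[[comp]]
    s <- sum(w[g])
    if (!role_active) next  # all incident links already masked off
    if (s <= 1e-12) {
      stop("arrangement ", arr$id, " leaves active compartment ", comp,
           " with no incoming weight")
    }
    w[g] <- w[g] / s
  }
  validate_weight_ranges(w)
  w
}

#' Adaptation actions separating two arrangements
#'
#' Returns the adaptation action codes at the highest institutional level at
#' which the two arrangements differ: constitutional (CCA) if their CCA
#' indices differ, else collective (KCA) if their link masks differ, else
#' operational (OCA) if any chosen intensity differs.  Each code is tagged
#' with the level and the ordered transition `a -> b`.
#'
#' @param a,b [arrangement()] objects.
#' @return A list of [action_code()] objects (empty if the arrangements are
#'   equivalent).
#' @export
diff_arrangements <- function(a, b) {
  stopifnot(inherits(a, "arrangement"), inherits(b, "arrangement"))
  codes <- list()
  if (a$cca_index != b$cca_index) {
    tr <- c(as.character(a$cca_index), as.character(b$cca_index))
    codes <- list(action_code("GS", 4, trigger = "P", target = "P",
                              level = "CCA", transition = tr))
    # roles gained or lost by the constitutional change
    for (r in names(a$role_mask)) {
      if (a$role_mask[[r]] != b$role_mask[[r]]) {
        codes <- c(codes, list(action_code("A", 1, trigger = "P", target = r,
                                           level = "CCA", transition = tr)))
      }
    }
    return(codes)
  }
  if (!identical(unname(a$link_mask), unname(b$link_mask))) {
    tr <- c(as.character(a$kca_index), as.character(b$kca_index))
    changed <- names(a$link_mask)[a$link_mask != b$link_mask]
    return(lapply(changed, function(wn) {
      d <- .weight_code_defaults[[wn]]
      action_code(d$tier1, d$tier2, trigger = d$trigger, target = d$target,
                  level = "KCA", transition = tr)
    }))
  }
  oa <- if (is.null(a$oca)) data.frame(weight = character(), value = numeric()) else a$oca
  ob <- if (is.null(b$oca)) data.frame(weight = character(), value = numeric()) else b$oca
  all_w <- union(oa$weight, ob$weight)
  va <- stats::setNames(rep(NA_real_, length(all_w)), all_w)
  vb <- va
  va[oa$weight] <- oa$value
  vb[ob$weight] <- ob$value
  va[is.na(va)] <- -Inf; vb[is.na(vb)] <- -Inf
  changed <- all_w[va != vb]
  tr <- c(a$id, b$id)
  lapply(changed, function(wn) {
    d <- .weight_code_defaults[[wn]]
    action_code(d$tier1, d$tier2, trigger = d$trigger, target = d$target,
                level = "OCA", transition = tr)
  })
}
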