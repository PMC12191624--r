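#' Construct a binary causal network
#'
#' A causal network is a directed acyclic graph over named binary variables,
#' each link carrying a polarity: `"generative"` (the cause raises the
#' probability of its effect) or `"inhibitory"` (the cause lowers it).
#' Networks of up to 16 variables are supported, the regime in which exact
#' enumeration of all `2^n` system states is practical.
#'
#' @param variables character vector of variable names, in declaration order.
#'   The declaration order fixes the state indexing: the first variable is
#'   the most significant bit (see [state_index()]).
#' @param links a data frame (or list of length-3 vectors) with columns
#'   `from`, `to`, `polarity`; polarity is `"generative"` or `"inhibitory"`.
#' @return an object of class `causal_network` with elements `variables`,
#'   `links` (data frame), `parents` (named list of parent names per
#'   variable) and `roots` (variables with no parents).
#' @examples
#' dm <- diamond_network("generative")
#' dm$roots
#' @export
causal_network <- function(variables, links) {
  stopifnot(is.character(variables), length(variables) >= 1)
  if (anyDuplicated(variables)) stop("duplicate variable names")
  if (length(variables) > 16) stop("at most 16 variables supported")
  if (is.list(links) && !is.data.frame(links)) {
    links <- do.call(rbind, lapply(links, function(l) {
      data.frame(from = l[[1]], to = l[[2]], polarity = l[[3]])
    }))
  }
  if (is.null(links) || nrow(links) == 0) {
    links <- data.frame(from = character(), to = character(),
                        polarity = character())
  }
  stopifnot(all(c("from", "to", "polarity") %in% names(links)))
  if (!all(links$from %in% variables) || !all(links$to %in% variables))
    stop("link endpoints must be declared variables")
  if (!all(links$polarity %in% c("generative", "inhibitory")))
    stop("polarity must be 'generative' or 'inhibitory'")
  if (anyDuplicated(links[, c("from", "to")]))
    stop("duplicate links")
  parents <- lapply(variables, function(v) links$from[links$to == v])
  names(parents) <- variables
  # acyclicity by Kahn's algorithm
  indeg <- vapply(parents, length, integer(1))
  active <- rep(TRUE, length(variables))
  names(active) <- variables
  repeat {
    src <- names(indeg)[indeg == 0 & active]
    if (length(src) == 0) break
    for (s in src) {
      active[s] <- FALSE
      kids <- links$to[links$from == s]
      indeg[kids] <- indeg[kids] - 1L
    }
  }
  if (any(active)) stop("network contains a directed cycle")
  structure(
    list(variables = variables,
         links = links[, c("from", "to", "polarity")],
         parents = parents,
         roots = variables[indeg == 0 & vapply(parents, length, 1L) == 0]),
    class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat("causal_network over", length(x$variables), "binary variables:",
      paste(x$variables, collapse = ", "), "\n")
  if (nrow(x$links)) {
    arrows <- ifelse(x$links$polarity == "generative", "->", "-|")
    cat(paste0("  ", x$links$from, " ", arrows, " ", x$links$to),
        sep = "\n")
  }
  invisible(x)
}

#' Parameterization of a causal network
#'
#' Holds root-variable base rates, link weights and exogenous (background)
#' weights for the logistic conditional probability tables. Root priors are
#' direct probabilities; link and exogenous weights live on the logistic
#' scale. Generative links must have weight >= 0, inhibitory links <= 0.
#'
#' @param network a [causal_network()].
#' @param root_prior named numeric vector, one probability in (0,1) per root
#'   variable; an unnamed scalar is recycled to all roots.
#' @param link_weight either a numeric vector of length `nrow(network$links)`
#'   (per-link, in link declaration order) or a named list/vector with
#'   elements `generative` and (if needed) `inhibitory` that tie all links of
#'   each polarity to a single weight.
#' @param exo_weight either a single number shared by every non-root variable
#'   (the default tie, matching a single background-strength parameter) or a
#'   named vector with one entry per non-root variable.
#' @return an object of class `parameterization` with per-root `root_prior`,
#'   per-link `link_weight` and per-non-root `exo_weight`.
#' @export
parameterization <- function(network, root_prior, link_weight, exo_weight) {
  stopifnot(inherits(network, "causal_network"))
  roots <- network$roots
  nonroots <- setdiff(network$variables, roots)

  if (is.null(names(root_prior))) {
    if (length(root_prior) == 1) {
      root_prior <- stats::setNames(rep(root_prior, length(roots)), roots)
    } else stop("root_prior must be named or scalar")
  }
  if (!all(roots %in% names(root_prior)))
    stop("root_prior missing for: ",
         paste(setdiff(roots, names(root_prior)), collapse = ", "))
  root_prior <- root_prior[roots]
  if (any(root_prior <= 0 | root_prior >= 1))
    stop("root priors must lie strictly inside (0,1)")

  nl <- nrow(network$links)
  if (!is.null(names(link_weight)) &&
      any(names(link_weight) %in% c("generative", "inhibitory"))) {
    lw <- numeric(nl)
    for (pol in unique(network$links$polarity)) {
      if (is.na(link_weight[pol]))
        stop("tied link_weight missing for polarity ", pol)
      lw[network$links$polarity == pol] <- unlist(link_weight)[pol]
    }
    link_weight <- lw
  }
  if (length(link_weight) != nl)
    stop("need one weight per link (", nl, ")")
  gen <- network$links$polarity == "generative"
  if (any(link_weight[gen] < 0))
    stop("generative link weights must be >= 0")
  if (any(link_weight[!gen] > 0))
    stop("inhibitory link weights must be <= 0")

  if (length(nonroots)) {
    if (is.null(names(exo_weight))) {
      if (length(exo_weight) == 1) {
        exo_weight <- stats::setNames(rep(exo_weight, length(nonroots)),
                                      nonroots)
      } else stop("exo_weight must be named or scalar")
    }
    if (!all(nonroots %in% names(exo_weight)))
      stop("exo_weight missing for: ",
           paste(setdiff(nonroots, names(exo_weight)), collapse = ", "))
    exo_weight <- exo_weight[nonroots]
  } else exo_weight <- numeric(0)

  structure(list(root_prior = root_prior,
                 link_weight = as.numeric(link_weight),
                 exo_weight = exo_weight),
            class = "parameterization")
}

# ---- system states -------------------------------------------------------

#' Map between system states and state indices
#'
#' A system state assigns 0/1 to every variable. States are indexed
#' 0..2^n - 1 with the FIRST declared variable as the most significant bit,
#' so for a four-variable network (X, YA, YB, Z) the state "1111" has index
#' 15 and "1000" (only X present) has index 8.
#'
#' @param bits integer vector of 0/1 in network variable order.
#' @return `state_index`: the integer index in 0..2^n-1.
#' @export
state_index <- function(bits) {
  stopifnot(all(bits %in% c(0, 1)))
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}

#' @rdname state_index
#' @param index integer in 0..2^n-1.
#' @param n number of variables.
#' @return `state_bits`: integer 0/1 vector of length `n`, MSB first.
#' @export
state_bits <- function(index, n) {
  stopifnot(index >= 0, index < 2^n)
  as.integer(intToBits(index))[n:1]
}

# all 2^n states as a (2^n x n) 0/1 matrix, row i = state index i-1
state_matrix <- function(n) {
  m <- matrix(0L, 2^n, n)
  for (j in seq_len(n)) {
    period <- 2^(n - j)
    m[, j] <- rep(rep(c(0L, 1L), each = period), length.out = 2^n)
  }
  m
}

#' Format a state as a bit string
#' @param bits 0/1 vector.
#' @return character like `"1101"`.
#' @export
state_label <- function(bits) paste(as.integer(bits), collapse = "")

# ---- conditional probability tables --------------------------------------

#' Conditional probability of a single variable given its parents
#'
#' Root variables return their base rate. A non-root variable with parents
#' coded +1 (present) / -1 (absent) has
#' `p(v = 1 | parents) = plogis(sum_j w_j * c_j + w_exo)`: the logistic of
#' the weighted parent codes plus the variable's exogenous weight. Multiple
#' parents combine additively inside the one logistic.
#'
#' @param network a [causal_network()].
#' @param params a [parameterization()].
#' @param variable variable name.
#' @param parent_assignment named 0/1 vector covering exactly the variable's
#'   parents (empty/NULL for roots).
#' @return probability in (0,1).
#' @export
cpd_prob <- function(network, params, variable, parent_assignment = NULL) {
  stopifnot(variable %in% network$variables)
  pa <- network$parents[[variable]]
  given <- names(parent_assignment)
  if (!setequal(given, pa))
    stop("parent_assignment must cover exactly the parents of ", variable,
         " (", paste(pa, collapse = ", "), ")")
  if (length(pa) == 0) return(unname(params$root_prior[variable]))
  idx <- which(network$links$to == variable)
  w <- params$link_weight[idx]
  names(w) <- network$links$from[idx]
  codes <- ifelse(parent_assignment[names(w)] == 1, 1, -1)
  stats::plogis(sum(w * codes) + unname(params$exo_weight[variable]))
}

# per-variable CPD value at every one of the 2^n states, as a (2^n x n)
# matrix of p(v = state_v | parents at state); row products give the joint
cpd_state_matrix <- function(network, params) {
  vars <- network$variables
  n <- length(vars)
  S <- state_matrix(n)
  out <- matrix(NA_real_, 2^n, n)
  for (j in seq_len(n)) {
    v <- vars[j]
    pa <- network$parents[[v]]
    if (length(pa) == 0) {
      p1 <- params$root_prior[v]
    } else {
      idx <- which(network$links$to == v)
      w <- params$link_weight[idx]
      pj <- match(network$links$from[idx], vars)
      eta <- as.numeric((2 * S[, pj, drop = FALSE] - 1) %*% w) +
        params$exo_weight[v]
      p1 <- stats::plogis(eta)
    }
    out[, j] <- ifelse(S[, j] == 1, p1, 1 - p1)
  }
  out
}

#' Exact joint distribution over all system states
#'
#' Multiplies the per-variable conditional probability tables at each of the
#' `2^n` states, the standard factorization of a causal Bayes net joint.
#' With logistic CPDs and interior root priors every entry is strictly
#' positive.
#'
#' @inheritParams cpd_prob
#' @return a numeric vector of length `2^n`, class `joint_distribution`,
#'   indexed by state index + 1 (see [state_index()]); carries the variable
#'   names as attribute `variables`.
#' @export
joint_distribution <- function(network, params) {
  M <- cpd_state_matrix(network, params)
  p <- apply(M, 1, prod)
  structure(p, variables = network$variables, class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  vars <- attr(x, "variables")
  n <- length(vars)
  labs <- apply(state_matrix(n), 1, state_label)
  df <- data.frame(state = labs, prob = as.numeric(x))
  cat("joint_distribution over", paste(vars, collapse = ","), "\n")
  print(df, row.names = FALSE)
  invisible(x)
}

# ---- queries -------------------------------------------------------------

#' Construct a conditional-probability query
#'
#' Semantically `p(target = 1 | evidence)`; the evidence is a (possibly
#' empty) partial assignment of other variables to 0/1.
#'
#' @param target variable name.
#' @param evidence named 0/1 vector (possibly empty).
#' @param id optional stable string id; defaults to a canonical
#'   `"target|A=1,B=0"` form.
#' @return an object of class `cp_query`.
#' @export
query <- function(target, evidence = NULL, id = NULL) {
  if (length(evidence)) {
    stopifnot(!is.null(names(evidence)), all(evidence %in% c(0, 1)))
    if (target %in% names(evidence)) stop("target cannot appear in evidence")
  }
  if (is.null(id)) id <- query_id(target, evidence)
  structure(list(target = target, evidence = evidence, id = id),
            class = "cp_query")
}

query_id <- function(target, evidence) {
  if (!length(evidence)) return(target)
  paste0(target, "|", paste0(names(evidence), "=", as.integer(evidence),
                             collapse = ","))
}

#' Conditional probability from a joint distribution
#'
#' Sums the joint mass over states matching the evidence with the target
#' present, and divides by the mass matching the evidence. If the evidence
#' has zero mass (possible for degenerate sampled joints, never for exact
#' logistic joints) the `zero_mass_fallback` is returned.
#'
#' @param joint a [joint_distribution()] (or any vector with a `variables`
#'   attribute).
#' @param q a [query()].
#' @param zero_mass_fallback probability returned when the evidence has zero
#'   probability; default 0.5, a maximally uninformative judgment.
#' @return probability.
#' @export
conditional_query <- function(joint, q, zero_mass_fallback = 0.5) {
  vars <- attr(joint, "variables")
  if (is.null(vars)) stop("joint must carry a 'variables' attribute")
  stopifnot(inherits(q, "cp_query"))
  bad <- setdiff(c(q$target, names(q$evidence)), vars)
  if (length(bad)) stop("unknown variables: ", paste(bad, collapse = ", "))
  n <- length(vars)
  S <- state_matrix(n)
  keep <- rep(TRUE, 2^n)
  for (v in names(q$evidence))
    keep <- keep & (S[, match(v, vars)] == q$evidence[[v]])
  den <- sum(joint[keep])
  if (den == 0) return(zero_mass_fallback)
  num <- sum(joint[keep & S[, match(q$target, vars)] == 1])
  num / den
}

#' Normative model predictions for a battery of queries
#'
#' Answers every query in the battery from the exact joint distribution —
#' the predictions of an ideal causal-graphical-model reasoner. These
#' predictions obey the Markov condition exactly: conditioning on a shared
#' cause screens its effects off from one another.
#'
#' @inheritParams cpd_prob
#' @param battery a [query_battery()].
#' @return named numeric vector of probabilities in battery order.
#' @export
normative_predictions <- function(network, params, battery) {
  joint <- joint_distribution(network, params)
  mm <- battery_matrices(network, battery)
  num <- as.numeric(mm$num %*% as.numeric(joint))
  den <- as.numeric(mm$den %*% as.numeric(joint))
  stats::setNames(num / den, battery$id)
}

# ---- canonical study networks --------------------------------------------

#' The four-variable diamond networks of the screening-off study
#'
#' X causes both YA and YB, which in turn are independent causes of Z. In
#' the `"generative"` condition all four links are generative; in
#' `"ya_inhibitory"` the YA->Z link is inhibitory; in `"yb_inhibitory"` the
#' YB->Z link is. The two inhibitory diamonds admit no state qualitatively
#' consistent with all four links, hence no prototypes.
#'
#' @param condition one of `"generative"`, `"ya_inhibitory"`,
#'   `"yb_inhibitory"` (condition labels `"Generative"`, `"YA-Inhibitory"`,
#'   `"YB-Inhibitory"` are also accepted).
#' @return a [causal_network()] over X, YA, YB, Z.
#' @export
diamond_network <- function(condition = c("generative", "ya_inhibitory",
                                          "yb_inhibitory")) {
  key <- tolower(gsub("-", "_", condition[1]))
  key <- match.arg(key, c("generative", "ya_inhibitory", "yb_inhibitory"))
  pol <- c(`X->YA` = "generative", `X->YB` = "generative",
           `YA->Z` = "generative", `YB->Z` = "generative")
  if (key == "ya_inhibitory") pol["YA->Z"] <- "inhibitory"
  if (key == "yb_inhibitory") pol["YB->Z"] <- "inhibitory"
  causal_network(
    c("X", "YA", "YB", "Z"),
    data.frame(from = c("X", "X", "YA", "YB"),
               to = c("YA", "YB", "Z", "Z"),
               polarity = unname(pol)))
}

#' Three-variable teaching networks
#'
#' Small fixtures from earlier screening-off experiments: a common cause
#' EA <- C -> EB, a chain X -> Y -> Z, a common effect CA -> E <- CB, and a
#' mixed common cause whose C->EB link is inhibitory.
#'
#' @return a [causal_network()].
#' @export
common_cause_network <- function() {
  causal_network(c("C", "EA", "EB"),
                 data.frame(from = c("C", "C"), to = c("EA", "EB"),
                            polarity = c("generative", "generative")))
}

#' @rdname common_cause_network
#' @export
chain_network <- function() {
  causal_network(c("X", "Y", "Z"),
                 data.frame(from = c("X", "Y"), to = c("Y", "Z"),
                            polarity = c("generative", "generative")))
}

#' @rdname common_cause_network
#' @export
common_effect_network <- function() {
  causal_network(c("CA", "CB", "E"),
                 data.frame(from = c("CA", "CB"), to = c("E", "E"),
                            polarity = c("generative", "generative")))
}

#' @rdname common_cause_network
#' @export
mixed_common_cause_network <- function() {
  causal_network(c("C", "EA", "EB"),
                 data.frame(from = c("C", "C"), to = c("EA", "EB"),
                            polarity = c("generative", "inhibitory")))
}
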