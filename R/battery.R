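#' Construct a query battery
#'
#' An ordered list of conditional-probability queries with stable string
#' ids, represented as a data frame with columns `id`, `target` and
#' `evidence` (a list column of named 0/1 vectors).
#'
#' @param queries list of [query()] objects.
#' @return a `query_battery` data frame.
#' @export
query_battery <- function(queries) {
  stopifnot(all(vapply(queries, inherits, TRUE, "cp_query")))
  ids <- vapply(queries, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("query ids must be unique")
  out <- data.frame(id = ids, target = vapply(queries, `[[`, "", "target"))
  out$evidence <- lapply(queries, `[[`, "evidence")
  class(out) <- c("query_battery", "data.frame")
  out
}

# numerator/denominator indicator matrices (n_query x 2^n) so that a whole
# battery is answered by two matrix products against a joint/occupancy
battery_matrices <- function(network, battery) {
  vars <- network$variables
  n <- length(vars)
  S <- state_matrix(n)
  nq <- nrow(battery)
  num <- matrix(0, nq, 2^n)
  den <- matrix(0, nq, 2^n)
  for (i in seq_len(nq)) {
    keep <- rep(TRUE, 2^n)
    ev <- battery$evidence[[i]]
    for (v in names(ev)) keep <- keep & (S[, match(v, vars)] == ev[[v]])
    den[i, keep] <- 1
    num[i, keep & S[, match(battery$target[i], vars)] == 1] <- 1
  }
  list(num = num, den = den)
}

#' The 12 screening-off (Markov) queries for a shared cause
#'
#' For each ordered pair of effects (Yi, Yj) of the shared cause `x_var`,
#' and each state x of the cause, builds the triplet
#' p(Yi=1 | X=x, Yj=0), p(Yi=1 | X=x), p(Yi=1 | X=x, Yj=1) — the
#' other-effect-absent / unknown / present probes whose flatness expresses
#' the Markov condition. Order: Yi = first of `y_pair` with x = 0 then
#' x = 1, then the roles of the Ys reversed.
#'
#' @param network a [causal_network()].
#' @param x_var name of the shared cause.
#' @param y_pair character vector of the two effect names.
#' @return a `query_battery` of 12 queries carrying attribute
#'   `markov_cells`, a data frame mapping each of the four (Yi, x) cells to
#'   its Yj-absent and Yj-present query ids.
#' @export
markov_battery <- function(network, x_var, y_pair) {
  stopifnot(length(y_pair) == 2,
            all(c(x_var, y_pair) %in% network$variables))
  for (y in y_pair)
    if (!any(network$links$from == x_var & network$links$to == y))
      stop(x_var, " must be a direct cause of ", y)
  qs <- list()
  cells <- NULL
  for (i in 1:2) {
    yi <- y_pair[i]; yj <- y_pair[3 - i]
    for (x in 0:1) {
      ev <- function(yj_val) {
        e <- c(x, yj_val); names(e) <- c(x_var, yj); e
      }
      q_abs <- query(yi, ev(0))
      q_unk <- query(yi, stats::setNames(x, x_var))
      q_pre <- query(yi, ev(1))
      qs <- c(qs, list(q_abs, q_unk, q_pre))
      cells <- rbind(cells,
                     data.frame(target = yi, x = x, id_absent = q_abs$id,
                                id_present = q_pre$id))
    }
  }
  b <- query_battery(qs)
  attr(b, "markov_cells") <- cells
  b
}

#' Default 32-query inference battery for the diamond network
#'
#' The 12 Markov queries of [markov_battery()] plus 20 further one- and
#' two-variable-evidence queries spanning the rest of the structure:
#' p(Z=1|YA=a,YB=b) for all four (a,b); p(X=1|Yi=y); p(Yi=1|Z=z);
#' p(X=1|Z=z); p(Z=1|X=x); and p(Z=1|Yi=y). The membership of the
#' non-Markov queries is a documented package default and can be replaced
#' wholesale via `extra_queries`.
#'
#' @param network a diamond network over X, YA, YB, Z (see
#'   [diamond_network()]).
#' @param extra_queries optional list of [query()] objects replacing the
#'   default 20 non-Markov queries.
#' @return a `query_battery` (32 queries by default) with the
#'   `markov_cells` attribute of its Markov subset.
#' @export
default_battery_32 <- function(network, extra_queries = NULL) {
  if (!setequal(network$variables, c("X", "YA", "YB", "Z")))
    stop("expected the four-variable diamond over X, YA, YB, Z")
  mb <- markov_battery(network, "X", c("YA", "YB"))
  if (is.null(extra_queries)) {
    extra_queries <- list()
    for (a in 0:1) for (b in 0:1)
      extra_queries <- c(extra_queries,
                         list(query("Z", c(YA = a, YB = b))))
    for (yi in c("YA", "YB")) for (y in 0:1)
      extra_queries <- c(extra_queries,
                         list(query("X", stats::setNames(y, yi))))
    for (yi in c("YA", "YB")) for (z in 0:1)
      extra_queries <- c(extra_queries, list(query(yi, c(Z = z))))
    for (z in 0:1)
      extra_queries <- c(extra_queries, list(query("X", c(Z = z))))
    for (x in 0:1)
      extra_queries <- c(extra_queries, list(query("Z", c(X = x))))
    for (yi in c("YA", "YB")) for (y in 0:1)
      extra_queries <- c(extra_queries,
                         list(query("Z", stats::setNames(y, yi))))
  }
  all_q <- c(
    lapply(seq_len(nrow(mb)), function(i)
      query(mb$target[i], mb$evidence[[i]], id = mb$id[i])),
    extra_queries)
  b <- query_battery(all_q)
  attr(b, "markov_cells") <- attr(mb, "markov_cells")
  b
}

#' Markov-violation summary score
#'
#' For each of the four (Yi, x) cells the difference between the judged
#' probability of Yi when the screened-off other effect Yj is present and
#' when it is absent; the score is the mean of the four differences, on the
#' 0-100 rating scale.
#'
#' Sign convention: score = (Yj present) - (Yj absent), so the classic
#' positive Markov violation (a screened-off variable's presence raising
#' the judged probability) yields a positive score, and the exact normative
#' model scores 0.
#'
#' @param values named numeric vector of ratings (0-100) or model
#'   predictions, named by query id; must contain the battery's 8
#'   conditioned Markov queries.
#' @param battery a battery carrying the `markov_cells` attribute
#'   ([markov_battery()] or [default_battery_32()]).
#' @param values_are_probabilities if `TRUE`, values are model
#'   probabilities in \[0,1\] and are scaled by 100 before differencing.
#' @return the mean violation on the 0-100 scale.
#' @export
markov_violation_score <- function(values, battery,
                                   values_are_probabilities = FALSE) {
  cells <- attr(battery, "markov_cells")
  if (is.null(cells)) stop("battery lacks Markov-cell structure")
  need <- c(cells$id_present, cells$id_absent)
  miss <- setdiff(need, names(values))
  if (length(miss))
    stop("missing required Markov queries: ", paste(miss, collapse = ", "))
  v <- values
  if (values_are_probabilities) v <- v * 100
  mean(v[cells$id_present] - v[cells$id_absent])
}
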