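#' Derive prototype states by qualitative consistency
#'
#' A prototype is a full assignment of the network's variables that is
#' qualitatively consistent with every causal link, ignoring causal
#' direction and link strength: across a generative link the two variables
#' take equal values, across an inhibitory link opposite values. A network
#' mixing generative and inhibitory paths between the same pair of
#' variables (e.g. a diamond with one inhibitory arm) has no such state, so
#' the set may be empty.
#'
#' @param network a [causal_network()].
#' @return an object of class `prototype_set`: a character vector of state
#'   labels (bit strings, first variable leftmost), with 0-based state
#'   indices in attribute `index`. May be length 0.
#' @export
derive_prototypes <- function(network) {
  vars <- network$variables
  n <- length(vars)
  S <- state_matrix(n)
  ok <- rep(TRUE, 2^n)
  for (k in seq_len(nrow(network$links))) {
    a <- S[, match(network$links$from[k], vars)]
    b <- S[, match(network$links$to[k], vars)]
    ok <- ok & if (network$links$polarity[k] == "generative") a == b else a != b
  }
  idx <- which(ok) - 1L
  labs <- apply(S[ok, , drop = FALSE], 1, state_label)
  structure(as.character(labs), index = idx, class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  if (length(x) == 0) cat("prototype_set: (empty)\n")
  else cat("prototype_set:", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

#' Sampler settings
#'
#' @param lambda chain length, a real >= 1. The chain's start state counts
#'   as the first sample, so `lambda = 1` returns the start distribution
#'   itself; non-integer values interpolate linearly between adjacent
#'   integer chain lengths, keeping model predictions continuous in lambda.
#' @param start_mode `"prototypes"` (uniform over the prototype set),
#'   `"uniform"` (uniform over all states) or `"custom"`.
#' @param start_dist normalized distribution over states, required when
#'   `start_mode = "custom"`.
#' @param zero_mass_fallback probability returned by queries whose evidence
#'   receives zero occupancy mass.
#' @return an object of class `sampler_settings`.
#' @export
sampler_settings <- function(lambda,
                             start_mode = c("prototypes", "uniform", "custom"),
                             start_dist = NULL,
                             zero_mass_fallback = 0.5) {
  start_mode <- match.arg(start_mode)
  stopifnot(is.numeric(lambda), length(lambda) == 1, is.finite(lambda),
            lambda >= 1)
  if (start_mode == "custom") {
    if (is.null(start_dist)) stop("custom start_mode needs start_dist")
    if (abs(sum(start_dist) - 1) > 1e-9 || any(start_dist < 0))
      stop("start_dist must be a normalized distribution")
  }
  structure(list(lambda = lambda, start_mode = start_mode,
                 start_dist = start_dist,
                 zero_mass_fallback = zero_mass_fallback),
            class = "sampler_settings")
}

#' Metropolis-Hastings transition matrix on the state hypercube
#'
#' The proposal flips one of the n variables chosen uniformly at random (a
#' single "mutation", probability 1/n each); the proposal is accepted with
#' probability `min(1, pi(s')/pi(s))` and rejected mass accrues to the
#' self-transition. The matrix is column-stochastic: column s holds the
#' distribution of the next state given current state s, so distributions
#' propagate as `T %*% p`. Satisfies detailed balance with respect to the
#' target joint `pi`.
#'
#' @param joint a strictly positive [joint_distribution()].
#' @return a `2^n x 2^n` column-stochastic matrix with the joint's
#'   `variables` attribute attached.
#' @export
transition_matrix <- function(joint) {
  pi <- as.numeric(joint)
  if (any(pi <= 0)) stop("joint must be strictly positive")
  vars <- attr(joint, "variables")
  n <- length(vars)
  N <- 2^n
  Tm <- matrix(0, N, N)
  for (s in seq_len(N)) {
    nb <- bitwXor(s - 1L, 2^(0:(n - 1))) + 1L
    acc <- pmin(1, pi[nb] / pi[s])
    Tm[nb, s] <- acc / n
    Tm[s, s] <- 1 - sum(acc) / n
  }
  attr(Tm, "variables") <- vars
  Tm
}

#' Occupancy distribution of a finite chain
#'
#' The expected fraction of the chain's first L samples spent in each state:
#' `(1/L) * sum_{t=0}^{L-1} T^t %*% start`, the start state counting as the
#' first sample. For non-integer `lambda` the occupancies at
#' `floor(lambda)` and `ceiling(lambda)` are interpolated linearly. As
#' `lambda` grows the occupancy converges to the stationary joint; at small
#' `lambda` it retains the start-state bias that produces the model's
#' systematic reasoning errors.
#'
#' @param Tm a [transition_matrix()].
#' @param start normalized distribution over states (length `2^n`).
#' @param lambda chain length >= 1.
#' @return a distribution over states with the `variables` attribute of
#'   `Tm`, class `joint_distribution`.
#' @export
occupancy_distribution <- function(Tm, start, lambda) {
  stopifnot(lambda >= 1, length(start) == nrow(Tm))
  if (abs(sum(start) - 1) > 1e-9 || any(start < 0))
    stop("start must be a normalized distribution")
  occ_int <- function(L) {
    v <- as.numeric(start)
    acc <- v
    if (L > 1) for (t in seq_len(L - 1)) {
      v <- as.numeric(Tm %*% v)
      acc <- acc + v
    }
    acc / L
  }
  lo <- floor(lambda)
  if (lo == lambda) out <- occ_int(lambda)
  else {
    w <- lambda - lo
    # one pass: occupancy at lo and lo+1 share the same partial sums
    v <- as.numeric(start)
    acc <- v
    if (lo > 1) for (t in seq_len(lo - 1)) {
      v <- as.numeric(Tm %*% v)
      acc <- acc + v
    }
    occ_lo <- acc / lo
    v <- as.numeric(Tm %*% v)
    occ_hi <- (acc + v) / (lo + 1)
    out <- (1 - w) * occ_lo + w * occ_hi
  }
  structure(out, variables = attr(Tm, "variables"),
            class = "joint_distribution")
}

# start distribution implied by settings; errors if prototypes requested but
# none exist
start_distribution <- function(network, settings) {
  N <- 2^length(network$variables)
  switch(settings$start_mode,
    prototypes = {
      pr <- derive_prototypes(network)
      if (length(pr) == 0)
        stop("network has no prototype states; use start_mode = 'uniform'")
      d <- numeric(N)
      d[attr(pr, "index") + 1L] <- 1 / length(pr)
      d
    },
    uniform = rep(1 / N, N),
    custom = {
      if (length(settings$start_dist) != N)
        stop("start_dist has wrong length")
      as.numeric(settings$start_dist)
    })
}

#' Mutation-sampler predicted judgments
#'
#' The model's predicted conditional-probability judgments: the chain's
#' occupancy distribution (exact finite-chain expectation, no Monte Carlo
#' noise) stands in for the joint distribution when answering each query in
#' the battery. With `start_mode = "prototypes"` sampling starts uniformly
#' over the prototype set; if the network has no prototypes an error directs
#' the caller to `"uniform"`, the no-prototype variant in which sampling
#' starts at a randomly chosen state.
#'
#' @inheritParams cpd_prob
#' @param settings a [sampler_settings()].
#' @param battery a [query_battery()].
#' @return named numeric vector of predicted probabilities in battery order.
#' @export
sampler_predictions <- function(network, params, settings, battery) {
  joint <- joint_distribution(network, params)
  Tm <- transition_matrix(joint)
  start <- start_distribution(network, settings)
  occ <- occupancy_distribution(Tm, start, settings$lambda)
  mm <- battery_matrices(network, battery)
  num <- as.numeric(mm$num %*% as.numeric(occ))
  den <- as.numeric(mm$den %*% as.numeric(occ))
  out <- ifelse(den == 0, settings$zero_mass_fallback, num / pmax(den, .Machine$double.xmin))
  stats::setNames(out, battery$id)
}

#' Simulate a stochastic mutation-sampler chain
#'
#' The stochastic counterpart of [occupancy_distribution()]: an actual
#' Metropolis-Hastings trajectory over system states, reproducible under a
#' seed. Useful for studying within-subject response variability; the
#' deterministic occupancy is the expectation of the empirical state
#' frequencies of such chains.
#'
#' @inheritParams sampler_predictions
#' @param n_samples number of states in the trajectory (including the start).
#' @param seed integer seed.
#' @return a data frame with columns `step` (1-based), `state` (bit-string
#'   label) and `index` (0-based state index).
#' @export
simulate_chain <- function(network, params, settings, n_samples, seed) {
  stopifnot(n_samples >= 1, !missing(seed))
  joint <- as.numeric(joint_distribution(network, params))
  n <- length(network$variables)
  start <- start_distribution(network, settings)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  s <- sample.int(2^n, 1, prob = start) - 1L
  idx <- integer(n_samples)
  idx[1] <- s
  if (n_samples > 1) {
    flips <- sample.int(n, n_samples - 1, replace = TRUE)
    u <- stats::runif(n_samples - 1)
    for (t in 2:n_samples) {
      prop <- bitwXor(s, 2^(flips[t - 1] - 1L))
      if (u[t - 1] < joint[prop + 1L] / joint[s + 1L]) s <- prop
      idx[t] <- s
    }
  }
  S <- state_matrix(n)
  data.frame(step = seq_len(n_samples),
             state = apply(S[idx + 1L, , drop = FALSE], 1, state_label),
             index = idx)
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
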