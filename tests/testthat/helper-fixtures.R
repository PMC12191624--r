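# shared fixtures and independent oracles for the test suite

# random parameterization in the documented realistic box
random_params <- function(network) {
  has_inh <- any(network$links$polarity == "inhibitory")
  lw <- ifelse(network$links$polarity == "generative",
               runif(1, 0.2, 1.0), runif(1, -1.0, -0.2))
  parameterization(network,
                   root_prior = runif(1, 0.4, 0.8),
                   link_weight = lw,
                   exo_weight = runif(1, 0, 1))
}

# brute-force joint oracle: per-state product of cpd_prob() calls, one
# variable at a time (no shared code with the vectorized enumeration)
oracle_joint <- function(network, params) {
  vars <- network$variables
  n <- length(vars)
  sapply(0:(2^n - 1), function(i) {
    bits <- state_bits(i, n)
    names(bits) <- vars
    p <- 1
    for (v in vars) {
      pa <- network$parents[[v]]
      pv <- cpd_prob(network, params, v,
                     if (length(pa)) bits[pa] else NULL)
      p <- p * if (bits[[v]] == 1) pv else 1 - pv
    }
    p
  })
}

# brute-force conditional oracle by state enumeration
oracle_conditional <- function(network, params, target, evidence) {
  vars <- network$variables
  n <- length(vars)
  joint <- oracle_joint(network, params)
  num <- den <- 0
  for (i in 0:(2^n - 1)) {
    bits <- state_bits(i, n)
    names(bits) <- vars
    if (length(evidence) && any(bits[names(evidence)] != evidence)) next
    den <- den + joint[i + 1]
    if (bits[[target]] == 1) num <- num + joint[i + 1]
  }
  num / den
}

# brute-force prototype oracle: enumerate states, check link constraints
oracle_prototypes <- function(network) {
  vars <- network$variables
  n <- length(vars)
  out <- character(0)
  for (i in 0:(2^n - 1)) {
    bits <- state_bits(i, n)
    names(bits) <- vars
    ok <- TRUE
    for (k in seq_len(nrow(network$links))) {
      a <- bits[[network$links$from[k]]]
      b <- bits[[network$links$to[k]]]
      same <- network$links$polarity[k] == "generative"
      if ((same && a != b) || (!same && a == b)) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, state_label(bits))
  }
  out
}

# total variation distance between two distributions
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# small uniform-joint helper (all weights zero, root priors one half)
flat_params <- function(network) {
  parameterization(network, root_prior = 0.5,
                   link_weight = rep(0, nrow(network$links)),
                   exo_weight = 0)
}
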