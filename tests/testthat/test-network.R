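test_that("network construction enforces structural invariants", {
  expect_error(causal_network(c("A", "A"),
                              data.frame(from = "A", to = "A",
                                         polarity = "generative")),
               "duplicate variable")
  expect_error(causal_network(c("A", "B"),
                              data.frame(from = "A", to = "C",
                                         polarity = "generative")),
               "declared variables")
  expect_error(causal_network(c("A", "B"),
                              data.frame(from = c("A", "B"), to = c("B", "A"),
                                         polarity = "generative")),
               "cycle")
  expect_error(causal_network(c("A", "B"),
                              data.frame(from = c("A", "A"), to = c("B", "B"),
                                         polarity = "generative")),
               "duplicate links")
  net <- diamond_network("generative")
  expect_equal(net$roots, "X")
  expect_equal(sort(net$parents$Z), c("YA", "YB"))
})

test_that("state indexing puts the first declared variable in the MSB", {
  expect_equal(state_index(c(1, 1, 1, 1)), 15)
  expect_equal(state_index(c(1, 0, 0, 0)), 8)
  expect_equal(state_bits(8, 4), c(1L, 0L, 0L, 0L))
  expect_equal(state_label(state_bits(13, 4)), "1101")
  for (i in 0:15) expect_equal(state_index(state_bits(i, 4)), i)
})

test_that("logistic CPD matches hand-computed values", {
  net <- common_cause_network()
  p0 <- flat_params(net)
  expect_equal(cpd_prob(net, p0, "EA", c(C = 1)), 0.5)
  expect_equal(cpd_prob(net, p0, "EA", c(C = 0)), 0.5)
  # typical fitted generative weights: plogis(0.476 + 0.454), plogis(-0.022)
  pp <- parameterization(net, 0.6, c(generative = 0.476), 0.454)
  expect_equal(cpd_prob(net, pp, "EA", c(C = 1)), 0.7171, tolerance = 1e-4)
  expect_equal(cpd_prob(net, pp, "EA", c(C = 0)), 0.4945, tolerance = 1e-4)
  expect_equal(cpd_prob(net, pp, "C"), 0.6)
  expect_error(cpd_prob(net, pp, "EA", c(C = 1, EB = 0)), "exactly")
  expect_error(cpd_prob(net, pp, "EA"), "exactly")
})

test_that("joint distribution is the product factorization and normalizes", {
  dm <- diamond_network("generative")
  # all-zero weights give the uniform joint
  expect_equal(as.numeric(joint_distribution(dm, flat_params(dm))),
               rep(1 / 16, 16))
  set.seed(11)
  for (net in list(dm, diamond_network("ya_inhibitory"),
                   common_cause_network(), chain_network())) {
    for (rep in 1:25) {
      pp <- random_params(net)
      j <- joint_distribution(net, pp)
      expect_equal(sum(j), 1, tolerance = 1e-12)
      expect_true(all(j > 0))
      expect_equal(as.numeric(j), oracle_joint(net, pp), tolerance = 1e-12)
    }
  }
})

test_that("conditional queries sum and renormalize correctly", {
  dm <- diamond_network("generative")
  j <- structure(numeric(16), variables = dm$variables,
                 class = "joint_distribution")
  j[state_index(c(1, 1, 1, 1)) + 1] <- 0.5
  j[state_index(c(0, 0, 0, 0)) + 1] <- 0.5
  expect_equal(conditional_query(j, query("YA", c(X = 1))), 1.0)
  # zero-mass evidence falls back to the supplied default
  expect_equal(conditional_query(j, query("YA", c(X = 1, YB = 0)),
                                 zero_mass_fallback = 0.5), 0.5)
  u <- joint_distribution(dm, flat_params(dm))
  expect_equal(conditional_query(u, query("Z", c(X = 0, YA = 1))), 0.5)
  expect_error(conditional_query(u, query("Q", c(X = 1))), "unknown")
  # random-parameter queries match brute-force enumeration
  set.seed(21)
  for (rep in 1:10) {
    pp <- random_params(dm)
    jj <- joint_distribution(dm, pp)
    ev <- c(X = sample(0:1, 1), YB = sample(0:1, 1))
    expect_equal(conditional_query(jj, query("YA", ev)),
                 oracle_conditional(dm, pp, "YA", ev), tolerance = 1e-12)
  }
})

test_that("the exact model screens off: flat Markov triplets everywhere", {
  set.seed(31)
  dm <- diamond_network("generative")
  b <- markov_battery(dm, "X", c("YA", "YB"))
  for (rep in 1:30) {
    pp <- random_params(dm)
    np <- normative_predictions(dm, pp, b)
    cells <- attr(b, "markov_cells")
    expect_lt(max(abs(np[cells$id_present] - np[cells$id_absent])), 1e-10)
  }
  # three-variable fixtures obey screening off as well
  cc <- common_cause_network()
  for (rep in 1:10) {
    pp <- random_params(cc)
    j <- joint_distribution(cc, pp)
    for (cval in 0:1) {
      base <- conditional_query(j, query("EA", c(C = cval)))
      for (ebval in 0:1)
        expect_equal(conditional_query(j, query("EA", c(C = cval, EB = ebval))),
                     base, tolerance = 1e-10)
    }
  }
  ch <- chain_network()
  for (rep in 1:10) {
    pp <- random_params(ch)
    j <- joint_distribution(ch, pp)
    for (yval in 0:1) {
      base <- conditional_query(j, query("Z", c(Y = yval)))
      for (xval in 0:1)
        expect_equal(conditional_query(j, query("Z", c(Y = yval, X = xval))),
                     base, tolerance = 1e-10)
    }
  }
})

test_that("query answers are invariant to declaration order and labels", {
  set.seed(41)
  dm <- diamond_network("generative")
  pp <- random_params(dm)
  # same diamond declared in a different order with different labels
  perm <- causal_network(
    c("sink", "armB", "armA", "root"),
    data.frame(from = c("root", "root", "armA", "armB"),
               to = c("armA", "armB", "sink", "sink"),
               polarity = "generative"))
  lw <- pp$link_weight[c(1, 2, 3, 4)]  # X->YA, X->YB, YA->Z, YB->Z
  pp2 <- parameterization(perm, root_prior = c(root = pp$root_prior[["X"]]),
                          link_weight = lw,
                          exo_weight = pp$exo_weight[["Z"]])
  j1 <- joint_distribution(dm, pp)
  j2 <- joint_distribution(perm, pp2)
  qs <- list(list(q1 = query("YA", c(X = 1, YB = 0)),
                  q2 = query("armA", c(root = 1, armB = 0))),
             list(q1 = query("Z", c(X = 0)),
                  q2 = query("sink", c(root = 0))),
             list(q1 = query("X", NULL), q2 = query("root", NULL)))
  for (pair in qs)
    expect_equal(conditional_query(j1, pair$q1),
                 conditional_query(j2, pair$q2), tolerance = 1e-12)
})

test_that("parameterization validates signs, coverage and ranges", {
  dm <- diamond_network("ya_inhibitory")
  expect_error(parameterization(dm, 1.0, c(generative = 0.5,
                                           inhibitory = -0.5), 0.4),
               "inside")
  expect_error(parameterization(dm, 0.6, c(generative = -0.5,
                                           inhibitory = -0.5), 0.4),
               ">= 0")
  expect_error(parameterization(dm, 0.6, c(generative = 0.5,
                                           inhibitory = 0.5), 0.4),
               "<= 0")
  expect_error(parameterization(dm, 0.6, c(generative = 0.5), 0.4),
               "inhibitory")
  # untied exogenous weights for the three-variable fixtures
  cc <- common_cause_network()
  pp <- parameterization(cc, 0.6, c(generative = 0.8),
                         c(EA = 0.2, EB = 0.7))
  expect_equal(unname(pp$exo_weight), c(0.2, 0.7))
})
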