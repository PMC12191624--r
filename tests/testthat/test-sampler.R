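test_that("MH transition matrix has the single-flip structure", {
  dm <- diamond_network("generative")
  u <- joint_distribution(dm, flat_params(dm))
  Tm <- transition_matrix(u)
  expect_equal(colSums(Tm), rep(1, 16), tolerance = 1e-12)
  # uniform target accepts every proposal: 1/4 to each neighbor, no self
  for (s in 1:16) {
    nb <- bitwXor(s - 1L, 2^(0:3)) + 1L
    expect_equal(unname(Tm[nb, s]), rep(0.25, 4))
    expect_equal(unname(Tm[s, s]), 0)
  }
  # nonzero off-diagonals only at Hamming distance 1
  set.seed(7)
  pp <- random_params(dm)
  Tm2 <- transition_matrix(joint_distribution(dm, pp))
  for (s in 1:16) for (r in 1:16) {
    hd <- sum(state_bits(s - 1, 4) != state_bits(r - 1, 4))
    if (hd > 1) expect_identical(Tm2[r, s], 0)
  }
  # asymmetric target: uphill moves accepted, downhill thinned by the ratio
  j <- structure(rep(1 / 20, 16), variables = dm$variables,
                 class = "joint_distribution")
  j[16] <- 2 / 20; j[1] <- 1 / 20  # pi(1111) = 2 * pi(0111)
  s_lo <- state_index(c(0, 1, 1, 1)) + 1
  s_hi <- 16
  expect_equal(Tm2_entry <- transition_matrix(j)[s_hi, s_lo], 1 / 4)
  expect_equal(transition_matrix(j)[s_lo, s_hi], 0.5 / 4)
  expect_error(transition_matrix(structure(c(0, rep(1 / 15, 15)),
                                           variables = dm$variables)),
               "strictly positive")
})

test_that("detailed balance and stationarity hold for random targets", {
  set.seed(13)
  dm <- diamond_network("generative")
  nets <- list(dm, diamond_network("ya_inhibitory"), chain_network())
  for (rep in 1:100) {
    net <- nets[[(rep %% 3) + 1]]
    pp <- random_params(net)
    pi <- joint_distribution(net, pp)
    Tm <- transition_matrix(pi)
    db <- outer(as.numeric(pi), rep(1, length(pi))) * t(Tm)
    expect_lt(max(abs(db - t(db))), 1e-12)
    expect_lt(max(abs(Tm %*% as.numeric(pi) - as.numeric(pi))), 1e-12)
  }
})

test_that("occupancy distribution averages the first L chain steps", {
  dm <- diamond_network("generative")
  u <- joint_distribution(dm, flat_params(dm))
  Tm <- transition_matrix(u)
  start <- numeric(16); start[1] <- 1  # point mass on 0000
  expect_equal(as.numeric(occupancy_distribution(Tm, start, 1)), start)
  # one uniform-proposal step from 0000: half the mass stays (t = 0 term),
  # an eighth reaches each single-present neighbor
  occ2 <- occupancy_distribution(Tm, start, 2)
  expected <- numeric(16)
  expected[1] <- 0.5
  expected[state_index(c(1, 0, 0, 0)) + 1] <- 0.125
  expected[state_index(c(0, 1, 0, 0)) + 1] <- 0.125
  expected[state_index(c(0, 0, 1, 0)) + 1] <- 0.125
  expected[state_index(c(0, 0, 0, 1)) + 1] <- 0.125
  expect_equal(as.numeric(occ2), expected)
  # non-integer lambda interpolates between adjacent integers
  o3 <- as.numeric(occupancy_distribution(Tm, start, 3))
  o35 <- as.numeric(occupancy_distribution(Tm, start, 3.5))
  o4 <- as.numeric(occupancy_distribution(Tm, start, 4))
  expect_equal(o35, 0.5 * o3 + 0.5 * o4, tolerance = 1e-12)
  expect_error(occupancy_distribution(Tm, start, 0.5), "lambda")
})

test_that("occupancy is a valid distribution and converges to the target", {
  set.seed(17)
  dm <- diamond_network("generative")
  for (rep in 1:10) {
    pp <- random_params(dm)
    pi <- joint_distribution(dm, pp)
    Tm <- transition_matrix(pi)
    start <- numeric(16); start[c(1, 16)] <- 0.5
    for (lam in c(1, 2.7, 4, 12.5, 40)) {
      occ <- occupancy_distribution(Tm, start, lam)
      expect_true(all(occ >= 0))
      expect_equal(sum(occ), 1, tolerance = 1e-12)
    }
    # longer chains are closer to stationarity
    tv4 <- tv_dist(occupancy_distribution(Tm, start, 4), as.numeric(pi))
    tv1000 <- tv_dist(occupancy_distribution(Tm, start, 1000), as.numeric(pi))
    expect_lt(tv1000, tv4)
  }
  # ergodic limit: occupancy at lambda = 1e4 is within TV 0.01 of the joint
  set.seed(19)
  pp <- random_params(dm)
  pi <- joint_distribution(dm, pp)
  Tm <- transition_matrix(pi)
  start <- numeric(16); start[c(1, 16)] <- 0.5
  expect_lt(tv_dist(occupancy_distribution(Tm, start, 1e4), as.numeric(pi)),
            0.01)
})

test_that("sampler predictions expose the start-state bias", {
  dm <- diamond_network("generative")
  b <- default_battery_32(dm)
  pp <- parameterization(dm, 0.65, c(generative = 0.48), 0.45)
  # lambda = 1 in prototype mode is a pure half/half prototype response
  small <- query_battery(list(query("YA"), query("Z", c(X = 1))))
  p1 <- sampler_predictions(dm, pp, sampler_settings(1, "prototypes"), small)
  expect_equal(unname(p1[["YA"]]), 0.5)
  expect_equal(unname(p1[["Z|X=1"]]), 1.0)  # within 1111 mass, Z is present
  # long uniform-start chains recover the normative answers
  plong <- sampler_predictions(dm, pp, sampler_settings(1e4, "uniform"), b)
  expect_lt(max(abs(plong - normative_predictions(dm, pp, b))), 1e-2)
  # moderate chains with prototypes produce a positive Markov violation
  p17 <- sampler_predictions(dm, pp, sampler_settings(17, "prototypes"), b)
  expect_gt(markov_violation_score(p17, b, values_are_probabilities = TRUE),
            0)
  # prototype mode on a network without prototypes directs to uniform
  expect_error(
    sampler_predictions(diamond_network("ya_inhibitory"),
                        parameterization(diamond_network("ya_inhibitory"),
                                         0.65,
                                         c(generative = 0.48,
                                           inhibitory = -0.4), 0.45),
                        sampler_settings(17, "prototypes"), b),
    "uniform")
})

test_that("prototype-mode violations are positive cell by cell except at one
           extreme corner of the parameter box", {
  gen <- diamond_network("generative")
  b <- markov_battery(gen, "X", c("YA", "YB"))
  cells <- attr(b, "markov_cells")
  box <- expand.grid(wX = c(0.4, 0.6, 0.8), wgen = c(0.2, 0.6, 1.0),
                     wexo = c(0, 0.5, 1), lambda = c(2, 5, 10, 17, 30, 50))
  failing <- NULL
  for (i in seq_len(nrow(box))) {
    pp <- parameterization(gen, box$wX[i], c(generative = box$wgen[i]),
                           box$wexo[i])
    pred <- sampler_predictions(gen, pp,
                                sampler_settings(box$lambda[i], "prototypes"),
                                b)
    if (any(pred[cells$id_present] <= pred[cells$id_absent]))
      failing <- rbind(failing, box[i, ])
  }
  # at the shortest chain with a strong base rate and a weak link the two
  # rarely-visited X=0 cells dip slightly negative; everywhere else all
  # four cells violate in the positive direction
  expect_equal(nrow(failing), 1)
  expect_equal(unlist(failing),
               c(wX = 0.8, wgen = 0.2, wexo = 0.5, lambda = 2))
})

test_that("stochastic chains are reproducible and converge in frequency", {
  dm <- diamond_network("generative")
  st <- sampler_settings(10, "uniform")
  pp <- flat_params(dm)
  c1 <- simulate_chain(dm, pp, st, 500, seed = 42)
  c2 <- simulate_chain(dm, pp, st, 500, seed = 42)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 500)
  # consecutive states differ by at most one bit (mutation moves only)
  hd <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               c1$state[-500], c1$state[-1])
  expect_true(all(hd <= 1))
  # uniform target: long-run state frequencies near 1/16; the allowance is
  # 3 standard errors inflated for the chain's autocorrelation (the
  # single-flip walk on the 4-cube has a relaxation time of a few steps)
  long <- simulate_chain(dm, pp, st, 1e5, seed = 7)
  freq <- tabulate(long$index + 1, 16) / 1e5
  se <- sqrt((1 / 16) * (15 / 16) / 1e5)
  expect_true(all(abs(freq - 1 / 16) < 3 * 3 * se))
  # empirical conditionals from a long chain match the exact conditional
  set.seed(23)
  pp2 <- random_params(dm)
  long2 <- simulate_chain(dm, pp2, sampler_settings(10, "uniform"), 2e5,
                          seed = 11)
  S <- t(sapply(long2$index, state_bits, n = 4))
  emp <- mean(S[S[, 1] == 1, 2])
  exact <- conditional_query(joint_distribution(dm, pp2),
                             query("YA", c(X = 1)))
  expect_equal(emp, exact, tolerance = 0.02)
})
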