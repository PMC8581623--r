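test_that("composition labels follow the A^a-B^b-C^c convention", {
  m9 <- matrix(1:9, 1)
  d <- label_states(m9)
  expect_identical(d$labels, "1^9")
  m72 <- matrix(c(1, 1, 2:8), 1)
  expect_identical(label_states(m72)$labels, "1^7-2^1")
  # {1,2,3},{4,5},{6},{7},{8},{9} -> four monomers, one dimer, one trimer
  m431 <- matrix(c(1, 1, 1, 2, 2, 3, 4, 5, 6), 1)
  expect_identical(label_states(m431)$labels, "1^4-2^1-3^1")
  expect_error(label_states(m9, n_copies = 12), "composition")
})

test_that("transition counting slides over each replicate separately", {
  const <- rep(1L, 20)
  C <- count_transitions(list(const), lag = 3, n_states = 2)
  expect_equal(C[1, 1], 17)
  expect_equal(sum(C) - C[1, 1], 0)
  alt <- rep(c(1L, 2L), length.out = 11)
  C2 <- count_transitions(alt, lag = 1)
  expect_equal(C2[1, 2], 5)
  expect_equal(C2[2, 1], 5)
  expect_equal(C2[1, 1] + C2[2, 2], 0)
  # replicates sum but never bridge: two copies double the counts
  C3 <- count_transitions(list(alt, alt), lag = 1)
  expect_equal(unclass(C3), unclass(C2) * 2, ignore_attr = TRUE)
  expect_error(count_transitions(alt, lag = 11), "shorter")
  expect_error(count_transitions(alt, lag = 0), "positive")
})

test_that("MLE transition matrix and stationary distribution match closed forms", {
  C <- rbind(c(9L, 1L), c(2L, 8L))
  attr(C, "lag") <- 1L; attr(C, "frame_dt") <- 1
  m <- estimate_msm(C)
  expect_equal(unname(m$P), rbind(c(0.9, 0.1), c(0.2, 0.8)), tolerance = 1e-12)
  expect_equal(unname(m$pi), c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(rowSums(m$P), c(1, 1), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.vector(m$pi %*% m$P), unname(m$pi), tolerance = 1e-8)
  expect_equal(Re(m$mu[1L]), 1, tolerance = 1e-12)
  expect_true(all(abs(m$mu) <= 1 + 1e-12))
  # single state
  C1 <- matrix(5L, 1, 1); attr(C1, "lag") <- 1L; attr(C1, "frame_dt") <- 1
  m1 <- estimate_msm(C1)
  expect_equal(unname(m1$P), matrix(1, 1, 1))
  expect_equal(unname(m1$pi), 1)
})

test_that("estimation recovers a known chain and satisfies Chapman-Kolmogorov", {
  P <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  s <- generate_markov_chain(P, 1e5, seed = 21)
  m <- estimate_msm(s, lag = 1)
  expect_lt(max(abs(m$P - P)), 0.02)
  # CK: a direct estimate at lag 2 approximates P(1)^2
  m2 <- estimate_msm(s, lag = 2)
  expect_lt(max(abs(m2$P - m$P %*% m$P)), 0.03)
})

test_that("implied timescales follow k = -tau/ln(mu) and are flat for a Markov chain", {
  # plug-in arithmetic check
  C <- rbind(c(85L, 15L), c(15L, 85L))  # mu2 = 0.7 exactly
  attr(C, "lag") <- 5L; attr(C, "frame_dt") <- 1
  m <- estimate_msm(C)
  expect_equal(m$implied_timescales, -5 / log(0.7), tolerance = 1e-10)
  # near-unit eigenvalue: timescale reported as exceeding any window
  C2 <- rbind(c(1000000L, 1L), c(1L, 1000000L))
  attr(C2, "lag") <- 1L; attr(C2, "frame_dt") <- 1
  expect_gt(estimate_msm(C2)$implied_timescales, 1e5)
  # flatness across lags for an exactly Markovian chain, against the
  # between-chain standard error
  P <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  lags <- c(1L, 2L, 5L, 10L)
  ts <- sapply(1:8, function(r) {
    s <- generate_markov_chain(P, 2e4, seed = 300 + r)
    implied_timescales(s, lags, n_timescales = 1L)$ts1
  })
  mn <- rowMeans(ts); se <- apply(ts, 1, stats::sd) / sqrt(ncol(ts))
  for (i in 2:length(lags)) {
    expect_lt(abs(mn[i] - mn[1L]), 2 * sqrt(se[i]^2 + se[1L]^2))
  }
})

test_that("mean first passage times solve the linear system (2-state closed form)", {
  C <- rbind(c(9L, 1L), c(2L, 8L))
  attr(C, "lag") <- 1L; attr(C, "frame_dt") <- 1
  m <- estimate_msm(C)
  expect_equal(unname(m$mfpt), rbind(c(0, 10), c(5, 0)), tolerance = 1e-10)
  expect_equal(diag(m$mfpt), c(0, 0), ignore_attr = TRUE)
  # bare-matrix interface with an explicit lag time
  mf <- mean_first_passage_times(rbind(c(0.9, 0.1), c(0.2, 0.8)), tau = 2)
  expect_equal(unname(mf), rbind(c(0, 20), c(10, 0)), tolerance = 1e-10)
  # near-absorbing chain: large positive mfpt
  mf2 <- mean_first_passage_times(rbind(c(0.999, 0.001), c(0.001, 0.999)),
                                  tau = 1)
  expect_true(all(mf2[row(mf2) != col(mf2)] >= 999))
})

test_that("state lifetimes are tau/(1 - P_ii) and increase with self-transition", {
  P <- rbind(c(0.8, 0.2), c(0.5, 0.5))
  lt <- state_lifetimes(P, tau = 5)
  expect_equal(unname(lt), c(25, 10), tolerance = 1e-12)
  expect_equal(unname(state_lifetimes(rbind(c(0, 1), c(1, 0)), tau = 5)),
               c(5, 5))
  pii <- seq(0.1, 0.9, by = 0.2)
  lts <- 5 / (1 - pii)
  expect_true(all(diff(lts) > 0))
  expect_equal(unname(state_lifetimes(rbind(c(1, 0), c(0.5, 0.5)), tau = 5))[1],
               Inf)
})

test_that("MSM simulation is ergodic and closes the estimation round trip", {
  C <- rbind(c(9L, 1L), c(2L, 8L))
  attr(C, "lag") <- 1L; attr(C, "frame_dt") <- 1
  m <- estimate_msm(C)
  s <- simulate(m, nsim = 1e6, seed = 5)
  expect_lt(abs(mean(s == 1L) - m$pi[1L]), 0.01)
  m2 <- estimate_msm(s, lag = 1)
  expect_lt(max(abs(m2$P - m$P)), 0.01)
  # identity matrix: constant trajectory
  Ci <- diag(10L); attr(Ci, "lag") <- 1L; attr(Ci, "frame_dt") <- 1
  # identity counts are reducible; the largest (first) strongly connected
  # component is a single absorbing state
  mi <- estimate_msm(Ci)
  expect_true(all(simulate(mi, nsim = 100, seed = 2) == 1L))
})

test_that("reversible MLE satisfies detailed balance", {
  P <- rbind(c(0.7, 0.2, 0.1), c(0.3, 0.5, 0.2), c(0.2, 0.3, 0.5))
  s <- generate_markov_chain(P, 5e4, seed = 51)
  m <- estimate_msm(s, lag = 1, reversible = TRUE)
  flux <- m$pi * m$P
  expect_equal(unname(flux), unname(t(flux)), tolerance = 1e-6)
  # and it still reproduces the chain reasonably
  expect_lt(max(abs(m$P - P)), 0.05)
})

test_that("states outside the largest connected set are excluded, not dropped silently", {
  # state 3 is a source: reachable set {1,2} is the largest SCC
  s <- c(3L, 3L, 1L, 2L, 1L, 2L, 1L, 1L, 2L, 2L, 1L, 2L)
  m <- estimate_msm(s, lag = 1)
  expect_identical(nrow(m$P), 2L)
  expect_identical(m$excluded, 3L)
})

test_that("full pipeline: simulated system to MSM over composition states", {
  sim <- demo_sim(n_frames = 4000, seed = 47)
  dtraj <- label_states(sim$ground_truth$membership, frame_dt = 1)
  expect_true("1^9" %in% dtraj$labels)
  m <- estimate_msm(dtraj, lag = 50)
  expect_equal(unname(rowSums(m$P)), rep(1, nrow(m$P)), tolerance = 1e-10)
  expect_equal(as.vector(m$pi %*% m$P), unname(m$pi), tolerance = 1e-8)
  net <- rate_network(m, threshold = 50)
  expect_true(all(net$rate_per_s >= 50))
  expect_true(all(c("from", "to", "rate_per_s") %in% names(net)))
})
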