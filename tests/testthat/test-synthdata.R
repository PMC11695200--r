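test_that("sample_state_sequence handles degenerate chains exactly", {
  # absorbing identity chain: constant sequence
  s <- sample_state_sequence(diag(3), 50, seed = 1)
  expect_equal(length(unique(s)), 1L)
  # period-2 chain: strict alternation
  p2 <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  s2 <- sample_state_sequence(p2, 6, seed = 2)
  expect_true(all(diff(s2) != 0))
  expect_equal(s2[seq(1, 5, 2)], rep(s2[1], 3))
})

test_that("uniform chain visits states at their stationary frequency", {
  p <- matrix(0.5, 2, 2)
  s <- sample_state_sequence(p, 1e5, seed = 3)
  expect_lt(abs(mean(s == 1) - 0.5), 0.01)
})

test_that("empirical transition frequencies converge to the chain", {
  p <- matrix(c(0.8, 0.15, 0.05,
                0.1, 0.7, 0.2,
                0.25, 0.25, 0.5), 3, byrow = TRUE)
  s <- sample_state_sequence(p, 1e5, seed = 4)
  emp <- prop.table(table(factor(s[-length(s)], 1:3),
                          factor(s[-1], 1:3)), margin = 1)
  expect_lt(max(abs(emp - p)), 0.02)
})

test_that("state sequence sampling validates its inputs and is reproducible", {
  expect_error(sample_state_sequence(matrix(1, 2, 3), 10), "square")
  bad <- matrix(c(0.5, 0.4, 0.4, 0.4), 2)  # rows don't sum to 1
  expect_error(sample_state_sequence(bad, 10), "sum to 1")
  expect_identical(sample_state_sequence(diag(2), 20, seed = 9),
                   sample_state_sequence(diag(2), 20, seed = 9))
})

test_that("stationary_distribution solves pi P = pi", {
  p <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  pi_hat <- stationary_distribution(p)
  expect_equal(sum(pi_hat), 1)
  expect_equal(as.numeric(pi_hat %*% p), pi_hat, tolerance = 1e-12)
})

test_that("make_cohort is bit-reproducible and covariance-consistent", {
  cfg <- sim_config(n_per_group = c(a = 2, b = 1), n_timepoints = 5000,
                    channels = default_channels()[1:4, ], n_nodes = 0,
                    n_states = 1, transition_matrix = matrix(1, 1, 1),
                    state_covariances = list(clip_sigma <- {
                      r <- diag(4); r[1, 2] <- r[2, 1] <- 0.5; r
                    }),
                    group_effect_spec = list(), seed = 11)
  ch1 <- make_cohort(cfg)
  ch2 <- make_cohort(cfg)
  expect_identical(ch1$panel$series, ch2$panel$series)
  expect_identical(ch1$truth$state_sequences, ch2$truth$state_sequences)
  # sample covariance converges to the configured one
  emp <- cov(ch1$panel$series[[1]])
  expect_lt(max(abs(emp - clip_sigma)), 0.1)
})

test_that("independent channels show near-zero off-diagonal correlation", {
  t_len <- 2000
  cfg <- sim_config(n_per_group = c(a = 1, b = 1), n_timepoints = t_len,
                    channels = default_channels()[1:5, ], n_nodes = 0,
                    n_states = 1, transition_matrix = matrix(1, 1, 1),
                    state_covariances = list(diag(5)),
                    group_effect_spec = list(), seed = 12)
  ch <- make_cohort(cfg)
  r <- cor(ch$panel$series[[1]])
  off <- abs(r[lower.tri(r)])
  expect_lt(mean(off), 3 / sqrt(t_len))
})

test_that("per-state sample covariances track the state covariance library", {
  cfg <- sim_config(n_per_group = c(a = 1, b = 1), n_timepoints = 4000,
                    channels = default_channels()[1:6, ], n_nodes = 0,
                    n_states = 2,
                    transition_matrix = default_transition_matrix(2, 0.95),
                    state_covariances = state_covariance_library(
                      default_channels()[1:6, ], 2),
                    group_effect_spec = list(), seed = 13)
  ch <- make_cohort(cfg)
  x <- ch$panel$series[[1]]
  sq <- ch$truth$state_sequences[[1]]
  for (k in 1:2) {
    rows <- which(sq == k)
    emp <- crossprod(x[rows, ]) / length(rows)  # known zero mean
    expect_lt(max(abs(emp - cfg$state_covariances[[k]])), 0.15)
  }
})

test_that("group z-shifts move the target pair and invalid shifts error", {
  eff <- list(list(pair = c(1L, 2L), shift = 0.4, group = "a"))
  cfg <- sim_config(n_per_group = c(a = 1, b = 1), n_timepoints = 6000,
                    channels = default_channels()[1:3, ], n_nodes = 0,
                    n_states = 1, transition_matrix = matrix(1, 1, 1),
                    state_covariances = list(diag(3)),
                    group_effect_spec = eff, seed = 14)
  ch <- make_cohort(cfg)
  man <- ch$panel$manifest
  z_a <- atanh(cor(ch$panel$series[[which(man$group == "a")]])[1, 2])
  z_b <- atanh(cor(ch$panel$series[[which(man$group == "b")]])[1, 2])
  expect_lt(abs(z_a - 0.4), 0.06)
  expect_lt(abs(z_b), 0.06)

  bad <- list(list(pair = c(1L, 2L), shift = 50, group = "a"))
  cfg_bad <- sim_config(n_per_group = c(a = 1, b = 1), n_timepoints = 50,
                        channels = default_channels()[1:3, ], n_nodes = 0,
                        n_states = 1, transition_matrix = matrix(1, 1, 1),
                        state_covariances = list(diag(3)),
                        group_effect_spec = bad, seed = 15)
  expect_error(make_cohort(cfg_bad), "CEN.1.*CEN.2|positive definite")
})

test_that("sim_config validates transition matrices and covariances", {
  expect_error(sim_config(transition_matrix = matrix(1, 2, 2) / 1.5,
                          n_states = 2,
                          state_covariances = state_covariance_library(
                            default_channels(), 2)),
               "sum to 1")
  bad_cov <- state_covariance_library(default_channels(), 6)
  bad_cov[[1]] <- matrix(0, 13, 13)
  expect_error(sim_config(state_covariances = bad_cov), "positive definite")
})

test_that("state covariance library is positive definite and well separated", {
  lib <- state_covariance_library(default_channels(), 6)
  for (s in lib) {
    expect_true(max(abs(s - t(s))) < 1e-10)
    expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  cents <- t(vapply(lib, function(s) {
    r <- cov2cor(s)
    atanh(pmin(pmax(r[lower.tri(r)], -0.999), 0.999))
  }, numeric(sum(lower.tri(lib[[1]])))))
  d <- as.matrix(dist(cents))
  diag(d) <- Inf
  # per-coordinate windowed-z noise at width 20 / sigma 3 is ~0.27; the
  # benchmark requires centroids >= 5x that apart
  expect_gt(min(d), 5 * 0.27)
})

test_that("planted layered networks honor switch structure and degenerate cases", {
  # no switchers: identical partitions across layers
  ml0 <- make_layered_network(10, 5, seed = 1)
  expect_true(all(ml0$truth$planted_partitions ==
                    ml0$truth$planted_partitions[, 1]))
  # p_in = 1 (p_out ~ 0): two disconnected cliques per layer
  ml1 <- make_layered_network(8, 3, p_in = 1, p_out = 1e-9, seed = 2)
  for (l in 1:3) {
    a <- ml1$net$layers[[l]]
    part <- ml1$truth$planted_partitions[, l]
    same <- outer(part, part, `==`); diag(same) <- FALSE
    expect_true(all(a[same] == 1))
    expect_true(all(a[!same & !diag(8)] == 0))
  }
  # switchers change at exactly the configured layer
  ml2 <- make_layered_network(10, 6, switcher_nodes = 1:2, switch_layers = 4,
                              seed = 3)
  p <- ml2$truth$planted_partitions
  expect_true(all(p[, 3] == p[, 1]))
  expect_true(all(p[1:2, 4] != p[1:2, 3]))
  expect_true(all(p[3:10, 4] == p[3:10, 3]))
  expect_error(make_layered_network(10, 5, p_in = 0.1, p_out = 0.5),
               "p_in")
})
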