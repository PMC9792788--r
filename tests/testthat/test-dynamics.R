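test_that("every corner is a rest point for random games", {
  corners <- corner_states()
  for (q in random_games(10)) {
    for (i in seq_len(nrow(corners))) {
      cc <- unlist(corners[i, c("x", "y", "z", "p")])
      expect_equal(unname(replicator_rhs(cc, q)), rep(0, 4))
    }
  }
})

test_that("RHS matches v(1-v) delta and both routes agree", {
  p <- baseline_params()
  s <- c(0.5, 0.5, 0.5, 0.5)
  r <- replicator_rhs(s, p)
  expect_equal(r[["y"]], 0.25 * -0.2) # platform rate at the centre
  expect_equal(unname(r), unname(s * (1 - s) * payoff_deltas(p, s)))
  expect_equal(unname(replicator_rhs(s, p, method = "tensor")), unname(r),
               tolerance = 1e-10)
  expect_error(replicator_rhs(c(0.5, 0.5, 0.5, 1.5), p), "\\[0, 1\\]")
})

test_that("trajectories stay in the unit hypercube and corners are fixed", {
  set.seed(81)
  games <- random_games(8)
  for (q in games) {
    s0 <- runif(4, 0.05, 0.95)
    traj <- simulate_replicator(q, s0, horizon = 60)
    m <- as.matrix(traj[, c("x", "y", "z", "p")])
    expect_true(all(m >= 0 & m <= 1))
    expect_lt(attr(traj, "max_excursion"), 1e-6)
  }
  # starting exactly at a corner the trajectory is constant
  p <- baseline_params()
  traj <- simulate_replicator(p, c(0, 1, 1, 1), horizon = 20)
  expect_equal(unlist(traj[nrow(traj), c("x", "y", "z", "p")]),
               c(x = 0, y = 1, z = 1, p = 1))
})

test_that("the calibrated game splits between its two stable corners by basin", {
  p <- baseline_params()
  lo <- classify_endpoint(simulate_replicator(p, c(0.3, 0.3, 0.3, 0.3)))
  hi <- classify_endpoint(simulate_replicator(p, c(0.7, 0.7, 0.7, 0.7)))
  expect_true(lo$converged)
  expect_identical(lo$corner, "E1")
  expect_lt(lo$distance, 1e-3)
  expect_true(hi$converged)
  expect_identical(hi$corner, "E12")
  expect_lt(hi$distance, 1e-3)
})

test_that("endpoint classification flags unconverged trajectories", {
  p <- baseline_params()
  traj <- simulate_replicator(p, c(0.3, 0.3, 0.3, 0.3), horizon = 2)
  ep <- classify_endpoint(traj)
  expect_false(ep$converged)
  expect_true(is.na(ep$corner))
})

test_that("endpoints of (x, y, p) are invariant to the initial z", {
  p <- modify_params(baseline_params(), R32 = 2, R13 = 2) # dual-ESS variant
  for (z0 in c(0.1, 0.5, 0.9)) {
    ep <- classify_endpoint(simulate_replicator(p, c(0.3, 0.3, z0, 0.3)))
    expect_true(ep$converged)
    expect_identical(ep$corner, "E10")
  }
})

test_that("settling time is deterministic and monotone in the tolerance", {
  p <- baseline_params()
  s0 <- c(0.3, 0.3, 0.3, 0.3)
  t1 <- convergence_time(p, s0, "y")
  t2 <- convergence_time(p, s0, "y")
  expect_identical(as.numeric(t1), as.numeric(t2))
  t_loose <- convergence_time(p, s0, "y", epsilon = 1e-2)
  expect_lte(as.numeric(t_loose), as.numeric(t1))
  # a component that cannot settle by the horizon is reported, not faked
  expect_warning(res <- convergence_time(p, s0, "y", horizon = 1),
                 "not converged")
  expect_true(is.na(res))
})
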