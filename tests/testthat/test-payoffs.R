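test_that("payoff matrix cells match the model's formulas", {
  p <- baseline_params()
  tens <- build_payoff_tensor(p)
  # profile (self-built, part-time, leasing, physical)
  expect_equal(tens["self-built", "part-time", "leasing", "physical", "institution"],
               p$R11 - p$C11 + p$T2)
  expect_equal(tens["self-built", "part-time", "leasing", "physical", "platform"],
               -p$C21)
  expect_equal(tens["self-built", "part-time", "leasing", "physical", "provider"],
               p$R31 - p$C31)
  # patient cell R41 + R44 - C41 - C45 = 0.5 with the inert defaults
  expect_equal(tens["self-built", "part-time", "leasing", "physical", "patient"], 0.5)
  # platform under (part-time, leasing, internet) earns R21 - C21 + T1
  expect_equal(tens["self-built", "part-time", "leasing", "internet", "platform"],
               p$R21 - p$C21 + p$T1)
  # institution relying-on under full-time mode: alpha share of (R13 - F1)
  expect_equal(tens["relying-on", "full-time", "no-leasing", "internet", "institution"],
               p$alpha * (p$R13 - p$F1) - p$C12 + p$T3)
})

test_that("provider payoffs depend only on (z, p), not on (x, y)", {
  for (q in random_games(5)) {
    tens <- build_payoff_tensor(q)
    for (zi in 1:2) for (pi in 1:2) {
      cells <- tens[, , zi, pi, "provider"]
      expect_equal(max(cells) - min(cells), 0)
    }
  }
})

test_that("mean payoff identity and corner degeneracy hold", {
  p <- baseline_params()
  # at a pure state the expected payoffs are single matrix cells
  gp <- group_payoffs(p, c(1, 1, 1, 1))
  tens <- build_payoff_tensor(p)
  expect_equal(gp$x[["U1"]], tens[1, 1, 1, 1, "institution"])
  expect_equal(gp$x[["U2"]], tens[2, 1, 1, 1, "institution"])
  # Ubar = v U1 + (1 - v) U2 for random states
  for (s in random_states(20)) {
    gp <- group_payoffs(p, s)
    for (g in seq_along(gp)) {
      u <- gp[[g]]
      expect_equal(u[["Ubar"]],
                   s[g] * u[["U1"]] + (1 - s[g]) * u[["U2"]], tolerance = 1e-12)
    }
  }
})

test_that("closed-form payoff differences agree with the tensor expectation", {
  games <- random_games(25)
  states <- random_states(40)
  for (q in games) {
    tens <- build_payoff_tensor(q)
    for (s in states) {
      gp <- group_payoffs(q, s, tensor = tens)
      u_diff <- vapply(gp, function(u) u[["U1"]] - u[["U2"]], numeric(1))
      expect_equal(unname(payoff_deltas(q, s)), unname(u_diff),
                   tolerance = 1e-10)
    }
  }
})

test_that("the eight cancelled parameters never affect the payoff differences", {
  p <- baseline_params()
  s <- c(0.37, 0.81, 0.12, 0.64)
  ref <- payoff_deltas(p, s)
  set.seed(99)
  for (nm in c("R11", "R44", "R45", "C41", "C42", "T1", "T2", "T3")) {
    q <- do.call(modify_params,
                 stats::setNames(list(p, runif(1, -3, 3)), c("", nm)))
    expect_equal(payoff_deltas(q, s), ref, tolerance = 1e-14, label = nm)
  }
})

test_that("deltas decouple as the dynamics dictate", {
  # x, y, p differences never depend on z; the z difference only on p
  for (q in random_games(10)) {
    s <- c(0.4, 0.6, 0.2, 0.5)
    for (znew in c(0, 0.33, 0.9)) {
      s2 <- s; s2[3] <- znew
      expect_equal(payoff_deltas(q, s2)[c("x", "y", "p")],
                   payoff_deltas(q, s)[c("x", "y", "p")])
    }
    s3 <- s; s3[1] <- 0.9; s3[2] <- 0.1
    expect_equal(payoff_deltas(q, s3)[["z"]], payoff_deltas(q, s)[["z"]])
  }
})

test_that("delta special cases reproduce the expression values", {
  p <- baseline_params()
  # platform difference at p = 1 is the cost gap C22 - C21
  expect_equal(payoff_deltas(p, c(0.5, 0.5, 0.5, 1))[["y"]], 0.2)
  # platform difference at p = 0.5: 0.5 (R21 - R22) + (C22 - C21) = -0.2
  expect_equal(payoff_deltas(p, c(0.5, 0.5, 0.5, 0.5))[["y"]], -0.2)
  ev <- expr_values_vec <- setNames(expression_values(p)$value,
                                    expression_values(p)$id)
  # provider difference at p = 0 is expression e2; at p = 1, e3
  expect_equal(payoff_deltas(p, c(0.5, 0.5, 0.5, 0))[["z"]], ev[["e2"]])
  expect_equal(payoff_deltas(p, c(0.5, 0.5, 0.5, 1))[["z"]], ev[["e3"]])
  # institution difference at (y = 1, p = 0) is e5; at (y = 0, p = 0), e4
  expect_equal(payoff_deltas(p, c(0.5, 1, 0.5, 0))[["x"]], ev[["e5"]])
  expect_equal(payoff_deltas(p, c(0.5, 0, 0.5, 0))[["x"]], ev[["e4"]])
  # patient difference at y = 0 is e6; at y = 1, e7
  expect_equal(payoff_deltas(p, c(0.5, 0, 0.5, 0.5))[["p"]], ev[["e6"]])
  expect_equal(payoff_deltas(p, c(0.5, 1, 0.5, 0.5))[["p"]], ev[["e7"]])
})

test_that("expression values at the calibration match their closed forms", {
  ev <- expression_values(baseline_params())
  vals <- setNames(ev$value, ev$id)
  expect_equal(vals[["e1"]], -0.6)
  expect_equal(vals[["e2"]], -0.1)
  expect_equal(vals[["e3"]], 0.2)
  expect_equal(vals[["e4"]], -0.59)
  expect_equal(vals[["e5"]], -0.5)
  expect_equal(vals[["e6"]], -0.1)
  expect_equal(vals[["e7"]], 0.1)
  expect_equal(ev$sign, c("-", "-", "+", "-", "-", "-", "+"))
})

test_that("expressions exactly at zero are classified boundary", {
  # C31 = 0.9 makes e3 = (R31 - C31) - (R33 - C32) = 0 exactly
  ev <- expression_values(bp(C31 = 0.9))
  expect_equal(ev$sign[ev$id == "e3"], "boundary")
})
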