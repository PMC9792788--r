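test_that("corner eigenvalues at the calibration match the published rows", {
  p <- baseline_params()
  # E1: the four eigenvalues are expressions 1, 2, 4, 6
  e1 <- corner_eigenvalues(p, "E1")
  expect_equal(unname(as.numeric(e1)), c(-0.6, -0.1, -0.59, -0.1))
  expect_identical(attr(e1, "groups"), c("y", "z", "x", "p"))
  # E12: cost gaps and the negated e3 / e7
  e12 <- corner_eigenvalues(p, "E12")
  expect_equal(unname(as.numeric(e12)), c(-0.1, -0.2, -0.2, -0.1))
  # E5 first eigenvalue is -e4
  e5 <- corner_eigenvalues(p, "E5")
  expect_equal(e5[["x"]], 0.59)
  expect_error(corner_eigenvalues(p, "E99"), "unknown corner")
})

test_that("finite-difference Jacobian is diagonal at corners and matches closed forms", {
  p <- baseline_params()
  J <- numeric_jacobian(p, c(0, 0, 0, 0))
  offdiag <- J; diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 1e-8)
  eig <- corner_eigenvalues(p, "E1")
  expect_equal(unname(diag(J)[attr(eig, "groups")]), unname(as.numeric(eig)),
               tolerance = 1e-8)
  # at interior states the Jacobian has genuine off-diagonal structure
  Jint <- numeric_jacobian(p, c(0.4, 0.5, 0.5, 0.5))
  expect_gt(abs(Jint["x", "p"]), 1e-4)
})

test_that("closed-form eigenvalues agree with the numeric oracle over random games", {
  corners <- corner_states()
  for (q in random_games(40, seed = 7)) {
    for (i in seq_len(nrow(corners))) {
      cc <- unlist(corners[i, c("x", "y", "z", "p")])
      eig <- corner_eigenvalues(q, corners$id[i])
      J <- numeric_jacobian(q, cc)
      expect_equal(unname(diag(J)[attr(eig, "groups")]),
                   unname(as.numeric(eig)), tolerance = 1e-8)
    }
  }
})

test_that("ESS classification reproduces the published scenario verdicts", {
  expect_setequal(ess_set(baseline_params()), c("E1", "E12"))
  expect_setequal(ess_set(bp(R32 = 2)), c("E3", "E12"))
  expect_setequal(ess_set(bp(R22 = 1.8, R42 = 1.5)), "E4")
  rep <- classify_equilibria(baseline_params())
  # assumption-forced unstable corners
  for (id in c("E2", "E6", "E8", "E13", "E14", "E16")) {
    expect_identical(rep[rep$id == id, "verdict"], "unstable", label = id)
  }
  # sign patterns of the assumption-forced eigenvalues
  expect_match(rep[rep$id == "E2", "signs"], "^-,\\+")
  expect_match(rep[rep$id == "E8", "signs"], "^\\+,\\+")
  expect_match(rep[rep$id == "E16", "signs"], "^\\+,-")
})

test_that("never-stable corners stay unstable across random valid games", {
  for (q in random_games(30, seed = 13)) {
    rep <- classify_equilibria(q)
    bad <- rep$id[rep$verdict != "unstable" &
                    rep$id %in% c("E2", "E6", "E8", "E13", "E14", "E16")]
    expect_length(bad, 0)
  }
})

test_that("zero eigenvalues are inconclusive, never silently stable", {
  rep <- classify_equilibria(bp(C31 = 0.9, R32 = 2)) # e3 = 0 exactly
  expect_identical(rep[rep$id == "E12", "verdict"], "inconclusive")
  expect_false("E12" %in% attr(rep, "ess"))
})

test_that("satisfied conditions mirror the ESS set through the corner mapping", {
  expect_equal(as.integer(check_conditions(baseline_params())), c(1L, 9L))
  expect_equal(as.integer(check_conditions(bp(R32 = 2, R13 = 2))), c(7L, 9L))
  expect_equal(as.integer(check_conditions(bp(R22 = 1.8, R42 = 1.5,
                                              R13 = 2, R32 = 2))), 10L)
  cornermap <- compatibility_matrix()$corners
  for (q in random_games(40, seed = 29)) {
    conds <- as.integer(check_conditions(q))
    from_ess <- sort(unname(cornermap[intersect(names(cornermap), ess_set(q))]))
    expect_equal(sort(conds), from_ess)
  }
})

test_that("condition compatibility reproduces the mutual-exclusion structure", {
  expect_true(permitted_conditions(c(1, 9)))
  expect_true(permitted_conditions(c(1, 5)))
  expect_false(permitted_conditions(c(1, 2)))
  expect_false(permitted_conditions(c(5, 9)))
  # conditions 3, 6, 8, 10 admit no partner
  for (solo in c(3, 6, 8, 10)) {
    expect_true(permitted_conditions(solo))
    partners <- setdiff(1:10, solo)
    expect_false(any(vapply(partners, function(o)
      permitted_conditions(c(solo, o)), logical(1))), label = paste(solo))
  }
  # dual-capable conditions pair only with 5 or 9
  for (dual in c(1, 2, 4, 7)) {
    ok <- vapply(setdiff(1:10, dual), function(o)
      permitted_conditions(c(dual, o)), logical(1))
    expect_setequal(setdiff(1:10, dual)[ok], c(5, 9))
  }
})

test_that("the compatibility table exposes the published sign columns", {
  cm <- compatibility_matrix()
  expect_equal(dim(cm$signs), c(7, 10))
  expect_equal(unname(cm$signs[, "1"]),
               c("-", "-", NA, "-", NA, "-", NA))
  expect_equal(unname(cm$signs[, "9"]),
               c(NA, NA, "+", NA, NA, NA, "+"))
  expect_equal(cm$corners[["E15"]], 10L)
})
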