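test_that("string IP has one x per span, one y per split, one z per distinct substring", {
  ip <- buildStringIP("abcabcab", m = 7)
  expect_identical(sum(ip@vars$kind == "x"), 36L)
  aa <- buildStringIP("aa", m = 2)
  expect_identical(sum(aa@vars$kind == "y"), 1L)
  expect_identical(sum(aa@vars$kind == "z"), 2L)
  expect_error(buildStringIP("aa", m = 0), "positive")
})

test_that("budgeted feasibility matches the known minima and detects infeasibility", {
  tr <- exampleSixVertexTree()
  i7 <- buildOrderedIP(tr, m = 7); expect_true(ipFeasible(solveIP(i7), i7))
  i6 <- buildOrderedIP(tr, m = 6); expect_false(ipFeasible(solveIP(i6), i6))
  # below the forced terminal classes the program itself is infeasible,
  # reported distinctly from a timeout
  i2 <- buildOrderedIP(tr, m = 2)
  expect_identical(solveIP(i2)@status, "infeasible")
  # a budget of all candidate classes is always feasible
  iAll <- buildOrderedIP(tr, m = i2@meta$nClasses)
  expect_true(ipFeasible(solveIP(iAll), iAll))
  # string boundary from the brute-force oracle
  s <- "abcabcab"
  mStar <- oracleMinCFG(s)
  sa <- buildStringIP(s, m = mStar); expect_true(ipFeasible(solveIP(sa), sa))
  sb <- buildStringIP(s, m = mStar - 1L); expect_false(ipFeasible(solveIP(sb), sb))
})

test_that("feasibility is monotone in the budget", {
  tr <- exampleSixVertexTree()
  feas <- vapply(3:9, function(m) {
    inst <- buildOrderedIP(tr, m = m)
    ipFeasible(solveIP(inst), inst)
  }, logical(1))
  expect_true(all(diff(feas) >= 0))
  expect_identical(feas, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("minimize-mode and probe-mode budget search agree", {
  tr <- exampleSixVertexTree()
  cases <- list(list("abcabcab", "cfg"), list(tr, "seotg"), list(tr, "seutg"),
                list(typeAPath(7), "seotg"))
  for (cs in cases) {
    a <- findMinimumM(cs[[1]], cs[[2]], method = "minimize")
    b <- findMinimumM(cs[[1]], cs[[2]], method = "probe")
    expect_identical(a$m, b$m)
    expect_true(ipFeasible(b$result, b$instance))
  }
})

test_that("the minimum is bounded below by the forced terminal classes", {
  set.seed(21)
  for (r in 1:4) {
    tr <- randomLabeledTree(sample(3:7, 1), c("a", "b"))
    fit <- findMinimumM(tr, "seotg")
    expect_gte(fit$m, length(fit$instance@meta$forcedClasses))
  }
  fit <- findMinimumM("abcabcab", "cfg")
  expect_gte(fit$m, 3L)
})

test_that("equality budget mode solves the worked example identically", {
  tr <- exampleSixVertexTree()
  i7 <- buildOrderedIP(tr, m = 7, budgetMode = "eq")
  expect_true(ipFeasible(solveIP(i7), i7))
  expect_identical(findMinimumM(tr, "seotg", method = "probe", budgetMode = "eq")$m, 7L)
})

test_that("tagged-terminal forcing is a no-op for the minimum", {
  tr <- exampleSixVertexTree()
  expect_identical(findMinimumM(tr, "seotg", forceTaggedTerminals = FALSE)$m, 7L)
  expect_identical(findMinimumM(tr, "seutg", forceTaggedTerminals = FALSE)$m, 6L)
})
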