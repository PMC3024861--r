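test_that("bisection of a single edge is one terminal rule", {
  g <- treeBisection(typeAPath(2))
  expect_identical(nrow(g@rules), 1L)
  expect_identical(g@rules$kind, "R1u")
})

test_that("bisection always regenerates the input and never beats the exact minimum", {
  p11 <- typeAPath(11)
  gb <- treeBisection(p11)
  expect_true(verifyRoundtrip(gb, p11))
  expect_gte(nonterminalCount(gb), findMinimumM(p11, "seotg")$m)  # >= 7
  set.seed(33)
  for (r in 1:5) {
    tr <- randomLabeledTree(sample(4:10, 1), c("a", "b"))
    g <- treeBisection(tr)
    expect_true(verifyRoundtrip(g, tr))
    expect_gte(nonterminalCount(g), findMinimumM(tr, "seotg")$m)
  }
})

test_that("bisection balances edge counts at every division", {
  tr <- typeBTree(4)
  g <- treeBisection(tr)
  edgesOfClass <- function(key) sum(startsWith(strsplit(key, "\x1e", fixed = TRUE)[[1L]], "o"))
  walk <- function(nd) {
    if (length(nd$children)) {
      e1 <- edgesOfClass(nd$children[[1]]$class)
      e2 <- edgesOfClass(nd$children[[2]]$class)
      expect_lte(abs(e1 - e2), edgesOfClass(nd$class) - 1L)
      expect_identical(e1 + e2, edgesOfClass(nd$class))
      lapply(nd$children, walk)
    }
  }
  walk(g@derivation)
  expect_true(verifyRoundtrip(g, tr))
})
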