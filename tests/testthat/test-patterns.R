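test_that("the example's repeated {a,b}-child subtree is reported twice", {
  tr <- exampleSixVertexTree()
  g <- compressTree(tr, "unordered")
  rep3 <- extractRepeats(g, minVertices = 3)
  expect_identical(nrow(rep3), 1L)
  expect_identical(rep3$occurrences, 2L)
  expect_identical(rep3$vertices, 3L)
  expect_identical(rep3$labels, "a:1,b:1")
})

test_that("grammars without reuse yield an empty pattern list", {
  g <- compressTree(typeAPath(2), "ordered")
  expect_identical(nrow(extractRepeats(g)), 0L)
  expect_error(extractRepeats(compressString("ab")), "tree grammars")
})

test_that("three planted copies of a subtree are found with count 3", {
  tr <- threeCopyTree()
  # direct matching oracle: the three children of the root carry equal
  # canonical subtrees of 5 vertices
  keys <- vapply(childrenOf(tr, 1), function(v)
    esKey(canonicalEulerString(tr, unorderedSubtree(1, v))), character(1))
  expect_identical(length(unique(keys)), 1L)
  g <- compressTree(tr, "unordered")
  found <- extractRepeats(g, minVertices = 5)
  expect_true(unique(keys) %in% found$key)
  row <- found[found$key == unique(keys), ]
  expect_identical(row$occurrences, 3L)
  expect_identical(row$vertices, 5L)
  expect_identical(row$edges + 1L, row$vertices)
})

test_that("unordered patterns are invariant under sibling shuffling", {
  set.seed(17)
  tr <- exampleSixVertexTree()
  g1 <- compressTree(tr, "unordered")
  g2 <- compressTree(shuffleChildren(tr), "unordered")
  p1 <- extractRepeats(g1); p2 <- extractRepeats(g2)
  expect_identical(p1[, c("key", "occurrences", "vertices")],
                   p2[, c("key", "occurrences", "vertices")])
})

test_that("pattern edges never exceed the input's edge count", {
  tr <- threeCopyTree()
  g <- compressTree(tr, "unordered")
  pats <- extractRepeats(g)
  expect_true(all(pats$occurrences * pats$edges <= nEdges(tr)))
})
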