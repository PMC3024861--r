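test_that("LabeledTree enforces preorder numbering and a single root", {
  expect_s4_class(labeledTree(c(NA, 1, 1), c(NA, "a", "b")), "LabeledTree")
  expect_error(labeledTree(c(NA, 3, 1), c(NA, "a", "b")), "preorder")
  expect_error(labeledTree(c(2, NA, 1), c("a", NA, "b")), "root")
  tr <- exampleSixVertexTree()
  expect_identical(nVertices(tr), 6L)
  expect_identical(nEdges(tr), 5L)
  expect_identical(childrenOf(tr, 1), c(2L, 3L, 6L))
  expect_identical(ancestorsOf(tr, 5), c(3L, 1L))
  expect_false(5 %in% ancestorsOf(tr, 5))
  expect_true(isLeaf(tr, 4) && !isLeaf(tr, 3))
})

test_that("Euler strings serialize edges depth-first with matched closings", {
  single <- labeledTree(c(NA, 1), c(NA, "a"))
  expect_identical(format(eulerString(single)), "a a'")
  tr <- exampleSixVertexTree()
  expect_identical(format(eulerString(tr)), "a a' c a a' b b' c' b b'")
  tagged <- eulerString(tr, orderedSubtree(1, 3, 3, tag = 3))
  expect_identical(tagged@role, c("open", "tag", "close"))
  expect_identical(format(tagged), "c x c'")
  # deeper tag: truncation below it, descent elsewhere untouched
  deep <- eulerString(tr, orderedSubtree(1, 2, 6, tag = 4))
  expect_identical(format(deep), "a a' c a x a' b b' c' b b'")
})

test_that("invalid subtree indices are rejected with diagnostics", {
  tr <- exampleSixVertexTree()
  expect_error(eulerString(tr, orderedSubtree(1, 4, 5)), "not a child")
  expect_error(eulerString(tr, orderedSubtree(3, 4, 5, tag = 6)), "outside the span")
  expect_error(canonicalEulerString(tr, unorderedSubtree(1, c(4, 5))), "non-children")
  expect_error(canonicalEulerString(tr, unorderedSubtree(3, c(4, 5), tag = 2)), "no child in C")
  expect_error(unorderedSubtree(1, integer(0)), "nonempty")
})

test_that("unordered canonicalization sorts children and moves the tag first", {
  tr <- exampleSixVertexTree()
  # root children presented (a, c-subtree, b) serialize as (a, b, c-subtree)
  expect_identical(format(canonicalEulerString(tr)), "a a' b b' c a a' b b' c'")
  tagged <- canonicalEulerString(tr, unorderedSubtree(1, c(2, 3, 6), tag = 3))
  expect_true(startsWith(format(tagged), "c x c'"))
  # idempotence: canonicalizing the canonical tree changes nothing
  reparsed <- parseEulerString(canonicalEulerString(tr))
  expect_identical(esKey(canonicalEulerString(reparsed$tree)),
                   esKey(canonicalEulerString(tr)))
})

test_that("parsing an Euler string back and re-serializing is the identity", {
  fixtures <- list(exampleSixVertexTree(), typeAPath(5), typeBTree(4))
  set.seed(3)
  for (r in 1:5) fixtures <- c(fixtures, list(randomLabeledTree(sample(3:9, 1), c("a", "b", "c"))))
  for (tr in fixtures) {
    es <- eulerString(tr)
    back <- parseEulerString(es)
    expect_identical(esKey(eulerString(back$tree)), esKey(es))
    expect_true(is.na(back$tag))
  }
  # tagged round trip
  tr <- exampleSixVertexTree()
  es <- eulerString(tr, orderedSubtree(1, 2, 6, tag = 3))
  back <- parseEulerString(es)
  ch <- childrenOf(back$tree, 1)
  re <- eulerString(back$tree, orderedSubtree(1, ch[1], ch[length(ch)], tag = back$tag))
  expect_identical(esKey(re), esKey(es))
})

test_that("canonical equality agrees with brute-force unordered isomorphism", {
  set.seed(11)
  trees <- replicate(10, randomLabeledTree(sample(3:7, 1), c("a", "b")), simplify = FALSE)
  # add a guaranteed isomorphic pair with different sibling orders
  tr <- exampleSixVertexTree()
  trees <- c(trees, list(tr, shuffleChildren(tr)))
  keysets <- lapply(trees, allOrderingKeys)
  canon <- vapply(trees, function(t) esKey(canonicalEulerString(t)), character(1))
  for (i in seq_along(trees)) for (j in seq_along(trees)) {
    if (j <= i) next
    iso <- length(intersect(keysets[[i]], keysets[[j]])) > 0
    expect_identical(canon[i] == canon[j], iso)
  }
})
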