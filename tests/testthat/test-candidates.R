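test_that("substring enumeration lists every span once", {
  sp <- enumerateSubstrings("abcabcab")
  expect_identical(nrow(sp), 36L)
  expect_identical(nrow(enumerateSubstrings("a")), 1L)
  expect_identical(sort(unique(enumerateSubstrings("aa")$sub)), c("a", "aa"))
  expect_error(enumerateSubstrings(""), "non-empty")
})

test_that("ordered enumeration of the 6-vertex example reproduces the published counts", {
  eo <- enumerateOrdered(exampleSixVertexTree())
  expect_identical(sum(eo$divisions$kind == "H"), 9L)
  expect_identical(sum(eo$divisions$kind == "V"), 4L)
  expect_identical(nrow(eo$divisions), 13L)
  expect_identical(nrow(eo$subtrees), 13L)   # candidate subtree indices
})

test_that("unordered enumeration of the example splits child subsets", {
  eu <- enumerateUnordered(exampleSixVertexTree())
  expect_identical(sum(eu$divisions$kind == "H"), 12L)
  expect_identical(sum(eu$divisions$kind == "V"), 4L)
  expect_identical(nrow(eu$subtrees), 14L)   # candidate subtree indices
})

test_that("single edges admit no division; a 2-edge path admits one vertical", {
  single <- typeAPath(2)
  expect_identical(nrow(enumerateOrdered(single)$divisions), 0L)
  expect_identical(nrow(enumerateUnordered(single)$divisions), 0L)
  p3 <- typeAPath(3)
  for (enum in list(enumerateOrdered(p3), enumerateUnordered(p3))) {
    expect_identical(sum(enum$divisions$kind == "H"), 0L)
    expect_identical(sum(enum$divisions$kind == "V"), 1L)
  }
})

test_that("enumeration is closed under division and base cases are exactly single edges", {
  set.seed(5)
  trees <- c(list(exampleSixVertexTree(), typeBTree(3)),
             replicate(4, randomLabeledTree(sample(4:9, 1), c("a", "b")), simplify = FALSE))
  for (tr in trees) for (enum in list(enumerateOrdered(tr), enumerateUnordered(tr))) {
    st <- enum$subtrees; dv <- enum$divisions
    expect_true(all(dv$part1 %in% st$key) && all(dv$part2 %in% st$key))
    hasDiv <- st$key %in% dv$parent
    expect_identical(hasDiv, st$nEdges >= 2L)      # >=2 edges iff divisible
    # tags: never at a leaf, at most one tag marker per Euler string
    expect_true(all(vapply(strsplit(st$es, "\x1e", fixed = TRUE),
                           function(tk) sum(tk == "x") <= 1L, logical(1))))
    expect_true(all(is.na(st$t) | !vapply(st$t, function(v) isLeaf(tr, v), logical(1))))
  }
})

test_that("ordered and unordered enumerations coincide on chains", {
  chain <- typeAPath(6)
  eo <- enumerateOrdered(chain); eu <- enumerateUnordered(chain)
  expect_identical(nrow(eo$subtrees), nrow(eu$subtrees))
  expect_identical(table(eo$divisions$kind), table(eu$divisions$kind))
})

test_that("a star of identical edges yields one untagged root class per subset size", {
  star <- labeledTree(c(NA, 1, 1, 1), c(NA, "a", "a", "a"))
  eu <- enumerateUnordered(star)
  rootUntagged <- eu$subtrees[eu$subtrees$i == 1L & is.na(eu$subtrees$t), ]
  expect_identical(length(unique(rootUntagged$es)), 3L)  # sizes 1, 2, 3
})

test_that("the degree guard refuses high-degree unordered enumeration by name", {
  wide <- labeledTree(c(NA, rep(1L, 6)), c(NA, rep("a", 6)))
  expect_error(enumerateUnordered(wide, maxDegree = 5L), "vertex 1 has 6 children")
  expect_silent(enumerateUnordered(wide, maxDegree = 6L))
  expect_no_error(enumerateUnordered(randomLabeledTree(20, "a", maxDegree = 2),
                                     maxDegree = 16L))
})
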