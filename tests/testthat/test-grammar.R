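test_that("the ordered example yields 7 nonterminals from 4 binary rules and regenerates", {
  tr <- exampleSixVertexTree()
  fit <- findMinimumM(tr, "seotg")
  g <- extractGrammar(fit$instance, fit$result)
  expect_identical(nonterminalCount(g), 7L)
  expect_identical(fit$m, nonterminalCount(g))
  expect_identical(sum(g@rules$kind %in% c("R2", "R3")), 4L)
  expect_setequal(g@rules$label[!is.na(g@rules$label)], c("a", "b", "c"))
  expect_true(verifyRoundtrip(g, tr))
  # alternative size metric: letters on right-hand sides
  expect_identical(grammarSize(g), 4L * 2L + 3L)
})

test_that("the unordered example merges the two isomorphic child subtrees", {
  tr <- exampleSixVertexTree()
  fit <- findMinimumM(tr, "seutg")
  g <- extractGrammar(fit$instance, fit$result)
  expect_identical(nonterminalCount(g), 6L)
  expect_true(verifyRoundtrip(g, tr))
  pairKey <- esKey(canonicalEulerString(tr, unorderedSubtree(3, c(4, 5))))
  expect_identical(esKey(canonicalEulerString(tr, unorderedSubtree(1, c(2, 6)))), pairKey)
  # that shared nonterminal is expanded at two different places
  hits <- 0L
  walk <- function(nd) {
    if (nd$class == pairKey) hits <<- hits + 1L
    lapply(nd$children, walk)
  }
  walk(g@derivation)
  expect_identical(hits, 2L)
})

test_that("degenerate inputs give single terminal rules", {
  single <- typeAPath(2)
  g <- compressTree(single, "ordered")
  expect_identical(nrow(g@rules), 1L)
  expect_identical(g@rules$kind, "R1u")
  expect_identical(nonterminalCount(g), 1L)
  gs <- compressString("a")
  expect_identical(nonterminalCount(gs), 1L)
  expect_true(verifyRoundtrip(gs, "a"))
})

test_that("string grammars regenerate exactly and match the brute-force count", {
  g <- compressString("ab")
  expect_identical(nonterminalCount(g), 3L)
  expect_identical(oracleMinCFG("ab"), 3L)
  expect_true(verifyRoundtrip(g, "ab"))
  expect_false(verifyRoundtrip(g, "ba"))
})

test_that("deleting a binary rule breaks expansion", {
  tr <- exampleSixVertexTree()
  g <- compressTree(tr, "ordered")
  mutated <- g
  drop <- which(mutated@rules$kind %in% c("R2", "R3"))[1L]
  mutated@rules <- mutated@rules[-drop, , drop = FALSE]
  expect_error(verifyRoundtrip(mutated, tr), "unbound nonterminal")
})

test_that("derivation leaves conserve the input's labeled edges", {
  set.seed(9)
  trees <- c(list(exampleSixVertexTree(), typeBTree(3)),
             replicate(3, randomLabeledTree(sample(4:8, 1), c("a", "b")), simplify = FALSE))
  for (tr in trees) for (mode in c("ordered", "unordered")) {
    g <- compressTree(tr, mode)
    expect_identical(derivationLeafLabels(g), sort(tr@label[-1L]))
    expect_true(verifyRoundtrip(g, tr))
  }
})

test_that("merged nonterminals always carry identical canonical Euler strings", {
  # content-addressed keys make accidental merges impossible; check that all
  # derivation nodes sharing a class are isomorphic subtrees of the input
  tr <- threeCopyTree()
  g <- compressTree(tr, "unordered")
  seenIdx <- new.env(parent = emptyenv())
  walk <- function(nd) {
    assign(nd$class, c(if (exists(nd$class, seenIdx, inherits = FALSE))
      get(nd$class, seenIdx), nd$index), envir = seenIdx)
    lapply(nd$children, walk)
  }
  walk(g@derivation)
  enum <- enumerateUnordered(tr)
  esOf <- stats::setNames(enum$subtrees$es, enum$subtrees$key)
  for (cls in ls(seenIdx))
    expect_true(all(esOf[get(cls, seenIdx)] == cls))
})

test_that("grammar JSON serialization round-trips losslessly", {
  tr <- exampleSixVertexTree()
  for (g in list(compressTree(tr, "ordered"), compressTree(tr, "unordered"),
                 compressString("abcabcab"))) {
    path <- withr::local_tempfile(fileext = ".json")
    writeGrammar(g, path)
    g2 <- readGrammar(path)
    expect_identical(g2@rules, g@rules)
    expect_identical(g2@start, g@start)
    expect_identical(g2@terminals, g@terminals)
    expect_identical(g2@derivation, g@derivation)
    # stable output: serializing the reread grammar gives identical text
    path2 <- withr::local_tempfile(fileext = ".json")
    writeGrammar(g2, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})
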