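#' Built-in study inputs
#'
#' Small generators reproducing the inputs used in the worked examples and
#' timing experiments:
#'
#' * `exampleSixVertexTree()` — the 6-vertex tree with edges
#'   (1,2)=a, (1,3)=c, (1,6)=b, (3,4)=a, (3,5)=b: edges labeled a and b
#'   connected to both endpoints of a c edge. Its minimum ordered grammar has
#'   7 nonterminals, its minimum unordered grammar 6.
#' * `typeAPath(n)` — a path of `n` vertices, every edge labeled `a`
#'   (maximum degree two), the "Type A" family.
#' * `typeBTree(degree, leavesPerChild)` — a height-two "Type B" tree: a root
#'   with `degree` children, each bearing `leavesPerChild` leaf children,
#'   edge labels alternating between `a` and `b`. With the default
#'   `leavesPerChild = 2` the vertex counts match the published family for
#'   degrees 6..20 (1 + d + 2d vertices); the exact published topology was
#'   only shown as a drawing, so this generator is a reconstruction and no
#'   acceptance-grade quantity depends on it.
#' * `exampleRepeatString()` — the string `"abcabcab"`, whose minimum simple
#'   CFG uses 7 nonterminals.
#'
#' @param n number of vertices (>= 2)
#' @param degree number of children of the root (>= 1)
#' @param leavesPerChild leaf children per internal child
#' @return a [LabeledTree-class] (or a character scalar)
#' @export
exampleSixVertexTree <- function() {
  labeledTree(c(NA, 1L, 1L, 3L, 3L, 1L), c(NA, "a", "c", "a", "b", "b"))
}

#' @rdname exampleSixVertexTree
#' @export
typeAPath <- function(n) {
  if (n < 2L) stop("a path needs at least 2 vertices")
  labeledTree(c(NA, seq_len(n - 1L)), c(NA, rep("a", n - 1L)))
}

#' @rdname exampleSixVertexTree
#' @export
typeBTree <- function(degree, leavesPerChild = 2L) {
  stopifnot(degree >= 1L, leavesPerChild >= 0L)
  parent <- NA_integer_; label <- NA_character_
  lab <- function(idx) if (idx %% 2L == 1L) "a" else "b"
  for (d in seq_len(degree)) {
    parent <- c(parent, 1L); label <- c(label, lab(d))
    v <- length(parent)
    for (l in seq_len(leavesPerChild)) {
      parent <- c(parent, v); label <- c(label, lab(d + l))
    }
  }
  labeledTree(parent, label)
}

#' @rdname exampleSixVertexTree
#' @export
exampleRepeatString <- function() "abcabcab"

#' @rdname exampleSixVertexTree
#' @param name fixture name: `"example6"`, `"type_a"`, `"type_b"` or
#'   `"abcabcab"`
#' @export
makeFixture <- function(name = c("example6", "type_a", "type_b", "abcabcab"),
                        n = 11L, degree = 3L, leavesPerChild = 2L) {
  switch(match.arg(name),
         example6 = exampleSixVertexTree(),
         type_a = typeAPath(n),
         type_b = typeBTree(degree, leavesPerChild),
         abcabcab = exampleRepeatString())
}
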