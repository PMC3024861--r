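#' Construct a LabeledTree from parent pointers
#'
#' Low-level constructor. Vertices must already be numbered 1..n in preorder
#' (root = 1, every parent smaller than its child); use [treeFromEdges()] to
#' build a tree from an arbitrary edge list with renumbering.
#'
#' @param parent integer vector, `parent[v]` = parent of vertex `v`
#'   (`NA` for the root at position 1).
#' @param label character vector of edge labels (`label[v]` labels the edge
#'   above `v`; `NA` for the root).
#' @param origId optional character vector of original identifiers.
#' @return a [LabeledTree-class]
#' @examples
#' # the 6-vertex example: root 1 with children 2(a), 3(c), 6(b); 3 has 4(a), 5(b)
#' tr <- labeledTree(c(NA, 1, 1, 3, 3, 1), c(NA, "a", "c", "a", "b", "b"))
#' nEdges(tr)
#' @export
labeledTree <- function(parent, label, origId = NULL) {
  parent <- as.integer(parent)
  n <- length(parent)
  children <- rep(list(integer(0)), n)
  for (v in seq_len(n)) {
    p <- parent[v]
    if (!is.na(p)) children[[p]] <- c(children[[p]], v)
  }
  if (is.null(origId)) origId <- as.character(seq_len(n))
  new("LabeledTree", parent = parent, label = as.character(label),
      children = children, origId = as.character(origId))
}

#' Build a LabeledTree from an edge table
#'
#' Accepts edges between arbitrary vertex identifiers, determines the root
#' (the unique vertex that never appears as a child), orders siblings by the
#' `rank` column (or by input order when absent), renumbers vertices to
#' preorder and keeps the original identifiers in `origId`.
#'
#' @param edges data.frame with columns `parent`, `child`, `label` and
#'   optionally `rank` (sibling order, unique per parent).
#' @return a [LabeledTree-class]
#' @export
treeFromEdges <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("parent", "child", "label") %in% names(edges)))
  if (nrow(edges) < 1L) stop("edge table is empty")
  par <- as.character(edges$parent); chd <- as.character(edges$child)
  lab <- as.character(edges$label)
  rank <- if ("rank" %in% names(edges)) as.numeric(edges$rank) else seq_len(nrow(edges))
  if (anyDuplicated(chd)) stop("vertex ", chd[duplicated(chd)][1L], " has more than one parent")
  ids <- unique(c(par, chd))
  roots <- setdiff(ids, chd)
  if (length(roots) != 1L)
    stop("input must have exactly one root (found: ", paste(roots, collapse = ", "), ")")
  kids <- split(seq_len(nrow(edges)), par)
  for (p in names(kids)) {
    o <- kids[[p]]
    if (anyDuplicated(rank[o])) stop("duplicate sibling ranks under vertex ", p)
    kids[[p]] <- o[order(rank[o])]
  }
  # preorder walk; a cycle would leave edges unvisited
  orderOrig <- character(0); parentOf <- character(0); labelOf <- character(0)
  walk <- function(v, pl) {
    orderOrig <<- c(orderOrig, v)
    parentOf <<- c(parentOf, pl[1L]); labelOf <<- c(labelOf, pl[2L])
    for (e in kids[[v]]) walk(chd[e], c(v, lab[e]))
  }
  walk(roots, c(NA_character_, NA_character_))
  if (length(orderOrig) != length(ids))
    stop("edge table contains a cycle or disconnected component")
  num <- stats::setNames(seq_along(orderOrig), orderOrig)
  labeledTree(parent = unname(num[parentOf]), label = labelOf, origId = orderOrig)
}

#' @rdname LabeledTree-class
#' @export
setMethod("nVertices", "LabeledTree", function(x) length(x@parent))

#' @rdname LabeledTree-class
#' @export
setMethod("nEdges", "LabeledTree", function(x) length(x@parent) - 1L)

#' Accessors for LabeledTree
#'
#' `childrenOf` returns the ordered children of a vertex; `edgeLabel` the
#' label of the edge above a vertex; `ancestorsOf` the strict ancestors of a
#' vertex from parent up to the root (a vertex is never its own ancestor);
#' `isLeaf` whether a vertex has no children; `descendantCount` the number of
#' edges strictly below a vertex.
#'
#' @param tree a [LabeledTree-class]
#' @param v vertex number (1-based preorder)
#' @return `childrenOf`: integer vector; `edgeLabel`: character;
#'   `ancestorsOf`: integer vector; `isLeaf`: logical;
#'   `descendantCount`: integer.
#' @export
childrenOf <- function(tree, v) tree@children[[v]]

#' @rdname childrenOf
#' @export
edgeLabel <- function(tree, v) tree@label[v]

#' @rdname childrenOf
#' @export
ancestorsOf <- function(tree, v) {
  out <- integer(0)
  p <- tree@parent[v]
  while (!is.na(p)) { out <- c(out, p); p <- tree@parent[p] }
  out
}

#' @rdname childrenOf
#' @export
isLeaf <- function(tree, v) length(tree@children[[v]]) == 0L

#' @rdname childrenOf
#' @export
descendantCount <- function(tree, v) {
  n <- nVertices(tree)
  cnt <- integer(n)
  for (w in rev(seq_len(n))) cnt[w] <- sum(1L + cnt[tree@children[[w]]])
  cnt[v]
}

# all descendant-edge counts at once (vector over vertices)
.descCounts <- function(tree) {
  n <- nVertices(tree)
  cnt <- integer(n)
  for (w in rev(seq_len(n))) cnt[w] <- sum(1L + cnt[tree@children[[w]]])
  cnt
}

# vertices of the full subtree hanging below v (v excluded): preorder block
.descendants <- function(tree, v) {
  cnt <- .descCounts(tree)[v]
  if (cnt == 0L) integer(0) else (v + 1L):(v + cnt)
}

setMethod("show", "LabeledTree", function(object) {
  cat(sprintf("LabeledTree with %d vertices, %d edges\n",
              nVertices(object), nEdges(object)))
  if (nEdges(object) > 0L) {
    labs <- table(object@label[-1L])
    cat("  edge labels:", paste(sprintf("%s(%d)", names(labs), labs), collapse = " "), "\n")
  }
  deg <- lengths(object@children)
  cat(sprintf("  max out-degree: %d, leaves: %d\n", max(deg), sum(deg == 0L)))
})

#' Construct subtree indices
#'
#' `orderedSubtree(i, h, k, tag)` names the ordered subtree rooted at `i`
#' spanning children `h`..`k`; `unorderedSubtree(i, C, tag)` names the
#' unordered subtree with child subset `C`. `tag = NULL` (the default) means
#' untagged. `wholeTree(tree, mode)` is the index of the entire tree, the
#' start point of every derivation.
#'
#' @param i root vertex
#' @param h,k left-most / right-most child of `i` included
#' @param C integer vector of children of `i`
#' @param tag tag vertex or `NULL` for untagged
#' @return an [OrderedSubtree-class] or [UnorderedSubtree-class]
#' @export
orderedSubtree <- function(i, h, k, tag = NULL) {
  new("OrderedSubtree", i = as.integer(i),
      t = if (is.null(tag)) NA_integer_ else as.integer(tag),
      h = as.integer(h), k = as.integer(k))
}

#' @rdname orderedSubtree
#' @export
unorderedSubtree <- function(i, C, tag = NULL) {
  # slot assignment, not new(..., C = ): "C" would partially match new()'s
  # formal argument "Class"
  obj <- new("UnorderedSubtree")
  obj@i <- as.integer(i)
  obj@t <- if (is.null(tag)) NA_integer_ else as.integer(tag)
  obj@C <- sort(as.integer(C))
  validObject(obj)
  obj
}

#' @rdname orderedSubtree
#' @param tree a [LabeledTree-class]
#' @param mode `"ordered"` or `"unordered"`
#' @export
wholeTree <- function(tree, mode = c("ordered", "unordered")) {
  mode <- match.arg(mode)
  ch <- childrenOf(tree, 1L)
  if (length(ch) == 0L) stop("tree has no edges")
  if (mode == "ordered") orderedSubtree(1L, ch[1L], ch[length(ch)])
  else unorderedSubtree(1L, ch)
}

setMethod("show", "OrderedSubtree", function(object) {
  cat(sprintf("OrderedSubtree T_{%d,%s,%d,%d}\n", object@i,
              if (is.na(object@t)) "-" else object@t, object@h, object@k))
})

setMethod("show", "UnorderedSubtree", function(object) {
  cat(sprintf("UnorderedSubtree T_{%d,%s,{%s}}\n", object@i,
              if (is.na(object@t)) "-" else object@t,
              paste(object@C, collapse = ",")))
})

#' Random rooted edge-labeled tree
#'
#' Generates a uniform random recursive tree: vertex v (for v = 2..n) attaches
#' to a parent drawn uniformly from 1..v-1, and every edge label is drawn
#' uniformly from `labels`. The result is preorder-renumbered. Uses R's RNG;
#' call `set.seed()` for reproducibility.
#'
#' @param n number of vertices (>= 2)
#' @param labels character vector of edge labels to draw from
#' @param maxDegree optional cap on the number of children per vertex;
#'   attachment redraws until satisfied
#' @return a [LabeledTree-class]
#' @export
randomLabeledTree <- function(n, labels = c("a", "b"), maxDegree = Inf) {
  stopifnot(n >= 2)
  parent <- rep(NA_integer_, n)
  deg <- integer(n)
  for (v in 2:n) {
    repeat {
      p <- if (v == 2L) 1L else sample.int(v - 1L, 1L)
      if (deg[p] < maxDegree) break
    }
    parent[v] <- p; deg[p] <- deg[p] + 1L
  }
  lab <- c(NA_character_, sample(labels, n - 1L, replace = TRUE))
  edges <- data.frame(parent = parent[-1L], child = 2:n, label = lab[-1L],
                      rank = seq_len(n - 1L))
  treeFromEdges(edges)
}
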