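#' @import methods
#' @importFrom Matrix sparseMatrix
#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

# Reserved control characters used to build unambiguous string keys from
# tokens; edge labels must not contain them (enforced by LabeledTree validity).
.TOKSEP <- "\x1f"

#' Rooted tree with labeled edges
#'
#' `LabeledTree` stores a rooted tree whose edges (not vertices) carry labels
#' from a finite terminal alphabet. Vertices are numbered 1..n in preorder
#' with the root at 1, so every non-root vertex's parent has a smaller number
#' and each child list is increasing. The same object serves both the ordered
#' interpretation (child lists are sequences) and the unordered one (child
#' lists are read as sets).
#'
#' @slot parent integer vector; `parent[v]` is the parent of vertex `v`,
#'   `NA` for the root.
#' @slot label character vector; `label[v]` is the label of the edge from
#'   `parent[v]` to `v`, `NA` for the root.
#' @slot children list of integer vectors; `children[[v]]` are the children
#'   of `v` in left-to-right order.
#' @slot origId character vector of the vertex identifiers used in the input
#'   file (or the preorder numbers as strings for programmatically built
#'   trees).
#'
#' @seealso [labeledTree()], [treeFromEdges()], [readEdgelist()]
#' @export
setClass("LabeledTree",
  representation(parent = "integer", label = "character",
                 children = "list", origId = "character"))

setValidity("LabeledTree", function(object) {
  n <- length(object@parent)
  if (n < 1L) return("tree must have at least one vertex")
  if (length(object@label) != n || length(object@children) != n ||
      length(object@origId) != n)
    return("parent, label, children and origId must have equal length")
  if (!is.na(object@parent[1L])) return("vertex 1 must be the root (parent NA)")
  if (n > 1L) {
    p <- object@parent[-1L]
    if (anyNA(p)) return("only vertex 1 may lack a parent (single root)")
    if (any(p >= 2:n)) return("not preorder-numbered: parent[v] must be < v")
    lab <- object@label[-1L]
    if (anyNA(lab)) return("every edge needs a label")
    if (any(grepl("[\x1e\x1f]", lab))) return("labels must not contain control bytes \\x1e/\\x1f")
  }
  for (v in seq_len(n)) {
    ch <- object@children[[v]]
    if (length(ch)) {
      if (any(object@parent[ch] != v)) return("children list inconsistent with parent")
      if (is.unsorted(ch, strictly = TRUE))
        return("child lists must be strictly increasing (preorder)")
    }
  }
  if (sum(tabulate(object@parent[!is.na(object@parent)], n)) != n - 1L)
    return("children/parent do not form a tree")
  TRUE
})

#' Indexed ordered subtree
#'
#' Names the ordered subtree of a [LabeledTree] rooted at vertex `i`,
#' spanning the consecutive children `h`..`k` of `i` together with all their
#' descendants, truncated below the tag vertex `t` when one is present. A tag
#' marks the single vertex at which another tree may later be attached; an
#' untagged subtree has `t = NA`.
#'
#' @slot i root vertex.
#' @slot t tag vertex, or `NA` when untagged.
#' @slot h,k left-most and right-most child of `i` included in the span.
#' @export
setClass("OrderedSubtree",
  representation(i = "integer", t = "integer", h = "integer", k = "integer"))

#' Indexed unordered subtree
#'
#' The unordered counterpart of [OrderedSubtree-class]: the subtree rooted at
#' `i` containing the child subset `C` (a set, not a span) with all
#' descendants, truncated below the tag `t` when tagged.
#'
#' @slot i root vertex.
#' @slot t tag vertex, or `NA` when untagged.
#' @slot C integer vector, a nonempty subset of the children of `i`.
#' @export
setClass("UnorderedSubtree",
  representation(i = "integer", t = "integer", C = "integer"),
  prototype(i = 1L, t = NA_integer_, C = 1L))

setValidity("UnorderedSubtree", function(object) {
  if (length(object@C) < 1L) return("child subset C must be nonempty")
  if (is.unsorted(object@C, strictly = TRUE)) return("C must be strictly increasing")
  TRUE
})

#' Euler string of a (possibly tagged) subtree
#'
#' The depth-first serialization of an ordered edge-labeled tree: each edge
#' emits its label on descent (an *open* token) and a matched closing token on
#' ascent; a tagged edge emits open, the tag marker, then close. Two subtrees
#' are isomorphic exactly when their Euler strings are equal (after
#' canonicalization, in the unordered case). Closing tokens are distinct
#' tokens carrying the label plus a close flag, never decorated strings, so
#' arbitrary label alphabets are safe.
#'
#' @slot role character vector over `"open"`, `"close"`, `"tag"`.
#' @slot label character vector; the edge label for open/close tokens,
#'   `NA` for the tag marker.
#' @seealso [eulerString()], [canonicalEulerString()], [parseEulerString()]
#' @export
setClass("EulerString",
  representation(role = "character", label = "character"))

setValidity("EulerString", function(object) {
  if (length(object@role) != length(object@label))
    return("role and label must have equal length")
  if (!all(object@role %in% c("open", "close", "tag")))
    return("roles must be open/close/tag")
  if (sum(object@role == "tag") > 1L) return("at most one tag marker")
  depth <- 0L
  for (idx in seq_along(object@role)) {
    r <- object@role[idx]
    if (r == "open") depth <- depth + 1L
    else if (r == "close") depth <- depth - 1L
    if (depth < 0L) return("unbalanced open/close tokens")
  }
  if (depth != 0L) return("unbalanced open/close tokens")
  TRUE
})

#' Integer program for a minimum-grammar problem
#'
#' A solver-agnostic 0/1 integer linear program. Variables come in three
#' families: `x` (one per substring span or subtree index: the span/subtree is
#' generated by some nonterminal), `y` (one per candidate division: the
#' concatenation or horizontal/vertical tree division used to generate it) and
#' `z` (one per distinct substring or canonical Euler string: the nonterminal
#' class is used at all). Row bounds encode equalities and inequalities.
#'
#' @slot obj numeric objective coefficients.
#' @slot A sparse constraint matrix (`Matrix::dgCMatrix`).
#' @slot rowlb,rowub numeric per-row lower/upper bounds (`-Inf`/`Inf` allowed).
#' @slot maximize logical; direction of optimization.
#' @slot vars data.frame describing each column (`name`, `kind` in x/y/z,
#'   `key` identifying the span/subtree/class).
#' @slot meta list carrying the enumeration tables and settings needed to
#'   reconstruct a grammar from a solution.
#' @export
setClass("IPInstance",
  representation(obj = "numeric", A = "Matrix", rowlb = "numeric",
                 rowub = "numeric", maximize = "logical",
                 vars = "data.frame", meta = "list"))

#' Result of solving an integer program
#'
#' @slot status one of `"optimal"`, `"infeasible"`, `"timeout"`.
#' @slot assignment named numeric vector of variable values (empty when no
#'   incumbent exists).
#' @slot objective achieved objective value (`NA` if none).
#' @slot stats list of solver statistics (wall time, backend, message) kept
#'   for logging only.
#' @export
setClass("SolveResult",
  representation(status = "character", assignment = "numeric",
                 objective = "numeric", stats = "list"))

#' Simple grammar for a string or tree
#'
#' A simple context-free grammar (rules `A -> a` and `A -> BC`) or a simple
#' elementary ordered/unordered tree grammar (terminal edge rules `R1u`/`R1t`,
#' horizontal root divisions `R2`, vertical divisions at a tag `R3`).
#' Nonterminals are content-addressed: each is keyed by the substring or
#' canonical Euler string it generates, so isomorphic subtrees share one
#' nonterminal and rule merging is order-independent. The recorded derivation
#' tree remembers which rule produced which span or subtree of the input.
#'
#' @slot kind `"cfg"`, `"seotg"` or `"seutg"`.
#' @slot terminals character vector of terminal symbols used.
#' @slot start key of the start nonterminal (the whole input's class).
#' @slot rules data.frame with columns `lhs`, `kind` (`CFG1`, `CFG2`, `R1u`,
#'   `R1t`, `R2`, `R3`), `rhs1`, `rhs2` (class keys, `NA` for terminal rules)
#'   and `label` (terminal symbol for terminal rules).
#' @slot derivation nested list; each node holds `index` (span or subtree
#'   index key), `class` (nonterminal key) and `children`.
#' @slot info list of extras (mode, solver statistics, label mapping, ...).
#' @export
setClass("Grammar",
  representation(kind = "character", terminals = "character",
                 start = "character", rules = "data.frame",
                 derivation = "list", info = "list"))

setValidity("Grammar", function(object) {
  if (!object@kind %in% c("cfg", "seotg", "seutg")) return("unknown grammar kind")
  need <- c("lhs", "kind", "rhs1", "rhs2", "label")
  if (!all(need %in% names(object@rules))) return("rules lack required columns")
  bin <- object@rules$kind %in% c("CFG2", "R2", "R3")
  if (any(bin & (is.na(object@rules$rhs1) | is.na(object@rules$rhs2))))
    return("binary rules need two right-hand sides")
  if (any(!bin & is.na(object@rules$label)))
    return("terminal rules need a label")
  TRUE
})
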