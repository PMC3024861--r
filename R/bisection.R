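#' Balanced-division baseline (TREE-BISECTION)
#'
#' Polynomial-time baseline for comparison with the exact IP minimum: starting
#' from the whole ordered tree, repeatedly divide each subtree with two or
#' more edges — horizontally at the root or vertically at an internal vertex —
#' choosing the legal division that makes the two parts' edge counts as equal
#' as possible (ties: horizontal before vertical, then the leftmost split
#' index), until every part is a single edge. Nonterminals are merged by Euler
#' string as in grammar extraction. The resulting grammar always regenerates
#' the input, and its nonterminal count is never below the exact SEOTG
#' minimum.
#'
#' Balance is measured in edges; the division steps are the same legal moves
#' the IP enumerates, with deterministic tie-breaking.
#'
#' @param tree a [LabeledTree-class]
#' @return a [Grammar-class] of kind `"seotg"`
#' @export
treeBisection <- function(tree) {
  if (nEdges(tree) < 1L) stop("tree has no edges")
  cnt <- .descCounts(tree)
  rules <- list()
  addRule <- function(lhs, rkind, rhs1, rhs2, label) {
    rules[[length(rules) + 1L]] <<- data.frame(lhs = lhs, kind = rkind,
                                               rhs1 = rhs1, rhs2 = rhs2, label = label)
  }
  spanOf <- function(i, h, k) {
    ch <- childrenOf(tree, i)
    ch[match(h, ch):match(k, ch)]
  }
  edgesOf <- function(p) .nEdgesOrd(cnt, spanOf(p[["i"]], p[["h"]], p[["k"]]), p[["t"]])
  walk <- function(i, t, h, k) {
    cls <- .esKeyOrdered(tree, i, t, h, k)
    ne <- .nEdgesOrd(cnt, spanOf(i, h, k), t)
    if (ne == 1L) {
      lab <- substring(.esSplit(cls)[1L], 3L)
      addRule(cls, if (is.na(t)) "R1u" else "R1t", NA_character_, NA_character_, lab)
      return(list(index = .keyOrd(i, t, h, k), class = cls, children = list()))
    }
    divs <- .divisionsOrdered(tree, cnt, i, t, h, k)
    imbalance <- vapply(divs, function(d) abs(edgesOf(d$p1) - edgesOf(d$p2)), numeric(1))
    kinds <- vapply(divs, `[[`, character(1), "kind")
    params <- suppressWarnings(as.numeric(vapply(divs, `[[`, character(1), "param")))
    d <- divs[[order(imbalance, kinds, params)[1L]]]
    addRule(cls, if (d$kind == "H") "R2" else "R3",
            .esKeyOrdered(tree, d$p1[["i"]], d$p1[["t"]], d$p1[["h"]], d$p1[["k"]]),
            .esKeyOrdered(tree, d$p2[["i"]], d$p2[["t"]], d$p2[["h"]], d$p2[["k"]]),
            NA_character_)
    list(index = .keyOrd(i, t, h, k), class = cls,
         children = list(walk(d$p1[["i"]], d$p1[["t"]], d$p1[["h"]], d$p1[["k"]]),
                         walk(d$p2[["i"]], d$p2[["t"]], d$p2[["h"]], d$p2[["k"]])))
  }
  ch <- childrenOf(tree, 1L)
  deriv <- walk(1L, NA_integer_, ch[1L], ch[length(ch)])
  rules <- unique(do.call(rbind, rules))
  rules <- rules[order(rules$kind, rules$lhs, method = "radix"), , drop = FALSE]
  rownames(rules) <- NULL
  new("Grammar", kind = "seotg",
      terminals = sort(unique(tree@label[-1L]), method = "radix"),
      start = .esKeyOrdered(tree, 1L, NA_integer_, ch[1L], ch[length(ch)]),
      rules = rules, derivation = deriv, info = list(method = "bisection"))
}
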