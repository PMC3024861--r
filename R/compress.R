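#' One-call minimum-grammar compression
#'
#' `compressString` finds the minimum simple CFG of a string;
#' `compressTree` the minimum simple EOTG (`mode = "ordered"`) or SEUTG
#' (`mode = "unordered"`) of a tree, or the TREE-BISECTION baseline grammar
#' (`method = "bisection"`, ordered mode). These wrap [findMinimumM()] and
#' [extractGrammar()] and attach the minimum and solver statistics to the
#' grammar's `info`.
#'
#' @param s character scalar
#' @param tree a [LabeledTree-class]
#' @param mode `"ordered"` or `"unordered"` sibling semantics
#' @param method `"ip"` (exact minimum) or `"bisection"` (baseline)
#' @param searchMethod passed to [findMinimumM()] (`"minimize"` or `"probe"`)
#' @param ... further arguments to [findMinimumM()] (`timeLimit`, `seed`,
#'   `budgetMode`, `forceTaggedTerminals`, `maxDegree`, `python`)
#' @return a [Grammar-class]; `info(g)$m` holds the minimum nonterminal count
#'   for IP grammars
#' @examples
#' \donttest{
#' g <- compressString("abcabcab")
#' nonterminalCount(g)  # 7
#' }
#' @export
compressString <- function(s, searchMethod = "minimize", ...) {
  fit <- findMinimumM(s, mode = "cfg", method = searchMethod, ...)
  g <- extractGrammar(fit$instance, fit$result)
  g@info$m <- fit$m
  g
}

#' @rdname compressString
#' @export
compressTree <- function(tree, mode = c("ordered", "unordered"),
                         method = c("ip", "bisection"),
                         searchMethod = "minimize", ...) {
  mode <- match.arg(mode); method <- match.arg(method)
  if (method == "bisection") {
    if (mode == "unordered")
      stop("the bisection baseline is defined for ordered trees")
    return(treeBisection(tree))
  }
  fit <- findMinimumM(tree, mode = if (mode == "ordered") "seotg" else "seutg",
                      method = searchMethod, ...)
  g <- extractGrammar(fit$instance, fit$result)
  g@info$m <- fit$m
  g
}
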