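#' Repeated-subtree patterns from a grammar derivation
#'
#' Reports every nonterminal that is expanded two or more times in the
#' derivation tree of a tree grammar: repeated subtrees of the input, the
#' grammar-compression view of structural motifs (for glycans, repeated
#' monosaccharide subtrees). Occurrences are counted in the derivation —
#' non-overlapping by construction, since the derivation's leaves partition
#' the input's edges — not in the rule set. Tagged nonterminals (contexts
#' with an attachment point) are reported too and flagged.
#'
#' @param g a tree [Grammar-class] (kind `"seotg"` or `"seutg"`) with a
#'   derivation
#' @param minVertices drop patterns with fewer vertices (default 1 keeps all,
#'   including repeated single edges)
#' @return data.frame, one row per pattern, sorted by occurrences then vertex
#'   count (both descending): `pattern` (readable Euler string), `occurrences`,
#'   `vertices`, `edges`, `tagged`, `labels` (edge-label multiset), `key`.
#' @examples
#' \donttest{
#' tr <- labeledTree(c(NA, 1, 1, 3, 3, 1), c(NA, "a", "c", "a", "b", "b"))
#' g <- compressTree(tr, mode = "unordered")
#' extractRepeats(g, minVertices = 3)  # the {a,b}-child subtree, twice
#' }
#' @export
extractRepeats <- function(g, minVertices = 1L) {
  if (!g@kind %in% c("seotg", "seutg"))
    stop("pattern extraction is defined for tree grammars")
  if (!length(g@derivation)) stop("grammar has no derivation")
  counts <- new.env(parent = emptyenv())
  tally <- function(nd) {
    k <- nd$class
    assign(k, (if (exists(k, counts, inherits = FALSE)) get(k, counts) else 0L) + 1L,
           envir = counts)
    for (ch in nd$children) tally(ch)
  }
  tally(g@derivation)
  keys <- ls(counts)
  occ <- vapply(keys, get, integer(1), envir = counts)
  keep <- occ >= 2L
  keys <- keys[keep]; occ <- occ[keep]
  if (!length(keys))
    return(data.frame(pattern = character(0), occurrences = integer(0),
                      vertices = integer(0), edges = integer(0),
                      tagged = logical(0), labels = character(0), key = character(0)))
  toks <- lapply(keys, .esSplit)
  edges <- vapply(toks, function(tk) sum(startsWith(tk, "o")), integer(1))
  tagged <- vapply(toks, function(tk) .tokTag %in% tk, logical(1))
  labels <- vapply(toks, function(tk) {
    tb <- table(substring(tk[startsWith(tk, "o")], 3L))
    paste(sprintf("%s:%d", names(tb), tb), collapse = ",")
  }, character(1))
  out <- data.frame(pattern = unname(.prettyKey(keys, g@kind)),
                    occurrences = unname(occ), vertices = edges + 1L,
                    edges = edges, tagged = tagged, labels = labels, key = keys)
  out <- out[out$vertices >= minVertices, , drop = FALSE]
  out <- out[order(-out$occurrences, -out$vertices, out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a pattern report as tab-separated text
#'
#' @param patterns data.frame from [extractRepeats()]
#' @param path file path
#' @export
writePatterns <- function(patterns, path) {
  utils::write.table(patterns[, c("pattern", "occurrences", "vertices", "tagged", "labels")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
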