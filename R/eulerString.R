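# ---- internal token encoding -------------------------------------------------
# A token is "o\x1f<label>", "c\x1f<label>" or "x"; a whole Euler string is the
# tokens joined by "\x1e". Labels are validated not to contain either byte.

.tokOpen  <- function(label) paste0("o", .TOKSEP, label)
.tokClose <- function(label) paste0("c", .TOKSEP, label)
.tokTag   <- "x"

.esJoin <- function(tokens) paste(tokens, collapse = "\x1e")
.esSplit <- function(key) if (nzchar(key)) strsplit(key, "\x1e", fixed = TRUE)[[1L]] else character(0)

.esFromTokens <- function(tokens) {
  role <- character(length(tokens)); label <- rep(NA_character_, length(tokens))
  isTag <- tokens == .tokTag
  role[isTag] <- "tag"
  rest <- !isTag
  role[rest] <- ifelse(startsWith(tokens[rest], "o"), "open", "close")
  label[rest] <- substring(tokens[rest], 3L)
  new("EulerString", role = role, label = label)
}

.esToTokens <- function(es) {
  ifelse(es@role == "tag", .tokTag,
         ifelse(es@role == "open", .tokOpen(es@label), .tokClose(es@label)))
}

#' Collapse an Euler string to a single key string
#'
#' The key is an unambiguous flat encoding (tokens joined by a reserved
#' separator byte); equal keys mean equal Euler strings. These keys are what
#' index the `z` variables of the integer programs and the nonterminals of
#' extracted grammars.
#'
#' @param es an [EulerString-class]
#' @return character scalar
#' @export
esKey <- function(es) .esJoin(.esToTokens(es))

setMethod("show", "EulerString", function(object) {
  cat("EulerString:", format(object), "\n")
})

#' @describeIn esKey human-readable rendering: labels for open tokens, a
#'   trailing apostrophe for the matched close, `x` for the tag marker.
#' @param x an `EulerString`
#' @param ... ignored
#' @export
format.EulerString <- function(x, ...) {
  paste(ifelse(x@role == "tag", "x",
        ifelse(x@role == "open", x@label, paste0(x@label, "'"))), collapse = " ")
}

setMethod("format", "EulerString", function(x, ...) format.EulerString(x, ...))

# ---- subtree index validation -----------------------------------------------

.checkOrderedSub <- function(tree, sub) {
  ch <- childrenOf(tree, sub@i)
  ph <- match(sub@h, ch); pk <- match(sub@k, ch)
  if (is.na(ph) || is.na(pk))
    stop(sprintf("h=%d or k=%d is not a child of i=%d", sub@h, sub@k, sub@i))
  if (ph > pk) stop("left-most child h must not be right of k")
  if (!is.na(sub@t)) {
    span <- ch[ph:pk]
    inSpan <- any(vapply(span, function(c0) sub@t == c0 || sub@t %in% .descendants(tree, c0), logical(1)))
    if (!inSpan) stop(sprintf("tag t=%d lies outside the span of children %d..%d of %d",
                              sub@t, sub@h, sub@k, sub@i))
  }
  ch[ph:pk]
}

.checkUnorderedSub <- function(tree, sub) {
  ch <- childrenOf(tree, sub@i)
  if (!all(sub@C %in% ch))
    stop(sprintf("C contains non-children of i=%d", sub@i))
  if (!is.na(sub@t)) {
    inC <- any(vapply(sub@C, function(c0) sub@t == c0 || sub@t %in% .descendants(tree, c0), logical(1)))
    if (!inC) stop(sprintf("tag t=%d lies under no child in C", sub@t))
  }
  sub@C
}

# ---- serialization -----------------------------------------------------------

# encoded tokens for the edge above v and everything below, truncated at tag
.serEdgeTokens <- function(tree, v, tag) {
  lab <- tree@label[v]
  inner <- if (!is.na(tag) && v == tag) .tokTag
           else unlist(lapply(tree@children[[v]], .serEdgeTokens, tree = tree, tag = tag),
                       use.names = FALSE)
  c(.tokOpen(lab), inner, .tokClose(lab))
}

.esTokensOrdered <- function(tree, i, t, h, k) {
  ch <- childrenOf(tree, i)
  span <- ch[match(h, ch):match(k, ch)]
  unlist(lapply(span, .serEdgeTokens, tree = tree, tag = t), use.names = FALSE)
}

#' Euler string of an ordered subtree
#'
#' Serializes the subtree by a depth-first left-to-right traversal, emitting
#' the edge label on descent and a matched closing token on ascent; a tagged
#' edge with label `A` emits `A x A-close`. Equal Euler strings characterize
#' isomorphism of ordered subtrees.
#'
#' @param tree a [LabeledTree-class]
#' @param sub an [OrderedSubtree-class]; `NULL` serializes the whole tree
#' @return an [EulerString-class]
#' @examples
#' tr <- labeledTree(c(NA, 1, 1, 3, 3, 1), c(NA, "a", "c", "a", "b", "b"))
#' format(eulerString(tr))               # a a' c a a' b b' c' b b'
#' @export
eulerString <- function(tree, sub = NULL) {
  if (is.null(sub)) sub <- wholeTree(tree, "ordered")
  .checkOrderedSub(tree, sub)
  .esFromTokens(.esTokensOrdered(tree, sub@i, sub@t, sub@h, sub@k))
}

# ---- unordered canonicalization ---------------------------------------------

# canonical encoded tokens of the edge above v (recursively sorted children,
# tag-containing child first at every vertex)
.canonEdgeTokens <- function(tree, v, tag) {
  lab <- tree@label[v]
  inner <- if (!is.na(tag) && v == tag) .tokTag
           else .canonChildBlocks(tree, tree@children[[v]], tag)
  c(.tokOpen(lab), inner, .tokClose(lab))
}

.canonChildBlocks <- function(tree, kids, tag) {
  if (length(kids) == 0L) return(character(0))
  blocks <- lapply(kids, .canonEdgeTokens, tree = tree, tag = tag)
  keys <- vapply(blocks, .esJoin, character(1))
  hasTag <- vapply(blocks, function(b) .tokTag %in% b, logical(1))
  # the tag-bearing child is placed first; the rest sort by their canonical key
  # (radix = C collation, independent of the session locale)
  unlist(blocks[order(!hasTag, keys, method = "radix")], use.names = FALSE)
}

#' Canonical Euler string of an unordered subtree
#'
#' Transforms the unordered subtree into a canonical ordered tree — children
#' of every vertex sorted by the canonical key of their own subtree (label
#' first, then structure, so equal labels are still resolved), with the
#' tag-containing child moved to the front — and returns its Euler string.
#' Two unordered subtrees get the same output iff they are isomorphic as
#' unordered trees; applying canonicalization to an already-canonical tree is
#' a no-op.
#'
#' @param tree a [LabeledTree-class]
#' @param sub an [UnorderedSubtree-class]; `NULL` canonicalizes the whole tree
#' @return an [EulerString-class]
#' @export
canonicalEulerString <- function(tree, sub = NULL) {
  if (is.null(sub)) sub <- wholeTree(tree, "unordered")
  .checkUnorderedSub(tree, sub)
  .esFromTokens(.canonChildBlocks(tree, sub@C, sub@t))
}

# fast internal path used by enumeration (no S4 construction)
.canonKeyUnordered <- function(tree, i, t, C) .esJoin(.canonChildBlocks(tree, C, t))
.esKeyOrdered <- function(tree, i, t, h, k) .esJoin(.esTokensOrdered(tree, i, t, h, k))

# ---- parsing -----------------------------------------------------------------

#' Rebuild a tree from an Euler string
#'
#' Inverse of [eulerString()]: parses the token sequence back into a
#' [LabeledTree-class] under a fresh root (the serialized edges hang below
#' vertex 1) and reports the tagged vertex when a tag marker is present.
#' Re-serializing the result reproduces the input exactly.
#'
#' @param es an [EulerString-class] (or a key produced by [esKey()])
#' @return list with elements `tree` ([LabeledTree-class]) and `tag`
#'   (vertex number or `NA`)
#' @export
parseEulerString <- function(es) {
  tokens <- if (is.character(es)) .esSplit(es) else .esToTokens(es)
  parent <- NA_integer_; label <- NA_character_
  cur <- 1L; nxt <- 2L; tag <- NA_integer_
  for (tok in tokens) {
    if (tok == .tokTag) {
      if (!is.na(tag)) stop("more than one tag marker")
      tag <- cur
    } else if (startsWith(tok, "o")) {
      parent[nxt] <- cur; label[nxt] <- substring(tok, 3L)
      cur <- nxt; nxt <- nxt + 1L
    } else {
      if (is.na(parent[cur]) && cur == 1L) stop("unbalanced Euler string")
      if (substring(tok, 3L) != label[cur]) stop("mismatched closing token")
      cur <- parent[cur]
    }
  }
  if (cur != 1L) stop("unbalanced Euler string")
  list(tree = labeledTree(parent, label), tag = tag)
}
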