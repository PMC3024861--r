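# ---- index keys ---------------------------------------------------------------

.tagStr <- function(t) if (is.na(t)) "e" else as.character(t)

.keyOrd <- function(i, t, h, k) paste("O", i, .tagStr(t), h, k, sep = ":")
.keyUno <- function(i, t, C) paste("U", i, .tagStr(t), paste(C, collapse = ","), sep = ":")

# child of i whose subtree block contains vertex t (preorder blocks)
.containingChild <- function(span, cnt, t) {
  for (c0 in span) if (t >= c0 && t <= c0 + cnt[c0]) return(c0)
  NA_integer_
}

.nEdgesOrd <- function(cnt, span, t) sum(1L + cnt[span]) - (if (is.na(t)) 0L else cnt[t])

# vertices of the subtree below i spanned by `span`, truncated below tag t
.subVerts <- function(cnt, span, t) {
  v <- unlist(lapply(span, function(c0) c0:(c0 + cnt[c0])), use.names = FALSE)
  if (!is.na(t) && cnt[t] > 0L) v <- setdiff(v, (t + 1L):(t + cnt[t]))
  v
}

# ---- divisions of a single subtree --------------------------------------------
# Horizontal divisions split the child span/subset at the root; the tag, when
# present, stays on the unique side whose children contain it. Vertical
# divisions pick an internal vertex t' (for a tagged subtree: an ancestor of
# the tag) that becomes the tag of the upper part; the lower part is the full
# subtree of t', inheriting the parent's tag.

.divisionsOrdered <- function(tree, cnt, i, t, h, k) {
  ch <- childrenOf(tree, i)
  ph <- match(h, ch); pk <- match(k, ch)
  span <- ch[ph:pk]
  out <- list()
  cStar <- if (is.na(t)) NA_integer_ else .containingChild(span, cnt, t)
  if (pk > ph) {
    for (lp in ph:(pk - 1L)) {
      l <- ch[lp]
      leftTag <- rightTag <- NA_integer_
      if (!is.na(t)) {
        if (match(cStar, ch) <= lp) leftTag <- t else rightTag <- t
      }
      out[[length(out) + 1L]] <- list(
        kind = "H", param = as.character(l),
        p1 = c(i = i, t = leftTag,  h = h,         k = l),
        p2 = c(i = i, t = rightTag, h = ch[lp + 1L], k = k))
    }
  }
  tP <- if (is.na(t)) {
    verts <- .subVerts(cnt, span, t)
    verts[cnt[verts] > 0L]                      # internal vertices of the subtree
  } else {
    setdiff(intersect(ancestorsOf(tree, t), .subVerts(cnt, span, t)), i)
  }
  for (tp in tP) {
    kids <- childrenOf(tree, tp)
    out[[length(out) + 1L]] <- list(
      kind = "V", param = as.character(tp),
      p1 = c(i = i, t = tp, h = h, k = k),
      p2 = c(i = tp, t = t, h = kids[1L], k = kids[length(kids)]))
  }
  out
}

.divisionsUnordered <- function(tree, cnt, i, t, C) {
  out <- list()
  cStar <- if (is.na(t)) NA_integer_ else .containingChild(C, cnt, t)
  nc <- length(C)
  if (nc > 1L) {
    # unordered bipartitions {C1, C2}: C1 always contains the smallest child
    for (mask in 0:(2^(nc - 1L) - 2L)) {
      sel <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(nc - 1L) - 1L)) > 0L))
      C1 <- C[sel]; C2 <- C[!sel]
      t1 <- t2 <- NA_integer_
      if (!is.na(t)) { if (cStar %in% C1) t1 <- t else t2 <- t }
      out[[length(out) + 1L]] <- list(
        kind = "H", param = paste(C1, collapse = ","),
        p1 = list(i = i, t = t1, C = C1),
        p2 = list(i = i, t = t2, C = C2))
    }
  }
  tP <- if (is.na(t)) {
    verts <- .subVerts(cnt, C, t)
    verts[cnt[verts] > 0L]
  } else {
    setdiff(intersect(ancestorsOf(tree, t), .subVerts(cnt, C, t)), i)
  }
  for (tp in tP) {
    out[[length(out) + 1L]] <- list(
      kind = "V", param = as.character(tp),
      p1 = list(i = i, t = tp, C = C),
      p2 = list(i = tp, t = t, C = childrenOf(tree, tp)))
  }
  out
}

# ---- enumeration by top-down closure ------------------------------------------

#' Enumerate candidate substrings of a string
#'
#' All 1-based closed spans `(i, j)` with `i <= j`; each becomes one `x`
#' variable of the string IP. A string of length n yields n(n+1)/2 spans.
#'
#' @param s character scalar (non-empty)
#' @return data.frame with columns `i`, `j`, `sub` (the substring)
#' @export
enumerateSubstrings <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  n <- nchar(s)
  if (n < 1L) stop("string must be non-empty")
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  out <- data.frame(i = ij[, "row"], j = ij[, "col"])
  out <- out[order(out$i, out$j), , drop = FALSE]
  out$sub <- substring(s, out$i, out$j)
  rownames(out) <- NULL
  out
}

# shared worklist closure; `mode` picks index arithmetic
.enumerateTree <- function(tree, mode, maxDegree = Inf) {
  if (nEdges(tree) < 1L) stop("tree has no edges")
  cnt <- .descCounts(tree)
  if (mode == "unordered") {
    deg <- lengths(tree@children)
    bad <- which(deg > maxDegree)
    if (length(bad))
      stop(sprintf("vertex %d has %d children, exceeding the degree guard (%d) for unordered enumeration",
                   bad[1L], deg[bad[1L]], maxDegree))
  }
  keyOf <- function(s) if (mode == "ordered") .keyOrd(s[["i"]], s[["t"]], s[["h"]], s[["k"]])
                       else .keyUno(s[["i"]], s[["t"]], s[["C"]])
  root <- if (mode == "ordered") {
    ch <- childrenOf(tree, 1L)
    c(i = 1L, t = NA_integer_, h = ch[1L], k = ch[length(ch)])
  } else list(i = 1L, t = NA_integer_, C = childrenOf(tree, 1L))
  subs <- new.env(parent = emptyenv())
  divRows <- list()
  queue <- list(root)
  assign(keyOf(root), root, envir = subs)
  while (length(queue)) {
    s <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    sk <- keyOf(s)
    span <- if (mode == "ordered") {
      ch <- childrenOf(tree, s[["i"]])
      ch[match(s[["h"]], ch):match(s[["k"]], ch)]
    } else s[["C"]]
    if (.nEdgesOrd(cnt, span, s[["t"]]) == 1L) next
    divs <- if (mode == "ordered")
      .divisionsOrdered(tree, cnt, s[["i"]], s[["t"]], s[["h"]], s[["k"]])
    else .divisionsUnordered(tree, cnt, s[["i"]], s[["t"]], s[["C"]])
    for (d in divs) {
      k1 <- keyOf(d$p1); k2 <- keyOf(d$p2)
      divRows[[length(divRows) + 1L]] <-
        data.frame(key = paste(sk, d$kind, d$param, sep = "|"), parent = sk,
                   kind = d$kind, param = d$param, part1 = k1, part2 = k2)
      for (pp in list(d$p1, d$p2)) {
        pk <- keyOf(pp)
        if (!exists(pk, envir = subs, inherits = FALSE)) {
          assign(pk, pp, envir = subs)
          queue[[length(queue) + 1L]] <- pp
        }
      }
    }
  }
  keys <- sort(ls(subs), method = "radix")
  rows <- lapply(keys, function(kk) {
    s <- get(kk, envir = subs)
    span <- if (mode == "ordered") {
      ch <- childrenOf(tree, s[["i"]])
      ch[match(s[["h"]], ch):match(s[["k"]], ch)]
    } else s[["C"]]
    ne <- .nEdgesOrd(cnt, span, s[["t"]])
    es <- if (mode == "ordered")
      .esKeyOrdered(tree, s[["i"]], s[["t"]], s[["h"]], s[["k"]])
    else .canonKeyUnordered(tree, s[["i"]], s[["t"]], s[["C"]])
    data.frame(key = kk, i = s[["i"]], t = s[["t"]],
               spec = if (mode == "ordered") paste(s[["h"]], s[["k"]], sep = ",")
                      else paste(s[["C"]], collapse = ","),
               nEdges = ne, base = ne == 1L, es = es)
  })
  subtrees <- do.call(rbind, rows)
  divisions <- if (length(divRows)) do.call(rbind, divRows)
    else data.frame(key = character(0), parent = character(0), kind = character(0),
                    param = character(0), part1 = character(0), part2 = character(0))
  rownames(subtrees) <- rownames(divisions) <- NULL
  list(subtrees = subtrees, divisions = divisions, mode = mode)
}

#' Enumerate candidate subtrees and divisions
#'
#' Computes, top-down from the whole tree, every subtree index reachable by
#' repeated horizontal and vertical division, together with every legal
#' division. Only reachable indices become IP variables, which keeps the
#' programs at the sizes reported for the worked examples. Base elements are
#' single untagged leaf edges and single tagged edges at internal vertices
#' (a tag at a leaf admits no attachment and never arises, because vertical
#' divisions only place tags at internal vertices).
#'
#' `enumerateOrdered` spans consecutive children; `enumerateUnordered` splits
#' child *subsets* into unordered pairs, deduplicating subtree classes by
#' canonical Euler string. Because the number of subsets grows exponentially
#' with vertex degree, unordered enumeration refuses trees whose maximum
#' out-degree exceeds `maxDegree`, naming the offending vertex.
#'
#' @param tree a [LabeledTree-class]
#' @param maxDegree degree guard for unordered enumeration (default 16)
#' @return list with data.frame `subtrees` (columns `key`, `i`, `t`, `spec`
#'   = "h,k" span or child subset, `nEdges`, `base`, `es`), data.frame
#'   `divisions` (columns `key`, `parent`, `kind` `"H"`/`"V"`, `param`,
#'   `part1`, `part2`) and `mode`.
#' @examples
#' tr <- labeledTree(c(NA, 1, 1, 3, 3, 1), c(NA, "a", "c", "a", "b", "b"))
#' table(enumerateOrdered(tr)$divisions$kind)    # 9 horizontal, 4 vertical
#' table(enumerateUnordered(tr)$divisions$kind)  # 12 horizontal, 4 vertical
#' @export
enumerateOrdered <- function(tree) .enumerateTree(tree, "ordered")

#' @rdname enumerateOrdered
#' @export
enumerateUnordered <- function(tree, maxDegree = 16L)
  .enumerateTree(tree, "unordered", maxDegree = maxDegree)
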