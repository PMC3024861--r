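#' Read and write rooted labeled trees as edge lists
#'
#' The edge-list format is tab-separated text with one record per edge:
#' columns `parent`, `child`, `label` and optionally `rank` (sibling order;
#' unique per parent, ignored in unordered mode). A header line is detected
#' and skipped. Vertex identifiers may be arbitrary strings; the tree is
#' renumbered to preorder on reading, with original identifiers kept in the
#' `origId` slot. Files with several parentless vertices (forests), duplicate
#' ranks or cycles are rejected with a diagnostic.
#'
#' @param path file path
#' @return `readEdgelist`: a [LabeledTree-class]; `writeEdgelist` invisibly
#'   returns `path`.
#' @export
readEdgelist <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE,
                           strip.white = TRUE)
  if (ncol(raw) < 3L) stop("edge list needs at least 3 tab-separated columns in ", path)
  if (tolower(raw[1L, 1L]) %in% c("parent", "from")) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) < 1L) stop("no edge records in ", path)
  edges <- data.frame(parent = raw[[1L]], child = raw[[2L]], label = raw[[3L]],
                      rank = if (ncol(raw) >= 4L) as.numeric(raw[[4L]])
                             else seq_len(nrow(raw)))
  if (anyNA(edges$rank)) stop("non-numeric sibling rank in ", path)
  tryCatch(treeFromEdges(edges),
           error = function(e) stop("parse error in ", path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' @rdname readEdgelist
#' @param tree a [LabeledTree-class]
#' @export
writeEdgelist <- function(tree, path) {
  if (nEdges(tree) < 1L) stop("tree has no edges")
  v <- 2:nVertices(tree)
  rank <- unlist(lapply(tree@children, seq_along), use.names = FALSE)
  rk <- integer(nVertices(tree))
  rk[unlist(tree@children, use.names = FALSE)] <- rank
  utils::write.table(
    data.frame(parent = tree@origId[tree@parent[v]], child = tree@origId[v],
               label = tree@label[v], rank = rk[v]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a glycan structure from a KEGG KCF record
#'
#' Parses the NODE and EDGE blocks of a KCF (KEGG Chemical Function) file into
#' a rooted edge-labeled tree. The root is the reducing-end monosaccharide,
#' KCF node 1 by convention. Each edge is labeled with a lower-case letter
#' standing for the monosaccharide at its lower (child) endpoint; letters are
#' assigned in deterministic first-seen order (a, b, c, ...) over a preorder
#' walk from the root, and the sugar-name-to-letter table is returned
#' alongside so runs are reproducible. Anomeric/linkage annotations after
#' `:` in the EDGE block are ignored. Records whose edges do not form a tree
#' on the declared nodes are rejected.
#'
#' @param path file path of a KCF record
#' @return list with `tree` (a [LabeledTree-class]) and `labelMap` (named
#'   character vector, sugar name -> letter)
#' @export
readKCF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    start <- grep(paste0("^", tag, "\\b"), lines)
    if (!length(start)) stop("KCF record lacks a ", tag, " block in ", path)
    nrec <- as.integer(sub(paste0("^", tag, "\\s+(\\d+).*"), "\\1", lines[start[1L]]))
    if (is.na(nrec)) stop("malformed ", tag, " header in ", path)
    if (nrec == 0L) return(character(0))
    lines[(start[1L] + 1L):(start[1L] + nrec)]
  }
  nodeLines <- grab("NODE")
  edgeLines <- grab("EDGE")
  nf <- lapply(strsplit(trimws(nodeLines), "\\s+"), function(x) x[1:2])
  nodeName <- stats::setNames(vapply(nf, `[`, character(1), 2L),
                              vapply(nf, `[`, character(1), 1L))
  ef <- strsplit(trimws(edgeLines), "\\s+")
  u <- vapply(ef, function(x) sub(":.*", "", x[2L]), character(1))
  v <- vapply(ef, function(x) sub(":.*", "", x[3L]), character(1))
  if (!all(c(u, v) %in% names(nodeName)))
    stop("EDGE block references undeclared nodes in ", path)
  if (length(edgeLines) == 0L) {
    if (length(nodeName) != 1L) stop("disconnected KCF record in ", path)
    return(list(tree = labeledTree(NA_integer_, NA_character_,
                                   origId = names(nodeName)[1L]),
                labelMap = stats::setNames(character(0), character(0))))
  }
  if (length(edgeLines) != length(nodeName) - 1L)
    stop("KCF edges do not form a tree in ", path)
  if (!"1" %in% names(nodeName)) stop("KCF record has no node 1 (reducing end) in ", path)
  # orient away from the reducing end
  adj <- new.env(parent = emptyenv())
  addAdj <- function(a, b, e) assign(a, rbind(if (exists(a, adj, inherits = FALSE)) get(a, adj),
                                              c(b, e)), envir = adj)
  for (e in seq_along(u)) { addAdj(u[e], v[e], e); addAdj(v[e], u[e], e) }
  parentOf <- character(0); order. <- character(0)
  seen <- new.env(parent = emptyenv())
  walkFrom <- function(a) {
    assign(a, TRUE, envir = seen)
    order. <<- c(order., a)
    nb <- if (exists(a, adj, inherits = FALSE)) get(a, adj) else NULL
    if (!is.null(nb)) {
      nbo <- nb[order(as.numeric(nb[, 1L])), , drop = FALSE]
      for (r in seq_len(nrow(nbo))) {
        b <- nbo[r, 1L]
        if (!exists(b, seen, inherits = FALSE)) {
          parentOf[b] <<- a
          walkFrom(b)
        }
      }
    }
  }
  walkFrom("1")
  if (length(order.) != length(nodeName)) stop("disconnected KCF record in ", path)
  kids <- order.[order. != "1"]
  edges <- data.frame(parent = parentOf[kids], child = kids,
                      sugar = unname(nodeName[kids]),
                      rank = as.numeric(kids))
  sugars <- unique(edges$sugar[order(match(edges$child, order.))])
  labelMap <- stats::setNames(letters[seq_along(sugars)], sugars)
  if (length(sugars) > length(letters)) stop("more than 26 distinct sugars")
  edges$label <- unname(labelMap[edges$sugar])
  list(tree = treeFromEdges(edges[, c("parent", "child", "label", "rank")]),
       labelMap = labelMap)
}
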