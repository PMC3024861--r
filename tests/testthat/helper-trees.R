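# shared test utilities (fixtures are generated, never stored)

# a copy of `tree` with sibling order randomly permuted at every vertex
shuffleChildren <- function(tree) {
  v <- 2:nVertices(tree)
  ranks <- unlist(lapply(tree@children, function(ch) sample(seq_along(ch))),
                  use.names = FALSE)
  rk <- integer(nVertices(tree))
  rk[unlist(tree@children, use.names = FALSE)] <- ranks
  treeFromEdges(data.frame(parent = tree@parent[v], child = v,
                           label = tree@label[v], rank = rk[v]))
}

# multiset of terminal labels at the leaves of a derivation tree
derivationLeafLabels <- function(g) {
  labs <- character(0)
  walk <- function(nd) {
    if (!length(nd$children)) {
      ru <- g@rules[g@rules$lhs == nd$class & !(g@rules$kind %in% c("CFG2", "R2", "R3")), ]
      labs <<- c(labs, ru$label[1L])
    } else lapply(nd$children, walk)
  }
  walk(g@derivation)
  sort(labs)
}

# tree of three identical 4-edge subtrees (a over {b, c-d}) under one root
threeCopyTree <- function() {
  edges <- NULL
  nid <- 1L
  for (copy in 1:3) {
    v <- paste0("v", copy); w <- paste0("w", copy)
    x <- paste0("x", copy); y <- paste0("y", copy)
    edges <- rbind(edges,
                   data.frame(parent = "r", child = v, label = "a", rank = copy),
                   data.frame(parent = v, child = w, label = "b", rank = 1),
                   data.frame(parent = v, child = x, label = "c", rank = 2),
                   data.frame(parent = x, child = y, label = "d", rank = 1))
  }
  treeFromEdges(edges)
}
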