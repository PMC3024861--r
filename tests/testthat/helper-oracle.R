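# Independent brute-force oracles, kept deliberately separate from the IP path.
#
# oracleMinCFG: exhaustive search for the smallest set S of distinct substrings
# containing the input and all its single characters such that every
# multi-character member splits into two members (the defining property of a
# simple CFG generating exactly s). Depth-first search with iterative
# deepening on |S|.
oracleMinCFG <- function(s) {
  n <- nchar(s)
  chars <- unique(strsplit(s, "")[[1L]])
  required <- unique(c(chars, s))
  splitsOf <- new.env(parent = emptyenv())
  getSplits <- function(u) {
    if (!exists(u, splitsOf, inherits = FALSE)) {
      L <- nchar(u)
      assign(u, lapply(seq_len(L - 1L), function(k)
        c(substr(u, 1L, k), substr(u, k + 1L, L))), envir = splitsOf)
    }
    get(u, splitsOf, inherits = FALSE)
  }
  # S valid iff every member of length > 1 has a split with both parts in S
  unjustified <- function(S) {
    long <- S[nchar(S) > 1L]
    long[!vapply(long, function(u)
      any(vapply(getSplits(u), function(p) all(p %in% S), logical(1))), logical(1))]
  }
  seen <- new.env(parent = emptyenv())
  dfs <- function(S, limit) {
    key <- paste(sort(S), collapse = "\x01")
    if (exists(key, seen, inherits = FALSE) && get(key, seen) <= limit) return(FALSE)
    assign(key, limit, envir = seen)
    todo <- unjustified(S)
    if (!length(todo)) return(TRUE)
    if (length(S) >= limit) return(FALSE)
    u <- todo[which.max(nchar(todo))]
    for (p in getSplits(u)) {
      S2 <- union(S, p)
      if (length(S2) <= limit && dfs(S2, limit)) return(TRUE)
    }
    FALSE
  }
  limit <- length(required)
  repeat {
    seen <- new.env(parent = emptyenv())
    if (dfs(required, limit)) return(limit)
    limit <- limit + 1L
  }
}

# oracleMinTree: exact minimum by explicit search over nonterminal-class
# subsets plus a fixpoint derivability check — no integer program involved.
# A class set S admits a grammar iff the whole-tree index is derivable, where
# an index is derivable when its class is in S and it is a single edge or some
# division has both parts derivable. Every complete derivation ends in all
# single-edge classes, so those are required.
oracleMinTree <- function(tree, mode = c("ordered", "unordered")) {
  mode <- match.arg(mode)
  enum <- if (mode == "ordered") enumerateOrdered(tree) else enumerateUnordered(tree)
  st <- enum$subtrees; dv <- enum$divisions
  rootKey <- st$key[st$i == 1L & is.na(st$t) & st$nEdges == nEdges(tree)]
  stopifnot(length(rootKey) == 1L)
  required <- unique(st$es[st$base])
  optional <- setdiff(unique(st$es), required)
  ord <- order(st$nEdges)
  divByParent <- if (nrow(dv)) split(dv, dv$parent) else list()
  feasible <- function(S) {
    ok <- stats::setNames(logical(nrow(st)), st$key)
    for (r in ord) {
      if (!(st$es[r] %in% S)) next
      if (st$base[r]) { ok[[st$key[r]]] <- TRUE; next }
      ds <- divByParent[[st$key[r]]]
      if (!is.null(ds)) ok[[st$key[r]]] <- any(ok[ds$part1] & ok[ds$part2])
    }
    ok[[rootKey]]
  }
  if (feasible(required)) return(length(required))
  for (extra in seq_along(optional)) {
    combos <- utils::combn(length(optional), extra)
    for (cc in seq_len(ncol(combos)))
      if (feasible(c(required, optional[combos[, cc]])))
        return(length(required) + extra)
  }
  stop("oracle failed to find any grammar")  # cannot happen: all classes suffice
}

# all strings over an alphabet up to a length (for exhaustive oracle sweeps)
allStrings <- function(alphabet, maxLen) {
  out <- character(0)
  cur <- ""
  grow <- function(prefix, len) {
    if (len > 0L) out <<- c(out, prefix)
    if (len == maxLen) return()
    for (a in alphabet) grow(paste0(prefix, a), len + 1L)
  }
  grow("", 0L)
  out
}

# brute-force unordered isomorphism via the set of Euler strings over all
# child orderings (tiny trees only)
allOrderingKeys <- function(tree) {
  n <- nVertices(tree)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  serialize <- function(ordering) {
    ser <- function(v) {
      kids <- ordering[[v]]
      inner <- unlist(lapply(kids, function(c0)
        c(paste0("o", tree@label[c0]), ser(c0), paste0("c", tree@label[c0]))),
        use.names = FALSE)
      if (is.null(inner)) character(0) else inner
    }
    paste(ser(1L), collapse = "|")
  }
  choices <- lapply(seq_len(n), function(v) perms(tree@children[[v]]))
  keys <- character(0)
  rec <- function(v, ordering) {
    # enumerate orderings vertex by vertex
    if (v > n) { keys <<- c(keys, serialize(ordering)); return() }
    for (p in choices[[v]]) {
      ordering[[v]] <- p
      rec(v + 1L, ordering)
    }
  }
  rec(1L, vector("list", n))
  unique(keys)
}
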