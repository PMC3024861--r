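# pretty rendering of a class key (substring as-is, Euler key via format())
.prettyKey <- function(key, kind) {
  if (kind == "cfg") key
  else vapply(key, function(k) format(.esFromTokens(.esSplit(k))), character(1))
}

#' Reconstruct a grammar from an IP solution
#'
#' Walks top-down from the root variable, choosing for every active subtree
#' (or span) one active division — horizontal before vertical, then smallest
#' split index / lexicographically smallest child subset, a preference that
#' only fixes the output order; the counts are preference-invariant. Each
#' chosen division emits one binary rule, each base element one terminal
#' rule. Nonterminals are keyed by the substring or canonical Euler string
#' they generate, so indices generating the same content merge into one
#' nonterminal and duplicate rules collapse.
#'
#' @param instance the solved [IPInstance-class]
#' @param result a [SolveResult-class] with the root variable active
#' @return a [Grammar-class] with its derivation tree
#' @export
extractGrammar <- function(instance, result) {
  if (result@status != "optimal" || result@assignment[[instance@meta$rootVar]] < 0.5)
    stop("grammar extraction needs an optimal solution with an active root variable")
  val <- result@assignment
  kind <- instance@meta$kind
  rules <- list()
  addRule <- function(lhs, rkind, rhs1, rhs2, label) {
    rules[[length(rules) + 1L]] <<- data.frame(lhs = lhs, kind = rkind,
                                               rhs1 = rhs1, rhs2 = rhs2, label = label)
  }
  if (kind == "cfg") {
    s <- instance@meta$input
    xv <- function(i, j) val[[paste0("x_", i, "_", j)]]
    yv <- function(i, k, j) val[[paste0("y_", i, "_", k, "_", j)]]
    walk <- function(i, j) {
      cls <- substring(s, i, j)
      if (i == j) {
        addRule(cls, "CFG1", NA_character_, NA_character_, cls)
        return(list(index = paste(i, j, sep = ","), class = cls, children = list()))
      }
      ks <- (i:(j - 1L))[vapply(i:(j - 1L), function(k) yv(i, k, j) > 0.5, logical(1))]
      if (!length(ks)) stop(sprintf("inconsistent solution: no active split for span (%d,%d)", i, j))
      k <- ks[1L]
      addRule(cls, "CFG2", substring(s, i, k), substring(s, k + 1L, j), NA_character_)
      list(index = paste(i, j, sep = ","), class = cls,
           children = list(walk(i, k), walk(k + 1L, j)))
    }
    deriv <- walk(1L, instance@meta$n)
    terminals <- sort(unique(strsplit(s, "")[[1L]]), method = "radix")
    start <- s
  } else {
    st <- instance@meta$subtrees; dv <- instance@meta$divisions
    esOf <- stats::setNames(st$es, st$key)
    baseOf <- stats::setNames(st$base, st$key)
    tagOf <- stats::setNames(st$t, st$key)
    divByParent <- if (nrow(dv)) split(dv, dv$parent) else list()
    walk <- function(key) {
      cls <- esOf[[key]]
      if (baseOf[[key]]) {
        lab <- substring(.esSplit(cls)[1L], 3L)
        addRule(cls, if (is.na(tagOf[[key]])) "R1u" else "R1t",
                NA_character_, NA_character_, lab)
        return(list(index = key, class = cls, children = list()))
      }
      ds <- divByParent[[key]]
      act <- ds[val[paste0("y", match(ds$key, dv$key))] > 0.5, , drop = FALSE]
      if (!nrow(act)) stop("inconsistent solution: no active division for ", key)
      pnum <- suppressWarnings(as.numeric(act$param))
      act <- act[order(act$kind, pnum, act$param, method = "radix"), , drop = FALSE]
      d <- act[1L, ]
      addRule(cls, if (d$kind == "H") "R2" else "R3",
              esOf[[d$part1]], esOf[[d$part2]], NA_character_)
      list(index = key, class = cls,
           children = list(walk(d$part1), walk(d$part2)))
    }
    deriv <- walk(instance@meta$rootKey)
    terminals <- sort(unique(vapply(st$es[st$base], function(e) substring(.esSplit(e)[1L], 3L),
                                    character(1))), method = "radix")
    start <- esOf[[instance@meta$rootKey]]
  }
  rules <- unique(do.call(rbind, rules))
  rules <- rules[order(rules$kind, rules$lhs, method = "radix"), , drop = FALSE]
  rownames(rules) <- NULL
  new("Grammar", kind = kind, terminals = terminals, start = start,
      rules = rules, derivation = deriv,
      info = list(objective = result@objective, solver = result@stats,
                  method = "ip"))
}

#' @rdname nonterminalCount
#' @export
setMethod("nonterminalCount", "Grammar", function(g) length(unique(g@rules$lhs)))

#' @rdname grammarSize
#' @export
setMethod("grammarSize", "Grammar", function(g)
  sum(ifelse(g@rules$kind %in% c("CFG2", "R2", "R3"), 2L, 1L)))

setMethod("show", "Grammar", function(object) {
  bin <- object@rules$kind %in% c("CFG2", "R2", "R3")
  cat(sprintf("%s grammar: %d nonterminals (%d binary rules + %d terminal classes), size %d\n",
              toupper(object@kind), nonterminalCount(object),
              length(unique(object@rules$lhs[bin])),
              length(unique(object@rules$lhs[!bin])), grammarSize(object)))
  cat("start: ", .prettyKey(object@start, object@kind), "\n", sep = "")
  for (r in seq_len(nrow(object@rules))) {
    ru <- object@rules[r, ]
    if (ru$kind %in% c("CFG2", "R2", "R3"))
      cat(sprintf("  [%s] %s -> %s | %s\n", ru$kind,
                  .prettyKey(ru$lhs, object@kind),
                  .prettyKey(ru$rhs1, object@kind), .prettyKey(ru$rhs2, object@kind)))
    else
      cat(sprintf("  [%s] %s -> %s\n", ru$kind,
                  .prettyKey(ru$lhs, object@kind), ru$label))
  }
})

# expand a nonterminal class to its generated content (string or Euler tokens)
.expandClass <- function(g, cls, inProgress = character(0)) {
  if (cls %in% inProgress) stop("cyclic rules while expanding")
  rows <- which(g@rules$lhs == cls)
  if (!length(rows)) stop("unbound nonterminal during expansion: ", cls)
  ru <- g@rules[rows[1L], ]
  if (ru$kind == "CFG1") return(ru$label)
  if (ru$kind == "CFG2")
    return(paste0(.expandClass(g, ru$rhs1, c(inProgress, cls)),
                  .expandClass(g, ru$rhs2, c(inProgress, cls))))
  if (ru$kind == "R1u") return(c(.tokOpen(ru$label), .tokClose(ru$label)))
  if (ru$kind == "R1t") return(c(.tokOpen(ru$label), .tokTag, .tokClose(ru$label)))
  e1 <- .expandClass(g, ru$rhs1, c(inProgress, cls))
  e2 <- .expandClass(g, ru$rhs2, c(inProgress, cls))
  if (ru$kind == "R2") return(c(e1, e2))
  pos <- match(.tokTag, e1)                      # R3: attach lower part at the tag
  if (is.na(pos)) stop("vertical rule whose upper part has no tag: ", cls)
  append(e1[-pos], e2, after = pos - 1L)
}

#' Verify that a grammar regenerates its input
#'
#' Expands the start symbol using only the production rules and compares the
#' result with the input: character-for-character for strings, by Euler
#' string for ordered trees, and by canonical Euler string for unordered
#' trees. Raises an error if expansion meets a nonterminal with no rule.
#'
#' @param g a [Grammar-class]
#' @param input the original string or [LabeledTree-class]
#' @return logical
#' @export
verifyRoundtrip <- function(g, input) {
  expanded <- .expandClass(g, g@start)
  if (g@kind == "cfg") return(identical(expanded, input))
  stopifnot(is(input, "LabeledTree"))
  if (g@kind == "seotg")
    return(identical(.esJoin(expanded), esKey(eulerString(input))))
  parsed <- parseEulerString(.esJoin(expanded))
  identical(esKey(canonicalEulerString(parsed$tree)),
            esKey(canonicalEulerString(input)))
}

#' Serialize a grammar to a structured JSON document
#'
#' Loss-free, stably ordered (rules are sorted) and diffable; [readGrammar()]
#' restores an identical [Grammar-class].
#'
#' @param g a [Grammar-class]
#' @param path file path
#' @return `writeGrammar` invisibly returns `path`; `readGrammar` the Grammar.
#' @export
writeGrammar <- function(g, path) {
  doc <- list(kind = g@kind, terminals = g@terminals, start = g@start,
              rules = g@rules, derivation = g@derivation,
              pretty = list(start = .prettyKey(g@start, g@kind),
                            nonterminals = unname(.prettyKey(unique(g@rules$lhs), g@kind))),
              metrics = list(nonterminals = nonterminalCount(g), size = grammarSize(g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeGrammar
#' @export
readGrammar <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  rules <- do.call(rbind, lapply(doc$rules, function(r)
    data.frame(lhs = chr(r$lhs), kind = chr(r$kind), rhs1 = chr(r$rhs1),
               rhs2 = chr(r$rhs2), label = chr(r$label))))
  fixNode <- function(nd) {
    list(index = nd$index, class = nd$class,
         children = if (length(nd$children)) lapply(nd$children, fixNode) else list())
  }
  new("Grammar", kind = doc$kind,
      terminals = vapply(doc$terminals, as.character, character(1)),
      start = doc$start, rules = rules, derivation = fixNode(doc$derivation),
      info = list())
}
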