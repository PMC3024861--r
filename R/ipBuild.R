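# ---- constraint assembler ------------------------------------------------------

.ipBuilder <- function(nVar) {
  env <- new.env(parent = emptyenv())
  env$ri <- env$ci <- env$vv <- list(); env$lb <- env$ub <- numeric(0)
  env$row <- 0L
  env$add <- function(cols, coefs, lb, ub) {
    env$row <- env$row + 1L
    env$ri[[env$row]] <- rep.int(env$row, length(cols))
    env$ci[[env$row]] <- cols
    env$vv[[env$row]] <- coefs
    env$lb[env$row] <- lb; env$ub[env$row] <- ub
  }
  env$matrix <- function() {
    Matrix::sparseMatrix(i = unlist(env$ri), j = unlist(env$ci), x = unlist(env$vv),
                         dims = c(env$row, nVar))
  }
  env
}

.newIP <- function(builder, obj, maximize, vars, meta) {
  new("IPInstance", obj = obj, A = builder$matrix(),
      rowlb = builder$lb, rowub = builder$ub,
      maximize = maximize, vars = vars, meta = meta)
}

setMethod("show", "IPInstance", function(object) {
  k <- table(object@vars$kind)
  cat(sprintf("IPInstance (%s, %s): %d variables (x=%d, y=%d, z=%d), %d constraints\n",
              object@meta$kind, object@meta$objective,
              nrow(object@vars), k[["x"]], sum(object@vars$kind == "y"),
              sum(object@vars$kind == "z"), nrow(object@A)))
  if (!is.null(object@meta$m)) cat(sprintf("  nonterminal budget m = %d (%s)\n",
                                           object@meta$m, object@meta$budgetMode))
})

.checkBudget <- function(m, objective) {
  if (objective == "feasibility") {
    if (is.null(m) || m < 1L) stop("budget m must be a positive integer")
    as.integer(m)
  } else NULL
}

# ---- string IP -----------------------------------------------------------------

#' Integer program for the minimum simple CFG of a string
#'
#' Builds the 0/1 program whose feasibility (the root variable attaining 1)
#' is equivalent to the existence of a simple CFG with at most `m`
#' nonterminals generating exactly `s`. Variables: `x[i,j]` (substring
#' `s[i..j]` is generated by some nonterminal), `y[i,k,j]` (it is generated by
#' concatenating `s[i..k]` and `s[k+1..j]`), `z[u]` (a nonterminal generating
#' `u` is used). Constraints: every single character is generated; every
#' generated multi-character span is covered by at least one active split
#' (`x <= sum y`); an active split requires both parts (`2y <= x + x`, the
#' linearization of the "iff", which preserves the optimum because `y` is only
#' pushed up by the coverage constraint); spans generating the same substring
#' share one nonterminal (`x <= z`); and at most `m` (or, with
#' `budgetMode = "eq"`, exactly `m`) nonterminal classes are used. With
#' `objective = "minimize"` the budget row is dropped, the root variable is
#' fixed to 1 and the sum of `z` is minimized instead, so one solve yields the
#' minimum nonterminal count directly. The budget is written `<=` by default:
#' any solution can be padded with unused classes, so feasibility is monotone
#' in `m`.
#'
#' @param s character scalar
#' @param m nonterminal budget (required for `objective = "feasibility"`)
#' @param budgetMode `"le"` (default) or `"eq"`
#' @param objective `"feasibility"` (maximize the root variable) or
#'   `"minimize"` (minimize the number of used classes)
#' @return an [IPInstance-class]
#' @export
buildStringIP <- function(s, m = NULL, budgetMode = c("le", "eq"),
                          objective = c("feasibility", "minimize")) {
  objective <- match.arg(objective); budgetMode <- match.arg(budgetMode)
  m <- .checkBudget(m, objective)
  spans <- enumerateSubstrings(s)
  n <- nchar(s)
  spans$key <- paste(spans$i, spans$j, sep = ",")
  ydef <- do.call(rbind, lapply(which(spans$j > spans$i), function(r) {
    i <- spans$i[r]; j <- spans$j[r]
    data.frame(i = i, k = i:(j - 1L), j = j)
  }))
  if (is.null(ydef)) ydef <- data.frame(i = integer(0), k = integer(0), j = integer(0))
  zclass <- unique(spans$sub)
  vars <- data.frame(
    name = c(paste0("x_", spans$i, "_", spans$j),
             if (nrow(ydef)) paste0("y_", ydef$i, "_", ydef$k, "_", ydef$j),
             paste0("z_", seq_along(zclass))),
    kind = rep(c("x", "y", "z"), c(nrow(spans), nrow(ydef), length(zclass))),
    key = c(spans$key,
            if (nrow(ydef)) paste(ydef$i, ydef$k, ydef$j, sep = ","),
            zclass))
  xCol <- stats::setNames(seq_len(nrow(spans)), spans$key)
  yCol <- if (nrow(ydef)) stats::setNames(nrow(spans) + seq_len(nrow(ydef)),
                                          paste(ydef$i, ydef$k, ydef$j, sep = ",")) else integer(0)
  zCol <- stats::setNames(nrow(spans) + nrow(ydef) + seq_along(zclass), zclass)
  b <- .ipBuilder(nrow(vars))
  for (i in seq_len(n)) b$add(xCol[paste(i, i, sep = ",")], 1, 1, 1)          # (1)
  for (r in which(spans$j > spans$i)) {                                        # (2)
    i <- spans$i[r]; j <- spans$j[r]
    ks <- yCol[paste(i, i:(j - 1L), j, sep = ",")]
    b$add(c(xCol[spans$key[r]], ks), c(1, rep(-1, length(ks))), -Inf, 0)
  }
  if (nrow(ydef)) for (r in seq_len(nrow(ydef))) {                             # (3)
    i <- ydef$i[r]; k <- ydef$k[r]; j <- ydef$j[r]
    b$add(c(yCol[paste(i, k, j, sep = ",")],
            xCol[paste(i, k, sep = ",")], xCol[paste(k + 1L, j, sep = ",")]),
          c(2, -1, -1), -Inf, 0)
  }
  for (r in seq_len(nrow(spans)))                                              # (4)
    b$add(c(xCol[spans$key[r]], zCol[spans$sub[r]]), c(1, -1), -Inf, 0)
  if (objective == "feasibility") {
    b$add(unname(zCol), rep(1, length(zCol)),                                  # (5)
          if (budgetMode == "eq") m else -Inf, m)
    obj <- numeric(nrow(vars)); obj[xCol[paste(1L, n, sep = ",")]] <- 1
    maximize <- TRUE
  } else {
    b$add(xCol[paste(1L, n, sep = ",")], 1, 1, 1)
    obj <- numeric(nrow(vars)); obj[zCol] <- 1
    maximize <- FALSE
  }
  .newIP(b, obj, maximize, vars,
         meta = list(kind = "cfg", objective = objective, m = m,
                     budgetMode = budgetMode, input = s, n = n,
                     spans = spans, rootVar = unname(xCol[paste(1L, n, sep = ",")]),
                     rootKey = paste(1L, n, sep = ","),
                     forcedClasses = unique(spans$sub[spans$i == spans$j]),
                     nClasses = length(zclass)))
}

# ---- tree IPs ------------------------------------------------------------------

.buildTreeIP <- function(tree, enum, m, budgetMode, objective,
                         forceTaggedTerminals, kind) {
  st <- enum$subtrees; dv <- enum$divisions
  zclass <- unique(st$es)
  vars <- data.frame(
    name = c(paste0("x", seq_len(nrow(st))),
             if (nrow(dv)) paste0("y", seq_len(nrow(dv))),
             paste0("z", seq_along(zclass))),
    kind = rep(c("x", "y", "z"), c(nrow(st), nrow(dv), length(zclass))),
    key = c(st$key, dv$key, zclass))
  xCol <- stats::setNames(seq_len(nrow(st)), st$key)
  yCol <- if (nrow(dv)) stats::setNames(nrow(st) + seq_len(nrow(dv)), dv$key) else integer(0)
  zCol <- stats::setNames(nrow(st) + nrow(dv) + seq_along(zclass), zclass)
  b <- .ipBuilder(nrow(vars))
  for (r in which(st$base)) {                                                  # (1u,t)
    if (is.na(st$t[r]) || forceTaggedTerminals)
      b$add(xCol[st$key[r]], 1, 1, 1)
  }
  divByParent <- if (nrow(dv)) split(seq_len(nrow(dv)), dv$parent) else list()
  for (r in which(!st$base)) {                                                 # (2)
    ds <- divByParent[[st$key[r]]]
    b$add(c(xCol[st$key[r]], yCol[dv$key[ds]]), c(1, rep(-1, length(ds))), -Inf, 0)
  }
  if (nrow(dv)) for (r in seq_len(nrow(dv)))                                   # (3)
    b$add(c(yCol[dv$key[r]], xCol[dv$part1[r]], xCol[dv$part2[r]]),
          c(2, -1, -1), -Inf, 0)
  for (r in seq_len(nrow(st)))                                                 # (4)
    b$add(c(xCol[st$key[r]], zCol[st$es[r]]), c(1, -1), -Inf, 0)
  rootKey <- if (enum$mode == "ordered") {
    ch <- childrenOf(tree, 1L)
    .keyOrd(1L, NA_integer_, ch[1L], ch[length(ch)])
  } else .keyUno(1L, NA_integer_, childrenOf(tree, 1L))
  if (objective == "feasibility") {
    b$add(unname(zCol), rep(1, length(zCol)),                                  # (5)
          if (budgetMode == "eq") m else -Inf, m)
    obj <- numeric(nrow(vars)); obj[xCol[rootKey]] <- 1
    maximize <- TRUE
  } else {
    b$add(xCol[rootKey], 1, 1, 1)
    obj <- numeric(nrow(vars)); obj[zCol] <- 1
    maximize <- FALSE
  }
  forced <- unique(st$es[st$base & (is.na(st$t) | forceTaggedTerminals)])
  .newIP(b, obj, maximize, vars,
         meta = list(kind = kind, objective = objective, m = m,
                     budgetMode = budgetMode, mode = enum$mode,
                     subtrees = st, divisions = dv,
                     rootVar = unname(xCol[rootKey]), rootKey = rootKey,
                     forcedClasses = forced, nClasses = length(zclass),
                     forceTaggedTerminals = forceTaggedTerminals))
}

#' Integer programs for minimum simple tree grammars
#'
#' `buildOrderedIP` targets simple elementary ordered tree grammars (SEOTG),
#' `buildUnorderedIP` simple elementary unordered tree grammars (SEUTG).
#' Variables come from [enumerateOrdered()] / [enumerateUnordered()]: `x` per
#' candidate subtree index, `y` per horizontal or vertical division, `z` per
#' distinct (canonical) Euler string class. Constraints mirror the string
#' program: every single untagged leaf edge — and, by default, every single
#' tagged internal edge — is forced to be generated; every active non-base
#' subtree needs an active division whose two parts are active; subtrees with
#' equal (canonical) Euler strings share one `z` class; the number of classes
#' used is bounded by `m`. Forcing tagged terminal edges follows the literal
#' reading of the base constraints and is exposed as
#' `forceTaggedTerminals`; both settings give the same minimum because every
#' complete derivation ends in exactly those single edges.
#'
#' @param tree a [LabeledTree-class]
#' @param maxDegree degree guard for the unordered child-subset enumeration
#' @param forceTaggedTerminals force `x = 1` for single tagged internal edges
#' @inheritParams buildStringIP
#' @return an [IPInstance-class]
#' @export
buildOrderedIP <- function(tree, m = NULL, budgetMode = c("le", "eq"),
                           objective = c("feasibility", "minimize"),
                           forceTaggedTerminals = TRUE) {
  objective <- match.arg(objective); budgetMode <- match.arg(budgetMode)
  m <- .checkBudget(m, objective)
  .buildTreeIP(tree, enumerateOrdered(tree), m, budgetMode, objective,
               forceTaggedTerminals, "seotg")
}

#' @rdname buildOrderedIP
#' @export
buildUnorderedIP <- function(tree, m = NULL, budgetMode = c("le", "eq"),
                             objective = c("feasibility", "minimize"),
                             forceTaggedTerminals = TRUE, maxDegree = 16L) {
  objective <- match.arg(objective); budgetMode <- match.arg(budgetMode)
  m <- .checkBudget(m, objective)
  .buildTreeIP(tree, enumerateUnordered(tree, maxDegree = maxDegree), m,
               budgetMode, objective, forceTaggedTerminals, "seutg")
}
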