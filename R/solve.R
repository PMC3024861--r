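# ---- solver backend ------------------------------------------------------------

.pythonBin <- function(python = NULL) {
  cand <- c(python, getOption("treegram.python"),
            Sys.getenv("TREEGRAM_PYTHON", ""), "python3", "python")
  cand <- cand[nzchar(cand)]
  for (p in cand) {
    path <- Sys.which(p)
    if (nzchar(path) || file.exists(p)) return(if (nzchar(path)) path else p)
  }
  stop("no python interpreter found for the HiGHS backend; ",
       "set options(treegram.python = ...) or TREEGRAM_PYTHON")
}

.solverScript <- function() {
  p <- system.file("python", "milp_solve.py", package = "treegram")
  if (!nzchar(p)) p <- file.path("inst", "python", "milp_solve.py")  # source tree
  if (!file.exists(p)) stop("solver bridge script not found")
  p
}

#' Solve a minimum-grammar integer program exactly
#'
#' Dispatches the 0/1 program to the HiGHS branch-and-bound solver (exact,
#' single-threaded, zero MIP gap) through the SciPy interface of the `python`
#' interpreter on the PATH. The backend is deterministic for a fixed problem;
#' `seed` is recorded in the statistics for provenance but does not influence
#' the result. A hit time limit is reported as status `"timeout"`, distinct
#' from `"infeasible"`.
#'
#' In feasibility mode the program itself is optimal whenever the budget
#' admits the forced terminal classes; whether a grammar with the budget
#' exists is read off the root variable (see [ipFeasible()]).
#'
#' @param instance an [IPInstance-class]
#' @param timeLimit seconds, `Inf` for none
#' @param seed integer, logged only (the backend is deterministic)
#' @param python optional path to a python interpreter with SciPy
#' @return a [SolveResult-class]
#' @export
solveIP <- function(instance, timeLimit = Inf, seed = 1L, python = NULL) {
  bin <- .pythonBin(python)
  tri <- as(instance@A, "TsparseMatrix")
  inf <- 1e30
  prob <- list(
    n = ncol(instance@A), m = nrow(instance@A),
    obj = instance@obj, maximize = instance@maximize,
    Ai = tri@i + 1L, Aj = tri@j + 1L, Av = tri@x,
    rowlb = pmax(instance@rowlb, -inf), rowub = pmin(instance@rowub, inf),
    timeLimit = if (is.finite(timeLimit)) timeLimit else NULL)
  infile <- tempfile(fileext = ".json"); outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(prob, infile, auto_unbox = TRUE, digits = NA, null = "null")
  t0 <- proc.time()[["elapsed"]]
  out <- suppressWarnings(system2(bin, c(shQuote(.solverScript()),
                                         shQuote(infile), shQuote(outfile)),
                                  stdout = TRUE, stderr = TRUE))
  code <- attr(out, "status")
  if (!is.null(code) && code != 0L)
    stop("solver backend failed: ", paste(out, collapse = "\n"))
  res <- jsonlite::read_json(outfile, simplifyVector = TRUE)
  wall <- proc.time()[["elapsed"]] - t0
  if (identical(res$status, "error"))
    stop("solver backend error: ", res$message)
  assignment <- if (!is.null(res$x)) stats::setNames(as.numeric(res$x), instance@vars$name)
                else stats::setNames(numeric(0), character(0))
  new("SolveResult",
      status = res$status,
      assignment = assignment,
      objective = if (!is.null(res$objective)) as.numeric(res$objective) else NA_real_,
      stats = list(backend = "highs/scipy", wallTime = wall, seed = as.integer(seed),
                   message = res$message, nVars = ncol(instance@A),
                   nConstraints = nrow(instance@A)))
}

setMethod("show", "SolveResult", function(object) {
  cat(sprintf("SolveResult: %s", object@status))
  if (!is.na(object@objective)) cat(sprintf(", objective = %g", object@objective))
  cat(sprintf(" (%.3fs, %s)\n", object@stats$wallTime, object@stats$backend))
})

#' Did the budgeted program admit a grammar?
#'
#' A feasibility-mode program is "infeasible at budget m" either when the
#' program itself is infeasible (the forced terminal classes alone exceed the
#' budget) or when it is optimal with the root variable at 0.
#'
#' @param result a [SolveResult-class]
#' @param instance the [IPInstance-class] it solved
#' @return logical
#' @export
ipFeasible <- function(result, instance) {
  result@status == "optimal" &&
    result@assignment[[instance@meta$rootVar]] > 0.5
}

# ---- minimum search ------------------------------------------------------------

.buildFor <- function(input, mode, m, budgetMode, objective,
                      forceTaggedTerminals, maxDegree) {
  switch(mode,
    cfg = buildStringIP(input, m = m, budgetMode = budgetMode, objective = objective),
    seotg = buildOrderedIP(input, m = m, budgetMode = budgetMode, objective = objective,
                           forceTaggedTerminals = forceTaggedTerminals),
    seutg = buildUnorderedIP(input, m = m, budgetMode = budgetMode, objective = objective,
                             forceTaggedTerminals = forceTaggedTerminals,
                             maxDegree = maxDegree))
}

#' Minimum number of nonterminals for a string or tree
#'
#' Finds the smallest `m` for which a simple CFG (`mode = "cfg"`), simple
#' EOTG (`"seotg"`) or simple EUTG (`"seutg"`) with `m` nonterminals generates
#' exactly the input. Two search strategies are provided and agree on every
#' input: `"minimize"` (default) solves once, minimizing the number of used
#' nonterminal classes with the root variable fixed to 1; `"probe"` runs
#' budgeted feasibility solves, exploiting that feasibility is monotone in the
#' budget, between the lower bound forced by the terminal classes and the
#' total number of candidate classes.
#'
#' @param input character scalar (for `"cfg"`) or [LabeledTree-class]
#' @param mode `"cfg"`, `"seotg"` or `"seutg"`
#' @param method `"minimize"` or `"probe"`
#' @param budgetMode budget row sense for probe mode, `"le"` or `"eq"`
#' @param forceTaggedTerminals see [buildOrderedIP()]
#' @param maxDegree degree guard for unordered enumeration
#' @param timeLimit per-solve limit in seconds (`Inf` for none); a timeout is
#'   propagated as an error carrying the best known bounds
#' @param seed integer recorded with the solver statistics
#' @param python optional python interpreter path
#' @return list with `m` (integer), `result` ([SolveResult-class] whose root
#'   variable is active at the optimum), `instance` (the solved
#'   [IPInstance-class]) and `probes` (number of solves performed)
#' @examples
#' \donttest{
#' findMinimumM("abcabcab", mode = "cfg")$m   # 7
#' }
#' @export
findMinimumM <- function(input, mode = c("cfg", "seotg", "seutg"),
                         method = c("minimize", "probe"),
                         budgetMode = c("le", "eq"),
                         forceTaggedTerminals = TRUE, maxDegree = 16L,
                         timeLimit = Inf, seed = 1L, python = NULL) {
  mode <- match.arg(mode); method <- match.arg(method)
  budgetMode <- match.arg(budgetMode)
  if (mode == "cfg") stopifnot(is.character(input), length(input) == 1L)
  else stopifnot(is(input, "LabeledTree"))
  if (method == "minimize") {
    inst <- .buildFor(input, mode, NULL, budgetMode, "minimize",
                      forceTaggedTerminals, maxDegree)
    res <- solveIP(inst, timeLimit = timeLimit, seed = seed, python = python)
    if (res@status == "timeout")
      stop("solver timed out; best bound unavailable in minimize mode")
    if (res@status != "optimal") stop("unexpected solver status: ", res@status)
    return(list(m = as.integer(round(res@objective)), result = res,
                instance = inst, probes = 1L))
  }
  # probe mode: binary search on the budget between the forced lower bound and
  # the total class count (always feasible)
  probe <- .buildFor(input, mode, 1L, budgetMode, "feasibility",
                     forceTaggedTerminals, maxDegree)
  lo <- length(probe@meta$forcedClasses)
  hi <- probe@meta$nClasses
  best <- NULL; bestM <- NA_integer_; probes <- 0L
  while (lo < hi) {
    mid <- lo + (hi - lo) %/% 2L
    inst <- .buildFor(input, mode, mid, budgetMode, "feasibility",
                      forceTaggedTerminals, maxDegree)
    res <- solveIP(inst, timeLimit = timeLimit, seed = seed, python = python)
    probes <- probes + 1L
    if (res@status == "timeout")
      stop(sprintf("solver timed out probing m = %d (feasible <= %d, infeasible < %d)",
                   mid, hi, lo))
    if (ipFeasible(res, inst)) {
      hi <- mid; best <- list(result = res, instance = inst); bestM <- mid
    } else lo <- mid + 1L
  }
  if (is.na(bestM) || bestM != lo) {
    inst <- .buildFor(input, mode, lo, budgetMode, "feasibility",
                      forceTaggedTerminals, maxDegree)
    res <- solveIP(inst, timeLimit = timeLimit, seed = seed, python = python)
    probes <- probes + 1L
    if (!ipFeasible(res, inst)) stop("internal error: budget search lost feasibility")
    best <- list(result = res, instance = inst)
  }
  list(m = as.integer(lo), result = best$result, instance = best$instance,
       probes = probes)
}
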