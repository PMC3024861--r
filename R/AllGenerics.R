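#' @rdname LabeledTree-class
#' @param x a `LabeledTree`
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname LabeledTree-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' Number of nonterminal symbols of a grammar
#'
#' Counts distinct nonterminals the way grammar sizes are reported in the
#' tables: the number of distinct binary-rule left-hand sides plus the number
#' of distinct terminal classes used (a tagged and an untagged occurrence of
#' the same label are distinct classes because their Euler strings differ).
#' Because nonterminals are content-addressed this is simply the number of
#' distinct rule left-hand sides.
#'
#' @param g a [Grammar-class]
#' @return integer
#' @export
setGeneric("nonterminalCount", function(g) standardGeneric("nonterminalCount"))

#' Alternative grammar size: total letters on rule right-hand sides
#'
#' @param g a [Grammar-class]
#' @return integer (binary rules contribute 2, terminal rules 1)
#' @export
setGeneric("grammarSize", function(g) standardGeneric("grammarSize"))
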