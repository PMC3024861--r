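---
title: "Exact minimum tree grammars by integer programming: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact minimum tree grammars by integer programming: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the grammars

`treegram` computes, exactly, the smallest *simple* grammar generating a given
string or rooted edge-labeled tree. "Simple" restricts rules to two shapes —
terminal (`A -> a`) and binary — and the size measure is the number of distinct
nonterminal symbols `m`; the terminal rules needed are fixed by the input's
alphabet, so `m` is the quantity worth minimizing. An alternative metric, total
letters on rule right-hand sides, is reported by `grammarSize()` but plays no
role in the optimization.

For trees the binary rules are the elementary tree-grammar operations:

* **horizontal** (`R2`): split a subtree at its root into two groups of child
  subtrees — consecutive spans for ordered trees, arbitrary nonempty subsets
  for unordered trees;
* **vertical** (`R3`): cut at an internal vertex `t`, leaving an upper part in
  which `t` becomes a *tag* (a marked attachment vertex, at most one per tree)
  and a lower part consisting of `t`'s full subtree.

A grammar that generates exactly one tree corresponds one-to-one to a
recursive division of that tree by these moves; the package searches over all
such divisions.

## Subtree identification: Euler strings

Two subtrees may share a nonterminal exactly when they are isomorphic, so
isomorphism classes must be computable. Every (possibly tagged) ordered
subtree is serialized depth-first, emitting its edge label on descent and a
matched *closing token* on ascent; a tagged edge labeled `A` serializes as
`A x A-close`. Closing tokens are distinct tokens carrying a close flag, not
decorated label strings, so arbitrary alphabets are safe; keys join tokens
with reserved control bytes that labels may not contain (enforced by the
`LabeledTree` validity method). Equality of Euler strings is equality of
ordered subtrees.

For unordered trees the Euler string is taken after canonicalization: the
children of every vertex are sorted recursively by the canonical key of their
own edge-subtree, with the tag-bearing child moved to the front. Sorting by
the full recursive key rather than by the top edge label alone matters: when
two children share a label, only the subtree below distinguishes them, and a
label-only sort would not be a canonical form. Sorting uses radix (C-locale)
order so results are independent of the session locale. The form is
idempotent, and tests verify agreement with a brute-force isomorphism check
(all child orderings) on random trees.

The tag sentinel for "untagged" is `NA` in the index classes
(`OrderedSubtree`, `UnorderedSubtree`) and a dedicated argument default
(`tag = NULL`) in user-facing constructors; no magic vertex id is exposed.
Vertices are numbered 1..n in preorder with the root at 1, matching the
conventions of the worked examples.

## Candidate enumeration

Only subtree indices reachable by divisions from the whole tree can occur in
a derivation, so enumeration runs top-down as a worklist closure instead of
generating all index tuples. Two readings needed fixing where the defining
description is ambiguous:

* *Horizontal division of a tagged subtree.* The tag stays on exactly the one
  part whose children contain it; anything else would create a two-tag tree,
  which the grammar class forbids.
* *Base elements.* Divisions terminate at single edges: untagged leaf edges
  and tagged edges at internal vertices. A tag never lands on a leaf — vertical
  divisions only place tags at internal vertices — so "tagged leaf edges" are
  unreachable and are not generated.

On the built-in 6-vertex example this yields 9 horizontal + 4 vertical
divisions over 13 candidate indices (ordered) and 12 + 4 over 14 candidate
indices (unordered); the acceptance tests pin these counts. Unordered
horizontal splits are generated as *unordered* pairs of child subsets (the
part containing the smallest child is listed first); ordered pairs would
double-count every division.

Because the number of child subsets grows as `2^degree`, unordered
enumeration refuses trees whose maximum out-degree exceeds a configurable
guard (default 16), naming the offending vertex. This mirrors the observed
practical limit of the unordered method on high-degree trees; the ordered
method remains available there.

## The integer programs

Variables: `x` per candidate span/subtree index ("this piece is generated by
some nonterminal"), `y` per split/division ("generated this way"), `z` per
distinct substring or canonical Euler string ("this nonterminal class is
used"). Constraints (1)–(5) are described in the README; two formulation
choices deserve a note.

* **The budget row is `sum z <= m`, not `= m`.** Any grammar can be padded
  with unused classes, so the two readings admit the same minima, but with
  `<=` feasibility is monotone in `m`, which the probe search exploits and a
  property test asserts. `budgetMode = "eq"` restores the literal equality.
* **The split "iff" is linearized one-directionally** as
  `2y <= x_left + x_right` together with the coverage row `x <= sum y`.
  The dropped direction (both parts active forces `y = 1`) never changes
  feasibility or the optimum: `y` is only ever needed where coverage pushes
  it up.
* **Forced terminals.** Single untagged leaf edges are forced to 1; single
  tagged internal edges are forced too by default
  (`forceTaggedTerminals = TRUE`, the literal reading of the base
  constraints). The flag exists because the forcing is logically redundant —
  every complete derivation terminates in exactly those single edges — and
  tests confirm both settings give identical minima.

`findMinimumM()` offers two equivalent searches: a single solve minimizing
`sum z` subject to the root variable fixed at 1 (default; one solver call),
and budgeted feasibility probes by binary search between the forced-class
lower bound and the total class count. Agreement of the two modes is tested.

## Solver backend

The solver is deliberately a pluggable contract rather than part of the
method: any backend providing exact 0/1 branch-and-bound satisfies it. The
package ships a thin bridge that writes the program as JSON and solves it
with HiGHS through SciPy's `scipy.optimize.milp`, using the `python`
interpreter on the PATH (configurable via `options(treegram.python = ...)`) —
chosen for exact optimality proofs, determinism, and availability alongside
R without compiled dependencies in the package itself. The backend runs single-threaded with a
zero MIP gap; it is deterministic for a fixed instance, so the `seed`
argument is recorded for provenance but cannot alter results. Time limits are
passed through, and a hit limit is reported as status `"timeout"`, distinct
from `"infeasible"` (which, in feasibility mode, arises exactly when the
forced terminal classes already exceed the budget; a budget that is merely
too small for the whole tree shows as an optimal solve with the root variable
at 0).

## Grammar reconstruction and verification

Extraction walks the solution top-down, choosing among active divisions with
a fixed preference (horizontal first, then smallest split index or
lexicographically smallest subset) purely for determinism — any active choice
yields a minimum grammar, and the tests assert counts and regeneration, never
one specific rule set, because optima are routinely non-unique (the built-in
string example has several minimum grammars). Nonterminals are
content-addressed by the generated substring or canonical Euler string, which
makes merging trivial and order-independent; `nonterminalCount()` is then
simply the number of distinct rule left-hand sides, equal to distinct
binary-rule heads plus distinct terminal classes (a tagged and an untagged
edge of the same label are different classes). `verifyRoundtrip()` re-derives
the input from the start symbol using only the rules — substituting the lower
part at the tag marker for vertical rules — and compares Euler strings
(canonical ones in unordered mode); every extracted grammar must pass it.

Patterns (`extractRepeats()`) are nonterminals expanded at least twice in the
recorded derivation. Counting in the derivation rather than the rule set
makes occurrences non-overlapping by construction (derivation leaves
partition the input's edges) and matches the intended reading of "contains k
of the same subtrees". Tagged nonterminals are reported too, flagged, since
repeated contexts are themselves informative.

## TREE-BISECTION baseline

The baseline repeatedly applies the division that makes the two parts' edge
counts most similar (ties: horizontal, then leftmost), recursing until single
edges remain. The original algorithm is specified elsewhere only at this
level of detail, so this implementation fixes tie-breaking and balances
*edge* counts (vertex counts would differ by at most the tag bookkeeping);
consequently only its guaranteed properties are asserted — it regenerates the
input and never beats the exact minimum — not any specific published size.

## Study inputs and the synthetic generator

* `exampleSixVertexTree()` — the worked example (`a`,`b` edges at both ends of
  a `c` edge); minimum 7 ordered / 6 unordered, recomputed by the acceptance
  tests.
* `typeAPath(n)` — single-label paths (max degree 2). The 11-vertex path
  needs 7 nonterminals in both modes (tagged path segments of lengths 1, 2,
  4, 8 form the doubling backbone).
* `typeBTree(degree, leavesPerChild = 2)` — height-two trees with labels
  alternating `a`/`b`. The published family is shown only as a drawing; with
  the default two leaves per child the generator reproduces its vertex counts
  (1 + d + 2d) for degrees 6 through 20, and is documented as a
  reconstruction: no acceptance-grade quantity depends on it.
* `randomLabeledTree(n, labels)` — uniform random recursive trees with i.i.d.
  edge labels, used for property tests. This emulates small, irregular,
  moderately deep topologies with label repetition; it does not emulate real
  glycan data (biased branching, degree ≤ 4, sugar-specific label
  frequencies), so passing property tests demonstrates correctness of the
  machinery, not biological performance.
* KCF glycan records are read from disk with the reducing end (node 1) as
  root and edges labeled by the child monosaccharide. Letters are assigned in
  deterministic first-seen order and the name-to-letter table is returned:
  published letter assignments for individual glycans are mutually
  inconsistent across records, and grammar sizes are invariant under label
  renaming, so a global dictionary would add nothing but ambiguity.

## Problem sizes used by the test suite

Exhaustive checks run where exhaustion is cheap: all 126 strings over
`{a, b}` up to length 6 are compared against an independent brute-force
search (substring-set search with a closure check), as is every enumeration
count above. Tree oracle equivalence uses an independent
subset-plus-fixpoint search on a fixed-seed sample of random trees with up to
6 edges in both modes; the ordering/bisection dominance properties
(`unordered minimum <= ordered minimum <= bisection size`) run on 50 random
trees of up to 10 vertices. The suite completes in a few minutes on one CPU;
exact solves on paths beyond ~20 vertices or unordered trees of high degree
grow quickly (branch-and-bound over thousands of binary variables) and are
deliberately outside the default suite.

## Known limitations

* Inputs are single rooted trees; forests and cyclic structures are out of
  scope, as is inference of common grammars across multiple trees.
* The unordered formulation is exponential in vertex degree (the guard makes
  this an explicit refusal rather than a hang).
* Minimum grammars are reported as *one* optimal solution; enumerating all
  optima is not attempted.
* The CFG branch handles strings as atomic character sequences; there is no
  special handling of large alphabets or long inputs (the IP has
  `O(n^3)` `y`-variables).
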