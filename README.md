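# treegram

Exact minimum grammar-based compression of strings and rooted edge-labeled
trees, with repeated-subtree (motif) extraction for glycan-like structures.

Finding the smallest grammar that generates a given object is a classical,
NP-hard compression problem. `treegram` solves it *exactly*, by integer linear
programming, for three classes of simple grammars:

* **simple CFG** for strings — rules restricted to `A -> a` and `A -> BC`;
* **simple EOTG** (elementary ordered tree grammar) for rooted ordered trees
  with labeled edges — a terminal rule replaces a nonterminal edge by a
  labeled edge (`R1`), a horizontal rule splits a subtree at its root into two
  child spans (`R2`), and a vertical rule splits it at an internal vertex that
  becomes a *tag*, an attachment point for the lower part (`R3`);
* **simple EUTG** for rooted unordered trees — the same rules with child
  *sets* instead of spans, so isomorphic subtrees merge regardless of sibling
  order.

The compression measure is the number of distinct nonterminal symbols `m`.
Subtrees are identified up to isomorphism through **Euler strings** (depth-first
serializations with matched closing tokens; tagged edges carry an `x` marker),
canonicalized for unordered trees by recursively sorting children. Because
repeated subtrees collapse onto one nonterminal, the minimum grammar of a
glycan tree directly exposes its repeated structural motifs.

## The integer program

For a string `s` of length `n`, binary variables encode a grammar bottom-up:
`x[i,j] = 1` when some nonterminal generates the substring `s[i..j]`,
`y[i,k,j] = 1` when it is produced by concatenating `s[i..k]` and `s[k+1..j]`,
and `z[u] = 1` when a nonterminal generating the string `u` is used at all.
The constraints are

1. `x[i,i] = 1` — every character must be generated;
2. `x[i,j] <= sum_k y[i,k,j]` — every generated span is covered by a split;
3. `2 y[i,k,j] <= x[i,k] + x[k+1,j]` — a split requires both parts;
4. `x[i,j] <= z[u]` for `u = s[i..j]` — equal substrings share a nonterminal;
5. `sum_u z[u] <= m` — at most `m` nonterminals.

A grammar with `m` nonterminals exists iff `x[1,n]` can reach 1. The tree
programs are the same construction over candidate subtree indices
`T_{i,t,h,k}` (root `i`, tag `t`, child span `h..k`; child subset `C` in the
unordered case) with horizontal and vertical divisions in place of splits,
and `z` indexed by (canonical) Euler strings. Candidates are enumerated
top-down from the whole tree, so only indices reachable in a derivation
become variables. The minimum `m` is found either by a single solve
minimizing `sum z` with the root variable fixed (default) or by monotone
feasibility probes on the budget; both agree. Programs are solved exactly
with HiGHS (via SciPy's `milp`, single-threaded and deterministic).

Also included: the polynomial-time **TREE-BISECTION** baseline (balanced
recursive division; never better than the exact minimum), readers for plain
edge-list files and KEGG KCF glycan records, and generators for the built-in
study inputs.

## Worked example

The 6-vertex tree with edges (1,2)=a, (1,3)=c, (1,6)=b, (3,4)=a, (3,5)=b —
`a` and `b` edges attached to both endpoints of a `c` edge:

```r
library(treegram)
tr <- exampleSixVertexTree()
format(eulerString(tr))
#> [1] "a a' c a a' b b' c' b b'"

compressTree(tr, mode = "ordered")
#> SEOTG grammar: 7 nonterminals (4 binary rules + 3 terminal classes), size 11
#> start: a a' c a a' b b' c' b b'
#>   [R1t] c x c' -> c
#>   [R1u] a a' -> a
#>   [R1u] b b' -> b
#>   [R2] a a' b b' -> a a' | b b'
#>   [R2] a a' c a a' b b' c' -> a a' | c a a' b b' c'
#>   [R2] a a' c a a' b b' c' b b' -> a a' c a a' b b' c' | b b'
#>   [R3] c a a' b b' c' -> c x c' | a a' b b'
```

Ordered, 7 nonterminals are needed. Treating the tree as unordered lets the
two isomorphic subtrees (a root with one `a` child and one `b` child) share a
nonterminal, and the minimum drops to 6:

```r
gu <- compressTree(tr, mode = "unordered")
nonterminalCount(gu)
#> [1] 6
extractRepeats(gu, minVertices = 3)[, 1:4]
#>     pattern occurrences vertices edges
#> 1 a a' b b'           2        3     2
```

The repeated 3-vertex subtree is exactly the motif the grammar exposes. For
strings:

```r
nonterminalCount(compressString("abcabcab"))
#> [1] 7
```

A command-line wrapper ships in `inst/scripts/treegram`
(`treegram {string|tree|fixtures}`; exit codes 0 = ok, 2 = infeasible budget,
3 = timeout, 4 = input error).

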