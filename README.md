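# mixasm

Reference-free reconciliation ("mixing") of draft bacterial genome
assemblies.

## The problem

De novo assemblers fragment the same genome in different places: where one
draft breaks a contig, another often spans the breakpoint intact. When no
reference genome is available — the normal situation in a de novo project —
merging two or more drafts is one of the few ways to reduce fragmentation
(raise the N50, lower the contig count) without going back to the bench.
`mixasm` performs this merge symmetrically: no draft is privileged as
"master", no reads are required, only the drafts and the pairwise
alignments between their contigs (nucmer `show-coords -rcl -T` output or a
documented TSV dialect; a built-in simulator with exact ground-truth
alignments makes everything testable offline).

## The method

For contigs $C_i$, $C_j$ an alignment is a tuple
$\langle C_i, C_j, b_i, e_i, b_j, e_j, l\rangle$; only *terminal*
alignments — touching an extremity of both contigs — can glue contigs end
to end. After a five-rule cleanup (self alignments, reciprocal duplicates,
length $l \le t_a$, >99% containments, spurious high-count contigs), each
terminal alignment contributes eight vertices to a weighted *extension
graph*: per contig, the border and internal extremities of the alignment
footprint, each readable forward or reverse, plus global In/Out anchors.
Edge weights are bases contributed: contig remainders $|C|-l$ on the In/Out
edges, the overlap length $l$ on the cross-contig edge, inter-footprint
gaps (e.g. $|B| - l_\alpha - l_\gamma$) on edges joining two alignments
sharing a contig. Every In→Out path spells a merged contig whose length is
the path weight.

The output is a **maximal independent longest path set**: maximum-weight
simple In→Out paths extracted iteratively, each extraction forbidding the
vertices already used, so paths share at most In/Out. Cyclic graphs are
made acyclic first by expanding each strongly connected component into its
simple entry→exit paths. Paths are stitched into sequences (overlap bases
taken from the earlier contig; no consensus), and a coverage graph over the
result — edge from an element ≥90% contained in another, computed by
projecting the original alignments through the path layouts — drives the
removal of redundant elements.

## Worked example

Two simulated drafts of a 100 kb genome, five contigs each with staggered
breakpoints, merged end to end:

```r
library(mixasm)
set.seed(7)
spec <- sim_spec(genome_len = 100000L, n_assemblies = 2L, seed = 7)
sim  <- simulate_mix(spec)
res  <- mix_pipeline(sim$assemblies, sim$aset)
print(res$filter_report)
print(res$stats, row.names = FALSE)
```

which prints:

```
alignment filter: 9 in -> 7 out
  rule 1 self:        -0
  rule 2 reciprocal:  -0
  rule 3 short:       -0
  rule 4 contained:   -2
  rule 5 spurious:    -0 (0 contig(s))
 assembly n_contigs largest  total    n50
     sim1         5   23647 100000  19356
     sim2         5   22368 100000  19909
      mix         1  100000 100000 100000
```

Reading this: 9 ground-truth alignments went in; two were containments
(a contig of one draft lying entirely inside a contig of the other) and
were dropped by rule 4. The extension graph over the remaining 7 terminal
alignments admits a single longest path of weight 100,000 — the whole
genome — so the two 5-contig drafts (N50 ≈ 19–20 kb) merge into **one**
contig of 100,000 bases whose sequence equals the simulated genome exactly,
and every input contig is consumed or pruned (duplication ratio 1.0).

The same pipeline from the command line:

```sh
exec/mix sim --genome-len 100000 --outdir simout --seed 7
exec/mix run --out merged.fa simout/sim1.fa simout/sim2.fa simout/alignments.tsv
exec/mix stats merged.fa
```

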