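---
title: "Reconciling draft bacterial assemblies with mixasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling draft bacterial assemblies with mixasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixasm)
```

## The problem

De novo assemblers differ in their algorithmic foundations, and the same
read set assembled twice yields two drafts fragmented in different places.
When no reference genome exists, a finishing step that *merges* drafts can
recover contiguity that no single assembler achieved: where one draft
breaks, another often carries an intact contig across the breakpoint.
`mixasm` merges two or more drafts symmetrically (no master/slave
asymmetry and no reads needed), using only the drafts themselves and the
pairwise alignments between their contigs. The goal is to reduce
fragmentation — fewer, longer contigs, higher N50 — while keeping sequence
duplication close to the ideal ratio of 1.

## Model

### Alignments and terminality

A contig is an identifier plus a nucleotide sequence; the inputs are
combined after prefixing ids with their assembly label. An alignment
between contigs $C_i$ and $C_j$ is a tuple
$\langle C_i, C_j, b_i, e_i, b_j, e_j, l \rangle$ of footprint coordinates
(internally 0-based half-open, so $l = e_i - b_i$) plus a strand flag. Only
*terminal* alignments — those touching an extremity of **both** contigs —
can glue contigs end to end; internal alignments are ignored because the
merger does not second-guess the internal structure the assemblers
produced. An end tolerance `eps` (default 0: exact extremities) lets users
admit alignments that stop a few bases short of a contig end, as real
aligners often report.

### Cleaning rules

Before graph construction the alignment set is filtered by five ordered
rules: (1) self alignments are dropped; (2) of two reciprocal alignments
$\langle C_i,C_j\rangle$ / $\langle C_j,C_i\rangle$ covering the same
region, one is kept; (3) only alignments with $l > t_a$ survive (strict;
default $t_a = 200$ bases, chosen to exceed typical repeat-induced overlap
lengths in bacterial drafts and exposed as a tunable); (4) alignments
covering more than 99% of either contig are containments, not extension
overlaps, and are dropped (exactly 99% survives); (5) contigs aligned an
abnormally high number of times are spurious (typically repeats) and all
their alignments are dropped. Neither "same region" nor "abnormally high"
has a canonical definition; this package uses ≥ 50% reciprocal overlap of
the projected intervals on both contigs (a standard deduplication rule) and
a Tukey-style upper fence, count $> Q_3 + 3\,\mathrm{IQR}$ with
linear-interpolation quartiles, falling back to count $> 3 \times$ median
when the IQR is zero and flagging nothing when all counts are equal. Rule
5's distribution is computed on the set surviving rules 1–4.

### The extension graph

Every surviving terminal alignment contributes eight vertices: for each of
the two contigs, the two extremities of the alignment footprint — *border*
(the one at the contig end) and *internal* — each readable *forward* or
*reverse*. Two artificial vertices In and Out anchor paths. An In→Out path
spells a left-to-right walk over a merged sequence, and every edge carries
the number of bases it contributes:

* In/Out edges carry the leading/trailing remainder of the first/last
  contig;
* gray footprint edges (internal↔border within one contig) carry 0 — the
  overlap itself is charged once, by
* the turquoise cross-contig edge between the two border vertices, weighted
  $l$;
* orange edges connect two alignment footprints on a contig shared by two
  alignments, weighted by the gap between the footprints (for footprints
  $\alpha, \gamma$ on contig $B$ at opposite ends, $|B| - l_\alpha -
  l_\gamma$).

Which direction combinations are wired follows from requiring every walk to
read each contig consistently in one direction and to emit the two copies
of an overlap in the same strand: a forward alignment glues opposite
footprint sides (end-of-one onto start-of-the-other), a reverse alignment
glues equal sides. A terminal alignment whose side/strand geometry admits
no such dovetail (e.g. two forward prefixes) cannot glue anything and is
dropped with a count. By construction the graph is mirror-symmetric:
flipping every direction and swapping In/Out is an isomorphism, reflecting
that a merged contig and its reverse complement are the same object.

Two numerical choices matter here. First, path weight must equal merged
length (that is what "maximizing cumulative contig length" means), so an
orange edge is only added when the two footprints do not overlap in the
walk direction; clamping a negative gap to zero instead would let paths
claim overlap bases twice and actively attract the longest-path search to
them. Skipped overlapping-footprint transitions are counted and logged.
Second, with the end tolerance at 0 the In/Out remainders equal $|C| - l$
exactly; with `eps > 0` the actual remainder ($b$ or $|C|-e$) is used.

### Maximal independent longest path sets

The output paths are extracted greedily: repeatedly take a maximum-weight
simple In→Out path among vertices not used by earlier paths, until Out is
unreachable. Extracted paths are therefore pairwise vertex-independent
(sharing at most In/Out) and have non-increasing weights. Cycles — rare in
practice but possible — are handled by replacing each non-singleton
strongly connected component with one fresh chain per simple entry→exit
path inside it, tracked by a relabeling map back to original vertices; the
result is acyclic and amenable to the linear-time topological-order dynamic
program. Because two chains from the same component can represent
overlapping vertex sets, a DP optimum whose relabeled vertices repeat is
rejected and recomputed by exact (capped) enumeration on the cyclic
restriction; the component-expansion path count itself is capped
(default 10,000) with an error advising a larger $t_a$.

Determinism under ties is fixed by a lexicographic composite objective:
maximize weight, then the number of vertices covered, then the smallest
vertex name. The vertex-count criterion also steers equal-weight choices
toward larger total vertex coverage, the defining property of a *maximal*
independent longest path set; a one-step greedy cannot guarantee global
coverage maximality on adversarial graphs, and the acceptance suite
measures how it fares against exhaustive enumeration on random graphs.

On extension graphs two strengthenings apply, both off for plain graphs.
(1) *Mirror handling*: every path coexists with its mirror (the same
merged contig read reverse-complemented); after an extraction the mirror
vertices are forbidden and only one reading is reported — the one with
fewer reverse-direction vertices (ties: lexicographic), so merged contigs
come out predominantly forward. (2) *Contig consumption*: all vertices of
every contig used by a path are forbidden for later paths. Vertex identity
is per alignment, so plain vertex independence would let a later path pull
a consumed contig back in through a different alignment; with three input
drafts this manufactures a second, fully redundant genome-length path whose
per-pair coverage never reaches the pruning threshold. Consuming contigs
enforces what the merger is for: each input base contributes to at most one
merged contig.

### Stitching

Each path becomes one merged sequence by concatenating the chunks its
edges name: remainders, overlap regions (taken from the contig earlier in
path order — no consensus is attempted over the overlap, matching the
philosophy of not re-arbitrating the assemblers' calls), inter-footprint
gaps, with reverse-direction segments reverse-complemented. Rendered length
equals path weight by construction. The final candidate set is one contig
per path (`MIX__path_<k>`) plus every input contig no path consumed.

### Pruning

Merging near-identical drafts duplicates most of the genome, so candidates
largely contained in other candidates are removed. The original
(uncleaned) alignment set is projected through the path layouts: entry
$(x, y)$ of the coverage matrix is the fraction of $x$'s positions covered
(interval union, each position once) by alignments between a contig of $x$
and a contig of $y$; alignments internal to one element are excluded, and
coverage is strictly per pair (no aggregation across multiple targets).
Pairs reaching the threshold (default 0.90) become one directed edge, the
source being the more-covered element (ties: shorter, then smaller id).
Cycles — possible when elements cover each other — are broken by keeping
the longest element of each strongly connected component as representative.
A topological sweep then removes, to fixpoint, every element that is
covered but covers nothing. The fixpoint iteration is the conservative
closure of a single pass, which is ambiguous when a removal creates new
removable elements. Merged paths are *not* exempt: a path wholly covered by
another element is redundant by the same argument as any contig, and
protecting it would leave duplicated genome copies in the output (an
option `protect_paths` restores the conservative behaviour).

## The synthetic world

The generator emulates the situation the merger targets: one bacterial-
scale genome (i.i.d. bases, default GC 0.38, typical for the low-GC
organisms that motivated reference-free finishing), fragmented
independently 2–3 times. Draft 1 cuts the genome at breakpoints spaced at
least three maximal overlaps apart; draft $i>1$ shifts each interior
breakpoint rightward by an independent stagger drawn from
$[\mathrm{ov_{min}}, \mathrm{ov_{max}}]$ (default 500–5000 bases). Contigs
within one draft abut without overlap — real assemblers rarely emit
overlapping neighbours — while contigs of different drafts share terminal
overlaps of exactly the stagger lengths, all above $t_a$. Ground-truth
alignments are emitted from the known genome intervals (strand-aware, with
optional whole-contig reverse complementing), standing in for an external
aligner; optional i.i.d. substitutions perturb sequences without moving
coordinates (no indels, so the single alignment length is exact on both
sides — indel simulation is a noted extension).

What a green end-to-end test establishes: on collinear, error-free,
staggered fragmentations the pipeline returns exactly one contig equal to
the genome with duplication exactly 1.0. What it does not establish:
robustness to misassemblies, repeats longer than $t_a$, indel-divergent
drafts, or aligner noise — real drafts violate all of these to some
degree, which is why the cleaning thresholds are exposed as tunables.

## Defaults worth knowing

| parameter | default | meaning |
|---|---|---|
| `t_a` | 200 bases | minimum alignment length kept (strict) |
| containment | 99% | rule-4 fraction; above this an alignment is a containment |
| `eps` | 0 bases | end tolerance for "terminal" |
| `coverage_threshold` | 0.90 | pruning containment fraction |
| `scc_path_cap` | 10,000 | simple paths enumerated per SCC before erroring |

## Known limitations

* The greedy longest-first extraction is exact per iteration but does not
  globally optimize vertex coverage on adversarial tie structures.
* Overlap bases are taken verbatim from the first contig in path order;
  disagreements inside an overlap are not resolved by consensus.
* Coverage is per element pair; a contig 50% covered by each of two
  elements is never pruned.
* No read-level evidence is used anywhere; misjoins supported by a spurious
  terminal alignment that survives cleaning will propagate.
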