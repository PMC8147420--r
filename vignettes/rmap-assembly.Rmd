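---
title: "Assembling Rmaps with a bi-labelled de Bruijn graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling Rmaps with a bi-labelled de Bruijn graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmapasm)
```

## The problem

An Rmap is the restriction map of a single DNA molecule: an ordered list of
fragment lengths (bp) between consecutive recognition sites of a nicking
enzyme. Observed Rmaps carry three kinds of error: *missed* cut sites (an
enzyme fails to nick, merging two fragments), *false* cut sites (random
breakage splits a fragment) and *sizing* error (fragment lengths are
estimated optically). Assembly means reconstructing a consensus genome-wide
optical map from many overlapping, error-bearing Rmaps.

Classic overlap-layout-consensus approaches need all-vs-all Rmap
alignments, which does not scale. The approach implemented here transfers
the de Bruijn graph paradigm to this numeric, error-tolerant setting.

## The model

### Bi-labels

For fragment list $R = [r_1, \dots, r_{|R|}]$, integers $k$ and $D$, the
**bi-label** at position $i$ is
$[s^1_k \,|\, r_p,\dots,r_q \,|\, s^2_k]$ with $p = i + k$, where $s^1_k$
and $s^2_k$ are the $k$-mers (runs of $k$ fragments) starting at $i$ and
$q+1$, and $q$ is minimal with $\ell(s_{p,q}) \ge D$
($\ell(\cdot)$ = summed fragment length). The middle part is the **skip
segment**: it is constrained only by total length, never by fragment
count, so a missed or false cut inside it changes nothing that the graph
can see. That is the error tolerance that makes a de Bruijn construction
possible on this data.

Two bi-labels are **proximal** when they are

* *fragment proximal*: each of the $2k$ k-mer fragments differs by at most
  $t_f$, and
* *length proximal*: the three segment lengths
  ($\ell(b^1), \ell(b^2), \ell(b^s)$) each differ by at most $t_\ell$.

Proximity is symmetric and reflexive but **not transitive**; nothing in the
package assumes transitivity.

### The graph

Node labels are the $(k-1)$-mer analogues: the *prefix* bi-label keeps the
$(k-1)$-prefix of $b^1$ and re-derives a minimal skip starting at $b^1_k$;
the *suffix* bi-label keeps the $(k-1)$-suffix of $b^1$ and inherits the
skip unchanged. For consecutive positions of one Rmap,
`suffix_bilabel(b_i) == prefix_bilabel(b_{i+1})` exactly — the chain
property that connects the graph. Each representative bi-label becomes a
directed edge from its prefix node to its suffix node; nodes are first
deduplicated on exact equality, then *glued* whenever two node labels are
proximal.

### Proximity search

All bi-labels are bucketed by
$(\lfloor\ell(b^1)/t_\ell\rfloor, \lfloor\ell(b^2)/t_\ell\rfloor,
\lfloor\ell(b^s)/t_\ell\rfloor)$; each bucket holds a $2k$-dimensional k-d
tree over the k-mer fragment vectors (median split, implicit index array,
leaf size 8, in C++). A query visits every bucket whose length windows can
contain a proximal partner — the k-mer windows use
$m = \min(k\,t_f, t_\ell)$, and the skip window spans the full $\pm
t_\ell$, i.e. the home bucket *and both neighbours* — runs the orthogonal
range query $[b \pm t_f]^{2k}$, and post-filters candidates with the exact
predicate. Visiting the neighbouring skip buckets is a deliberate
completeness choice: length-proximal skip lengths can straddle a bucket
boundary, and correctness here is defined as exact agreement with the
brute-force all-pairs scan (which the test suite enforces on random sets).

## Pipeline and parameters

`assemble_rmaps()` runs: extract bi-labels → support counting and
low-frequency filtering → greedy proximal reduction → graph construction
and gluing → tip/bubble removal → unitig extraction and consensus
spelling.

| parameter | default | meaning |
|---|---|---|
| `k` | 6 | k-mer size (fragments). 6 is the largest $k$ with $0.9^k \ge 0.5$, i.e. a k-mer is error free with probability ≥ 50% at a 10% per-cut residual error rate (`default_kmer_size()`). |
| `D` | 15000 bp | minimum skip-segment length. Smaller D yields more bi-labels per Rmap (needed when Rmaps are short). |
| `t_f` | 500 bp | per-fragment sizing tolerance; should exceed the residual per-fragment sizing error of the (error-corrected) input. |
| `t_l` | 2000 bp | segment-length tolerance and bucket width. |
| `min_support` | 3 | a bi-label must have this many proximal partners to survive. Low-support bi-labels are overwhelmingly error-dominated; support scales linearly with coverage. |
| `min_contig_frags` | 250 | reporting threshold for contigs (all unitigs stay available in `all_contigs`). |
| `max_tip_len`, `max_bubble_len` | `4k` edges | cleaning thresholds, see below. |

Inputs are assumed error-corrected (as produced by an external Rmap error
corrector); with raw data, expect to lower `k` and raise `t_f`.

## Design choices where the design was open

* **Units.** Internal unit is integer bp; the 3-line optical-map text
  format stores kbp with three decimals. Rounding is nearest integer, ties
  away from zero, so file round-trips are exact.
* **Digestion.** Overlapping recognition-site occurrences all produce
  cuts; reverse-strand occurrences are not searched separately. Cuts on a
  sequence boundary are dropped rather than emitting zero-length
  fragments.
* **Reduction determinism.** The greedy reduction scans bi-labels in
  descending support order with ties broken by (Rmap id, position,
  orientation); each bi-label maps to the earliest-accepted representative
  it is proximal to. Edge support is the member count, so supports always
  sum to the number of filtered bi-labels.
* **Gluing order.** Because proximity is not transitive, merge order
  matters. Nodes are processed in array order; a merged node adopts the
  survivor's coordinates for all later queries; passes repeat until no
  live proximal pair remains (the suite verifies the post-condition by
  brute force).
* **Cleaning thresholds.** "Short" tips and bubbles are measured in edges.
  The bubble cap of twice the bi-label size is read as $2 \times 2k$
  edges, and the same default is used for tips; both are tunable, and the
  edge-count interpretation is flagged as a calibration point. Bubbles are
  resolved by deleting only the first edge of the lower-support path (ties
  by edge id), never the whole path.
* **Traversal.** Depth-first from every zero-in-degree node; a unitig
  extends only through nodes with in-degree = out-degree = 1 and stops at
  branches, convergences, terminals and repeated nodes (cycles). Nodes
  where a path stops are expanded in turn, so every reachable edge is
  reported exactly once; edges in purely cyclic components are counted and
  logged, not spelled.
* **Consensus spelling.** Consecutive unary edges overlap in all but
  their first fragment, so a path spells as: first consensus fragment of
  every edge but the last, then the last edge in full. Each emitted
  fragment is the mean over the bi-labels the edge represents (the members
  of its representative), rounded to bp; for the skip segment only members
  with the representative's fragment count are averaged, since other
  members' skip fragments do not align coordinate-wise. Junctions are
  verified (suffix of one edge proximal to the prefix of the next);
  violations raise an assembly-integrity error rather than emitting a
  chimeric map.
* **Dual-direction mode** treats the reversed fragment list as an
  independent read; no reverse-canonicalisation is defined, so forward-
  and reverse-derived bi-labels merge only if genuinely proximal. Without
  it, the two strands of a simulated genome simply assemble as two
  mirror-image contigs.

## The simulator: what it emulates and what it does not

`simulate_rmaps()` draws molecules uniformly over a linear genome until
the target fold coverage is reached (molecule lengths
Normal(mean, sd), default mean 350 kbp ≈ 40 fragments at typical
nicking-site densities). Per molecule it applies the standard three-part
error model: each true cut is dropped with probability `p_miss`
(Bernoulli; default 0.15), false cuts arrive as a Poisson process
(default 1 per 100 kbp), and each fragment of true length $r$ is observed
as $\max(1, \mathrm{round}(\mathcal{N}(r, (s\sqrt r)^2)))$ — the
standard-deviation-grows-with-length family; default $s = 3.35$ gives
sd ≈ 150 bp at 2 kbp. A multiplicative Laplace alternative is available
with user-supplied parameters. About half of the molecules are reversed.
Ground truth records every molecule placement and the true genome
coordinate flanking every observed fragment, which lets the evaluator
compute genome fraction without any external aligner.

Not modelled (documented simplifications): digestion probability depending
on flanking fragment lengths, depletion of false cuts near molecule ends,
chimeric molecules, and per-run stretch/scaling drift. Consequently a
green simulation test establishes correctness of the assembly machinery
under the stated error model, not robustness to every artefact of real
Bionano runs.

`trim_flanks = TRUE` drops the first and last fragment of every molecule.
A molecule almost never starts or ends on a cut site, so these two
fragments are partial; exact-recovery tests enable trimming because a
truncated flank that happens to fall within $t_f$ of the true fragment
would otherwise join the consensus and shift it by a few bp.

## Evaluation

`assembly_stats()` reports contig counts and max/mean sizes in fragments
and bp. `genome_fraction_truth()` is the union of the genomic intervals
covered by each contig's constituent bi-labels (via simulator ground
truth) over the genome length. `fit_align()` is a deliberately simple
dynamic-programming fit aligner: steps consume up to `max_site_diff`
fragments per side, step cost is the absolute aggregated-length
difference, a step is admissible if its cost is at most
`sizing_tol × (fragments merged)`, and a contig counts as aligned if its
best full-length placement has mean per-step cost ≤ `sizing_tol`. It is a
stand-in for a full likelihood-scored aligner, used to flag unalignable
contigs (and, via discordant placement of the two halves, candidate
mis-assemblies); its acceptance rule is a proxy, not a calibrated score.

## Choices behind the error-free recovery test

The error-free acceptance world (200 kbp genome, 50×) leaves molecule
length, enzyme, tolerances and filtering free. Molecules are scaled to
10% of the genome (20 kbp) and the site is 4 letters (~256 bp fragments):
on a *linear* genome a position can only be assembled once enough
molecules span a whole bi-label, so each genome end loses roughly
`(min_support + 1) / coverage × molecule length`; genome-length molecules
would make a ≥ 99% genome fraction unreachable for any assembler. The
low-frequency filter is disabled (`min_support = 0`) because it exists
solely to remove error-dominated bi-labels and this world has none, and
tolerances are tiny (`t_f = 10`, `t_l = 50`) because they only need to
absorb consensus rounding — larger values would merely invite chance
cross-locus proximity among ~256 bp fragments.

The noisy scaled-down test (460 kbp, ~1.1 kbp fragments) keeps the
canonical error rates (15% missed cuts, 1 false cut per 100 kbp), uses
residual post-correction sizing noise, and runs at 300× because expected
same-strand support per locus is roughly
`coverage/2 × P(both k-mers clean)` ≈ `coverage × 0.05` at a 15% per-cut
error rate — the full-scale experiments used 900× for the same reason.
Its assertions are sanity floors for this scaled world; the full-scale
published numbers require the real genomes and external tools and are out
of desk scope.

## Known limitations

* Purely cyclic components are logged, not spelled.
* Contigs are unitigs: no scaffolding, stitching or repeat resolution
  beyond unary paths.
* The k-d forest is an in-memory index; no persistence.
* `fit_align()` does not model the full sizing-error likelihood; its
  unaligned/mis-assembly calls are heuristic.
* Complexity claims for the k-d tree are not asserted by tests;
  correctness is defined by oracle equivalence only.
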