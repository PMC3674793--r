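---
title: "Scaffolding draft prokaryotic genomes from inversion signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding draft prokaryotic genomes from inversion signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscaf)
```

## The model

`sigscaf` works on the block-level abstraction of a pair of
single-replicon genomes. Conserved blocks shared by the draft (query) and
the finished reference are numbered `1..n` in reference order, so the
reference is the identity permutation and the query is a signed
permutation `Π`; contigs are substrings of `Π`, possibly
reverse-complemented, that tile it without overlap. Everything the
scaffolder knows is in those signed substrings.

Four working assumptions underlie the exact-recovery guarantee: (1) no
conserved block is repeated in either genome; (2) contigs are correctly
assembled; (3) each genome is a single replicon; (4) block 1 occurs at
the first position of some contig with a plus sign, or at the last
position with a minus sign. Assumption (1) is enforced by the one-to-one
match filter and validated by the `block_contig_set` constructor; (3) is
enforced by refusing multi-record references at the block-building stage;
(4) is checked by `normalize_start()`, which on failure falls back to a
start directive (place the contig containing block 1, oriented so block 1
reads positive, and continue from its oriented far end) rather than
remapping block labels — the two are equivalent and the directive keeps
block numbering stable for downstream reporting.

An inversion `ρ(i, j)` reverses a window and flips its signs. Its scar at
either end is an *inversion signature*: a breakpoint whose two blocks
carry different signs. The two ends of one inversion satisfy
`Π_i = −Π_j − 1` and `Π_{i+1} = −Π_{j+1} + 1`; `partner_signature()` is
this involution. Breakpoints are interior only — positions `1..n−1`;
genome ends are not breakpoints.

## The algorithm and its reconstruction choices

`scaffold_contigs()` maintains a search target `t` (a signed block),
starting at `+1`. A target found at the first position of an unplaced
contig on the plus strand (or last position on the minus strand) extends
the scaffold, and the next target is the oriented last block plus one —
arithmetically, so a scaffold ending in `−5` searches `−4`. A target
found anywhere else is read in the direction in which it spells `−t`; if
the following block `x` has the sign of `t`, then `(−t, x)` is a
signature and the partner relation sends the search to `−x + 1`. Jumps
may read contigs already placed. Anything else is a dead end: a new
scaffold opens at the smallest-id unplaced contig, placed forward
(forward is a convention; nothing in the evidence distinguishes the two
orientations of a fresh scaffold seed).

Two bookkeeping decisions deserve a note, because both were forced by
worked traces rather than free choices:

* **Searched blocks are tracked per signed value.** A block may
  legitimately serve one search in each reading direction — placed on
  `+b` and later consulted for a jump on `−b` (this happens whenever a
  placed contig ends inside an inverted run, e.g. a contig spelling
  `[+25, −26]` is placed on `+25` and the following search of `−25`
  must be allowed to fire the jump on the signature `(+25, −26)`).
  Only a repeat of the *same signed* search indicates a loop and opens a
  new scaffold. The worst-case iteration count is then `2n + m` rather
  than `n + m`, but across the demonstration genome and every simulated
  input in the test suite the observed count stays within `n + m`: a
  placement consumes the search that found it, so both signed copies of
  a block are searched without placement only under pathological
  signature collisions that the tests never produced.
* **Jumps fire only on genuine signatures.** The sign condition
  (`sign(x) == sign(t)`) is exactly the signature condition: a same-sign
  following block would be a plain breakpoint with no partner
  prediction, and is treated as a dead end.

The evaluation convention concatenates all scaffolds in creation order
into one layout and counts oriented adjacencies, a junction being correct
when it or its reverse complement is consecutive in the true layout; for
circular replicons (the default) the wrap junction counts too. Coverage
weights each contig by its correct ends — both, one, or neither end
giving full, half, or zero length. Orientation-aware counting is a
deliberate choice: an orientation flip destroys both junctions of the
flipped stretch, which is how the demonstration genome arrives at 7 of 9
with coverage 7/9 from a single missing signature pair.

## The inversion-class hierarchy and the strip convention

Series of inversions fall into four nested classes: *symmetric* (all
windows share the genome centre, `n = i + j − 1`), *nested* (windows
strictly shrink), *safe* (each inversion acts strictly inside a strip of
the current permutation), and *generic*. `classify_series()` returns the
most restrictive class that holds, and `enumerate_reachable()` is a
brute-force closure oracle (guarded to `n ≤ 7`) with which the tests
verify `P1 ⊂ P2 ⊂ P3 ⊂ P4` strictly for `n ∈ {3, 4, 5}`.

For the *safe* check, strips are computed on the permutation framed by
sentinels `0` and `n + 1`. This convention is load-bearing: without it no
inversion touching position 1 or `n` could ever act inside a strip, the
first inversion of a nested series such as `ρ(1, 7)` would not be safe,
and the containment of nested within safe would fail. With framing, a
series like `ρ(8, 8), ρ(1, 2), ρ(4, 6), ρ(5, 5)` on eight blocks
classifies as safe, as it should. The user-facing `find_strips()` and
`find_breakpoints()` remain unframed (interior), which is what one wants
when reading scars off a permutation. An empty series classifies as
symmetric — vacuous truth keeps the classifier total and monotone.

Boundary-touching safe inversions, however, produce *unpaired*
signatures (their outer scar falls off the genome end), and unpaired
signatures carry no partner prediction: the orientation of a
boundary-only inverted stretch is genuinely unrecoverable from block
evidence. The simulator therefore samples safe inversions strictly
inside *unframed* strips of length at least 3 — positions 1 and `n` are
never inverted, every signature created is a member of a pair, and the
exact-recovery guarantee applies. The classifier still labels such
series safe; the distinction only matters for what recovery can promise.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` realises the conditions of the recovery guarantee:
an identity reference of `n` blocks, `k` seeded inversions of the
requested class, fragmentation into `m` contigs at uniform cut points,
independent reverse-complementing of each contig with probability 1/2,
and a shuffle of contig identifiers. Cut points are drawn under two
constraints that are part of the study conditions rather than
conveniences: block 1 stays at a usable contig boundary (assumption 4),
and every signature pair keeps at least one member strictly inside a
contig — one randomly chosen member per pair is protected outright, so a
valid cut set exists by construction whenever `m ≤ n − k`; infeasible
combinations are refused with an explanatory error rather than silently
relaxed. `drop_pair_members = d` deliberately cuts one member of `d`
pairs (keeping all other pairs fully intact, so exactly `d` pairs end up
single-witnessed); `gap_blocks` deletes blocks at contig borders with
dense renumbering, mimicking blocks that fall between contigs and are
never observed. Nucleotide emission writes each block as an independent
uniform-random sequence of `block_len` bp (default 500, floor 50 —
enough that block boundaries cannot collide with the match-filter
length floor of 100 bp), plus the exact match table those sequences
would induce.

What passing simulations show is that the algorithm and its
preconditions compose as claimed on clean block-level data. What they do
not show: robustness to misassembled contigs, repeat-induced block
ambiguity, alignment noise, indels and transpositions, or multi-replicon
genomes — real-data effects the simulator deliberately holds at zero
(and real aligner output brings its own filtering questions, below).

Problem sizes in the shipped tests were chosen to exercise the method at
desk scale: the recovery property runs 200 seeded safe simulations with
`n ∈ [20, 200]`, `k ∈ [1, 10]`, `m ∈ [2, min(30, n − k)]` (the cap is
the feasibility bound above); class-hierarchy enumeration stops at
`n = 5` (the generic closure is `2^n n!`-sized); robustness and
linearity sweeps use `n` up to 120 with generic inversions.

## From alignments to blocks

`parse_match_table()` consumes a tab-separated match table in the
`show-coords -T` style: `ref_start, ref_end, qry_start, qry_end, length,
identity_pct, qry_id`, 1-based inclusive, minus strand encoded by a
reversed query interval. Running the aligner itself is out of scope;
the package consumes its tabular output. `filter_one_to_one()` reduces
the table to non-repeated evidence: drop matches under `min_match_len`
(default 100 bp — suppresses spurious micro-matches; no principled
threshold exists, so it is a parameter), then greedily keep by
descending length unless a kept match is overlapped by more than
`max_overlap_frac` (default 0.5) of the shorter interval on the
reference axis or the same-contig query axis. This is a greedy stand-in
for LIS-based one-to-one delta filtering; its contract — each genome
region supports at most one block — is what the scaffolder relies on,
not the specific optimisation. Each surviving match becomes one block;
collinear matches are not chained (chaining is a modelling decision
real pipelines differ on, and nothing downstream requires it). Residual
same-contig duplicate evidence keeps the longer match with a warning.
Multi-record reference FASTAs are refused: scaffold each replicon
against its own reference in separate runs.

## Degenerate inputs and tie-breaks

Filter ties break by ascending reference start, then lexicographic
contig name — full determinism. A jump target of `0` or beyond `n` takes
the new-scaffold path. Single-block contigs satisfy both placement rules
at once; the forward rule is checked first, so an isolated `[+b]` found
as continuation places forward. The empty match set, duplicated blocks,
contig-set mismatches in evaluation, and impossible simulation requests
(nested deeper than `⌈n/2⌉`, safe with no interior strip, more contigs
than evidence allows) all raise immediate, specific errors.

## Known limitations

* The guarantee is conditional: missing signature pairs (dropped members,
  unsafe overwriting, boundary inversions) degrade the result to
  plausible-but-unguaranteed scaffolds, as the demonstration genome's two
  misoriented contigs illustrate.
* Only inversions are modelled; transpositions, translocations and
  duplications are outside the rearrangement model.
* One replicon per run; paired-read linkage is not used.
* The iteration bound `n + m` is asserted empirically (the signed
  searched-tracking admits `2n + m` in the worst case).
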