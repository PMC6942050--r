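---
title: "Comparative structural analysis of distal-junction contigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative structural analysis of distal-junction contigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrodj)
```

## The problem

The short arms of the five human acrocentric chromosomes carry the rDNA
arrays that seed nucleoli, and immediately telomeric of each array lies the
distal junction (DJ). DJ sequence is remarkable in two ways: it is nearly
identical (~99%) across *heterologous* chromosomes over its proximal
~300 kb, and it carries a stereotyped architecture — a stub of rDNA at one
end, inverted repeats long enough to host lncRNA transcription units on each
arm, and large blocks of 48-bp CER satellite with multi-kb foreign
(retroviral-like) insertions. Deletions shared between different
chromosomes with breakpoints identical at the base level imply that the
homogeneity is maintained by genetic exchange between heterologous
acrocentrics, not merely by purifying selection.

`acrodj` implements that comparative analysis as a pipeline of small,
testable steps: alignment and identity, architecture annotation, indel
markers and exchange inference, grouping, and junction/far-distal homology —
plus a synthetic cohort generator whose ground-truth manifest makes every
step verifiable without external data.

## Alignment model

All alignment is global, unit-cost (Levenshtein): match 0, mismatch 1, each
inserted or deleted base 1. Two implementation layers sit under one
interface:

* inputs whose DP area (product of lengths) is at most `dp_max_area`
  (default 64 Mcell) are solved exactly;
* larger inputs are anchored: k-mers (default `k = 21`) that occur exactly
  once in each sequence and match exactly define anchors; anchors are
  collapsed into maximal exact runs, chained by a weighted
  longest-increasing-subsequence on both coordinates (ties toward the
  leftmost chain, so repeat-rich input yields deterministic output), and the
  inter-anchor gaps are closed by exact DP, banded at width
  `2·|length difference| + band_pad` when a gap exceeds `dp_max_area`.

The DP is a three-state Gotoh recursion in which gap opening costs an
epsilon (1/2^20 of a unit) on top of the per-base cost. The epsilon cannot
change the unit-cost optimum (gap events never approach 2^20), but among
the co-optimal alignments it selects one with the fewest gap events. This
matters for indel calling: with plain unit costs a planted 100-bp deletion
is frequently scattered by the traceback into many short gaps threaded
through coincidentally matching bases, and no tie-break rule applied cell
by cell repairs that reliably. With the epsilon the deletion is reported as
one operation, which left-normalisation then places deterministically.

Identity is reported in two modes. `substitution_only` (the default) is
`100·m/(m+s)` over matched and substituted columns; it is the convention
under which a terminal block with 53 substitutions over ~112 kb and no
indel contribution reads 99.95%. `blast_like` adds indel bases to the
denominator. Columns opposite an `N` are excluded from both numerator and
denominator in both modes — accession sequences may contain gap-filled Ns
and they should neither count as matches nor as differences.

Windowed profiles (`window_identity()`) compute one global alignment per
query and assign alignment columns to reference windows, rather than
re-aligning each window against its best-matching segment. For collinear
contigs the two procedures agree; the single-alignment form is
deterministic, faster, and makes the additivity property exact (window
substitution counts sum to the global count when no indel straddles a
boundary). Windows tile the reference by default ("100-kb blocks"); the
step is configurable because a "sliding window" could also be read as
overlapping. A final partial window is kept when it is at least half a
window wide.

## Satellite, inverted repeats, inserts

**Period estimation** uses the distance from each position to the nearest
downstream identical k-mer (`k = 12`, distances capped at
`max_period = 2000`). The period is the mode of that distribution provided
the mode covers ≥ 30% of recorded distances and has at least 10 supporting
hits — the second guard exists because a few chance recurrences in random
sequence would otherwise produce a spurious confident mode. This approach
tolerates a few percent monomer divergence and returns an integer period
directly; no spectral method is needed.

**Satellite blocks** are maximal runs of positions whose k-mer recurs
within `max_period`, merged across gaps ≤ `merge_gap`. Embedded foreign
inserts break such runs, so same-period components separated by at most
`max_insert_gap` (default 20 kb, comfortably above the ~9-kb retroviral
integrations seen in real arrays) are merged into one block whose
inter-component gaps are exactly what `find_foreign_inserts()` reports. A
consequence of this operational definition: two same-period arrays
separated by < 20 kb of unique sequence are reported as one block with the
unique interval as an "insert" — structurally the two cases are
indistinguishable without a homology reference, and none is bundled.

The k-mer scan systematically loses ~(period + k) bp at every array
terminus (terminal k-mers have nothing downstream to recur against), so
component boundaries are refined by a periodic-phase walk: a position
agrees if it matches the copy one or two periods behind (ahead, for the
left boundary); the walk keeps a rolling 24-position window of agreements,
stops when the window drops below half, and places the boundary at the end
of the last run of 6 consecutive agreements. Matching against either of
two prior copies keeps the agreement rate near 1 even at ~12% copy-to-copy
divergence, while in aperiodic flanking sequence it falls to ~0.44 and the
walk stops within a few tens of bases. On simulated members the refined
boundaries are exact.

**Inverted repeats** are detected from exact shared k-mers (`k = 21`)
between the contig and its reverse complement; a pair of mirrored positions
is an anti-diagonal anchor, and anchors of one repeat share (arm1 + arm2)
coordinate sum up to `sum_tol`. Satellite blocks are masked first —
near-palindromic monomers otherwise generate spurious anti-diagonal anchors
— and unmasked again for boundary refinement and arm identity. An indel
inside one arm shifts the coordinate sum, splitting a repeat into several
anchor groups; groups whose arm1 intervals advance while their arm2
intervals recede, with bounded gaps and a sum offset ≤ `max_arm_indel`, are
chained back into one repeat. Outer and inner arm boundaries are refined by
mismatch-tolerant extension, and arm identity is the substitution-only
identity of arm 1 against the reverse complement of arm 2.

## Indel markers and exchange inference

Indel calls take every alignment gap ≥ `min_len` (default 50 bp — below
that, placement ambiguity in repeat-rich sequence makes breakpoint identity
unreliable; configurable) and left-normalise it: a deletion shifts left
while the base before it equals the base at its end; an insertion rotates
its inserted string correspondingly. Breakpoint flanks (30 bp each side)
are read from the reference after normalisation.

Calls cluster into one marker only under *exact* agreement of type, length,
position and both flank strings; same-type/same-length near-matches are
surfaced in a `candidates` attribute, never merged silently. In the marker
matrix, absence is verified rather than assumed: a 0 requires the query to
align contiguously across the marker locus with no large indel overlapping
it, otherwise the entry is missing (NA) and is excluded pairwise from
downstream tests — never imputed.

Exchange between heterologous chromosomes is formalised as the four-gamete
condition: under a single-origin assumption for each marker, a pair of
markers exhibiting all four joint presence/absence patterns requires at
least one exchange between their positions. `exchange_intervals()`
classifies every adjacent marker pair as `exchange_required` or `linked`,
reduces the exchange-required intervals to a minimal disjoint set by a
greedy left-to-right scan (its size is a lower bound on the number of
exchanges), and classifies mechanism: since non-crossover (gene-conversion)
tracts are bounded by ~1 kb, an exchange interval adjoined by a homogeneous
shared block longer than 1 kb is labelled `CO`, else `NCO_possible`. The
adjoining shared block is measured as the widest contiguous run of linked
intervals next to the exchange interval; when no linked interval adjoins,
the length defaults to 0 and the conservative `NCO_possible` is returned.

`dj_reference_markers()` encodes the published three-deletion marker table
of the WAV17 DJ contig (1.5 kb at 110 kb carried by A9-13, A9-15, GM10063;
0.3 kb and 5.0 kb at 161 kb and 172 kb carried by A9-22, WAV17, GM10063).
One reported carrier list labels WAV17 as HSA22 where it is HSA21
everywhere else; the package treats WAV17 as HSA21 and notes the
discrepancy here rather than resolving intent. Likewise the 110→161 kb gap
is verbally called "50 kb" though the printed positions imply 51 kb; the
package reports the computed width.

## Grouping

The relationship tree over contigs is built from pairwise substitution
distances (substitutions per aligned site, N-columns excluded) over a
region — by default the terminal 100 kb, because classification is driven
by the distal ends where between-group identity falls below 90%. A
multiple-sequence-alignment step is deliberately replaced by pairwise
distances + average linkage: the distances are already computed, the tree
method is then fully specified, and the grouping depends only on relative
distances. Labels are sorted before clustering so the partition cannot
depend on input order. `k` is a user choice (no automatic model selection:
the three-group description of real cohorts is explicitly not definitive);
threshold cuts are validated against the connected components of the
distance graph and refuse silently non-ultrametric input. Neighbor joining
(via ape) is available for display.

## Junction and far-distal homology

The rDNA/DJ junction is defined operationally: the end of the maximal
near-exact (≥ 99% identity) terminal match between a contig end and a
user-supplied rDNA reference, located by anchors and finished by a
mismatch-tolerant extension that crosses an isolated mismatch only when the
next 12 bases confirm the match. Both contig ends are tried, so a
reverse-complemented contig yields the mirrored junction. The junction's
position on the rDNA reference is reported as `rdna_offset` relative to
whatever reference the user supplies, rather than hard-coding any distance
to the pre-rRNA transcription start site, because rDNA coordinate systems
differ between references. The bundled
`inst/extdata/rdna_reference_synthetic.fa` is a deterministic synthetic
stand-in (it shares no homology with real rDNA) so that the simulator and
the examples run self-contained; junction analysis of real contigs requires
a real rDNA segment.

Far-distal structure is mapped with `homology_blocks()`: anchor chains on
both strands, split where the anchor diagonal jumps by more than
`max_diag_jump` (the signature of an internal insertion/deletion), with
per-block identities from alignment. Reverse-strand blocks are reported in
forward target coordinates with `strand = "reverse"`, which covers
cross-species inversions as data rather than special-cased logic.
Target-side gaps between collinear forward blocks are reported as candidate
internal deletions. `min_identity` defaults to 85% so that diverged
paralogous copies at 86–87% identity are captured while random noise is
excluded.

## The synthetic cohort generator

`build_ancestor()` lays out: rDNA stub | unique | IR arm |
spacer | revcomp(arm) | unique | satellite array (tandem copies of one
random period-48 monomer) | tail. `evolve_cohort()` then applies, per
group: shared indels on ancestor coordinates (identical breakpoints within
a group hold *by construction* — the generator mirrors the observation, it
does not simulate the mutational origin), one foreign insert per
integration event (each event has its own random sequence, so same-group
copies are near-identical and different events are unalignable), and
group-level substitutions; then per member, independent substitutions; then
exchange events as single-crossover suffix transfers at ancestor-coordinate
breakpoints (two events compose to an interval transfer, which is how the
recombinant preset member carries a foreign proximal segment while keeping
its own distal tail). Substitutions are Bernoulli per site with a uniform
choice among the three alternative bases — no transition bias, because
only percent identity is quantified downstream.

The published account gives no per-region mutation rates, so the divergence
defaults are fixed once to reproduce the qualitative gradient and not
revisited: group-level proximal rate 0.005/bp and distal rate 0.06/bp
(between-group proximal identity ~99%, distal ~88%), member-level rate
2.5e-4/bp (within-group terminal identity ~99.95%). The two-level (group
then member) scheme is this package's design: recoverable group structure
requires group-shared divergence, which a single per-member rate cannot
produce. The `threegroup` preset (60-kb ancestor, three groups
of 2/2/3, three shared deletions in the left IR arm, one insert per group,
one recombinant member built from two crossovers) runs the full pipeline in
seconds; `full_scale` scales the same scenario to 400 kb with 105-kb arms,
a 40-kb satellite and deletions of 1.5/0.3/5 kb at 110/161/172 kb for
stress testing.

The manifest records every realized event (indels with ancestor-normalised
breakpoints, insert sequences, each substitution, exchange splice
coordinates, per-member coordinate maps and segment ownership, and the
observable junction position — the stub end plus any coincidental match
continuation into the rDNA reference). `replay_manifest()` rebuilds every
member from the manifest without touching the random number generator, and
`manifest_expected_markers()` derives by coordinate arithmetic alone the
markers that calling against a given reference should produce, including
the polarity inversion when the reference itself carries a variant. The
test suites and acceptance checks compare pipeline output against these
manifest-derived expectations, with the reference fixed to a member that
carries no shared indel so that deletion normalisation is driven purely by
reference bases.

What the generator does **not** emulate: read-level artefacts (capture
bias, CCS errors, coverage gaps), coalescent realism of the substitution
process, satellite higher-order structure, and homology between different
integration events. A green synthetic test therefore establishes that the
algorithms recover planted structure under the stated divergence model — it
does not establish sequencing-level robustness.

## Numerical conventions and degenerate inputs

* All coordinates are 0-based half-open everywhere internally; BED output
  is written natively in that convention.
* Empty sequences are errors for alignment; an unalignable pair (no shared
  unique k-mer anchors on large divergent input) raises a typed condition
  (`dj_unalignable`), distinct from a low-identity success.
* A window with no aligned columns is missing (NA), never zero.
* `four_gamete()` on a marker against itself is `FALSE`; a pair with no
  chromosome non-missing at both markers is an error ("untestable pair").
* `classify_mechanism()` uses a strict threshold: exactly 1000 bp is
  `NCO_possible`.
* Determinism: anchors are unique k-mers, chains break ties leftmost,
  grouping sorts labels, and the simulator consumes one seeded RNG stream
  in a fixed order — identical inputs give byte-identical outputs.

## Known limitations

* Anchored alignment is heuristic above `dp_max_area`: optimality is
  guaranteed only through the chained anchors. The oracle-equivalence tests
  cover the exact-DP regime and related-pair anchored cases.
* Satellite block spans are operational (periodicity-based); reported
  boundaries on real, hierarchically structured arrays are approximate and
  no tolerance tighter than ±10% of span should be assumed there.
* Foreign inserts are defined structurally (aperiodic intervals inside
  arrays), not by homology to a retroviral reference; cross-insert identity
  comparison stands in for family assignment.
* The marker pipeline is intended for the conserved proximal region;
  breakpoint identity inside diverged satellite arrays is not reliable and
  such variation is handled by the annotation module instead.
* Junction finding assumes the rDNA stub aligns to the reference without
  large internal indels (true of terminal stubs of a few kb).
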