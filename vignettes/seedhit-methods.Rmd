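---
title: "seedhit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedhit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seedhit` is a desk-scale implementation of a sensitive seed-and-extend
protein aligner built around double indexing with multiple spaced seeds, a
cascade of heuristic filters, chaining-guided banded Smith–Waterman
extension, frameshift-aware translated search, probabilistic repeat masking,
a file-based distributed work protocol, and an evaluation harness for
homology-detection benchmarking. This vignette explains the model behind
each stage, the tunable parameters and their defaults, the numerical
choices, and what the synthetic benchmarks do and do not demonstrate.

## Search model

A query is compared against a reference database in stages, each stage
passing a shrinking set of candidate hits to the next:

1. **Masking.** Tandem/low-complexity repeats are soft-masked in both query
   and reference (see below); masked positions are excluded from seeding
   only, so reported alignments always show original residues.
2. **Seeding (double indexing).** Spaced seeds — patterns of *match* and
   *don't-care* positions — are extracted from **both** query and reference
   at every placement where no matched position is masked or ambiguous.
   Matching seeds are found with a hash join: both seed tables are
   recursively partitioned on successive 8-bit radix digits of the seed code
   (most significant first) until the query partition is small
   (`partition_limit`, default 32,768 entries), then joined by hashing. The
   result is provably identical to a nested-loop join and independent of the
   partition limit; processing the shapes one at a time keeps only one
   shape's tables in memory.
3. **Hamming window filter.** Each seed hit is scored by counting identical
   letters in a 48-letter window that starts 24 positions left of the seed
   (clipped identically on both sequences at the ends; the cut-off scales
   proportionally, rounded down). Per-mode cut-offs default to 14/13/12/11
   identities for fast/sensitive/very-sensitive/ultra-sensitive. The window
   placement and the cut-off values are this package's choices, exposed via
   `sensitivity_preset()`.
4. **Ungapped extension.** Surviving hits are extended greedily in both
   directions along the diagonal with an x-drop rule (default 20 raw score
   units) and trimmed back to the maximal-score ends. The segment's
   ungapped e-value (Karlin–Altschul, ungapped constants) must not exceed
   `ungapped_evalue` (default 1e4).
5. **Leftmost-seed redundancy filter.** Double indexing rediscovers one
   local alignment once per shape and placement. A hit is discarded when an
   earlier-indexed shape hits anywhere in the bit-encoded match/mismatch
   window ending at the current seed, or the current shape hits at an
   earlier offset. The decision is precomputed for all 2^L window patterns
   (our shipped shapes keep spans at most 16, so the table is exact and at
   most 65,536 entries per shape); a property test asserts the table equals
   a direct per-shape scan. This filter is purely an efficiency device: a
   test verifies the final alignments are identical with it disabled.
6. **Adaptive ranked extension.** Per query, targets are ranked by their
   best ungapped segment score (ties by target ordinal; the ranking key is
   the *maximum* per target — the alternative, summing segment scores, is
   noted as an open reading and rejected for its sensitivity to duplicated
   segments). The ranked list is processed in chunks of 400 targets
   (`ext_chunk_size`); if a chunk yields no alignment at or below the
   reporting e-value, extension for that query stops.
7. **Gapped-score heuristic filter.** Before the expensive extension, the
   best contiguous ungapped score is computed on every diagonal of a band
   around the target's segments (a query-profile sweep). With sorted
   per-diagonal maxima $s_{(1)} \ge s_{(2)} \ge \dots$ the estimate is
   $\hat S = s_{(1)} + \sum_{i \ge 2}\max(0, s_{(i)} - \text{gap\_open})$,
   which bounds any banded alignment that does not revisit a diagonal; hits
   with e-value($\hat S$) above `gapped_filter_evalue` (default 1e3) are
   dropped, and 0 disables the filter (a test verifies disabling changes no
   final alignment on the benchmark fixtures).
8. **Chaining.** Diagonal segments are sorted by subject start and chained
   left to right: a connection from segment $u$ to $v$ requires both starts
   to increase strictly, costs nothing on the same diagonal and
   `gap_open + gap_extend × |Δdiagonal|` otherwise. When consecutive
   segments overlap in query or subject, the lower-scoring segment is
   trimmed column-wise with scores recomputed from the matrix, which keeps
   every chain score recomputable. The best chain's diagonal range, padded
   by `band_pad` (default 16) on each side, defines the extension band. At
   desk scale the sweep considers every earlier segment, which makes the
   result provably equal to exhaustive subset enumeration (the oracle used
   in tests); an ordered map keyed by diagonal (the red–black tree of large
   implementations) is an access-path optimization that desk-scale segment
   counts do not need.
9. **Extension.** Affine-gap local alignment with traceback, either banded
   (restricted to diagonals within the chain band) or full-matrix
   (`ext_mode = "full"`). Full-precision integer arithmetic is used
   throughout; 8-bit score saturation with recompute-on-overflow is a
   hardware-level optimization that changes no result and is deliberately
   not reproduced.
10. **Reporting.** Alignments with e-value at or below `evalue_cutoff`
    (default 1e-3) are sorted per query by ascending e-value, descending
    bit score, then subject id, and capped at `max_target_seqs` (default
    25). Output is BLAST tabular (outfmt 6).

## Scoring statistics

Alignments are scored with BLOSUM62 (gap open 11, gap extend 1; a gap of
length $k$ costs $11 + k$). Bit scores and e-values follow
$S' = (\lambda S - \ln K)/\ln 2$, $E = mn\,2^{-S'}$ with the standard
published constants ($\lambda = 0.3176$, $K = 0.134$ ungapped;
$\lambda = 0.267$, $K = 0.041$ for gapped (11,1)). No finite-size length
correction is applied — a documented simplification that affects absolute
e-values slightly but no ordering. The stop character scores −4 against
everything, including itself, so translated frames crossing a stop are
penalized consistently.

The simplified composition adjustment (`comp_based_stats = 1`) rescales the
20×20 block of the matrix by the ratio of statistical scales: the ungapped
$\lambda$ solved for the observed (symmetrized) pair composition over the
$\lambda$ of the matrix background. A literal ratio of expected scores is
not usable here because strongly biased compositions drive the expected
score non-negative, where no local-alignment scale exists; when that
happens, the observed composition is blended stepwise toward the background
until a scale exists. The adjustment is exactly the identity at background
composition and symmetric in query and subject.

## Spaced-seed shapes

Modes ship 2 shapes of weight 10 (fast), 16 of weight 8 (sensitive), 14 of
weight 7 (very-sensitive) and 64 of weight 7 (ultra-sensitive), stored as
plain-text pattern files under `inst/extdata/` and overridable with a
custom file. The shipped patterns were generated once by a seeded greedy
heuristic that maximizes the minimal shifted overlap distance between
selected patterns, with spans capped at 16 so the leftmost-filter table
stays exact; only the counts and weights are normative. Seeds are drawn
from the full 20-letter alphabet (codes packed base-20 into a double, exact
below $2^{53}$); no reduced alphabet and no seed-frequency cap are applied
— both are documented extension hooks. The seed layer guarantees
completeness: any pair of sequences sharing an exact match at the matched
positions of a shipped shape produces at least one seed match.

## Repeat masking

Masking uses a hidden-state model with one background state and repeat
states for copy offsets $d = 1..D$ (default $D = 50$). The emission
likelihood ratio of repeat state $d$ at position $i$ is
$\exp(\lambda\,S(x_i, x_{i-d}))$ with the ungapped $\lambda$; transitions
use a repeat-start prior $\rho = 0.005$ decaying geometrically across
offsets (decay 0.9, shorter periods dominate biological tandem repeats) and
a repeat-exit probability $\varepsilon = 0.05$. Forward–backward posteriors
above the threshold $\tau = 0.5$ are soft-masked. This is a tantan-style
model, not a bit-compatible reimplementation of the tantan program; the
parameters are this package's own and are all exposed in `mask_params()`.
Both query and reference are masked symmetrically — whether masking one
side suffices is left open by the method description, and symmetric masking
is the conservative choice.

## Frameshift-aware translated search

Translated (blastx-style) search translates all six frames for seeding. For
reporting, either each frame is extended as a protein query and the best
alignment per target is reported with its frame (coordinates mapped back to
nucleotides, minus-strand alignments with descending query coordinates), or
— when a frameshift penalty `-F` is set — the read is realigned against the
target with a dynamic program over (nucleotide, subject) coordinates: codon
moves consume 3 nucleotides, frameshift moves consume 2 or 4 at penalty
$F$ (the emitted residue is always the translation of the last three
consumed nucleotides), and protein-level gaps are affine. Both strands are
evaluated. $F = \infty$ provably collapses to the best single-frame local
alignment. How hits from different frames of one read should be merged into
per-read output is not specified by the method description; this package
reports per read with the frame recorded.

## Distributed protocol

Query and reference databases are split into contiguous chunks by a letter
budget (never splitting a sequence; optional deterministic shuffling evens
out load). The Cartesian product of chunks forms work packages, held in one
file-based stack per query chunk. All stack operations use
create-then-atomic-rename — the only portable filesystem transaction — so
any number of workers can pop concurrently with exactly-once semantics, and
workers may join or leave at any time; there is no coordinator process.
Chunk searches compute e-values against the chunk's letter count; result
parts carry raw scores, and the worker that observes all parts of a query
chunk present claims a join token (again by rename) and recomputes
e-values against the full reference letter count, re-applies the reporting
cut-off and `max_target_seqs` globally, and writes the chunk output —
making the merged result identical to a monolithic run. Claims abandoned by
dead workers are requeued by `recover_workdir()` once they are older than a
staleness threshold (default 600 s; recovery timing is unspecified by the
method description, which defers recovery to "a subsequent run"). One
subtlety is worth stating: the adaptive-ranking stop rule conditions on the
other targets in the same run, so with very small extension chunks a
distributed run could in principle extend targets a monolithic run skips;
at the package's default chunk size (400) every desk-scale benchmark here
is extended exhaustively and the equivalence is exact.

## Synthetic benchmark generator

The evaluation harness generates protein families with known ground truth:
per family an ancestral domain is drawn from the background composition and
each member is mutated independently. Substitutions are sampled conditional
on the scoring matrix (probability proportional to
$p_b \exp(\lambda S(a,b))$), and per-site mutation probabilities follow
gamma-distributed rates (shape 0.7) held constant within blocks of
geometric length (mean 10 residues). The block structure models the
spatially autocorrelated conservation of real domains — conserved motifs
next to variable loops — which is precisely the feature that gives spaced
seeds anchors in remote homologs; with uniform per-site rates, weight-7
seeds have essentially no anchor at 25% identity and no seed-based method
can approach an optimal-alignment ranker there. The rate scale is
calibrated numerically per family (including the probability that two
independent substitutions coincide) so that realized pairwise member
identity matches the family's target; a test verifies at least 90% of
member pairs land within ±10 identity points of a 50% target. Domains are
embedded in random flanks, a configurable fraction of members carries a
second domain from a different fold, and decoys are window-shuffled member
sequences (40-letter windows, letter multisets preserved).

What the generator does **not** emulate: real length variation and indel
evolution within domains (members differ by substitutions only, so
benchmark alignments are nearly gapless; gap handling is exercised by the
oracle-equivalence tests instead), domain shuffling beyond the two-domain
case, compositional drift between families, and the scale and redundancy
structure of real reference databases. Passing the benchmark therefore
demonstrates correct ranking and recovery behavior of the pipeline under
controlled homology, not field performance on real data.

Ground-truth statistics follow the structural-classification convention:
a false positive is a hit between sequences of different folds; same-fold,
different-family hits are neutral. AUC1 is the fraction of a query domain's
family retrieved strictly before the first false positive (averaged over
the query's domains, then over queries; unannotated subjects count as false
positives); the ROC reports mean false positives per query against mean
family coverage across e-value thresholds. Sequence identity for
identity-resolved analyses is computed by global (Needleman–Wunsch)
alignment of the annotated ranges, identical columns over all alignment
columns; suggested bin edges are [20,30), …, [90,100].

## Numerical and policy choices

- Internal coordinates are 0-based half-open; only the tabular output is
  1-based inclusive.
- Unknown residues map to X and score through the matrix's X column.
- Degenerate inputs: empty sequences and empty bands raise errors; an
  all-negative scoring pair yields score 0 and an empty transcript; a
  position with no prior context always has repeat posterior 0.
- Ordering is deterministic everywhere: seed matches sort by (code, query
  location, subject location); target ranking breaks score ties by ordinal;
  reporting breaks e-value ties by bit score then subject id.
- Problem sizes in the tests and the acceptance script (for example 1,000
  oracle alignment pairs, a 20×50 brute-force grid, a 36-query family
  benchmark, 8 workers × 200 packages × 20 stress repetitions) were chosen
  as the smallest sets at which the statistical properties are stable.

## Known limitations

- E-values lack the finite-size correction, so very short queries get
  slightly optimistic e-values.
- The gapped-score heuristic can underestimate alignments whose optimal
  path leaves the segment-derived diagonal band, and overestimation is not
  guaranteed for paths revisiting a diagonal (measured ≥ 90% overestimation
  on benchmark homolog pairs, matching the design intent).
- BLAST's full compositional matrix adjustment is out of scope; only the
  simplified scale adjustment is provided (`--comp-based-stats 1`), and the
  flag values 3/4 are reserved.
- No on-disk seed index is kept (runtime indexing only), and no
  seed-frequency cap is applied to ultra-frequent seeds.
- The tantan-style masker is not output-compatible with the tantan program.
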