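---
title: "Mapping putative DNA:RNA triplexes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping putative DNA:RNA triplexes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplexmap)
```

## The model

A DNA:RNA triplex forms when a single-stranded RNA stretch occupies the
major groove of a DNA duplex, hydrogen-bonding to the purine bases of one
strand through Hoogsteen (or reverse-Hoogsteen) geometry. Two sequence
constraints follow. The duplex must present a homopurine tract: one strand
all A/G, the complementary strand all C/T — a *triplex-target site* (TTS).
And the RNA must be drawn from one of three motif alphabets — a
*triplex-forming oligonucleotide* (TFO):

| Motif  | Alphabet | Orientation vs. purine strand | Triads |
|--------|----------|------------------------------|--------|
| pyrimidine | `{U/T, C}` | parallel | T·A:T, C·G:C |
| purine     | `{G, A}`   | antiparallel | G·G:C, A·A:T |
| purine–pyrimidine | `{G, U/T}` | either | G·G:C, T·A:T |

Stability in vitro rises with tract length; this package, like the scan it
reimplements, requires a minimum of 20 bases for both TFOs and TTSs and, by
default, strict motif compliance (no mismatches). Both thresholds are
configuration keys (`min_tfo_length`, `min_tts_length`, `error_rate`).

### Detection

`find_maximal_runs()` is the core primitive: the maximal substrings over an
alphabet, at least `min_len` long. Maximality is structural — the flanking
base, where it exists, lies outside the alphabet — so a reported run can
never be extended. `N` or any non-alphabet base terminates runs. TFOs are
maximal runs over each of the three motif alphabets in each transcript;
TTSs are maximal runs over `{A,G}` (purine strand `+`) and `{C,T}` (purine
strand `-`, the purine-strand sequence being the reverse complement) on
each chromosome. The two TTS classes can never overlap, since every base
belongs to exactly one class.

A run of pure G satisfies both the `[GA]` and `[GT]` alphabets (pure T
satisfies `[TC]` and `[GT]`). Published per-motif counts imply a per-motif
scanner, so such runs are reported once per motif; they share a `run_id`
and carry `multi_motif = TRUE`, letting callers count unique intervals
instead when that is the quantity of interest. Whether published totals
count such runs once or twice is not decidable from the published numbers
alone; both counts are exposed.

### The mismatch-tolerant mode

`error_rate > 0` (the published comparison mode is 5 %, i.e. one error per
20 bases) admits interior non-motif bases provided every 20-base window
within a run contains at most `floor(20 * error_rate)` of them, and both
run ends are motif bases. The default remains 0: the tolerant mode
multiplies runtime and output volume without changing the qualitative
genomic distribution, and matching downstream is always exact.

### Signatures and matching

Every admissible target of a TFO can be written in *purine space*: a string
over `{A,G}` read 5'→3' along the purine strand. The derivation applies
the triad table: `[TC]` maps T→A, C→G in the same direction (parallel);
`[GA]` reverses the TFO with letters unchanged (antiparallel); `[GT]`
yields both a parallel (T→A, same direction) and an antiparallel (reversed,
T→A) signature. Identical `[GT]` signatures — mirror-symmetric runs —
collapse to one with orientation `both`.

`enumerate_matches()` reports **every maximal common substring of length ≥
20** between each signature and each TTS purine-strand sequence, by 20-mer
seeding on shared diagonals with outward extension. The engine's contract,
not its algorithm, is fixed: the test suite holds it equal to an
independent quadratic dynamic-programming oracle on hundreds of random
instances. Because the strings live on a two-letter alphabet, periodic
tracts legitimately match at several shifted diagonals; each maximal
diagonal run is one match. A `[GT]` TFO hitting the same genomic window in
both orientations is one physical site: such duplicates are collapsed with
orientation `both`.

Coordinates: matches against purine-strand `-` TTSs are converted to
plus-strand genomic intervals through the tract's 3'→5' flip, so all
downstream interval arithmetic happens in one frame.

### Self-matches

A GA- or TC-motif TFO's own genomic tract is itself a TTS, so a scan
reports trivial matches of a transcript onto its source locus. These carry
no regulatory information and are removed. One subtlety the package makes
explicit: under the orientation rules above, a TFO's signature aligns with
its own tract only when the TFO sequence is mirror-symmetric (binding
reverses the reading direction), so self-matches are a property of
near-mirror repeats rather than of every TFO. `remove_self_matches()`
drops, by default, any match whose target interval overlaps the source
TFO's genomic tract by at least one base (`self_match_mode = "overlap"`);
partial-offset matches onto one's own tract are equally trivial. The
published phrase "located at the same position" could also be read as
exact coordinate identity, so `self_match_mode = "exact"` is available.
TFOs losing *all* their matches are reported as dropped.

### Merging

Two matches overlapping over **more than 10 bases** (i.e. ≥ 11; the
boundary is tested explicitly) are the same physical site. Sites are
single-linkage clusters of target intervals under that linkage — computed
by a sorted sweep, verified against an all-pairs union-find oracle, and
idempotent by construction (consecutive merged spans can overlap by at most
the threshold). Merging runs separately per source class (pre-lncRNA vs
pre-mRNA) because per-class totals are the quantities of interest;
`merge_scope = "global"` merges across classes. Whether the reference
analysis merged per class or globally is not stated; per-class is the
default.

### Densities and selection

Long genes accumulate matches by length alone. To call genes
triplex-*enriched*, counts are normalised to matches per 1000 bases, with a
pooled baseline: total gene-assigned matches divided by summed gene length
(`baseline_scope = "genic"`; the phrase "all the matching combinations"
could also include intergenic matches, so `"all"` is available). Selection
takes the minimal count-ranked prefix of genes accounting for
`cumulative_fraction = 0.75` of matches, then keeps genes with density
strictly above the baseline. Ties break by density, then lexicographic id,
for determinism. Ranking by density instead of count (`rank_by =
"density"`) is available since the published method does not state which
ordering formed the prefix. Transcript selection applies the same two
filters with counts grouped by source transcript and transcript lengths as
the normaliser.

Match-to-gene assignment is majority-overlap: the gene with the largest
overlapping base count wins, and within it exon vs intron by base count
with ties to exon (exon annotation being the more conservative claim).
Chromosome profiles assign each merged site to the 200-kb bin containing
its midpoint — sites (≤ a few hundred bases) are tiny relative to bins, so
midpoint assignment cannot double-count.

### Structural accessibility

A TFO buried in intramolecular secondary structure is unlikely to engage a
duplex. The estimate is purely combinatorial (no energy model): a
transcript region is "potentially paired" if it lies in an arm of a
hairpin stem — strict Watson–Crick complementary arms of ≥ `min_stem = 4`
bases around a loop of `loop_min = 4` to `loop_max = 8` bases — or of a
long-range pairing (arms ≥ 10 bases, separation ≤ 500 bases; the lower
separation bound is 0, as no minimum is implied for long-range contacts).
Arms are maximal: not extendable outward or inward while preserving
complementarity and the loop bounds. G:U wobble pairs are excluded by
default (`wobble = FALSE`) since the original search specifies none, and
arms are perfect (no internal mismatches, no overlapping arms). A TFO
counts as paired on ≥ 1 base of overlap with any arm — containment is not
required, and this too is configurable. The output is the paired fraction
per source class.

### Enrichment and networks

GO over-representation is the exact upper hypergeometric tail: with `N`
population genes, `K` term-annotated, `n` in the study list and `k`
annotated study genes, `p = P(X ≥ k)`. Annotations are used as given (no
true-path up-propagation, matching what an annotation service applies from
the user's perspective); terms with `K = 0` are skipped. Multiplicity
correction defaults to Benjamini–Hochberg (`correction = "bonferroni"`
available, since the original web service's correction is unstated).

The interaction network keeps edges whose endpoints are both selected,
collapses duplicate and antiparallel records (relation `both` when
suppression and enhancement co-occur), prunes connected components below
`min_component_size = 4` (isolated pairs and triplets), and detects
overlapping modules by clique agglomeration: maximal cliques of ≥
`min_clique = 3` nodes are merged greedily while any pair has overlap
similarity `|A∩B| / min(|A|,|B|) ≥ 0.5`. This is a deliberately simplified
stand-in for spanning-cluster (EAGLE-style) community detection, whose
exact published parameters are unavailable; modules may share genes, and
module sizes are outcomes, not parameters.

## The synthetic generator

`synthetic_spec()` + `simulate_triplex_data()` produce genomes whose entire
detectable triplex structure is known:

* **Background capping.** Pre-RNAs are genomic spans, so a spontaneous
  ≥ 20-base run over *any* of `{A,G}`, `{C,T}`, `{G,T}`, `{A,C}` would be
  an unplanted TFO or TTS. Background is generated i.i.d. and then
  repaired: any run reaching 20 over any of the four alphabets outside a
  planted tract is broken by substituting a complementary-class base at an
  unprotected position, rescanning to convergence. The cap (19) sits just
  below the detection minimum by construction.
* **Planting.** Tracts are written with two non-extending flanking bases
  per side, making maximality — hence detected coordinates — exact.
  Single-letter sub-runs inside tracts are capped at 8, so no planted tract
  smuggles in a second-alphabet run. GA/TC TFO tracts are genuine duplex
  tracts and join the TTS truth table; intronic target tracts are genuine
  motif runs and join the TFO truth table. Randomly placed TTSs are
  intergenic for exactly this reason (a genic one would be an unplanted
  TFO); genic targets enter via `genic_target_fraction`.
* **Matched vs self-only TFOs.** A `matched_fraction` (default 0.75) of
  TFOs get a decoy TTS elsewhere carrying their signature; the remainder
  are mirror-symmetric GA/TC tracts whose only admissible target is their
  own locus. Because 20-mers over two letters collide at an appreciable
  birthday rate, self-only tracts are regenerated until their signature
  shares no 20-mer with any other tract — making "dropped by self-match
  removal" exactly the designed quarter.
* **Determinism.** Every output is a pure function of the spec; the seed
  is part of it. The same spec yields byte-identical FASTA, GFF3 and truth
  tables.

What the generator does **not** emulate: realistic base composition or
repeat structure (real genomes are far richer in low-complexity purine
tracts), splice variants (one pre-RNA per gene), overlapping genes, and
chromosome-scale heterogeneity. Passing tests therefore demonstrate
algorithmic correctness against exact truth — counts, coordinates,
partitions — not biological performance on a real genome, where detection
volume and the match combinatorics are orders of magnitude larger.

## Parameters at a glance

| Key | Default | Meaning |
|-----|---------|---------|
| `min_tfo_length`, `min_tts_length` | 20 bases | detection minima |
| `error_rate` | 0 | interior mismatches per 20-base window (fraction) |
| `overlap_threshold` | 10 bases | merge if overlap strictly exceeds this |
| `merge_scope` | `class` | merge per source class or globally |
| `bin_size` | 200 000 bases | chromosome profile bin |
| `cumulative_fraction` | 0.75 | match share the selected prefix must reach |
| `rank_by` | `count` | prefix ranking (or `density`) |
| `min_stem`, `loop_min`, `loop_max` | 4, 4, 8 bases | hairpin search |
| `lr_stem`, `lr_max_sep` | 10, 500 bases | long-range pairing search |
| `min_component_size` | 4 genes | network pruning |
| `min_clique` | 3 genes | module seed size |
| `self_match_mode` | `overlap` | self-match removal rule (or `exact`) |
| `baseline_scope` | `genic` | baseline numerator (or `all`) |
| `correction` | `BH` | enrichment correction (or `bonferroni`) |

## Numerical and implementation notes

* All internal coordinates are 0-based half-open; GFF3 (1-based closed) and
  BED convert at the I/O boundary only. Truth tables are 0-based half-open
  and say so in their headers.
* The match engine seeds with `min_len`-mers: every maximal common
  substring of length ≥ `min_len` contains at least one seed, so the
  seed-and-extend enumeration is exhaustive, not heuristic.
* Stem search walks anti-diagonals of the (implicit) complementarity
  matrix; a maximal complementary run yields at most one stem, trimmed
  inward to the smallest separation ≥ `loop_min` (trim parity follows the
  anti-diagonal, so separations move in steps of 2).
* Hypergeometric tails use the exact distribution function; the test suite
  pins them to a combinatorial enumeration oracle to 12 significant digits
  over the full parameter grid for populations up to 25.
* Degenerate inputs are defined, not accidental: empty record sets give
  empty (zero-count) tables; an empty TFO set makes the accessibility
  fraction undefined and errors; zero total gene length errors.

## Problem sizes

The test suite exercises the oracles at the scales the analysis prescribes:
1000 random sequences for run detection, 200 random purine pairs for the
matching oracle, a 1-Mb genome with 50 planted TTSs and 100 planted TFOs
for planted recovery and self-match accounting, 500 random intervals for
merge semantics, 300-base sequences for the stem oracle, and the full
hypergeometric grid to N = 25. `scripts/acceptance.R` re-runs the 1-Mb
study end to end; the default suite finishes in well under five minutes on
one CPU.

## Known limitations

* No thermodynamic scoring: matches are combinatorial candidates, not
  ranked binding predictions, and no pH or stability model is applied.
* Mature-transcript analysis assumes exon-concatenated sequences supplied
  (or derived) per gene model; fusion transcripts and trans-splicing are
  out of scope.
* The module detector is a clique-agglomeration approximation of
  spanning-cluster detection, adequate for planted-clique recovery but not
  parameter-compatible with the original EAGLE implementation.
* Genome-FASTA inputs are assumed to give genes on the coding strand when
  transcript tables are built externally; the synthetic generator
  guarantees this by construction.
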