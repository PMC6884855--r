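---
title: "Large-scale DNA barcoding from multiplexed 1D nanopore reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Large-scale DNA barcoding from multiplexed 1D nanopore reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanobarcoder)
```

## The problem

Species discovery in hyperdiverse invertebrate groups is rate-limited by
specimen sorting. The "reverse workflow" inverts the traditional order:
every specimen is DNA-barcoded first (here the 658-bp Folmer fragment of
mitochondrial COI, amplified with LCO1490/HCO2198), specimens are grouped
into molecular operational taxonomic units (mOTUs) from the barcodes, and
morphology is used afterwards to verify a small subset per mOTU. Nanopore
sequencers make this affordable outside capital-intensive facilities, but
1D nanopore reads carry roughly 10--15% errors, concentrated in
insertions and deletions around homopolymer runs. Every stage of this
package exists to turn that error-prone signal into barcodes accurate
enough for species delimitation, at the scale of thousands of specimens
per flowcell.

`nanobarcoder` implements the full desk side of that workflow: tag
design, read simulation with ground truth, demultiplexing, consensus
calling and polishing, reading-frame-based error correction and
consolidation, QC against independent reference barcodes, mOTU
delimitation, richness estimation, and re-pooling plans.

## Dual-index tags that survive indel errors

Specimens are identified by a 13-nt tag appended to each primer; a pair
of 96-tag panels addresses 96 × 96 > 9200 products. Conventional index
design enforces a minimum *Hamming* distance, which is blind to the
dominant nanopore error mode: two tags can differ at many positions yet
collapse onto each other under a single indel. The design route is
therefore two-staged:

1. `generate_tag_candidates()` rejection-samples tags at pairwise
   distance ≥ 6 (Hamming by default — this stage mirrors conventional
   tools, and a Levenshtein variant is available);
2. `filter_tagset()` applies the indel-aware screens: homopolymer runs
   longer than 2 nt are banned (indel hotspots), tags ending in the
   forward primer's leading motif (`GG` by default, parameterised) are
   banned because they blur the tag/primer boundary, and candidates are
   recursively eliminated — dropping the candidate in the most
   sub-threshold pairs, ties to the lexicographically last — until every
   pair differs by ≥ 3 edits *of any type*.

Demultiplexing tolerates up to 2 tag errors via `build_mutant_index()`:
every string reachable from a tag by ≤ 2 edits is enumerated once and
stored in a lookup, so per-read matching is a hash probe instead of an
alignment. A mutant reachable from two tags is *ambiguous*: it is removed
from the index and recorded, so a lookup never guesses. One deliberate
exception: an exact original tag always resolves to itself, even if it
happens to lie within the error budget of another tag — an exact match
is authoritative.

## The read simulator: what it does and does not emulate

`make_templates()` builds specimen COI templates with a known species
structure: species ancestors derive from a real phorid COI barcode
(GenBank MN403533, bundled; padded by one neutral 5' base to the
canonical 658-nt length) by stop-free random substitutions, specimens
derive from their ancestor the same way. Substitution budgets guarantee
intraspecific p-distances ≤ `intra_max` (default 1%) and interspecific
distances ≥ `inter_min` (default 8%), and realised distances are
verified. Every template stays translatable under the invertebrate
mitochondrial code — the property the error-correction stage exploits.

`simulate_reads()` renders each specimen's product as
`tag_f · LCO1490 · template · revcomp(HCO2198) · revcomp(tag_r)` — 735 nt
for a 658-nt template — emits reads in random orientation, and applies
per-base errors from `error_model()`. The defaults are 4.8%
substitutions, 3.6% insertions and 3.6% deletions (12% total, 60% indel
share), inside the reported 10--15% envelope for 1D reads; indel rates
double inside homopolymer runs ≥ 3 nt (`homopolymer_multiplier = 2`; the
bias is well documented, its magnitude is not, so it is a parameter).
Library anomalies are injected on demand: ligated double products (1470
nt), reads carrying tag pairs absent from the layout, cross-well
contamination, and blank negative wells. Coverage defaults to a
log-normal, matching un-normalised amplicon pools where weak products
populate the re-pooling classes.

The simulator does *not* model signal-level artefacts: quality scores
are uniform placeholders, errors are independent across reads (no
flowcell- or pore-specific systematics), chimeras other than two-product
ligation do not occur, and the "underperforming tag" phenomenon seen in
real panels is data, not mechanism. Passing the recovery tests therefore
demonstrates the pipeline's arithmetic and error tolerance, not
robustness to every failure mode of real flowcells.

## Demultiplexing

Reads shorter than 600 nt are dropped (`length_filter()`), since a full
product is 735 nt. Reads of 1300--2000 nt are scanned after position 650
for a second primer start and split into two candidate subreads
(`split_ligated()`); longer concatenations pass through flagged, as
splitting is only defined for two ligated products. Primers are located
by IUPAC-aware semi-global alignment restricted to the first and last
100 bp of the read (`find_primer()`, error cap 6 for a 25--26-nt
primer). The 20-nt flank outside each primer is homopolymer-compressed
(runs > 3 nt truncated, `compress_homopolymers()`) and every window of
tag-compatible length is probed against the mutant index
(`extract_and_assign_tag()`); windows nearest the primer take
precedence, and disagreement at the best offset yields no call. A read
is assigned only when **both** tags resolve and the pair exists in the
plate layout — single-tag rescue is deliberately rejected as
unverifiable. Reads resolving to tag pairs *absent* from the layout are
counted separately: they can only arise from misassignment, so their
rate is the demultiplexing error estimate (`demux_error_from_unused()`).
Qualities are ignored throughout: on this data, quality filtering costs
more demultiplexable reads than it saves.

Coordinates are 0-based half-open everywhere; bins store primer-trimmed
template sequences re-oriented to the forward strand.

## Consensus: staggered alignment and the per-site majority rule

The draft barcode is called from a random subsample of ≤ 100 reads per
bin (alignment cost control; the subsample is seed-reproducible). Reads
are multiply aligned with **zero gap-opening cost** (gap-extend 1,
mismatch 1): with opening free, indels and substitutions cost the same,
so the aligner staggers disagreements into separate columns instead of
collapsing them — which is what lets a per-column vote see all the
evidence. This is the opposite of what one wants for homologous
alignment and exactly right for error-laden reads of a single true
sequence.

The built-in engine is a center-star progressive aligner. The center is
the subsampled *medoid* read — the read with the smallest total edit
distance to evenly spaced probe reads, the classical center-star
criterion. An earlier draft of the package used the longest read as
center; that choice systematically anchors the alignment on
insertion-rich reads and measurably degraded consolidated accuracy on
simulations, so the medoid became the default. The candidate and probe
subsets are evenly spaced, keeping the choice deterministic. An external
aligner (`engine = "mafft"`, invoked with `--op 0`) is a pluggable
alternative where the binary exists, and must agree with the built-in
engine on the consensus invariants.

`majority_consensus()` applies the per-site ≥ 50% rule: a column whose
gap count reaches half the depth emits nothing; otherwise the modal base
is emitted if it reaches half the depth, else `N`. Ties at exactly 50%
call the base (ambiguity is defined as *below* half); ties between two
modal bases give `N` (no evidence to choose). Voting per site instead of
filtering whole reads is what lets barcodes be called at 5--20×
coverage. Bins under 5× yield no barcode, and drafts with ≥ 1%
ambiguities are rejected (`filter_draft()`) — the re-pooling stage
exists to rescue exactly those.

`polish_barcode()` then re-aligns **all** bin reads (not just the
subsample) to the draft, excludes reads whose alignment divergence
exceeds 15% (sized for 10--15% read error), and re-votes per column. If
fewer than 5 reads survive, the draft is kept and flagged.

## Reading-frame-based indel correction

COI translates without stop codons in its proper frame, so residual
indels betray themselves. `aa_correct()` aligns the barcode to its best
homologous reference (`pick_reference()`, best overlap identity ≥ 70%;
in validation the simulation templates serve leave-one-out). At each
internal alignment indel, candidate repairs — delete the inserted bases,
or insert `N`s for deleted ones; never guess a base — are placed at every
position within `3 × namino` nt of the indel and scored by amino-acid
identity to the reference translation over `namino` codons on each side
(default 2, selectable 1--3; the sweep in the test suite confirms 2 is
not dominated). Ties resolve to the alignment's own position. A run of
≥ 5 consecutive indel columns rejects the barcode as irrecoverable.
Terminal overhangs are length differences, not indel errors, and are
left alone. Because a repair placed at a repeat-shifted position can
occasionally leave an in-frame stop, `final_translation_check()`
replaces any remaining stop codon by `NNN` (whole-codon granularity) and
reports the count. The genetic code defaults to the invertebrate
mitochondrial table and is configurable.

`consolidate_barcodes()` merges the two corrected tracks
(draft-derived and polish-derived) by strict consensus: corrected
barcodes should be indel-free, so the pair is aligned at an elevated
gap-opening cost (3 versus the ~1.5 default of common aligners) and
**any** gap rejects the pair. Per position: agreement keeps the base, a
substitution conflict becomes `N`, and `N` in one track defers to the
other's base. Consolidation therefore removes exactly the errors on
which the tracks disagree; errors shared by both tracks — necessarily
correlated, since both derive from the same reads — survive, which is
why its accuracy sits at or above the corrected tracks' mean rather than
strictly above both.

## QC, mOTUs, richness, re-pooling

`per_base_accuracy()` scores a barcode against an independent reference
(e.g. a short-read barcode of the same extract): `N` is ambiguity, not
error; divergence is computed over determined sites; barcodes diverging
> 3% are excluded before averaging, as such discrepancies indicate
wet-lab mix-ups rather than consensus error. `trim_to_reference()` cuts
the full barcode to the fragment covered by the internal degenerate
primer pair (313 nt, 48% of the barcode, for the standard primers).
`reference_caller()` implements the dominant-sequence rule for
short-read sets (> 50× set coverage, ≥ 10× sequence coverage, ≥ 5×
dominance). `contamination_screen()` applies the ≥ 95% non-target
removal rule against a labelled library, and `secondary_signal_check()`
flags cluster pairs where secondary sequences (≥ 10 counts) from ≥ 2
specimens of one cluster match another cluster's barcodes at ≥ 99% over
≥ 300 nt — repeated cross-cluster signal is more consistent with a
paralog (NuMT) than with sporadic contamination, though the two cannot
be fully distinguished.

mOTU delimitation (`cluster_otus()`) is objective clustering:
single-linkage agglomeration on uncorrected p-distances with pairwise
deletion of gap/ambiguity sites, with a **strict** threshold (a pair at
exactly the threshold is not merged — so "clustering at 3%" means chains
of distances < 0.03). It is implemented as union-find and tested against
an independent connected-components oracle. Partition agreement uses the
match ratio `2·N_match/(N1+N2)` over exactly-identical clusters;
`congruence_threshold_scan()` reports, per incongruent cluster, the
smallest grid threshold at which both clusterings contain it exactly.
`chao1()` uses the classical estimator `S_obs + F1²/(2·F2)`, falling
back to the bias-corrected `S_obs + F1(F1−1)/2` when doubletons are
absent; the abundance CV is reported (the classical form is
conventionally justified when CV > 0.5) but does not gate the choice.
`accumulation_curve()` rarefies specimens without replacement.

`classify_coverage()` encodes the re-pooling decision after a first
sequencing pass: ≤ 10× very low, 10--50× low (both bounds inclusive,
resolving the boundary as (10, 50]), QC-flagged products "problem"
regardless of coverage. `plate_maps()` renders diff-able text grids of
the 96-well plates marking the wells to re-pool.

## Numerical and degenerate-input choices

* Alignment primitives are compiled (Rcpp): unit-cost Levenshtein (with
  capped early-exit variants for rejection sampling), IUPAC-aware
  semi-global primer search (ties to the leftmost hit), and a Gotoh
  aligner with configurable match/mismatch/gap-open/gap-extend costs.
  Overlap (free-end) alignment uses a match reward of −1: a pure
  cost-minimising overlap alignment is degenerate (the fully staggered
  solution costs zero), so reward is required to make overlap optimal.
* Frame detection minimises stop codons over all six frame/strand
  combinations, ties toward frame 0 on the forward strand; sequences
  with > 10 stops in the best frame, or with no informative codon at all
  (e.g. all-N), are flagged untranslatable.
* Empty bins, all-gap columns, missing references, and single-track
  consolidation all return flagged results rather than errors, so a
  plate-scale run never aborts on one bad well.

## Validation scale and what the tests show

The test suite validates each operation against independent oracles
(quadratic-DP edit distance, brute-force tag assignment by direct edit
distance, an independent per-column vote, graph connected components,
`ape`'s p-distances) and runs an end-to-end parameter-recovery
experiment at the study's conditions: 50 specimens across 17 species
with realistic abundances, 12% read error at a 60% indel share,
log-normal coverage with median ≈ 150 reads per amplicon. At that scale
the suite asserts ≥ 99% correct assignment of demultiplexed reads, < 1%
of reads in unused tag combinations, consolidated barcodes of ≥ 99.9%
mean identity with ≤ 1% ambiguities, monotone accuracy through the
stages (draft < polished < corrected < consolidated), and perfect
recovery of the simulated species partition at the 3% threshold (match
ratio ≥ 0.95 asserted). The same experiment, re-seeded from the command
line, is what `scripts/acceptance.R` reports. These sizes keep the whole
suite in a few minutes on one core while leaving every assertion
comfortably away from small-sample noise.
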