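# nanobarcoder

Large-scale COI DNA barcoding from multiplexed 1D nanopore amplicon
reads, in R.

## The problem

Sorting thousands of specimens from hyperdiverse invertebrate taxa into
species is the bottleneck of biodiversity discovery. The *reverse
workflow* barcodes **every** specimen first — the 658-bp Folmer fragment
of mitochondrial COI, amplified with LCO1490/HCO2198 and a 13-nt
specimen tag on each primer — groups the barcodes into molecular
operational taxonomic units (mOTUs), and lets taxonomists verify a few
specimens per mOTU afterwards. Nanopore sequencing makes this affordable
anywhere, but 1D reads carry ~10–15% errors concentrated in homopolymer
indels. `nanobarcoder` implements the computational pipeline that turns
those reads into barcodes accurate enough for species delimitation:

* **tag design** — dual-index 13-nt tag panels screened with an
  indel-aware edit distance (pairwise Levenshtein ≥ 3, no homopolymers
  > 2 nt, no primer-like 3' motif) and a precomputed *mutant index*
  (every string within 2 edits of a tag) for alignment-free,
  error-tolerant demultiplexing;
* **demultiplexing** — IUPAC-aware primer search in the first/last
  100 bp, homopolymer-compressed 20-nt tag flanks, both tags required,
  splitting of ligated double products (1300–2000 nt), and a
  demultiplexing-error estimate from reads falling into tag
  combinations absent from the plate layout;
* **consensus** — per-bin multiple alignment at **zero gap-opening
  cost** (indel and substitution evidence staggered into separate
  columns) with a per-site ≥ 50% majority rule, so barcodes can be
  called from as little as 5× coverage; then realign-and-vote polishing
  of the draft against all bin reads;
* **amino-acid correction** — COI must translate; residual indels are
  repaired against the best homologous reference, candidate repairs
  scored by amino-acid identity over `namino` codons per side,
  barcodes with ≥ 5 consecutive indels rejected, residual stop codons
  replaced by `NNN`; the two corrected tracks are **consolidated** by
  strict consensus (any gap in their alignment rejects the pair;
  substitution conflicts become `N`);
* **QC** — per-base accuracy against independent reference barcodes
  (> 3% divergence excluded as wet-lab error), trimming to the 313-nt
  internal fragment, contamination screening, dominant-sequence
  reference calling, paralog (NuMT) flags from secondary read signal;
* **mOTUs and richness** — objective clustering (single linkage on
  uncorrected p-distances, strict threshold), the match ratio
  2·N<sub>match</sub>/(N₁+N₂) between partitions, congruence threshold
  scans, classical Chao1 (S<sub>obs</sub> + F₁²/2F₂, bias-corrected
  fallback when F₂ = 0) and rarefaction curves;
* **re-pooling** — coverage classes (≤ 10× very low, 10–50× low,
  QC-flagged "problem") and text plate maps that guide re-sequencing of
  weak amplicons on a washed flowcell;
* **simulation** — a ground-truth generator (templates with a known
  species structure derived from a real phorid COI barcode, tagged
  735-nt products, configurable substitution/insertion/deletion rates
  with homopolymer bias, ligated dimers, unused-tag reads,
  contamination, negatives) so every stage is testable end to end.

## Worked example

```r
library(nanobarcoder)

## 1. design an indel-tolerant tag panel
candidates <- generate_tag_candidates(200, length = 13, min_dist = 6, seed = 7)
panel <- filter_tagset(candidates, min_dist = 3, excluded_motif = "GG")
panel
#> Tag set: 106 tags of 13 nt
#>   minimum pairwise edit distance: 4
#>   dropped: homopolymer=89, motif=5, pairwise=0 of 200 candidates

## 2. simulate a small tagged run with known truth (12% read error)
tags  <- setNames(panel$tags, sprintf("T%03d", seq_along(panel$tags)))
truth <- make_templates(c(3, 3, 3), seed = 7)        # 3 species x 3 specimens
layout <- make_plate_layout(truth$specimen_id, tags[1], tags[2:11])
truth  <- assign_layout(truth, layout, coverage = 80)
sim    <- simulate_reads(truth, model = error_model(), seed = 7)

## 3. demultiplex against the mutant index
fidx <- build_mutant_index(tags[1], max_errors = 2)
ridx <- build_mutant_index(tags[2:11], max_errors = 2)
dmx  <- demultiplex(sim$reads, fidx, ridx, layout)
dmx
#> Demultiplexing result
#>   reads: 720 raw, 720 after length filter, 720 units after splitting
#>   assigned: 519 (72.1%) into 9 bins; unused combinations: 0; unassigned: 201

## 4. consensus -> polish -> amino-acid correction -> consolidation
refs <- setNames(truth$template, truth$specimen_id)
bars <- call_barcodes(dmx$bins, ref_library = refs, seed = 7)
bars
#> Barcode set: 9 bins
#>   draft                9
#>   polished             9
#>   draft_corrected      9
#>   polished_corrected   9
#>   consolidated         9

## 5. accuracy against truth, mOTUs, richness
cons <- stage_sequences(bars, "consolidated")
mean(vapply(names(cons), function(s)
  per_base_accuracy(cons[[s]], refs[[s]])$accuracy_pct, numeric(1)))
#> [1] 99.93202

dm <- pdistance_matrix(cons)
p3 <- cluster_otus(dm, threshold = 0.03)
p3
#> Partition at 3.0%: 9 specimens in 3 mOTUs
match_ratio(p3, as_partition(setNames(truth$species,
                                      truth$specimen_id)[names(cons)]))$ratio
#> [1] 1
chao1(as.integer(table(p3$membership)))$estimate
#> [1] 3
```

Reading the numbers: 72% of the error-laden reads resolve both tags and
land in the right bins (the rest are unassigned, never misassigned —
the mutant index refuses ambiguous calls); all nine specimens yield
consolidated barcodes averaging 99.93% identity to their true
templates; clustering them at 3% recovers exactly the three simulated
species (match ratio 1.0), and with no singletons Chao1 equals the
observed richness.

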