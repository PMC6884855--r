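ref657 <- unname(coi_reference())

test_that("per-base accuracy scores substitutions and respects the 3% gate", {
  frag <- substr(ref657, 345, 657)       # a 313-nt fragment
  expect_equal(nchar(frag), 313)
  same <- per_base_accuracy(frag, frag)
  expect_equal(same$accuracy_pct, 100)
  expect_equal(same$divergence, 0)
  expect_false(same$excluded)

  sub1 <- frag
  substr(sub1, 100, 100) <- if (substr(frag, 100, 100) == "A") "G" else "A"
  one <- per_base_accuracy(sub1, frag)
  expect_equal(one$divergence, 1 / 313)
  expect_false(one$excluded)

  sub20 <- frag
  set.seed(3)
  pos <- sample(313, 20)
  for (p in pos)
    substr(sub20, p, p) <- chartr("ACGT", "GTAC", substr(sub20, p, p))
  many <- per_base_accuracy(sub20, frag)
  expect_equal(many$mismatches, 20)
  expect_gt(many$divergence, 0.03)
  expect_true(many$excluded)

  ## N in the query is ambiguity, not error
  subn <- frag
  substr(subn, 50, 50) <- "N"
  amb <- per_base_accuracy(subn, frag)
  expect_equal(amb$n_ambiguous, 1)
  expect_equal(amb$divergence, 0)

  ## exclusion bookkeeping is conservative: flagged + retained = total
  results <- list(same, one, many, amb)
  expect_equal(sum(vapply(results, `[[`, logical(1), "excluded")) +
                 sum(!vapply(results, `[[`, logical(1), "excluded")),
               length(results))
})

test_that("full barcodes trim to the 313-nt short-read fragment", {
  tr <- trim_to_reference(ref657)
  expect_true(tr$found)
  expect_equal(nchar(tr$sequence), 313)
  expect_identical(tr$sequence, substr(ref657, tr$start, tr$end))
  ## ~48% of the full-length barcode
  expect_equal(round(100 * nchar(tr$sequence) / 658), 48)
  ## no internal primer site -> flagged, nothing trimmed
  set.seed(4)
  none <- trim_to_reference(random_dna(1, 400))
  expect_false(none$found)
  expect_true(is.na(none$sequence))
})

test_that("unused tag combinations estimate the demultiplexing error", {
  fake <- function(n_assigned, unused_counts) {
    structure(list(
      unused = if (length(unused_counts))
        data.frame(tag_pair = paste("F01", names(unused_counts)),
                   count = as.integer(unused_counts))
      else data.frame(tag_pair = character(0), count = integer(0)),
      stats = list(n_assigned = n_assigned)), class = "demux_result")
  }
  lay <- make_plate_layout(c("s1", "s2"),
                           c(F01 = "ACTGCATGACTGA"),
                           c(R01 = "GTACGTACGTACG", R02 = "TGCATGCATGCAT",
                             R03 = "CAGTCAGTCAGTC"))
  ## no unused-combination reads -> rate 0
  z <- demux_error_from_unused(fake(500, integer(0)), lay)
  expect_equal(z$rate, 0)
  ## known counts
  e <- demux_error_from_unused(fake(995, c(R09 = 3, R10 = 2)), lay)
  expect_equal(e$rate, 5 / 1000)
  expect_equal(e$per_tag$count[e$per_tag$tag == "F01"], 5)
  ## every combination used -> not estimable
  lay_full <- lay[1:2, ]
  full <- demux_error_from_unused(fake(100, integer(0)), lay_full,
                                  fwd_tags = c(F01 = "ACTGCATGACTGA"),
                                  rev_tags = c(R01 = "GTACGTACGTACG",
                                               R02 = "TGCATGCATGCAT"))
  expect_false(full$estimable)
  expect_true(is.na(full$rate))
})

test_that("demultiplexing error recovered from simulation matches the injected rate", {
  ex <- test_experiment(species_sizes = c(3, 3), coverage = 25, seed = 61,
                        anomalies = anomaly_spec(
                          fraction_unused_tag_reads = 0.04))
  dx <- demultiplex(ex$sim$reads, ex$fwd_index, ex$rev_index, ex$layout)
  est <- demux_error_from_unused(dx, ex$layout,
                                 ex$panel$fwd, ex$panel$rev)
  expect_true(est$estimable)
  ## injected unused reads demultiplex at roughly the overall rate, so
  ## the estimate should be within a loose binomial band of 4%
  expect_gt(est$rate, 0.005)
  expect_lt(est$rate, 0.12)
})

test_that("contamination screening separates target, contaminant, unknown", {
  set.seed(5)
  target <- ref657
  other <- nanobarcoder:::mutate_stopfree(ref657, 5, frame = 0)
  junk <- random_dna(1, 657)
  lib <- c(phorid1 = target, wolbachia1 = other, outgroup = junk)
  taxa <- c("Phoridae", "Wolbachia", "Unknown")

  expect_equal(contamination_screen(target, lib, taxa, "Phoridae")$decision,
               "keep")
  ## barcode ~99% identical to a non-target reference is removed
  expect_equal(contamination_screen(other, lib[-1], taxa[-1],
                                    "Phoridae")$decision, "remove")
  ## nothing close and no target hit in the ranking -> inspect
  far <- random_dna(1, 657)
  res <- contamination_screen(far, lib[-1], taxa[-1], "Phoridae",
                              top_k = 0)
  expect_equal(res$decision, "inspect")
  expect_error(contamination_screen(target, character(0), character(0),
                                    "Phoridae"), "empty")
})

test_that("reference barcodes are called only from dominant clean signal", {
  ok <- reference_caller(c(seqA = 100, seqB = 10))
  expect_true(ok$accepted)
  expect_equal(ok$barcode, "seqA")
  ## dominance below 5x fails
  weak <- reference_caller(c(seqA = 40, seqB = 20))
  expect_false(weak$accepted)
  expect_equal(weak$reason, "dominance too low")
  ## total coverage at or below 50 fails
  low <- reference_caller(c(seqA = 25, seqB = 5))
  expect_false(low$accepted)
  expect_equal(low$reason, "set coverage too low")
  ## dominant sequence itself under 10x fails even with set coverage
  thin <- reference_caller(setNames(c(9, rep(8, 6)),
                                    paste0("seq", LETTERS[1:7])))
  expect_false(thin$accepted)
  expect_equal(thin$reason, "sequence coverage too low")
  ## single clean sequence passes
  single <- reference_caller(c(seqA = 60))
  expect_true(single$accepted)
})

test_that("repeated cross-cluster secondary signal flags paralogy", {
  set.seed(6)
  bcX1 <- ref657
  bcX2 <- nanobarcoder:::mutate_stopfree(ref657, 3, frame = 0)
  bcY <- nanobarcoder:::mutate_stopfree(ref657, 60, frame = 0)
  barcodes <- c(x1 = bcX1, x2 = bcX2, y1 = bcY)
  clusters <- c(x1 = "X", x2 = "X", y1 = "Y")

  ## secondary signal of both X specimens matches cluster Y's barcode
  sec <- list(x1 = setNames(12L, bcY), x2 = setNames(15L, bcY))
  rep1 <- secondary_signal_check(sec, barcodes, clusters)
  expect_true(nrow(rep1$hits) >= 2)
  expect_equal(rep1$flagged_pairs$cluster, "X")
  expect_equal(rep1$flagged_pairs$matched_cluster, "Y")
  expect_gte(rep1$flagged_pairs$n_specimens, 2)

  ## a specimen's own barcode produces no cross report
  own <- secondary_signal_check(list(x1 = setNames(30L, bcX1)),
                                barcodes, clusters)
  expect_equal(nrow(own$hits), 0)

  ## matches below 99% identity are not reported
  div <- nanobarcoder:::mutate_stopfree(ref657, 15, frame = 0)  # ~2% off
  rep2 <- secondary_signal_check(list(x1 = setNames(20L, div)),
                                 barcodes[3], clusters[3])
  expect_equal(nrow(rep2$hits), 0)

  ## below the count floor nothing is tested
  rep3 <- secondary_signal_check(list(x1 = setNames(5L, bcY)),
                                 barcodes, clusters)
  expect_equal(nrow(rep3$hits), 0)
})
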