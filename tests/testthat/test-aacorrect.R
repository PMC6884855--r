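ref657 <- unname(coi_reference())
ref658 <- unname(coi_reference(pad_to_canonical = TRUE))

test_that("frame detection finds the stop-free frame of a real COI barcode", {
  fr <- detect_frame(ref657)
  expect_equal(fr$frame, 0)
  expect_equal(fr$strand, "+")
  expect_equal(fr$stops, 0)
  expect_false(fr$untranslatable)
  ## the padded canonical-length variant shifts the frame by one
  expect_equal(detect_frame(ref658)$frame, 1)
  ## frame detection is strand-aware
  fr_rc <- detect_frame(revcomp(ref657))
  expect_equal(fr_rc$strand, "-")
  expect_equal(fr_rc$stops, 0)
})

test_that("a frameshift produces downstream stops; all-N is untranslatable", {
  ## direct-translation oracle: fewest stops over all frame/strand combos
  oracle_min_stops <- function(s) {
    min(vapply(0:2, function(f)
      min(nanobarcoder:::count_stops(s, f),
          nanobarcoder:::count_stops(revcomp(s), f)), integer(1)))
  }
  ## pick a deletion site that the oracle confirms breaks every frame
  ## (a lucky shift can leave one alternative frame stop-free)
  for (p in 90:130) {
    shifted <- paste0(substr(ref657, 1, p - 1), substr(ref657, p + 1, 657))
    if (oracle_min_stops(shifted) >= 1) break
  }
  expect_gte(oracle_min_stops(shifted), 1)
  fr <- detect_frame(shifted)
  expect_equal(fr$stops, oracle_min_stops(shifted))
  nn <- detect_frame(strrep("N", 120))
  expect_true(nn$untranslatable)
})

test_that("indel-free barcodes pass through correction unchanged", {
  ## a conspecific-level reference: the padded sequence with a few
  ## substitutions
  set.seed(5)
  ref <- nanobarcoder:::mutate_stopfree(ref658, 6, frame = 1)
  out <- aa_correct(ref658, ref, ref_frame = 1)
  expect_equal(out$status, "unchanged")
  expect_identical(out$barcode$sequence, ref658)
  expect_equal(out$n_insertions_removed, 0)
})

test_that("single indel errors are repaired to a translatable barcode", {
  set.seed(6)
  ref <- nanobarcoder:::mutate_stopfree(ref658, 5, frame = 1)
  n_ok_len <- 0L; n_ok_frame <- 0L; accs <- numeric(0)
  for (i in 1:100) {
    p <- sample(30:620, 1)
    broken <- paste0(substr(ref658, 1, p - 1), substr(ref658, p + 1, 658))
    out <- aa_correct(broken, ref, ref_frame = 1)
    expect_equal(out$status, "corrected")
    seq <- out$barcode$sequence
    if (nchar(seq) == 658) n_ok_len <- n_ok_len + 1L
    if (nanobarcoder:::count_stops(seq, 1) == 0) n_ok_frame <- n_ok_frame + 1L
    accs <- c(accs, per_base_accuracy(seq, ref658)$matches)
  }
  expect_equal(n_ok_len, 100)        # deletion refilled with N
  expect_equal(n_ok_frame, 100)      # reading frame restored
  ## at most the deleted base (plus its N placeholder) is lost
  expect_true(all(accs >= 656))

  ## symmetric case: one inserted base is deleted again; the occasional
  ## repair at a repeat-shifted position can leave a stop, which the
  ## final translation check converts to ambiguities -- the pipeline
  ## guarantee is stop-free output
  set.seed(7)
  for (i in 1:20) {
    p <- sample(30:620, 1)
    broken <- paste0(substr(ref658, 1, p), "A", substr(ref658, p + 1, 658))
    out <- aa_correct(broken, ref, ref_frame = 1)
    expect_equal(out$status, "corrected")
    expect_equal(nchar(out$barcode$sequence), 658)
    fixed <- final_translation_check(out$barcode$sequence, frame = 1)
    expect_equal(nanobarcoder:::count_stops(fixed$barcode, 1), 0)
  }
})

test_that("runs of five or more consecutive indels are rejected", {
  ref <- ref658
  ins5 <- paste0(substr(ref, 1, 300), "ACGTA", substr(ref, 301, 658))
  out <- aa_correct(ins5, ref, ref_frame = 1)
  expect_null(out$barcode)
  expect_equal(out$status, "rejected_consecutive_indels")
  ## four consecutive indels are still correctable
  ins4 <- paste0(substr(ref, 1, 300), "ACGT", substr(ref, 301, 658))
  out4 <- aa_correct(ins4, ref, ref_frame = 1)
  expect_false(is.null(out4$barcode))
})

test_that("residual stop codons are replaced by whole-codon ambiguities", {
  clean <- final_translation_check(ref657, frame = 0)
  expect_identical(clean$barcode, ref657)
  expect_equal(clean$n_replaced, 0)
  ## plant one in-frame TAA
  s1 <- ref657
  substr(s1, 301, 303) <- "TAA"
  out1 <- final_translation_check(s1, frame = 0)
  expect_equal(out1$n_replaced, 1)
  expect_identical(substr(out1$barcode, 301, 303), "NNN")
  expect_identical(substr(out1$barcode, 1, 300), substr(ref657, 1, 300))
  ## two stops, two codons replaced
  s2 <- s1
  substr(s2, 601, 603) <- "TAG"
  out2 <- final_translation_check(s2, frame = 0)
  expect_equal(out2$n_replaced, 2)
  expect_identical(substr(out2$barcode, 601, 603), "NNN")
})

test_that("consolidation takes a strict consensus and rejects gapped pairs", {
  a <- barcode("s", ref658, stage = "draft_corrected")
  b <- barcode("s", ref658, stage = "polished_corrected")
  same <- consolidate_barcodes(a, b)
  expect_equal(same$status, "consolidated")
  expect_identical(same$barcode$sequence, ref658)
  expect_equal(same$n_conflicts, 0)

  ## substitution conflict -> N at that position
  s2 <- ref658
  pos <- 200
  old <- substr(s2, pos, pos)
  substr(s2, pos, pos) <- if (old == "A") "G" else "A"
  conf <- consolidate_barcodes(a, barcode("s", s2))
  expect_equal(conf$n_conflicts, 1)
  expect_identical(substr(conf$barcode$sequence, pos, pos), "N")

  ## N in one track defers to the determined base of the other
  s3 <- ref658
  substr(s3, 150, 150) <- "N"
  defer <- consolidate_barcodes(barcode("s", s3), b)
  expect_identical(defer$barcode$sequence, ref658)

  ## length mismatch forces a gap -> rejection
  short <- barcode("s", paste0(substr(ref658, 1, 299),
                               substr(ref658, 301, 658)))
  rej <- consolidate_barcodes(a, short)
  expect_null(rej$barcode)
  expect_equal(rej$status, "rejected_indels")

  ## a missing track passes the other through, flagged
  single <- consolidate_barcodes(a, NULL)
  expect_equal(single$status, "single_track")
  expect_identical(single$barcode$sequence, ref658)

  ## idempotence on any corrected barcode
  expect_identical(consolidate_barcodes(a, a)$barcode$sequence, a$sequence)
})

test_that("correction never loses more barcodes with a wider window and the default namino is sound", {
  ## frameshifted barcodes over a range of positions; accuracy with
  ## namino = 2 should not trail namino = 1 nor namino = 3 meaningfully
  set.seed(8)
  ref <- nanobarcoder:::mutate_stopfree(ref658, 5, frame = 1)
  acc <- matrix(NA_real_, 60, 3)
  for (i in 1:60) {
    p <- sample(40:620, 1)
    broken <- if (i %% 2) {
      paste0(substr(ref658, 1, p - 1), substr(ref658, p + 1, 658))
    } else {
      paste0(substr(ref658, 1, p), "C", substr(ref658, p + 1, 658))
    }
    for (na in 1:3) {
      out <- aa_correct(broken, ref, namino = na, ref_frame = 1)
      if (!is.null(out$barcode))
        acc[i, na] <- per_base_accuracy(out$barcode$sequence,
                                        ref658)$accuracy_pct
    }
  }
  m <- colMeans(acc, na.rm = TRUE)
  expect_gte(m[2], m[1] - 1e-9)
  expect_gte(m[2], m[3] - 0.1)
})
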