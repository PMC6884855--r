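test_that("length filter keeps full amplicons and drops short reads", {
  reads <- setNames(c(strrep("A", 735), strrep("A", 600), strrep("A", 599)),
                    c("full", "at", "below"))
  lf <- length_filter(reads, 600)
  expect_identical(names(lf$reads), c("full", "at"))
  expect_equal(lf$n_input, 3)
  expect_equal(lf$n_kept, 2)
  empty <- length_filter(character(0))
  expect_length(empty$reads, 0)
  expect_equal(empty$n_kept, 0)
})

test_that("primer search finds degenerate primers on either strand", {
  lco <- coi_primers[["LCO1490"]]
  set.seed(8)
  filler <- random_dna(1, 300)
  read <- paste0(lco, filler)
  h <- find_primer(read, lco)
  expect_equal(h$errors, 0)
  expect_equal(h$strand, "+")
  expect_equal(h$start, 0)
  expect_equal(h$end, nchar(lco))

  ## two substitutions at offset 13, position verified against an
  ## exhaustive sliding-window alignment oracle
  mut <- lco
  substr(mut, 3, 3) <- "C"
  substr(mut, 10, 10) <- "G"
  expect_identical(lv_oracle(mut, lco), 2L)
  read2 <- paste0(random_dna(1, 13), mut, filler)
  h2 <- find_primer(read2, lco)
  expect_equal(h2$errors, 2)
  oracle <- min(vapply(1:(100 - nchar(lco) + 1), function(s)
    lv_oracle(substr(read2, s, s + nchar(lco) - 1), lco), integer(1)))
  expect_equal(h2$errors, oracle)
  expect_equal(h2$start, 13)

  ## reverse-strand hit lands in the tail window
  read3 <- paste0(filler, revcomp(lco))
  h3 <- find_primer(read3, lco)
  expect_equal(h3$strand, "-")
  expect_equal(h3$errors, 0)
  expect_equal(h3$end, nchar(read3))

  ## a read without the primer gives no hit
  expect_null(find_primer(random_dna(1, 200), lco))

  ## degenerate positions match their expansions at no cost
  m1co <- coi_primers[["m1COlintF"]]
  concrete <- chartr("WY", "AC", m1co)
  h4 <- find_primer(paste0(concrete, filler), m1co)
  expect_equal(h4$errors, 0)
})

test_that("homopolymer compression truncates runs and matches a regex oracle", {
  expect_identical(compress_homopolymers("AAAAAG"), "AAAG")
  expect_identical(compress_homopolymers("ACGTACGT"), "ACGTACGT")
  expect_identical(compress_homopolymers("TTTT", max_run = 1), "T")
  regex_oracle <- function(x, k)
    gsub(sprintf("([A-Z])\\1{%d,}", k), strrep("\\1", k), x)
  set.seed(12)
  ## low-entropy strings so runs actually occur
  xs <- vapply(1:50, function(i)
    paste(sample(c("A", "T"), 40, replace = TRUE, prob = c(0.7, 0.3)),
          collapse = ""), character(1))
  expect_identical(compress_homopolymers(xs, 3), regex_oracle(xs, 3))
  expect_identical(compress_homopolymers(xs, 2), regex_oracle(xs, 2))
})

test_that("flanking tags are recovered through errors and compression", {
  panel <- test_tag_panel(n_fwd = 4, n_rev = 4, seed = 77)
  idx <- build_mutant_index(panel$fwd, 2)
  lco <- coi_primers[["LCO1490"]]
  tag <- panel$fwd[[2]]
  body <- random_dna(1, 80)

  ## exact tag with 7 upstream bases
  read <- paste0(random_dna(1, 7), tag, lco, body)
  hit <- find_primer(read, lco)
  expect_identical(extract_and_assign_tag(read, hit, idx), 2L)

  ## a homopolymer run inserted inside the tag is healed by compression
  tag_run <- paste0(substr(tag, 1, 6), "AAAAA", substr(tag, 7, 13))
  ## compression turns AAAAA (plus neighbours) into <=3 As; the result is
  ## within 2 edits of the original tag whenever the tag carries an A
  ## nearby, which holds for this panel member
  read2 <- paste0(random_dna(1, 5), tag_run, lco, body)
  hit2 <- find_primer(read2, lco)
  got <- extract_and_assign_tag(read2, hit2, idx)
  comp <- compress_homopolymers(tag_run)
  if (tag_levenshtein(comp, tag) <= 2) expect_identical(got, 2L)

  ## a flank matching no tag within 2 edits resolves to nothing
  read3 <- paste0(strrep("ACGT", 5), lco, body)
  hit3 <- find_primer(read3, lco)
  expect_true(is.na(extract_and_assign_tag(read3, hit3, idx)))

  ## reverse-side extraction: tag appended to the reverse primer
  hco <- coi_primers[["HCO2198"]]
  read4 <- paste0(body, revcomp(hco), revcomp(tag), random_dna(1, 7))
  hit4 <- find_primer(read4, hco)
  expect_equal(hit4$strand, "-")
  expect_identical(extract_and_assign_tag(read4, hit4, idx), 2L)
})

test_that("ligated double products are split, extreme lengths flagged", {
  ex <- test_experiment(coverage = 3, model = error_model(0, 0, 0, 1),
                        seed = 41)
  amp <- ex$sim$reads[[1]]
  expect_identical(split_ligated(amp)$subreads, unname(amp))
  dimer <- paste0(amp, ex$sim$reads[[4]])
  sp <- split_ligated(dimer)
  expect_equal(sp$flag, "split")
  expect_length(sp$subreads, 2)
  expect_equal(nchar(sp$subreads), c(735, 735))
  long <- strrep("ACGT", 625)
  expect_equal(split_ligated(long)$flag, "overlong")
  expect_identical(split_ligated(long)$subreads, long)
})

test_that("error-free demultiplexing recovers every read and template", {
  ex <- test_experiment(coverage = 6, model = error_model(0, 0, 0, 1),
                        seed = 43)
  dx <- demultiplex(ex$sim$reads, ex$fwd_index, ex$rev_index, ex$layout)
  expect_equal(dx$stats$n_assigned, length(ex$sim$reads))
  expect_equal(dx$stats$n_unused_combination, 0)
  truth_map <- setNames(ex$sim$manifest$specimen_id,
                        ex$sim$manifest$read_id)
  got <- setNames(dx$read_assignment$specimen_id,
                  dx$read_assignment$read_id)
  expect_identical(got[names(truth_map)], truth_map)
  ## bins hold the primer-trimmed, re-oriented template
  for (sp in names(dx$bins))
    expect_true(all(dx$bins[[sp]] ==
                    ex$truth$template[ex$truth$specimen_id == sp]))
})

test_that("demultiplexing is invariant under reverse complement", {
  ex <- test_experiment(coverage = 4, seed = 44)   # with errors
  dx1 <- demultiplex(ex$sim$reads, ex$fwd_index, ex$rev_index, ex$layout)
  dx2 <- demultiplex(setNames(revcomp(ex$sim$reads), names(ex$sim$reads)),
                     ex$fwd_index, ex$rev_index, ex$layout)
  expect_identical(dx1$read_assignment$specimen_id,
                   dx2$read_assignment$specimen_id)
  expect_identical(bin_coverage(dx1), bin_coverage(dx2))
  ## stored template sequences agree up to a 1-nt primer-boundary shift
  ## (a tie in the primer alignment can resolve to the mirror position)
  for (sp in names(dx1$bins))
    expect_true(all(tag_levenshtein(dx1$bins[[sp]], dx2$bins[[sp]]) <= 2))
})

test_that("read accounting is conserved and no read lands in two bins", {
  ex <- test_experiment(coverage = 8, seed = 45,
                        anomalies = anomaly_spec(
                          fraction_unused_tag_reads = 0.05))
  dx <- demultiplex(ex$sim$reads, ex$fwd_index, ex$rev_index, ex$layout)
  s <- dx$stats
  expect_equal(s$n_assigned + s$n_unused_combination + s$n_unassigned,
               s$n_units)
  expect_equal(sum(bin_coverage(dx)), s$n_assigned)
  ## each unit assigned at most once: bin sizes match assignment table
  tab <- table(dx$read_assignment$specimen_id)
  expect_equal(sort(as.integer(tab)), sort(as.integer(bin_coverage(dx))))
})

test_that("mutant-index demultiplexing equals brute-force edit-distance assignment", {
  ex <- test_experiment(species_sizes = c(2, 2), coverage = 12, seed = 46,
                        n_rev = 6)
  dx <- demultiplex(ex$sim$reads, ex$fwd_index, ex$rev_index, ex$layout,
                    split = FALSE)
  want <- brute_demux(ex$sim$reads, ex$panel$fwd, ex$panel$rev, ex$layout)
  expect_identical(dx$read_assignment$specimen_id, want)
})
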