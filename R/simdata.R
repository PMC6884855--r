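## Ground-truth simulation of tagged COI amplicon sequencing.
##
## The simulator emulates the data structure of a multiplexed 1D nanopore
## barcoding run: each specimen's 658-nt COI template is flanked by tagged
## primers into a 735-nt product, reads are emitted in random orientation
## with per-base substitution/insertion/deletion errors (indel rates
## inflated inside homopolymer runs), and library anomalies (ligated
## double amplicons, unused tag combinations, cross-well contamination,
## blank negatives) can be injected at controlled rates. Every read is
## recorded in a truth manifest so downstream stages can be scored.

GENETIC_CODE_INVERT_MITO <- "SGC4"   # Biostrings id of translation table 5

## codon table lookup, N-containing codons -> X
get_code <- function(code = GENETIC_CODE_INVERT_MITO) {
  Biostrings::getGeneticCode(code)
}

#' Translate a DNA string in a given frame
#'
#' @param seq DNA string.
#' @param frame 0, 1 or 2: offset of the first complete codon.
#' @param code genetic code identifier understood by
#'   [Biostrings::getGeneticCode()]; default is the invertebrate
#'   mitochondrial code.
#' @return single amino-acid string; codons containing non-ACGT symbols
#'   translate to `X`, stop codons to `*`. Trailing partial codons are
#'   dropped.
#' @export
nb_translate <- function(seq, frame = 0, code = GENETIC_CODE_INVERT_MITO) {
  tab <- get_code(code)
  s <- clean_seq(seq)
  s <- substr(s, frame + 1, nchar(s))
  n_codon <- nchar(s) %/% 3
  if (n_codon == 0) return("")
  starts <- (seq_len(n_codon) - 1L) * 3L + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

count_stops <- function(seq, frame, code = GENETIC_CODE_INVERT_MITO) {
  aa <- nb_translate(seq, frame, code)
  lengths(regmatches(aa, gregexpr("*", aa, fixed = TRUE)))
}

## apply k random substitutions to seq, never creating a stop codon in the
## annotated frame and never touching positions in `protect` (1-based)
mutate_stopfree <- function(seq, k, frame, code = GENETIC_CODE_INVERT_MITO,
                            protect = integer(0)) {
  tab <- get_code(code)
  stops <- names(tab)[tab == "*"]
  ch <- seq_chars(seq)[[1]]
  L <- length(ch)
  eligible <- setdiff(seq_len(L), protect)
  pos <- sample(eligible, min(k, length(eligible)))
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    cand <- sample(setdiff(bases, ch[p]))
    for (b in cand) {
      old <- ch[p]
      ch[p] <- b
      ci <- (p - 1 - frame) %/% 3          # codon index, 0-based
      ok <- TRUE
      if (p > frame && ci >= 0) {
        cs <- frame + ci * 3 + 1
        if (cs + 2 <= L) {
          codon <- paste(ch[cs:(cs + 2)], collapse = "")
          ok <- !(codon %in% stops)
        }
      }
      if (ok) break
      ch[p] <- old
    }
  }
  paste(ch, collapse = "")
}

#' Simulate specimen COI templates with a known species structure
#'
#' Species ancestors are derived from a base COI sequence by stop-free
#' random substitutions, then specimens are derived from their ancestor the
#' same way. Substitution budgets are chosen so that intra-species
#' p-distances stay at or below `intra_max` and between-species distances
#' at or above `inter_min`; the realised distances are verified and
#' offending sequences are redrawn a bounded number of times.
#'
#' @param species_sizes integer vector: number of specimens per species.
#' @param intra_max maximum intraspecific p-distance (default 0.01).
#' @param inter_min minimum interspecific p-distance (default 0.08).
#' @param base base template sequence; default is the bundled phorid COI
#'   reference padded to the canonical 658-nt fragment length.
#' @param frame reading-frame offset of `base` (default 1 for the padded
#'   bundled reference).
#' @param seed integer RNG seed, or NULL.
#' @param code genetic code identifier.
#' @param max_tries redraw attempts per sequence before giving up.
#' @return object of class `specimen_truth`: data.frame with columns
#'   `specimen_id`, `species`, `template`; the reading frame and code are
#'   attached as attributes.
#' @export
make_templates <- function(species_sizes, intra_max = 0.01,
                           inter_min = 0.08,
                           base = coi_reference(pad_to_canonical = TRUE),
                           frame = 1, seed = NULL,
                           code = GENETIC_CODE_INVERT_MITO,
                           max_tries = 50) {
  stopifnot(all(species_sizes >= 1))
  if (intra_max >= inter_min)
    stop("infeasible divergence structure: intra_max must be < inter_min",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  base <- clean_seq(base[[1]])
  L <- nchar(base)
  n_sp <- length(species_sizes)

  ## ancestor substitution budget: half-distance inter_min plus headroom so
  ## that random overlap between two ancestors' mutated positions still
  ## leaves >= inter_min differences
  k_anc <- ceiling(L * inter_min / 2 * 1.6)
  p_anc <- function() mutate_stopfree(base, k_anc, frame, code)
  ancestors <- character(n_sp)
  if (n_sp >= 1) ancestors[1] <- if (n_sp == 1) base else p_anc()
  if (n_sp > 1) {
    for (i in seq(2, n_sp)) {
      for (tr in seq_len(max_tries)) {
        cand <- p_anc()
        d <- vapply(ancestors[seq_len(i - 1)], function(a)
          mean(seq_chars(cand)[[1]] != seq_chars(a)[[1]]), numeric(1))
        if (all(d >= inter_min + intra_max)) { ancestors[i] <- cand; break }
        if (tr == max_tries)
          stop("could not place species ancestor ", i,
               " at the requested divergence", call. = FALSE)
      }
    }
  }

  ## specimens: at most floor(intra_max * L / 2) substitutions from the
  ## ancestor, so any two conspecifics differ by <= intra_max * L
  k_max <- floor(intra_max * L / 2)
  ids <- character(0); sp <- integer(0); tmpl <- character(0)
  for (s in seq_len(n_sp)) {
    for (j in seq_len(species_sizes[s])) {
      k <- sample.int(k_max + 1L, 1L) - 1L
      tmpl <- c(tmpl, mutate_stopfree(ancestors[s], k, frame, code))
      sp <- c(sp, s)
    }
  }
  ids <- sprintf("SP%03d_%02d", sp, unlist(lapply(species_sizes, seq_len)))
  out <- data.frame(specimen_id = ids, species = sp, template = tmpl,
                    stringsAsFactors = FALSE)
  attr(out, "frame") <- frame
  attr(out, "code") <- code
  class(out) <- c("specimen_truth", "data.frame")
  out
}

#' Draw per-specimen sequencing coverage
#'
#' Coverage (reads per amplicon) is drawn from a log-normal, the shape
#' typically seen for pooled amplicons without normalisation: a long right
#' tail plus a sizeable fraction of weak products, so the <= 10x and
#' <= 50x re-pooling classes are populated.
#'
#' @param n number of specimens.
#' @param meanlog,sdlog log-normal parameters (defaults give a median of
#'   ~55 reads).
#' @param min_coverage floor applied after rounding (default 0; use e.g. 20
#'   to guarantee callable bins).
#' @param seed RNG seed or NULL.
#' @return integer vector of coverages.
#' @export
draw_coverage <- function(n, meanlog = 4, sdlog = 1, min_coverage = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pmax(as.integer(round(rlnorm(n, meanlog, sdlog))), min_coverage)
}

#' Per-base sequencing error model
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities of a
#'   substitution, an insertion after the base, and a deletion of the
#'   base. The defaults give a 12% total error rate with a 60% indel
#'   share, typical of 1D nanopore reads (overall 1D error is commonly
#'   quoted at 10--15%).
#' @param homopolymer_multiplier factor applied to both indel rates for
#'   bases inside homopolymer runs of length >= 3.
#' @return object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.048, ins_rate = 0.036,
                        del_rate = 0.036, homopolymer_multiplier = 2) {
  stopifnot(sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1, homopolymer_multiplier >= 0)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 homopolymer_multiplier = homopolymer_multiplier,
                 total = sub_rate + ins_rate + del_rate),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "Error model: sub %.1f%%, ins %.1f%%, del %.1f%% (total %.1f%%), homopolymer x%g\n",
    100 * x$sub_rate, 100 * x$ins_rate, 100 * x$del_rate, 100 * x$total,
    x$homopolymer_multiplier))
  invisible(x)
}

#' Library anomaly specification
#'
#' @param fraction_ligated_dimers fraction of reads replaced by two
#'   ligated amplicons (1470 nt before errors).
#' @param fraction_unused_tag_reads fraction of extra reads carrying tag
#'   combinations absent from the layout.
#' @param fraction_cross_contaminating_reads fraction of extra reads that
#'   carry one specimen's tags but another specimen's template.
#' @param negatives character vector of specimen ids to treat as blank
#'   negative controls (no reads emitted).
#' @return object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(fraction_ligated_dimers = 0,
                         fraction_unused_tag_reads = 0,
                         fraction_cross_contaminating_reads = 0,
                         negatives = character(0)) {
  fr <- c(fraction_ligated_dimers, fraction_unused_tag_reads,
          fraction_cross_contaminating_reads)
  stopifnot(all(fr >= 0), all(fr <= 1))
  structure(list(fraction_ligated_dimers = fraction_ligated_dimers,
                 fraction_unused_tag_reads = fraction_unused_tag_reads,
                 fraction_cross_contaminating_reads =
                   fraction_cross_contaminating_reads,
                 negatives = negatives),
            class = "anomaly_spec")
}

## inject errors into one sequence; returns the mutated string
apply_errors <- function(seq, model) {
  ch <- seq_chars(seq)[[1]]
  L <- length(ch)
  if (L == 0 || model$total == 0) return(seq)
  ## per-position indel multiplier inside homopolymer runs >= 3
  r <- rle(ch)
  in_run <- rep(r$lengths >= 3, r$lengths)
  mult <- ifelse(in_run, model$homopolymer_multiplier, 1)
  ins_p <- pmin(model$ins_rate * mult, 0.95)
  del_p <- pmin(model$del_rate * mult, 0.95)
  bases <- c("A", "C", "G", "T")
  ## substitutions
  do_sub <- runif(L) < model$sub_rate
  if (any(do_sub)) {
    ch[do_sub] <- vapply(ch[do_sub], function(b)
      sample(setdiff(bases, b), 1), character(1), USE.NAMES = FALSE)
  }
  ## deletions
  keep <- runif(L) >= del_p
  ## insertions (after each surviving base; inserted base copies its
  ## neighbour half the time, mimicking run-length noise)
  do_ins <- runif(L) < ins_p
  parts <- ifelse(keep, ch, "")
  insb <- ifelse(do_ins & keep,
                 ifelse(runif(L) < 0.5, ch, sample(bases, L, replace = TRUE)),
                 "")
  paste0(parts, insb, collapse = "")
}

## assemble the +-strand product for one specimen
build_amplicon <- function(template, tag_f, tag_r, primers = coi_primers) {
  paste0(tag_f, primers[["LCO1490"]], template,
         revcomp(primers[["HCO2198"]]), revcomp(tag_r))
}

#' Simulate tagged nanopore amplicon reads with a truth manifest
#'
#' Each specimen's product is `tag_f + forward primer + template +
#' revcomp(reverse primer) + revcomp(tag_r)` (735 nt for a 658-nt
#' template). Reads are emitted in random orientation, carry per-base
#' errors from `model`, and optional anomalies from `anomalies`.
#'
#' @param truth a `specimen_truth` data.frame (see [make_templates()])
#'   augmented with columns `tag_f`, `tag_r` (tag sequences) and
#'   `coverage` (reads per specimen); see [assign_layout()].
#' @param model an [error_model()].
#' @param anomalies an [anomaly_spec()].
#' @param primers named primer vector with `LCO1490` and `HCO2198`.
#' @param unused_tag_pairs data.frame with columns `tag_f`, `tag_r` of
#'   combinations absent from the layout; required when
#'   `fraction_unused_tag_reads > 0`.
#' @param seed RNG seed or NULL.
#' @return list with `reads` (named character vector) and `manifest`
#'   (data.frame: `read_id`, `specimen_id`, `type` in
#'   normal/dimer/unused_tags/cross_contamination, `template_of`, and
#'   `dimer_partner`, the specimen whose product forms the second half
#'   of a ligated read).
#' @export
simulate_reads <- function(truth, model = error_model(),
                           anomalies = anomaly_spec(),
                           primers = coi_primers,
                           unused_tag_pairs = NULL, seed = NULL) {
  stopifnot(all(c("specimen_id", "template", "tag_f", "tag_r", "coverage")
                %in% names(truth)))
  if (!is.null(seed)) set.seed(seed)
  truth <- as.data.frame(truth)
  truth$coverage[truth$specimen_id %in% anomalies$negatives] <- 0L

  amp <- vapply(seq_len(nrow(truth)), function(i)
    build_amplicon(truth$template[i], truth$tag_f[i], truth$tag_r[i],
                   primers), character(1))
  names(amp) <- truth$specimen_id

  src <- rep(seq_len(nrow(truth)), truth$coverage)
  n <- length(src)
  type <- rep("normal", n)
  template_of <- truth$specimen_id[src]

  ## ligated dimers: the read is this product plus a random second product
  is_dimer <- runif(n) < anomalies$fraction_ligated_dimers
  ## cross-contamination: this specimen's tags, another specimen's template
  is_cross <- !is_dimer &
    runif(n) < anomalies$fraction_cross_contaminating_reads

  seqs <- character(n)
  dimer_partner <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    i <- src[k]
    if (is_cross[k] && nrow(truth) > 1) {
      j <- sample(setdiff(seq_len(nrow(truth)), i), 1)
      s <- build_amplicon(truth$template[j], truth$tag_f[i],
                          truth$tag_r[i], primers)
      type[k] <- "cross_contamination"
      template_of[k] <- truth$specimen_id[j]
    } else {
      s <- amp[i]
    }
    if (is_dimer[k]) {
      j <- sample(seq_len(nrow(truth)), 1)
      s <- paste0(s, amp[j])
      type[k] <- "dimer"
      dimer_partner[k] <- truth$specimen_id[j]
    }
    seqs[k] <- s
  }

  ## reads into unused tag combinations (extra reads on top of coverage)
  n_unused <- round(anomalies$fraction_unused_tag_reads * n)
  if (n_unused > 0) {
    if (is.null(unused_tag_pairs) || nrow(unused_tag_pairs) == 0)
      stop("unused_tag_pairs required when fraction_unused_tag_reads > 0",
           call. = FALSE)
    pick_pair <- sample(nrow(unused_tag_pairs), n_unused, replace = TRUE)
    pick_tmpl <- sample(nrow(truth), n_unused, replace = TRUE)
    useq <- vapply(seq_len(n_unused), function(k)
      build_amplicon(truth$template[pick_tmpl[k]],
                     unused_tag_pairs$tag_f[pick_pair[k]],
                     unused_tag_pairs$tag_r[pick_pair[k]], primers),
      character(1))
    seqs <- c(seqs, useq)
    type <- c(type, rep("unused_tags", n_unused))
    src <- c(src, rep(NA_integer_, n_unused))
    template_of <- c(template_of, truth$specimen_id[pick_tmpl])
    dimer_partner <- c(dimer_partner, rep(NA_character_, n_unused))
  }

  n_all <- length(seqs)
  ## random orientation, then errors
  flip <- runif(n_all) < 0.5
  seqs[flip] <- revcomp(seqs[flip])
  if (model$total > 0)
    seqs <- vapply(seqs, apply_errors, character(1), model = model,
                   USE.NAMES = FALSE)

  ids <- sprintf("read%06d", seq_len(n_all))
  names(seqs) <- ids
  manifest <- data.frame(
    read_id = ids,
    specimen_id = ifelse(is.na(src), NA_character_,
                         truth$specimen_id[ifelse(is.na(src), 1L, src)]),
    type = type,
    template_of = template_of,
    dimer_partner = dimer_partner,
    stringsAsFactors = FALSE)
  list(reads = seqs, manifest = manifest)
}
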