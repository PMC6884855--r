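## Reading-frame-based indel correction of COI consensus barcodes.
##
## Protein-coding COI translates without stop codons in its proper frame,
## so residual indel errors in a consensus barcode betray themselves as
## frameshifts. Each barcode is aligned against its best homologous
## reference; at every alignment indel, candidate repairs (delete the
## inserted bases, or insert Ns for the deleted ones) are scored by
## amino-acid identity to the reference translation over a window of
## `namino` codons on each side, and the best-scoring repair is applied.
## Barcodes with runs of >= 5 consecutive indels are considered
## irrecoverable and rejected. A final translation check replaces any
## remaining in-frame stop codon by NNN. The two corrected consensus
## tracks (draft-derived and polish-derived) are then consolidated into a
## strict consensus, rejecting pairs whose alignment still needs gaps.

#' Detect the reading frame of a COI barcode
#'
#' Translates the sequence in all six frame/strand combinations under the
#' configured mitochondrial code and returns the combination with the
#' fewest stop codons; ties break toward frame 0 on the + strand.
#'
#' @param seq DNA string (>= 30 nt recommended).
#' @param code genetic code identifier (default invertebrate
#'   mitochondrial).
#' @param max_stops stop count above which the sequence is flagged
#'   untranslatable (default 10).
#' @return list with `frame` (0/1/2), `strand` ("+"/"-"), `stops`
#'   (count in the chosen frame) and `untranslatable` (logical; also set
#'   when no codon translates to a determined amino acid, e.g. an all-N
#'   sequence).
#' @export
detect_frame <- function(seq, code = GENETIC_CODE_INVERT_MITO,
                         max_stops = 10) {
  seq <- clean_seq(seq)
  combos <- expand.grid(frame = 0:2, strand = c("+", "-"),
                        stringsAsFactors = FALSE)
  stops <- vapply(seq_len(nrow(combos)), function(i) {
    s <- if (combos$strand[i] == "+") seq else revcomp(seq)
    count_stops(s, combos$frame[i], code)
  }, integer(1))
  best <- which.min(stops)     # expand.grid order ties toward frame 0, "+"
  bs <- if (combos$strand[best] == "+") seq else revcomp(seq)
  aa <- nb_translate(bs, combos$frame[best], code)
  informative <- nchar(gsub("X", "", aa, fixed = TRUE))
  list(frame = combos$frame[best], strand = combos$strand[best],
       stops = stops[best],
       untranslatable = stops[best] > max_stops || informative == 0)
}

## amino-acid identity between two equal-frame DNA windows
aa_identity <- function(a, b, code) {
  pa <- strsplit(nb_translate(a, 0, code), "")[[1]]
  pb <- strsplit(nb_translate(b, 0, code), "")[[1]]
  n <- min(length(pa), length(pb))
  if (n == 0) return(0)
  sum(pa[seq_len(n)] == pb[seq_len(n)])
}

## indel runs in an alignment: columns where exactly one row is gapped,
## grouped into maximal consecutive stretches
indel_runs <- function(qa, ra) {
  q <- strsplit(qa, "")[[1]]; r <- strsplit(ra, "")[[1]]
  gap <- (q == "-") | (r == "-")
  if (!any(gap)) return(NULL)
  rr <- rle(gap)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1L
  data.frame(start = starts[rr$values], end = ends[rr$values])
}

#' Select the best homologous reference for a barcode
#'
#' Ranks the reference library by alignment identity to the query and
#' returns the best match above `min_identity`.
#'
#' @param seq query barcode sequence.
#' @param ref_library named character vector of reference barcodes.
#' @param min_identity minimum fractional identity (default 0.7).
#' @param exclude reference names never returned (e.g. the query's own
#'   specimen in leave-one-out validation).
#' @return list with `name`, `sequence`, `identity`, or NULL when no
#'   reference passes.
#' @export
pick_reference <- function(seq, ref_library, min_identity = 0.7,
                           exclude = character(0)) {
  ref_library <- ref_library[setdiff(names(ref_library), exclude)]
  if (length(ref_library) == 0) return(NULL)
  ident <- vapply(ref_library, function(r) {
    al <- .align_pair_cpp(toupper(seq), toupper(r), 1, 2, 1, FALSE, TRUE, -1)
    a <- strsplit(al[1], "")[[1]]; b <- strsplit(al[2], "")[[1]]
    inner <- a != "-" & b != "-"
    if (!any(inner)) return(0)
    sum(a[inner] == b[inner]) / sum(inner)
  }, numeric(1))
  best <- which.max(ident)
  if (ident[best] < min_identity) return(NULL)
  list(name = names(ref_library)[best],
       sequence = unname(toupper(ref_library[[best]])),
       identity = unname(ident[best]))
}

#' Amino-acid-guided indel correction of a consensus barcode
#'
#' Aligns the barcode to a homologous reference of known frame and
#' repairs every internal alignment indel: inserted bases are deleted,
#' deleted bases are replaced by N (no base is ever guessed). When the
#' repair position is ambiguous (typically inside a homopolymer run) the
#' candidate positions within `3 * namino` nt of the indel are scored by
#' amino-acid identity to the reference translation over `namino` codons
#' on each side and the best-scoring repair is applied (ties toward the
#' alignment's own position). Barcodes containing a run of
#' `max_consecutive_indels` or more consecutive indel columns are
#' rejected.
#'
#' @param bc a `barcode` (or a plain sequence string).
#' @param reference homologous reference sequence, in frame `ref_frame`.
#' @param namino codons inspected on each side of an indel (1, 2 or 3;
#'   default 2).
#' @param max_consecutive_indels rejection threshold (default 5).
#' @param ref_frame frame offset of the reference (default 0).
#' @param code genetic code identifier.
#' @return list with `barcode` (corrected `barcode` object or NULL when
#'   rejected), `status` ("corrected", "unchanged", or
#'   "rejected_consecutive_indels"), `n_insertions_removed`,
#'   `n_deletions_filled`.
#' @export
aa_correct <- function(bc, reference, namino = 2,
                       max_consecutive_indels = 5, ref_frame = 0,
                       code = GENETIC_CODE_INVERT_MITO) {
  stopifnot(namino %in% 1:3)
  is_bc <- inherits(bc, "barcode")
  seq <- toupper(if (is_bc) bc$sequence else bc)
  reference <- toupper(reference)
  al <- .align_pair_cpp(seq, reference, 1, 2, 1, FALSE, TRUE, -1)
  qa <- al[1]; ra <- al[2]
  runs <- indel_runs(qa, ra)

  q <- strsplit(qa, "")[[1]]; r <- strsplit(ra, "")[[1]]
  ## ignore terminal overhangs (length difference, not indel errors)
  inner <- which(q != "-" & r != "-")
  if (length(inner) == 0)
    return(list(barcode = NULL, status = "rejected_no_overlap",
                n_insertions_removed = 0, n_deletions_filled = 0))
  lo <- min(inner); hi <- max(inner)
  if (!is.null(runs))
    runs <- runs[runs$start > lo & runs$end < hi, , drop = FALSE]

  if (!is.null(runs) && nrow(runs) &&
      any(runs$end - runs$start + 1L >= max_consecutive_indels))
    return(list(barcode = NULL, status = "rejected_consecutive_indels",
                n_insertions_removed = 0, n_deletions_filled = 0))

  n_ins <- 0L; n_del <- 0L
  if (!is.null(runs) && nrow(runs)) {
    ## work on a copy of the query; process runs right-to-left so earlier
    ## coordinates stay valid
    qpos <- cumsum(q != "-")            # alignment column -> query position
    rpos <- cumsum(r != "-")
    work <- seq
    for (k in rev(seq_len(nrow(runs)))) {
      cols <- runs$start[k]:runs$end[k]
      ins_cols <- cols[r[cols] == "-"]  # bases present only in the query
      del_cols <- cols[q[cols] == "-"]  # bases present only in the reference
      if (length(ins_cols)) {
        L <- length(ins_cols)
        p0 <- qpos[ins_cols[1]]         # first inserted base, query coords
        cands <- candidate_positions(work, p0, L, namino)
        scored <- vapply(cands, function(p) {
          cand_seq <- paste0(substr(work, 1, p - 1),
                             substr(work, p + L, nchar(work)))
          score_window(cand_seq, reference, p, rpos[ins_cols[1]],
                       namino, ref_frame, code)
        }, numeric(1))
        best <- cands[order(-scored, abs(cands - p0))][1]
        work <- paste0(substr(work, 1, best - 1),
                       substr(work, best + L, nchar(work)))
        n_ins <- n_ins + L
      }
      if (length(del_cols)) {
        L <- length(del_cols)
        p0 <- qpos[del_cols[1]] + 1L    # insertion point, query coords
        cands <- candidate_positions(work, p0, 0, namino)
        scored <- vapply(cands, function(p) {
          cand_seq <- paste0(substr(work, 1, p - 1), strrep("N", L),
                             substr(work, p, nchar(work)))
          score_window(cand_seq, reference, p, rpos[del_cols[1]],
                       namino, ref_frame, code)
        }, numeric(1))
        best <- cands[order(-scored, abs(cands - p0))][1]
        work <- paste0(substr(work, 1, best - 1), strrep("N", L),
                       substr(work, best, nchar(work)))
        n_del <- n_del + L
      }
    }
    seq_out <- work
    status <- "corrected"
  } else {
    seq_out <- seq
    status <- "unchanged"
  }

  out <- if (is_bc) {
    b <- barcode(bc$specimen_id, seq_out,
                 stage = paste0(bc$stage, "_corrected"),
                 coverage = bc$coverage, flags = bc$flags)
    b
  } else barcode("query", seq_out, stage = "draft_corrected")
  list(barcode = out, status = status,
       n_insertions_removed = n_ins, n_deletions_filled = n_del)
}

## candidate repair positions within 3*namino nt of p0 (1-based, clamped)
candidate_positions <- function(seq, p0, L, namino) {
  w <- 3L * namino
  lo <- max(1L, p0 - w)
  hi <- min(nchar(seq) - max(L - 1L, 0L), p0 + w)
  if (hi < lo) return(p0)
  lo:hi
}

## amino-acid identity of the candidate sequence to the reference over a
## window of namino codons each side of the edit site
score_window <- function(cand_seq, reference, qpos, rpos, namino,
                         ref_frame, code) {
  ## codon index of the edit in reference coordinates
  ci <- max(0L, (rpos - 1L - ref_frame) %/% 3L)
  lo_c <- max(0L, ci - namino)
  hi_c <- ci + namino
  rwin <- substr(reference, ref_frame + lo_c * 3 + 1,
                 min(nchar(reference), ref_frame + (hi_c + 1) * 3))
  ## corresponding query window, assuming co-linearity after the edit
  qlo <- ref_frame + lo_c * 3 + 1 + (qpos - rpos)
  qwin <- substr(cand_seq, max(1, qlo),
                 min(nchar(cand_seq), max(1, qlo) + nchar(rwin) - 1))
  aa_identity(qwin, rwin, code)
}

#' Replace residual in-frame stop codons by ambiguities
#'
#' Safety net after correction: any stop codon remaining in the annotated
#' frame is replaced by NNN, because a stop inside COI always marks an
#' uncorrected error rather than biology.
#'
#' @param bc a `barcode` or plain sequence.
#' @param frame frame offset of the sequence (default 0).
#' @param code genetic code identifier.
#' @return list with `barcode` (or `sequence` input type preserved) and
#'   `n_replaced`.
#' @export
final_translation_check <- function(bc, frame = 0,
                                    code = GENETIC_CODE_INVERT_MITO) {
  is_bc <- inherits(bc, "barcode")
  seq <- toupper(if (is_bc) bc$sequence else bc)
  tab <- get_code(code)
  stops <- names(tab)[tab == "*"]
  ch <- strsplit(seq, "")[[1]]
  n_codon <- (length(ch) - frame) %/% 3
  n_rep <- 0L
  for (i in seq_len(n_codon)) {
    cs <- frame + (i - 1L) * 3L + 1L
    if (paste(ch[cs:(cs + 2)], collapse = "") %in% stops) {
      ch[cs:(cs + 2)] <- "N"
      n_rep <- n_rep + 1L
    }
  }
  seq_out <- paste(ch, collapse = "")
  if (is_bc) {
    out <- barcode(bc$specimen_id, seq_out, stage = bc$stage,
                   coverage = bc$coverage, flags = bc$flags)
  } else out <- seq_out
  list(barcode = out, n_replaced = n_rep)
}

#' Consolidate two corrected barcode tracks into a strict consensus
#'
#' The two amino-acid-corrected barcodes (draft-derived and
#' polish-derived) are pairwise-aligned at an elevated gap-opening cost;
#' since corrected barcodes are expected to be indel-free, any gap in the
#' alignment rejects the pair. Otherwise the strict consensus over
#' determined symbols is returned: agreement keeps the base, substitution
#' conflicts become N, and an N in one track defers to the other track's
#' base.
#'
#' @param a,b corrected `barcode` objects (either may be NULL, in which
#'   case the other passes through flagged).
#' @param gap_open gap-opening cost of the consolidation alignment
#'   (default 3; the default alignment cost elsewhere is ~1.5).
#' @param gap_ext gap extension cost (default 1).
#' @return list with `barcode` (stage "consolidated", or NULL when
#'   rejected), `status` ("consolidated", "single_track",
#'   "rejected_indels"), `n_conflicts`.
#' @export
consolidate_barcodes <- function(a, b, gap_open = 3, gap_ext = 1) {
  if (is.null(a) && is.null(b))
    return(list(barcode = NULL, status = "rejected_missing",
                n_conflicts = NA_integer_))
  if (is.null(a) || is.null(b)) {
    keep <- if (is.null(a)) b else a
    out <- barcode(keep$specimen_id, keep$sequence, "consolidated",
                   keep$coverage, flags = c(keep$flags, "single_track"))
    return(list(barcode = out, status = "single_track", n_conflicts = 0L))
  }
  al <- .align_pair_cpp(toupper(a$sequence), toupper(b$sequence),
                        1, gap_open, gap_ext, FALSE, FALSE)
  qa <- strsplit(al[1], "")[[1]]; qb <- strsplit(al[2], "")[[1]]
  if (any(qa == "-") || any(qb == "-"))
    return(list(barcode = NULL, status = "rejected_indels",
                n_conflicts = NA_integer_))
  cons <- ifelse(qa == qb, qa,
                 ifelse(qa == "N", qb,
                        ifelse(qb == "N", qa, "N")))
  n_conf <- sum(qa != qb & qa != "N" & qb != "N")
  out <- barcode(a$specimen_id, paste(cons, collapse = ""),
                 "consolidated", max(a$coverage, b$coverage))
  list(barcode = out, status = "consolidated", n_conflicts = n_conf)
}
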