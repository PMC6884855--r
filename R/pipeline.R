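## End-to-end barcode calling: demultiplexed bins -> consolidated
## barcodes. Chains the consensus, polishing, amino-acid correction and
## consolidation stages with the standard filters, keeping every
## intermediate stage for QC.

#' Call barcodes for all demultiplexed bins
#'
#' For each bin with sufficient coverage: draft consensus from a read
#' subsample, ambiguity filter, polishing against all reads, amino-acid
#' indel correction of both tracks against the best reference-library
#' match, final stop-codon check, and strict-consensus consolidation.
#'
#' @param bins named list: specimen -> character vector of oriented,
#'   primer-trimmed reads (e.g. `demux_result$bins`).
#' @param ref_library named character vector of homologous reference
#'   barcodes used for the amino-acid correction (e.g. published
#'   conspecific barcodes). Specimens whose own id appears in the library
#'   are matched leave-one-out.
#' @param subsample_n draft subsample size (default 100).
#' @param min_cov minimum bin coverage to call (default 5).
#' @param max_ambiguity draft rejection threshold on the N fraction
#'   (default 0.01).
#' @param max_divergence polish read-exclusion threshold (default 0.15).
#' @param namino correction window in codons (default 2).
#' @param ref_frame reading-frame offset of the reference library
#'   sequences (default 1, the canonical padded fragment).
#' @param gap_open_consolidate consolidation gap-opening cost (default 3).
#' @param seed RNG seed for subsampling.
#' @param code genetic code identifier.
#' @return object of class `barcode_set`: per-specimen list with elements
#'   `draft`, `polished`, `draft_corrected`, `polished_corrected`,
#'   `consolidated` (each a `barcode` or NULL) and `status`.
#' @export
call_barcodes <- function(bins, ref_library, subsample_n = 100,
                          min_cov = 5, max_ambiguity = 0.01,
                          max_divergence = 0.15, namino = 2,
                          ref_frame = 1, gap_open_consolidate = 3,
                          seed = NULL, code = GENETIC_CODE_INVERT_MITO) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(bins))
  names(out) <- names(bins)
  for (sp in names(bins)) {
    reads <- bins[[sp]]
    rec <- list(draft = NULL, polished = NULL, draft_corrected = NULL,
                polished_corrected = NULL, consolidated = NULL,
                status = "ok")
    draft <- call_draft_barcode(reads, sp, subsample_n, min_cov)
    if (is.null(draft)) {
      rec$status <- "low_coverage"
      out[[sp]] <- rec
      next
    }
    if (!filter_draft(draft, max_ambiguity)) {
      rec$status <- "too_ambiguous"
      rec$draft <- draft
      out[[sp]] <- rec
      next
    }
    rec$draft <- draft
    rec$polished <- polish_barcode(draft, reads, max_divergence, min_cov)

    ref <- pick_reference(draft$sequence, ref_library, exclude = sp)
    if (is.null(ref)) {
      rec$status <- "no_reference"
      out[[sp]] <- rec
      next
    }
    correct_track <- function(bc) {
      cr <- aa_correct(bc, ref$sequence, namino = namino,
                       ref_frame = ref_frame, code = code)
      if (is.null(cr$barcode)) return(NULL)
      fr <- detect_frame(cr$barcode$sequence, code)
      final_translation_check(cr$barcode, fr$frame, code)$barcode
    }
    rec$draft_corrected <- correct_track(rec$draft)
    rec$polished_corrected <- correct_track(rec$polished)
    cons <- consolidate_barcodes(rec$draft_corrected,
                                 rec$polished_corrected,
                                 gap_open = gap_open_consolidate)
    rec$consolidated <- cons$barcode
    if (is.null(cons$barcode)) rec$status <- cons$status
    out[[sp]] <- rec
  }
  class(out) <- "barcode_set"
  out
}

#' Extract the sequences of one stage from a barcode set
#'
#' @param x a `barcode_set`.
#' @param stage one of draft, polished, draft_corrected,
#'   polished_corrected, consolidated.
#' @return named character vector (specimens whose stage is missing are
#'   dropped).
#' @export
stage_sequences <- function(x, stage = "consolidated") {
  stopifnot(inherits(x, "barcode_set"))
  keep <- !vapply(x, function(r) is.null(r[[stage]]), logical(1))
  vapply(x[keep], function(r) r[[stage]]$sequence, character(1))
}

#' @export
print.barcode_set <- function(x, ...) {
  n <- length(x)
  stages <- c("draft", "polished", "draft_corrected",
              "polished_corrected", "consolidated")
  cnt <- vapply(stages, function(s) length(stage_sequences(x, s)),
                integer(1))
  cat("Barcode set:", n, "bins\n")
  for (s in stages)
    cat(sprintf("  %-20s %d\n", s, cnt[[s]]))
  invisible(x)
}
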