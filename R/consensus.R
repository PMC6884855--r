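## Consensus barcode calling.
##
## A draft barcode is called per specimen from a read subsample: reads are
## multiply aligned with a zero gap-opening cost so indel and substitution
## evidence is staggered over columns rather than collapsed, then a
## per-column >= 50% majority vote emits the base (or N, or nothing when
## gaps dominate). The draft is then polished by re-aligning *all* bin
## reads to it, dropping reads that diverge too far, and re-voting.

#' Barcode container
#'
#' Light S3 container for a consensus barcode and its bookkeeping.
#'
#' @param specimen_id specimen identifier.
#' @param sequence DNA string, possibly containing N.
#' @param stage one of draft, polished, draft_corrected,
#'   polished_corrected, consolidated.
#' @param coverage number of reads in the bin (not the subsample).
#' @param flags character vector of processing flags.
#' @return object of class `barcode` with computed `ambiguity_fraction`.
#' @export
barcode <- function(specimen_id, sequence, stage = "draft", coverage = NA,
                    flags = character(0)) {
  sequence <- clean_seq(sequence)
  n_amb <- sum(seq_chars(sequence)[[1]] == "N")
  structure(list(specimen_id = specimen_id, sequence = sequence,
                 stage = stage, coverage = coverage,
                 ambiguity_fraction =
                   if (nchar(sequence)) n_amb / nchar(sequence) else NA_real_,
                 flags = flags),
            class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("<barcode %s | %s | %d nt | %.2f%% N | coverage %s>\n",
              x$specimen_id, x$stage, nchar(x$sequence),
              100 * x$ambiguity_fraction, x$coverage))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Random read subsample
#'
#' Uniform sample without replacement of at most `n` reads, used to cap
#' the alignment cost of draft calling; reproducible for a fixed seed.
#'
#' @param reads character vector of bin reads.
#' @param n subsample size (default 100).
#' @param seed RNG seed or NULL.
#' @return character vector of sampled reads.
#' @export
subsample_reads <- function(reads, n = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(reads) <= n) return(reads)
  reads[sort(sample.int(length(reads), n))]
}

## Parse one center/read pairwise alignment into per-center-position
## matched characters and insertion strings. Returns list(match = chr[n],
## ins = chr[n+1]) where ins[k] holds read bases inserted after center
## position k-1 (ins[1] = before the first center base).
parse_center_alignment <- function(c_aln, r_aln) {
  cc <- strsplit(c_aln, "", fixed = TRUE)[[1]]
  rr <- strsplit(r_aln, "", fixed = TRUE)[[1]]
  is_base <- cc != "-"
  n <- sum(is_base)
  match <- rr[is_base]
  grp <- cumsum(is_base)[!is_base]        # 0..n: preceding center position
  ins <- rep("", n + 1)
  if (length(grp)) {
    tapped <- tapply(rr[!is_base], grp, paste, collapse = "")
    ins[as.integer(names(tapped)) + 1L] <- tapped
  }
  list(match = match, ins = ins)
}

## Assemble MSA rows from parsed alignments given the per-gap maximum
## insertion lengths. Inserted bases are left-aligned within their block.
assemble_msa <- function(parsed, ins_max, n, include_center = NULL) {
  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  rows <- vapply(parsed, function(p) {
    blocks <- character(2 * n + 1)
    blocks[seq(1, 2 * n + 1, by = 2)] <- pad(p$ins, ins_max)[seq_len(n + 1)] # nolint
    blocks[seq(2, 2 * n, by = 2)] <- p$match
    paste(blocks, collapse = "")
  }, character(1))
  if (!is.null(include_center)) {
    cb <- strsplit(include_center, "", fixed = TRUE)[[1]]
    blocks <- character(2 * n + 1)
    blocks[seq(1, 2 * n + 1, by = 2)] <- strrep("-", ins_max)
    blocks[seq(2, 2 * n, by = 2)] <- cb
    rows <- c(paste(blocks, collapse = ""), rows)
  }
  rows
}

## deterministic medoid surrogate: among evenly spaced candidate reads,
## pick the one with the smallest total edit distance to evenly spaced
## probe reads (the classical center-star criterion, subsampled)
pick_center <- function(reads, n_cand = 12, n_probe = 25) {
  n <- length(reads)
  if (n <= 2) return(1L)
  cand <- unique(round(seq(1, n, length.out = min(n_cand, n))))
  probe <- unique(round(seq(1, n, length.out = min(n_probe, n))))
  cap <- as.integer(ceiling(0.4 * max(nchar(reads))))
  tot <- vapply(cand, function(i)
    sum(.lv_capped_cpp(reads[[i]], reads[probe], cap)), numeric(1))
  cand[which.min(tot)]
}

#' Multiple alignment of bin reads (zero gap-opening cost)
#'
#' Built-in progressive aligner: a center-star alignment whose center is
#' the (subsampled) medoid read -- the read with the smallest total edit
#' distance to the others, the classical center-star criterion, which
#' avoids anchoring the alignment on an unusually error- or
#' insertion-rich read. Every other read is pairwise-aligned to the
#' center with gap-open 0 / gap-extend 1 / mismatch 1 and the pairwise
#' alignments are merged (insertions relative to the center are pooled
#' per center position, left-aligned within their block). The zero
#' opening cost treats indels and substitutions symmetrically,
#' staggering the alignment so per-column votes see all the evidence. An
#' external aligner (`engine = "mafft"`, run with `--op 0`) is available
#' where the binary is installed and must produce equivalent consensus
#' calls.
#'
#' @param reads character vector of reads (>= 1).
#' @param gap_open,gap_ext,mismatch alignment costs for the built-in
#'   engine.
#' @param engine "builtin" or "mafft".
#' @return character vector of aligned rows (equal width), one per read.
#' @export
align_bin <- function(reads, gap_open = 0, gap_ext = 1, mismatch = 1,
                      engine = c("builtin", "mafft")) {
  engine <- match.arg(engine)
  reads <- toupper(reads)
  if (length(reads) == 0) stop("empty bin", call. = FALSE)
  if (length(reads) == 1) return(reads)
  if (engine == "mafft") return(align_bin_mafft(reads))
  center_i <- pick_center(reads)
  center <- reads[[center_i]]
  others <- reads[-center_i]
  n <- nchar(center)
  parsed <- lapply(others, function(r) {
    al <- .align_pair_cpp(center, r, mismatch, gap_open, gap_ext,
                          FALSE, FALSE)
    parse_center_alignment(al[1], al[2])
  })
  ins_max <- Reduce(pmax, lapply(parsed, function(p) nchar(p$ins)))
  rows <- assemble_msa(parsed, ins_max, n, include_center = center)
  ## restore input order (center first in assembly)
  ord <- c(center_i, seq_along(reads)[-center_i])
  rows[order(ord)]
}

## external-aligner engine; requires the mafft binary on PATH
align_bin_mafft <- function(reads) {
  if (Sys.which("mafft") == "")
    stop("mafft binary not found on PATH", call. = FALSE)
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(setNames(reads, sprintf("r%04d", seq_along(reads))), fin)
  system2("mafft", c("--op", "0", "--quiet", fin), stdout = fout)
  out <- read_fasta(fout)
  unname(toupper(out[sprintf("r%04d", seq_along(reads))]))
}

#' Per-column symbol counts of an alignment
#'
#' @param msa character vector of equal-width aligned rows.
#' @return data.frame with one row per column: counts of A, C, G, T,
#'   `other` (ambiguity codes), `gap`, and `depth` (their sum).
#' @export
consensus_columns <- function(msa) {
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  cnt <- function(s) colSums(m == s)
  a <- cnt("A"); c_ <- cnt("C"); g <- cnt("G"); t <- cnt("T"); gap <- cnt("-")
  other <- nrow(m) - a - c_ - g - t - gap
  data.frame(column = seq_len(ncol(m)), A = a, C = c_, G = g, T = t,
             other = other, gap = gap, depth = nrow(m))
}

#' Majority-rule consensus of an aligned bin
#'
#' Per column: when gaps account for >= 50% of the depth no base is
#' emitted; otherwise the modal base is emitted if its count reaches 50%
#' of the depth (ties at exactly 50% call the base; ties between two
#' modal bases give N) and N is emitted when no base reaches the
#' majority. Bins with fewer than `min_cov` reads yield no barcode.
#'
#' @param msa character vector of aligned rows.
#' @param specimen_id id recorded on the barcode.
#' @param min_cov minimum reads required to call (default 5).
#' @param coverage bin coverage recorded on the barcode (defaults to the
#'   number of MSA rows).
#' @return a `barcode` of stage "draft", or NULL when depth < `min_cov`.
#' @export
majority_consensus <- function(msa, specimen_id = "specimen",
                               min_cov = 5, coverage = NULL) {
  depth <- length(msa)
  if (depth < min_cov) return(NULL)
  prof <- consensus_columns(msa)
  base_counts <- as.matrix(prof[, c("A", "C", "G", "T")])
  emit <- prof$gap < depth / 2
  modal <- max.col(base_counts, ties.method = "first")
  modal_count <- base_counts[cbind(seq_len(nrow(prof)), modal)]
  tie <- rowSums(base_counts == modal_count) > 1
  call <- ifelse(modal_count >= depth / 2 & !tie,
                 c("A", "C", "G", "T")[modal], "N")
  seq <- paste(call[emit], collapse = "")
  barcode(specimen_id, seq, stage = "draft",
          coverage = if (is.null(coverage)) depth else coverage)
}

#' Draft-barcode acceptance filter
#'
#' A preliminary barcode is retained when its ambiguity fraction is below
#' `max_ambiguity` (default 1% N).
#'
#' @param bc a `barcode` (or NULL).
#' @param max_ambiguity rejection threshold on the N fraction.
#' @return TRUE (accept) or FALSE (reject).
#' @export
filter_draft <- function(bc, max_ambiguity = 0.01) {
  if (is.null(bc)) return(FALSE)
  bc$ambiguity_fraction < max_ambiguity
}

#' Call a draft barcode from a demultiplexed bin
#'
#' Convenience wrapper: subsample, align, vote.
#'
#' @param reads character vector of bin reads.
#' @param specimen_id id recorded on the barcode.
#' @param subsample_n reads used for the alignment (default 100).
#' @param min_cov minimum coverage to call (default 5).
#' @param seed RNG seed for the subsample.
#' @param engine alignment engine, see [align_bin()].
#' @return a `barcode` of stage "draft", or NULL.
#' @export
call_draft_barcode <- function(reads, specimen_id = "specimen",
                               subsample_n = 100, min_cov = 5,
                               seed = NULL, engine = "builtin") {
  if (length(reads) < min_cov) return(NULL)
  sub <- subsample_reads(reads, subsample_n, seed)
  msa <- align_bin(sub, engine = engine)
  majority_consensus(msa, specimen_id, min_cov = min_cov,
                     coverage = length(reads))
}

#' Polish a draft barcode by realigning all bin reads
#'
#' Every bin read (not just the draft subsample) is pairwise-aligned to
#' the draft; reads whose alignment divergence (edit columns / alignment
#' length) exceeds `max_divergence` are excluded, and the per-column
#' majority vote is recomputed over the remaining reads against the
#' draft as alignment anchor. When every read is excluded the draft is
#' returned with a `polish_failed` flag.
#'
#' @param draft a `barcode` of stage "draft".
#' @param reads all bin reads.
#' @param max_divergence read exclusion threshold (default 0.15, sized
#'   for ~10-15% 1D read error).
#' @param min_cov minimum surviving reads (default 5).
#' @return a `barcode` of stage "polished" (or the flagged draft).
#' @export
polish_barcode <- function(draft, reads, max_divergence = 0.15,
                           min_cov = 5) {
  stopifnot(inherits(draft, "barcode"))
  center <- draft$sequence
  reads <- toupper(reads)
  als <- lapply(reads, function(r)
    .align_pair_cpp(center, r, 1, 0, 1, FALSE, FALSE))
  div <- vapply(als, function(al) {
    a <- strsplit(al[1], "")[[1]]; b <- strsplit(al[2], "")[[1]]
    mean(a != b)
  }, numeric(1))
  keep <- div <= max_divergence
  if (sum(keep) < min_cov) {
    draft$flags <- c(draft$flags, "polish_failed")
    return(draft)
  }
  parsed <- lapply(als[keep], function(al)
    parse_center_alignment(al[1], al[2]))
  ins_max <- Reduce(pmax, lapply(parsed, function(p) nchar(p$ins)))
  rows <- assemble_msa(parsed, ins_max, nchar(center))
  out <- majority_consensus(rows, draft$specimen_id, min_cov = min_cov,
                            coverage = draft$coverage)
  out$stage <- "polished"
  out$flags <- c(draft$flags, sprintf("polish_excluded=%d", sum(!keep)))
  out
}
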