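## Error-tolerant demultiplexing of tagged nanopore amplicon reads.
##
## A read is assigned to a specimen when both primers are located (within
## the first/last 100 bp, either strand), both flanking tags resolve
## uniquely in the mutant index, and the resulting tag pair is present in
## the plate layout. Homopolymers in the tag flanks are compressed before
## matching, because run-length errors are the dominant nanopore failure
## mode. Reads in the 1300-2000 nt class are first split into two
## candidate subreads, since two amplicons occasionally ligate during
## library preparation.

#' Filter reads by minimum length
#'
#' The full tagged product is 735 nt, so reads much shorter than the
#' amplicon carry no complete barcode; the conventional cutoff is 600 nt.
#'
#' @param reads named character vector of read sequences.
#' @param min_len minimum length retained (default 600).
#' @return list with `reads` (the retained reads), `n_input`, `n_kept`.
#' @export
length_filter <- function(reads, min_len = 600) {
  stopifnot(min_len >= 0)
  keep <- nchar(reads) >= min_len
  list(reads = reads[keep], n_input = length(reads), n_kept = sum(keep))
}

#' Locate a primer near a read end
#'
#' Best semi-global alignment (primer fully aligned, read locally) of the
#' primer within the first `window` bp of the read (strand `+`) and of its
#' reverse complement within the last `window` bp (strand `-`). IUPAC
#' degeneracies in the primer match their expansions at no cost.
#'
#' @param read a single read sequence.
#' @param primer primer sequence (may contain IUPAC codes).
#' @param window search window at each read end in nt (default 100).
#' @param max_errors maximum edit errors tolerated (default 6 for a
#'   25--26-nt primer).
#' @return a list (`primer`, `strand`, `start`, `end`, `errors`) with
#'   0-based half-open read coordinates, or NULL when no hit is within
#'   `max_errors`.
#' @export
find_primer <- function(read, primer, window = 100, max_errors = 6) {
  read <- toupper(read)
  n <- nchar(read)
  if (n == 0) return(NULL)
  w <- min(window, n)
  hits <- list()
  head_seq <- substr(read, 1, w)
  h <- .primer_search_cpp(toupper(primer), head_seq)
  if (h[1] >= 0)
    hits[[length(hits) + 1]] <- list(primer = primer, strand = "+",
                                     start = h[2], end = h[3],
                                     errors = h[1])
  tail_off <- n - w
  tail_seq <- substr(read, tail_off + 1, n)
  h <- .primer_search_cpp(revcomp(toupper(primer)), tail_seq)
  if (h[1] >= 0)
    hits[[length(hits) + 1]] <- list(primer = primer, strand = "-",
                                     start = h[2] + tail_off,
                                     end = h[3] + tail_off,
                                     errors = h[1])
  if (length(hits) == 0) return(NULL)
  errs <- vapply(hits, `[[`, numeric(1), "errors")
  best <- hits[[which.min(errs)]]
  if (best$errors > max_errors) return(NULL)
  best
}

#' Compress homopolymer runs
#'
#' Truncates every run of identical bases longer than `max_run` to
#' `max_run` copies, leaving order untouched. Applied to tag flanks before
#' index lookup so run-length sequencing errors cannot push a tag outside
#' the mutant neighbourhood.
#'
#' @param seq character vector of sequences.
#' @param max_run longest run preserved (default 3).
#' @return character vector of compressed sequences.
#' @export
compress_homopolymers <- function(seq, max_run = 3) {
  stopifnot(max_run >= 1)
  vapply(seq_chars(seq), function(ch) {
    if (length(ch) == 0) return("")
    r <- rle(ch)
    r$lengths <- pmin(r$lengths, max_run)
    paste(inverse.rle(r), collapse = "")
  }, character(1))
}

#' Extract the flanking tag of a primer hit and resolve it
#'
#' Takes `flank` nt outward of the primer alignment, orients it so the tag
#' reads 5'-3' as designed (tag adjacent to the primer), compresses
#' homopolymers, and looks up every window of tag-compatible length
#' (tag length +- `index$max_errors`) in the mutant index. The unique
#' resolved tag wins; when several windows resolve, the window closest to
#' the primer takes precedence, but two windows resolving to different
#' tags at the same best offset give NA.
#'
#' @param read read sequence.
#' @param hit a primer hit from [find_primer()]. For a `+` strand hit the
#'   flank is taken upstream of `start`; for `-`, downstream of `end`,
#'   reverse-complemented.
#' @param index a `mutant_index` built from the tag panel.
#' @param flank flank width in nt (default 20).
#' @param max_run homopolymer compression threshold (default 3).
#' @return integer tag index into `index$tags`, or NA.
#' @export
extract_and_assign_tag <- function(read, hit, index, flank = 20,
                                   max_run = 3) {
  read <- toupper(read)
  n <- nchar(read)
  if (is.null(hit)) return(NA_integer_)
  if (hit$strand == "+") {
    lo <- max(1, hit$start - flank + 1)
    fl <- substr(read, lo, hit$start)          # tag at the 3' end of flank
    fl <- paste(rev(strsplit(fl, "")[[1]]), collapse = "")  # primer-proximal first
    reversed <- TRUE
  } else {
    hi <- min(n, hit$end + flank)
    fl <- substr(read, hit$end + 1, hi)
    fl <- revcomp(fl)
    fl <- paste(rev(strsplit(fl, "")[[1]]), collapse = "")
    reversed <- TRUE
  }
  ## fl is now written primer-proximal base first, reversed; windows taken
  ## from the start are closest to the primer. Un-reverse each window for
  ## lookup.
  flc <- compress_homopolymers(fl, max_run)
  L <- nchar(flc)
  tag_len <- nchar(index$tags[1])
  lens <- seq(max(1, tag_len - index$max_errors),
              tag_len + index$max_errors)
  wins <- character(0); offs <- integer(0)
  for (len in lens) {
    if (L < len) next
    starts <- seq_len(L - len + 1)
    w <- substring(flc, starts, starts + len - 1)
    wins <- c(wins, vapply(strsplit(w, ""), function(ch)
      paste(rev(ch), collapse = ""), character(1)))
    offs <- c(offs, starts)
  }
  if (length(wins) == 0) return(NA_integer_)
  ids <- lookup_tag(index, wins)
  ok <- !is.na(ids)
  if (!any(ok)) return(NA_integer_)
  ids <- ids[ok]; offs <- offs[ok]
  best <- which(offs == min(offs))
  cand <- unique(ids[best])
  if (length(cand) > 1) return(NA_integer_)
  if (length(unique(ids)) > 1) {
    ## windows at worse offsets disagreeing with the best are ignored;
    ## the primer-proximal window is authoritative
  }
  cand
}

#' Split reads consisting of two ligated amplicons
#'
#' Reads shorter than `lower` nt pass through; reads of `lower` to
#' `upper` nt are scanned for the start of a second product after
#' position `search_from` and split there; reads of `upper` nt or longer
#' pass through flagged (splitting is only supported for two ligated
#' products).
#'
#' @param read single read sequence.
#' @param primers primer vector with `LCO1490` and `HCO2198`.
#' @param lower,upper size-class bounds (defaults 1300 and 2000).
#' @param search_from position after which the second product's primer is
#'   searched (default 650).
#' @param max_errors primer error cap.
#' @return list with `subreads` (character vector of 1 or 2) and `flag`
#'   (`""`, `"split"` or `"overlong"`).
#' @export
split_ligated <- function(read, primers = coi_primers, lower = 1300,
                          upper = 2000, search_from = 650, max_errors = 6) {
  read <- toupper(read)
  n <- nchar(read)
  if (n < lower) return(list(subreads = read, flag = ""))
  if (n >= upper) return(list(subreads = read, flag = "overlong"))
  tail_seq <- substr(read, search_from + 1, n)
  ## the boundary is marked by a forward-primer start (second product in
  ## read orientation) or a reverse-primer start (second product flipped);
  ## both are preceded by their 13-nt tag
  cands <- list()
  for (p in c("LCO1490", "HCO2198")) {
    h <- .primer_search_cpp(toupper(primers[[p]]), tail_seq)
    if (h[1] >= 0 && h[1] <= max_errors)
      cands[[length(cands) + 1]] <- c(err = h[1], start = h[2])
  }
  if (length(cands) == 0) return(list(subreads = read, flag = ""))
  errs <- vapply(cands, `[`, numeric(1), "err")
  starts <- vapply(cands, `[`, numeric(1), "start")
  cut <- search_from + min(starts[errs == min(errs)]) - 13
  cut <- max(cut, 1)
  list(subreads = c(substr(read, 1, cut), substr(read, cut + 1, n)),
       flag = "split")
}

#' Demultiplex reads into per-specimen bins
#'
#' Full pipeline for one read set: length filter, ligated-read splitting,
#' primer location on both ends, tag extraction and mutant-index lookup,
#' then assignment of the resolved tag pair against the layout. Reads
#' whose tag pair is absent from the layout are counted separately as the
#' demultiplexing-error estimate. Bin reads are stored primer-trimmed
#' (template region only) and re-oriented to the forward strand.
#'
#' @param reads named character vector of reads.
#' @param fwd_index,rev_index `mutant_index` objects for the forward and
#'   reverse tag panels.
#' @param layout a `plate_layout`.
#' @param primers primer vector with `LCO1490` and `HCO2198`.
#' @param min_len length-filter cutoff (default 600); NULL to skip.
#' @param window primer search window (default 100).
#' @param max_primer_errors primer error cap (default 6).
#' @param flank tag flank width (default 20).
#' @param max_run homopolymer compression threshold (default 3).
#' @param split split ligated double reads first (default TRUE).
#' @return object of class `demux_result`: list with `bins` (named list,
#'   specimen -> character vector of oriented template sequences),
#'   `unused` (data.frame of tag pairs absent from the layout, with
#'   counts), `read_assignment` (read id -> specimen or NA) and `stats`.
#' @export
demultiplex <- function(reads, fwd_index, rev_index, layout,
                        primers = coi_primers, min_len = 600,
                        window = 100, max_primer_errors = 6, flank = 20,
                        max_run = 3, split = TRUE) {
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  n_raw <- length(reads)
  if (!is.null(min_len)) {
    lf <- length_filter(reads, min_len)
    reads <- lf$reads
  }
  n_filtered <- length(reads)

  ## optional splitting of ligated double products
  units <- reads
  unit_src <- names(reads)
  n_split <- 0L
  if (split && length(reads)) {
    out_seq <- list(); out_src <- list()
    for (i in seq_along(reads)) {
      sp <- split_ligated(reads[[i]], primers)
      out_seq[[i]] <- sp$subreads
      out_src[[i]] <- rep(names(reads)[i], length(sp$subreads))
      if (sp$flag == "split") n_split <- n_split + 1L
    }
    units <- unlist(out_seq)
    unit_src <- unlist(out_src)
  }

  used_key <- paste(layout$tag_f_id, layout$tag_r_id)
  spec_of <- setNames(layout$specimen_id, used_key)

  assign_spec <- rep(NA_character_, length(units))
  assign_key <- rep(NA_character_, length(units))
  for (i in seq_along(units)) {
    rd <- units[[i]]
    hf <- find_primer(rd, primers[["LCO1490"]], window, max_primer_errors)
    hr <- find_primer(rd, primers[["HCO2198"]], window, max_primer_errors)
    if (is.null(hf) || is.null(hr)) next
    if (hf$strand == hr$strand) next       # primers must face each other
    if (hf$strand == "-") {                # read is reverse: flip it
      rd <- revcomp(rd)
      n <- nchar(rd)
      hf2 <- list(primer = hf$primer, strand = "+",
                  start = n - hf$end, end = n - hf$start, errors = hf$errors)
      hr2 <- list(primer = hr$primer, strand = "-",
                  start = n - hr$end, end = n - hr$start, errors = hr$errors)
      hf <- hf2; hr <- hr2
    }
    if (hf$end >= hr$start) next           # malformed arrangement
    tf <- extract_and_assign_tag(rd, hf, fwd_index, flank, max_run)
    tr <- extract_and_assign_tag(rd, hr, rev_index, flank, max_run)
    if (is.na(tf) || is.na(tr)) next
    fid <- names(fwd_index$tags)[tf]
    if (is.null(fid)) fid <- sprintf("F%02d", tf)
    rid <- names(rev_index$tags)[tr]
    if (is.null(rid)) rid <- sprintf("R%02d", tr)
    key <- paste(fid, rid)
    assign_key[i] <- key
    if (!is.na(spec_of[key])) {
      assign_spec[i] <- spec_of[[key]]
      ## store the primer-trimmed, oriented template region
      units[[i]] <- substr(rd, hf$end + 1, hr$start)
    }
  }

  assigned <- !is.na(assign_spec)
  in_layout_keys <- assign_key %in% used_key
  unused_mask <- !is.na(assign_key) & !in_layout_keys
  bins <- split(unname(units[assigned]), assign_spec[assigned])
  bins <- lapply(bins, function(x) setNames(x, NULL))

  unused <- data.frame(table(assign_key[unused_mask]),
                       stringsAsFactors = FALSE)
  if (nrow(unused)) {
    names(unused) <- c("tag_pair", "count")
    unused$tag_pair <- as.character(unused$tag_pair)
  } else {
    unused <- data.frame(tag_pair = character(0), count = integer(0))
  }

  stats <- list(
    n_raw = n_raw,
    n_after_length_filter = n_filtered,
    n_units = length(units),
    n_split_reads = n_split,
    n_assigned = sum(assigned),
    n_unused_combination = sum(unused_mask),
    n_unassigned = sum(!assigned & !unused_mask),
    demux_rate = if (n_filtered > 0) sum(assigned) / n_filtered else NA_real_
  )
  structure(list(bins = bins,
                 unused = unused,
                 read_assignment = data.frame(
                   read_id = unit_src,
                   specimen_id = assign_spec,
                   tag_pair = assign_key,
                   stringsAsFactors = FALSE),
                 stats = stats),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  s <- x$stats
  cat("Demultiplexing result\n")
  cat(sprintf("  reads: %d raw, %d after length filter, %d units after splitting\n",
              s$n_raw, s$n_after_length_filter, s$n_units))
  cat(sprintf("  assigned: %d (%.1f%%) into %d bins; unused combinations: %d; unassigned: %d\n",
              s$n_assigned, 100 * s$demux_rate, length(x$bins),
              s$n_unused_combination, s$n_unassigned))
  invisible(x)
}

#' Per-bin coverage of a demultiplexing result
#'
#' @param demux a `demux_result`.
#' @return named integer vector, reads per specimen bin.
#' @export
bin_coverage <- function(demux) {
  vapply(demux$bins, length, integer(1))
}

#' Write demultiplexed bins and a summary table
#'
#' One FASTA per bin plus `demux_summary.tsv` (specimen, coverage) and
#' `unused_combinations.tsv`.
#'
#' @param demux a `demux_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_demux <- function(demux, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(demux$bins)) {
    seqs <- demux$bins[[sp]]
    names(seqs) <- sprintf("%s_read%04d", sp, seq_along(seqs))
    write_fasta(seqs, file.path(dir, paste0(sp, ".fasta")))
  }
  cov <- bin_coverage(demux)
  write.table(data.frame(specimen_id = names(cov), coverage = unname(cov)),
              file.path(dir, "demux_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(demux$unused, file.path(dir, "unused_combinations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
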