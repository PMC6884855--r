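## Quality control of nanopore consensus barcodes.
##
## Barcodes are validated against independent reference barcodes (e.g.
## short-read sequences of the same extracts), demultiplexing error is
## estimated from reads falling into unused tag combinations,
## contaminants are screened against a labelled reference library, and
## secondary signal in read sets flags putative paralogs (NuMTs) or
## low-level cross-well contamination.

#' Per-base accuracy of a barcode against a reference
#'
#' Pairwise-aligns query and reference and scores aligned columns.
#' Ambiguities (N) in the query are counted separately, not as errors;
#' divergence is (mismatches + indels) / (aligned columns excluding query
#' N). Barcodes whose divergence exceeds `max_divergence` (default 3%)
#' are flagged excluded: such discrepancies indicate a wet-lab mix-up
#' rather than consensus error, and are removed before accuracy
#' averaging.
#'
#' @param query barcode sequence (or `barcode` object).
#' @param reference reference sequence for the same specimen.
#' @param max_divergence exclusion threshold (default 0.03).
#' @return list with `overlap` (aligned columns), `matches`,
#'   `mismatches`, `indels`, `n_ambiguous`, `identity` (fraction),
#'   `accuracy_pct`, `divergence`, `excluded`.
#' @export
per_base_accuracy <- function(query, reference, max_divergence = 0.03) {
  if (inherits(query, "barcode")) query <- query$sequence
  al <- .align_pair_cpp(toupper(query), toupper(reference), 1, 2, 1,
                        FALSE, TRUE, -1)
  q <- strsplit(al[1], "")[[1]]; r <- strsplit(al[2], "")[[1]]
  ## trim terminal overhangs: score only between the first and last
  ## column where both sequences have a base
  both <- which(q != "-" & r != "-")
  if (length(both) == 0) stop("no usable overlap", call. = FALSE)
  span <- min(both):max(both)
  q <- q[span]; r <- r[span]
  amb <- q == "N"
  scored <- !amb
  matches <- sum(scored & q == r)
  indels <- sum(scored & (q == "-" | r == "-"))
  mism <- sum(scored) - matches - indels
  divergence <- (mism + indels) / sum(scored)
  list(overlap = length(span), matches = matches, mismatches = mism,
       indels = indels, n_ambiguous = sum(amb),
       identity = matches / sum(scored),
       accuracy_pct = 100 * matches / sum(scored),
       divergence = divergence,
       excluded = divergence > max_divergence)
}

#' Trim a full-length barcode to the reference (short-read) fragment
#'
#' Locates the internal degenerate forward primer in the barcode and
#' returns the region downstream of it, up to the reverse primer site
#' when present (for the standard COI primers this is the 313-nt fragment
#' covered by short-read validation barcodes, 48% of the full barcode).
#'
#' @param seq full-length barcode sequence.
#' @param fwd_primer,rev_primer internal primer pair (defaults
#'   m1COlintF / jgHCO2198).
#' @param max_errors primer site error tolerance (default 5).
#' @return list with `sequence` (trimmed, or NA), `found` (logical),
#'   `start`, `end` (1-based coordinates of the fragment in `seq`).
#' @export
trim_to_reference <- function(seq, fwd_primer = coi_primers[["m1COlintF"]],
                              rev_primer = coi_primers[["jgHCO2198"]],
                              max_errors = 5) {
  seq <- toupper(seq)
  hf <- .primer_search_cpp(toupper(fwd_primer), seq)
  if (hf[1] < 0 || hf[1] > max_errors)
    return(list(sequence = NA_character_, found = FALSE,
                start = NA_integer_, end = NA_integer_))
  from <- hf[3] + 1L                       # first base after the primer
  to <- nchar(seq)
  hr <- .primer_search_cpp(revcomp(toupper(rev_primer)), seq)
  if (hr[1] >= 0 && hr[1] <= max_errors && hr[2] + 1L > from)
    to <- hr[2]                            # last base before the primer
  list(sequence = substr(seq, from, to), found = TRUE,
       start = from, end = to)
}

#' Demultiplexing error estimated from unused tag combinations
#'
#' Reads assigned to tag pairs absent from the layout can only arise from
#' tag misassignment, so their proportion bounds the demultiplexing error
#' rate.
#'
#' @param demux a `demux_result`.
#' @param layout the `plate_layout` in force; when every combination of
#'   the panels is used the rate is not estimable.
#' @param fwd_tags,rev_tags optional full tag panels, to determine
#'   whether unused combinations exist at all.
#' @return list with `estimable`, `rate` (unused / total demultiplexed),
#'   `n_unused`, `n_total`, `per_tag` (counts per offending tag).
#' @export
demux_error_from_unused <- function(demux, layout, fwd_tags = NULL,
                                    rev_tags = NULL) {
  n_unused <- sum(demux$unused$count)
  n_total <- demux$stats$n_assigned + n_unused
  estimable <- TRUE
  if (!is.null(fwd_tags) && !is.null(rev_tags)) {
    n_combos <- length(fwd_tags) * length(rev_tags)
    estimable <- n_combos > length(unique(paste(layout$tag_f_id,
                                                layout$tag_r_id)))
  }
  per_tag <- data.frame(tag = character(0), count = integer(0))
  if (nrow(demux$unused)) {
    tags <- unlist(strsplit(demux$unused$tag_pair, " "))
    cnt <- rep(demux$unused$count, each = 2)
    agg <- tapply(cnt, tags, sum)
    per_tag <- data.frame(tag = names(agg), count = as.integer(agg))
    per_tag <- per_tag[order(-per_tag$count), , drop = FALSE]
    rownames(per_tag) <- NULL
  }
  list(estimable = estimable,
       rate = if (estimable && n_total > 0) n_unused / n_total else NA_real_,
       n_unused = n_unused, n_total = n_total, per_tag = per_tag)
}

## fractional identity of the best overlap alignment of two sequences
alignment_identity <- function(a, b) {
  al <- .align_pair_cpp(toupper(a), toupper(b), 1, 2, 1, FALSE, TRUE, -1)
  q <- strsplit(al[1], "")[[1]]; r <- strsplit(al[2], "")[[1]]
  both <- which(q != "-" & r != "-")
  if (length(both) == 0) return(c(identity = 0, length = 0))
  span <- min(both):max(both)
  c(identity = sum(q[span] == r[span]) / length(span),
    length = length(span))
}

#' Screen a barcode against a labelled reference library
#'
#' A barcode matching a non-target-taxon reference at or above
#' `threshold` identity is removed as a contaminant; when the best match
#' is below `threshold` and no target-taxon sequence appears among the
#' `top_k` matches the specimen is flagged for (morphological)
#' inspection; otherwise it is kept.
#'
#' @param seq barcode sequence.
#' @param library named character vector of reference sequences.
#' @param taxa character vector of taxon labels, parallel to `library`.
#' @param target_taxon label counting as "self" (e.g. "Phoridae").
#' @param threshold identity threshold (default 0.95).
#' @param top_k matches inspected for a target-taxon hit (default 100).
#' @return list with `decision` ("keep", "remove", "inspect"),
#'   `best_match`, `best_identity`, `best_taxon`.
#' @export
contamination_screen <- function(seq, library, taxa, target_taxon,
                                 threshold = 0.95, top_k = 100) {
  if (length(library) == 0) stop("empty reference library", call. = FALSE)
  stopifnot(length(library) == length(taxa))
  ident <- vapply(library, function(r) alignment_identity(seq, r)[1],
                  numeric(1))
  ord <- order(-ident)
  best <- ord[1]
  decision <-
    if (ident[best] >= threshold && taxa[best] != target_taxon) "remove"
    else if (ident[best] < threshold &&
             !(target_taxon %in% taxa[head(ord, top_k)])) "inspect"
    else "keep"
  list(decision = decision,
       best_match = names(library)[best],
       best_identity = unname(ident[best]),
       best_taxon = taxa[best])
}

#' Call a reference barcode from a short-read sequence tally
#'
#' The dominant unique sequence of a demultiplexed short-read set becomes
#' the specimen's reference barcode when three conditions hold: total set
#' coverage above `set_cov_min`, count of the dominant sequence at least
#' `seq_cov_min`, and dominance of at least `dominance` over the runner-up.
#'
#' @param counts named integer vector: unique sequence -> read count.
#' @param set_cov_min minimum total reads in the set (default 50,
#'   exceeded strictly).
#' @param seq_cov_min minimum count of the dominant sequence (default 10).
#' @param dominance minimum ratio dominant / runner-up (default 5).
#' @return list with `barcode` (sequence or NA), `accepted`, `reason`.
#' @export
reference_caller <- function(counts, set_cov_min = 50, seq_cov_min = 10,
                             dominance = 5) {
  if (length(counts) == 0)
    return(list(barcode = NA_character_, accepted = FALSE,
                reason = "empty set"))
  total <- sum(counts)
  ord <- order(-counts)
  top <- counts[ord[1]]
  second <- if (length(counts) > 1) counts[ord[2]] else 0
  reason <- NULL
  if (total <= set_cov_min) reason <- "set coverage too low"
  else if (top < seq_cov_min) reason <- "sequence coverage too low"
  else if (second > 0 && top < dominance * second)
    reason <- "dominance too low"
  if (is.null(reason))
    list(barcode = names(counts)[ord[1]], accepted = TRUE, reason = "ok")
  else
    list(barcode = NA_character_, accepted = FALSE, reason = reason)
}

#' Flag putative paralogs or contamination from secondary read signal
#'
#' Secondary sequences (non-dominant unique sequences with at least
#' `min_count` reads in a specimen's short-read set) are matched against
#' the final barcodes of all *other* specimens. Matches at or above
#' `min_identity` over at least `min_len` aligned nt are reported and
#' aggregated by the (source cluster, target cluster) pair; pairs
#' supported by at least `min_specimens` distinct source specimens are
#' flagged, since repeated cross-cluster signal is more consistent with a
#' paralog than with sporadic contamination.
#'
#' @param secondary named list: specimen -> named integer vector of
#'   secondary sequence counts.
#' @param barcodes named character vector of final barcodes per specimen.
#' @param clusters named vector: specimen -> cluster id.
#' @param min_identity minimum fractional identity (default 0.99).
#' @param min_len minimum aligned length (default 300).
#' @param min_count minimum secondary-sequence count (default 10).
#' @param min_specimens support needed to flag a cluster pair (default 2).
#' @return list with `hits` (data.frame: specimen, cluster, matched
#'   specimen, matched cluster, identity, length) and `flagged_pairs`
#'   (data.frame: cluster pair with supporting specimen count).
#' @export
secondary_signal_check <- function(secondary, barcodes, clusters,
                                   min_identity = 0.99, min_len = 300,
                                   min_count = 10, min_specimens = 2) {
  hits <- list()
  for (sp in names(secondary)) {
    seqs <- secondary[[sp]]
    seqs <- seqs[seqs >= min_count]
    for (s in names(seqs)) {
      for (other in setdiff(names(barcodes), sp)) {
        ai <- alignment_identity(s, barcodes[[other]])
        if (ai["identity"] >= min_identity && ai["length"] >= min_len &&
            !identical(clusters[[sp]], clusters[[other]])) {
          hits[[length(hits) + 1]] <- data.frame(
            specimen = sp, cluster = clusters[[sp]],
            matched_specimen = other, matched_cluster = clusters[[other]],
            identity = unname(ai["identity"]),
            length = unname(ai["length"]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(specimen = character(0), cluster = character(0),
               matched_specimen = character(0),
               matched_cluster = character(0),
               identity = numeric(0), length = numeric(0))
  flagged <- data.frame(cluster = character(0),
                        matched_cluster = character(0),
                        n_specimens = integer(0))
  if (nrow(hits)) {
    key <- paste(hits$cluster, hits$matched_cluster, sep = "->")
    supp <- tapply(hits$specimen, key, function(x) length(unique(x)))
    flag <- names(supp)[supp >= min_specimens]
    if (length(flag)) {
      parts <- strsplit(flag, "->", fixed = TRUE)
      flagged <- data.frame(
        cluster = vapply(parts, `[`, character(1), 1),
        matched_cluster = vapply(parts, `[`, character(1), 2),
        n_specimens = as.integer(supp[flag]),
        stringsAsFactors = FALSE)
    }
  }
  list(hits = hits, flagged_pairs = flagged)
}
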