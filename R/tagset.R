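## Tag design and validation.
##
## Specimens are indexed by appending a 13-nt tag to each PCR primer, so a
## plate grid of 96 x 96 tag combinations can address > 9000 products on one
## flowcell. Nanopore reads carry substitution AND indel errors, so tag sets
## are screened with an indel-aware (Levenshtein) distance rather than the
## Hamming distance used for short-read index design, and demultiplexing
## tolerates up to 2 tag errors via a precomputed mutant lookup.

#' Unit-cost edit (Levenshtein) distance
#'
#' Standard edit distance over insertions, deletions and substitutions,
#' each at cost 1. Characters are compared literally (no IUPAC expansion),
#' which is the appropriate metric for tag design.
#'
#' @param a,b character vectors of sequences; recycled elementwise.
#' @return integer vector of distances.
#' @seealso [tag_distance_matrix()] for all-against-all distances.
#' @export
tag_levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(toupper(a), n)
  b <- rep_len(toupper(b), n)
  vapply(seq_len(n), function(i) .lv_pair_cpp(a[i], b[i]), integer(1))
}

#' All-against-all edit distance matrix
#'
#' @param x,y character vectors; `y` defaults to `x`.
#' @return integer matrix of Levenshtein distances, `length(x)` by
#'   `length(y)`.
#' @export
tag_distance_matrix <- function(x, y = x) {
  m <- .lv_cross_cpp(toupper(x), toupper(y))
  dimnames(m) <- list(names(x), names(y))
  m
}

#' Generate random tag candidates at a minimum mutual distance
#'
#' Rejection sampling: random DNA strings are accepted greedily when their
#' distance to every previously accepted candidate is at least `min_dist`.
#' The generation metric defaults to Hamming distance (substitutions
#' only), the criterion used by conventional index-design tools; such
#' sets are only a starting point, because pairs at large Hamming but
#' small *edit* distance remain confusable under indel errors — that is
#' what the subsequent [filter_tagset()] screen removes. Deterministic
#' for a fixed seed.
#'
#' @param n number of candidates to generate.
#' @param length tag length in nt (default 13).
#' @param min_dist minimum pairwise distance among candidates.
#' @param seed integer RNG seed, or NULL to use the current RNG state.
#' @param metric "hamming" (default) or "levenshtein".
#' @param max_attempts total sampling attempts before giving up.
#' @return character vector of `n` candidate tags.
#' @export
generate_tag_candidates <- function(n, length = 13, min_dist = 6,
                                    seed = NULL,
                                    metric = c("hamming", "levenshtein"),
                                    max_attempts = max(200000L, 400L * n)) {
  stopifnot(n >= 1, length >= 1, min_dist >= 0, length >= min_dist || n == 1)
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  distfun <- if (metric == "hamming") .hamming_capped_cpp else .lv_capped_cpp
  kept <- character(0)
  attempts <- 0L
  while (base::length(kept) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " tags of length ", length,
           " at minimum distance ", min_dist, " within ", max_attempts,
           " attempts", call. = FALSE)
    cand <- random_dna(1, length)
    if (base::length(kept) == 0 ||
        all(distfun(cand, kept, as.integer(min_dist)) >= min_dist))
      kept <- c(kept, cand)
  }
  kept
}

## length of the longest homopolymer run
max_homopolymer_run <- function(x) {
  vapply(seq_chars(x), function(ch) {
    if (length(ch) == 0) return(0L)
    max(rle(ch)$lengths)
  }, integer(1))
}

#' Filter tag candidates into a validated tag set
#'
#' Applies three screens: (i) tags with homopolymer runs longer than
#' `max_homopolymer` nt are removed, because nanopore indel errors
#' concentrate in such runs; (ii) tags ending in `excluded_motif` are
#' removed (by default "GG", which would extend the leading motif of the
#' forward primer and blur the tag/primer boundary); (iii) candidates are
#' eliminated recursively until every pair differs by at least `min_dist`
#' edits of any type. The elimination drops, at each round, the candidate
#' involved in the largest number of sub-threshold pairs (ties resolved by
#' dropping the lexicographically last), so the fewest tags are lost.
#'
#' @param candidates character vector of equal-length DNA tags.
#' @param min_dist minimum pairwise Levenshtein distance to enforce
#'   (default 3).
#' @param max_homopolymer longest allowed homopolymer run (default 2).
#' @param excluded_motif 3'-terminal motif to exclude, or NULL / "" to skip.
#' @return object of class `tag_set`: a list with elements `tags`
#'   (character vector), `min_pairwise_edit` (achieved minimum),
#'   `excluded_motif`, and `n_dropped` per filtering stage.
#' @export
filter_tagset <- function(candidates, min_dist = 3, max_homopolymer = 2,
                          excluded_motif = "GG") {
  candidates <- unique(toupper(candidates))
  assert_dna(candidates, "tag candidate")
  if (length(unique(nchar(candidates))) > 1)
    stop("tag candidates must have equal length", call. = FALSE)
  n0 <- length(candidates)

  keep <- max_homopolymer_run(candidates) <= max_homopolymer
  n_homopolymer <- sum(!keep)
  candidates <- candidates[keep]

  n_motif <- 0L
  if (!is.null(excluded_motif) && nzchar(excluded_motif)) {
    bad <- endsWith(candidates, toupper(excluded_motif))
    n_motif <- sum(bad)
    candidates <- candidates[!bad]
  }

  ## recursive elimination on the pairwise distance graph
  n_pairwise <- 0L
  if (length(candidates) > 1) {
    d <- tag_distance_matrix(candidates)
    close <- d < min_dist
    diag(close) <- FALSE
    while (any(close)) {
      deg <- rowSums(close)
      worst <- which(deg == max(deg))
      if (length(worst) > 1)
        worst <- worst[order(candidates[worst])][length(worst)]
      candidates <- candidates[-worst]
      close <- close[-worst, -worst, drop = FALSE]
      n_pairwise <- n_pairwise + 1L
    }
  }
  if (length(candidates) == 0)
    warning("all candidates were filtered out")

  min_edit <- if (length(candidates) > 1) {
    d <- tag_distance_matrix(candidates)
    min(d[upper.tri(d)])
  } else NA_integer_

  structure(list(
    tags = candidates,
    min_pairwise_edit = min_edit,
    excluded_motif = excluded_motif,
    max_homopolymer = max_homopolymer,
    n_dropped = c(homopolymer = n_homopolymer, motif = n_motif,
                  pairwise = n_pairwise),
    n_input = n0
  ), class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("Tag set:", length(x$tags), "tags of", nchar(x$tags[1]), "nt\n")
  cat("  minimum pairwise edit distance:", x$min_pairwise_edit, "\n")
  cat("  dropped:", paste(names(x$n_dropped), x$n_dropped, sep = "=",
                          collapse = ", "),
      "of", x$n_input, "candidates\n")
  invisible(x)
}

## All strings one edit away from each element of x (plus x itself is NOT
## included). Vectorised over positions and bases.
mutate_once <- function(x) {
  out <- vector("list", length(x))
  bases <- c("A", "C", "G", "T")
  lens <- nchar(x)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    s <- x[idx]
    muts <- vector("list", 3L)
    ## substitutions
    sub <- unlist(lapply(seq_len(L), function(p) {
      pre <- substr(s, 1, p - 1); post <- substr(s, p + 1, L)
      unlist(lapply(bases, function(b) paste0(pre, b, post)))
    }))
    ## deletions
    del <- unlist(lapply(seq_len(L), function(p)
      paste0(substr(s, 1, p - 1), substr(s, p + 1, L))))
    ## insertions
    ins <- unlist(lapply(seq_len(L + 1), function(p) {
      pre <- substr(s, 1, p - 1); post <- substr(s, p, L)
      unlist(lapply(bases, function(b) paste0(pre, b, post)))
    }))
    all <- c(sub, del, ins)
    src <- rep(rep(idx, length.out = length(s)),
               times = length(all) / length(s))
    for (k in seq_along(idx)) {
      i <- idx[k]
      out[[i]] <- unique(all[src == i])
    }
  }
  out
}

#' Build the mutant lookup index for error-tolerant tag matching
#'
#' Enumerates every string reachable from each tag by up to `max_errors`
#' edits (insertions, deletions, substitutions) and records the originating
#' tag. Mutants reachable from two or more different tags are ambiguous;
#' they are excluded from the lookup and reported in the collision list, so
#' a lookup never silently guesses.
#'
#' @param tags character vector of tags, or a `tag_set`.
#' @param max_errors maximum number of edits per tag (default 2, matching
#'   the demultiplexing tolerance).
#' @return object of class `mutant_index`: list with `keys` (mutant
#'   strings), `tag_id` (integer index of the source tag per key), `tags`,
#'   `max_errors`, and `collisions` (ambiguous mutants).
#' @export
build_mutant_index <- function(tags, max_errors = 2) {
  if (inherits(tags, "tag_set")) tags <- tags$tags
  tags <- toupper(tags)
  stopifnot(max_errors >= 0, !anyDuplicated(tags))
  per_tag <- as.list(tags)
  if (max_errors >= 1) {
    frontier <- lapply(tags, function(t) t)
    for (e in seq_len(max_errors)) {
      frontier <- lapply(seq_along(tags), function(i) {
        m <- unlist(mutate_once(unlist(frontier[i])))
        unique(m)
      })
      per_tag <- lapply(seq_along(tags), function(i)
        unique(c(per_tag[[i]], frontier[[i]])))
    }
  }
  keys <- unlist(per_tag, use.names = FALSE)
  ids <- rep(seq_along(tags), lengths(per_tag))
  ## resolve collisions: any key claimed by >= 2 distinct tags is dropped
  ## from the map -- except an exact original tag, which always resolves
  ## to itself (an exact match is authoritative even when the tag lies
  ## within max_errors of another tag)
  dup_keys <- unique(keys[duplicated(keys)])
  collisions <- character(0)
  if (length(dup_keys)) {
    claim <- split(ids[keys %in% dup_keys], keys[keys %in% dup_keys])
    ambig <- names(claim)[vapply(claim, function(v)
      length(unique(v)) > 1, logical(1))]
    collisions <- setdiff(ambig, tags)
    drop <- keys %in% collisions |
      (keys %in% intersect(ambig, tags) & keys != tags[ids])
    keys <- keys[!drop]; ids <- ids[!drop]
    dd <- duplicated(keys)           # same key, same tag: keep one
    keys <- keys[!dd]; ids <- ids[!dd]
  }
  structure(list(keys = keys, tag_id = ids, tags = tags,
                 max_errors = max_errors, collisions = collisions),
            class = "mutant_index")
}

#' @export
print.mutant_index <- function(x, ...) {
  cat("Mutant index:", length(x$tags), "tags,", length(x$keys),
      "lookup keys (<=", x$max_errors, "errors),",
      length(x$collisions), "ambiguous mutants excluded\n")
  invisible(x)
}

#' Look up putative tag sequences in a mutant index
#'
#' @param index a `mutant_index`.
#' @param x character vector of observed candidate tag strings.
#' @return integer vector: the index of the resolved tag in `index$tags`
#'   per query, or NA when the query is no tag's mutant (or an excluded
#'   ambiguous mutant).
#' @export
lookup_tag <- function(index, x) {
  index$tag_id[match(toupper(x), index$keys)]
}

#' Read and write tag files
#'
#' Tags are exchanged as TSV with columns `tag_id`, `role`
#' (forward/reverse) and `sequence`; an optional `deprecated` column flags
#' tags that should not be used in new layouts.
#'
#' @param path file path.
#' @return data.frame of tags.
#' @export
read_tag_file <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "role", "sequence")
  if (!all(need %in% names(df)))
    stop("tag file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$sequence <- toupper(df$sequence)
  assert_dna(df$sequence, "tag")
  df
}

#' @rdname read_tag_file
#' @param tags data.frame with columns `tag_id`, `role`, `sequence`.
#' @export
write_tag_file <- function(tags, path) {
  write.table(tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
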