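## Shared fixtures, all generated in code.

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), character(1))
}

## a small validated tag panel, deterministic
test_tag_panel <- function(n_fwd = 2, n_rev = 8, seed = 101) {
  cands <- generate_tag_candidates(60, 13, 6, seed = seed)
  ts <- filter_tagset(cands)
  stopifnot(length(ts$tags) >= n_fwd + n_rev)
  list(
    fwd = setNames(ts$tags[seq_len(n_fwd)], sprintf("F%02d", seq_len(n_fwd))),
    rev = setNames(ts$tags[n_fwd + seq_len(n_rev)],
                   sprintf("R%02d", seq_len(n_rev))),
    tagset = ts)
}

## small simulated experiment: templates, layout, reads, indices
test_experiment <- function(species_sizes = c(3, 3, 2), coverage = 40,
                            model = error_model(), seed = 7,
                            anomalies = anomaly_spec(), n_rev = 10) {
  panel <- test_tag_panel(n_rev = n_rev, seed = seed + 1)
  truth <- make_templates(species_sizes, seed = seed)
  layout <- make_plate_layout(truth$specimen_id, panel$fwd, panel$rev)
  truth <- assign_layout(truth, layout, coverage = coverage)
  unused <- unused_tag_pairs(layout, panel$fwd, panel$rev)
  sim <- simulate_reads(truth, model = model, anomalies = anomalies,
                        unused_tag_pairs = unused, seed = seed + 2)
  list(truth = truth, layout = layout, sim = sim, panel = panel,
       fwd_index = build_mutant_index(panel$fwd, 2),
       rev_index = build_mutant_index(panel$rev, 2),
       refs = setNames(truth$template, truth$specimen_id))
}

## independent quadratic-DP edit distance oracle (utils::adist)
lv_oracle <- function(a, b) as.integer(utils::adist(a, b))

## independent per-column majority vote, recomputed from scratch
column_vote_oracle <- function(msa, min_cov = 5) {
  if (length(msa) < min_cov) return(NULL)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  depth <- nrow(m)
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (sum(col == "-") >= depth / 2) next
    cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(col == b),
                  integer(1))
    mx <- max(cnt)
    if (mx >= depth / 2 && sum(cnt == mx) == 1)
      out <- c(out, names(cnt)[which.max(cnt)])
    else out <- c(out, "N")
  }
  paste(out, collapse = "")
}

## connected components of the graph {d < t}, breadth-first, independent
## of the union-find implementation under test
components_oracle <- function(dm, threshold) {
  n <- nrow(dm)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(dm[v, ] < threshold & is.na(comp))
      queue <- c(queue, nb)
    }
  }
  comp
}

## brute-force demultiplexer: same primer location, but tags resolved by
## direct edit distance <= 2 of every window of the compressed flank
## against every tag, unique winner at the primer-proximal offset
brute_tag <- function(read, hit, tags) {
  if (is.null(hit)) return(NA_integer_)
  n <- nchar(read)
  fl <- if (hit$strand == "+") {
    substr(read, max(1, hit$start - 19), hit$start)
  } else revcomp(substr(read, hit$end + 1, min(n, hit$end + 20)))
  flc <- compress_homopolymers(fl, 3)
  L <- nchar(flc)
  best_off <- Inf; best <- integer(0)
  for (len in 11:15) {
    if (L < len) next
    for (s in seq_len(L - len + 1)) {
      w <- substr(flc, s, s + len - 1)
      off <- L - (s + len - 1)   # distance from the primer-proximal end
      d <- tag_levenshtein(rep(w, length(tags)), tags)
      hits <- which(d <= 2)
      if (length(hits)) {
        if (off < best_off) { best_off <- off; best <- hits }
        else if (off == best_off) best <- union(best, hits)
      }
    }
  }
  if (length(unique(best)) == 1) best[1] else NA_integer_
}

## full brute-force read assignment against a layout
brute_demux <- function(reads, fwd_tags, rev_tags, layout) {
  lco <- coi_primers[["LCO1490"]]; hco <- coi_primers[["HCO2198"]]
  spec_of <- setNames(layout$specimen_id,
                      paste(layout$tag_f_id, layout$tag_r_id))
  vapply(reads, function(rd) {
    hf <- find_primer(rd, lco); hr <- find_primer(rd, hco)
    if (is.null(hf) || is.null(hr) || hf$strand == hr$strand)
      return(NA_character_)
    if (hf$strand == "-") {
      rd <- revcomp(rd); n <- nchar(rd)
      hf <- list(strand = "+", start = n - hf$end, end = n - hf$start)
      hr <- list(strand = "-", start = n - hr$end, end = n - hr$start)
    }
    if (hf$end >= hr$start) return(NA_character_)
    tf <- brute_tag(rd, hf, fwd_tags)
    tr <- brute_tag(rd, hr, rev_tags)
    if (is.na(tf) || is.na(tr)) return(NA_character_)
    key <- paste(names(fwd_tags)[tf], names(rev_tags)[tr])
    if (key %in% names(spec_of)) spec_of[[key]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

## p-distance of two aligned sequences via ape, as an independent oracle
pdist_oracle <- function(seqs) {
  m <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(m) <- names(seqs)
  as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "raw",
                          pairwise.deletion = TRUE))
}
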