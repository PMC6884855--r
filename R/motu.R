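## mOTU delimitation, congruence and species richness.
##
## Barcodes are clustered into molecular operational taxonomic units by
## objective clustering: single-linkage agglomeration on uncorrected
## p-distances, where two specimens share a mOTU iff they are connected
## by a chain of pairwise distances strictly below the threshold.
## Agreement between two partitions of the same specimens is quantified
## by the match ratio 2*N_match / (N1 + N2), and species richness is
## estimated with the classical Chao1 formula on mOTU abundances.

#' Uncorrected p-distance between two aligned sequences
#'
#' Mismatches over compared sites, with pairwise deletion: any site where
#' either sequence carries a gap or an ambiguity (non-ACGT) is excluded.
#'
#' @param a,b aligned sequences of equal length.
#' @return fraction in [0, 1].
#' @export
pairwise_pdistance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]; cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb))
    stop("sequences must be aligned to equal length", call. = FALSE)
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites", call. = FALSE)
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' All-against-all p-distance matrix
#'
#' Aligns the barcodes (center-star progressive alignment, or an external
#' aligner) and computes uncorrected pairwise p-distances with pairwise
#' deletion of gap/ambiguity sites.
#'
#' @param seqs named character vector of barcode sequences.
#' @param aligned set TRUE when `seqs` are already aligned to equal
#'   length.
#' @param engine alignment engine, see [align_bin()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(seqs, aligned = FALSE, engine = "builtin") {
  if (is.null(names(seqs))) names(seqs) <- sprintf("S%04d", seq_along(seqs))
  if (!aligned) {
    msa <- align_bin(toupper(seqs), gap_open = 2, engine = engine)
  } else msa <- toupper(seqs)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) stop("no comparable sites for pair ", i, ",", j,
                           call. = FALSE)
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    }
  }
  d
}

#' Objective clustering (single linkage) at a distance threshold
#'
#' Two specimens share a cluster iff they are connected by a chain of
#' pairwise distances strictly below `threshold`. Implemented as
#' union-find over the sub-threshold pairs; deterministic, with clusters
#' numbered by their smallest member index.
#'
#' @param dm symmetric p-distance matrix (with specimen dimnames).
#' @param threshold clustering threshold; a pair at exactly the threshold
#'   is *not* merged.
#' @return object of class `cluster_partition`: list with `threshold`,
#'   `membership` (named integer vector) and `clusters` (list of member
#'   id vectors).
#' @export
cluster_otus <- function(dm, threshold) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), threshold > 0,
            threshold < 1)
  n <- nrow(dm)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      if (dm[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  memb <- match(root, sort(unique(root)))
  names(memb) <- ids
  clusters <- split(ids, memb)
  structure(list(threshold = threshold, membership = memb,
                 clusters = unname(clusters)),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("Partition at %.1f%%: %d specimens in %d mOTUs\n",
              100 * x$threshold, length(x$membership),
              length(x$clusters)))
  invisible(x)
}

#' Build a partition from a plain membership vector
#'
#' Convenience for comparing against an external partition (e.g. the
#' simulated species truth).
#'
#' @param membership named vector: specimen -> group label.
#' @param threshold annotation only.
#' @return a `cluster_partition`.
#' @export
as_partition <- function(membership, threshold = NA_real_) {
  ids <- names(membership)
  stopifnot(!is.null(ids))
  memb <- match(membership, unique(membership))
  names(memb) <- ids
  structure(list(threshold = threshold, membership = memb,
                 clusters = unname(split(ids, memb))),
            class = "cluster_partition")
}

#' Match ratio between two partitions
#'
#' 2 * N_match / (N1 + N2), where N_match counts clusters whose member
#' sets are identical between the partitions and N1, N2 are the cluster
#' counts. 1 iff the partitions are identical; symmetric in its
#' arguments.
#'
#' @param p1,p2 `cluster_partition` objects over the same specimens.
#' @return list with `n_match`, `n1`, `n2`, `ratio`.
#' @export
match_ratio <- function(p1, p2) {
  u1 <- sort(names(p1$membership)); u2 <- sort(names(p2$membership))
  if (!identical(u1, u2))
    stop("partitions cover different specimen sets", call. = FALSE)
  key <- function(p) vapply(p$clusters, function(cl)
    paste(sort(cl), collapse = "\r"), character(1))
  k1 <- key(p1); k2 <- key(p2)
  n_match <- length(intersect(k1, k2))
  list(n_match = n_match, n1 = length(k1), n2 = length(k2),
       ratio = 2 * n_match / (length(k1) + length(k2)))
}

#' Threshold scan for congruence of incongruent clusters
#'
#' For every cluster of the first partition (at `base_threshold`) whose
#' member set is not a cluster of the second, scans a threshold grid and
#' reports the smallest threshold at which both clusterings contain the
#' cluster's member set as an exact cluster ("never" = NA when no grid
#' threshold works).
#'
#' @param dm_a,dm_b p-distance matrices over the same specimens (e.g.
#'   full-length vs fragment barcodes).
#' @param base_threshold threshold defining the clusters under scrutiny
#'   (default 0.03).
#' @param thresholds grid scanned (default 1--10% in 0.1% steps).
#' @return data.frame with columns `members`, `congruent_at` (threshold
#'   or NA).
#' @export
congruence_threshold_scan <- function(dm_a, dm_b, base_threshold = 0.03,
                                      thresholds = seq(0.01, 0.10,
                                                       by = 0.001)) {
  stopifnot(identical(sort(rownames(dm_a)), sort(rownames(dm_b))))
  dm_b <- dm_b[rownames(dm_a), rownames(dm_a)]
  pa <- cluster_otus(dm_a, base_threshold)
  pb <- cluster_otus(dm_b, base_threshold)
  keyset <- function(p) vapply(p$clusters, function(cl)
    paste(sort(cl), collapse = "\r"), character(1))
  kb <- keyset(pb)
  bad <- pa$clusters[!(keyset(pa) %in% kb)]
  if (length(bad) == 0)
    return(data.frame(members = character(0), congruent_at = numeric(0)))
  grid_parts <- lapply(thresholds, function(t)
    list(a = keyset(cluster_otus(dm_a, t)),
         b = keyset(cluster_otus(dm_b, t))))
  out <- vapply(bad, function(cl) {
    k <- paste(sort(cl), collapse = "\r")
    hit <- which(vapply(grid_parts, function(g)
      (k %in% g$a) && (k %in% g$b), logical(1)))
    if (length(hit)) thresholds[hit[1]] else NA_real_
  }, numeric(1))
  data.frame(members = vapply(bad, paste, character(1), collapse = ","),
             congruent_at = out, row.names = NULL)
}

#' Chao1 species-richness estimate
#'
#' Classical formula S_obs + F1^2 / (2 F2) when doubletons are present;
#' when F2 = 0 the bias-corrected fallback S_obs + F1 (F1 - 1) / 2 is
#' used. The coefficient of variation of the abundance distribution is
#' reported alongside (the classical formula is conventionally preferred
#' when CV > 0.5) but does not gate the formula choice.
#'
#' @param x either an abundance vector (one entry per mOTU) or a list
#'   with elements `S_obs`, `F1`, `F2`.
#' @return list with `S_obs`, `F1`, `F2`, `estimate`, `variant`
#'   ("classical" or "bias_corrected"), `cv` (NA when only counts were
#'   given).
#' @export
chao1 <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    S <- x$S_obs; F1 <- x$F1; F2 <- x$F2; cv <- NA_real_
  } else {
    x <- x[x > 0]
    S <- length(x); F1 <- sum(x == 1); F2 <- sum(x == 2)
    cv <- stats::sd(x) / mean(x)
  }
  stopifnot(S >= 0, F1 >= 0, F2 >= 0)
  if (F2 > 0) {
    est <- S + F1^2 / (2 * F2)
    variant <- "classical"
  } else {
    est <- S + F1 * (F1 - 1) / 2
    variant <- "bias_corrected"
  }
  list(S_obs = S, F1 = F1, F2 = F2, estimate = est, variant = variant,
       cv = cv)
}

#' Rarefied species-accumulation curve with Chao1
#'
#' Specimens are subsampled without replacement at each size over `reps`
#' randomisations; the mean observed richness, singleton and doubleton
#' counts, and Chao1 estimate are reported per size.
#'
#' @param motus vector of mOTU assignments, one entry per specimen.
#' @param sizes subsample sizes (default 1 to all specimens in 10 steps).
#' @param reps randomisations per size (default 100).
#' @param seed RNG seed or NULL.
#' @return data.frame with columns `n`, `S_mean`, `F1_mean`, `F2_mean`,
#'   `chao1_mean`.
#' @export
accumulation_curve <- function(motus, sizes = NULL, reps = 100,
                               seed = NULL) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_tot <- length(motus)
  if (is.null(sizes))
    sizes <- unique(pmax(1, round(seq(1, n_tot, length.out = 10))))
  out <- lapply(sizes, function(n) {
    acc <- replicate(reps, {
      sub <- motus[sample.int(n_tot, n)]
      tab <- table(sub)
      ch <- chao1(as.integer(tab))
      c(S = ch$S_obs, F1 = ch$F1, F2 = ch$F2, chao1 = ch$estimate)
    })
    means <- rowMeans(acc)
    data.frame(n = n, S_mean = means["S"], F1_mean = means["F1"],
               F2_mean = means["F2"], chao1_mean = means["chao1"])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
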