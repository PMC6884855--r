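## Plate layouts: the mapping well -> specimen -> tag pair.
##
## Specimens are arrayed in 96-well plates (rows A-H, columns 1-12). Each
## plate is amplified with one forward tag per plate-column-set design or,
## as here, one tag pair per well drawn from the forward and reverse tag
## panels; the layout is the single source of truth for which tag
## combinations are "used" during demultiplexing and QC.

WELL_ROWS <- LETTERS[1:8]
WELL_COLS <- 1:12

well_names <- function() {
  as.vector(t(outer(WELL_ROWS, WELL_COLS, paste0)))
}

#' Build a plate layout for a set of specimens
#'
#' Assigns specimens to consecutive wells of as many 96-well plates as
#' needed. In the dual-index scheme one forward tag is shared per plate
#' and reverse tags distinguish the wells, so up to
#' `length(fwd_tags) * length(rev_tags)` specimens can be pooled.
#'
#' @param specimen_ids character vector of specimen identifiers.
#' @param fwd_tags,rev_tags named character vectors of tag sequences (names
#'   are tag ids); one forward tag is used per plate.
#' @param negatives_per_plate number of wells per plate left as negative
#'   controls (default 1, the last assigned well of each plate).
#' @return data.frame of class `plate_layout` with columns `plate`, `well`,
#'   `specimen_id` (NA for negatives), `tag_f_id`, `tag_r_id`, `tag_f`,
#'   `tag_r`, `is_negative`.
#' @export
make_plate_layout <- function(specimen_ids, fwd_tags, rev_tags,
                              negatives_per_plate = 1) {
  if (is.null(names(fwd_tags)))
    names(fwd_tags) <- sprintf("F%02d", seq_along(fwd_tags))
  if (is.null(names(rev_tags)))
    names(rev_tags) <- sprintf("R%02d", seq_along(rev_tags))
  per_plate <- min(96L, length(rev_tags)) - negatives_per_plate
  if (per_plate < 1)
    stop("not enough reverse tags per plate", call. = FALSE)
  n_plates <- ceiling(length(specimen_ids) / per_plate)
  if (n_plates > length(fwd_tags))
    stop("not enough forward tags for ", n_plates, " plates", call. = FALSE)
  rows <- list()
  k <- 0L
  for (p in seq_len(n_plates)) {
    n_here <- min(per_plate, length(specimen_ids) - k)
    slots <- seq_len(n_here + negatives_per_plate)
    wells <- well_names()[slots]
    is_neg <- slots > n_here
    sid <- rep(NA_character_, length(slots))
    sid[!is_neg] <- specimen_ids[k + seq_len(n_here)]
    rows[[p]] <- data.frame(
      plate = sprintf("P%02d", p),
      well = wells,
      specimen_id = sid,
      tag_f_id = names(fwd_tags)[p],
      tag_r_id = names(rev_tags)[slots],
      tag_f = unname(fwd_tags[p]),
      tag_r = unname(rev_tags[slots]),
      is_negative = is_neg,
      stringsAsFactors = FALSE)
    k <- k + n_here
  }
  out <- do.call(rbind, rows)
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Attach layout tag pairs and coverage to a specimen truth table
#'
#' @param truth a `specimen_truth` data.frame (see [make_templates()]).
#' @param layout a `plate_layout` covering all specimens in `truth`.
#' @param coverage integer vector of reads per specimen (recycled), or NULL
#'   to draw from [draw_coverage()].
#' @param ... passed to [draw_coverage()] when `coverage` is NULL.
#' @return `truth` with columns `plate`, `well`, `tag_f`, `tag_r`,
#'   `tag_f_id`, `tag_r_id`, `coverage` added.
#' @export
assign_layout <- function(truth, layout, coverage = NULL, ...) {
  i <- match(truth$specimen_id, layout$specimen_id)
  if (anyNA(i))
    stop("layout is missing specimens: ",
         paste(head(truth$specimen_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  for (col in c("plate", "well", "tag_f", "tag_r", "tag_f_id", "tag_r_id"))
    truth[[col]] <- layout[[col]][i]
  if (is.null(coverage)) coverage <- draw_coverage(nrow(truth), ...)
  truth$coverage <- as.integer(rep_len(coverage, nrow(truth)))
  truth
}

#' Tag combinations absent from a layout
#'
#' Enumerates the tag pairs that could be formed from the panels but are
#' not used by any well; reads demultiplexed into these combinations are
#' direct evidence of tag misassignment.
#'
#' @param layout a `plate_layout`.
#' @param fwd_tags,rev_tags the full tag panels (named vectors).
#' @return data.frame with columns `tag_f_id`, `tag_r_id`, `tag_f`,
#'   `tag_r`.
#' @export
unused_tag_pairs <- function(layout, fwd_tags, rev_tags) {
  all_pairs <- expand.grid(tag_f_id = names(fwd_tags),
                           tag_r_id = names(rev_tags),
                           stringsAsFactors = FALSE)
  used <- paste(layout$tag_f_id, layout$tag_r_id)
  keep <- !(paste(all_pairs$tag_f_id, all_pairs$tag_r_id) %in% used)
  out <- all_pairs[keep, , drop = FALSE]
  out$tag_f <- unname(fwd_tags[out$tag_f_id])
  out$tag_r <- unname(rev_tags[out$tag_r_id])
  rownames(out) <- NULL
  out
}

#' Read a plate layout CSV
#'
#' Expected columns: `plate`, `well`, `specimen_id`, `tag_f_id`,
#' `tag_r_id`, `tag_f`, `tag_r`, and optionally `is_negative`.
#'
#' @param path CSV file path.
#' @return a `plate_layout` data.frame.
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "well", "specimen_id", "tag_f", "tag_r")
  if (!all(need %in% names(df)))
    stop("layout must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$is_negative)) df$is_negative <- FALSE
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' @rdname read_layout
#' @param layout a `plate_layout`.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}
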