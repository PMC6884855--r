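## Re-pooling decisions after a first sequencing pass.
##
## Real-time coverage estimates from the first run identify weak
## amplicons; only those are re-pooled into a second library (often on
## the washed flowcell), which raises overall barcoding success without
## resequencing everything. Classes: very low (<= 10x), low (10x < c <=
## 50x), problem (flagged during preliminary barcode QC regardless of
## coverage), ok.

#' Classify amplicon coverage for re-pooling
#'
#' @param coverage named integer vector: specimen -> first-pass read
#'   count.
#' @param problem_flags character vector of specimen ids flagged by QC
#'   (high ambiguity or reference divergence); these are classed
#'   "problem" regardless of coverage.
#' @param very_low inclusive upper bound of the very-low class
#'   (default 10).
#' @param low inclusive upper bound of the low class (default 50).
#' @return object of class `repool_selection`: data.frame with columns
#'   `specimen_id`, `coverage`, `class` (very_low/low/problem/ok).
#' @export
classify_coverage <- function(coverage, problem_flags = character(0),
                              very_low = 10, low = 50) {
  stopifnot(all(coverage >= 0), very_low < low)
  ids <- names(coverage)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_along(coverage))
  cls <- ifelse(ids %in% problem_flags, "problem",
                ifelse(coverage <= very_low, "very_low",
                       ifelse(coverage <= low, "low", "ok")))
  out <- data.frame(specimen_id = ids, coverage = as.integer(coverage),
                    class = cls, stringsAsFactors = FALSE)
  class(out) <- c("repool_selection", "data.frame")
  out
}

#' @export
print.repool_selection <- function(x, ...) {
  tab <- table(factor(x$class,
                      levels = c("very_low", "low", "problem", "ok")))
  cat("Re-pool selection:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  to re-pool:", sum(x$class != "ok"), "of", nrow(x), "\n")
  invisible(x)
}

#' Render plate maps of wells selected for re-pooling
#'
#' One text grid per plate (rows A-H, columns 1-12) marking each well
#' with a class symbol, the visual guide used at the bench when
#' re-pooling weak products across many plates.
#'
#' @param layout a `plate_layout`.
#' @param selection a `repool_selection` covering the layout's specimens.
#' @param symbols named character vector mapping class -> mark.
#' @return named character vector, one printable grid per plate
#'   (class `plate_maps`).
#' @export
plate_maps <- function(layout, selection,
                       symbols = c(very_low = "V", low = "L",
                                   problem = "P", ok = ".",
                                   negative = "n", empty = " ")) {
  extra <- setdiff(selection$specimen_id,
                   layout$specimen_id[!is.na(layout$specimen_id)])
  if (length(extra))
    stop("selection contains specimens absent from the layout: ",
         paste(head(extra), collapse = ", "), call. = FALSE)
  cls <- setNames(selection$class, selection$specimen_id)
  maps <- character(0)
  for (p in unique(layout$plate)) {
    sub <- layout[layout$plate == p, , drop = FALSE]
    grid <- matrix(symbols[["empty"]], nrow = 8, ncol = 12,
                   dimnames = list(WELL_ROWS, WELL_COLS))
    for (k in seq_len(nrow(sub))) {
      row <- substr(sub$well[k], 1, 1)
      col <- as.integer(substr(sub$well[k], 2, nchar(sub$well[k])))
      mark <- if (isTRUE(sub$is_negative[k])) symbols[["negative"]]
        else if (!is.na(sub$specimen_id[k]) &&
                 sub$specimen_id[k] %in% names(cls))
          symbols[[cls[[sub$specimen_id[k]]]]]
        else symbols[["empty"]]
      grid[row, as.character(col)] <- mark
    }
    header <- paste0("   ", paste(sprintf("%2d", WELL_COLS),
                                  collapse = " "))
    body <- vapply(WELL_ROWS, function(r)
      paste0(r, "  ", paste(sprintf("%2s", grid[r, ]), collapse = " ")),
      character(1))
    maps[p] <- paste(c(paste("Plate", p), header, body), collapse = "\n")
  }
  class(maps) <- "plate_maps"
  maps
}

#' @export
print.plate_maps <- function(x, ...) {
  for (m in x) cat(m, "\n\n", sep = "")
  invisible(x)
}

#' Write a re-pooling plan
#'
#' `repool_plan.tsv` (specimen, coverage, class) plus one text plate map
#' per plate.
#'
#' @param selection a `repool_selection`.
#' @param layout a `plate_layout`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_repool_plan <- function(selection, layout, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(selection),
              file.path(dir, "repool_plan.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  maps <- plate_maps(layout, selection)
  writeLines(paste(maps, collapse = "\n\n"),
             file.path(dir, "plate_maps.txt"))
  invisible(dir)
}
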