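#' Construct a genomic region table
#'
#' Region tables are plain data.frames in the 0-based half-open convention
#' (`start` inclusive, `end` exclusive) used throughout the package. Every
#' reader normalizes to this convention at the boundary; 1-based inputs
#' (RepeatMasker) are converted on read.
#'
#' @param chrom character vector of chromosome names (exact-string comparison;
#'   "chr1" and "1" are different chromosomes).
#' @param start 0-based inclusive start positions.
#' @param end exclusive end positions; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (unknown). Recycled.
#' @param name optional region labels.
#' @param score optional numeric scores.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `score`, sorted by (chrom, start, end).
#' @examples
#' regions(c("chr1", "chr1"), c(0, 500), c(100, 680))
#' @export
regions <- function(chrom, start, end, strand = ".", name = NA_character_,
                    score = NA_real_) {
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(chrom)),
    name = rep_len(as.character(name), length(chrom)),
    score = rep_len(as.numeric(score), length(chrom)),
    stringsAsFactors = FALSE
  )
  validate_regions(x)
  sort_regions(x)
}

#' Validate a region table
#'
#' Checks the invariants every region table must satisfy: non-empty
#' chromosome names, `0 <= start < end`, strand in `{+, -, .}`.
#'
#' @param x data.frame with at least `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_regions <- function(x, what = "region table") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing column(s) %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop(sprintf("%s: empty chromosome name", what))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop(sprintf("%s: start >= end (or start < 0) at row %d [%s:%s-%s]",
                 what, bad[1], x$chrom[bad[1]],
                 format(x$start[bad[1]], scientific = FALSE),
                 format(x$end[bad[1]], scientific = FALSE)))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    stop(sprintf("%s: strand must be one of '+', '-', '.'", what))
  }
  invisible(x)
}

#' Sort a region table by (chrom, start, end)
#' @param x region table.
#' @return `x` with rows reordered; row names dropped.
#' @export
sort_regions <- function(x) {
  o <- order(x$chrom, x$start, x$end, method = "radix")
  x <- x[o, , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Test whether a region table is sorted by (chrom, start)
#' @param x region table.
#' @return logical scalar.
#' @export
is_sorted_regions <- function(x) {
  if (nrow(x) < 2) return(TRUE)
  !is.unsorted(order(x$chrom, x$start, x$end, method = "radix"), strictly = FALSE) &&
    all(order(x$chrom, x$start, x$end, method = "radix") == seq_len(nrow(x)))
}

stop_if_unsorted <- function(x, arg) {
  if (!is_sorted_regions(x)) {
    stop(sprintf("'%s' must be sorted by (chrom, start); use sort_regions()", arg))
  }
  invisible(x)
}

#' Region widths in bp
#' @param x region table.
#' @return numeric vector `end - start`.
#' @export
region_width <- function(x) x$end - x$start

#' Region midpoints
#'
#' Midpoint is `floor((start + end) / 2)`, the convention used for
#' distance-to-nearest computations.
#' @param x region table.
#' @return numeric vector of midpoints.
#' @export
region_midpoint <- function(x) floor((x$start + x$end) / 2)

# Split row indices of a region table by chromosome.
split_by_chrom <- function(x) split(seq_len(nrow(x)), x$chrom)

# IRanges view of a set of rows (0-based half-open -> 1-based closed).
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start + 1), end = as.integer(end))
}
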