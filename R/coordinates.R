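# Formal coordinate model.
#
# The discrete model treats genomic coordinates as natural numbers under the
# metric d(a,b) = |a - b| + 1, so that the distance between two coordinates
# equals the number of base pairs covered by the closed interval between
# them. Intervals in that model are 1-based and end-inclusive; the package's
# canonical interval representation is 0-based half-open (the GTrack header
# defaults), related by start0 = start1 - 1, end0 = end1. Both directions of
# the bijection are exposed here.

#' Discrete metric on genomic coordinates
#'
#' The distance between two 1-based coordinates, `|a - b| + 1`, equal to
#' the number of base pairs covered by the closed interval between them.
#'
#' @param a,b Coordinates (natural numbers, 1-based inclusive model).
#' @return Positive integer distance in base pairs. Vectorised.
#' @export
#' @examples
#' metric_distance(1, 3)  # 3
metric_distance <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  abs(a - b) + 1
}

#' Length of a canonical segment
#'
#' Segments use canonical 0-based half-open coordinates; the length
#' `end - start` equals the number of base pairs covered, i.e. the
#' discrete metric distance between the equivalent 1-based inclusive
#' endpoints.
#'
#' @param start,end Canonical coordinates, `end > start`.
#' @return Positive integer length in base pairs. Vectorised.
#' @export
segment_length <- function(start, end) {
  if (any(end <= start))
    stop("empty segment: end must be greater than start", call. = FALSE)
  end - start
}

#' Point membership in a segment
#'
#' A point falls inside a segment iff its singleton coordinate set is a
#' subset of the segment's coordinate set; in canonical coordinates,
#' `start <= position < end`. A seqid mismatch yields `FALSE`, not an
#' error.
#'
#' @param seqid,position The point (canonical coordinates).
#' @param seg_seqid,start,end The segment (canonical half-open).
#' @return Logical. Vectorised.
#' @export
point_in_segment <- function(seqid, position, seg_seqid, start, end) {
  seqid == seg_seqid & position >= start & position < end
}

#' Segment overlap
#'
#' Two segments overlap iff they share a seqid and their coordinate sets
#' intersect; containment counts as overlap, half-open adjacency does not.
#'
#' @param seqid1,start1,end1 First segment (canonical half-open).
#' @param seqid2,start2,end2 Second segment.
#' @return Logical. Vectorised.
#' @export
segments_overlap <- function(seqid1, start1, end1, seqid2, start2, end2) {
  seqid1 == seqid2 & start1 < end2 & start2 < end1
}

#' Convert file-dialect coordinates to canonical form
#'
#' GTrack files may use 0- or 1-based starts and inclusive or exclusive
#' ends; the canonical internal form is 0-based half-open:
#' `start' = start - one_indexed`, `end' = end - one_indexed + end_inclusive`.
#'
#' @param start,end Raw integer coordinates as printed in the file; either
#'   may be `NA` (column absent).
#' @param one_indexed Do coordinates start at 1?
#' @param end_inclusive Is the end coordinate included in the interval?
#' @return A list with canonical `start` and `end`.
#' @export
#' @examples
#' normalize_coordinates(1, 3, TRUE, TRUE)   # [0, 3): covers 3 bp
normalize_coordinates <- function(start, end, one_indexed = FALSE,
                                  end_inclusive = FALSE) {
  shift <- as.integer(isTRUE(one_indexed))
  incl <- as.integer(isTRUE(end_inclusive))
  list(start = start - shift, end = end - shift + incl)
}

#' Convert canonical coordinates back to a file dialect
#'
#' Inverse of [normalize_coordinates()]:
#' `start = start' + one_indexed`, `end = end' + one_indexed - end_inclusive`.
#'
#' @inheritParams normalize_coordinates
#' @return A list with dialect `start` and `end`.
#' @export
denormalize_coordinates <- function(start, end, one_indexed = FALSE,
                                    end_inclusive = FALSE) {
  shift <- as.integer(isTRUE(one_indexed))
  incl <- as.integer(isTRUE(end_inclusive))
  list(start = start + shift, end = end + shift - incl)
}
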