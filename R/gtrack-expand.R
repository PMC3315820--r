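# "Expand GTrack headers": generate a full header set for a partially
# headed file by inspecting its data. Inference never contradicts the
# data and never narrows beyond evidence (integer 0/1 values stay
# 'number' unless the creator declared 'binary').

# ---- shared structural verifiers ----

.regions_sorted <- function(regions) {
  if (nrow(regions) < 2L) return(TRUE)
  key <- order(ifelse(is.na(regions$genome), "", regions$genome),
               regions$seqid, regions$start)
  identical(key, seq_len(nrow(regions)))
}

.elements_sorted <- function(doc) {
  el <- doc$elements
  if (nrow(el) < 2L) return(TRUE)
  blocks <- split(seq_len(nrow(el)), ifelse(is.na(el$region), 0L, el$region))
  all(vapply(blocks, function(ix) {
    sub <- el[ix, ]
    key <- order(sub$seqid, sub$start, .effective_end(sub))
    identical(key, seq_along(ix))
  }, logical(1)))
}

.overlapping_pairs_exist <- function(doc) {
  el <- doc$elements
  # elements without resolvable coordinates cannot witness an overlap
  el <- el[!is.na(el$start), ]
  if (nrow(el) < 2L) return(FALSE)
  start <- el$start
  end <- .effective_end(el)
  for (sq in unique(el$seqid)) {
    ix <- which(el$seqid == sq)
    if (length(ix) < 2L) next
    o <- ix[order(start[ix], end[ix])]
    if (any(start[o][-1] < end[o][-length(o)])) return(TRUE)
  }
  FALSE
}

# candidate (value type, dimension) pairs, from most to least specific
.value_type_candidates <- function(declared_type, declared_dim) {
  cand <- rbind(
    data.frame(type = declared_type, dim = declared_dim),
    expand.grid(type = c("number", "character", "category"),
                dim = c("scalar", "list"), stringsAsFactors = FALSE)[
                  , c("type", "dim")]
  )
  cand[!duplicated(cand), ]
}

#' Expand partially completed GTrack headers
#'
#' Fills in a complete header set for a document (or raw GTrack text) by
#' inspecting its contents: the track type from the column
#' specification; the value type and dimension from the value cells (the
#' declared type is kept whenever the data conform to it); and the
#' sortedness, overlap and interruption guarantees by verifying them
#' over the data.
#'
#' @param x A `gtrack_document`, file path or GTrack text.
#' @return A full named list of header values.
#' @export
expand_headers <- function(x) {
  raw_value_cells <- NULL
  uninterrupted <- NULL
  if (!inherits(x, "gtrack_document")) {
    lines <- .read_lines(x)
    doc <- .parse_impl(lines)$doc
    kinds <- ifelse(startsWith(lines, "####"), "region",
             ifelse(startsWith(lines, "#"), "meta",
             ifelse(grepl("^\\s*$", lines), "blank", "data")))
    d <- which(kinds == "data")
    if (length(d) > 1L)
      uninterrupted <- all(kinds[min(d):max(d)] == "data")
    else uninterrupted <- TRUE
    if ("value" %in% doc$columns) {
      vi <- match("value", doc$columns)
      raw_value_cells <- vapply(strsplit(lines[d], "\t", fixed = TRUE),
                                function(cc) if (length(cc) >= vi) cc[vi]
                                             else ".", "")
    }
  } else {
    doc <- x
    uninterrupted <- nrow(doc$regions) <= 1L && length(doc$comments) == 0L
    if ("value" %in% doc$columns)
      raw_value_cells <- .fmt_value_cell(doc$elements$value)
  }
  h <- doc$headers
  h$track_type <- track_type_name(doc$type)
  if (!is.null(raw_value_cells)) {
    cand <- .value_type_candidates(h$value_type, h$value_dimension)
    for (k in seq_len(nrow(cand))) {
      ok <- all(vapply(raw_value_cells, .cell_conforms, logical(1),
                       type = cand$type[k], dimension = cand$dim[k]))
      if (ok) {
        h$value_type <- cand$type[k]
        h$value_dimension <- cand$dim[k]
        break
      }
    }
  }
  h$sorted_elements <- .regions_sorted(doc$regions) && .elements_sorted(doc)
  h$no_overlapping_elements <- !.overlapping_pairs_exist(doc)
  h$uninterrupted_data_lines <- isTRUE(uninterrupted)
  h
}
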