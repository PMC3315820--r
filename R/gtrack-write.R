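# GTrack 1.0 writer: the inverse of the parser. Writes canonical
# documents in any of the four coordinate dialects; parsing the output
# reproduces the canonical document (up to comment placement).

.fmt_coord <- function(x) sprintf("%.0f", x)

.fmt_value_cell <- function(x) {
  if (is.numeric(x)) {
    # element-wise: format() on a vector pads to a common width
    out <- vapply(x, function(v)
      if (is.na(v)) "." else format(v, trim = TRUE, scientific = FALSE,
                                    digits = 15), "")
  } else {
    out <- ifelse(is.na(x), ".", as.character(x))
  }
  out
}

# Table 4 emission order
.header_order <- function() .header_table$key

#' Write a GTrack 1.0 document
#'
#' @param doc A `gtrack_document` (canonical coordinates).
#' @param file Optional path; when `NULL` the lines are returned
#'   invisibly-visible as a character vector.
#' @param one_indexed,end_inclusive Coordinate dialect to emit; the
#'   corresponding header lines are written when `TRUE`.
#' @param emit_defaults Write every header line, including those at their
#'   default values.
#' @return Character vector of lines (also written to `file` if given).
#' @export
write_gtrack <- function(doc, file = NULL, one_indexed = FALSE,
                         end_inclusive = FALSE, emit_defaults = FALSE) {
  stopifnot(inherits(doc, "gtrack_document"))
  if (isTRUE(doc$headers$undirected_edges))
    doc <- .complete_reciprocal_edges(doc)

  headers <- doc$headers
  headers$one_indexed <- isTRUE(one_indexed)
  headers$end_inclusive <- isTRUE(end_inclusive)
  defaults <- default_headers()
  emit_keys <- Filter(function(k) {
    emit_defaults || k %in% doc$explicit ||
      !identical(headers[[k]], defaults[[k]])
  }, .header_order())
  header_lines <- vapply(emit_keys, function(k) {
    sprintf("##%s: %s", .header_display(k),
            .format_header_value(k, headers[[k]]))
  }, "")

  comment_lines <- if (length(doc$comments)) paste0("#", doc$comments)
    else character()

  colspec_line <- paste0("###", paste(doc$columns, collapse = "\t"))

  el <- doc$elements
  data_cells <- .element_cells(doc, one_indexed, end_inclusive)

  body <- character()
  no_region <- which(is.na(el$region))
  body <- c(body, data_cells[no_region])
  if (nrow(doc$regions)) {
    for (r in seq_len(nrow(doc$regions))) {
      reg <- doc$regions[r, ]
      cc <- denormalize_coordinates(reg$start, reg$end, one_indexed,
                                    end_inclusive)
      parts <- c(
        if (!is.na(reg$genome)) sprintf("genome=%s", reg$genome),
        sprintf("seqid=%s", reg$seqid),
        sprintf("start=%s", .fmt_coord(cc$start)),
        sprintf("end=%s", .fmt_coord(cc$end))
      )
      body <- c(body, paste0("####", paste(parts, collapse = "; ")))
      body <- c(body, data_cells[which(!is.na(el$region) & el$region == r)])
    }
  }

  lines <- unname(c(header_lines, comment_lines, colspec_line, body))
  if (!is.null(file)) {
    writeLines(lines, file, sep = "\n")
    return(invisible(lines))
  }
  lines
}

# Format one data line per element, respecting the column specification
# and the requested dialect.
.element_cells <- function(doc, one_indexed, end_inclusive) {
  el <- doc$elements
  n <- nrow(el)
  if (n == 0L) return(character())
  type <- doc$type
  shift <- as.integer(isTRUE(one_indexed))
  incl <- as.integer(isTRUE(end_inclusive))
  cols <- lapply(doc$columns, function(cn) {
    switch(cn,
      genome = ifelse(is.na(el$genome), ".", el$genome),
      seqid = el$seqid,
      start = .fmt_coord(el$start + shift),
      end = .fmt_coord(el$end + shift - incl),
      value = .fmt_value_cell(el$value),
      strand = ifelse(is.na(el$strand), ".", el$strand),
      id = ifelse(is.na(el$id), ".", el$id),
      edges = ifelse(is.na(el$edges), ".", el$edges),
      {
        v <- el[[cn]]
        ifelse(is.na(v), ".", as.character(v))
      })
  })
  do.call(paste, c(cols, sep = "\t"))
}

# For undirected graphs every edge must appear reciprocally with equal
# weight; the writer completes missing reciprocal edges.
.complete_reciprocal_edges <- function(doc) {
  el <- doc$elements
  if (!"edges" %in% names(el) || !nrow(el)) return(doc)
  h <- doc$headers
  lists <- lapply(el$edges, parse_edges, headers = h)
  id_of <- el$id
  for (i in seq_len(nrow(el))) {
    e <- lists[[i]]
    if (!nrow(e)) next
    for (k in seq_len(nrow(e))) {
      j <- match(e$target[k], id_of)
      if (is.na(j)) next
      back <- lists[[j]]
      if (!is.na(id_of[i]) && !id_of[i] %in% back$target) {
        lists[[j]] <- rbind(back,
                            data.frame(target = id_of[i],
                                       weight = e$weight[k],
                                       stringsAsFactors = FALSE))
      }
    }
  }
  el$edges <- vapply(lists, function(e) {
    if (!nrow(e)) return(NA_character_)
    paste(ifelse(is.na(e$weight), e$target,
                 paste0(e$target, "=", e$weight)), collapse = ",")
  }, "")
  doc$elements <- el
  doc
}
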