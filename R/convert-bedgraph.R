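# bedGraph conversion: 4 columns (chrom, start, end, value), 0-based
# half-open, float values. The recommended format for continuous data
# that is sparse or has elements of varying size.

#' Read bedGraph records
#' @param x Path, string or lines.
#' @return data.frame(chrom, start, end, value).
#' @export
read_bedgraph <- function(x) {
  lines <- .read_lines(x)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) &
                   !grepl("^\\s*$", lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 4L))
    stop("bedGraph lines must have exactly 4 fields", call. = FALSE)
  m <- matrix(unlist(cells), ncol = 4L, byrow = TRUE)
  data.frame(chrom = m[, 1], start = as.numeric(m[, 2]),
             end = as.numeric(m[, 3]), value = as.numeric(m[, 4]),
             stringsAsFactors = FALSE)
}

#' Write bedGraph records
#' @param records data.frame(chrom, start, end, value).
#' @param file Optional output path.
#' @return Character vector of lines, each with exactly 4 fields.
#' @export
write_bedgraph <- function(records, file = NULL) {
  lines <- paste(records$chrom, .fmt_coord(records$start),
                 .fmt_coord(records$end), .fmt_value_cell(records$value),
                 sep = "\t")
  if (!is.null(file)) writeLines(lines, file)
  lines
}

#' Convert bedGraph records to a GTrack document
#'
#' bedGraph carries sparse numeric intervals of varying size: the result
#' is a valued segments (VS) document.
#'
#' @param records data.frame(chrom, start, end, value).
#' @return A `gtrack_document` of type VS.
#' @export
bedgraph_to_gtrack <- function(records) {
  el <- data.frame(seqid = records$chrom, start = records$start,
                   end = records$end, value = records$value,
                   stringsAsFactors = FALSE)
  gtrack_document("VS", columns = c("seqid", "start", "end", "value"),
                  elements = el)
}

#' Convert a GTrack document to bedGraph records
#'
#' Valued sparse documents map directly; step functions flatten their
#' tiling into contiguous records; valued points become length-1
#' records. Linked dense types are unsupported.
#'
#' @param doc A `gtrack_document` with numeric scalar values.
#' @return data.frame(chrom, start, end, value).
#' @export
gtrack_to_bedgraph <- function(doc) {
  if (!has_values(doc$type))
    stop("unsupported conversion: type ", doc$type, " has no value column",
         call. = FALSE)
  if (doc$type %in% c("LF", "LBP", "LSF", "LGP"))
    stop("unsupported conversion: dense linked type ", doc$type,
         call. = FALSE)
  if (!.numeric_value_storage(doc$headers$value_type,
                              doc$headers$value_dimension))
    stop("bedGraph requires numeric scalar values", call. = FALSE)
  el <- doc$elements
  data.frame(chrom = el$seqid, start = el$start,
             end = .effective_end(el), value = el$value,
             stringsAsFactors = FALSE)
}
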