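# GFF3 conversion. GFF3 data lines have exactly nine tab-separated
# fields (seqid, source, type, start, end, score, strand, phase,
# attributes), 1-based end-inclusive coordinates, "." for missing.
# On import every attribute key seen anywhere in the input becomes one
# extra column on all lines ("." where absent), honouring the GTrack
# equal-columns principle; with link_parents the ID/Parent attributes
# populate the id and edges columns instead, producing a linked type.

#' Read GFF3 records
#' @param x Path, string or lines; `##` directives and comments skipped.
#' @return A data.frame with the nine GFF columns; `attributes` is the
#'   raw attribute string.
#' @export
read_gff3 <- function(x) {
  lines <- .read_lines(x)
  lines <- lines[!startsWith(lines, "#") & !grepl("^\\s*$", lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != 9L)
  if (length(bad))
    stop("GFF3 data lines must have exactly 9 fields (line ", bad[1],
         " has ", lengths(cells)[bad[1]], ")", call. = FALSE)
  m <- matrix(unlist(cells), ncol = 9L, byrow = TRUE)
  data.frame(seqid = m[, 1], source = m[, 2], type = m[, 3],
             start = as.numeric(m[, 4]), end = as.numeric(m[, 5]),
             score = m[, 6], strand = m[, 7], phase = m[, 8],
             attributes = m[, 9], stringsAsFactors = FALSE)
}

# ordered key=value parse of one attribute string
.parse_gff_attributes <- function(s) {
  if (is.na(s) || s == "." || s == "") return(character())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  keys <- sub("=.*$", "", parts)
  vals <- sub("^[^=]*=", "", parts)
  stats::setNames(vals, keys)
}

#' Convert GFF3 records to a GTrack document
#'
#' @param records As from [read_gff3()].
#' @param link_parents When `TRUE`, ID/Parent attributes populate the id
#'   and edges columns and the document becomes a linked type.
#' @return A `gtrack_document` (S/VS, or LS/LVS with `link_parents`;
#'   the value column is the score, omitted when no record has one).
#' @export
gff_to_gtrack <- function(records, link_parents = FALSE) {
  n <- nrow(records)
  attrs <- lapply(records$attributes, .parse_gff_attributes)
  keys <- unique(unlist(lapply(attrs, names)))
  if (link_parents) keys <- setdiff(keys, c("ID", "Parent"))
  has_score <- any(records$score != ".")
  cc <- normalize_coordinates(records$start, records$end,
                              one_indexed = TRUE, end_inclusive = TRUE)
  el <- data.frame(seqid = records$seqid, start = cc$start, end = cc$end,
                   stringsAsFactors = FALSE)
  el$strand <- ifelse(records$strand %in% c("+", "-"), records$strand,
                      NA_character_)
  columns <- c("seqid", "source", "type", "start", "end",
               if (has_score) "value", "strand", "phase")
  if (has_score)
    el$value <- suppressWarnings(
      as.numeric(ifelse(records$score == ".", NA, records$score)))
  el$source <- records$source
  el$type <- records$type
  el$phase <- ifelse(records$phase == ".", NA_character_, records$phase)
  if (link_parents) {
    el$id <- vapply(attrs, function(a)
      if ("ID" %in% names(a)) a[["ID"]] else NA_character_, "")
    el$edges <- vapply(attrs, function(a)
      if ("Parent" %in% names(a)) a[["Parent"]] else NA_character_, "")
    columns <- c(columns, "id", "edges")
  }
  for (k in keys) {
    el[[k]] <- vapply(attrs, function(a)
      if (k %in% names(a)) a[[k]] else NA_character_, "")
    columns <- c(columns, k)
  }
  type <- properties_to_type(core_properties(
    gaps = TRUE, lengths = TRUE, values = has_score,
    interconnections = link_parents))
  gtrack_document(type, columns = columns, elements = el)
}

#' Convert a GTrack document to GFF3 records
#'
#' Every emitted data line has exactly nine tab-separated fields; extra
#' columns and edges are serialized into the attributes field (id as
#' `ID`, unweighted edges as `Parent`, weighted edges as an `edges`
#' attribute). Dense types are rejected: representing every base pair as
#' a nine-column data line would be highly impractical.
#'
#' @param doc A sparse `gtrack_document`.
#' @return A data.frame of GFF3 records.
#' @export
gtrack_to_gff <- function(doc) {
  if (is_dense(doc$type))
    stop("unsupported conversion: representing dense type ", doc$type,
         " in GFF would be highly impractical (one nine-column line per base pair)",
         call. = FALSE)
  el <- doc$elements
  n <- nrow(el)
  cc <- denormalize_coordinates(el$start, .effective_end(el),
                                one_indexed = TRUE, end_inclusive = TRUE)
  extras <- setdiff(extra_columns(doc), c("source", "type", "phase"))
  attr_str <- vapply(seq_len(max(n, 0L)), function(i) {
    parts <- character()
    if ("id" %in% doc$columns && !is.na(el$id[i]))
      parts <- c(parts, paste0("ID=", el$id[i]))
    if ("edges" %in% doc$columns && !is.na(el$edges[i])) {
      e <- parse_edges(el$edges[i], doc$headers)
      if (nrow(e)) {
        if (all(is.na(e$weight)))
          parts <- c(parts, paste0("Parent=", paste(e$target, collapse = ",")))
        else
          parts <- c(parts, paste0("edges=", paste(
            ifelse(is.na(e$weight), e$target,
                   paste0(e$target, ":", e$weight)), collapse = ",")))
      }
    }
    for (k in extras) {
      v <- el[[k]][i]
      if (!is.na(v) && v != ".") parts <- c(parts, paste0(k, "=", v))
    }
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, "")
  data.frame(
    seqid = el$seqid,
    source = if ("source" %in% names(el))
      ifelse(is.na(el$source), ".", el$source) else rep(".", n),
    type = if ("type" %in% names(el))
      ifelse(is.na(el$type), ".", el$type) else rep(".", n),
    start = cc$start, end = cc$end,
    score = if ("value" %in% doc$columns) .fmt_value_cell(el$value)
            else rep(".", n),
    strand = ifelse(is.na(el$strand), ".", el$strand),
    phase = if ("phase" %in% names(el))
      ifelse(is.na(el$phase), ".", el$phase) else rep(".", n),
    attributes = attr_str,
    stringsAsFactors = FALSE)
}

#' Write GFF3 records
#' @param records As from [read_gff3()] or [gtrack_to_gff()].
#' @param file Optional output path.
#' @return Character lines, each with exactly 9 tab-separated fields.
#' @export
write_gff3 <- function(records, file = NULL) {
  lines <- paste(records$seqid, records$source, records$type,
                 .fmt_coord(records$start), .fmt_coord(records$end),
                 records$score, records$strand, records$phase,
                 records$attributes, sep = "\t")
  lines <- c("##gff-version 3", lines)
  if (!is.null(file)) writeLines(lines, file)
  lines
}
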