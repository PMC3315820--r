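# In-memory representation of a GTrack document.
#
# A gtrack_document is a list with components:
#   type     - track type id ("P" ... "LBP")
#   headers  - full header set (canonical values; dialect headers are
#              always at their defaults because coordinates are canonical)
#   explicit - keys of headers that were explicitly set (and so are
#              written out even when writing without emit_defaults)
#   columns  - the file's column specification (canonical: aliased value /
#              edges columns renamed to their literal names; fixed
#              geometry materialised into explicit core columns)
#   regions  - data.frame(genome, seqid, start, end), canonical half-open;
#              zero rows when the document declares no bounding regions
#   elements - data.frame(region, seqid, start, end, value, strand, id,
#              edges, <extra columns>); region indexes into regions (NA
#              outside any); start always populated (computed for dense
#              types); end is NA for types without the lengths property
#   comments - "#" comment lines, preserved without placement
#
# Coordinates are canonical: 0-based, half-open.

#' Construct a GTrack document
#'
#' Low-level constructor; most users obtain documents from
#' [parse_gtrack()], the converters or [generate_gtrack()].
#'
#' @param type Track type id.
#' @param columns Character vector: the column specification. Defaults to
#'   the minimal column set for `type`.
#' @param elements A data.frame of track elements in canonical
#'   coordinates (see Details in the package vignette).
#' @param regions A data.frame of bounding regions (genome, seqid, start,
#'   end), or `NULL`.
#' @param headers Named list of explicit header values (merged over
#'   defaults).
#' @param comments Character vector of comment lines (without the leading
#'   `#`).
#' @return A `gtrack_document`.
#' @export
gtrack_document <- function(type, columns = NULL, elements = NULL,
                            regions = NULL, headers = list(),
                            comments = character()) {
  type <- .check_type(type)
  if (is.null(columns)) {
    columns <- columns_for_type(type, include_id = TRUE)
    if (is_sparse(type)) columns <- c("seqid", columns)
  }
  headers$track_type <- track_type_name(type)
  h <- .make_headers(headers)
  regions <- .as_region_frame(regions)
  elements <- .as_element_frame(elements, type, columns)
  structure(
    list(type = type, headers = h,
         explicit = union("track_type", names(headers)),
         columns = columns, regions = regions, elements = elements,
         comments = comments),
    class = "gtrack_document"
  )
}

.as_region_frame <- function(regions) {
  if (is.null(regions))
    return(data.frame(genome = character(), seqid = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  if (is.null(regions$genome)) regions$genome <- NA_character_
  stopifnot(all(c("seqid", "start", "end") %in% names(regions)))
  regions <- regions[c("genome", "seqid", "start", "end")]
  regions$start <- as.numeric(regions$start)
  regions$end <- as.numeric(regions$end)
  rownames(regions) <- NULL
  regions
}

.element_base_cols <- c("region", "genome", "seqid", "start", "end", "value",
                        "strand", "id", "edges")

.as_element_frame <- function(elements, type, columns) {
  if (is.null(elements))
    elements <- data.frame(seqid = character(), stringsAsFactors = FALSE)
  elements <- as.data.frame(elements, stringsAsFactors = FALSE)
  n <- nrow(elements)
  if (is.null(elements[["region"]])) elements$region <- rep(NA_integer_, n)
  if (is.null(elements[["genome"]])) elements$genome <- rep(NA_character_, n)
  if (is.null(elements[["seqid"]])) elements$seqid <- rep(NA_character_, n)
  if (is.null(elements[["start"]])) elements$start <- rep(NA_real_, n)
  if (is.null(elements[["end"]])) elements$end <- rep(NA_real_, n)
  if (is.null(elements[["value"]])) elements$value <- rep(NA, n)
  if (is.null(elements[["strand"]])) elements$strand <- rep(NA_character_, n)
  if (is.null(elements[["id"]])) elements$id <- rep(NA_character_, n)
  if (is.null(elements[["edges"]])) elements$edges <- rep(NA_character_, n)
  elements$start <- as.numeric(elements$start)
  elements$end <- as.numeric(elements$end)
  extras <- setdiff(names(elements), .element_base_cols)
  elements <- elements[c(.element_base_cols, extras)]
  rownames(elements) <- NULL
  elements
}

#' Extra (non-reserved) columns of a document
#' @param doc A `gtrack_document`.
#' @return Character vector of extra column names, in column-spec order.
#' @export
extra_columns <- function(doc) setdiff(doc$columns, reserved_columns())

# Effective end for interval computations: point-like elements cover a
# single base pair.
.effective_end <- function(elements) {
  ifelse(is.na(elements$end), elements$start + 1, elements$end)
}

#' @export
print.gtrack_document <- function(x, ...) {
  cat(sprintf("GTrack document: type %s (%s), %d element(s), %d bounding region(s)\n",
              x$type, track_type_name(x$type), nrow(x$elements),
              nrow(x$regions)))
  cat("columns:", paste(x$columns, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.gtrack_document <- function(x, ...) {
  sprintf("<gtrack_document %s: %d elements>", x$type, nrow(x$elements))
}

# Strict structural equality on the canonical form (headers, columns,
# regions, elements; comment placement is not significant).
#' Compare two documents in canonical form
#' @param a,b `gtrack_document`s.
#' @return `TRUE` or a character description of the first difference.
#' @export
gtrack_all_equal <- function(a, b) {
  isTRUE(all.equal(a[c("type", "headers", "columns", "regions", "elements")],
                   b[c("type", "headers", "columns", "regions", "elements")]))
}
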