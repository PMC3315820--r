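# Registry of the fifteen track types. Each row is one point of the
# four-property lattice; the all-FALSE combination carries no information
# and is not a track type.
.track_type_table <- local({
  tab <- data.frame(
    id     = c("P", "VP", "S", "VS", "GP", "SF", "F",
               "LP", "LVP", "LS", "LVS", "LGP", "LSF", "LF", "LBP"),
    name   = c("points", "valued points", "segments", "valued segments",
               "genome partition", "step function", "function",
               "linked points", "linked valued points", "linked segments",
               "linked valued segments", "linked genome partition",
               "linked step function", "linked function",
               "linked base pairs"),
    gaps             = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                         TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    lengths          = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
                         FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    values           = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE,
                         FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
    interconnections = c(rep(FALSE, 7), rep(TRUE, 8)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$id
  tab
})

#' The fifteen track type identifiers
#'
#' Genomic tracks are classified by which of four core informational
#' properties their elements carry: gaps (elements do not tile the genome),
#' lengths (elements span more than a single base pair), values (a
#' designated main value) and interconnections (edges between elements).
#' The fifteen non-empty combinations of these properties each define one
#' track type.
#'
#' @return Character vector of the 15 track type ids, e.g. `"P"`, `"LVS"`.
#' @export
#' @examples
#' track_type_ids()
track_type_ids <- function() .track_type_table$id

#' @rdname track_type_ids
#' @param id A track type id.
#' @return For `track_type_name`, the full lower-case name used by the
#'   GTrack `track type` header (e.g. `"valued segments"`).
#' @export
track_type_name <- function(id) {
  .track_type_table[.check_type(id), "name"]
}

#' @rdname track_type_ids
#' @param name A full track type name (case-insensitive).
#' @export
track_type_from_name <- function(name) {
  m <- match(tolower(trimws(name)), .track_type_table$name)
  if (is.na(m))
    stop("unknown track type name: ", sQuote(name), call. = FALSE)
  .track_type_table$id[m]
}

.check_type <- function(id) {
  if (length(id) != 1L || !id %in% .track_type_table$id)
    stop("not a valid track type id: ", sQuote(paste(id, collapse = ",")),
         call. = FALSE)
  id
}

#' Core informational properties
#'
#' Constructs the set of four booleans identifying a point in the track
#' type lattice. At least one property must be defined: the all-false
#' combination carries no information and is not a track type.
#'
#' @param gaps,lengths,values,interconnections Logical scalars.
#' @return A named logical vector of class `core_properties`.
#' @export
#' @examples
#' core_properties(gaps = TRUE, lengths = TRUE)  # a segments track
core_properties <- function(gaps = FALSE, lengths = FALSE, values = FALSE,
                            interconnections = FALSE) {
  p <- c(gaps = isTRUE(gaps), lengths = isTRUE(lengths),
         values = isTRUE(values), interconnections = isTRUE(interconnections))
  structure(p, class = "core_properties")
}

#' Map core properties to the track type they define
#'
#' @param props A `core_properties` vector (or named logical vector with
#'   entries gaps, lengths, values, interconnections).
#' @return The track type id.
#' @export
#' @examples
#' properties_to_type(core_properties(gaps = TRUE))         # "P"
#' properties_to_type(core_properties(TRUE, TRUE, TRUE, TRUE))  # "LVS"
properties_to_type <- function(props) {
  p <- props[c("gaps", "lengths", "values", "interconnections")]
  if (anyNA(p))
    stop("core properties must name gaps, lengths, values, interconnections",
         call. = FALSE)
  if (!any(p))
    stop("empty type: at least one core property must be defined",
         call. = FALSE)
  tab <- .track_type_table
  hit <- tab$gaps == p[["gaps"]] & tab$lengths == p[["lengths"]] &
    tab$values == p[["values"]] & tab$interconnections == p[["interconnections"]]
  tab$id[hit]
}

#' Core properties defined by a track type
#'
#' @inheritParams track_type_name
#' @return A `core_properties` vector.
#' @export
type_to_properties <- function(id) {
  row <- .track_type_table[.check_type(id), ]
  core_properties(row$gaps, row$lengths, row$values, row$interconnections)
}

# Core reserved columns and the property each one's presence encodes.
.core_column_property <- c(start = "gaps", end = "lengths",
                           value = "values", edges = "interconnections")

#' Reserved GTrack column names
#'
#' The eight reserved words of the GTrack column specification line. The
#' four core columns (start, end, value, edges) encode the four core
#' informational properties; genome, seqid, strand and id are non-core.
#'
#' @return Character vector of length 8.
#' @export
reserved_columns <- function() {
  c("genome", "seqid", "start", "end", "value", "strand", "id", "edges")
}

#' Infer a track type from the core columns present
#'
#' Presence of the core columns start, end, value and edges encodes the
#' core properties gaps, lengths, values and interconnections
#' respectively.
#'
#' @param core_columns Character vector of column names; only core column
#'   names are considered.
#' @return The track type id.
#' @export
#' @examples
#' type_from_columns(c("seqid", "start", "end"))   # "S"
#' type_from_columns(c("end", "value"))            # "SF"
type_from_columns <- function(core_columns) {
  core <- intersect(names(.core_column_property), core_columns)
  props <- core_properties()
  props[.core_column_property[core]] <- TRUE
  properties_to_type(props)
}

#' Core columns required by a track type
#'
#' Inverse of [type_from_columns()]. Linked types additionally require the
#' non-core `id` column, reported via the `include_id` argument.
#'
#' @inheritParams track_type_name
#' @param include_id If `TRUE`, include `"id"` for linked types.
#' @return Character vector of required column names.
#' @export
columns_for_type <- function(id, include_id = FALSE) {
  props <- type_to_properties(.check_type(id))
  cols <- names(.core_column_property)[.core_column_property %in%
                                         names(props)[props]]
  # keep canonical order start, end, value, edges
  cols <- intersect(c("start", "end", "value", "edges"), cols)
  if (include_id && is_linked(id)) cols <- c(cols, "id")
  cols
}

#' Track type predicates
#'
#' Dense types lack the gaps property (their elements tile their bounding
#' regions exactly); linked (extended) types carry interconnections; basic
#' types do not.
#'
#' @inheritParams track_type_name
#' @return Logical scalar.
#' @export
is_dense <- function(id) !.track_type_table[.check_type(id), "gaps"]

#' @rdname is_dense
#' @export
is_sparse <- function(id) .track_type_table[.check_type(id), "gaps"]

#' @rdname is_dense
#' @export
is_linked <- function(id) .track_type_table[.check_type(id), "interconnections"]

#' @rdname is_dense
#' @export
is_basic <- function(id) !is_linked(id)

#' @rdname is_dense
#' @export
has_values <- function(id) .track_type_table[.check_type(id), "values"]

#' @rdname is_dense
#' @export
has_lengths <- function(id) .track_type_table[.check_type(id), "lengths"]
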