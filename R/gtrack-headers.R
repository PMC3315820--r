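# GTrack header variables: canonical key, display name (as written on
# "##" lines, matched case-insensitively), type and default value. A
# header line is optional whenever its value equals the default.

.header_table <- local({
  h <- function(key, display, type, default)
    list(key = key, display = display, type = type, default = default)
  defs <- list(
    h("gtrack_version", "gtrack version", "character", "1.0"),
    h("track_type", "track type", "character", "segments"),
    h("value_type", "value type", "enum", "number"),
    h("value_dimension", "value dimension", "enum", "scalar"),
    h("undirected_edges", "undirected edges", "logical", FALSE),
    h("edge_weights", "edge weights", "logical", FALSE),
    h("edge_weight_type", "edge weight type", "enum", "number"),
    h("edge_weight_dimension", "edge weight dimension", "enum", "scalar"),
    h("uninterrupted_data_lines", "uninterrupted data lines", "logical", FALSE),
    h("sorted_elements", "sorted elements", "logical", FALSE),
    h("no_overlapping_elements", "no overlapping elements", "logical", FALSE),
    h("circular_elements", "circular elements", "logical", FALSE),
    h("one_indexed", "1-indexed", "logical", FALSE),
    h("end_inclusive", "end inclusive", "logical", FALSE),
    h("value_column", "value column", "character", "value"),
    h("edges_column", "edges column", "character", "edges"),
    h("fixed_length", "fixed length", "integer", 1L),
    h("fixed_gap_size", "fixed gap size", "integer", 0L),
    h("fixed_size_data_lines", "fixed-size data lines", "logical", FALSE),
    h("data_line_size", "data line size", "integer", 1L),
    h("subtype_name", "gtrack subtype", "character", ""),
    h("subtype_version", "subtype version", "character", "1.0"),
    h("subtype_url", "subtype url", "character", ""),
    h("subtype_adherence", "subtype adherence", "enum", "free")
  )
  keys <- vapply(defs, `[[`, "", "key")
  data.frame(
    key = keys,
    display = vapply(defs, `[[`, "", "display"),
    type = vapply(defs, `[[`, "", "type"),
    row.names = keys,
    stringsAsFactors = FALSE
  ) -> tab
  attr(tab, "defaults") <- stats::setNames(lapply(defs, `[[`, "default"), keys)
  tab
})

.value_types <- c("number", "binary", "category", "character")
.dimensions <- c("scalar", "list")

#' Default GTrack header set
#'
#' All header variables with their default values; a header line in a
#' GTrack file is optional whenever its value equals the default.
#'
#' @return Named list of header values, canonical snake_case keys.
#' @export
default_headers <- function() attr(.header_table, "defaults")

# display-name lookup, case-insensitive
.header_key_from_display <- function(display) {
  m <- match(tolower(trimws(display)), tolower(.header_table$display))
  if (is.na(m)) NA_character_ else .header_table$key[m]
}

.header_display <- function(key) .header_table[key, "display"]

# Parse a raw header value string into its canonical R type.
.parse_header_value <- function(key, raw) {
  key <- unname(key)
  raw <- unname(trimws(raw))
  type <- .header_table[key, "type"]
  switch(type,
    logical = {
      if (!tolower(raw) %in% c("true", "false"))
        stop("header ", sQuote(.header_display(key)),
             " must be true or false, got ", sQuote(raw), call. = FALSE)
      tolower(raw) == "true"
    },
    integer = {
      v <- suppressWarnings(as.integer(raw))
      if (is.na(v)) stop("header ", sQuote(.header_display(key)),
                         " must be an integer, got ", sQuote(raw),
                         call. = FALSE)
      v
    },
    enum = {
      allowed <- if (key %in% c("value_type", "edge_weight_type")) .value_types
                 else if (key %in% c("value_dimension", "edge_weight_dimension"))
                   .dimensions
                 else c("free", "strict")
      if (!raw %in% allowed)
        stop("header ", sQuote(.header_display(key)), " must be one of ",
             paste(allowed, collapse = ", "), call. = FALSE)
      raw
    },
    raw
  )
}

.format_header_value <- function(key, value) {
  if (is.logical(value)) tolower(as.character(value)) else as.character(value)
}

# Merge explicit header assignments over the defaults.
.make_headers <- function(explicit = list()) {
  h <- default_headers()
  bad <- setdiff(names(explicit), names(h))
  if (length(bad))
    stop("unknown header variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  h[names(explicit)] <- explicit
  h
}
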