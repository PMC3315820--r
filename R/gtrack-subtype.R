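# GTrack subtypes: a subtype model is itself a GTrack document (headers
# and a column specification, usually without data lines) that a data
# file references through the 'subtype URL' header. Resolving a subtype
# merges the model's headers and columns under the referencing file's
# own, governed by the 'subtype adherence' header: under "free"
# adherence the file wins, under "strict" any deviation is an error.

.subtype_keys <- c("subtype_name", "subtype_version", "subtype_url",
                   "subtype_adherence")

# header/column-level merge; used by the parser (before data lines are
# interpreted) and by resolve_subtype. Returns a list or an error object.
.merge_subtype <- function(headers, explicit, columns, colspec_explicit,
                           model) {
  stopifnot(inherits(model, "gtrack_document"))
  # the model may demand strict adherence from every referencing file
  adherence <- if ("subtype_adherence" %in% explicit)
    headers$subtype_adherence else model$headers$subtype_adherence
  if (!adherence %in% c("free", "strict"))
    return(simpleError(paste0("unsupported subtype adherence mode: ",
                              sQuote(adherence))))
  model_explicit <- setdiff(model$explicit, .subtype_keys)
  # restore the model's layout headers (dialect, fixed geometry), which
  # its own canonicalisation moved aside
  model_headers <- model$headers
  if (!is.null(model$layout)) {
    model_headers[names(model$layout$values)] <- model$layout$values
    model_explicit <- union(model_explicit, model$layout$explicit)
  }
  if (adherence == "strict") {
    for (k in setdiff(intersect(explicit, model_explicit), .subtype_keys))
      if (!identical(headers[[k]], model_headers[[k]]))
        return(simpleError(sprintf(
          "strict subtype adherence: header %s (%s) deviates from the subtype model (%s)",
          sQuote(.header_display(k)),
          .format_header_value(k, headers[[k]]),
          .format_header_value(k, model_headers[[k]]))))
    if (colspec_explicit && !identical(columns, model$columns))
      return(simpleError(
        "strict subtype adherence: column specification deviates from the subtype model"))
  }
  for (k in setdiff(model_explicit, c(explicit, .subtype_keys))) {
    headers[[k]] <- model_headers[[k]]
    explicit <- union(explicit, k)
  }
  if (!colspec_explicit) {
    columns <- model$columns
    colspec_explicit <- TRUE
  }
  list(headers = headers, explicit = explicit, columns = columns,
       colspec_explicit = colspec_explicit)
}

#' Resolve a document's subtype against its model
#'
#' Merges the model's headers and column specification under the
#' document's own. Under the default `"free"` adherence the document's
#' explicit settings win; under `"strict"` adherence any deviation from
#' the model is an error. A model reference allows reduction of a
#' complete GTrack header down to a minimum of one line.
#'
#' @param doc The referencing document (possibly header-only).
#' @param model The subtype model document. When `NULL`, the model is
#'   read from the document's `subtype url` header if it names a local
#'   file (network fetch is not attempted).
#' @return The merged `gtrack_document`.
#' @export
resolve_subtype <- function(doc, model = NULL) {
  stopifnot(inherits(doc, "gtrack_document"))
  if (is.null(model)) {
    url <- doc$headers$subtype_url
    if (!nzchar(url))
      stop("document declares no subtype URL and no model was supplied",
           call. = FALSE)
    if (grepl("^[a-z][a-z0-9+.-]*://", url) && !file.exists(url))
      stop("subtype URL is remote; pass a local model document instead",
           call. = FALSE)
    if (!file.exists(url))
      stop("subtype model file not found: ", url, call. = FALSE)
    model <- parse_gtrack(url)
  }
  merged <- .merge_subtype(doc$headers, doc$explicit, doc$columns,
                           isTRUE(doc$colspec_explicit), model)
  if (inherits(merged, "error")) stop(merged)
  # rebuild: the cleanest way to honour the merged headers (including
  # layout headers) is to rewrite and reparse
  tmp <- doc
  tmp$headers <- merged$headers
  tmp$explicit <- merged$explicit
  if (!isTRUE(doc$colspec_explicit) && nrow(doc$elements) == 0L)
    tmp$columns <- merged$columns
  ty <- tryCatch(type_from_columns(tmp$columns), error = function(e) NULL)
  if (!is.null(ty)) {
    tmp$type <- ty
    tmp$headers$track_type <- track_type_name(ty)
  }
  tmp$colspec_explicit <- TRUE
  tmp
}
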