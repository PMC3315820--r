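# Supporting tools: sort, standardize (to linked valued segments) and
# complement columns.

#' Sort a GTrack document
#'
#' Orders bounding regions by (genome, seqid, start) and the elements
#' within each region (and the region-less block) by (seqid, start, end,
#' id). Dense blocks are left untouched: their element order is
#' semantic. The `sorted elements` header is set.
#'
#' @param doc A `gtrack_document`.
#' @return The sorted document.
#' @export
sort_gtrack <- function(doc) {
  el <- doc$elements
  reg <- doc$regions
  if (nrow(reg)) {
    perm <- order(ifelse(is.na(reg$genome), "", reg$genome),
                  reg$seqid, reg$start)
    doc$regions <- reg[perm, ]
    rownames(doc$regions) <- NULL
    remap <- match(seq_len(nrow(reg)), perm)
    el$region <- remap[el$region]
  }
  if (nrow(el) && !is_dense(doc$type)) {
    key_region <- ifelse(is.na(el$region), 0L, el$region)
    ord <- order(key_region, el$seqid, el$start, .effective_end(el),
                 ifelse(is.na(el$id), "", el$id))
    el <- el[ord, ]
  } else if (nrow(el)) {
    # dense: keep element order within each region, but follow the
    # region permutation
    ord <- order(ifelse(is.na(el$region), 0L, el$region),
                 seq_len(nrow(el)))
    el <- el[ord, ]
  }
  rownames(el) <- NULL
  doc$elements <- el
  doc$headers$sorted_elements <- TRUE
  doc$explicit <- union(doc$explicit, "sorted_elements")
  doc
}

# default indexing scheme for element ids: seqid:start-end in canonical
# coordinates, with ".k" suffixes on collisions
.default_ids <- function(el) {
  base <- sprintf("%s:%s-%s", el$seqid, .fmt_coord(el$start),
                  .fmt_coord(.effective_end(el)))
  out <- base
  dup <- duplicated(base) | duplicated(base, fromLast = TRUE)
  if (any(dup)) {
    for (b in unique(base[dup])) {
      ix <- which(base == b)
      out[ix] <- paste0(b, ".", seq_along(ix))
    }
  }
  out
}

#' Standardize a GTrack document to linked valued segments
#'
#' Re-expresses any of the fifteen track types as type LVS: every
#' element becomes a segment with value, id and edges columns present
#' (periods where undefined). Points become length-1 segments;
#' partitions and step functions keep their parts; functions become
#' per-base-pair segments (with a warning above 1e6 elements, the size
#' explosion inherent to per-bp tabular lines); missing ids are
#' assigned by the default indexing scheme `seqid:start-end`.
#'
#' @param doc A `gtrack_document`.
#' @return A `gtrack_document` of type LVS.
#' @export
standardize_gtrack <- function(doc) {
  el <- doc$elements
  n <- nrow(el)
  if (is_dense(doc$type) && !has_lengths(doc$type) && n > 1e6)
    warning("standardizing a per-base-pair track with ", n,
            " elements; output will be large")
  out <- el
  out$region <- NA_integer_   # standardized output is boundless
  out$end <- .effective_end(el)
  if (!"value" %in% names(el) || !has_values(doc$type)) {
    # no value information: missing values (periods)
    out$value <- rep(NA_real_, n)
  }
  if (!"id" %in% doc$columns) {
    out$id <- if (n) .default_ids(out) else character()
  } else if (n) {
    missing_id <- is.na(out$id)
    if (any(missing_id)) out$id[missing_id] <- .default_ids(out)[missing_id]
  }
  if (!"edges" %in% doc$columns) out$edges <- rep(NA_character_, n)
  keep_headers <- doc$headers[intersect(
    doc$explicit, c("value_type", "value_dimension", "undirected_edges",
                    "edge_weights", "edge_weight_type",
                    "edge_weight_dimension"))]
  extras <- extra_columns(doc)
  columns <- c("seqid", "start", "end", "value",
               if ("strand" %in% doc$columns) "strand",
               "id", "edges", extras)
  out <- out[c(.element_base_cols, extras)]
  gtrack_document("LVS", columns = columns, elements = out,
                  regions = NULL, headers = keep_headers)
}

#' Complement a document's columns from another document
#'
#' Columns present in `source` but absent in `target` are appended to
#' `target`; cells are matched by the key (element id, or genomic
#' position seqid:start-end), with periods where no source row matches.
#' Existing target cells are never overwritten.
#'
#' @param target,source `gtrack_document`s.
#' @param key `"id"` or `"position"`.
#' @return The complemented target document.
#' @export
complement_columns <- function(target, source, key = c("id", "position")) {
  key <- match.arg(key)
  keyvec <- function(doc) {
    el <- doc$elements
    if (key == "id") {
      if (!"id" %in% doc$columns)
        stop("key column 'id' is not present in both documents",
             call. = FALSE)
      el$id
    } else {
      sprintf("%s:%s-%s", el$seqid, .fmt_coord(el$start),
              .fmt_coord(.effective_end(el)))
    }
  }
  tk <- keyvec(target)
  sk <- keyvec(source)
  if (anyDuplicated(sk[!is.na(sk)]))
    stop("ambiguous key: duplicate ", key, " values in the source document",
         call. = FALSE)
  new_cols <- setdiff(source$columns, target$columns)
  m <- match(tk, sk)
  sel <- source$elements
  for (cn in new_cols) {
    v <- switch(cn,
      value = sel$value, strand = sel$strand, id = sel$id,
      edges = sel$edges, genome = sel$genome, sel[[cn]])
    picked <- v[m]
    if (is.numeric(v)) picked[is.na(m)] <- NA
    target$elements[[cn]] <- picked
    target$columns <- c(target$columns, cn)
  }
  # a gained core column may change the track type
  core <- intersect(c("start", "end", "value", "edges"), target$columns)
  ty <- tryCatch(type_from_columns(core), error = function(e) NULL)
  if (!is.null(ty) && ty != target$type && is_sparse(target$type)) {
    target$type <- ty
    target$headers$track_type <- track_type_name(ty)
  }
  target
}
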