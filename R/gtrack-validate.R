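# GTrack validation: checks a raw file or a parsed document against the
# format specification and its own declared headers. Validation is total
# (it never throws); every problem is returned as a typed issue.
#
# Rule codes:
#   R1  column set matches the declared track type / header declarations
#   R2  an edges column requires the id column
#   R3  equal column count on every data line
#   R4  id uniqueness
#   R5  edge targets resolve to existing ids
#   R6  edge reciprocity when 'undirected edges'
#   R7  sorted order when 'sorted elements'
#   R8  no overlaps when 'no overlapping elements'
#   R9  dense types have bounding regions and tile them exactly
#   R10 cells parse per their declared types
#   R11 byte length of data lines under 'fixed-size data lines'
#   R12 elements fall inside their bounding region
#   R13 bounding regions do not overlap
#   R14 strand cells are one of +, -, .
#   R15 (warning) length-1 segments in a segments-class track

#' Validate a GTrack file or document
#'
#' @param x Raw GTrack text (path, string or lines) or a
#'   `gtrack_document`.
#' @return A data.frame of issues with columns `code`, `severity`,
#'   `line` and `message`; zero rows iff the input is fully conformant
#'   (warnings do not block conformance of the data, but are reported).
#' @export
#' @examples
#' validate_gtrack(c("###seqid\tstart\tend", "chr1\t10\t20"))
validate_gtrack <- function(x) {
  if (inherits(x, "gtrack_document")) {
    iss <- .new_issues()
    doc <- x
    .validate_document_columns(doc, iss)
  } else {
    res <- .parse_impl(.read_lines(x))
    iss <- .new_issues()
    for (k in seq_len(nrow(res$issues)))
      .add_issue(iss, res$issues$code[k], res$issues$severity[k],
                 res$issues$line[k], res$issues$message[k])
    doc <- res$doc
  }
  .validate_document_rules(doc, iss)
  out <- .issues_frame(iss)
  # the document-level re-checks can repeat a finding the line-level
  # parse already attributed; keep the attributed copy
  dup <- is.na(out$line) &
    paste(out$code, out$message) %in%
      paste(out$code, out$message)[!is.na(out$line)]
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# R1/R2 re-checks for documents built in memory
.validate_document_columns <- function(doc, iss) {
  core <- intersect(c("start", "end", "value", "edges"), doc$columns)
  ty <- tryCatch(type_from_columns(core), error = function(e) e)
  if (inherits(ty, "error"))
    .add_issue(iss, "R1", "error", NA, conditionMessage(ty))
  else if (ty != doc$type)
    .add_issue(iss, "R1", "error", NA,
               sprintf("track type %s does not match the column set (which implies %s)",
                       sQuote(doc$type), sQuote(ty)))
  if ("edges" %in% doc$columns && !"id" %in% doc$columns)
    .add_issue(iss, "R2", "error", NA,
               "an edges column requires the id column to be present")
  invisible(NULL)
}

.validate_document_rules <- function(doc, iss) {
  el <- doc$elements
  h <- doc$headers

  ## R4: id uniqueness
  if ("id" %in% doc$columns) {
    ids <- el$id[!is.na(el$id)]
    for (dup in unique(ids[duplicated(ids)]))
      .add_issue(iss, "R4", "error", NA,
                 paste0("duplicate element id ", sQuote(dup)))
  }

  ## R5/R6: edge target resolution and reciprocity
  if ("edges" %in% doc$columns && nrow(el)) {
    lists <- lapply(el$edges, function(e)
      tryCatch(parse_edges(e, h), error = function(cond)
        data.frame(target = character(), weight = character(),
                   stringsAsFactors = FALSE)))
    all_ids <- el$id
    for (i in seq_len(nrow(el))) {
      e <- lists[[i]]
      for (k in seq_len(nrow(e))) {
        j <- match(e$target[k], all_ids)
        if (is.na(j)) {
          .add_issue(iss, "R5", "error", NA,
                     sprintf("edge target %s does not resolve to any element id",
                             sQuote(e$target[k])))
        } else if (isTRUE(h$undirected_edges)) {
          back <- lists[[j]]
          m <- match(all_ids[i], back$target)
          if (is.na(all_ids[i]) || is.na(m))
            .add_issue(iss, "R6", "error", NA,
                       sprintf("undirected edge %s -> %s lacks its reciprocal edge",
                               sQuote(all_ids[i]), sQuote(e$target[k])))
          else if (!identical(back$weight[m], e$weight[k]))
            .add_issue(iss, "R6", "error", NA,
                       sprintf("undirected edge %s <-> %s has unequal weights",
                               sQuote(all_ids[i]), sQuote(e$target[k])))
        }
      }
    }
  }

  ## R7: sortedness
  if (isTRUE(h$sorted_elements)) {
    if (!.regions_sorted(doc$regions))
      .add_issue(iss, "R7", "error", NA,
                 "'sorted elements' is declared but bounding regions are not in sorted order")
    if (!.elements_sorted(doc))
      .add_issue(iss, "R7", "error", NA,
                 "'sorted elements' is declared but track elements are not in sorted order")
  }

  ## R8: overlaps
  if (isTRUE(h$no_overlapping_elements) && .overlapping_pairs_exist(doc))
    .add_issue(iss, "R8", "error", NA,
               "'no overlapping elements' is declared but elements overlap")

  ## R9: dense coverage (for documents built in memory; raw parses have
  ## already enforced tiling)
  if (is_dense(doc$type)) {
    if (nrow(doc$regions) == 0L && nrow(el) > 0L)
      .add_issue(iss, "R9", "error", NA,
                 "dense track types require bounding regions")
    for (r in seq_len(nrow(doc$regions))) {
      sel <- which(!is.na(el$region) & el$region == r)
      reg <- doc$regions[r, ]
      ok <- if (has_lengths(doc$type)) {
        length(sel) > 0L &&
          identical(c(reg$start, el$end[sel][-length(sel)]),
                    el$start[sel]) &&
          all(diff(el$end[sel]) > 0) &&
          el$start[sel][1] == reg$start &&
          el$end[sel][length(sel)] == reg$end
      } else {
        length(sel) == reg$end - reg$start &&
          identical(el$start[sel], reg$start + seq_along(sel) - 1)
      }
      if (!ok)
        .add_issue(iss, "R9", "error", NA,
                   sprintf("elements do not exactly tile bounding region %s:[%g,%g)",
                           reg$seqid, reg$start, reg$end))
    }
    extra <- which(is.na(el$region))
    if (length(extra))
      .add_issue(iss, "R9", "error", NA,
                 "dense elements outside any bounding region")
  }

  ## R12: elements inside their bounding region (sparse; dense covered by R9)
  if (is_sparse(doc$type) && nrow(doc$regions) > 0L && nrow(el)) {
    eff_end <- .effective_end(el)
    for (i in seq_len(nrow(el))) {
      r <- el$region[i]
      circular <- isTRUE(h$circular_elements) && !is.na(el$end[i]) &&
        el$end[i] <= el$start[i]
      if (is.na(r)) {
        .add_issue(iss, "R12", "error", NA,
                   sprintf("element %s:%g is outside all bounding regions",
                           el$seqid[i], el$start[i]))
      } else if (!circular) {
        reg <- doc$regions[r, ]
        if (!identical(el$seqid[i], reg$seqid) ||
            el$start[i] < reg$start || eff_end[i] > reg$end)
          .add_issue(iss, "R12", "error", NA,
                     sprintf("element %s:[%g,%g) lies outside its bounding region %s:[%g,%g)",
                             el$seqid[i], el$start[i], eff_end[i],
                             reg$seqid, reg$start, reg$end))
      }
    }
  }

  ## R13: bounding regions non-overlapping (per genome+seqid)
  reg <- doc$regions
  if (nrow(reg) > 1L) {
    grp <- paste(ifelse(is.na(reg$genome), "", reg$genome), reg$seqid)
    for (g in unique(grp)) {
      ix <- which(grp == g)
      if (length(ix) < 2L) next
      o <- ix[order(reg$start[ix])]
      if (any(reg$start[o][-1] < reg$end[o][-length(o)]))
        .add_issue(iss, "R13", "error", NA,
                   paste0("overlapping bounding regions on ", reg$seqid[ix[1]]))
    }
  }

  ## R14 on documents built in memory
  if ("strand" %in% doc$columns && nrow(el)) {
    bad <- which(!is.na(el$strand) & !el$strand %in% c("+", "-"))
    for (i in bad)
      .add_issue(iss, "R14", "error", NA,
                 sprintf("strand cell %s is not one of +, -, .",
                         sQuote(el$strand[i])))
  }

  ## R15 (warning): length-1 segments under the formal model
  if (is_sparse(doc$type) && has_lengths(doc$type) && nrow(el)) {
    n1 <- sum(!is.na(el$end) & el$end - el$start == 1)
    if (n1 > 0L)
      .add_issue(iss, "R15", "warning", NA,
                 sprintf("%d length-1 segment(s); the formal model excludes segments of length 1 (points)",
                         n1))
  }
  invisible(NULL)
}

#' Assert structural expectations on a document's headers
#'
#' A quick consumer check: read the headers and fail explicitly unless
#' the declared structure matches the stated expectations (for example,
#' a segments track with no overlapping elements).
#'
#' @param doc A `gtrack_document`.
#' @param track_type Expected track type id (or full name), or `NULL`.
#' @param headers Named list of expected header values (only the listed
#'   ones are checked).
#' @return Invisibly `TRUE`; a failed expectation is an error naming
#'   the first deviating property.
#' @export
#' @examples
#' doc <- parse_gtrack(c("##no overlapping elements: true",
#'                       "###seqid\tstart\tend", "chr1\t0\t5"))
#' assert_structure(doc, track_type = "S",
#'                  headers = list(no_overlapping_elements = TRUE))
assert_structure <- function(doc, track_type = NULL, headers = list()) {
  stopifnot(inherits(doc, "gtrack_document"))
  if (!is.null(track_type)) {
    want <- if (track_type %in% track_type_ids()) track_type
            else track_type_from_name(track_type)
    if (doc$type != want)
      stop("structure assertion failed: track type is ", doc$type,
           ", expected ", want, call. = FALSE)
  }
  for (k in names(headers))
    if (!identical(doc$headers[[k]], headers[[k]]))
      stop("structure assertion failed: header ", sQuote(k), " is ",
           .format_header_value(k, doc$headers[[k]]), ", expected ",
           .format_header_value(k, headers[[k]]), call. = FALSE)
  invisible(TRUE)
}
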