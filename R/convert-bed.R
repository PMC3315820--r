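# BED (3-12 column) conversion. BED uses 0-based half-open coordinates,
# matching the canonical internal convention, so coordinates convert
# without shifts.

.bed_fields <- c("chrom", "chromStart", "chromEnd", "name", "score",
                 "strand", "thickStart", "thickEnd", "itemRgb",
                 "blockCount", "blockSizes", "blockStarts")

#' Read BED records
#'
#' @param x Path, string or lines of a BED (3-12 column) file; `track`,
#'   `browser` and comment lines are skipped.
#' @return A data.frame with the twelve BED fields (`NA` where absent)
#'   and an `n_fields` attribute giving the populated column count.
#' @export
read_bed <- function(x) {
  lines <- .read_lines(x)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) &
                   !grepl("^\\s*$", lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  nf <- if (length(cells)) max(lengths(cells)) else 3L
  if (nf < 3L || nf > 12L)
    stop("BED records must have 3-12 columns, found ", nf, call. = FALSE)
  rec <- as.data.frame(matrix(NA_character_, length(cells), 12L,
                              dimnames = list(NULL, .bed_fields)),
                       stringsAsFactors = FALSE)
  for (i in seq_along(cells)) {
    cc <- cells[[i]]
    if (length(cc) < 3L)
      stop("BED line ", i, " has fewer than 3 columns", call. = FALSE)
    rec[i, seq_along(cc)] <- cc
  }
  for (col in c("chromStart", "chromEnd", "score", "thickStart",
                "thickEnd", "blockCount"))
    rec[[col]] <- suppressWarnings(as.numeric(rec[[col]]))
  structure(rec, n_fields = nf)
}

#' Write BED records
#'
#' @param records A data.frame as returned by [read_bed()].
#' @param file Optional output path.
#' @param n_fields Number of leading columns to emit (ladder without
#'   gaps); defaults to the records' `n_fields` attribute.
#' @return Character vector of lines.
#' @export
write_bed <- function(records, file = NULL, n_fields = NULL) {
  if (is.null(n_fields)) n_fields <- attr(records, "n_fields")
  if (is.null(n_fields)) n_fields <- 3L
  cols <- .bed_fields[seq_len(n_fields)]
  cells <- lapply(cols, function(cn) {
    v <- records[[cn]]
    if (is.numeric(v)) ifelse(is.na(v), ".", .fmt_value_cell(v))
    else ifelse(is.na(v), ".", as.character(v))
  })
  lines <- do.call(paste, c(cells, sep = "\t"))
  if (!is.null(file)) writeLines(lines, file)
  lines
}

#' Convert BED records to a GTrack document
#'
#' In `direct` mode each BED record becomes one element; the score
#' becomes the value column when present (type S or VS) and remaining
#' BED fields become extra columns. In `linked` mode BED12 blocks are
#' expanded into child subsegments, each carrying an edge to its parent
#' record's element (type LS or LVS); parent ids come from the name
#' field when present, else synthesized ordinals `bedN`, and child ids
#' are `parentId.k`.
#'
#' @param records BED records (data.frame from [read_bed()]).
#' @param mode `"direct"` or `"linked"`.
#' @return A `gtrack_document`.
#' @export
bed_to_gtrack <- function(records, mode = c("direct", "linked")) {
  mode <- match.arg(mode)
  nf <- attr(records, "n_fields")
  if (is.null(nf)) nf <- sum(.bed_fields %in% names(records))
  has_score <- nf >= 5L
  has_name <- nf >= 4L
  has_strand <- nf >= 6L
  n <- nrow(records)

  if (mode == "direct") {
    el <- data.frame(seqid = records$chrom,
                     start = records$chromStart,
                     end = records$chromEnd,
                     stringsAsFactors = FALSE)
    columns <- c("seqid", "start", "end")
    if (has_score) {
      el$value <- records$score
      columns <- c(columns, "value")
    }
    if (has_strand) {
      el$strand <- ifelse(records$strand %in% c("+", "-"),
                          records$strand, NA_character_)
      columns <- c(columns, "strand")
    }
    if (has_name) {
      el$name <- records$name
      columns <- c(columns, "name")
    }
    for (extra in .bed_fields[-seq_len(6L)][seq_len(max(0L, nf - 6L))]) {
      el[[extra]] <- as.character(records[[extra]])
      columns <- c(columns, extra)
    }
    type <- if (has_score) "VS" else "S"
    return(gtrack_document(type, columns = columns, elements = el))
  }

  ## linked: expand blocks into child subsegments pointing at the parent
  parent_id <- if (has_name && !anyDuplicated(records$name))
    records$name else paste0("bed", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- data.frame(seqid = records$chrom[i], start = records$chromStart[i],
                    end = records$chromEnd[i],
                    value = if (has_score) records$score[i] else NA_real_,
                    strand = if (has_strand &&
                                 records$strand[i] %in% c("+", "-"))
                      records$strand[i] else NA_character_,
                    id = parent_id[i], edges = NA_character_,
                    stringsAsFactors = FALSE)
    kids <- NULL
    bc <- records$blockCount[i]
    if (!is.na(bc) && bc > 0) {
      sizes <- as.numeric(strsplit(records$blockSizes[i], ",")[[1]])
      starts <- as.numeric(strsplit(records$blockStarts[i], ",")[[1]])
      if (length(sizes) != bc || length(starts) != bc)
        stop("malformed block lists in BED record ", i, call. = FALSE)
      kids <- data.frame(seqid = records$chrom[i],
                         start = records$chromStart[i] + starts,
                         end = records$chromStart[i] + starts + sizes,
                         value = NA_real_, strand = p$strand,
                         id = paste0(parent_id[i], ".", seq_len(bc)),
                         edges = parent_id[i],
                         stringsAsFactors = FALSE)
    }
    rows[[i]] <- rbind(p, kids)
  }
  el <- do.call(rbind, rows)
  columns <- c("seqid", "start", "end",
               if (has_score) "value",
               if (has_strand) "strand", "id", "edges")
  type <- if (has_score) "LVS" else "LS"
  if (!has_score) el$value <- NULL
  gtrack_document(type, columns = columns, elements = el)
}

#' Convert a GTrack document to BED records
#'
#' Supported for sparse point/segment types; points become length-1 BED
#' intervals. Dense types cannot be represented in BED.
#'
#' @param doc A `gtrack_document` of type P, S, VP, VS, LS or LVS.
#' @return BED records (data.frame with `n_fields` attribute).
#' @export
gtrack_to_bed <- function(doc) {
  if (is_dense(doc$type))
    stop("unsupported conversion: dense track type ", doc$type,
         " cannot be represented in BED", call. = FALSE)
  el <- doc$elements
  rec <- data.frame(matrix(NA_character_, nrow(el), 12L,
                           dimnames = list(NULL, .bed_fields)),
                    stringsAsFactors = FALSE)
  rec$chrom <- el$seqid
  rec$chromStart <- el$start
  rec$chromEnd <- .effective_end(el)
  nf <- 3L
  name <- if ("id" %in% doc$columns) el$id
          else if ("name" %in% doc$columns) el$name else NULL
  has_score <- "value" %in% doc$columns
  has_strand <- "strand" %in% doc$columns
  if (!is.null(name) || has_score || has_strand) {
    rec$name <- if (is.null(name)) "." else ifelse(is.na(name), ".", name)
    nf <- 4L
  }
  if (has_score || has_strand) {
    rec$score <- if (has_score) suppressWarnings(as.numeric(el$value))
                 else NA_real_
    nf <- 5L
  }
  if (has_strand) {
    rec$strand <- ifelse(is.na(el$strand), ".", el$strand)
    nf <- 6L
  }
  for (col in c("chromStart", "chromEnd", "thickStart", "thickEnd",
                "blockCount"))
    rec[[col]] <- suppressWarnings(as.numeric(rec[[col]]))
  structure(rec, n_fields = nf)
}
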