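# WIG (wiggle) conversion. WIG coordinates are 1-based; a declaration
# line opens each block:
#   variableStep chrom=<seqid> [span=<bp>]  -- data lines "pos value"
#   fixedStep chrom=<seqid> start=<pos> step=<bp> [span=<bp>]
#                                           -- data lines "value"
# variableStep with span 1 carries sparse single-base-pair values
# (valued points); fixedStep with step equal to span carries dense data
# (a step function), with end positions deriving element placement.

#' Read WIG blocks
#' @param x Path, string or lines.
#' @return A list of blocks, each a list with `mode`, `chrom`, `span`,
#'   `step`, `start` and a data.frame `lines` (`pos` for variableStep,
#'   `value`).
#' @export
read_wig <- function(x) {
  lines <- .read_lines(x)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) &
                   !grepl("^\\s*$", lines)]
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
  }
  parse_attrs <- function(parts) {
    kv <- strsplit(parts, "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  for (ln in lines) {
    if (grepl("^(variableStep|fixedStep)\\b", ln)) {
      flush()
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      mode <- parts[1]
      at <- parse_attrs(parts[-1])
      cur <- list(mode = mode, chrom = unname(at["chrom"]),
                  span = if ("span" %in% names(at))
                    as.numeric(at["span"]) else 1,
                  step = if ("step" %in% names(at))
                    as.numeric(at["step"]) else NA_real_,
                  start = if ("start" %in% names(at))
                    as.numeric(at["start"]) else NA_real_,
                  pos = numeric(), value = numeric())
      if (mode == "fixedStep" && (is.na(cur$step) || is.na(cur$start)))
        stop("fixedStep declaration requires start and step", call. = FALSE)
      if (mode == "fixedStep" && cur$step < cur$span)
        stop("fixedStep requires step >= span", call. = FALSE)
    } else {
      if (is.null(cur)) stop("WIG data line before any declaration line",
                             call. = FALSE)
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (cur$mode == "variableStep") {
        if (length(f) != 2L) stop("variableStep data lines have 2 fields",
                                  call. = FALSE)
        cur$pos <- c(cur$pos, as.numeric(f[1]))
        cur$value <- c(cur$value, as.numeric(f[2]))
      } else {
        if (length(f) != 1L) stop("fixedStep data lines have 1 field",
                                  call. = FALSE)
        cur$value <- c(cur$value, as.numeric(f[1]))
      }
    }
  }
  flush()
  lapply(blocks, function(b) {
    b$lines <- data.frame(pos = if (b$mode == "variableStep") b$pos
                          else b$start + (seq_along(b$value) - 1) * b$step,
                          value = b$value)
    b$pos <- NULL; b$value <- NULL
    b
  })
}

#' Write WIG blocks
#' @param blocks As returned by [read_wig()].
#' @param file Optional output path.
#' @return Character vector of lines; span is always written explicitly.
#' @export
write_wig <- function(blocks, file = NULL) {
  out <- character()
  for (b in blocks) {
    if (b$mode == "variableStep") {
      out <- c(out, sprintf("variableStep chrom=%s span=%s", b$chrom,
                            .fmt_coord(b$span)),
               paste(.fmt_coord(b$lines$pos),
                     .fmt_value_cell(b$lines$value), sep = "\t"))
    } else {
      out <- c(out, sprintf("fixedStep chrom=%s start=%s step=%s span=%s",
                            b$chrom, .fmt_coord(b$lines$pos[1]),
                            .fmt_coord(b$step), .fmt_coord(b$span)),
               .fmt_value_cell(b$lines$value))
    }
  }
  if (!is.null(file)) writeLines(out, file)
  out
}

#' Convert WIG blocks to a GTrack document
#'
#' Typing rules: variableStep with span 1 gives valued points (VP);
#' variableStep with larger spans gives valued segments (VS); fixedStep
#' with step equal to span gives a step function (SF) with one bounding
#' region per block; fixedStep with step greater than span gives sparse
#' valued segments. Mixed inputs fall back to VS.
#'
#' @param blocks As returned by [read_wig()].
#' @return A `gtrack_document`.
#' @export
wig_to_gtrack <- function(blocks) {
  if (!length(blocks)) stop("no WIG blocks", call. = FALSE)
  block_type <- vapply(blocks, function(b) {
    if (b$mode == "variableStep") {
      if (b$span == 1) "VP" else "VS"
    } else if (b$step == b$span) "SF" else "VS"
  }, "")
  type <- if (all(block_type == "VP")) "VP"
          else if (all(block_type == "SF")) "SF" else "VS"

  if (type == "SF") {
    regions <- NULL; el <- NULL
    for (b in blocks) {
      n <- nrow(b$lines)
      r_start <- b$lines$pos[1] - 1
      r_end <- r_start + n * b$span
      if (any(diff(b$lines$pos) != b$step))
        stop("overlapping or discontiguous spans in fixedStep block",
             call. = FALSE)
      regions <- rbind(regions,
                       data.frame(seqid = b$chrom, start = r_start,
                                  end = r_end, stringsAsFactors = FALSE))
      el <- rbind(el, data.frame(region = nrow(regions), seqid = b$chrom,
                                 start = r_start + (seq_len(n) - 1) * b$span,
                                 end = r_start + seq_len(n) * b$span,
                                 value = b$lines$value,
                                 stringsAsFactors = FALSE))
    }
    return(gtrack_document("SF", columns = c("end", "value"),
                           elements = el, regions = regions))
  }

  el <- NULL
  for (b in blocks) {
    starts <- b$lines$pos - 1
    span <- if (b$mode == "fixedStep") b$span else b$span
    if (any(diff(sort(starts)) < span))
      stop("overlapping spans within a WIG block", call. = FALSE)
    el <- rbind(el, data.frame(seqid = b$chrom, start = starts,
                               end = starts + span, value = b$lines$value,
                               stringsAsFactors = FALSE))
  }
  if (type == "VP") {
    el$end <- NULL
    gtrack_document("VP", columns = c("seqid", "start", "value"),
                    elements = el)
  } else {
    gtrack_document("VS", columns = c("seqid", "start", "end", "value"),
                    elements = el)
  }
}

#' Convert a GTrack document to WIG blocks
#'
#' Chooses fixedStep for dense uniform data (F and uniform-part SF) and
#' variableStep otherwise (VP, uniform-length VS). Non-uniform valued
#' segments cannot be expressed in WIG; the error suggests bedGraph,
#' the recommended format for sparse or varying-size continuous data.
#'
#' @param doc A `gtrack_document` of type VP, VS (uniform lengths), SF
#'   (uniform part lengths) or F, with numeric scalar values.
#' @return A list of WIG blocks.
#' @export
gtrack_to_wig <- function(doc) {
  if (!.numeric_value_storage(doc$headers$value_type,
                              doc$headers$value_dimension))
    stop("WIG requires numeric scalar values", call. = FALSE)
  el <- doc$elements
  type <- doc$type
  blocks <- list()
  if (type == "VP") {
    for (sq in unique(el$seqid)) {
      sub <- el[el$seqid == sq, ]
      blocks[[length(blocks) + 1L]] <-
        list(mode = "variableStep", chrom = sq, span = 1, step = NA_real_,
             start = NA_real_,
             lines = data.frame(pos = sub$start + 1, value = sub$value))
    }
  } else if (type == "VS") {
    lens <- el$end - el$start
    if (length(unique(lens)) > 1L)
      stop("valued segments with varying lengths cannot be expressed in WIG; use bedGraph instead",
           call. = FALSE)
    span <- if (nrow(el)) lens[1] else 1
    for (sq in unique(el$seqid)) {
      sub <- el[el$seqid == sq, ]
      blocks[[length(blocks) + 1L]] <-
        list(mode = "variableStep", chrom = sq, span = span,
             step = NA_real_, start = NA_real_,
             lines = data.frame(pos = sub$start + 1, value = sub$value))
    }
  } else if (type == "SF") {
    for (r in seq_len(nrow(doc$regions))) {
      sub <- el[!is.na(el$region) & el$region == r, ]
      lens <- sub$end - sub$start
      if (length(unique(lens)) > 1L)
        stop("step function with varying part lengths cannot be expressed in WIG; use bedGraph instead",
             call. = FALSE)
      span <- lens[1]
      blocks[[length(blocks) + 1L]] <-
        list(mode = "fixedStep", chrom = doc$regions$seqid[r], span = span,
             step = span, start = sub$start[1] + 1,
             lines = data.frame(pos = sub$start + 1, value = sub$value))
    }
  } else if (type == "F") {
    for (r in seq_len(nrow(doc$regions))) {
      sub <- el[!is.na(el$region) & el$region == r, ]
      blocks[[length(blocks) + 1L]] <-
        list(mode = "fixedStep", chrom = doc$regions$seqid[r], span = 1,
             step = 1, start = sub$start[1] + 1,
             lines = data.frame(pos = sub$start + 1, value = sub$value))
    }
  } else {
    stop("unsupported conversion to WIG for track type ", type,
         call. = FALSE)
  }
  blocks
}
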