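# GTrack 1.0 parser.
#
# Line grammar: "####" bounding region, "###" column specification,
# "##" header ("##name: value", case-insensitive names), "#" comment,
# anything else a tab-separated data line. Bounding region lines hold
# "; "-separated key=value pairs over {genome, seqid, start, end}.
# Parsing always produces canonical 0-based half-open coordinates; the
# dialect headers (1-indexed, end inclusive), value/edges column aliases
# and fixed-geometry headers are normalised away in the returned document.

.new_issues <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

.add_issue <- function(env, code, severity, line, message) {
  env$rows[[length(env$rows) + 1L]] <-
    data.frame(code = code, severity = severity,
               line = if (is.null(line)) NA_integer_ else as.integer(line),
               message = message, stringsAsFactors = FALSE)
  invisible(NULL)
}

.issues_frame <- function(env) {
  if (!length(env$rows))
    return(data.frame(code = character(), severity = character(),
                      line = integer(), message = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, env$rows)
  ord <- order(is.na(out$line), out$line, out$code)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.read_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  else if (length(x) == 1L && grepl("\n", x))
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  sub("\r$", "", x)
}

# is value storage numeric for this value configuration?
.numeric_value_storage <- function(value_type, value_dimension) {
  value_type %in% c("number", "binary") && value_dimension == "scalar"
}

# Does a cell conform to a value type/dimension? ("." is always valid.)
.cell_conforms <- function(cell, type, dimension, list_sep = ",") {
  if (is.na(cell) || cell == ".") return(TRUE)
  comps <- if (dimension == "list")
    strsplit(cell, list_sep, fixed = TRUE)[[1]] else cell
  if (!length(comps)) return(FALSE)
  all(vapply(comps, function(v) {
    switch(type,
      number = !is.na(suppressWarnings(as.numeric(v))),
      binary = v %in% c("0", "1"),
      character = nchar(v) == 1L,
      category = !grepl("\t", v, fixed = TRUE))
  }, logical(1)))
}

#' Parse an edges cell
#'
#' The edges cell is a comma-separated list of target element ids; a
#' weighted edge uses the `id=weight` form, and list-valued weights
#' separate components with `|`. A lone period denotes no edges.
#'
#' @param text The edges cell.
#' @param headers A header set (for `edge_weights` and the weight
#'   type/dimension); defaults are used when omitted.
#' @return A data.frame with columns `target` and `weight` (character;
#'   `NA` when unweighted).
#' @export
#' @examples
#' parse_edges("g1,g2")
#' parse_edges("g1=0.5,g2=1.25", list(edge_weights = TRUE))
parse_edges <- function(text, headers = list()) {
  h <- .make_headers(headers[intersect(names(headers), names(default_headers()))])
  empty <- data.frame(target = character(), weight = character(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || text == "." || text == "") return(empty)
  items <- strsplit(text, ",", fixed = TRUE)[[1]]
  target <- sub("=.*$", "", items)
  weight <- ifelse(grepl("=", items, fixed = TRUE),
                   sub("^[^=]*=", "", items), NA_character_)
  if (any(!nzchar(target)))
    stop("edge with empty target id in ", sQuote(text), call. = FALSE)
  if (any(!is.na(weight)) && !isTRUE(h$edge_weights))
    stop("edge weights present but 'edge weights' header is false",
         call. = FALSE)
  if (isTRUE(h$edge_weights)) {
    ok <- vapply(weight, function(w) is.na(w) ||
                   .cell_conforms(w, h$edge_weight_type,
                                  h$edge_weight_dimension, list_sep = "|"),
                 logical(1))
    if (!all(ok))
      stop("unparseable edge weight in ", sQuote(text), call. = FALSE)
  }
  data.frame(target = target, weight = weight, stringsAsFactors = FALSE)
}

#' Compute positions of dense track elements
#'
#' Dense track types carry no start column. For types with the lengths
#' property (GP, SF, LGP, LSF) each element runs from the previous
#' element's end (initially the bounding region start) to its own end
#' coordinate, and the last end must equal the region end. For the
#' base-pair types (F, LF, LBP) the k-th data line is the single base
#' pair `region_start + k - 1` and the line count must equal the region
#' length.
#'
#' @param region_start,region_end Canonical bounds of the bounding region.
#' @param type Dense track type id.
#' @param ends Canonical end coordinates, for lengths-bearing dense types.
#' @param n Number of data lines, for base-pair dense types.
#' @return A list with vectors `start` and `end` (`end` is `NA` for
#'   base-pair types).
#' @export
compute_dense_positions <- function(region_start, region_end, type,
                                    ends = NULL, n = NULL) {
  if (!is_dense(type))
    stop("not a dense track type: ", type, call. = FALSE)
  if (has_lengths(type)) {
    ends <- as.numeric(ends)
    if (length(ends) == 0L)
      stop("dense region without data lines", call. = FALSE)
    if (any(diff(c(region_start, ends)) <= 0))
      stop("end positions must be strictly increasing within the bounding region",
           call. = FALSE)
    if (ends[length(ends)] != region_end)
      stop("last end position (", ends[length(ends)],
           ") does not equal the bounding region end (", region_end, ")",
           call. = FALSE)
    list(start = c(region_start, ends[-length(ends)]), end = ends)
  } else {
    n <- as.integer(n)
    if (n != region_end - region_start)
      stop("number of data lines (", n,
           ") does not equal the bounding region length (",
           region_end - region_start, ")", call. = FALSE)
    list(start = region_start + seq_len(n) - 1, end = rep(NA_real_, n))
  }
}

#' Materialise fixed-geometry coordinates
#'
#' The `fixed length` header implies the end coordinate of every element
#' (`end = start + L`); the `fixed gap size` header implies the start
#' coordinate (`start = previous end + g`, the first element starting at
#' the bounding region start).
#'
#' @param starts,ends Canonical coordinate vectors; `NULL` for the
#'   implied one.
#' @param fixed_length,fixed_gap_size Header values.
#' @param region_start Start of the enclosing bounding region (needed
#'   when starts are implied).
#' @return A list with explicit `start` and `end` vectors.
#' @export
apply_fixed_geometry <- function(starts = NULL, ends = NULL,
                                 fixed_length = NULL, fixed_gap_size = NULL,
                                 region_start = NULL) {
  if (!is.null(fixed_length) && !is.null(ends))
    stop("consistency check failure: both an end column and a fixed length are declared",
         call. = FALSE)
  if (!is.null(fixed_gap_size) && !is.null(starts))
    stop("consistency check failure: both a start column and a fixed gap size are declared",
         call. = FALSE)
  if (is.null(starts)) {
    if (is.null(fixed_gap_size))
      stop("no start coordinates and no fixed gap size", call. = FALSE)
    if (is.null(region_start))
      stop("fixed gap size requires an enclosing bounding region",
           call. = FALSE)
    n <- length(ends)
    if (!is.null(fixed_length)) {
      # both implied: elements of length L separated by gaps of g
      if (is.null(n) || n == 0L) n <- 0L
      stop("fixed gap size together with fixed length requires an element count",
           call. = FALSE)
    }
    # starts implied from ends: start_k = prev_end + g
    starts <- numeric(length(ends))
    prev <- region_start
    for (k in seq_along(ends)) {
      starts[k] <- prev + fixed_gap_size
      prev <- ends[k]
    }
  }
  if (is.null(ends)) {
    if (is.null(fixed_length))
      stop("no end coordinates and no fixed length", call. = FALSE)
    ends <- starts + fixed_length
  }
  list(start = starts, end = ends)
}

# fixed geometry when BOTH coordinates are implied (n elements)
.fixed_geometry_counts <- function(n, fixed_length, fixed_gap_size,
                                   region_start) {
  starts <- region_start + fixed_gap_size +
    (seq_len(n) - 1) * (fixed_length + fixed_gap_size)
  list(start = starts, end = starts + fixed_length)
}

#' Parse a GTrack 1.0 document
#'
#' @param x A file path, a single string containing newlines, or a
#'   character vector of lines.
#' @param model Optional subtype model document (see
#'   [resolve_subtype()]); its headers and column specification are
#'   merged under this file's own before data lines are interpreted.
#' @return A `gtrack_document` in canonical coordinates.
#' @export
#' @examples
#' txt <- c("##track type: points", "###seqid\tstart", "chr1\t100")
#' doc <- parse_gtrack(txt)
#' doc$elements$start
parse_gtrack <- function(x, model = NULL) {
  res <- .parse_impl(.read_lines(x), model = model)
  bad <- res$issues[res$issues$severity == "error", , drop = FALSE]
  if (nrow(bad)) {
    first <- bad[1L, ]
    stop(sprintf("GTrack parse error [%s]%s: %s", first$code,
                 if (is.na(first$line)) "" else paste0(" (line ", first$line, ")"),
                 first$message), call. = FALSE)
  }
  res$doc
}

.parse_impl <- function(lines, model = NULL) {
  iss <- .new_issues()
  n_lines <- length(lines)
  kind <- rep("data", n_lines)
  kind[grepl("^\\s*$", lines)] <- "blank"
  kind[startsWith(lines, "#")] <- "comment"
  kind[startsWith(lines, "##")] <- "header"
  kind[startsWith(lines, "###")] <- "colspec"
  kind[startsWith(lines, "####")] <- "region"

  comments <- sub("^# ?", "", lines[kind == "comment"])

  ## ---- headers ----
  headers <- default_headers()
  explicit <- character()
  for (i in which(kind == "header")) {
    body <- sub("^##", "", lines[i])
    if (!grepl(":", body, fixed = TRUE)) {
      .add_issue(iss, "R1", "error", i, "malformed header line (missing ':')")
      next
    }
    name <- sub(":.*$", "", body)
    value <- sub("^[^:]*:", "", body)
    key <- .header_key_from_display(name)
    if (is.na(key)) {
      .add_issue(iss, "R1", "error", i,
                 paste0("unknown header variable ", sQuote(trimws(name))))
      next
    }
    parsed <- tryCatch(.parse_header_value(key, value), error = function(e) e)
    if (inherits(parsed, "error")) {
      .add_issue(iss, "R10", "error", i, conditionMessage(parsed))
      next
    }
    headers[[key]] <- parsed
    explicit <- union(explicit, key)
  }

  ## ---- column specification ----
  colspec_lines <- which(kind == "colspec")
  colspec_explicit <- length(colspec_lines) > 0L
  if (length(colspec_lines) > 1L)
    .add_issue(iss, "R1", "error", colspec_lines[2L],
               "more than one column specification line")
  if (colspec_explicit) {
    columns <- strsplit(sub("^###", "", lines[colspec_lines[1L]]),
                        "\t", fixed = TRUE)[[1]]
    reserved <- match(tolower(columns), reserved_columns())
    columns[!is.na(reserved)] <- reserved_columns()[reserved[!is.na(reserved)]]
  } else {
    columns <- c("seqid", "start", "end")
  }

  ## ---- subtype model merge ----
  if (is.null(model) && nzchar(headers$subtype_url) &&
      !grepl("^[a-z][a-z0-9+.-]*://", headers$subtype_url) &&
      file.exists(headers$subtype_url)) {
    model <- tryCatch(parse_gtrack(headers$subtype_url),
                      error = function(e) e)
    if (inherits(model, "error")) {
      .add_issue(iss, "R1", "error", NA,
                 paste0("subtype model could not be parsed: ",
                        conditionMessage(model)))
      model <- NULL
    }
  }
  if (!is.null(model)) {
    merged <- .merge_subtype(headers, explicit, columns, colspec_explicit,
                             model)
    if (inherits(merged, "error")) {
      .add_issue(iss, "R1", "error", NA, conditionMessage(merged))
    } else {
      headers <- merged$headers
      explicit <- merged$explicit
      columns <- merged$columns
      colspec_explicit <- merged$colspec_explicit
    }
  }

  if (anyDuplicated(columns)) {
    .add_issue(iss, "R1", "error", if (colspec_explicit) colspec_lines[1L] else NA,
               "duplicate column names in the column specification")
    columns <- unique(columns)
  }

  ## ---- value / edges column aliasing ----
  for (alias in c("value", "edges")) {
    key <- paste0(alias, "_column")
    name <- headers[[key]]
    if (!identical(name, alias)) {
      if (alias %in% columns)
        .add_issue(iss, "R1", "error", NA,
                   sprintf("both a literal %s column and a '%s column' alias (%s) are present",
                           alias, alias, sQuote(name)))
      else if (!name %in% columns)
        .add_issue(iss, "R1", "error", NA,
                   sprintf("'%s column' header names %s, which is not a column",
                           alias, sQuote(name)))
      else
        columns[columns == name] <- alias
      headers[[key]] <- alias
      explicit <- setdiff(explicit, key)
    }
  }

  ## ---- fixed geometry declarations ----
  # fixed length takes effect only when explicitly declared with a
  # non-default value (the default of 1 on a points track has no effect);
  # fixed gap size takes effect whenever explicitly declared (a declared
  # gap of 0 means abutting elements).
  fixed_length <- if ("fixed_length" %in% explicit &&
                      headers$fixed_length != 1L) headers$fixed_length else NULL
  fixed_gap <- if ("fixed_gap_size" %in% explicit) headers$fixed_gap_size else NULL
  if (!is.null(fixed_length) && "end" %in% columns) {
    .add_issue(iss, "R1", "error", NA,
               "consistency check failure: both an end column and a fixed length are declared")
    fixed_length <- NULL
  }
  if (!is.null(fixed_gap) && "start" %in% columns) {
    .add_issue(iss, "R1", "error", NA,
               "consistency check failure: both a start column and a fixed gap size are declared")
    fixed_gap <- NULL
  }

  ## ---- track type ----
  core_present <- intersect(c("start", "end", "value", "edges"), columns)
  effective_core <- core_present
  if (!is.null(fixed_length)) effective_core <- union(effective_core, "end")
  if (!is.null(fixed_gap)) effective_core <- union(effective_core, "start")
  type <- tryCatch(type_from_columns(effective_core), error = function(e) e)
  if (inherits(type, "error")) {
    .add_issue(iss, "R1", "error", NA, conditionMessage(type))
    type <- "S"  # recovery only; the error issue stands
  }
  if ("track_type" %in% explicit) {
    declared <- tryCatch(track_type_from_name(headers$track_type),
                         error = function(e) e)
    if (inherits(declared, "error"))
      .add_issue(iss, "R1", "error", NA, conditionMessage(declared))
    else if (declared != type)
      .add_issue(iss, "R1", "error", NA,
                 sprintf("declared track type %s does not match the column set (which implies %s)",
                         sQuote(track_type_name(declared)),
                         sQuote(track_type_name(type))))
  }
  headers$track_type <- track_type_name(type)
  explicit <- union(explicit, "track_type")
  if ("edges" %in% columns && !"id" %in% columns)
    .add_issue(iss, "R2", "error", NA,
               "an edges column requires the id column to be present")

  dialect <- list(one_indexed = headers$one_indexed,
                  end_inclusive = headers$end_inclusive)
  fixed_size <- headers$fixed_size_data_lines
  dls <- headers$data_line_size
  layout_keys <- c("one_indexed", "end_inclusive", "fixed_length",
                   "fixed_gap_size", "fixed_size_data_lines",
                   "data_line_size")
  layout <- list(values = headers[layout_keys],
                 explicit = intersect(explicit, layout_keys))
  # dialect / physical-layout headers are normalised away
  headers$one_indexed <- FALSE
  headers$end_inclusive <- FALSE
  headers$fixed_length <- 1L
  headers$fixed_gap_size <- 0L
  headers$fixed_size_data_lines <- FALSE
  headers$data_line_size <- 1L
  explicit <- setdiff(explicit, c("one_indexed", "end_inclusive",
                                  "fixed_length", "fixed_gap_size",
                                  "fixed_size_data_lines", "data_line_size"))

  ## ---- bounding regions ----
  region_lines <- which(kind == "region")
  regions <- data.frame(genome = character(), seqid = character(),
                        start = numeric(), end = numeric(),
                        stringsAsFactors = FALSE)
  ok_regions <- logical(length(region_lines))
  for (ri in seq_along(region_lines)) {
    i <- region_lines[ri]
    body <- sub("^####", "", lines[i])
    pairs <- strsplit(body, ";", fixed = TRUE)[[1]]
    pairs <- trimws(pairs)
    pairs <- pairs[nzchar(pairs)]
    keys <- sub("=.*$", "", pairs)
    vals <- sub("^[^=]*=", "", pairs)
    keys <- trimws(keys); vals <- trimws(vals)
    if (any(!keys %in% c("genome", "seqid", "start", "end")) ||
        anyDuplicated(keys)) {
      .add_issue(iss, "R1", "error", i,
                 "bounding region keys must be unique and drawn from genome, seqid, start, end")
      next
    }
    kv <- stats::setNames(as.list(vals), keys)
    if (!all(c("seqid", "start", "end") %in% keys)) {
      .add_issue(iss, "R1", "error", i,
                 "bounding region must declare seqid, start and end")
      next
    }
    st <- suppressWarnings(as.numeric(kv$start))
    en <- suppressWarnings(as.numeric(kv$end))
    if (is.na(st) || is.na(en)) {
      .add_issue(iss, "R10", "error", i, "malformed bounding region coordinate")
      next
    }
    cc <- normalize_coordinates(st, en, dialect$one_indexed,
                                dialect$end_inclusive)
    if (cc$end <= cc$start) {
      .add_issue(iss, "R9", "error", i, "empty bounding region")
      next
    }
    regions[nrow(regions) + 1L, ] <-
      list(if (is.null(kv$genome)) NA_character_ else kv$genome,
           kv$seqid, cc$start, cc$end)
    ok_regions[ri] <- TRUE
  }

  if (is_dense(type) && length(region_lines) == 0L &&
      any(kind == "data"))
    .add_issue(iss, "R9", "error", which(kind == "data")[1L],
               "dense track types require bounding regions")

  ## ---- data lines ----
  data_lines <- which(kind == "data")
  # region index for each data line: the latest region line above it
  region_of <- if (length(region_lines))
    findInterval(data_lines, region_lines) else rep(0L, length(data_lines))
  texts <- lines[data_lines]
  if (fixed_size) {
    bad_len <- nchar(texts) != dls
    for (j in which(bad_len))
      .add_issue(iss, "R11", "error", data_lines[j],
                 sprintf("data line has %d characters, 'data line size' is %d",
                         nchar(texts[j]), dls))
    texts <- sub(" +$", "", texts)
  }
  cells <- strsplit(texts, "\t", fixed = TRUE)
  ncols <- lengths(cells)
  bad_count <- ncols != length(columns)
  for (j in which(bad_count))
    .add_issue(iss, "R3", "error", data_lines[j],
               sprintf("data line has %d column(s), expected %d",
                       ncols[j], length(columns)))
  keep <- !bad_count
  cells <- cells[keep]
  keep_lines <- data_lines[keep]
  keep_region <- region_of[keep]

  cell_mat <- if (length(cells))
    matrix(unlist(cells), nrow = length(cells), byrow = TRUE,
           dimnames = list(NULL, columns))
  else matrix(character(), 0, length(columns), dimnames = list(NULL, columns))

  col <- function(name) if (name %in% columns) cell_mat[, name] else NULL

  n <- nrow(cell_mat)
  numeric_col <- function(name) {
    raw <- col(name)
    if (is.null(raw)) return(NULL)
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v)
    for (j in which(bad))
      .add_issue(iss, "R10", "error", keep_lines[j],
                 sprintf("malformed %s coordinate %s", name, sQuote(raw[j])))
    v
  }

  raw_start <- numeric_col("start")
  raw_end <- numeric_col("end")

  starts <- rep(NA_real_, n)
  ends <- rep(NA_real_, n)

  if (!is.null(raw_start))
    starts <- raw_start - as.integer(dialect$one_indexed)
  if (!is.null(raw_end))
    ends <- raw_end - as.integer(dialect$one_indexed) +
      as.integer(dialect$end_inclusive)

  region_idx <- rep(NA_integer_, n)
  if (length(region_lines)) {
    ord2row <- cumsum(ok_regions)
    ord2row[!ok_regions[seq_along(ord2row)]] <- NA_integer_
    region_idx <- ifelse(keep_region == 0L, NA_integer_,
                         ord2row[pmax(keep_region, 1L)])
  }

  ## ---- per-region positioning (dense + fixed geometry) ----
  if (is_dense(type)) {
    for (j in which(is.na(region_idx)))
      .add_issue(iss, "R9", "error", keep_lines[j],
                 "dense data line outside any bounding region")
    for (r in unique(region_idx[!is.na(region_idx)])) {
      sel <- which(!is.na(region_idx) & region_idx == r)
      pos <- tryCatch(
        compute_dense_positions(regions$start[r], regions$end[r], type,
                                ends = ends[sel], n = length(sel)),
        error = function(e) e)
      if (inherits(pos, "error")) {
        .add_issue(iss, "R9", "error",
                   if (length(sel)) keep_lines[sel[length(sel)]] else NA,
                   conditionMessage(pos))
      } else {
        starts[sel] <- pos$start
        ends[sel] <- pos$end
      }
    }
    # required bounding regions with zero data lines
    if (has_lengths(type) || TRUE) {
      used <- unique(region_idx[!is.na(region_idx)])
      for (r in setdiff(seq_len(nrow(regions)), used))
        .add_issue(iss, "R9", "error", NA,
                   sprintf("bounding region %s:[%g,%g) of a dense track has no data lines",
                           regions$seqid[r], regions$start[r], regions$end[r]))
    }
  } else if (!is.null(fixed_length) || !is.null(fixed_gap)) {
    if (is.null(fixed_gap)) {
      ends <- starts + fixed_length
    } else {
      for (r in unique(region_idx)) {
        sel <- if (is.na(r)) which(is.na(region_idx))
               else which(!is.na(region_idx) & region_idx == r)
        if (is.na(r)) {
          if (length(sel))
            .add_issue(iss, "R9", "error", keep_lines[sel[1L]],
                       "fixed gap size requires an enclosing bounding region")
          next
        }
        if (!is.null(fixed_length)) {
          geom <- .fixed_geometry_counts(length(sel), fixed_length, fixed_gap,
                                         regions$start[r])
          starts[sel] <- geom$start
          ends[sel] <- geom$end
        } else {
          geom <- apply_fixed_geometry(starts = NULL, ends = ends[sel],
                                       fixed_gap_size = fixed_gap,
                                       region_start = regions$start[r])
          starts[sel] <- geom$start
        }
      }
    }
    columns <- .insert_core_columns(columns,
                                    add_start = !is.null(fixed_gap),
                                    add_end = !is.null(fixed_length))
  }

  ## ---- empty-interval check (sparse, lengths) ----
  if (is_sparse(type) && has_lengths(type) && !headers$circular_elements) {
    bad <- which(!is.na(starts) & !is.na(ends) & ends <= starts)
    for (j in bad)
      .add_issue(iss, "R10", "error", keep_lines[j],
                 sprintf("empty interval: end (%g) must exceed start (%g) in canonical coordinates",
                         ends[j], starts[j]))
  }

  ## ---- remaining columns ----
  seqids <- col("seqid")
  if (is.null(seqids)) {
    if (n > 0L && !length(region_lines))
      .add_issue(iss, "R1", "error", NA,
                 "no seqid column and no bounding regions to inherit seqid from")
    seqids <- ifelse(is.na(region_idx), NA_character_,
                     regions$seqid[pmax(region_idx, 1L)])
    if (n == 0L) seqids <- character()
  }
  genomes <- col("genome")
  if (is.null(genomes)) {
    genomes <- if (n > 0L)
      ifelse(is.na(region_idx), NA_character_,
             regions$genome[pmax(region_idx, 1L)]) else character()
  } else genomes[genomes == "."] <- NA_character_

  values_raw <- col("value")
  value_store <- NULL
  if (!is.null(values_raw)) {
    ok <- vapply(values_raw, .cell_conforms, logical(1),
                 type = headers$value_type, dimension = headers$value_dimension)
    for (j in which(!ok))
      .add_issue(iss, "R10", "error", keep_lines[j],
                 sprintf("value cell %s does not conform to value type '%s' (%s)",
                         sQuote(values_raw[j]), headers$value_type,
                         headers$value_dimension))
    if (.numeric_value_storage(headers$value_type, headers$value_dimension)) {
      value_store <- suppressWarnings(as.numeric(values_raw))
      value_store[values_raw == "."] <- NA_real_
      value_store[!ok] <- NA_real_
    } else {
      value_store <- values_raw
      value_store[values_raw == "."] <- NA_character_
    }
  }

  strands <- col("strand")
  if (!is.null(strands)) {
    bad <- !strands %in% c("+", "-", ".")
    for (j in which(bad))
      .add_issue(iss, "R14", "error", keep_lines[j],
                 sprintf("strand cell %s is not one of +, -, .",
                         sQuote(strands[j])))
    strands[strands == "."] <- NA_character_
  }

  ids <- col("id")
  if (!is.null(ids)) ids[ids == "."] <- NA_character_

  edges <- col("edges")
  if (!is.null(edges)) {
    for (j in seq_along(edges)) {
      parsed <- tryCatch(parse_edges(edges[j], headers), error = function(e) e)
      if (inherits(parsed, "error"))
        .add_issue(iss, "R10", "error", keep_lines[j],
                   conditionMessage(parsed))
    }
    edges[edges == "."] <- NA_character_
  }

  elements <- data.frame(region = region_idx, stringsAsFactors = FALSE)
  if (n == 0L) elements <- data.frame(region = integer(),
                                      stringsAsFactors = FALSE)
  elements$genome <- genomes
  elements$seqid <- seqids
  elements$start <- if (n) starts else numeric()
  elements$end <- if (n) ends else numeric()
  if (!is.null(value_store)) elements$value <- value_store
  if (!is.null(strands)) elements$strand <- strands
  if (!is.null(ids)) elements$id <- ids
  if (!is.null(edges)) elements$edges <- edges
  for (xc in setdiff(columns, reserved_columns()))
    elements[[xc]] <- if (n) cell_mat[, xc] else character()

  doc <- gtrack_document(type, columns = columns, elements = elements,
                         regions = regions,
                         headers = headers[explicit],
                         comments = comments)
  doc$colspec_explicit <- colspec_explicit
  doc$layout <- layout
  list(doc = doc, issues = .issues_frame(iss))
}

# insert materialised core columns at canonical spots
.insert_core_columns <- function(columns, add_start = FALSE, add_end = FALSE) {
  if (add_start && !"start" %in% columns) {
    at <- match("seqid", columns)
    at <- if (is.na(at)) 0L else at
    columns <- append(columns, "start", after = at)
  }
  if (add_end && !"end" %in% columns) {
    at <- match("start", columns)
    if (is.na(at)) at <- match("seqid", columns)
    if (is.na(at)) at <- 0L
    columns <- append(columns, "end", after = at)
  }
  columns
}
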