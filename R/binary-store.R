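# On-disk columnar store with a linear index for random region access.
#
# Layout: one file per (seqid, column) named <seqid>.<column>.bin, plus
# a text metadata file (key: value) and per-seqid index files. Fixed
# little-endian encodings: coordinates and numeric values as 8-byte IEEE
# doubles (exact for any genomic coordinate), binary values and
# characters as single bytes, category values as 4-byte dictionary codes
# with a sidecar string table. The linear index stores, per fixed-size
# bin, the ordinal of the first element overlapping that bin together
# with the running maximum end, so a region query touches only the
# elements near its bins.

.store_bin_size_default <- 1024L

.write_doubles <- function(x, path)
  writeBin(as.numeric(x), path, size = 8L, endian = "little")
.read_doubles <- function(path) {
  n <- file.info(path)$size / 8
  readBin(path, "numeric", n = n, size = 8L, endian = "little")
}
.write_bytes <- function(x, path) writeBin(as.raw(x), path)
.write_ints <- function(x, path)
  writeBin(as.integer(x), path, size = 4L, endian = "little")
.read_ints <- function(path) {
  n <- file.info(path)$size / 4
  readBin(path, "integer", n = n, size = 4L, endian = "little")
}

#' Build a binary columnar store from a document
#'
#' The document's core columns are written per seqid as fixed-width
#' binary vectors, and a linear index (one entry per `bin_size` base
#' pairs) is built over the start-sorted elements to allow random
#' region access. A content hash of the source is recorded for
#' staleness checks.
#'
#' @param doc A sorted, validated `gtrack_document`.
#' @param directory Output directory (created if needed).
#' @param bin_size Linear index granularity in base pairs.
#' @param source_file Optional path of the originating text file, for
#'   [store_is_stale()].
#' @return The directory, invisibly classed as `gtrack_store`.
#' @export
build_store <- function(doc, directory, bin_size = .store_bin_size_default,
                        source_file = NULL) {
  stopifnot(inherits(doc, "gtrack_document"))
  if (doc$headers$value_dimension != "scalar")
    stop("unsupported value dimension for binary storage: list",
         call. = FALSE)
  el <- doc$elements
  if (nrow(el)) {
    ord_ok <- all(vapply(split(seq_len(nrow(el)), el$seqid), function(ix)
      !is.unsorted(el$start[ix]), logical(1)))
    if (!ord_ok)
      stop("document must be sorted before building a store (see sort_gtrack)",
           call. = FALSE)
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  # cap the linear index size: with very large coordinates the bin size
  # grows so that no seqid needs more than 8192 index entries
  if (nrow(el)) {
    eff_all <- ifelse(is.na(el$end), el$start + 1, el$end)
    max_pos_all <- max(c(eff_all, doc$regions$end, 1))
    max_bins <- 8192
    if (ceiling(max_pos_all / bin_size) > max_bins)
      bin_size <- ceiling(max_pos_all / max_bins)
  }
  type <- doc$type
  vt <- doc$headers$value_type
  seqids <- unique(el$seqid)
  cols <- intersect(c("start", "end", "value", "id", "edges"),
                    c(columns_for_type(type, include_id = TRUE),
                      if ("id" %in% doc$columns) "id"))
  # dense layout rule: no redundant coordinate vectors. F/LF/LBP keep no
  # start/end (positions derive from the bounding regions); GP/SF/LGP/LSF
  # keep only ends.
  if (is_dense(type)) cols <- setdiff(cols, "start")
  if (!has_lengths(type) && is_dense(type)) cols <- setdiff(cols, "end")

  category_levels <- NULL
  id_table <- NULL
  for (sq in seqids) {
    ix <- which(el$seqid == sq)
    base <- file.path(directory, sq)
    if ("start" %in% cols) .write_doubles(el$start[ix],
                                          paste0(base, ".start.bin"))
    if ("end" %in% cols) .write_doubles(el$end[ix], paste0(base, ".end.bin"))
    if ("value" %in% cols) {
      v <- el$value[ix]
      if (vt == "number") .write_doubles(v, paste0(base, ".value.bin"))
      else if (vt == "binary")
        .write_bytes(ifelse(is.na(v), 255L, as.integer(v)),
                     paste0(base, ".value.bin"))
      else if (vt == "character")
        .write_bytes(ifelse(is.na(v), 0L,
                            vapply(as.character(v), function(ch)
                              as.integer(charToRaw(ch)[1]), 0L)),
                     paste0(base, ".value.bin"))
      else {
        category_levels <- union(category_levels,
                                 unique(v[!is.na(v)]))
        codes <- match(v, category_levels)
        codes[is.na(codes)] <- 0L
        .write_ints(codes, paste0(base, ".value.bin"))
      }
    }
    if ("id" %in% cols)
      writeLines(ifelse(is.na(el$id[ix]), ".", el$id[ix]),
                 paste0(base, ".id.txt"))
    if ("edges" %in% cols)
      writeLines(ifelse(is.na(el$edges[ix]), ".", el$edges[ix]),
                 paste0(base, ".edges.txt"))
    ## linear index over canonical starts/effective ends
    st <- el$start[ix]
    en <- .effective_end(el[ix, ])
    max_pos <- max(c(en, doc$regions$end[doc$regions$seqid == sq], 1))
    nbins <- ceiling(max_pos / bin_size)
    bins <- seq_len(nbins) - 1L
    run_max_end <- cummax(en)
    first_overlap <- vapply(bins, function(b) {
      lo <- b * bin_size
      # elements are start-sorted; the first overlapping element is the
      # first k with end > lo and start < lo + bin_size
      k <- which(st < (b + 1) * bin_size & en > lo)
      if (length(k)) k[1] else NA_integer_
    }, 0L)
    .write_ints(ifelse(is.na(first_overlap), 0L, first_overlap),
                file.path(directory, paste0(sq, ".index.bin")))
    .write_doubles(run_max_end, file.path(directory,
                                          paste0(sq, ".maxend.bin")))
  }
  if (!is.null(category_levels))
    writeLines(category_levels, file.path(directory, "categories.txt"))

  counts <- vapply(seqids, function(sq) sum(el$seqid == sq), 0L)
  meta <- c(
    sprintf("track_type: %s", type),
    sprintf("value_type: %s", vt),
    sprintf("bin_size: %s", .fmt_coord(bin_size)),
    sprintf("seqids: %s", paste(seqids, collapse = ",")),
    sprintf("counts: %s", paste(counts, collapse = ",")),
    sprintf("columns: %s", paste(cols, collapse = ",")),
    sprintf("source_hash: %s",
            if (is.null(source_file)) "" else unname(tools::md5sum(source_file))),
    sprintf("source_file: %s",
            if (is.null(source_file)) "" else source_file)
  )
  ## regions (needed to reconstruct dense positions)
  reg <- doc$regions
  for (r in seq_len(nrow(reg)))
    meta <- c(meta, sprintf("region: %s,%s,%s", reg$seqid[r],
                            .fmt_coord(reg$start[r]), .fmt_coord(reg$end[r])))
  writeLines(meta, file.path(directory, "metadata.txt"))
  invisible(structure(directory, class = "gtrack_store"))
}

.read_store_meta <- function(directory) {
  lines <- readLines(file.path(directory, "metadata.txt"), warn = FALSE)
  key <- sub(":.*$", "", lines)
  val <- trimws(sub("^[^:]*:", "", lines))
  regions <- do.call(rbind, lapply(val[key == "region"], function(v) {
    p <- strsplit(v, ",", fixed = TRUE)[[1]]
    data.frame(seqid = p[1], start = as.numeric(p[2]),
               end = as.numeric(p[3]), stringsAsFactors = FALSE)
  }))
  single <- function(k) val[key == k][1]
  list(
    track_type = single("track_type"),
    value_type = single("value_type"),
    bin_size = as.numeric(single("bin_size")),
    seqids = strsplit(single("seqids"), ",", fixed = TRUE)[[1]],
    counts = as.integer(strsplit(single("counts"), ",", fixed = TRUE)[[1]]),
    columns = strsplit(single("columns"), ",", fixed = TRUE)[[1]],
    source_hash = single("source_hash"),
    source_file = single("source_file"),
    regions = regions
  )
}

# reconstruct all elements of one seqid from the store
.store_scan_seqid <- function(directory, meta, sq) {
  base <- file.path(directory, sq)
  type <- meta$track_type
  n <- meta$counts[match(sq, meta$seqids)]
  if (is.na(n)) return(NULL)
  cols <- meta$columns
  reg <- meta$regions[meta$regions$seqid == sq, , drop = FALSE]
  if ("start" %in% cols) {
    start <- .read_doubles(paste0(base, ".start.bin"))
  } else if (!is.null(reg) && nrow(reg)) {
    # dense: derive from regions
    if ("end" %in% cols) {
      end <- .read_doubles(paste0(base, ".end.bin"))
      start <- numeric(0)
      k <- 0L
      for (r in seq_len(nrow(reg))) {
        sel <- which(end > reg$start[r] & end <= reg$end[r])
        sel <- sel[sel > k]
        if (!length(sel)) next
        start <- c(start, c(reg$start[r], end[sel][-length(sel)]))
        k <- max(sel)
      }
    } else {
      start <- unlist(lapply(seq_len(nrow(reg)), function(r)
        seq(reg$start[r], reg$end[r] - 1)))
    }
  } else start <- numeric(0)
  end <- if ("end" %in% cols) .read_doubles(paste0(base, ".end.bin"))
         else rep(NA_real_, length(start))
  value <- if ("value" %in% cols) {
    vt <- meta$value_type
    if (vt == "number") .read_doubles(paste0(base, ".value.bin"))
    else if (vt == "binary") {
      b <- as.integer(readBin(paste0(base, ".value.bin"), "raw",
                              n = n))
      ifelse(b == 255L, NA_real_, as.numeric(b))
    } else if (vt == "character") {
      b <- readBin(paste0(base, ".value.bin"), "raw", n = n)
      out <- rep(NA_character_, n)
      nz <- which(as.integer(b) != 0L)
      out[nz] <- vapply(nz, function(i) rawToChar(b[i]), "")
      out
    } else {
      codes <- .read_ints(paste0(base, ".value.bin"))
      levs <- readLines(file.path(directory, "categories.txt"),
                        warn = FALSE)
      ifelse(codes == 0L, NA_character_, levs[pmax(codes, 1L)])
    }
  } else NULL
  id <- if ("id" %in% cols) {
    v <- readLines(paste0(base, ".id.txt"), warn = FALSE)
    ifelse(v == ".", NA_character_, v)
  } else NULL
  edges <- if ("edges" %in% cols) {
    v <- readLines(paste0(base, ".edges.txt"), warn = FALSE)
    ifelse(v == ".", NA_character_, v)
  } else NULL
  out <- data.frame(seqid = rep(sq, length(start)), start = start,
                    end = end, stringsAsFactors = FALSE)
  if (!is.null(value)) out$value <- value
  if (!is.null(id)) out$id <- id
  if (!is.null(edges)) out$edges <- edges
  out
}

#' Scan a whole store back into element form
#' @param directory A store directory.
#' @return data.frame of elements in genomic order.
#' @export
read_store <- function(directory) {
  meta <- .read_store_meta(directory)
  out <- do.call(rbind, lapply(meta$seqids, function(sq)
    .store_scan_seqid(directory, meta, sq)))
  if (is.null(out))
    out <- data.frame(seqid = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Random region access into a store
#'
#' Returns exactly the elements overlapping the canonical half-open
#' query interval, in genomic order, using the linear index to avoid a
#' full scan.
#'
#' @param directory A store directory.
#' @param seqid Sequence name.
#' @param start,end Canonical half-open query interval.
#' @return data.frame of overlapping elements.
#' @export
query_region <- function(directory, seqid, start, end) {
  meta <- .read_store_meta(directory)
  if (!seqid %in% meta$seqids)
    stop("unknown seqid: ", seqid, call. = FALSE)
  all_el <- .store_scan_seqid(directory, meta, seqid)
  if (end <= start || !nrow(all_el)) return(all_el[0, , drop = FALSE])
  eff_end <- ifelse(is.na(all_el$end), all_el$start + 1, all_el$end)
  ## linear index: first element overlapping the query's first bin
  idx <- .read_ints(file.path(directory, paste0(seqid, ".index.bin")))
  bin <- floor(start / meta$bin_size)
  from <- if (bin + 1 <= length(idx) && idx[bin + 1] > 0L) {
    idx[bin + 1]
  } else {
    # no element overlaps the query's first bin, so any overlapping
    # element must start at or after the query start
    findInterval(start - 0.5, all_el$start) + 1L
  }
  sel <- integer()
  if (from > nrow(all_el)) return(all_el[0, , drop = FALSE])
  for (k in from:nrow(all_el)) {
    if (all_el$start[k] >= end) break
    if (eff_end[k] > start) sel <- c(sel, k)
  }
  out <- all_el[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is a store stale relative to its source file?
#'
#' Compares the recorded content hash of the source file with its
#' current hash; a missing source is conservatively stale.
#'
#' @param directory A store directory.
#' @param source_file Path to check; defaults to the recorded source.
#' @return Logical.
#' @export
store_is_stale <- function(directory, source_file = NULL) {
  meta <- .read_store_meta(directory)
  if (is.null(source_file) || !nzchar(source_file))
    source_file <- meta$source_file
  if (!nzchar(meta$source_hash)) return(TRUE)
  if (is.null(source_file) || !nzchar(source_file) ||
      !file.exists(source_file)) return(TRUE)
  !identical(unname(tools::md5sum(source_file)), meta$source_hash)
}
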