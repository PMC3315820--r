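# Deterministic fixture generator for all fifteen track types, plus a
# corruptor that injects a single validation-rule violation. Fixtures
# are structural, not biological: uniform values in [0,1), nucleotide
# characters, labels cat0..cat9 for categories.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

.gen_values <- function(n, value_type, value_dimension) {
  one <- function(m) switch(value_type,
    number = round(stats::runif(m), 4),
    binary = sample(0:1, m, replace = TRUE),
    category = paste0("cat", sample(0:9, m, replace = TRUE)),
    character = sample(c("A", "C", "G", "T"), m, replace = TRUE))
  if (value_dimension == "scalar") {
    v <- one(n)
    if (value_type %in% c("number", "binary")) as.numeric(v)
    else as.character(v)
  } else {
    vapply(seq_len(n), function(i)
      paste(one(sample(2:3, 1)), collapse = ","), "")
  }
}

.gen_edges <- function(ids, density, weighted, undirected) {
  n <- length(ids)
  cells <- rep(NA_character_, n)
  if (n < 2L || density <= 0) return(cells)
  fmt <- function(targets, weights) {
    paste(if (weighted) paste0(targets, "=", weights) else targets,
          collapse = ",")
  }
  if (undirected) {
    adj <- vector("list", n)
    wts <- vector("list", n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (stats::runif(1) < density / (n - 1) * 2) {
        w <- round(stats::runif(1), 3)
        adj[[i]] <- c(adj[[i]], ids[j]); wts[[i]] <- c(wts[[i]], w)
        adj[[j]] <- c(adj[[j]], ids[i]); wts[[j]] <- c(wts[[j]], w)
      }
    }
    for (i in seq_len(n))
      if (length(adj[[i]])) cells[i] <- fmt(adj[[i]], wts[[i]])
  } else {
    for (i in seq_len(n)) {
      if (stats::runif(1) < density) {
        k <- sample(setdiff(seq_len(n), i), min(sample(1:2, 1), n - 1L))
        cells[i] <- fmt(ids[k], round(stats::runif(length(k)), 3))
      }
    }
  }
  cells
}

#' Generate a valid GTrack document of a given type
#'
#' Deterministic given the seed; the generated document validates with
#' zero errors and its inferred type equals the requested one. Sparse
#' elements are non-overlapping and sorted; dense elements tile one
#' bounding region per sequence (two for multi-region types when the
#' sequence is long enough).
#'
#' @param type Track type id.
#' @param genome Named numeric vector of sequence lengths in bp.
#' @param n_elements Total sparse element count (dense counts derive
#'   from the tiling).
#' @param value_type,value_dimension Value configuration.
#' @param edge_density Fraction of elements carrying edges (linked
#'   types).
#' @param edge_weights Attach weights to edges.
#' @param undirected Make the edge set symmetric with equal weights.
#' @param seed Integer seed driving all randomness.
#' @return A `gtrack_document`.
#' @export
generate_gtrack <- function(type, genome = c(chr1 = 1000, chr2 = 800),
                            n_elements = 20, value_type = "number",
                            value_dimension = "scalar", edge_density = 0.4,
                            edge_weights = FALSE, undirected = FALSE,
                            seed = 42) {
  type <- .check_type(type)
  stopifnot(all(genome > 0))
  .with_seed(seed, {
    linked <- is_linked(type)
    valued <- has_values(type)
    headers <- list(sorted_elements = TRUE, no_overlapping_elements = TRUE)
    if (valued && value_type != "number") headers$value_type <- value_type
    if (valued && value_dimension != "scalar")
      headers$value_dimension <- value_dimension
    if (linked && edge_weights) headers$edge_weights <- TRUE
    if (linked && undirected) headers$undirected_edges <- TRUE

    if (is_sparse(type)) {
      rows <- NULL
      for (sq in names(genome)) {
        L <- genome[[sq]]
        ni <- max(1L, round(n_elements * L / sum(genome)))
        if (has_lengths(type)) {
          # even breakpoints: every segment is at least 2 bp long
          half <- L %/% 2L
          bp <- 2L * (sort(sample.int(half + 1L, min(2L * ni, half + 1L))) - 1L)
          ni <- length(bp) %/% 2L
          st <- bp[2 * seq_len(ni) - 1L]
          en <- bp[2 * seq_len(ni)]
        } else {
          st <- sort(sample.int(L, min(ni, L))) - 1L
          en <- rep(NA_real_, length(st))
          ni <- length(st)
        }
        rows <- rbind(rows, data.frame(seqid = sq, start = as.numeric(st),
                                       end = as.numeric(en),
                                       stringsAsFactors = FALSE))
      }
      el <- rows
      columns <- c("seqid", "start", if (has_lengths(type)) "end")
      if (valued) {
        el$value <- .gen_values(nrow(el), value_type, value_dimension)
        columns <- c(columns, "value")
      }
      if (has_lengths(type)) {
        el$strand <- sample(c("+", "-"), nrow(el), replace = TRUE)
        columns <- c(columns, "strand")
      }
      if (linked) {
        el$id <- paste0("e", seq_len(nrow(el)))
        el$edges <- .gen_edges(el$id, edge_density, edge_weights, undirected)
        columns <- c(columns, "id", "edges")
      }
      return(gtrack_document(type, columns = columns, elements = el,
                             headers = headers))
    }

    ## dense: tile one bounding region per sequence
    regions <- NULL; el <- NULL
    for (sq in names(genome)) {
      L <- genome[[sq]]
      regions <- rbind(regions,
                       data.frame(seqid = sq, start = 0, end = as.numeric(L),
                                  stringsAsFactors = FALSE))
      r <- nrow(regions)
      if (has_lengths(type)) {
        nparts <- max(2L, round(n_elements / length(genome)))
        cuts <- sort(sample.int(L - 1L, min(nparts - 1L, L - 1L)))
        ends <- as.numeric(c(cuts, L))
        starts <- c(0, ends[-length(ends)])
      } else {
        starts <- as.numeric(seq_len(L) - 1L)
        ends <- rep(NA_real_, L)
      }
      el <- rbind(el, data.frame(region = r, seqid = sq, start = starts,
                                 end = ends, stringsAsFactors = FALSE))
    }
    columns <- c(if (has_lengths(type)) "end", if (valued) "value")
    if (valued)
      el$value <- .gen_values(nrow(el), value_type, value_dimension)
    if (linked) {
      el$id <- paste0("e", seq_len(nrow(el)))
      density <- if (has_lengths(type)) edge_density
                 else min(edge_density, 40 / nrow(el))
      el$edges <- .gen_edges(el$id, density, edge_weights, undirected)
      columns <- c(columns, "id", "edges")
    }
    gtrack_document(type, columns = columns, elements = el,
                    regions = regions, headers = headers)
  })
}

#' Generate one fixture per track type
#'
#' @inheritParams generate_gtrack
#' @return Named list of 15 documents covering the type lattice.
#' @export
generate_all_types <- function(genome = c(chr1 = 1000, chr2 = 800),
                               seed = 42) {
  docs <- lapply(seq_along(track_type_ids()), function(k) {
    ty <- track_type_ids()[k]
    generate_gtrack(ty, genome = genome, seed = seed + k,
                    edge_weights = is_linked(ty),
                    undirected = FALSE)
  })
  stats::setNames(docs, track_type_ids())
}

# ---- corruptor ----

.corrupt_cell <- function(lines, columns, line_ix, column, value) {
  cells <- strsplit(lines[line_ix], "\t", fixed = TRUE)[[1]]
  cells[match(column, columns)] <- value
  lines[line_ix] <- paste(cells, collapse = "\t")
  lines
}

.data_line_ix <- function(lines) which(!startsWith(lines, "#"))[-1L]

#' Corrupt a document to violate one validation rule
#'
#' Writes the document and injects a single, targeted violation of the
#' requested rule; other violations are avoided where the file
#' structure permits.
#'
#' @param doc A valid `gtrack_document`.
#' @param rule_code One of `"R1"` ... `"R15"`.
#' @return Raw GTrack text (character lines) violating the rule.
#' @export
corrupt_gtrack <- function(doc, rule_code) {
  lines <- write_gtrack(doc)
  colspec_ix <- which(startsWith(lines, "###") & !startsWith(lines, "####"))[1]
  columns <- strsplit(sub("^###", "", lines[colspec_ix]), "\t",
                      fixed = TRUE)[[1]]
  dat <- which(!startsWith(lines, "#"))
  if (length(dat) < 1L) stop("document has no data lines", call. = FALSE)
  need <- function(ok, what) if (!ok)
    stop("rule ", rule_code, " is not applicable: needs ", what,
         call. = FALSE)
  type <- doc$type

  switch(rule_code,
    R1 = {
      other <- track_type_name(setdiff(track_type_ids(), type)[1])
      ti <- grep("^##track type:", lines)
      lines[ti] <- paste0("##track type: ", other)
      lines
    },
    R2 = {
      need("id" %in% columns && "edges" %in% columns, "a linked type")
      lines[colspec_ix] <- sub("(^|\t)id(\t|$)", "\\1ident\\2",
                               lines[colspec_ix])
      lines
    },
    R3 = {
      cells <- strsplit(lines[dat[1]], "\t", fixed = TRUE)[[1]]
      lines[dat[1]] <- paste(cells[-length(cells)], collapse = "\t")
      lines
    },
    R4 = {
      need("id" %in% columns && length(dat) >= 2L, "ids and >= 2 elements")
      first_id <- strsplit(lines[dat[1]], "\t",
                           fixed = TRUE)[[1]][match("id", columns)]
      .corrupt_cell(lines, columns, dat[2], "id", first_id)
    },
    R5 = {
      need("edges" %in% columns, "an edges column")
      has_edge <- vapply(dat, function(i)
        strsplit(lines[i], "\t", fixed = TRUE)[[1]][match("edges", columns)] != ".",
        logical(1))
      need(any(has_edge), "at least one edge")
      i <- dat[which(has_edge)[1]]
      cell <- if (isTRUE(doc$headers$edge_weights)) "ghost=1" else "ghost"
      .corrupt_cell(lines, columns, i, "edges", cell)
    },
    R6 = {
      need(isTRUE(doc$headers$undirected_edges), "undirected edges")
      has_edge <- vapply(dat, function(i)
        strsplit(lines[i], "\t", fixed = TRUE)[[1]][match("edges", columns)] != ".",
        logical(1))
      need(any(has_edge), "at least one edge")
      i <- dat[which(has_edge)[1]]
      cell <- strsplit(lines[i], "\t",
                       fixed = TRUE)[[1]][match("edges", columns)]
      first <- strsplit(cell, ",", fixed = TRUE)[[1]][1]
      target <- sub("=.*$", "", first)
      # remove the reciprocal edge from the target element
      tix <- dat[vapply(dat, function(k)
        strsplit(lines[k], "\t", fixed = TRUE)[[1]][match("id", columns)] ==
          target, logical(1))][1]
      .corrupt_cell(lines, columns, tix, "edges", ".")
    },
    R7 = {
      need(is_sparse(type) && length(dat) >= 2L,
           "a sparse document with >= 2 elements")
      tmp <- lines[dat[1]]
      lines[dat[1]] <- lines[dat[2]]
      lines[dat[2]] <- tmp
      lines
    },
    R8 = {
      need(is_sparse(type) && has_lengths(type) && length(dat) >= 2L,
           "sparse segments with >= 2 elements")
      c1 <- strsplit(lines[dat[1]], "\t", fixed = TRUE)[[1]]
      c2 <- strsplit(lines[dat[2]], "\t", fixed = TRUE)[[1]]
      for (cn in c("seqid", "start", "end"))
        c2[match(cn, columns)] <- c1[match(cn, columns)]
      lines[dat[2]] <- paste(c2, collapse = "\t")
      lines
    },
    R9 = {
      need(is_dense(type), "a dense type")
      ri <- which(startsWith(lines, "####"))[1]
      lines[ri] <- sub("end=(\\d+)", "end=\\1000", lines[ri])
      lines
    },
    R10 = {
      need("value" %in% columns, "a value column")
      .corrupt_cell(lines, columns, dat[1], "value", "not@a&value")
    },
    R11 = {
      width <- max(nchar(lines[dat])) + 2L
      pad <- function(s) formatC(s, width = -width)
      lines[dat[-1]] <- pad(lines[dat[-1]])
      # first data line left unpadded: wrong byte length
      hdr <- c(sprintf("##fixed-size data lines: true"),
               sprintf("##data line size: %d", width))
      append(lines, hdr, after = 0L)
    },
    R12 = {
      need(is_sparse(type), "a sparse type")
      sq <- strsplit(lines[dat[1]], "\t",
                     fixed = TRUE)[[1]][match("seqid", columns)]
      append(lines, sprintf("####seqid=%s; start=0; end=1", sq),
             after = dat[1] - 1L)
    },
    R13 = {
      ri <- which(startsWith(lines, "####"))
      if (length(ri)) {
        append(lines, lines[ri[1]], after = ri[1])
      } else {
        c(lines, "####seqid=chrZ; start=0; end=100",
          "####seqid=chrZ; start=50; end=150")
      }
    },
    R14 = {
      need("strand" %in% columns, "a strand column")
      .corrupt_cell(lines, columns, dat[1], "strand", "x")
    },
    R15 = {
      need(is_sparse(type) && has_lengths(type), "sparse segments")
      c1 <- strsplit(lines[dat[1]], "\t", fixed = TRUE)[[1]]
      st <- as.numeric(c1[match("start", columns)])
      .corrupt_cell(lines, columns, dat[1], "end", .fmt_coord(st + 1))
    },
    stop("unknown rule code: ", rule_code, call. = FALSE)
  )
}
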