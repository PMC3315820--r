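brute_force_overlaps <- function(el, seqid, qs, qe) {
  eff <- ifelse(is.na(el$end), el$start + 1, el$end)
  el[el$seqid == seqid & el$start < qe & eff > qs, , drop = FALSE]
}

test_that("a store scan reconstructs the elements exactly", {
  for (ty in c("P", "VS", "SF", "F", "LVS")) {
    doc <- sort_gtrack(generate_gtrack(ty, seed = 41,
                                       edge_weights = (ty == "LVS")))
    dir <- withr::local_tempdir()
    build_store(doc, dir)
    got <- read_store(dir)
    el <- doc$elements
    expect_equal(nrow(got), nrow(el), label = ty)
    expect_equal(got$start, el$start, label = ty)
    if ("value" %in% doc$columns)
      expect_equal(got$value, el$value, label = ty)
    if ("edges" %in% doc$columns)
      expect_identical(got$edges, el$edges, label = ty)
  }
})

test_that("region queries equal a brute-force overlap scan", {
  types <- c("P", "VS", "SF", "F", "LVS")
  queries_per_type <- 200  # 1000 seeded queries in total
  set.seed(43)
  for (ty in types) {
    doc <- sort_gtrack(generate_gtrack(ty, seed = 42))
    dir <- withr::local_tempdir()
    build_store(doc, dir)
    el <- doc$elements
    for (i in seq_len(queries_per_type)) {
      sq <- sample(c("chr1", "chr2"), 1)
      qs <- sample(0:1200, 1)
      qe <- qs + sample(1:400, 1)
      got <- query_region(dir, sq, qs, qe)
      want <- brute_force_overlaps(el, sq, qs, qe)
      expect_equal(nrow(got), nrow(want),
                   label = sprintf("%s %s:%d-%d", ty, sq, qs, qe))
      expect_equal(got$start, want$start,
                   label = sprintf("%s %s:%d-%d", ty, sq, qs, qe))
    }
  }
})

test_that("binary value encodings round-trip all four value types", {
  for (vt in c("number", "binary", "category", "character")) {
    doc <- sort_gtrack(generate_gtrack("VS", seed = 44, value_type = vt))
    dir <- withr::local_tempdir()
    build_store(doc, dir)
    got <- read_store(dir)
    expect_equal(got$value, doc$elements$value, label = vt)
  }
})

test_that("coordinates are stored as little-endian 8-byte doubles", {
  doc <- sort_gtrack(parse_gtrack(c("###seqid\tstart\tend",
                                    "chr1\t0\t4503599627370496")))
  dir <- withr::local_tempdir()
  build_store(doc, dir)
  raw_end <- readBin(file.path(dir, "chr1.end.bin"), "numeric", n = 1,
                     size = 8, endian = "little")
  expect_identical(raw_end, 4503599627370496)  # 2^52, exact
  expect_equal(file.info(file.path(dir, "chr1.end.bin"))$size, 8)
})

test_that("list-valued documents are rejected by the store", {
  doc <- generate_gtrack("VS", seed = 45, value_dimension = "list")
  expect_error(build_store(doc, withr::local_tempdir()),
               "value dimension")
})

test_that("unsorted documents are rejected with a pointer to sort_gtrack", {
  doc <- generate_gtrack("VS", seed = 46)
  doc$elements <- doc$elements[rev(seq_len(nrow(doc$elements))), ]
  expect_error(build_store(doc, withr::local_tempdir()), "sort_gtrack")
})

test_that("staleness tracks the source file content hash", {
  doc <- sort_gtrack(generate_gtrack("VS", seed = 47))
  src <- withr::local_tempfile(fileext = ".gtrack")
  write_gtrack(doc, src)
  dir <- withr::local_tempdir()
  build_store(doc, dir, source_file = src)
  expect_false(store_is_stale(dir))
  writeLines(c(readLines(src), "# touched"), src)
  expect_true(store_is_stale(dir))
  # a store built without a recorded source is conservatively stale
  dir2 <- withr::local_tempdir()
  build_store(doc, dir2)
  expect_true(store_is_stale(dir2))
})
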