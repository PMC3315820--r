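test_that("every generated fixture validates with zero errors", {
  docs <- generate_all_types(seed = 200)
  for (ty in names(docs)) {
    iss <- validate_gtrack(write_gtrack(docs[[ty]]))
    expect_equal(sum(iss$severity == "error"), 0, label = ty)
  }
})

test_that("each corruption rule R1-R14 is detected, R15 as a warning", {
  pick <- list(R1 = "VS", R2 = "LVS", R3 = "VS", R4 = "LVS", R5 = "LVS",
               R6 = "LVS", R7 = "VS", R8 = "VS", R9 = "SF", R10 = "VS",
               R11 = "VS", R12 = "VS", R13 = "SF", R14 = "VS", R15 = "VS")
  for (rc in names(pick)) {
    doc <- generate_gtrack(pick[[rc]], seed = 7,
                           edge_weights = (rc == "R5"),
                           undirected = (rc == "R6"))
    base <- validate_gtrack(write_gtrack(doc))
    expect_equal(sum(base$severity == "error"), 0, label = paste(rc, "base"))
    iss <- validate_gtrack(corrupt_gtrack(doc, rc))
    expect_true(rc %in% iss$code, label = rc)
    sev <- unique(iss$severity[iss$code == rc])
    expect_identical(sev, if (rc == "R15") "warning" else "error",
                     label = rc)
  }
})

test_that("the validator is total: malformed input yields issues, not errors", {
  garbage <- list(
    character(),
    "just one stray line of text",
    c("###a\tb", "1\t2\t3\t4"),
    c("##track type: nonsense", "###seqid\tstart", "chr1\tzero"),
    c("####seqid=chr1", "###value", "x"),
    c("##1-indexed: maybe", "###seqid\tstart", "chr1\t1"))
  for (g in garbage)
    expect_s3_class(validate_gtrack(g), "data.frame")
})

test_that("issues are reported in line order with closed codes", {
  txt <- c("###seqid\tstart\tend\tvalue\tstrand",
           "chr1\t0\t10\t0.5\tx",       # R14 on line 2
           "chr1\t5\t3\t0.5\t+",        # R10 empty interval on line 3
           "chr1\t20\t30\tabc\t+")      # R10 on line 4
  iss <- validate_gtrack(txt)
  lined <- iss$line[!is.na(iss$line)]
  expect_true(all(diff(lined) >= 0))
  expect_true(all(grepl("^R([1-9]|1[0-5])$", iss$code)))
  expect_true(all(c("R14", "R10") %in% iss$code))
})

test_that("unresolved and non-reciprocal edges are flagged", {
  dangling <- validate_gtrack(c(
    "###seqid\tstart\tid\tedges",
    "chr1\t0\ta\tmissing"))
  expect_true("R5" %in% dangling$code)
  oneway <- validate_gtrack(c(
    "##undirected edges: true",
    "###seqid\tstart\tid\tedges",
    "chr1\t0\ta\tb", "chr1\t5\tb\t."))
  expect_true("R6" %in% oneway$code)
  # unequal weights on a reciprocal pair are still non-reciprocal
  unequal <- validate_gtrack(c(
    "##undirected edges: true", "##edge weights: true",
    "###seqid\tstart\tid\tedges",
    "chr1\t0\ta\tb=1", "chr1\t5\tb\ta=2"))
  expect_true("R6" %in% unequal$code)
})

test_that("declared guarantees are checked against the data", {
  unsorted <- validate_gtrack(c(
    "##sorted elements: true",
    "###seqid\tstart", "chr1\t9", "chr1\t2"))
  expect_true("R7" %in% unsorted$code)
  overlapping <- validate_gtrack(c(
    "##no overlapping elements: true",
    "###seqid\tstart\tend", "chr1\t0\t10", "chr1\t5\t15"))
  expect_true("R8" %in% overlapping$code)
})

test_that("bounding-region rules cover containment and region overlap", {
  outside <- validate_gtrack(c(
    "###seqid\tstart\tend",
    "####seqid=chr1; start=0; end=10",
    "chr1\t5\t20"))
  expect_true("R12" %in% outside$code)
  regions <- validate_gtrack(c(
    "###seqid\tstart\tend",
    "####seqid=chr1; start=0; end=100",
    "chr1\t5\t20",
    "####seqid=chr1; start=50; end=150",
    "chr1\t60\t70"))
  expect_true("R13" %in% regions$code)
})

test_that("assert_structure enforces expectations and passes silently", {
  doc <- generate_gtrack("VS", seed = 3)
  expect_invisible(assert_structure(doc, track_type = "VS"))
  expect_true(assert_structure(doc, headers = list(sorted_elements = TRUE)))
  expect_error(assert_structure(doc, track_type = "F"),
               "structure assertion failed")
  expect_error(assert_structure(doc, headers = list(one_indexed = TRUE)),
               "structure assertion failed")
})
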