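all_fixtures <- generate_all_types(seed = 100)

test_that("write/parse round-trips are the identity on all 15 types", {
  for (ty in names(all_fixtures)) {
    doc <- all_fixtures[[ty]]
    reparsed <- parse_gtrack(write_gtrack(doc))
    expect_true(gtrack_all_equal(doc, reparsed), label = ty)
  }
})

test_that("round trips hold in every coordinate dialect", {
  for (ty in names(all_fixtures)) {
    doc <- all_fixtures[[ty]]
    for (oi in c(FALSE, TRUE)) for (ei in c(FALSE, TRUE)) {
      txt <- write_gtrack(doc, one_indexed = oi, end_inclusive = ei)
      expect_true(gtrack_all_equal(doc, parse_gtrack(txt)),
                  label = sprintf("%s oi=%s ei=%s", ty, oi, ei))
    }
  }
})

test_that("the four dialect spellings of one segment parse identically", {
  mk <- function(extra, s, e) parse_gtrack(c(
    extra, "###seqid\tstart\tend",
    sprintf("chr1\t%d\t%d", s, e)))
  docs <- list(
    mk(character(), 10, 20),
    mk("##end inclusive: true", 10, 19),
    mk("##1-indexed: true", 11, 21),
    mk(c("##1-indexed: true", "##end inclusive: true"), 11, 20))
  for (d in docs[-1])
    expect_true(gtrack_all_equal(docs[[1]], d))
})

test_that("value and edges column aliasing is transparent", {
  aliased <- parse_gtrack(c(
    "##value column: score",
    "###seqid\tstart\tend\tscore",
    "chr1\t0\t10\t0.25"))
  plain <- parse_gtrack(c(
    "###seqid\tstart\tend\tvalue",
    "chr1\t0\t10\t0.25"))
  expect_identical(aliased$type, "VS")
  expect_true(gtrack_all_equal(aliased, plain))
  # an alias may not collide with a literal reserved column
  bad <- validate_gtrack(c(
    "##value column: score",
    "###seqid\tstart\tend\tscore\tvalue",
    "chr1\t0\t10\t0.25\t0.5"))
  expect_true("R1" %in% bad$code)
})

test_that("header names are case-insensitive and defaults are implied", {
  doc <- parse_gtrack(c(
    "##Track Type: Valued Segments",
    "##VALUE TYPE: category",
    "###seqid\tstart\tend\tvalue",
    "chr1\t0\t10\thigh"))
  expect_identical(doc$type, "VS")
  expect_identical(doc$headers$value_type, "category")
  expect_false(doc$headers$one_indexed)       # implied default
  expect_identical(doc$headers$gtrack_version, "1.0")
})

test_that("dense types derive positions from the end column tiling", {
  doc <- parse_gtrack(c(
    "##track type: step function",
    "###end\tvalue",
    "####seqid=chr1; start=0; end=30",
    "10\t0.1", "25\t0.2", "30\t0.3"))
  expect_identical(doc$type, "SF")
  expect_equal(doc$elements$start, c(0, 10, 25))
  expect_equal(doc$elements$end, c(10, 25, 30))
  # a tiling violation is a dense-coverage error
  bad <- validate_gtrack(c(
    "##track type: step function",
    "###end\tvalue",
    "####seqid=chr1; start=0; end=30",
    "10\t0.1", "29\t0.2"))
  expect_true("R9" %in% bad$code)
})

test_that("function tracks carry one value line per base pair", {
  doc <- parse_gtrack(c(
    "##track type: function",
    "###value",
    "####seqid=chr1; start=5; end=8",
    "0.1", "0.2", "0.3"))
  expect_identical(doc$type, "F")
  expect_equal(doc$elements$start, c(5, 6, 7))
})

test_that("fixed geometry headers imply the omitted coordinate columns", {
  # fixed length: segments of 5 bp, only starts written
  fl <- parse_gtrack(c(
    "##track type: segments",
    "##fixed length: 5",
    "###seqid\tstart",
    "chr1\t0", "chr1\t10"))
  expect_identical(fl$type, "S")
  expect_equal(fl$elements$end, c(5, 15))
  # fixed gap size 0: abutting segments, only ends written
  fg <- parse_gtrack(c(
    "##track type: segments",
    "##fixed gap size: 0",
    "###end",
    "####seqid=chr1; start=0; end=30",
    "10", "30"))
  expect_equal(fg$elements$start, c(0, 10))
  # fixed length 1 is the default and implies nothing for points
  p <- parse_gtrack(c("##fixed length: 1", "###seqid\tstart", "chr1\t7"))
  expect_identical(p$type, "P")
})

test_that("a canonicalised document re-serialises stably", {
  for (ty in c("VS", "LVS", "SF")) {
    doc <- all_fixtures[[ty]]
    txt1 <- write_gtrack(doc)
    txt2 <- write_gtrack(parse_gtrack(txt1))
    expect_identical(txt1, txt2, label = ty)
  }
})

test_that("edge lists parse targets, weights and list weights", {
  e <- parse_edges("a=0.5,b=1.5", list(edge_weights = TRUE))
  expect_equal(e$target, c("a", "b"))
  expect_equal(e$weight, c("0.5", "1.5"))
  e2 <- parse_edges("a=0.5|0.7,b=1|2",
                    list(edge_weights = TRUE,
                         edge_weight_dimension = "list"))
  expect_equal(e2$weight, c("0.5|0.7", "1|2"))
  e3 <- parse_edges("a,b,c", list(edge_weights = FALSE))
  expect_equal(e3$target, c("a", "b", "c"))
  expect_true(all(is.na(e3$weight)))
})

test_that("writing an undirected document completes reciprocal edges", {
  doc <- parse_gtrack(c(
    "##track type: linked points",
    "###seqid\tstart\tid\tedges",
    "chr1\t0\ta\tb", "chr1\t5\tb\t."))
  doc$headers$undirected_edges <- TRUE
  doc$explicit <- union(doc$explicit, "undirected_edges")
  txt <- write_gtrack(doc)
  out <- parse_gtrack(txt)
  expect_identical(out$elements$edges[2], "a")
  expect_equal(sum(validate_gtrack(txt)$severity == "error"), 0)
})

test_that("comments and missing-value periods survive a round trip", {
  txt <- c("# produced by hand", "###seqid\tstart\tend\tvalue",
           "chr1\t0\t10\t.", "chr1\t20\t30\t1.5")
  doc <- parse_gtrack(txt)
  expect_true(is.na(doc$elements$value[1]))
  expect_identical(doc$comments, "produced by hand")
  expect_true(gtrack_all_equal(doc, parse_gtrack(write_gtrack(doc))))
})

test_that("subtype models merge under free and strict adherence", {
  model <- c("##track type: valued segments", "##value type: category",
             "###seqid\tstart\tend\tvalue")
  mf <- tempfile(fileext = ".gtrack"); writeLines(model, mf)
  # free: a one-line reference completes the header
  doc <- parse_gtrack(c(paste0("##subtype url: ", mf), "chr1\t10\t20\thigh"))
  expect_identical(doc$type, "VS")
  expect_identical(doc$headers$value_type, "category")
  # free: the referencing file's own headers win
  doc2 <- parse_gtrack(c(paste0("##subtype url: ", mf),
                         "##value type: character",
                         "chr1\t10\t20\tA"))
  expect_identical(doc2$headers$value_type, "character")
  # strict: any deviation is an error
  mstrict <- tempfile(fileext = ".gtrack")
  writeLines(c(model, "##subtype adherence: strict"), mstrict)
  expect_error(parse_gtrack(c(paste0("##subtype url: ", mstrict),
                              "##value type: number",
                              "###seqid\tstart\tend\tvalue",
                              "chr1\t10\t20\t0.5")),
               "strict subtype adherence")
  # resolve_subtype with an explicit model document
  header_only <- parse_gtrack(c(paste0("##subtype url: ", mf)))
  resolved <- resolve_subtype(header_only, parse_gtrack(mf))
  expect_identical(resolved$headers$value_type, "category")
})

test_that("expand_headers fills verifiable guarantees from the data", {
  txt <- write_gtrack(all_fixtures$VS)
  txt <- txt[!startsWith(txt, "##sorted") & !startsWith(txt, "##no overlap")]
  h <- expand_headers(txt)
  expect_true(h$sorted_elements)
  expect_true(h$no_overlapping_elements)
  expect_true(h$uninterrupted_data_lines)
  expect_identical(h$value_type, "number")
  # unsorted data must not be declared sorted
  shuffled <- parse_gtrack(txt)
  shuffled$elements <- shuffled$elements[rev(seq_len(nrow(shuffled$elements))), ]
  h2 <- expand_headers(write_gtrack(shuffled))
  expect_false(h2$sorted_elements)
  # categorical cells are recognised when numbers do not fit
  h3 <- expand_headers(c("###seqid\tstart\tvalue", "chr1\t0\thigh"))
  expect_identical(h3$value_type, "category")
})
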