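test_that("shuffled sparse documents re-sort to the sorted original", {
  for (ty in c("P", "VS", "LVS")) {
    doc <- generate_gtrack(ty, seed = 31)
    set.seed(32)
    shuffled <- doc
    shuffled$elements <- shuffled$elements[sample(nrow(doc$elements)), ]
    rownames(shuffled$elements) <- NULL
    expect_true(gtrack_all_equal(sort_gtrack(shuffled), sort_gtrack(doc)),
                label = ty)
  }
})

test_that("sorting is idempotent and declares the sorted guarantee", {
  doc <- sort_gtrack(generate_gtrack("S", seed = 33))
  expect_true(doc$headers$sorted_elements)
  expect_true(gtrack_all_equal(doc, sort_gtrack(doc)))
  expect_equal(sum(validate_gtrack(write_gtrack(doc))$severity == "error"), 0)
})

test_that("sorting preserves dense block order under region permutation", {
  doc <- generate_gtrack("SF", seed = 34)
  # reverse the regions; elements must follow their regions
  rev_doc <- doc
  rev_doc$regions <- rev_doc$regions[2:1, ]
  rownames(rev_doc$regions) <- NULL
  rev_doc$elements$region <- 3L - rev_doc$elements$region
  sorted <- sort_gtrack(rev_doc)
  expect_true(gtrack_all_equal(sorted, sort_gtrack(doc)))
})

test_that("standardize maps every type to a valid LVS document", {
  for (ty in track_type_ids()) {
    std <- standardize_gtrack(generate_gtrack(ty, seed = 35))
    expect_identical(std$type, "LVS", label = ty)
    expect_true(all(c("value", "id", "edges") %in% std$columns), label = ty)
    iss <- validate_gtrack(write_gtrack(std))
    expect_equal(sum(iss$severity == "error"), 0, label = ty)
  }
})

test_that("standardize preserves coordinates, values and edges", {
  doc <- generate_gtrack("LVP", seed = 36, edge_weights = TRUE)
  std <- standardize_gtrack(doc)
  expect_equal(std$elements$start, doc$elements$start)
  expect_equal(std$elements$end, doc$elements$start + 1)  # points -> 1 bp
  expect_equal(std$elements$value, doc$elements$value)
  expect_identical(std$elements$edges, doc$elements$edges)
  expect_identical(std$elements$id, doc$elements$id)
})

test_that("standardize assigns positional default ids when absent", {
  doc <- parse_gtrack(c("###seqid\tstart\tend",
                        "chr1\t0\t10", "chr1\t20\t30", "chr1\t20\t30"))
  std <- standardize_gtrack(doc)
  expect_identical(std$elements$id[1], "chr1:0-10")
  # collisions are disambiguated
  expect_false(anyDuplicated(std$elements$id) > 0)
})

test_that("complement_columns appends source columns by id or position", {
  base <- parse_gtrack(c("###seqid\tstart\tend\tid",
                         "chr1\t0\t10\ta", "chr1\t20\t30\tb"))
  extra <- parse_gtrack(c("###seqid\tstart\tend\tid\tvalue",
                          "chr1\t20\t30\tb\t0.9", "chr1\t0\t10\ta\t0.4"))
  out <- complement_columns(base, extra, key = "id")
  expect_true("value" %in% out$columns)
  expect_equal(out$elements$value, c(0.4, 0.9))
  # positional matching, with a period where no source row matches
  base2 <- parse_gtrack(c("###seqid\tstart\tend",
                          "chr1\t0\t10", "chr1\t40\t50"))
  extra2 <- parse_gtrack(c("###seqid\tstart\tend\tvalue",
                           "chr1\t0\t10\t1.5"))
  out2 <- complement_columns(base2, extra2, key = "position")
  expect_equal(out2$elements$value, c(1.5, NA))
  # a gained value column upgrades the inferred type
  expect_identical(out2$type, "VS")
})

test_that("ambiguous complement keys are rejected", {
  base <- parse_gtrack(c("###seqid\tstart\tend", "chr1\t0\t10"))
  dup <- parse_gtrack(c("###seqid\tstart\tend\tvalue",
                        "chr1\t0\t10\t1", "chr1\t0\t10\t2"))
  expect_error(complement_columns(base, dup, key = "position"),
               "ambiguous key")
})
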