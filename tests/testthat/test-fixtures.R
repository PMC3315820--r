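test_that("generation is deterministic in the seed", {
  a <- generate_gtrack("LVS", seed = 51, edge_weights = TRUE)
  b <- generate_gtrack("LVS", seed = 51, edge_weights = TRUE)
  c <- generate_gtrack("LVS", seed = 52, edge_weights = TRUE)
  expect_true(gtrack_all_equal(a, b))
  expect_false(gtrack_all_equal(a, c))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(53)
  before <- runif(1)
  set.seed(53)
  invisible(generate_gtrack("VS", seed = 54))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("generate_all_types yields 15 distinct types, 7 of them dense", {
  docs <- generate_all_types(seed = 55)
  types <- vapply(docs, `[[`, "", "type")
  expect_setequal(types, track_type_ids())
  expect_length(unique(types), 15L)
  expect_equal(sum(vapply(types, is_dense, logical(1))), 7L)
  # every generated document declares its requested type
  for (ty in names(docs))
    expect_identical(docs[[ty]]$type, ty)
})

test_that("generated values follow the documented distributions", {
  num <- generate_gtrack("VS", seed = 56, value_type = "number")
  expect_true(all(num$elements$value >= 0 & num$elements$value < 1))
  bin <- generate_gtrack("VS", seed = 56, value_type = "binary")
  expect_true(all(bin$elements$value %in% c(0, 1)))
  cat_ <- generate_gtrack("VS", seed = 56, value_type = "category")
  expect_true(all(grepl("^cat[0-9]$", cat_$elements$value)))
  chr <- generate_gtrack("VS", seed = 56, value_type = "character")
  expect_true(all(chr$elements$value %in% c("A", "C", "G", "T")))
  lst <- generate_gtrack("VS", seed = 56, value_dimension = "list")
  expect_true(all(grepl(",", lst$elements$value)))
})

test_that("undirected generation produces reciprocal equal-weight edges", {
  doc <- generate_gtrack("LVS", seed = 57, undirected = TRUE,
                         edge_weights = TRUE, edge_density = 0.9)
  expect_true(any(!is.na(doc$elements$edges)))
  iss <- validate_gtrack(write_gtrack(doc))
  expect_equal(sum(iss$severity == "error"), 0)
})

test_that("the corruptor rejects rules that do not apply to a document", {
  p <- generate_gtrack("P", seed = 58)
  expect_error(corrupt_gtrack(p, "R14"), "not applicable")
  expect_error(corrupt_gtrack(p, "R2"), "not applicable")
  expect_error(corrupt_gtrack(p, "R42"), "unknown rule")
})
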