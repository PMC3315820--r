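test_that("the type lattice enumerates 15 valid types out of 16 combinations", {
  combos <- expand.grid(gaps = c(FALSE, TRUE), lengths = c(FALSE, TRUE),
                        values = c(FALSE, TRUE),
                        interconnections = c(FALSE, TRUE))
  expect_equal(nrow(combos), 16L)
  types <- apply(combos, 1, function(row)
    tryCatch(properties_to_type(core_properties(
      gaps = row[["gaps"]], lengths = row[["lengths"]],
      values = row[["values"]], interconnections = row[["interconnections"]])),
      error = function(e) NA_character_))
  expect_equal(sum(is.na(types)), 1L)  # the all-FALSE corner is empty
  expect_setequal(types[!is.na(types)], track_type_ids())
  expect_length(track_type_ids(), 15L)
})

test_that("the empty property combination is rejected with a clear error", {
  expect_error(properties_to_type(core_properties()), "empty type")
})

test_that("basic/linked and dense/sparse partitions have the printed sizes", {
  ids <- track_type_ids()
  expect_equal(sum(vapply(ids, is_basic, logical(1))), 7L)
  expect_equal(sum(vapply(ids, is_linked, logical(1))), 8L)
  expect_equal(sum(vapply(ids, is_dense, logical(1))), 7L)
  expect_equal(sum(vapply(ids, is_sparse, logical(1))), 8L)
})

test_that("properties_to_type and type_to_properties are inverse", {
  for (ty in track_type_ids()) {
    p <- type_to_properties(ty)
    expect_identical(properties_to_type(p), ty)
  }
})

test_that("type names round-trip through the display form", {
  for (ty in track_type_ids())
    expect_identical(track_type_from_name(track_type_name(ty)), ty)
})

test_that("core column presence determines the type, both directions", {
  for (ty in track_type_ids()) {
    cols <- columns_for_type(ty)
    expect_identical(type_from_columns(cols), ty)
  }
})

test_that("the reserved-column list has exactly eight entries", {
  expect_length(reserved_columns(), 8L)
  expect_setequal(reserved_columns(),
                  c("genome", "seqid", "start", "end", "value", "strand",
                    "id", "edges"))
})
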