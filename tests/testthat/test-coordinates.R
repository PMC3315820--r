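# Oracle: brute-force enumeration of base-pair sets. Canonical segments
# are 0-based half-open, so [a, b) covers the set {a, ..., b-1}; the
# discrete metric lives in the 1-based inclusive formal model.

test_that("the discrete metric matches the counting oracle", {
  for (a in 1:12) for (b in 1:12) {
    oracle <- length(min(a, b):max(a, b))  # bp count from a to b
    expect_equal(metric_distance(a, b), oracle)
  }
  expect_equal(metric_distance(1, 3), 3)
  expect_equal(metric_distance(5, 5), 1)
})

test_that("segment length counts the base pairs the segment covers", {
  for (a in 0:7) for (b in (a + 1):8)
    expect_equal(segment_length(a, b), length(a:(b - 1)))
  expect_error(segment_length(5, 5), "empty segment")
})

test_that("point membership matches set enumeration", {
  for (a in 0:5) for (b in (a + 1):6) {
    seg <- a:(b - 1)
    for (p in 0:6) {
      expect_equal(point_in_segment("chr1", p, "chr1", a, b), p %in% seg)
      expect_false(point_in_segment("chr1", p, "chr2", a, b))
    }
  }
})

test_that("segment overlap matches set intersection", {
  for (a in 0:4) for (b in (a + 1):5) for (c in 0:4) for (d in (c + 1):5) {
    oracle <- length(intersect(a:(b - 1), c:(d - 1))) > 0
    expect_equal(segments_overlap("chr1", a, b, "chr1", c, d), oracle)
    expect_false(segments_overlap("chr1", a, b, "chr2", c, d))
  }
})

test_that("all four dialects normalize to the same canonical interval", {
  # the same physical segment (bp 11..20, 1-based inclusive) written in
  # each convention
  cases <- list(
    list(s = 10, e = 20, oi = FALSE, ei = FALSE),  # 0-based half-open
    list(s = 10, e = 19, oi = FALSE, ei = TRUE),   # 0-based inclusive
    list(s = 11, e = 21, oi = TRUE,  ei = FALSE),  # 1-based half-open
    list(s = 11, e = 20, oi = TRUE,  ei = TRUE))   # 1-based inclusive
  for (cs in cases) {
    cc <- normalize_coordinates(cs$s, cs$e, one_indexed = cs$oi,
                                end_inclusive = cs$ei)
    expect_equal(cc$start, 10)
    expect_equal(cc$end, 20)
    back <- denormalize_coordinates(cc$start, cc$end, one_indexed = cs$oi,
                                    end_inclusive = cs$ei)
    expect_equal(back$start, cs$s)
    expect_equal(back$end, cs$e)
  }
})

test_that("normalize and denormalize are inverse for random intervals", {
  set.seed(61)
  for (i in 1:50) {
    s <- sample(0:1e6, 1); e <- s + sample(1:1e4, 1)
    for (oi in c(FALSE, TRUE)) for (ei in c(FALSE, TRUE)) {
      d <- denormalize_coordinates(s, e, oi, ei)
      n <- normalize_coordinates(d$start, d$end, oi, ei)
      expect_equal(c(n$start, n$end), c(s, e))
    }
  }
})
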