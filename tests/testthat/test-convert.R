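test_that("BED round trips exactly through GTrack", {
  bed <- c("chr1\t10\t50\tfeat1\t5\t+",
           "chr1\t60\t90\tfeat2\t7\t-",
           "chr2\t0\t25\tfeat3\t1\t+")
  doc <- bed_to_gtrack(read_bed(bed))
  expect_identical(doc$type, "VS")
  expect_identical(write_bed(gtrack_to_bed(doc)), bed)
  # the 3-column rung of the ladder
  bed3 <- c("chr1\t0\t10", "chr1\t20\t30")
  doc3 <- bed_to_gtrack(read_bed(bed3))
  expect_identical(doc3$type, "S")
  expect_identical(write_bed(gtrack_to_bed(doc3)), bed3)
})

test_that("BED names induce linked types on request", {
  bed <- c("chr1\t10\t50\tgeneA", "chr1\t60\t90\tgeneB")
  doc <- bed_to_gtrack(read_bed(bed), mode = "linked")
  expect_true(is_linked(doc$type))
  expect_equal(sum(validate_gtrack(write_gtrack(doc))$severity == "error"), 0)
})

test_that("bedGraph round trips exactly through GTrack", {
  bg <- c("chr1\t0\t10\t0.5", "chr1\t10\t30\t0.75", "chr2\t5\t8\t-2")
  doc <- bedgraph_to_gtrack(read_bedgraph(bg))
  expect_identical(doc$type, "VS")
  expect_identical(write_bedgraph(gtrack_to_bedgraph(doc)), bg)
})

test_that("WIG block declarations type the track as the format implies", {
  vp <- wig_to_gtrack(read_wig(c("variableStep chrom=chr1",
                                 "1 0.5", "11 0.7")))
  expect_identical(vp$type, "VP")
  vs <- wig_to_gtrack(read_wig(c("variableStep chrom=chr1 span=5",
                                 "1 0.5", "11 0.7")))
  expect_identical(vs$type, "VS")
  sf <- wig_to_gtrack(read_wig(c("fixedStep chrom=chr1 start=1 step=10 span=10",
                                 "0.5", "0.7")))
  expect_identical(sf$type, "SF")
  sparse <- wig_to_gtrack(read_wig(c("fixedStep chrom=chr1 start=1 step=10 span=5",
                                     "0.5", "0.7")))
  expect_identical(sparse$type, "VS")
})

test_that("WIG values and coordinates survive a round trip", {
  wig <- c("variableStep chrom=chr1 span=5", "1 0.5", "11 0.7",
           "variableStep chrom=chr2 span=5", "3 -1.25")
  doc <- wig_to_gtrack(read_wig(wig))
  back <- wig_to_gtrack(read_wig(write_wig(gtrack_to_wig(doc))))
  expect_true(gtrack_all_equal(doc, back))
  # dense step functions ride fixedStep
  sf <- wig_to_gtrack(read_wig(c("fixedStep chrom=chr1 start=1 step=3 span=3",
                                 "0.5", "0.7", "0.9")))
  back2 <- wig_to_gtrack(read_wig(write_wig(gtrack_to_wig(sf))))
  expect_true(gtrack_all_equal(sf, back2))
})

test_that("varying segment lengths are rejected for WIG with a pointer to bedGraph", {
  doc <- parse_gtrack(c("###seqid\tstart\tend\tvalue",
                        "chr1\t0\t10\t0.5", "chr1\t20\t25\t0.6"))
  expect_error(gtrack_to_wig(doc), "bedGraph")
})

test_that("GFF3 records keep exactly nine fields and all attribute keys", {
  gff <- c("chr1\thavana\tgene\t11\t50\t0.9\t+\t.\tID=g1;biotype=lncRNA",
           "chr1\thavana\tmRNA\t11\t40\t.\t+\t.\tID=t1;Parent=g1",
           "chr2\t.\texon\t5\t9\t.\t-\t0\tNote=first")
  doc <- gff_to_gtrack(read_gff3(gff))
  # union-of-keys: every attribute key becomes a column on all lines
  expect_true(all(c("ID", "biotype", "Note") %in% doc$columns))
  expect_equal(nrow(doc$elements), 3)
  # 1-based inclusive -> canonical
  expect_equal(doc$elements$start[1], 10)
  expect_equal(doc$elements$end[1], 50)
  out <- write_gff3(gtrack_to_gff(doc))
  expect_identical(out[1], "##gff-version 3")
  expect_true(all(lengths(strsplit(out[-1], "\t", fixed = TRUE)) == 9L))
})

test_that("GFF3 Parent linking produces a valid linked track", {
  gff <- c("chr1\t.\tgene\t1\t100\t.\t+\t.\tID=g1",
           "chr1\t.\tmRNA\t1\t80\t.\t+\t.\tID=t1;Parent=g1")
  doc <- gff_to_gtrack(read_gff3(gff), link_parents = TRUE)
  expect_true(is_linked(doc$type))
  expect_identical(doc$elements$edges[2], "g1")
  expect_equal(sum(validate_gtrack(write_gtrack(doc))$severity == "error"), 0)
  back <- gtrack_to_gff(doc)
  expect_match(back$attributes[2], "Parent=g1")
})

test_that("GFF3 export of dense types is rejected as impractical", {
  f <- generate_gtrack("F", genome = c(chr1 = 50), seed = 5)
  expect_error(gtrack_to_gff(f), "impractical")
})

test_that("a column specification line turns tab text into a typed track", {
  doc <- tabular_to_gtrack("chr1\t10\t20\t0.5",
                           c("seqid", "start", "end", "value"))
  expect_identical(doc$type, "VS")
  expect_equal(doc$elements$start, 10)
  doc1 <- tabular_to_gtrack("chr1\t10\t20\t0.5",
                            c("seqid", "start", "end", "value"),
                            one_indexed = TRUE, end_inclusive = TRUE)
  expect_equal(doc1$elements$start, 9)
  expect_equal(doc1$elements$end, 20)
})

test_that("the analytic size model reproduces the WIG/bedGraph gap", {
  L <- 3.1e9
  wig <- estimate_representation_size(L, "wig", bytes_per_value = 5)
  bg <- estimate_representation_size(L, "bedgraph", bytes_per_value = 5)
  # around 20 GB vs around 100 GB for a per-bp human-genome track
  expect_gt(wig, 15e9); expect_lt(wig, 25e9)
  expect_gt(bg, 80e9); expect_lt(bg, 120e9)
  expect_gt(bg / wig, 4)
})

test_that("conversions agree with rtracklayer on a BED fixture when available", {
  skip_if_not_installed("rtracklayer")
  bed <- c("chr1\t10\t50\tfeat1\t5\t+", "chr1\t60\t90\tfeat2\t7\t-")
  f <- tempfile(fileext = ".bed"); writeLines(bed, f)
  gr <- rtracklayer::import(f, format = "BED")
  doc <- bed_to_gtrack(read_bed(bed))
  expect_equal(doc$elements$start,
               as.numeric(GenomicRanges::start(gr)) - 1)
  expect_equal(doc$elements$end, as.numeric(GenomicRanges::end(gr)))
  expect_equal(doc$elements$value, as.numeric(gr$score))
})
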