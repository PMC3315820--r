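# gtrackr

Parse, validate, convert and store genomic annotation tracks in the
GTrack tabular format.

GTrack is a tab-separated text format that represents *fifteen* kinds of
genomic tracks — points, segments, functions, partitions, step
functions, and their valued and linked variants — in a single grammar.
The fifteen types arise from four core informational properties of
track elements: **gaps** (elements do not tile the genome), **lengths**
(elements span more than one base pair), **values** (a designated main
value per element) and **interconnections** (edges between elements).
Each property maps to one core column (`start`, `end`, `value`,
`edges`), so the column specification line of a file determines its
type.

The package provides:

* a **type algebra** (`properties_to_type()`, `type_from_columns()`,
  `track_type_ids()`) and a formal coordinate model with the discrete
  metric `d(a, b) = |a - b| + 1` (`metric_distance()`);
* a **parser and writer** (`parse_gtrack()`, `write_gtrack()`) covering
  headers, column specifications, bounding regions, 0/1-based and
  inclusive/exclusive coordinate dialects, value/edges column aliasing,
  fixed geometry headers, dense positioning and subtypes;
* a **validator** (`validate_gtrack()`) with a closed catalogue of rule
  codes R1–R15, plus `assert_structure()` for consumer-side checks;
* **format converters** for BED, bedGraph, WIG and GFF3
  (`bed_to_gtrack()`, `wig_to_gtrack()`, …), a generic tabular importer
  (`tabular_to_gtrack()`) and an analytic file-size estimator
  (`estimate_representation_size()`);
* **track tools**: `sort_gtrack()`, `standardize_gtrack()` (any type →
  linked valued segments) and `complement_columns()`;
* a **binary columnar store** with a linear index for random region
  access (`build_store()`, `query_region()`, `store_is_stale()`);
* a deterministic **fixture generator and corruptor** for all fifteen
  types (`generate_gtrack()`, `generate_all_types()`,
  `corrupt_gtrack()`);
* a **command-line interface** (`gtrack_cli()`, installed at
  `inst/cli/gtrack.R`).

## Quick tour

Parsing infers the track type from the columns and normalises all
coordinates to the canonical 0-based half-open convention:

```r
library(gtrackr)

txt <- c("##track type: valued segments",
         "###seqid\tstart\tend\tvalue\tstrand",
         "chr1\t10\t50\t0.85\t+",
         "chr1\t90\t130\t0.42\t-")
doc <- parse_gtrack(txt)
doc
#> GTrack document: type VS (valued segments), 2 element(s), 0 bounding region(s)
#> columns: seqid, start, end, value, strand
```

Validation is total — it returns a data frame of findings rather than
stopping at the first problem — and every finding carries one of the
closed rule codes R1–R15:

```r
validate_gtrack(c("##no overlapping elements: true",
                  "###seqid\tstart\tend",
                  "chr1\t0\t10", "chr1\t5\t15"))
#>   code severity line                                                    message
#> 1   R8    error   NA 'no overlapping elements' is declared but elements overlap
```

Any of the fifteen types can be re-expressed as linked valued segments
(LVS), the most general type, with missing cells written as periods:

```r
writeLines(write_gtrack(standardize_gtrack(doc)))
#> ##track type: linked valued segments
#> ###seqid	start	end	value	strand	id	edges
#> chr1	10	50	0.85	+	chr1:10-50	.
#> chr1	90	130	0.42	-	chr1:90-130	.
```

Conversions to and from the classic formats are exact on coordinates
and values:

```r
doc2 <- bed_to_gtrack(read_bed("chr1\t10\t50\tpeak1\t5\t+"))
doc2$type
#> [1] "VS"
wig <- wig_to_gtrack(read_wig(c("fixedStep chrom=chr1 start=1 step=10 span=10",
                                "0.5", "0.7")))
wig$type   # step=span means a dense step function
#> [1] "SF"
```

And a sorted document can be laid down as a binary columnar store for
random region access:

```r
doc <- sort_gtrack(generate_gtrack("VS", seed = 1))
dir <- tempfile()
build_store(doc, dir)
query_region(dir, "chr1", 100, 400)
```

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "gtrack.R", package = "gtrackr"))')" \
  validate my_track.gtrack
```

`validate` prints one `LINE<TAB>CODE<TAB>MESSAGE` line per finding and
exits non-zero when any finding is an error. Other subcommands:
`convert`, `expand-headers`, `sort`, `standardize`, `complement`,
`import-tabular`, `synth`.

## Documentation

The methods vignette (`vignettes/gtrack-model.Rmd`) describes the type
algebra, the coordinate model, the canonicalisation strategy, the
validation rule catalogue and the binary store layout.
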