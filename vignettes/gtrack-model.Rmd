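---
title: "The fifteen-type track model and the GTrack format"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fifteen-type track model and the GTrack format}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtrackr)
```

## The type algebra

A genomic track is a set of positioned data units (elements) over a
genome. Four boolean *core informational properties* classify every
track element:

* **gaps** — the elements do not tile the genome (the track is
  *sparse*); without gaps, elements cover their bounding regions
  exactly (*dense*);
* **lengths** — elements span more than one base pair (segments or
  partition parts rather than points);
* **values** — each element carries a designated main value;
* **interconnections** — elements are linked to each other by edges.

Of the $2^4 = 16$ presence/absence combinations, the all-absent corner
carries no information, leaving **15 valid track types**: points (P),
valued points (VP), segments (S), valued segments (VS), genome
partition (GP), step function (SF), function (F), and their eight
linked counterparts (LP, LVP, LS, LVS, LGP, LSF, LF) plus linked
base pairs (LBP). Seven types are *basic* (no interconnections) and
eight are *linked*; seven are dense and eight are sparse.

```{r lattice}
combos <- expand.grid(gaps = c(FALSE, TRUE), lengths = c(FALSE, TRUE),
                      values = c(FALSE, TRUE),
                      interconnections = c(FALSE, TRUE))
types <- apply(combos, 1, function(row)
  tryCatch(properties_to_type(core_properties(
    gaps = row[["gaps"]], lengths = row[["lengths"]],
    values = row[["values"]], interconnections = row[["interconnections"]])),
    error = function(e) NA_character_))
table(valid = !is.na(types))
sort(types[!is.na(types)])
```

Each property corresponds to exactly one *core column* — gaps to
`start`, lengths to `end`, values to `value`, interconnections to
`edges` — so the set of core columns in a file determines its type:

```{r columns}
type_from_columns(c("start", "end", "value"))   # VS
columns_for_type("SF")                          # dense: no start column
```

## The formal coordinate model

The formal model treats coordinates as natural numbers under the
discrete metric $d(a, b) = |a - b| + 1$, equal to the number of base
pairs covered by the closed interval between the two coordinates:

```{r metric}
metric_distance(1, 3)
```

In this 1-based, end-inclusive model a point is a segment of length 1,
which is why validation rule R15 warns about explicit length-1
segments. Internally the package canonicalises every document to the
GTrack default dialect, 0-based half-open coordinates:
`start' = start - one_indexed` and `end' = end - one_indexed +
end_inclusive`. All four dialect combinations of the `1-indexed` and
`end inclusive` headers therefore parse to identical canonical
documents:

```{r dialects}
a <- parse_gtrack(c("###seqid\tstart\tend", "chr1\t10\t20"))
b <- parse_gtrack(c("##1-indexed: true", "##end inclusive: true",
                    "###seqid\tstart\tend", "chr1\t11\t20"))
gtrack_all_equal(a, b)
```

## The file grammar

A GTrack file has four line kinds, distinguished by their prefix:
`####` bounding regions, `###` the column specification, `##name:
value` header variables (24 of them, case-insensitive, omitted when at
their default), and `#` comments. A period denotes a missing value.
Dense types derive element positions from the `end` column tiling each
bounding region; function-class types carry one value line per base
pair:

```{r dense}
sf <- parse_gtrack(c("##track type: step function",
                     "###end\tvalue",
                     "####seqid=chr1; start=0; end=30",
                     "10\t0.1", "25\t0.2", "30\t0.3"))
sf$elements[c("seqid", "start", "end", "value")]
```

Fixed geometry headers (`fixed length`, `fixed gap size`) let a file
omit a coordinate column entirely; parsing materialises the implied
column. The `value column` and `edges column` headers alias an
arbitrarily named column to its reserved role; canonicalisation renames
it back. Subtype models — GTrack files referenced through the
`subtype url` header — are merged beneath the referencing file's own
headers under `free` adherence, or enforced exactly under `strict`
adherence.

## Validation

`validate_gtrack()` is *total*: any input yields a data frame of
findings ordered by line, each carrying one of the closed rule codes
R1–R15 (R15, the length-1 segment rule, is a warning; the rest are
errors). The codes cover header/column consistency (R1, R2), data line
shape (R3, R11), identifiers and edges (R4, R5, R6), declared
guarantees (R7 sortedness, R8 overlap), dense coverage (R9), cell
conformance (R10), bounding regions (R12, R13) and strand values (R14).

```{r validate}
validate_gtrack(c("##sorted elements: true",
                  "###seqid\tstart", "chr1\t9", "chr1\t2"))
```

The deterministic fixture generator and its rule-targeted corruptor
make the catalogue testable end to end: every generated document
validates cleanly, and each corruption is detected under its intended
code:

```{r corrupt}
doc <- generate_gtrack("LVS", seed = 7)
unique(validate_gtrack(corrupt_gtrack(doc, "R4"))$code)
```

## Conversion to and from other formats

BED, bedGraph, WIG and GFF3 all map into the type lattice: bedGraph is
sparse valued segments; WIG typing follows the block declarations
(`variableStep` with `span=1` gives valued points, `span>1` valued
segments; `fixedStep` with `step=span` is a dense step function,
`step>span` sparse valued segments); GFF3's nine-field lines become
(linked) segments with every attribute key expanded into a column on
all lines. A generic tabular file converts by prepending a single
column specification line (`tabular_to_gtrack()`).

The per-base-pair cost of each format is captured analytically:
repeating the chromosome label and both coordinates on every line is
why a genome-wide per-bp track of roughly 20 GB as WIG becomes
roughly 100 GB as bedGraph:

```{r sizes}
estimate_representation_size(3.1e9, "wig", bytes_per_value = 5) / 1e9
estimate_representation_size(3.1e9, "bedgraph", bytes_per_value = 5) / 1e9
```

## The binary columnar store

`build_store()` lays a sorted document down as one fixed-width binary
file per (seqid, column): coordinates and numeric values as 8-byte
little-endian IEEE doubles (exact for any genomic coordinate), binary
and character values as single bytes, categories as 4-byte dictionary
codes. Dense types store no redundant coordinates — step functions
keep only ends, functions only values — and positions are
reconstructed from the recorded bounding regions. A linear index holds,
per fixed-size genomic bin, the ordinal of the first overlapping
element, so `query_region()` reads only the elements near the query
instead of scanning the file. `store_is_stale()` compares a recorded
content hash of the source text with its current state.

```{r store}
doc <- sort_gtrack(generate_gtrack("VS", seed = 1))
dir <- tempfile()
build_store(doc, dir)
nrow(query_region(dir, "chr1", 100, 400))
```

## Supporting tools

`sort_gtrack()` orders regions and sparse elements canonically (dense
block order is semantic and preserved); `standardize_gtrack()`
re-expresses any type as linked valued segments, assigning default
`seqid:start-end` identifiers where needed; `complement_columns()`
merges columns from a second document by element id or genomic
position. All of these are also exposed through the command-line
interface (`gtrack_cli()`).
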