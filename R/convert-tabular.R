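# Generic tabular import: converting another tabular format to GTrack is
# as simple as adding a column specification line (plus any dialect
# headers). Also provides the analytic representation-size estimator
# used to compare per-base-pair formats.

#' Convert a generic tabular file to a GTrack document
#'
#' Prepends a column specification line (and any dialect headers) to
#' tab-separated text and parses the result; the track type is inferred
#' from the supplied column names.
#'
#' @param x Path, string or lines of tab-separated data (no header
#'   line).
#' @param column_names Character vector naming each column; reserved
#'   names (seqid, start, end, value, ...) get their GTrack meaning.
#' @param one_indexed,end_inclusive Coordinate dialect of the input.
#' @return A `gtrack_document`.
#' @export
#' @examples
#' txt <- "chr1\t10\t20\t0.5"
#' doc <- tabular_to_gtrack(txt, c("seqid", "start", "end", "value"))
#' doc$type  # "VS"
tabular_to_gtrack <- function(x, column_names, one_indexed = FALSE,
                              end_inclusive = FALSE) {
  lines <- .read_lines(x)
  lines <- lines[!grepl("^\\s*$", lines)]
  headers <- c(
    if (one_indexed) "##1-indexed: true",
    if (end_inclusive) "##end inclusive: true")
  colspec <- paste0("###", paste(column_names, collapse = "\t"))
  parse_gtrack(c(headers, colspec, lines))
}

#' Estimate the file size of a per-base-pair valued track
#'
#' Analytic byte estimates for representing a track with one value per
#' base pair. WIG (fixedStep) spends one value plus a newline per base
#' pair; bedGraph additionally repeats the chromosome label and both
#' coordinates on every line, which is why a genome-wide per-bp track
#' that takes around 20 GB as WIG expands to around 100 GB as bedGraph.
#'
#' @param genome_length Genome length in base pairs.
#' @param format `"wig"` or `"bedgraph"`.
#' @param bytes_per_value Printed width of one value.
#' @param bytes_per_coordinate Printed width of one coordinate.
#' @param chrom_label_bytes Printed width of the chromosome label.
#' @return Estimated size in bytes.
#' @export
#' @examples
#' estimate_representation_size(3.1e9, "wig", bytes_per_value = 5)
estimate_representation_size <- function(genome_length,
                                         format = c("wig", "bedgraph"),
                                         bytes_per_value = 5,
                                         bytes_per_coordinate = 10,
                                         chrom_label_bytes = 6) {
  format <- match.arg(format)
  per_line <- switch(format,
    # value + newline
    wig = bytes_per_value + 1,
    # chrom \t start \t end \t value \n
    bedgraph = chrom_label_bytes + 2 * bytes_per_coordinate +
      bytes_per_value + 4)
  genome_length * per_line
}
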