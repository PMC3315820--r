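# Applicability of analyses to track types.
#
# A track type poses a limit to which analyses are appropriate: an analysis
# stated for one pair of track types also gives meaning for any pair whose
# types define a superset of the required core properties (asking whether
# points fall inside segments works just as well for valued points vs
# valued segments). Only the applicability predicate is modelled here; no
# statistic is computed.

#' Is an analysis applicable to the given operand track types?
#'
#' @param required A list with one `core_properties` element per operand:
#'   the properties the analysis needs each operand track to define.
#' @param operand_types Character vector of track type ids, one per
#'   operand.
#' @return `TRUE` iff every operand's type defines a superset of the
#'   properties required of it.
#' @export
#' @examples
#' req <- list(core_properties(gaps = TRUE),
#'             core_properties(gaps = TRUE, lengths = TRUE))
#' analysis_applicable(req, c("P", "S"))    # points inside segments
#' analysis_applicable(req, c("VP", "VS"))  # still meaningful with values
#' analysis_applicable(req, c("P", "F"))    # FALSE: F lacks gaps
analysis_applicable <- function(required, operand_types) {
  if (length(required) != length(operand_types))
    stop("one requirement record per operand track is needed", call. = FALSE)
  ok <- mapply(function(req, ty) {
    have <- type_to_properties(ty)
    all(have[names(req)[req]])
  }, required, operand_types)
  all(ok)
}

#' Registry of example pairwise analyses
#'
#' Example analyses for unordered pairs of the five basic track types
#' points, segments, function, valued points and valued segments, each
#' recorded as the pair of core-property requirements it places on its two
#' operand tracks. Five types give `choose(5, 2) + 5 = 15` unordered
#' pairs; not every pair has a named example.
#'
#' @return A data.frame with columns `analysis`, `type1`, `type2`, and
#'   list-columns `required1`, `required2` of `core_properties`.
#' @export
analysis_registry <- function() {
  cp <- core_properties
  reg <- list(
    list("Different frequencies?", "P", "P",
         cp(gaps = TRUE), cp(gaps = TRUE)),
    list("Located inside?", "P", "S",
         cp(gaps = TRUE), cp(gaps = TRUE, lengths = TRUE)),
    list("Higher values at locations?", "P", "F",
         cp(gaps = TRUE), cp(values = TRUE)),
    list("Located in highly valued segments?", "P", "VS",
         cp(gaps = TRUE), cp(gaps = TRUE, lengths = TRUE, values = TRUE)),
    list("Overlap?", "S", "S",
         cp(gaps = TRUE, lengths = TRUE), cp(gaps = TRUE, lengths = TRUE)),
    list("Higher values inside?", "S", "F",
         cp(gaps = TRUE, lengths = TRUE), cp(values = TRUE)),
    list("Correlated?", "F", "F",
         cp(values = TRUE), cp(values = TRUE)),
    list("Nearby values similar?", "VP", "VP",
         cp(gaps = TRUE, values = TRUE), cp(gaps = TRUE, values = TRUE)),
    list("Categories differentially located in targets?", "VP", "VS",
         cp(gaps = TRUE, values = TRUE),
         cp(gaps = TRUE, lengths = TRUE, values = TRUE))
  )
  data.frame(
    analysis = vapply(reg, `[[`, "", 1L),
    type1 = vapply(reg, `[[`, "", 2L),
    type2 = vapply(reg, `[[`, "", 3L),
    required1 = I(lapply(reg, `[[`, 4L)),
    required2 = I(lapply(reg, `[[`, 5L)),
    stringsAsFactors = FALSE
  )
}

#' Unordered pairs of track types
#'
#' Enumerates the unordered pairs (including self-pairs) of a set of track
#' types; with the five basic types considered in pairwise analysis this
#' yields 15 combinations.
#'
#' @param types Character vector of track type ids.
#' @return A two-column data.frame of unordered pairs.
#' @export
track_type_pairs <- function(types = c("P", "S", "F", "VP", "VS")) {
  types <- vapply(types, .check_type, "")
  n <- length(types)
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  data.frame(type1 = types[idx[, "row"]], type2 = types[idx[, "col"]],
             stringsAsFactors = FALSE)
}
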