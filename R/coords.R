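# Coordinate conventions: everything the user sees (VCF, GFF3) is 1-based
# inclusive; internal interval arithmetic is half-open 0-based. The two
# converters below are exact inverses.

#' Convert a 1-based inclusive interval to 0-based half-open
#'
#' @param start,end 1-based inclusive bounds (vectors).
#' @return `data.frame` with columns `start0` and `end0` such that the
#'   half-open interval `[start0, end0)` covers the same bases.
#' @export
to_zero_based <- function(start, end) {
  stopifnot(all(start >= 1L), all(end >= start))
  data.frame(start0 = start - 1L, end0 = end)
}

#' Convert a 0-based half-open interval to 1-based inclusive
#'
#' @param start0,end0 0-based half-open bounds (vectors), `end0 > start0`.
#' @return `data.frame` with columns `start` and `end`, 1-based inclusive.
#' @export
to_one_based <- function(start0, end0) {
  stopifnot(all(start0 >= 0L), all(end0 > start0))
  data.frame(start = start0 + 1L, end = end0)
}
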