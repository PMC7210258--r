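`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_ox <- function(fmt, ..., class = "oxbspipe_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_ox("`%s` must be a single number in [%s, %s]", name,
            format(lower), format(upper), class = "oxbspipe_validation_error")
  invisible(x)
}

# Distance from points to the nearest edge of a set of 0-based half-open
# intervals; 0 for points inside an interval.
#' @noRd
.dist_to_intervals <- function(p0, starts, ends) {
  if (length(starts) == 0L) return(rep(Inf, length(p0)))
  ir <- IRanges::IRanges(start = starts + 1L, end = ends)
  pq <- IRanges::IRanges(start = p0 + 1L, width = 1L)
  d <- IRanges::distance(pq, ir[IRanges::nearest(pq, ir)])
  d[is.na(d)] <- Inf
  as.numeric(d)
}

# which 0-based half-open interval (if any) contains each 0-based point;
# returns index into intervals or NA
#' @noRd
.interval_index_of <- function(p0, starts, ends) {
  if (length(starts) == 0L) return(rep(NA_integer_, length(p0)))
  ir <- IRanges::IRanges(start = starts + 1L, end = ends)
  pq <- IRanges::IRanges(start = p0 + 1L, width = 1L)
  hit <- IRanges::findOverlaps(pq, ir, select = "first")
  as.integer(hit)
}
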