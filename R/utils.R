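# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed errors so callers can distinguish format/lookup/config failures.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "autozyg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

format_error <- function(msg) abort(msg, "autozyg_format_error")
lookup_error <- function(msg) abort(msg, "autozyg_lookup_error")
config_error <- function(msg) abort(msg, "autozyg_config_error")

VALID_ALLELES <- c("A", "C", "G", "T")

# Marker-state codes used by the run finder.
STATE_ANCHOR <- 0L  # homozygous (or matching) call: may start/end a run
STATE_HET <- 1L     # tolerated up to max_het_in_run per run
STATE_MISSING <- 2L # tolerated up to max_missing_in_run per run
STATE_BREAK <- 3L   # hard break: no run may contain it

#' All maximal qualifying runs over a marker-state string
#'
#' A window `[i, j]` qualifies when markers `i` and `j` are anchors, the
#' window contains no hard break, at most `max_het` het states and at most
#' `max_missing` missing states. A qualifying window is maximal when it is
#' not strictly contained in another qualifying window. When `max_het >= 1`
#' or `max_missing >= 1`, distinct maximal windows can overlap; all of them
#' are returned, sorted by start.
#'
#' @param states integer vector of STATE_* codes
#' @param max_het,max_missing per-run tolerances
#' @return data.frame with columns start, end (indices into `states`),
#'   n_het, n_missing
#' @noRd
find_maximal_runs <- function(states, max_het, max_missing) {
  n <- length(states)
  anchors <- which(states == STATE_ANCHOR)
  empty <- data.frame(start = integer(), end = integer(),
                      n_het = integer(), n_missing = integer())
  if (length(anchors) == 0L) return(empty)

  # last anchor at or before each index, for snapping window ends
  last_anchor <- cummax(ifelse(states == STATE_ANCHOR, seq_len(n), 0L))

  res_start <- integer()
  res_end <- integer()
  j <- 0L; het <- 0L; miss <- 0L  # current window is [i, j]
  prev_i <- 1L
  prev_recorded_end <- 0L

  for (i in anchors) {
    if (j < i) {
      j <- i - 1L; het <- 0L; miss <- 0L
    } else if (i > prev_i) {
      dropped <- states[prev_i:(i - 1L)]
      het <- het - sum(dropped == STATE_HET)
      miss <- miss - sum(dropped == STATE_MISSING)
    }
    prev_i <- i
    while (j < n) {
      s <- states[j + 1L]
      if (s == STATE_BREAK) break
      if (s == STATE_HET && het + 1L > max_het) break
      if (s == STATE_MISSING && miss + 1L > max_missing) break
      j <- j + 1L
      if (s == STATE_HET) het <- het + 1L
      if (s == STATE_MISSING) miss <- miss + 1L
    }
    end_anchor <- last_anchor[j]
    if (end_anchor > prev_recorded_end) {
      res_start <- c(res_start, i)
      res_end <- c(res_end, end_anchor)
      prev_recorded_end <- end_anchor
    }
  }

  if (length(res_start) == 0L) return(empty)
  cum_het <- cumsum(states == STATE_HET)
  cum_miss <- cumsum(states == STATE_MISSING)
  count_in <- function(cum, a, b) cum[b] - ifelse(a > 1L, cum[a - 1L], 0L)
  data.frame(
    start = res_start,
    end = res_end,
    n_het = as.integer(count_in(cum_het, res_start, res_end)),
    n_missing = as.integer(count_in(cum_miss, res_start, res_end))
  )
}

#' Subtract closed marker-index intervals from a marker-index interval
#'
#' Intervals are closed integer ranges over marker indices. Returns the
#' maximal sub-intervals of `region` (a length-2 integer vector) covered by
#' no interval in `cuts` (a 2-column matrix of start/end rows).
#'
#' @return 2-column integer matrix (start, end), zero rows when nothing
#'   remains
#' @noRd
subtract_marker_intervals <- function(region, cuts) {
  lo <- region[1]; hi <- region[2]
  keep <- rep(TRUE, hi - lo + 1L)
  if (length(cuts) > 0L && nrow(cuts) > 0L) {
    for (k in seq_len(nrow(cuts))) {
      a <- max(cuts[k, 1], lo); b <- min(cuts[k, 2], hi)
      if (a <= b) keep[(a - lo + 1L):(b - lo + 1L)] <- FALSE
    }
  }
  runs_from_mask(keep, offset = lo - 1L)
}

# Maximal runs of TRUE in a logical mask, as a (start, end) index matrix.
runs_from_mask <- function(mask, offset = 0L) {
  if (!any(mask)) {
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep] + offset, end = ends[keep] + offset)
}
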