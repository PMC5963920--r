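# Per-individual runs of homozygosity (ROH).
#
# A run is a maximal stretch of markers beginning and ending on homozygous
# calls, containing at most max_het_in_run heterozygous and
# max_missing_in_run missing calls, with at least min_markers markers and
# spanning at least min_length_bp. "Maximal" means not strictly contained
# in another qualifying stretch; when the het/missing tolerances are
# nonzero, distinct maximal runs can overlap and all are reported. This
# hard-count maximal-run definition (rather than a sliding-window density)
# is exactly checkable against brute-force enumeration.

#' ROH calling parameters
#'
#' Defaults suit dense SNP arrays with call rates around 99%: a run must
#' contain at least 25 markers, span at least 1 Mb, and may tolerate 1
#' heterozygous and 2 missing calls (genotyping error / dropout).
#'
#' @param min_markers minimum markers per run (>= 1)
#' @param max_het_in_run maximum heterozygous calls tolerated per run
#' @param max_missing_in_run maximum missing calls tolerated per run
#' @param min_length_bp minimum physical span (closed interval,
#'   `end - start + 1`)
#' @return a `roh_params` list
#' @export
roh_params <- function(min_markers = 25L, max_het_in_run = 1L,
                       max_missing_in_run = 2L, min_length_bp = 1e6) {
  stopifnot(min_markers >= 1, max_het_in_run >= 0,
            max_missing_in_run >= 0, min_length_bp >= 0)
  structure(list(min_markers = as.integer(min_markers),
                 max_het_in_run = as.integer(max_het_in_run),
                 max_missing_in_run = as.integer(max_missing_in_run),
                 min_length_bp = as.numeric(min_length_bp)),
            class = "roh_params")
}

# State codes for one sample's calls: anchor = homozygous, het, missing.
call_states <- function(a1, a2) {
  states <- rep(STATE_HET, length(a1))
  states[is.na(a1)] <- STATE_MISSING
  hom <- !is.na(a1) & a1 == a2
  states[hom] <- STATE_ANCHOR
  states
}

#' Call runs of homozygosity for one sample
#'
#' @param dataset a `genotype_dataset`
#' @param sample_id sample to scan (must be present in the dataset)
#' @param params a [roh_params()] object
#' @return data.frame with one row per segment: `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `start_idx`, `end_idx` (row indices into
#'   `dataset$markers`), `n_markers`, `n_het`, `n_missing`. Segment
#'   boundaries are the bp positions of the first and last homozygous
#'   markers of the run. Sorted by chromosome appearance then start;
#'   segments may overlap when tolerances are nonzero.
#' @export
call_roh <- function(dataset, sample_id, params = roh_params()) {
  si <- sample_index(dataset, sample_id)
  a1 <- dataset$allele1[, si]
  a2 <- dataset$allele2[, si]
  states <- call_states(a1, a2)
  roh_from_states(states, dataset$markers, params, sample_id)
}

# Shared core: run the maximal-run finder chromosome by chromosome over a
# precomputed state vector aligned to dataset markers.
roh_from_states <- function(states, markers, params, sample_id) {
  out <- list()
  for (ch in unique(markers$chromosome)) {
    idx <- which(markers$chromosome == ch)
    runs <- find_maximal_runs(states[idx], params$max_het_in_run,
                              params$max_missing_in_run)
    if (nrow(runs) == 0L) next
    start_idx <- idx[runs$start]
    end_idx <- idx[runs$end]
    seg <- data.frame(
      sample_id = sample_id,
      chromosome = ch,
      start_bp = markers$position_bp[start_idx],
      end_bp = markers$position_bp[end_idx],
      start_idx = start_idx,
      end_idx = end_idx,
      n_markers = runs$end - runs$start + 1L,
      n_het = runs$n_het,
      n_missing = runs$n_missing,
      stringsAsFactors = FALSE
    )
    keep <- seg$n_markers >= params$min_markers &
      (seg$end_bp - seg$start_bp + 1) >= params$min_length_bp
    out[[ch]] <- seg[keep, , drop = FALSE]
  }
  if (length(out) == 0L) {
    return(data.frame(sample_id = character(), chromosome = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      start_idx = integer(), end_idx = integer(),
                      n_markers = integer(), n_het = integer(),
                      n_missing = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname call_roh
#' @param path output TSV path
#' @param segments a segment data.frame from `call_roh`
#' @export
write_roh <- function(segments, path) {
  cols <- c("sample_id", "chromosome", "start_bp", "end_bp",
            "n_markers", "n_het", "n_missing")
  utils::write.table(segments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Logical coverage mask over dataset markers from ROH segments.
coverage_mask <- function(segments, n) {
  mask <- rep(FALSE, n)
  for (k in seq_len(nrow(segments))) {
    mask[segments$start_idx[k]:segments$end_idx[k]] <- TRUE
  }
  mask
}
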