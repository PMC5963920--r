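# Candidate autozygous loci: regions where every affected sibling has a
# qualifying ROH and all affecteds are homozygous for the same allele,
# which are then cut back by homozygous sharing with unaffected members
# and finally filtered by minimum genetic length (the confidence
# criterion, default 5 cM).
#
# Biallelic array genotypes cannot distinguish identity-by-descent from
# identity-by-state directly; shared allele-identical homozygosity plus a
# genetic-length threshold is the standard surrogate.

#' Mapping configuration
#'
#' @param min_genetic_length_cM minimum genetic length of a confident
#'   candidate region (default 5 cM); regions of exactly this length are
#'   retained
#' @param roh_params ROH tolerances, see [roh_params()]
#' @param exclusion_mode how unaffected sharing removes candidate
#'   territory: `"subtract"` trims the shared portion and keeps the
#'   flanks (default), `"drop"` discards any candidate touched at all
#' @param unaffected_identity_required when TRUE (default) an unaffected
#'   member excludes only where homozygous for the *same* allele as the
#'   affecteds; a sibling homozygous for the other allele does not
#'   disprove linkage. FALSE applies the stricter reading where any
#'   homozygosity excludes.
#' @return a `mapping_config` list
#' @export
mapping_config <- function(min_genetic_length_cM = 5.0,
                           roh_params = autozyg::roh_params(),
                           exclusion_mode = c("subtract", "drop"),
                           unaffected_identity_required = TRUE) {
  stopifnot(min_genetic_length_cM > 0)
  exclusion_mode <- match.arg(exclusion_mode)
  structure(list(min_genetic_length_cM = min_genetic_length_cM,
                 roh_params = roh_params,
                 exclusion_mode = exclusion_mode,
                 unaffected_identity_required = unaffected_identity_required),
            class = "mapping_config")
}

empty_regions <- function() {
  data.frame(chromosome = character(), start_bp = numeric(),
             end_bp = numeric(), start_idx = integer(),
             end_idx = integer(), n_markers = integer(),
             concordance = numeric(), genetic_length_cM = numeric())
}

# Classify every marker by the affecteds' joint genotype:
#   identical: all affecteds homozygous, non-missing, for one shared allele
#   violation: two affecteds homozygous for different alleles (hard break)
#   tolerated: anything else (het or missing among affecteds)
# Returns list(state = character vector, shared_allele = char vector with
# the shared homozygous allele at "identical" markers, NA elsewhere).
affected_identity <- function(dataset, aff_ids) {
  a1 <- dataset$allele1[, aff_ids, drop = FALSE]
  a2 <- dataset$allele2[, aff_ids, drop = FALSE]
  hom <- !is.na(a1) & a1 == a2
  n <- nrow(a1)
  state <- rep("tolerated", n)
  shared <- rep(NA_character_, n)
  all_hom <- rowSums(hom) == ncol(hom)
  # allele agreement among homozygous affecteds
  hom_allele <- a1
  hom_allele[!hom] <- NA_character_
  n_distinct <- apply(hom_allele, 1L, function(x) length(unique(x[!is.na(x)])))
  state[n_distinct >= 2L] <- "violation"
  ident <- all_hom & n_distinct == 1L
  state[ident] <- "identical"
  if (any(ident)) {
    shared[ident] <- apply(hom_allele[ident, , drop = FALSE], 1L,
                           function(x) x[!is.na(x)][1])
  }
  list(state = state, shared_allele = shared)
}

# Trim a marker-index interval so it begins and ends on "identical"
# markers; returns NULL when none are present.
snap_to_identical <- function(lo, hi, state) {
  idx <- lo:hi
  ident <- idx[state[idx] == "identical"]
  if (length(ident) == 0L) return(NULL)
  c(min(ident), max(ident))
}

region_row <- function(lo, hi, markers, state) {
  idx <- lo:hi
  data.frame(
    chromosome = markers$chromosome[lo],
    start_bp = markers$position_bp[lo],
    end_bp = markers$position_bp[hi],
    start_idx = lo, end_idx = hi,
    n_markers = hi - lo + 1L,
    concordance = mean(state[idx] == "identical"),
    genetic_length_cM = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Delineate candidate autozygous regions shared by the affected siblings
#'
#' A candidate region is a maximal stretch of markers that (a) lies inside
#' a qualifying ROH of every affected individual and (b) contains no
#' marker at which two affecteds are homozygous for different alleles.
#' Regions are split at such identity violations and their boundaries snap
#' to markers at which all affecteds are homozygous for the same allele.
#' `concordance` is the fraction of in-region markers with that property
#' (less than 1 only through tolerated het/missing calls).
#'
#' @param dataset a `genotype_dataset`
#' @param pedigree a [pedigree()] with at least one affected, genotyped
#'   individual
#' @param params ROH tolerances, see [roh_params()]
#' @return candidate-region data.frame (`chromosome`, `start_bp`,
#'   `end_bp`, `start_idx`, `end_idx`, `n_markers`, `concordance`,
#'   `genetic_length_cM` = NA until [filter_by_genetic_length()])
#' @export
shared_autozygous_regions <- function(dataset, pedigree,
                                      params = roh_params()) {
  aff <- intersect(affected_ids(pedigree), dataset$samples)
  if (length(aff) == 0L) {
    config_error("no affected individuals with genotypes in the dataset")
  }
  n <- n_markers(dataset)
  mask <- rep(TRUE, n)
  for (s in aff) {
    segs <- call_roh(dataset, s, params)
    mask <- mask & coverage_mask(segs, n)
  }
  ident <- affected_identity(dataset, aff)
  eligible <- mask & ident$state != "violation"

  out <- list()
  markers <- dataset$markers
  for (ch in unique(markers$chromosome)) {
    idx <- which(markers$chromosome == ch)
    runs <- runs_from_mask(eligible[idx], offset = idx[1] - 1L)
    for (k in seq_len(nrow(runs))) {
      snapped <- snap_to_identical(runs[k, 1], runs[k, 2], ident$state)
      if (is.null(snapped)) next
      out[[length(out) + 1L]] <- region_row(snapped[1], snapped[2],
                                            markers, ident$state)
    }
  }
  if (length(out) == 0L) return(empty_regions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclude candidate territory shared homozygously with unaffected members
#'
#' For each unaffected individual, intervals where that individual is
#' homozygous for the affecteds' shared allele across a candidate region's
#' markers are found with the same maximal-run machinery (and the same
#' tolerances and minimum size) as ROH calling. In `subtract` mode those
#' intervals are removed by closed-interval subtraction on the marker
#' grid, with surviving pieces re-snapped to allele-identical markers; in
#' `drop` mode any candidate overlapping such an interval is discarded
#' entirely. With no unaffected members the regions are returned
#' unchanged.
#'
#' @param regions output of [shared_autozygous_regions()]
#' @param dataset a `genotype_dataset`
#' @param pedigree a [pedigree()]
#' @param config a [mapping_config()]
#' @return candidate-region data.frame, same columns as the input
#' @export
exclude_unaffected <- function(regions, dataset, pedigree,
                               config = mapping_config()) {
  unaff <- intersect(unaffected_ids(pedigree), dataset$samples)
  if (length(unaff) == 0L || nrow(regions) == 0L) return(regions)
  aff <- intersect(affected_ids(pedigree), dataset$samples)
  ident <- affected_identity(dataset, aff)
  params <- config$roh_params
  markers <- dataset$markers

  out <- list()
  for (r in seq_len(nrow(regions))) {
    lo <- regions$start_idx[r]; hi <- regions$end_idx[r]
    idx <- lo:hi
    cuts <- matrix(integer(), ncol = 2L)
    for (u in unaff) {
      si <- sample_index(dataset, u)
      a1 <- dataset$allele1[idx, si]; a2 <- dataset$allele2[idx, si]
      states <- rep(STATE_HET, length(idx))
      states[is.na(a1)] <- STATE_MISSING
      hom <- !is.na(a1) & a1 == a2
      shared <- ident$shared_allele[idx]
      if (config$unaffected_identity_required) {
        # homozygous for the shared allele anchors an exclusion run;
        # homozygosity for the other allele is evidence *against* sharing
        # and breaks the run; hom calls where no shared allele is defined
        # are merely tolerated
        states[hom & !is.na(shared) & a1 == shared] <- STATE_ANCHOR
        states[hom & !is.na(shared) & a1 != shared] <- STATE_BREAK
      } else {
        states[hom] <- STATE_ANCHOR
      }
      runs <- find_maximal_runs(states, params$max_het_in_run,
                                params$max_missing_in_run)
      if (nrow(runs) == 0L) next
      abs_start <- idx[runs$start]; abs_end <- idx[runs$end]
      span <- markers$position_bp[abs_end] - markers$position_bp[abs_start] + 1
      keep <- (runs$end - runs$start + 1L) >= params$min_markers &
        span >= params$min_length_bp
      if (any(keep)) {
        cuts <- rbind(cuts, cbind(abs_start[keep], abs_end[keep]))
      }
    }
    if (nrow(cuts) == 0L) {
      out[[length(out) + 1L]] <- regions[r, , drop = FALSE]
      next
    }
    if (config$exclusion_mode == "drop") next
    remaining <- subtract_marker_intervals(c(lo, hi), cuts)
    for (k in seq_len(nrow(remaining))) {
      snapped <- snap_to_identical(remaining[k, 1], remaining[k, 2],
                                   ident$state)
      if (is.null(snapped)) next
      out[[length(out) + 1L]] <- region_row(snapped[1], snapped[2],
                                            markers, ident$state)
    }
  }
  if (length(out) == 0L) return(empty_regions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter candidate regions by genetic length
#'
#' Computes each region's genetic length as the difference of the
#' interpolated cM positions of its end and start markers, retains
#' regions at least `min_genetic_length_cM` long (>= convention), and
#' sorts the survivors by chromosome then start position.
#'
#' @param regions candidate-region data.frame
#' @param map a [genetic_map()]
#' @param config a [mapping_config()]
#' @return candidate-region data.frame with `genetic_length_cM` filled in
#' @export
filter_by_genetic_length <- function(regions, map = genetic_map(),
                                     config = mapping_config()) {
  if (nrow(regions) == 0L) return(regions)
  len <- vapply(seq_len(nrow(regions)), function(r) {
    ch <- regions$chromosome[r]
    interpolate_genetic_position(map, ch, regions$end_bp[r]) -
      interpolate_genetic_position(map, ch, regions$start_bp[r])
  }, numeric(1))
  regions$genetic_length_cM <- len
  keep <- len >= config$min_genetic_length_cM
  res <- regions[keep, , drop = FALSE]
  res <- res[order(res$chromosome, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}
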