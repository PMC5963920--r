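# Candidate-region delineation, unaffected exclusion, genetic-length filter.

# Pedigree used throughout: two parents, two affected, one unaffected child.
map_ped <- function() {
  pedigree(id = c("F", "M", "A1", "A2", "U1"),
           father_id = c(NA, NA, "F", "F", "F"),
           mother_id = c(NA, NA, "M", "M", "M"),
           status = c("unaffected", "unaffected", "affected", "affected",
                      "unaffected"))
}

# Loose ROH parameters for small hand-built marker grids.
loose <- function(...) {
  roh_params(min_markers = 5, max_het_in_run = 0, max_missing_in_run = 0,
             min_length_bp = 0, ...)
}

test_that("identical homozygous affecteds yield one full-span region", {
  n <- 50
  calls <- cbind(F = rep("AG", n), M = rep("AG", n),
                 A1 = rep("AA", n), A2 = rep("AA", n), U1 = rep("AG", n))
  ds <- toy_dataset(calls)
  reg <- shared_autozygous_regions(ds, map_ped(), loose())
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start_idx, 1L)
  expect_equal(reg$end_idx, n)
  expect_equal(reg$concordance, 1.0)
})

test_that("opposite-allele homozygosity splits the region at the violation", {
  n <- 49
  a1 <- rep("AA", n); a2 <- rep("AA", n)
  a2[25] <- "GG"  # A1 hom AA, A2 hom GG at marker 25
  calls <- cbind(F = rep("AG", n), M = rep("AG", n), A1 = a1, A2 = a2,
                 U1 = rep("AG", n))
  ds <- toy_dataset(calls)
  reg <- shared_autozygous_regions(ds, map_ped(), loose())
  expect_equal(reg$start_idx, c(1L, 26L))
  expect_equal(reg$end_idx, c(24L, n))
})

test_that("a fully heterozygous affected leaves no candidates, and a
           pedigree without affecteds is a configuration error", {
  n <- 40
  calls <- cbind(F = rep("AG", n), M = rep("AG", n), A1 = rep("AA", n),
                 A2 = rep("AG", n), U1 = rep("AA", n))
  ds <- toy_dataset(calls)
  expect_equal(nrow(shared_autozygous_regions(ds, map_ped(), loose())), 0L)

  ped0 <- pedigree(c("F", "M"), status = "unaffected")
  expect_error(shared_autozygous_regions(ds, ped0, loose()),
               "no affected", class = "autozyg_config_error")
})

test_that("subtract mode trims the unaffected-shared middle of a candidate", {
  # markers every 0.5 Mb from 10 Mb to 20 Mb
  pos <- seq(10e6, 20e6, by = 5e5)
  n <- length(pos)
  u <- rep("CT", n)
  u[pos >= 12e6 & pos <= 15e6] <- "CC"  # hom for the shared allele
  calls <- cbind(F = rep("CT", n), M = rep("CT", n),
                 A1 = rep("CC", n), A2 = rep("CC", n), U1 = u)
  ds <- toy_dataset(calls, positions = pos)
  reg <- shared_autozygous_regions(ds, map_ped(), loose())
  expect_equal(nrow(reg), 1L)
  out <- exclude_unaffected(reg, ds, map_ped(),
                            mapping_config(roh_params = loose()))
  expect_equal(nrow(out), 2L)
  expect_equal(out$start_bp, c(10e6, 15.5e6))
  expect_equal(out$end_bp, c(11.5e6, 20e6))
  # drop mode discards the overlapped candidate entirely
  out_drop <- exclude_unaffected(reg, ds, map_ped(),
                                 mapping_config(roh_params = loose(),
                                                exclusion_mode = "drop"))
  expect_equal(nrow(out_drop), 0L)
})

test_that("an unaffected homozygous for the *other* allele does not exclude,
           unless identity is not required", {
  pos <- seq(10e6, 20e6, by = 5e5)
  n <- length(pos)
  u <- rep("CT", n)
  u[pos >= 12e6 & pos <= 15e6] <- "TT"  # hom, but opposite allele
  calls <- cbind(F = rep("CT", n), M = rep("CT", n),
                 A1 = rep("CC", n), A2 = rep("CC", n), U1 = u)
  ds <- toy_dataset(calls, positions = pos)
  reg <- shared_autozygous_regions(ds, map_ped(), loose())
  out <- exclude_unaffected(reg, ds, map_ped(),
                            mapping_config(roh_params = loose()))
  expect_equal(nrow(out), 1L)
  expect_equal(out$start_bp, 10e6)
  strict <- mapping_config(roh_params = loose(),
                           unaffected_identity_required = FALSE)
  out2 <- exclude_unaffected(reg, ds, map_ped(), strict)
  expect_equal(nrow(out2), 2L)
})

test_that("no unaffected members leaves regions unchanged; full overlap
           removes the candidate", {
  n <- 30
  calls <- cbind(F = rep("AG", n), M = rep("AG", n),
                 A1 = rep("AA", n), A2 = rep("AA", n), U1 = rep("AA", n))
  ds <- toy_dataset(calls)
  ped_all_aff <- pedigree(c("F", "M", "A1", "A2", "U1"),
                          status = c("unknown", "unknown", "affected",
                                     "affected", "unknown"))
  reg <- shared_autozygous_regions(ds, ped_all_aff, loose())
  expect_identical(exclude_unaffected(reg, ds, ped_all_aff,
                                      mapping_config(roh_params = loose())),
                   reg)
  # U1 homozygous-identical across the whole candidate -> removed
  reg2 <- shared_autozygous_regions(ds, map_ped(), loose())
  out <- exclude_unaffected(reg2, ds, map_ped(),
                            mapping_config(roh_params = loose()))
  expect_equal(nrow(out), 0L)
})

test_that("marker-interval subtraction matches the IRanges oracle", {
  set.seed(2024)
  for (rep in 1:1000) {
    lo <- sample.int(50, 1)
    hi <- lo + sample.int(200, 1)
    k <- sample(0:5, 1)
    cuts <- if (k > 0) {
      s <- sample(seq(lo - 20, hi + 20), k, replace = TRUE)
      cbind(s, s + sample(0:40, k, replace = TRUE))
    } else matrix(integer(), ncol = 2)
    got <- autozyg:::subtract_marker_intervals(c(lo, hi), cuts)
    want <- IRanges::setdiff(
      IRanges::IRanges(lo, hi),
      if (nrow(cuts)) IRanges::IRanges(cuts[, 1], cuts[, 2])
      else IRanges::IRanges())
    expect_equal(unname(got[, 1]), IRanges::start(want))
    expect_equal(unname(got[, 2]), IRanges::end(want))
  }
})

test_that("genetic-length filter keeps >= threshold and sorts output", {
  regions <- data.frame(
    chromosome = c("2", "1", "1"),
    start_bp = c(1e6, 30e6, 1e6),
    end_bp = c(29e6, 34.9e6, 6e6),
    start_idx = NA_integer_, end_idx = NA_integer_,
    n_markers = NA_integer_, concordance = NA_real_,
    genetic_length_cM = NA_real_)
  out <- filter_by_genetic_length(regions, genetic_map(), mapping_config())
  # 28 cM kept; 4.9 cM removed; 5.0 cM kept (>= convention)
  expect_equal(out$chromosome, c("1", "2"))
  expect_equal(out$genetic_length_cM, c(5.0, 28.0))
})

test_that("each mapping stage never increases covered bp (monotonicity)", {
  for (s in 1:5) {
    st <- simulate_study(small_sim_config(seed = 100 + s))
    rp <- roh_params()
    mc <- mapping_config()
    reg <- shared_autozygous_regions(st$dataset, st$pedigree, rp)
    exc <- exclude_unaffected(reg, st$dataset, st$pedigree, mc)
    fin <- filter_by_genetic_length(exc, st$map, mc)
    expect_lte(covered_bp(exc), covered_bp(reg))
    expect_lte(covered_bp(fin), covered_bp(exc))
    # every marker of a surviving region is covered by each affected's ROH
    for (a in affected_ids(st$pedigree)) {
      segs <- call_roh(st$dataset, a, rp)
      mask <- rep(FALSE, nrow(st$dataset$markers))
      for (k in seq_len(nrow(segs))) {
        mask[segs$start_idx[k]:segs$end_idx[k]] <- TRUE
      }
      for (r in seq_len(nrow(fin))) {
        expect_true(all(mask[fin$start_idx[r]:fin$end_idx[r]]))
      }
    }
  }
})
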