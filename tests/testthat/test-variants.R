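# Variant prioritization: region intersection, rarity filters, recessive
# segregation and ranking.

region_df <- function(chromosome, start_bp, end_bp) {
  data.frame(chromosome = chromosome, start_bp = start_bp, end_bp = end_bp)
}

table1 <- read_variant_table(
  system.file("extdata", "table1_variants.tsv", package = "autozyg"))

test_that("a 28-Mb chromosome-5 window over the table captures 4 variants", {
  filters_off <- prioritization_config(maf_max = 1,
                                       exclude_known_polymorphisms = FALSE)
  # window placed to contain the CAMK2A position and maximize content
  w <- 28e6
  chr5 <- table1$position_bp[table1$chromosome == "5"]
  anchor <- 149602589
  starts <- sort(unique(c(chr5, chr5 - w + 1)))
  starts <- starts[starts <= anchor & starts + w - 1 >= anchor]
  best <- 0L; best_region <- NULL
  for (s in starts) {
    hit <- intersect_and_filter(table1, region_df("5", s, s + w - 1),
                                filters_off)
    if (nrow(hit) > best) {
      best <- nrow(hit)
      best_region <- region_df("5", s, s + w - 1)
    }
  }
  expect_equal(best, 4L)
  hit <- intersect_and_filter(table1, best_region, filters_off)
  expect_setequal(hit$gene, c("CAMK2A", "C5orf4", "HAVCR1"))
  expect_equal(sum(hit$gene == "HAVCR1"), 2L)
})

test_that("region and rarity filters behave and compose monotonically", {
  v <- table1
  expect_equal(nrow(intersect_and_filter(v, region_df(character(), numeric(),
                                                      numeric()))), 0L)
  # whole-genome region + filters off is the identity
  whole <- do.call(rbind, lapply(unique(v$chromosome), function(ch) {
    region_df(ch, 1, 3e9)
  }))
  all_back <- intersect_and_filter(v, whole,
                                   prioritization_config(1, FALSE))
  expect_equal(all_back$position_bp, v$position_bp)

  # MAF filter: 0.02 >= 0.01 removed, absent MAF passes
  v2 <- v[1:3, ]
  v2$population_maf <- c(0.02, 0.005, NA)
  kept <- intersect_and_filter(v2, whole, prioritization_config(0.01, FALSE))
  expect_equal(kept$position_bp, v2$position_bp[2:3])

  # known-polymorphism exclusion is non-increasing
  v3 <- v
  v3$known_polymorphism <- rep(c(TRUE, FALSE), length.out = nrow(v3))
  with_excl <- intersect_and_filter(v3, whole, prioritization_config(1, TRUE))
  without <- intersect_and_filter(v3, whole, prioritization_config(1, FALSE))
  expect_lte(nrow(with_excl), nrow(without))
  expect_false(any(with_excl$known_polymorphism))
})

fam_ped <- pedigree(
  id = c("I-1", "I-2", "II-1", "II-2", "II-3", "II-4", "II-5"),
  father_id = c(NA, NA, rep("I-1", 5)),
  mother_id = c(NA, NA, rep("I-2", 5)),
  status = c("unaffected", "unaffected", "affected", "unaffected",
             "unaffected", "affected", "unaffected"))

seg_variant <- function(gts) {
  as.data.frame(c(list(chromosome = "5", position_bp = 1e6, gene = "G",
                       cdna_change = "c.10C>T"),
                  stats::setNames(as.list(gts), paste0("gt_", fam_ped$id))),
                check.names = FALSE)
}

test_that("recessive segregation: carrier parents, hom-alt affecteds,
           no hom-alt unaffecteds", {
  good <- seg_variant(c("CT", "CT", "TT", "CT", "CC", "TT", "CT"))
  expect_true(check_recessive_segregation(good, fam_ped))

  hom_unaff <- seg_variant(c("CT", "CT", "TT", "TT", "CC", "TT", "CT"))
  expect_false(check_recessive_segregation(hom_unaff, fam_ped))

  het_aff <- seg_variant(c("CT", "CT", "CT", "CT", "CC", "TT", "CT"))
  expect_false(check_recessive_segregation(het_aff, fam_ped))

  hom_parent <- seg_variant(c("TT", "CT", "TT", "CT", "CC", "TT", "CT"))
  expect_false(check_recessive_segregation(hom_parent, fam_ped))

  incomplete <- seg_variant(c("CT", "CT", "TT", "CT", NA, "TT", "CT"))
  expect_error(check_recessive_segregation(incomplete, fam_ped),
               class = "autozyg_incomplete_segregation")
})

test_that("simulated causal variants segregate; perturbations break it", {
  for (s in 1:5) {
    st <- simulate_study(small_sim_config(seed = 200 + s))
    cv <- st$causal_variant
    expect_true(check_recessive_segregation(cv, st$pedigree))
    # perturb one genotype to violate the recessive pattern
    set.seed(s)
    aff <- affected_ids(st$pedigree)
    unaff <- setdiff(st$pedigree$id, c(aff, "I-1", "I-2"))
    breakers <- list(
      function(v) { v[[paste0("gt_", sample(aff, 1))]] <- "CT"; v },
      function(v) { v[[paste0("gt_", sample(unaff, 1))]] <- "TT"; v },
      function(v) { v[[paste0("gt_", sample(c("I-1", "I-2"), 1))]] <- "CC"; v })
    for (b in breakers) {
      expect_false(check_recessive_segregation(b(cv), st$pedigree))
    }
  }
})

test_that("ranking puts segregating never-observed variants first with a
           deterministic tie-break", {
  v <- rbind(
    seg_variant(c("CT", "CT", "TT", "CT", "CC", "TT", "CT")),  # segregates
    seg_variant(c("CT", "CT", "TT", "TT", "CC", "TT", "CT")))  # does not
  v$gene <- c("RARE", "COMMON")
  v$position_bp <- c(2e6, 1e6)
  v$population_maf <- c(NA, 0.2)
  v$known_polymorphism <- c(FALSE, TRUE)
  ranked <- rank_variants(v, fam_ped)
  expect_equal(ranked$gene, c("RARE", "COMMON"))
  expect_equal(ranked$rank, 1:2)
  expect_equal(ranked$segregates, c(TRUE, FALSE))

  # same keys -> (chromosome, position) tie-break
  v2 <- v
  v2$population_maf <- c(0.1, 0.1)
  v2$known_polymorphism <- FALSE
  v2$gt_II2 <- NULL
  gt_cols <- grep("^gt_", names(v2), value = TRUE)
  v2[gt_cols] <- NULL  # no genotypes: segregation not evaluable
  ranked2 <- rank_variants(v2, fam_ped)
  expect_equal(ranked2$position_bp, c(1e6, 2e6))
  expect_true(all(is.na(ranked2$segregates)))
})
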