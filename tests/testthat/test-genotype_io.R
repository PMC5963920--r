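# PED/MAP and variant-table text dialects.

write_ped_map_fixture <- function(dir, ped_lines, map_lines) {
  ped <- file.path(dir, "f.ped")
  map <- file.path(dir, "f.map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  list(ped = ped, map = map)
}

test_that("a small PED/MAP pair parses into pedigree and dataset", {
  d <- withr::local_tempdir()
  map_lines <- c("1\tm1\t0\t1000000", "1\tm2\t0\t2000000", "1\tm3\t0\t3000000")
  ped_lines <- c(
    "FAM F 0 0 1 1  A A  C C  G G",
    "FAM M 0 0 2 1  A G  C C  G T",
    "FAM C1 F M 0 2 A A  C C  G G",
    "FAM C2 F M 0 2 A G  C C  0 0",
    "FAM C3 F M 0 1 A A  C C  G T",
    "FAM C4 F M 0 1 A A  C C  T T",
    "FAM C5 F M 0 1 A G  C C  G G"
  )
  f <- write_ped_map_fixture(d, ped_lines, map_lines)
  out <- read_genotypes(f$ped, f$map)
  expect_equal(nrow(out$pedigree), 7L)
  expect_equal(affected_ids(out$pedigree), c("C1", "C2"))
  expect_equal(out$pedigree$father_id[3], "F")
  expect_equal(nrow(out$dataset$markers), 3L)
  expect_equal(out$dataset$samples, c("F", "M", "C1", "C2", "C3", "C4", "C5"))
  # "0 0" call is missing
  expect_true(is.na(out$dataset$allele1[3, "C2"]))
  expect_true(is.na(out$dataset$allele2[3, "C2"]))
  # all other calls parsed
  expect_equal(sum(is.na(out$dataset$allele1)), 1L)
  expect_equal(unname(out$dataset$allele1[1, "M"]), "A")
  expect_equal(unname(out$dataset$allele2[1, "M"]), "G")
})

test_that("format errors name the offending PED line", {
  d <- withr::local_tempdir()
  map_lines <- c("1\tm1\t0\t100", "1\tm2\t0\t200", "1\tm3\t0\t300")
  # 5 allele columns against a 3-marker MAP
  f <- write_ped_map_fixture(d, c("FAM A 0 0 0 1 A A C C G"), map_lines)
  expect_error(read_genotypes(f$ped, f$map), "line 1",
               class = "autozyg_format_error")

  f <- write_ped_map_fixture(d, c("FAM A 0 0 0 1 A A C C G X"), map_lines)
  expect_error(read_genotypes(f$ped, f$map), "allele symbol",
               class = "autozyg_format_error")

  f <- write_ped_map_fixture(
    d, c("FAM A 0 0 0 1 A A C C G G", "FAM A 0 0 0 1 A A C C G G"),
    map_lines)
  expect_error(read_genotypes(f$ped, f$map), "duplicate",
               class = "autozyg_format_error")
})

test_that("markers are re-sorted per chromosome with calls permuted", {
  d <- withr::local_tempdir()
  map_lines <- c("1\tm2\t0\t200", "1\tm1\t0\t100", "2\tm3\t0\t50")
  f <- write_ped_map_fixture(d, c("FAM A 0 0 0 1 C C A A G G"), map_lines)
  out <- read_genotypes(f$ped, f$map)
  expect_equal(out$dataset$markers$id, c("m1", "m2", "m3"))
  expect_equal(unname(out$dataset$allele1[, 1]), c("A", "C", "G"))
})

test_that("PED/MAP round-trip preserves the dataset exactly", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    calls <- cbind(random_calls(n), random_calls(n), random_calls(n))
    colnames(calls) <- c("F", "M", "C1")
    ds <- toy_dataset(calls, positions = sort(sample.int(1e7, n)))
    ped <- pedigree(c("F", "M", "C1"), c(NA, NA, "F"), c(NA, NA, "M"),
                    c("male", "female", "unknown"),
                    c("unaffected", "unaffected", "affected"))
    d <- withr::local_tempdir()
    write_genotypes(ds, ped, file.path(d, "x.ped"), file.path(d, "x.map"))
    back <- read_genotypes(file.path(d, "x.ped"), file.path(d, "x.map"))
    expect_equal(back$dataset$markers$id, ds$markers$id)
    expect_equal(back$dataset$markers$position_bp, ds$markers$position_bp)
    expect_identical(back$dataset$allele1, ds$allele1)
    expect_identical(back$dataset$allele2, ds$allele2)
    expect_equal(back$pedigree$status, ped$status)
  }
})

test_that("pedigree invariants are enforced", {
  expect_error(pedigree(c("a", "a")), "duplicate",
               class = "autozyg_format_error")
  expect_error(pedigree("a", father_id = "ghost"), "not in pedigree",
               class = "autozyg_format_error")
  # two-node parent cycle
  expect_error(pedigree(c("a", "b"), father_id = c("b", "a")),
               "cycle", class = "autozyg_format_error")
})

test_that("the packaged variant table fixture loads with 73 rows in order", {
  t1 <- read_variant_table(
    system.file("extdata", "table1_variants.tsv", package = "autozyg"))
  expect_equal(nrow(t1), 73L)
  row <- t1[t1$position_bp == 149602589, ]
  expect_equal(row$gene, "CAMK2A")
  expect_equal(row$chromosome, "5")
  expect_equal(row$cdna_change, "c.1429C>T")
  expect_equal(row$protein_change, "p.His477Tyr")
  # order preserved: first and last printed rows
  expect_equal(t1$gene[1], "AK2")
  expect_equal(t1$gene[73], "MPP1")
  # absent optional columns yield absent fields
  expect_true(all(is.na(t1$population_maf)))
  expect_false(any(t1$known_polymorphism))
})

test_that("variant table edge cases and errors", {
  d <- withr::local_tempdir()
  p <- file.path(d, "v.tsv")
  writeLines("chromosome\tposition\tgene\tcdna_change", p)
  expect_equal(nrow(read_variant_table(p)), 0L)

  writeLines(c("chromosome\tgene\tcdna_change", "1\tX\tc.1A>G"), p)
  expect_error(read_variant_table(p), "position",
               class = "autozyg_format_error")

  writeLines(c("chromosome\tposition\tgene\tcdna_change",
               "1\tabc\tX\tc.1A>G"), p)
  expect_error(read_variant_table(p), "non-integer",
               class = "autozyg_format_error")

  # thousands separators tolerated; row count/order preserved
  writeLines(c("chromosome\tposition\tgene\tcdna_change",
               "5\t149,602,589\tCAMK2A\tc.1429C>T",
               "5\t1000\tX\tc.2A>G"), p)
  v <- read_variant_table(p)
  expect_equal(v$position_bp, c(149602589, 1000))
})

test_that("variant table writes and re-reads losslessly", {
  t1 <- read_variant_table(
    system.file("extdata", "table1_variants.tsv", package = "autozyg"))
  d <- withr::local_tempdir()
  write_variant_table(t1, file.path(d, "out.tsv"))
  back <- read_variant_table(file.path(d, "out.tsv"))
  expect_equal(back$position_bp, t1$position_bp)
  expect_equal(back$gene, t1$gene)
  expect_equal(back$cdna_change, t1$cdna_change)
})
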