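# Prioritization of homozygous variants inside the mapped loci: region
# intersection, population-frequency and known-polymorphism filters,
# recessive segregation across the family, and deterministic ranking.

#' Variant prioritization configuration
#'
#' @param maf_max variants with a population minor allele frequency at or
#'   above this are removed (default 0.01, i.e. the < 1% rarity filter).
#'   Variants with no recorded MAF pass: absence from databases is
#'   evidence of rarity, never grounds for exclusion.
#' @param exclude_known_polymorphisms drop variants flagged as previously
#'   annotated polymorphisms (default TRUE)
#' @return a `prioritization_config` list
#' @export
prioritization_config <- function(maf_max = 0.01,
                                  exclude_known_polymorphisms = TRUE) {
  stopifnot(maf_max > 0, maf_max <= 1)
  structure(list(maf_max = maf_max,
                 exclude_known_polymorphisms = exclude_known_polymorphisms),
            class = "prioritization_config")
}

#' Keep variants inside candidate regions that pass the rarity filters
#'
#' Retains variants whose (chromosome, position) falls within any
#' candidate region (closed intervals, literal chromosome match), whose
#' population MAF — when recorded — is below `maf_max`, and which are not
#' flagged known polymorphisms when that exclusion is enabled. Input row
#' order is preserved. Appends logical bookkeeping columns `in_region`
#' and `passed_maf` describing all input rows before subsetting.
#'
#' @param variants a variant table (see [read_variant_table()])
#' @param regions a candidate-region data.frame
#' @param config a [prioritization_config()]
#' @return the surviving rows of `variants`
#' @export
intersect_and_filter <- function(variants, regions,
                                 config = prioritization_config()) {
  v <- as.data.frame(variants)
  if (nrow(v) == 0L) return(variants[0L, , drop = FALSE])
  in_region <- rep(FALSE, nrow(v))
  for (r in seq_len(nrow(regions))) {
    in_region <- in_region |
      (v$chromosome == regions$chromosome[r] &
         v$position_bp >= regions$start_bp[r] &
         v$position_bp <= regions$end_bp[r])
  }
  passed_maf <- is.na(v$population_maf) | v$population_maf < config$maf_max
  variants$in_region <- in_region
  variants$passed_maf <- passed_maf
  keep <- in_region & passed_maf
  if (config$exclude_known_polymorphisms) {
    keep <- keep & !variants$known_polymorphism
  }
  variants[keep, , drop = FALSE]
}

# Alternate allele of a variant: explicit alt_allele column, else parsed
# from a simple HGVS cDNA substitution like "c.1429C>T".
variant_alt_allele <- function(variant) {
  alt <- variant[["alt_allele"]]
  if (!is.null(alt) && !is.na(alt) && nzchar(alt)) return(alt)
  m <- regmatches(variant[["cdna_change"]],
                  regexec("([ACGT])\\s*>\\s*([ACGT])", variant[["cdna_change"]]))[[1]]
  if (length(m) == 3L) return(m[3])
  NA_character_
}

# Alt-allele dosage (0/1/2) from a two-letter genotype string such as
# "CT" or "C/T"; NA for blank/missing genotypes.
alt_dosage <- function(gt, alt) {
  if (is.null(gt) || is.na(gt)) return(NA_integer_)
  gt <- gsub("[/| ]", "", gt)
  if (!nzchar(gt) || gt %in% c("00", "0")) return(NA_integer_)
  sum(strsplit(gt, "")[[1]] == alt)
}

#' Check recessive segregation of a variant across the pedigree
#'
#' Returns TRUE iff every affected individual is homozygous for the
#' alternate allele, every genotyped parent of an affected is a
#' heterozygous carrier, and no unaffected individual is homozygous for
#' the alternate allele. Heterozygous unaffected siblings are consistent
#' with the model (carriers are healthy). Member genotypes are taken from
#' `gt_<id>` entries of the variant row.
#'
#' @param variant one variant: a single-row data.frame or named list with
#'   `cdna_change` (or `alt_allele`) and `gt_<id>` genotypes for every
#'   pedigree member
#' @param pedigree a [pedigree()]
#' @return TRUE or FALSE. A missing genotype for any pedigree member
#'   raises an error of class `autozyg_incomplete_segregation` — distinct
#'   from FALSE, since absent data neither confirms nor refutes
#'   segregation.
#' @export
check_recessive_segregation <- function(variant, pedigree) {
  if (is.data.frame(variant)) {
    stopifnot(nrow(variant) == 1L)
    variant <- as.list(variant)
  }
  alt <- variant_alt_allele(variant)
  if (is.na(alt)) {
    abort("cannot determine the alternate allele of the variant",
          "autozyg_incomplete_segregation")
  }
  dosage <- vapply(pedigree$id, function(id) {
    alt_dosage(variant[[paste0("gt_", id)]], alt)
  }, integer(1))
  if (anyNA(dosage)) {
    abort(sprintf("missing genotype for pedigree member(s): %s",
                  paste(pedigree$id[is.na(dosage)], collapse = ", ")),
          "autozyg_incomplete_segregation")
  }
  aff <- pedigree$status == "affected"
  if (!all(dosage[aff] == 2L)) return(FALSE)
  parents <- unique(stats::na.omit(c(pedigree$father_id[aff],
                                     pedigree$mother_id[aff])))
  if (!all(dosage[match(parents, pedigree$id)] == 1L)) return(FALSE)
  unaff <- pedigree$status == "unaffected"
  if (any(dosage[unaff] == 2L)) return(FALSE)
  TRUE
}

#' Rank surviving variants
#'
#' Orders variants for reporting: segregation-consistent first (variants
#' whose segregation cannot be evaluated sort between TRUE and FALSE),
#' then variants never seen in databases (`known_polymorphism` FALSE and
#' absent MAF before any recorded MAF), then ascending MAF, with a
#' deterministic (chromosome, position) tie-break. Adds `segregates`
#' (logical, NA when not evaluable) and `rank` columns.
#'
#' @param variants a variant table
#' @param pedigree a [pedigree()]; used for the segregation check
#' @return `variants` with `segregates` and `rank`, sorted by rank
#' @export
rank_variants <- function(variants, pedigree) {
  v <- variants
  if (nrow(v) == 0L) {
    v$segregates <- logical(0)
    v$rank <- integer(0)
    return(v)
  }
  seg <- vapply(seq_len(nrow(v)), function(i) {
    tryCatch(check_recessive_segregation(as.data.frame(v)[i, , drop = FALSE],
                                         pedigree),
             autozyg_incomplete_segregation = function(e) NA)
  }, logical(1))
  v$segregates <- seg
  seg_key <- ifelse(is.na(seg), 1L, ifelse(seg, 0L, 2L))
  known_key <- as.integer(v$known_polymorphism)
  maf_key <- ifelse(is.na(v$population_maf), -1, v$population_maf)
  ord <- order(seg_key, known_key, maf_key, v$chromosome, v$position_bp)
  v <- v[ord, , drop = FALSE]
  v$rank <- seq_len(nrow(v))
  rownames(v) <- NULL
  v
}
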