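# Pedigree and genotype containers plus the PED/MAP and TSV text dialects.
#
# Conventions used throughout the package:
#   * coordinates are 1-based inclusive bp; regions are closed intervals
#     [start_bp, end_bp] and span end_bp - start_bp + 1 bases;
#   * alleles are the letters A/C/G/T, 0 encodes a missing allele in PED
#     files, and a call with any missing allele is treated as missing;
#   * chromosome labels are opaque strings compared literally ("5" and
#     "chr5" are different chromosomes unless normalized by the caller).

#' Construct a pedigree
#'
#' A pedigree is a data.frame with one row per individual and columns
#' `id`, `father_id`, `mother_id`, `sex` (`"male"`, `"female"`,
#' `"unknown"`) and `status` (`"affected"`, `"unaffected"`, `"unknown"`).
#' Parent references must resolve to rows of the pedigree or be `NA`
#' (founders), ids must be unique and the parent graph acyclic.
#'
#' @param id character vector of individual ids
#' @param father_id,mother_id parent ids or `NA` for founders
#' @param sex,status factors as above, recycled if scalar
#' @return a `pedigree` (data.frame)
#' @examples
#' ped <- pedigree(
#'   id = c("F", "M", "C1", "C2"),
#'   father_id = c(NA, NA, "F", "F"),
#'   mother_id = c(NA, NA, "M", "M"),
#'   sex = c("male", "female", "unknown", "unknown"),
#'   status = c("unaffected", "unaffected", "affected", "unaffected")
#' )
#' affected_ids(ped)
#' @export
pedigree <- function(id, father_id = NA_character_, mother_id = NA_character_,
                     sex = "unknown", status = "unknown") {
  ped <- data.frame(
    id = as.character(id),
    father_id = as.character(rep_len(father_id, length(id))),
    mother_id = as.character(rep_len(mother_id, length(id))),
    sex = rep_len(as.character(sex), length(id)),
    status = rep_len(as.character(status), length(id)),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) {
    format_error(sprintf("duplicate individual id: %s",
                         ped$id[duplicated(ped$id)][1]))
  }
  for (col in c("father_id", "mother_id")) {
    bad <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$id)
    if (any(bad)) {
      format_error(sprintf("%s '%s' of individual '%s' not in pedigree",
                           col, ped[[col]][bad][1], ped$id[bad][1]))
    }
  }
  if (!all(ped$sex %in% c("male", "female", "unknown"))) {
    format_error("sex must be one of male/female/unknown")
  }
  if (!all(ped$status %in% c("affected", "unaffected", "unknown"))) {
    format_error("status must be one of affected/unaffected/unknown")
  }
  # acyclicity: repeatedly strip individuals whose parents are all resolved
  remaining <- ped$id
  resolved <- character()
  repeat {
    ready <- vapply(seq_along(remaining), function(i) {
      row <- ped[ped$id == remaining[i], ]
      ok <- function(p) is.na(p) || p %in% resolved
      ok(row$father_id) && ok(row$mother_id)
    }, logical(1))
    if (!any(ready)) break
    resolved <- c(resolved, remaining[ready])
    remaining <- remaining[!ready]
    if (length(remaining) == 0L) break
  }
  if (length(remaining) > 0L) {
    format_error("pedigree parent graph contains a cycle")
  }
  invisible(ped)
}

#' @rdname pedigree
#' @param ped a `pedigree`
#' @export
affected_ids <- function(ped) ped$id[ped$status == "affected"]

#' @rdname pedigree
#' @export
unaffected_ids <- function(ped) ped$id[ped$status == "unaffected"]

#' Construct a genotype dataset
#'
#' Holds array-style biallelic genotype calls for a set of samples over a
#' marker grid. Markers are re-sorted by (chromosome, position) with the
#' call matrices permuted consistently; positions must be strictly
#' increasing within a chromosome after sorting. Calls are unordered allele
#' pairs over A/C/G/T; a missing call has `NA` in both allele matrices.
#'
#' @param markers data.frame with columns `id`, `chromosome`,
#'   `position_bp` and optionally `genetic_pos_cM` (NA when unknown)
#' @param samples character vector of sample ids (columns of the call
#'   matrices)
#' @param allele1,allele2 character matrices, markers x samples
#' @return a `genotype_dataset` list with elements `markers`, `samples`,
#'   `allele1`, `allele2`
#' @export
genotype_dataset <- function(markers, samples, allele1, allele2) {
  markers <- as.data.frame(markers)
  stopifnot(all(c("id", "chromosome", "position_bp") %in% names(markers)))
  if (is.null(markers$genetic_pos_cM)) markers$genetic_pos_cM <- NA_real_
  markers$position_bp <- as.numeric(markers$position_bp)
  n <- nrow(markers)
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  if (!all(dim(allele1) == c(n, length(samples))) ||
      !all(dim(allele2) == c(n, length(samples)))) {
    format_error("call matrices must be |markers| x |samples|")
  }
  if (any(markers$position_bp < 1)) format_error("positions must be >= 1")
  syms <- c(allele1, allele2)
  bad <- !is.na(syms) & !(syms %in% VALID_ALLELES)
  if (any(bad)) {
    format_error(sprintf("unknown allele symbol '%s'", syms[bad][1]))
  }
  if (any(is.na(allele1) != is.na(allele2))) {
    format_error("half-missing calls are not allowed; use NA/NA")
  }
  # stable sort: chromosomes in order of first appearance, then position
  chrom <- factor(markers$chromosome, levels = unique(markers$chromosome))
  ord <- order(as.integer(chrom), markers$position_bp)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  allele1 <- allele1[ord, , drop = FALSE]
  allele2 <- allele2[ord, , drop = FALSE]
  dup <- stats::ave(markers$position_bp, markers$chromosome,
                    FUN = function(p) c(FALSE, diff(p) <= 0))
  if (any(dup > 0)) {
    format_error("marker positions must be strictly increasing per chromosome")
  }
  colnames(allele1) <- colnames(allele2) <- samples
  structure(
    list(markers = markers, samples = as.character(samples),
         allele1 = allele1, allele2 = allele2),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d markers x %d samples (%s)\n",
              nrow(x$markers), length(x$samples),
              paste(unique(x$markers$chromosome), collapse = ", ")))
  invisible(x)
}

n_markers <- function(dataset) nrow(dataset$markers)

sample_index <- function(dataset, sample_id) {
  i <- match(sample_id, dataset$samples)
  if (is.na(i)) lookup_error(sprintf("unknown sample id '%s'", sample_id))
  i
}

#' Read pedigree and genotypes from PED/MAP files
#'
#' The PED dialect is whitespace-separated with six leading columns
#' (family, individual, father, mother, sex 1=male/2=female/0=unknown,
#' status 2=affected/1=unaffected/0=unknown) followed by two allele columns
#' per marker (letters A/C/G/T, 0 = missing). The MAP file has four
#' columns: chromosome, marker id, genetic position (cM, 0 when unknown)
#' and bp position. Markers are re-sorted per chromosome by bp with calls
#' permuted consistently.
#'
#' @param ped_path,map_path file paths
#' @return list with elements `pedigree` and `dataset`
#' @seealso [write_genotypes()] for the inverse
#' @export
read_genotypes <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) format_error(paste("no such file:", ped_path))
  if (!file.exists(map_path)) format_error(paste("no such file:", map_path))

  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4L) format_error("MAP file must have 4 columns")
  names(map) <- c("chromosome", "id", "genetic_pos_cM", "position_bp")
  markers <- data.frame(
    id = map$id,
    chromosome = map$chromosome,
    position_bp = as.numeric(map$position_bp),
    genetic_pos_cM = as.numeric(map$genetic_pos_cM),
    stringsAsFactors = FALSE
  )
  markers$genetic_pos_cM[markers$genetic_pos_cM == 0] <- NA_real_
  nm <- nrow(markers)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  ids <- character(length(fields))
  fa <- mo <- sex <- status <- character(length(fields))
  a1 <- matrix(NA_character_, nm, length(fields))
  a2 <- matrix(NA_character_, nm, length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 6L + 2L * nm) {
      format_error(sprintf(
        "PED line %d: %d genotype columns, expected %d for %d MAP markers",
        i, length(f) - 6L, 2L * nm, nm))
    }
    ids[i] <- f[2]; fa[i] <- f[3]; mo[i] <- f[4]
    sex[i] <- c("0" = "unknown", "1" = "male", "2" = "female")[f[5]]
    status[i] <- c("0" = "unknown", "1" = "unaffected", "2" = "affected")[f[6]]
    g <- f[-(1:6)]
    bad <- !(g %in% c(VALID_ALLELES, "0"))
    if (any(bad)) {
      format_error(sprintf("PED line %d: unknown allele symbol '%s'",
                           i, g[bad][1]))
    }
    x1 <- g[seq(1L, 2L * nm, by = 2L)]
    x2 <- g[seq(2L, 2L * nm, by = 2L)]
    miss <- x1 == "0" | x2 == "0"
    x1[miss] <- NA_character_; x2[miss] <- NA_character_
    a1[, i] <- x1; a2[, i] <- x2
  }
  if (anyDuplicated(ids)) {
    format_error(sprintf("duplicate individual id '%s' in PED",
                         ids[duplicated(ids)][1]))
  }
  fa[fa == "0"] <- NA_character_
  mo[mo == "0"] <- NA_character_
  ped <- pedigree(ids, father_id = fa, mother_id = mo,
                  sex = sex, status = status)
  dataset <- genotype_dataset(markers, ids, a1, a2)
  list(pedigree = ped, dataset = dataset)
}

#' Write pedigree and genotypes to PED/MAP files
#'
#' Inverse of [read_genotypes()]: round-tripping preserves marker order,
#' calls and missingness.
#'
#' @param dataset a `genotype_dataset`
#' @param ped a `pedigree` covering all samples
#' @param ped_path,map_path output file paths
#' @param family_id family column written to the PED file
#' @export
write_genotypes <- function(dataset, ped, ped_path, map_path,
                            family_id = "FAM1") {
  m <- dataset$markers
  cm <- ifelse(is.na(m$genetic_pos_cM), 0, m$genetic_pos_cM)
  utils::write.table(
    data.frame(m$chromosome, m$id, cm, format(m$position_bp, scientific = FALSE, trim = TRUE)),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  sex_code <- c(male = "1", female = "2", unknown = "0")
  status_code <- c(affected = "2", unaffected = "1", unknown = "0")
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (s in dataset$samples) {
    row <- ped[ped$id == s, ]
    if (nrow(row) != 1L) lookup_error(sprintf("sample '%s' not in pedigree", s))
    x1 <- dataset$allele1[, s]; x2 <- dataset$allele2[, s]
    x1[is.na(x1)] <- "0"; x2[is.na(x2)] <- "0"
    geno <- as.vector(rbind(x1, x2))
    lead <- c(family_id, s,
              ifelse(is.na(row$father_id), "0", row$father_id),
              ifelse(is.na(row$mother_id), "0", row$mother_id),
              sex_code[[row$sex]], status_code[[row$status]])
    writeLines(paste(c(lead, geno), collapse = " "), con)
  }
  invisible(NULL)
}

#' Read a homozygous-variant table
#'
#' Reads a TSV with one row per homozygous variant found in the proband,
#' in the layout of a whole-exome candidate table. Required columns:
#' `chromosome`, `position`, `gene`, `cdna_change`. Optional columns:
#' `protein_change`, `maf` (population minor allele frequency, blank when
#' the variant is absent from databases), `known_polymorphism`
#' (TRUE/FALSE), `alt_allele`, and per-member genotype columns named
#' `gt_<individual id>` holding two-letter allele pairs (e.g. `CT`).
#' Thousands separators in `position` are tolerated. Row order is
#' preserved.
#'
#' @param tsv_path file path
#' @return data.frame of variants (class `variant_table`), one row per
#'   input data row, with columns `chromosome`, `position_bp`, `gene`,
#'   `cdna_change`, `protein_change`, `population_maf`,
#'   `known_polymorphism` plus any `gt_*` columns
#' @examples
#' t1 <- read_variant_table(
#'   system.file("extdata", "table1_variants.tsv", package = "autozyg"))
#' nrow(t1)
#' @export
read_variant_table <- function(tsv_path) {
  if (!file.exists(tsv_path)) format_error(paste("no such file:", tsv_path))
  df <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE)
  required <- c("chromosome", "position", "gene", "cdna_change")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    format_error(paste("variant table missing required column(s):",
                       paste(missing_cols, collapse = ", ")))
  }
  pos_raw <- gsub(",", "", df$position)
  pos <- suppressWarnings(as.numeric(pos_raw))
  if (nrow(df) > 0 && (anyNA(pos) || any(pos != floor(pos)))) {
    bad <- which(is.na(pos) | pos != floor(pos))[1]
    format_error(sprintf("variant table row %d: non-integer position '%s'",
                         bad, df$position[bad]))
  }
  out <- data.frame(
    chromosome = df$chromosome,
    position_bp = pos,
    gene = df$gene,
    cdna_change = df$cdna_change,
    protein_change = if (is.null(df$protein_change))
      rep(NA_character_, nrow(df)) else
      ifelse(nzchar(df$protein_change), df$protein_change, NA_character_),
    population_maf = if (is.null(df$maf)) rep(NA_real_, nrow(df)) else
      suppressWarnings(as.numeric(df$maf)),
    known_polymorphism = if (is.null(df$known_polymorphism))
      rep(FALSE, nrow(df)) else
      toupper(df$known_polymorphism) %in% c("TRUE", "T", "1", "YES"),
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0 && any(!is.na(out$population_maf) &
        (out$population_maf < 0 | out$population_maf > 1))) {
    format_error("population_maf must lie in [0, 1]")
  }
  if (!is.null(df$alt_allele)) out$alt_allele <- df$alt_allele
  gt_cols <- grep("^gt_", names(df), value = TRUE)
  for (g in gt_cols) out[[g]] <- df[[g]]
  class(out) <- c("variant_table", "data.frame")
  out
}

#' @rdname read_variant_table
#' @param variants a variant table data.frame
#' @export
write_variant_table <- function(variants, tsv_path) {
  df <- as.data.frame(variants)
  df$position <- format(df$position_bp, scientific = FALSE, trim = TRUE)
  df$position_bp <- NULL
  df$maf <- df$population_maf
  df$population_maf <- NULL
  front <- c("chromosome", "position", "gene", "cdna_change")
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(tsv_path)
}

#' Write candidate regions as a BED-like TSV
#'
#' Columns: chromosome, start_bp, end_bp, genetic_length_cM, n_markers
#' (plus concordance when present). Unlike true BED, coordinates are
#' 1-based closed intervals, stated in a header comment.
#'
#' @param regions a candidate-region data.frame
#' @param path output path
#' @export
write_regions <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# autozyg candidate regions; 1-based closed intervals", con)
  cols <- intersect(
    c("chromosome", "start_bp", "end_bp", "genetic_length_cM",
      "n_markers", "concordance"),
    names(regions))
  df <- as.data.frame(regions)[, cols, drop = FALSE]
  for (c2 in c("start_bp", "end_bp")) {
    if (c2 %in% names(df)) df[[c2]] <- format(df[[c2]], scientific = FALSE, trim = TRUE)
  }
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}
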