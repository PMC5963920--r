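# Synthetic consanguineous-pedigree studies with known ground truth.
#
# The emulated family mirrors a first-cousin union with a sibship of
# five (two affected): the two parents are children of two sibling
# parents who share a common founder couple. Founder haplotypes are drawn
# marker-wise from a uniform minor-allele-frequency law; transmission
# follows the Haldane model (Poisson crossover counts per Morgan, no
# interference, crossover positions uniform in cM). A rare causal variant
# is implanted on one founder haplotype and its descent forced by
# rejection sampling over meioses so that both affected children are
# autozygous at the causal locus while no unaffected sibling is
# homozygous for it — tract lengths around the locus stay faithful to the
# recombination model. Every haplotype carries a founder-haplotype label
# through all meioses, so realized autozygosity is known exactly.

MAX_REJECTION_TRIES <- 100000L

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is validated
#' against: one 150 Mb chromosome carrying 5,000 array markers, founder
#' minor allele frequencies uniform on \[0.05, 0.5\], a 0.2% genotyping
#' error rate and 0.5% missingness (array call rates above 99%), a
#' first-cousin parental loop with five children of whom two are
#' affected, and one implanted causal autozygous region.
#'
#' @param n_chromosomes number of chromosomes
#' @param chromosome_length_bp physical length of each chromosome
#' @param n_markers total markers, split evenly across chromosomes
#' @param maf_range founder minor-allele-frequency law: uniform on this
#'   interval
#' @param genotyping_error_rate per-call probability that one allele of a
#'   call is flipped to the other allele of the marker
#' @param missing_rate per-call probability the call is set missing
#' @param n_background_variants non-causal rows of the simulated
#'   homozygous-variant table
#' @param causal_locus `"auto"` (midpoint of chromosome 1) or a list with
#'   elements `chromosome` and `position_bp`; the causal variant is
#'   implanted at the marker nearest the requested position, where its
#'   descent is forced
#' @param cM_per_Mb constant recombination rate of the simulated genome
#' @param seed integer seed governing all randomness
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_chromosomes = 1L,
                              chromosome_length_bp = 150e6,
                              n_markers = 5000L,
                              maf_range = c(0.05, 0.5),
                              genotyping_error_rate = 0.002,
                              missing_rate = 0.005,
                              n_background_variants = 71L,
                              causal_locus = "auto",
                              cM_per_Mb = 1.0,
                              seed = 1L) {
  stopifnot(n_chromosomes >= 1, chromosome_length_bp > 1, n_markers >= 2,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1, cM_per_Mb > 0)
  if (!identical(causal_locus, "auto")) {
    if (!is.list(causal_locus) ||
        !all(c("chromosome", "position_bp") %in% names(causal_locus))) {
      config_error("causal_locus must be \"auto\" or list(chromosome, position_bp)")
    }
    if (causal_locus$position_bp < 1 ||
        causal_locus$position_bp > chromosome_length_bp ||
        !(causal_locus$chromosome %in% as.character(seq_len(n_chromosomes)))) {
      config_error("causal locus outside the simulated chromosomes")
    }
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = chromosome_length_bp,
                 n_markers = as.integer(n_markers),
                 maf_range = maf_range,
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate,
                 n_background_variants = as.integer(n_background_variants),
                 causal_locus = causal_locus,
                 cM_per_Mb = cM_per_Mb,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Marker grid: random distinct positions per chromosome, plus each
# marker's cM position and each chromosome's genetic length.
make_marker_grid <- function(config) {
  per_chrom <- diff(round(seq(0, config$n_markers,
                              length.out = config$n_chromosomes + 1L)))
  rows <- list()
  for (c2 in seq_len(config$n_chromosomes)) {
    pos <- sort(sample.int(config$chromosome_length_bp, per_chrom[c2]))
    rows[[c2]] <- data.frame(
      id = sprintf("rs%d_%06d", c2, seq_along(pos)),
      chromosome = as.character(c2),
      position_bp = as.numeric(pos),
      stringsAsFactors = FALSE
    )
  }
  markers <- do.call(rbind, rows)
  markers$genetic_pos_cM <- markers$position_bp * config$cM_per_Mb / 1e6
  chrom_len_cM <- rep(config$chromosome_length_bp * config$cM_per_Mb / 1e6,
                      config$n_chromosomes)
  names(chrom_len_cM) <- as.character(seq_len(config$n_chromosomes))
  list(markers = markers, chrom_len_cM = chrom_len_cM)
}

# Haldane selector for one chromosome: for each marker, which parental
# haplotype (1 or 2) the gamete copies.
haldane_selector <- function(genetic_pos_cM, chromosome_length_cM) {
  n_x <- stats::rpois(1L, chromosome_length_cM / 100)
  phase0 <- sample.int(2L, 1L)
  if (n_x == 0L) return(rep(phase0, length(genetic_pos_cM)))
  x <- sort(stats::runif(n_x, 0, chromosome_length_cM))
  1L + (phase0 - 1L + findInterval(genetic_pos_cM, x)) %% 2L
}

#' Draw one gamete from a pair of parental haplotypes (Haldane model)
#'
#' The crossover count is Poisson with mean equal to the chromosome's
#' genetic length in Morgans, crossover positions are uniform in cM (no
#' interference), the starting haplotype is chosen with equal
#' probability, and the gamete switches between the parental haplotypes
#' at each crossover.
#'
#' @param parent_haplotypes matrix with one row per marker and two
#'   columns, one per parental haplotype (any storage type)
#' @param genetic_pos_cM marker positions in cM, sorted
#' @param chromosome_length_cM genetic length of the chromosome over
#'   which crossovers are drawn (defaults to the last marker's position)
#' @return vector of length `nrow(parent_haplotypes)`: the transmitted
#'   haplotype
#' @export
meiosis <- function(parent_haplotypes, genetic_pos_cM,
                    chromosome_length_cM = max(genetic_pos_cM)) {
  stopifnot(ncol(parent_haplotypes) == 2L,
            nrow(parent_haplotypes) == length(genetic_pos_cM))
  sel <- haldane_selector(genetic_pos_cM, chromosome_length_cM)
  parent_haplotypes[cbind(seq_along(sel), sel)]
}

# --- internal genome-wide transmission on (allele, founder-id) pairs ----

# An individual is list(al = m x 2 character, id = m x 2 integer).
make_person <- function(hap1, hap2) {
  list(al = cbind(hap1$al, hap2$al), id = cbind(hap1$id, hap2$id))
}

# One gamete across all chromosomes; grid gives per-chromosome indices.
draw_gamete <- function(person, grid_split) {
  m <- nrow(person$al)
  sel <- integer(m)
  for (g in grid_split) {
    sel[g$idx] <- haldane_selector(g$cM, g$len_cM)
  }
  pick <- cbind(seq_len(m), sel)
  list(al = person$al[pick], id = person$id[pick])
}

split_grid <- function(grid) {
  lapply(names(grid$chrom_len_cM), function(ch) {
    idx <- which(grid$markers$chromosome == ch)
    list(idx = idx, cM = grid$markers$genetic_pos_cM[idx],
         len_cM = grid$chrom_len_cM[[ch]])
  })
}

make_founder <- function(maf, alt, ref, id_pair) {
  hap <- function(id1) {
    carries <- stats::runif(length(maf)) < maf
    list(al = ifelse(carries, alt, ref), id = rep(id1, length(maf)))
  }
  make_person(hap(id_pair[1]), hap(id_pair[2]))
}

# Rejection helper: redraw `draw()` until `cond()` holds.
draw_until <- function(draw, cond, what) {
  for (k in seq_len(MAX_REJECTION_TRIES)) {
    x <- draw()
    if (cond(x)) return(x)
  }
  config_error(paste("rejection sampling failed for:", what))
}

#' Simulate a consanguineous-pedigree study with known ground truth
#'
#' Builds the first-cousin pedigree, draws founder haplotypes, transmits
#' them by Haldane-model meioses with the causal founder haplotype's
#' descent forced by rejection sampling, applies genotyping error and
#' missingness, and assembles the genotype dataset, homozygous-variant
#' table, realized truth region and causal variant. All randomness
#' derives from `config$seed`; the same seed reproduces the study
#' exactly.
#'
#' @param config a [simulation_config()]
#' @return a `synthetic_study` list: `pedigree`, `dataset`, `map` (a
#'   [genetic_map()]), `variants`, `truth_regions` (data.frame
#'   chromosome/start_bp/end_bp of the shared autozygous tract around the
#'   causal locus), `causal_variant` (one row of `variants`), `config`
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  grid <- make_marker_grid(config)
  gs <- split_grid(grid)
  m <- nrow(grid$markers)

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  bases <- t(vapply(seq_len(m), function(i) sample(VALID_ALLELES, 2L),
                    character(2)))
  ref <- bases[, 1]; alt <- bases[, 2]

  # founders: G1 x G2 are the shared grandparents; Q1, Q2 marry into the
  # sibship. Founder haplotype ids 1..8; the causal haplotype is id 1.
  G1 <- make_founder(maf, alt, ref, c(1L, 2L))
  G2 <- make_founder(maf, alt, ref, c(3L, 4L))
  Q1 <- make_founder(maf, alt, ref, c(5L, 6L))
  Q2 <- make_founder(maf, alt, ref, c(7L, 8L))
  causal_id <- 1L

  if (identical(config$causal_locus, "auto")) {
    causal_chrom <- "1"
    causal_pos <- round(config$chromosome_length_bp / 2)
  } else {
    causal_chrom <- as.character(config$causal_locus$chromosome)
    causal_pos <- config$causal_locus$position_bp
  }
  on_chrom <- which(grid$markers$chromosome == causal_chrom)
  m_star <- on_chrom[which.min(abs(grid$markers$position_bp[on_chrom] -
                                     causal_pos))]
  # the variant is implanted at the marker where descent is forced, so
  # its position is autozygous by construction and always lies inside
  # the realized truth region
  causal_pos <- grid$markers$position_bp[m_star]

  # one parent-as-carrier chain: grandparent -> sib -> parent, redrawn
  # until the causal haplotype reaches the parent at the locus
  carrier_parent <- function(Qspouse) {
    gamete_from_sib <- draw_until(
      function() {
        sib <- make_person(draw_gamete(G1, gs), draw_gamete(G2, gs))
        draw_gamete(sib, gs)
      },
      function(g) g$id[m_star] == causal_id,
      "carrier parent at causal locus")
    make_person(gamete_from_sib, draw_gamete(Qspouse, gs))
  }
  P1 <- carrier_parent(Q1)  # father, child of sib 1
  P2 <- carrier_parent(Q2)  # mother, child of sib 2

  affected_flags <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  child_ids <- sprintf("II-%d", 1:5)
  children <- lapply(affected_flags, function(is_aff) {
    draw_until(
      function() make_person(draw_gamete(P1, gs), draw_gamete(P2, gs)),
      function(ch) {
        autozygous <- ch$id[m_star, 1] == causal_id &&
          ch$id[m_star, 2] == causal_id
        if (is_aff) autozygous else !autozygous
      },
      if (is_aff) "affected child autozygous at causal locus" else
        "unaffected child not homozygous at causal locus")
  })

  ped <- pedigree(
    id = c("I-1", "I-2", child_ids),
    father_id = c(NA, NA, rep("I-1", 5L)),
    mother_id = c(NA, NA, rep("I-2", 5L)),
    sex = c("male", "female", rep("unknown", 5L)),
    status = c("unaffected", "unaffected",
               ifelse(affected_flags, "affected", "unaffected"))
  )
  members <- c(list(P1, P2), children)
  names(members) <- ped$id

  # realized shared autozygous tract around the causal locus
  aff_members <- members[ped$id[ped$status == "affected"]]
  shared_autoz <- Reduce(`&`, lapply(aff_members, function(p) {
    p$id[, 1] == causal_id & p$id[, 2] == causal_id
  }))
  r <- rle(shared_autoz[on_chrom])
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  k <- which(starts <= match(m_star, on_chrom) &
               ends >= match(m_star, on_chrom) & r$values)
  truth_idx <- on_chrom[c(starts[k], ends[k])]
  truth_regions <- data.frame(
    chromosome = causal_chrom,
    start_bp = grid$markers$position_bp[truth_idx[1]],
    end_bp = grid$markers$position_bp[truth_idx[2]],
    stringsAsFactors = FALSE
  )

  # causal-variant dosage per member, recorded before genotyping error
  causal_dosage <- vapply(members, function(p) {
    sum(p$id[m_star, ] == causal_id)
  }, integer(1))

  a1 <- vapply(members, function(p) p$al[, 1], character(m))
  a2 <- vapply(members, function(p) p$al[, 2], character(m))

  # genotyping error: flip one allele of a call to the marker's other
  # allele; then missingness
  n_cells <- m * length(members)
  err <- matrix(stats::runif(n_cells) < config$genotyping_error_rate,
                m, length(members))
  if (any(err)) {
    which_slot <- matrix(sample.int(2L, n_cells, replace = TRUE),
                         m, length(members))
    flip1 <- err & which_slot == 1L
    flip2 <- err & which_slot == 2L
    other <- function(x) ifelse(x == ref, alt, ref)
    a1[flip1] <- other(a1)[flip1]
    a2[flip2] <- other(a2)[flip2]
  }
  miss <- matrix(stats::runif(n_cells) < config$missing_rate,
                 m, length(members))
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_

  dataset <- genotype_dataset(grid$markers, ped$id, a1, a2)
  map <- genetic_map(fallback_rate_cM_per_Mb = config$cM_per_Mb)

  variants <- build_variant_table(config, grid, ped, causal_chrom,
                                  causal_pos, causal_dosage)
  causal_variant <- variants[variants$gene == "GENE_CAUSAL", , drop = FALSE]

  structure(list(pedigree = ped, dataset = dataset, map = map,
                 variants = variants, truth_regions = truth_regions,
                 causal_variant = causal_variant, config = config),
            class = "synthetic_study")
}

# Homozygous-variant table: the causal variant (absent from databases,
# genotypes from realized descent) plus background variants that are
# homozygous in the proband, carry database frequencies from the founder
# law and are flagged as known polymorphisms; other members' genotypes
# are drawn per member under Hardy-Weinberg at the variant's frequency (a
# deliberate simplification: background variants are table rows only and
# never constrained to co-segregate).
build_variant_table <- function(config, grid, ped, causal_chrom,
                                causal_pos, causal_dosage) {
  gt_string <- function(dosage, ref, alt) {
    c(paste0(ref, ref), paste0(ref, alt), paste0(alt, alt))[dosage + 1L]
  }
  rows <- list()
  rows[[1L]] <- data.frame(
    chromosome = causal_chrom, position_bp = causal_pos,
    gene = "GENE_CAUSAL", cdna_change = "c.100C>T",
    protein_change = NA_character_, population_maf = NA_real_,
    known_polymorphism = FALSE, stringsAsFactors = FALSE)
  gts <- list(gt_string(causal_dosage, "C", "T"))

  nb <- config$n_background_variants
  if (nb > 0L) {
    chroms <- as.character(sample.int(config$n_chromosomes, nb,
                                      replace = TRUE))
    pos <- sample.int(config$chromosome_length_bp, nb)
    mafs <- stats::runif(nb, config$maf_range[1], config$maf_range[2])
    for (i in seq_len(nb)) {
      ra <- sample(VALID_ALLELES, 2L)
      dosage <- stats::rbinom(nrow(ped), 2L, mafs[i])
      dosage[1L + 2L] <- 2L  # proband (first child, row 3) homozygous
      rows[[i + 1L]] <- data.frame(
        chromosome = chroms[i], position_bp = pos[i],
        gene = sprintf("SIMG%03d", i),
        cdna_change = sprintf("c.%d%s>%s", sample(300:3000, 1L), ra[1], ra[2]),
        protein_change = NA_character_, population_maf = mafs[i],
        known_polymorphism = TRUE, stringsAsFactors = FALSE)
      gts[[i + 1L]] <- gt_string(dosage, ra[1], ra[2])
    }
  }
  v <- do.call(rbind, rows)
  gtm <- do.call(rbind, gts)
  colnames(gtm) <- paste0("gt_", ped$id)
  v <- cbind(v, as.data.frame(gtm, stringsAsFactors = FALSE))
  v <- v[order(as.integer(v$chromosome), v$position_bp), , drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("variant_table", "data.frame")
  v
}

#' Write a synthetic study to disk
#'
#' Emits `genotypes.ped` / `genotypes.map`, `genetic_map.tsv` (two
#' anchors per chromosome, equivalent to the constant-rate map used in
#' simulation), `variants.tsv` and `truth.json` (truth regions + causal
#' variant) into `dir`. The same study written twice produces identical
#' bytes.
#'
#' @param study a `synthetic_study`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(study$dataset, study$pedigree,
                  file.path(dir, "genotypes.ped"),
                  file.path(dir, "genotypes.map"))
  mk <- study$dataset$markers
  anchors <- do.call(rbind, lapply(unique(mk$chromosome), function(ch) {
    p <- mk[mk$chromosome == ch, ]
    p[c(1L, nrow(p)), c("chromosome", "position_bp", "genetic_pos_cM")]
  }))
  names(anchors) <- c("chromosome", "position_bp", "cM")
  utils::write.table(anchors, file.path(dir, "genetic_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_variant_table(study$variants, file.path(dir, "variants.tsv"))
  jsonlite::write_json(
    list(truth_regions = study$truth_regions,
         causal_variant = as.data.frame(study$causal_variant)),
    file.path(dir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Autozygous genome fractions of independent first-cousin offspring
#'
#' Simulates `n_offspring` independent first-cousin pedigree chains
#' (founder-haplotype labels only, no conditioning on a causal locus) and
#' returns each offspring's autozygous fraction: the proportion of
#' markers at which both haplotypes carry the same founder-haplotype
#' label. The expectation is the inbreeding coefficient of first-cousin
#' offspring, F = 1/16.
#'
#' @param n_offspring number of independent offspring
#' @param config a [simulation_config()]; its seed governs the draws
#' @return numeric vector of length `n_offspring`
#' @export
simulate_offspring_autozygosity <- function(n_offspring,
                                            config = simulation_config()) {
  set.seed(config$seed)
  grid <- make_marker_grid(config)
  gs <- split_grid(grid)
  m <- nrow(grid$markers)
  id_founder <- function(pair) {
    list(al = matrix("A", m, 2L),
         id = cbind(rep(pair[1], m), rep(pair[2], m)))
  }
  G1 <- id_founder(c(1L, 2L)); G2 <- id_founder(c(3L, 4L))
  Q1 <- id_founder(c(5L, 6L)); Q2 <- id_founder(c(7L, 8L))
  vapply(seq_len(n_offspring), function(i) {
    S1 <- make_person(draw_gamete(G1, gs), draw_gamete(G2, gs))
    S2 <- make_person(draw_gamete(G1, gs), draw_gamete(G2, gs))
    P1 <- make_person(draw_gamete(S1, gs), draw_gamete(Q1, gs))
    P2 <- make_person(draw_gamete(S2, gs), draw_gamete(Q2, gs))
    child <- make_person(draw_gamete(P1, gs), draw_gamete(P2, gs))
    mean(child$id[, 1] == child$id[, 2])
  }, numeric(1))
}
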