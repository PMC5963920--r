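# End-to-end orchestration: read -> ROH -> shared regions -> unaffected
# exclusion -> genetic-length filter -> variant intersection/filters ->
# segregation -> ranking, from a single key-value configuration.

#' Read a pipeline configuration file
#'
#' Plain text, one `key = value` per line, `#` comments allowed. Unknown
#' keys raise a configuration error. See [pipeline_defaults()] for the
#' full key set and defaults.
#'
#' @param path config file path
#' @return named list merged over the defaults
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(paste("no such config file:", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- pipeline_defaults()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) config_error(paste("bad config line:", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!(key %in% names(cfg))) config_error(paste("unknown config key:", key))
    cfg[[key]] <- val
  }
  coerce_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @export
pipeline_defaults <- function() {
  list(
    ped = NA_character_,            # PED genotype file (required)
    map = NA_character_,            # MAP marker file (required)
    genetic_map = NA_character_,    # optional bp<->cM anchor TSV
    variants = NA_character_,       # optional homozygous-variant TSV
    fallback_cM_per_Mb = 1.0,
    normalize_chromosomes = FALSE,  # strip a leading "chr" everywhere
    min_markers = 25L,
    max_het_in_run = 1L,
    max_missing_in_run = 2L,
    min_length_bp = 1e6,
    min_genetic_length_cM = 5.0,
    exclusion_mode = "subtract",
    unaffected_identity_required = TRUE,
    maf_max = 0.01,
    exclude_known_polymorphisms = TRUE
  )
}

coerce_pipeline_config <- function(cfg) {
  num_keys <- c("fallback_cM_per_Mb", "min_markers", "max_het_in_run",
                "max_missing_in_run", "min_length_bp",
                "min_genetic_length_cM", "maf_max")
  lgl_keys <- c("unaffected_identity_required", "exclude_known_polymorphisms",
                "normalize_chromosomes")
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in lgl_keys) {
    cfg[[k]] <- toupper(as.character(cfg[[k]])) %in% c("TRUE", "T", "1", "YES")
  }
  if (!cfg$exclusion_mode %in% c("subtract", "drop")) {
    config_error("exclusion_mode must be subtract or drop")
  }
  cfg
}

strip_chr <- function(x) sub("^chr", "", x)

#' Run the full mapping and prioritization pipeline
#'
#' Executes every stage from genotype reading to variant ranking and
#' returns a mapping report. An empty candidate list is a valid, reported
#' outcome, not an error; stage failures propagate with the stage name.
#'
#' @param config a config file path or a named list over
#'   [pipeline_defaults()]
#' @param out_dir optional output directory; when given, writes
#'   `regions.tsv`, `variants_annotated.tsv`, `report.json` and
#'   `pipeline.log`
#' @return a `mapping_report` list: `candidate_regions`,
#'   `variants_in_regions` (annotated and ranked), `top_candidate` (one
#'   row or NULL), `stage_counts`, `provenance` (config echo)
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  } else {
    defaults <- pipeline_defaults()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown) > 0L) {
      config_error(paste("unknown config key(s):",
                         paste(unknown, collapse = ", ")))
    }
    config <- coerce_pipeline_config(utils::modifyList(defaults, config))
  }
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[autozyg] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (is.na(config$ped) || is.na(config$map)) {
    config_error("config must set 'ped' and 'map'")
  }
  gen <- stage("read_genotypes", read_genotypes(config$ped, config$map))
  dataset <- gen$dataset
  ped <- gen$pedigree
  if (config$normalize_chromosomes) {
    dataset$markers$chromosome <- strip_chr(dataset$markers$chromosome)
  }
  say("read %d markers x %d samples; %d affected, %d unaffected",
      nrow(dataset$markers), length(dataset$samples),
      length(affected_ids(ped)), length(unaffected_ids(ped)))

  map <- if (!is.na(config$genetic_map)) {
    stage("read_genetic_map",
          read_genetic_map(config$genetic_map, config$fallback_cM_per_Mb))
  } else {
    genetic_map(fallback_rate_cM_per_Mb = config$fallback_cM_per_Mb)
  }

  rp <- roh_params(config$min_markers, config$max_het_in_run,
                   config$max_missing_in_run, config$min_length_bp)
  mc <- mapping_config(config$min_genetic_length_cM, rp,
                       config$exclusion_mode,
                       config$unaffected_identity_required)

  shared <- stage("shared_autozygous_regions",
                  shared_autozygous_regions(dataset, ped, rp))
  say("shared autozygous regions: %d (%.1f Mb)", nrow(shared),
      sum(shared$end_bp - shared$start_bp + 1) / 1e6)
  excluded <- stage("exclude_unaffected",
                    exclude_unaffected(shared, dataset, ped, mc))
  say("after unaffected exclusion (%s): %d (%.1f Mb)", mc$exclusion_mode,
      nrow(excluded), sum(excluded$end_bp - excluded$start_bp + 1) / 1e6)
  candidates <- stage("filter_by_genetic_length",
                      filter_by_genetic_length(excluded, map, mc))
  say("after %.1f cM length filter: %d (%.1f Mb)", mc$min_genetic_length_cM,
      nrow(candidates), sum(candidates$end_bp - candidates$start_bp + 1) / 1e6)

  counts <- list(
    markers = nrow(dataset$markers),
    samples = length(dataset$samples),
    regions_shared = nrow(shared),
    regions_after_exclusion = nrow(excluded),
    regions_candidate = nrow(candidates)
  )

  survivors <- NULL
  top <- NULL
  if (!is.na(config$variants)) {
    variants <- stage("read_variant_table",
                      read_variant_table(config$variants))
    if (config$normalize_chromosomes) {
      variants$chromosome <- strip_chr(variants$chromosome)
    }
    pc <- prioritization_config(config$maf_max,
                                config$exclude_known_polymorphisms)
    survivors <- stage("intersect_and_filter",
                       intersect_and_filter(variants, candidates, pc))
    say("variants: %d total, %d pass region + rarity filters",
        nrow(variants), nrow(survivors))
    survivors <- stage("rank_variants", rank_variants(survivors, ped))
    counts$variants_total <- nrow(variants)
    counts$variants_surviving <- nrow(survivors)
    counts$variants_segregating <- sum(survivors$segregates %in% TRUE)
    if (nrow(survivors) > 0L) {
      top <- survivors[1L, , drop = FALSE]
      say("top candidate: %s %s (%s)", top$gene, top$cdna_change,
          if (isTRUE(top$segregates)) "segregates" else "segregation unconfirmed")
    } else {
      say("no variant survives the filters")
    }
  }

  report <- structure(
    list(candidate_regions = candidates,
         variants_in_regions = survivors,
         top_candidate = top,
         stage_counts = counts,
         provenance = config),
    class = "mapping_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_regions(candidates, file.path(out_dir, "regions.tsv"))
    if (!is.null(survivors)) {
      write_variant_table(survivors, file.path(out_dir, "variants_annotated.tsv"))
    }
    jsonlite::write_json(
      list(candidate_regions = candidates,
           variants_in_regions = survivors,
           top_candidate = top,
           stage_counts = counts,
           config = config),
      file.path(out_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE,
      na = "null")
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  report
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("autozyg mapping report\n")
  cat(sprintf("  candidate regions: %d\n", nrow(x$candidate_regions)))
  for (r in seq_len(nrow(x$candidate_regions))) {
    cat(sprintf("    chr%s:%s-%s  %.1f cM, %d markers\n",
                x$candidate_regions$chromosome[r],
                format(x$candidate_regions$start_bp[r], big.mark = ","),
                format(x$candidate_regions$end_bp[r], big.mark = ","),
                x$candidate_regions$genetic_length_cM[r],
                x$candidate_regions$n_markers[r]))
  }
  if (!is.null(x$variants_in_regions)) {
    cat(sprintf("  variants surviving filters: %d\n",
                nrow(x$variants_in_regions)))
  }
  if (!is.null(x$top_candidate)) {
    cat(sprintf("  top candidate: %s %s\n", x$top_candidate$gene,
                x$top_candidate$cdna_change))
  }
  invisible(x)
}
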