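# cDNA -> protein coordinate mapping for simple coding substitutions
# (e.g. c.1429C>T on the CAMK2A cDNA, codon 477, His -> Tyr). Translation
# uses the standard genetic code.

# one-letter -> three-letter amino acid codes (HGVS style, stop = Ter)
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", "*" = "Ter"
)

#' Construct a coding sequence
#'
#' @param gene gene symbol
#' @param cds nucleotide string over A/C/G/T; length divisible by 3 and
#'   beginning with the ATG start codon
#' @return a `coding_sequence` list
#' @export
coding_sequence <- function(gene, cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) format_error("CDS length must be divisible by 3")
  if (substr(cds, 1L, 3L) != "ATG") format_error("CDS must begin with ATG")
  if (grepl("[^ACGT]", cds)) format_error("CDS may contain only A/C/G/T")
  structure(list(gene = gene, cds = cds), class = "coding_sequence")
}

#' Read coding sequences from a FASTA file
#'
#' One record per gene; record names are taken as gene symbols.
#'
#' @param path FASTA path
#' @return named list of [coding_sequence()] objects
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    coding_sequence(names(seqs)[i], as.character(seqs[[i]]))
  })
  names(out) <- names(seqs)
  out
}

#' Map a cDNA substitution to its protein consequence
#'
#' Given a 1-based cDNA position within the CDS and a reference/alternate
#' base pair, computes the affected codon index
#' (`floor((position - 1) / 3) + 1`) and the reference and substituted
#' amino acids under the standard genetic code.
#'
#' @param cds a [coding_sequence()] or a plain CDS string
#' @param position 1-based position within the CDS
#' @param ref_base,alt_base single bases; `ref_base` must match the CDS
#' @return a `protein_change` list with elements `ref_aa`, `codon_index`,
#'   `alt_aa` (one-letter codes, `*` = stop)
#' @examples
#' cds <- coding_sequence("TOY", paste0("ATG", "CAC", "TAA"))
#' annotate_cds_change(cds, 4, "C", "T")  # His2Tyr
#' @export
annotate_cds_change <- function(cds, position, ref_base, alt_base) {
  seq <- if (inherits(cds, "coding_sequence")) cds$cds else toupper(cds)
  n <- nchar(seq)
  if (position < 1 || position > n) {
    abort(sprintf("position %d outside CDS of length %d", position, n),
          "autozyg_bounds_error")
  }
  found <- substr(seq, position, position)
  if (found != toupper(ref_base)) {
    abort(sprintf("reference mismatch at position %d: CDS has %s, not %s",
                  position, found, ref_base),
          "autozyg_reference_mismatch")
  }
  codon_index <- (position - 1L) %/% 3L + 1L
  codon_start <- 3L * (codon_index - 1L) + 1L
  ref_codon <- substr(seq, codon_start, codon_start + 2L)
  offset <- position - codon_start + 1L
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- toupper(alt_base)
  code <- Biostrings::GENETIC_CODE
  structure(list(ref_aa = unname(code[[ref_codon]]),
                 codon_index = as.integer(codon_index),
                 alt_aa = unname(code[[alt_codon]])),
            class = "protein_change")
}

#' @rdname annotate_cds_change
#' @param x a `protein_change`
#' @return `format_protein_change()`: the HGVS p.-string, e.g.
#'   `"p.His477Tyr"`
#' @export
format_protein_change <- function(x) {
  sprintf("p.%s%d%s", AA_THREE[[x$ref_aa]], x$codon_index,
          AA_THREE[[x$alt_aa]])
}

#' @export
print.protein_change <- function(x, ...) {
  cat(format_protein_change(x), "\n")
  invisible(x)
}
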