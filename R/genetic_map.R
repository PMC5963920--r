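# bp <-> cM conversion. The genetic length criterion that defines a
# confident IBD block (default minimum 5 cM) needs physical positions
# expressed on the genetic map; when no map anchors are available a
# genome-average fallback rate (default 1 cM/Mb) is used instead.

#' Construct a genetic map
#'
#' @param anchors data.frame with columns `chromosome`, `position_bp`,
#'   `cM`; within each chromosome anchors are sorted by bp and cM must be
#'   non-decreasing in bp. May have zero rows.
#' @param fallback_rate_cM_per_Mb positive rate used for chromosomes
#'   without anchors (default 1 cM/Mb, the genome-wide average)
#' @return a `genetic_map`
#' @export
genetic_map <- function(anchors = NULL, fallback_rate_cM_per_Mb = 1.0) {
  if (is.null(anchors)) {
    anchors <- data.frame(chromosome = character(), position_bp = numeric(),
                          cM = numeric())
  }
  anchors <- as.data.frame(anchors)
  stopifnot(all(c("chromosome", "position_bp", "cM") %in% names(anchors)),
            fallback_rate_cM_per_Mb > 0)
  anchors <- anchors[order(anchors$chromosome, anchors$position_bp), ,
                     drop = FALSE]
  rownames(anchors) <- NULL
  for (ch in unique(anchors$chromosome)) {
    cm <- anchors$cM[anchors$chromosome == ch]
    if (is.unsorted(cm)) {
      format_error(sprintf("cM must be non-decreasing in bp on chromosome %s",
                           ch))
    }
  }
  structure(list(anchors = anchors,
                 fallback_rate_cM_per_Mb = fallback_rate_cM_per_Mb),
            class = "genetic_map")
}

#' Read a genetic map from a TSV of anchors
#'
#' Expects columns chromosome, position_bp, cM (no header needed when
#' exactly three columns; a header line is detected and skipped).
#'
#' @param path file path
#' @param fallback_rate_cM_per_Mb see [genetic_map()]
#' @export
read_genetic_map <- function(path, fallback_rate_cM_per_Mb = 1.0) {
  if (!file.exists(path)) format_error(paste("no such file:", path))
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- length(first) >= 2L && grepl("[A-Za-z]", first[2])
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          colClasses = "character")
  if (ncol(df) != 3L) format_error("genetic map must have 3 columns")
  names(df) <- c("chromosome", "position_bp", "cM")
  df$position_bp <- as.numeric(df$position_bp)
  df$cM <- as.numeric(df$cM)
  genetic_map(df, fallback_rate_cM_per_Mb)
}

#' Interpolate a genetic position (cM) from a physical position (bp)
#'
#' Piecewise-linear interpolation between flanking anchors of the marker's
#' chromosome. Outside the anchor range, linear extrapolation continues at
#' the rate of the nearest anchor interval. A chromosome with no anchors
#' falls back to `position_bp * fallback_rate / 1e6`; with a single anchor
#' the fallback rate is applied relative to that anchor. The result is
#' non-decreasing in `position_bp` on every chromosome.
#'
#' @param map a `genetic_map`
#' @param chromosome chromosome label (matched literally)
#' @param position_bp numeric vector of positions (>= 1)
#' @return numeric vector of cM positions
#' @examples
#' gm <- genetic_map(data.frame(chromosome = "1",
#'                              position_bp = c(1e6, 3e6), cM = c(1, 3)))
#' interpolate_genetic_position(gm, "1", 2e6)  # 2 cM
#' @export
interpolate_genetic_position <- function(map, chromosome, position_bp) {
  stopifnot(inherits(map, "genetic_map"), all(position_bp >= 1))
  a <- map$anchors[map$anchors$chromosome == chromosome, , drop = FALSE]
  rate_mb <- map$fallback_rate_cM_per_Mb
  if (nrow(a) == 0L) {
    return(position_bp * rate_mb / 1e6)
  }
  if (nrow(a) == 1L) {
    return(a$cM[1] + (position_bp - a$position_bp[1]) * rate_mb / 1e6)
  }
  bp <- a$position_bp
  cm <- a$cM
  n <- length(bp)
  i <- findInterval(position_bp, bp)
  # interval index used for the local rate: clamp to [1, n-1]
  k <- pmin(pmax(i, 1L), n - 1L)
  slope <- (cm[k + 1L] - cm[k]) / (bp[k + 1L] - bp[k])
  slope[!is.finite(slope)] <- 0
  cm[k] + (position_bp - bp[k]) * slope
}
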