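# Shared fixtures and independent oracles for the test suite.

# ---- toy genotype datasets ------------------------------------------------

# Build a genotype_dataset from two-character call strings ("AA", "AG",
# NA for missing), one column per sample. `calls` is a character matrix.
toy_dataset <- function(calls, positions = NULL, chromosome = "1",
                        samples = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(calls)))
  if (is.null(positions)) positions <- seq_len(nrow(calls)) * 1e5
  a1 <- substr(calls, 1, 1)
  a2 <- substr(calls, 2, 2)
  markers <- data.frame(
    id = paste0("m", seq_len(nrow(calls))),
    chromosome = rep_len(chromosome, nrow(calls)),
    position_bp = positions
  )
  genotype_dataset(markers, samples, a1, a2)
}

# Encode a state string for the run finder: h = hom, e = het, m = missing.
states_from_string <- function(s) {
  map <- c(h = 0L, e = 1L, m = 2L)
  unname(map[strsplit(s, "")[[1]]])
}

# Random call column over given per-marker hom/het/missing probabilities;
# returns two-character strings.
random_calls <- function(n, p_hom = 0.6, p_het = 0.3) {
  r <- runif(n)
  out <- character(n)
  out[r < p_hom] <- sample(c("AA", "GG"), sum(r < p_hom), replace = TRUE)
  het <- r >= p_hom & r < p_hom + p_het
  out[het] <- "AG"
  out[r >= p_hom + p_het] <- NA_character_
  out
}

# ---- brute-force maximal-run oracle ---------------------------------------

# Enumerates every qualifying window directly from the definition using
# whole-matrix prefix counts, then removes windows strictly contained in
# another qualifying window. Independent of the two-pointer scan used by
# the package.
oracle_maximal_runs <- function(states, max_het, max_missing) {
  n <- length(states)
  pre <- function(x) c(0L, cumsum(x))
  ch <- pre(states == 1L); cm <- pre(states == 2L); cb <- pre(states == 3L)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  ok <- j >= i &
    matrix(states == 0L, n, n) & t(matrix(states == 0L, n, n)) &
    (cb[j + 1L] - cb[i]) == 0L &
    (ch[j + 1L] - ch[i]) <= max_het &
    (cm[j + 1L] - cm[i]) <= max_missing
  # count of qualifying windows (i', j') with i' <= i and j' >= j:
  # cumulative sums down rows and leftwards over columns
  cnt <- apply(ok, 2, cumsum)
  cnt <- t(apply(t(cnt), 2, function(x) rev(cumsum(rev(x)))))
  maximal <- ok & (cnt - ok) == 0
  w <- which(maximal, arr.ind = TRUE)
  w <- w[order(w[, 1]), , drop = FALSE]
  data.frame(start = as.integer(w[, 1]), end = as.integer(w[, 2]))
}

# ---- misc -----------------------------------------------------------------

jaccard_bp <- function(a1, a2, b1, b2) {
  i <- max(0, min(a2, b2) - max(a1, b1) + 1)
  u <- (a2 - a1 + 1) + (b2 - b1 + 1) - i
  i / u
}

covered_bp <- function(regions) {
  if (nrow(regions) == 0L) return(0)
  sum(regions$end_bp - regions$start_bp + 1)
}

# A small, fast simulation configuration for unit tests.
small_sim_config <- function(seed, ...) {
  simulation_config(n_markers = 600L, chromosome_length_bp = 60e6,
                    seed = seed, ...)
}
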