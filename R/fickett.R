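# Fickett (1982) TESTCODE lookup tables. For each base, a "position" value
# (asymmetry of base usage across the three codon positions) and a "content"
# value (overall base fraction) are mapped to empirical coding probabilities
# through interval lookup, then combined as a weighted sum over the eight
# parameters. Values below are the published tables.

.fickett_position_prob <- rbind(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_position_cut <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1)

.fickett_content_prob <- rbind(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickett_content_cut <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17)

# First bin whose cut-off the value meets (cuts descending); bin 10 otherwise.
.fickett_bin <- function(value, cuts) {
  i <- which(value >= cuts)
  if (length(i)) i[1L] else 10L
}

#' Fickett TESTCODE statistic
#'
#' Computes the classical TESTCODE score: for each base, the positional
#' asymmetry `max(c1,c2,c3)/(min(c1,c2,c3)+1)` over the three frame positions
#' of the full sequence, and the overall base fraction, are each converted to
#' a coding probability via the published lookup tables and combined as a
#' weighted sum of the eight parameters. `N` bases are excluded from all
#' counts and denominators. An all-`N` sequence gets the score implied by
#' zero counts (every parameter falls in its lowest-evidence bin) and raises
#' a warning.
#'
#' @param seq A single sequence (character, `DNAString`, or length-1
#'   `DNAStringSet`) of length >= 2; scores are most meaningful for
#'   sequences >= 200 nt.
#' @return A numeric score, bounded by the extremes attainable from the
#'   lookup tables (roughly 0.26 to 1.37).
#' @export
fickett_score <- function(seq) {
  s <- as_single_sequence(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  keep <- chars %in% c("A", "C", "G", "T")
  n_acgt <- sum(keep)
  if (n_acgt == 0L) {
    warning("sequence has no unambiguous bases; returning the zero-count Fickett score")
  }
  pos <- (seq_along(chars) - 1L) %% 3L + 1L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(1:3, function(p) sum(chars == b & pos == p), integer(1))
    posval <- max(cnt) / (min(cnt) + 1)
    content <- if (n_acgt > 0L) sum(cnt) / n_acgt else 0
    score <- score +
      .fickett_position_prob[b, .fickett_bin(posval, .fickett_position_cut)] *
        .fickett_position_weight[[b]] +
      .fickett_content_prob[b, .fickett_bin(content, .fickett_content_cut)] *
        .fickett_content_weight[[b]]
  }
  unname(score)
}
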