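# Independent reference implementations used to cross-check the package.
# These are deliberately naive (nested loops, per-base bitmaps, all-pairs
# scans) and share no code with the implementation under test.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# Longest ORF by testing every ATG start against its first in-frame stop,
# walking codon by codon, in all three forward frames.
oracle_longest_orf <- function(s) {
  n <- nchar(s)
  best <- 0L
  i <- 1L
  while (i + 5L <= n) {
    if (substring(s, i, i + 2L) == "ATG") {
      j <- i + 3L
      while (j + 2L <= n) {
        if (substring(s, j, j + 2L) %in% ORACLE_STOPS) {
          len <- j + 2L - i + 1L
          if (len > best) best <- len
          break
        }
        j <- j + 3L
      }
    }
    i <- i + 1L
  }
  best
}

random_seq <- function(len, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
    collapse = ""
  )
}

# Straight-from-the-published-tables Fickett TESTCODE reference (scalar,
# if-chain binning; tables re-entered independently of the package copy).
oracle_fickett <- function(s) {
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
  )
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  con_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
  )
  con_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  pos_cut <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1)
  con_cut <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17)
  bin <- function(v, cuts) {
    for (k in seq_along(cuts)) if (v >= cuts[k]) return(k)
    10L
  }
  chars <- strsplit(toupper(s), "")[[1]]
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    c1 <- sum(chars == b & (seq_along(chars) %% 3) == 1)
    c2 <- sum(chars == b & (seq_along(chars) %% 3) == 2)
    c3 <- sum(chars == b & (seq_along(chars) %% 3) == 0)
    pv <- max(c1, c2, c3) / (min(c1, c2, c3) + 1)
    cv <- if (n_acgt > 0) (c1 + c2 + c3) / n_acgt else 0
    total <- total + pos_prob[[b]][bin(pv, pos_cut)] * pos_w[[b]] +
      con_prob[[b]][bin(cv, con_cut)] * con_w[[b]]
  }
  total
}

# Naive substring recount of hexamer frequencies (step 3 from position 1).
oracle_hexamer_counts <- function(seqs) {
  counts <- integer(0)
  for (s in seqs) {
    i <- 1L
    while (i + 5L <= nchar(s)) {
      h <- substring(s, i, i + 5L)
      if (!grepl("N", h, fixed = TRUE)) {
        counts[h] <- (if (is.na(counts[h])) 0L else counts[h]) + 1L
      }
      i <- i + 3L
    }
  }
  counts
}

# Per-base bitmap computation of exonic overlap fraction on a small toy
# chromosome (coordinates must stay below `size`).
oracle_bitmap_fraction <- function(exon_df, blocker_df, size = 100000L) {
  cand <- logical(size)
  for (r in seq_len(nrow(exon_df))) {
    cand[exon_df$start[r]:exon_df$end[r]] <- TRUE
  }
  blk <- logical(size)
  if (nrow(blocker_df)) {
    for (r in seq_len(nrow(blocker_df))) {
      blk[blocker_df$start[r]:blocker_df$end[r]] <- TRUE
    }
  }
  sum(cand & blk) / sum(cand)
}

# AUROC as the fraction of correctly ordered (positive, negative) pairs,
# ties counted 0.5, by explicit enumeration.
oracle_auroc_pairs <- function(pos, scores) {
  p <- scores[pos]
  q <- scores[!pos]
  tot <- 0
  for (a in p) {
    tot <- tot + sum(a > q) + 0.5 * sum(a == q)
  }
  tot / (length(p) * length(q))
}

# All-pairs minimum gap distance between two interval sets on one chrom.
oracle_min_gap <- function(q_start, q_end, f_start, f_end) {
  best <- Inf
  for (i in seq_along(f_start)) {
    if (f_start[i] > q_end) {
      d <- f_start[i] - q_end - 1L
    } else if (q_start > f_end[i]) {
      d <- q_start - f_end[i] - 1L
    } else {
      d <- 0L
    }
    best <- min(best, d)
  }
  best
}

# Small labeled random evaluation fixture with score ties.
random_eval_fixture <- function(n) {
  labels <- sample(c("coding", "lncRNA"), n, replace = TRUE)
  while (length(unique(labels)) < 2L) {
    labels <- sample(c("coding", "lncRNA"), n, replace = TRUE)
  }
  scores <- round(runif(n), 1)  # coarse grid forces ties
  list(labels = labels, scores = scores, pos = labels == "lncRNA")
}
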