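#' Names and order of the classifier's sequence features
#'
#' The fixed, versioned 21-feature registry used by [featurize()] and
#' recorded in every trained model. Order matters: model files store this
#' vector and [predict_score()] refuses matrices whose columns disagree.
#'
#' @return Character vector of length 21.
#' @export
feature_names <- function() {
  c(
    "log10_length", "gc_content", "gc1", "gc2", "gc3",
    "longest_orf_len", "orf_coverage", "second_orf_len", "orf_len_ratio",
    "orf_count", "fickett_full", "fickett_orf", "hexamer_orf",
    "hexamer_full", "freq_A", "freq_C", "freq_G", "freq_T",
    "cpg_oe", "tri_entropy", "stop_density"
  )
}

#' Extract the 21-feature vector of one transcript
#'
#' Computes the fixed feature registry for a single sequence: length and
#' composition (`log10_length`, `gc_content`, per-base frequencies,
#' `cpg_oe`, `tri_entropy`), ORF structure (longest/second ORF lengths,
#' coverage, ratio, count of ORFs >= 75 nt, codon-position GC of the longest
#' ORF, pooled stop-codon density over the three forward frames), the
#' Fickett TESTCODE statistic of the full sequence and of the longest ORF,
#' and hexamer bias scores of the longest ORF (in-frame) and full sequence
#' (sliding). ORF-dependent features are 0 when the sequence has no ORF.
#' `N` bases are excluded from composition denominators. The function is
#' pure: identical inputs give bit-identical vectors.
#'
#' @param seq A single sequence.
#' @param table A trained [hexamer_table][train_hexamer_table].
#' @return Named numeric vector of length 21 in [feature_names()] order;
#'   never contains `NA`/`NaN`.
#' @export
featurize <- function(seq, table) {
  m <- featurize_corpus(as_transcript_set(stats::setNames(
    as_single_sequence(seq), "x"
  )), table)
  m[1L, ]
}

#' Extract feature vectors for a set of transcripts
#'
#' @param x Sequences (`DNAStringSet` or named character vector).
#' @param table A trained [hexamer_table][train_hexamer_table].
#' @param min_orf_count_len Minimum ORF length (nt) counted by the
#'   `orf_count` feature; 75 nt (25 codons) is a conventional noise floor.
#' @return Numeric matrix, one row per transcript (rownames = ids), columns
#'   = [feature_names()].
#' @export
featurize_corpus <- function(x, table, min_orf_count_len = 75L) {
  stopifnot(inherits(table, "hexamer_table"))
  x <- as_transcript_set(x)
  n <- length(x)
  feats <- matrix(0, nrow = n, ncol = 21L,
    dimnames = list(names(x), feature_names())
  )
  if (n == 0L) return(feats)

  len <- Biostrings::width(x)
  lf <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  acgt <- rowSums(lf)
  tri <- Biostrings::oligonucleotideFrequency(x, 3L, step = 1L)
  din_cg <- Biostrings::oligonucleotideFrequency(x, 2L, step = 1L)[, "CG"]

  feats[, "log10_length"] <- log10(len)
  feats[, "gc_content"] <- ifelse(acgt > 0, (lf[, "C"] + lf[, "G"]) / acgt, 0)
  for (b in c("A", "C", "G", "T")) {
    feats[, paste0("freq_", b)] <- ifelse(acgt > 0, lf[, b] / acgt, 0)
  }
  cg_denom <- lf[, "C"] * lf[, "G"]
  feats[, "cpg_oe"] <- ifelse(cg_denom > 0, din_cg * acgt / cg_denom, 0)
  tri_tot <- rowSums(tri)
  p <- tri / pmax(tri_tot, 1L)
  plogp <- p * log2(p)
  plogp[!is.finite(plogp)] <- 0
  feats[, "tri_entropy"] <- -rowSums(plogp)

  seqs <- as.character(x)
  n_flagged <- 0L
  for (i in seq_len(n)) {
    s <- seqs[i]
    orfs <- find_orfs(s, min_len_nt = 6L)
    lo <- if (nrow(orfs) >= 1L) orfs$length_nt[1L] else 0L
    so <- if (nrow(orfs) >= 2L) orfs$length_nt[2L] else 0L
    feats[i, "longest_orf_len"] <- lo
    feats[i, "second_orf_len"] <- so
    feats[i, "orf_coverage"] <- lo / len[i]
    feats[i, "orf_len_ratio"] <- if (lo > 0L) so / lo else 0
    feats[i, "orf_count"] <- sum(orfs$length_nt >= min_orf_count_len)
    feats[i, "fickett_full"] <- fickett_score(s)
    feats[i, "hexamer_full"] <- hexamer_score(s, table, "full", quiet = TRUE)
    feats[i, "stop_density"] <- stop_codon_density(s)
    if (lo > 0L) {
      orf <- substring(s, orfs$start[1L], orfs$end[1L])
      feats[i, c("gc1", "gc2", "gc3")] <- codon_position_gc(orf)
      feats[i, "fickett_orf"] <- fickett_score(orf)
      feats[i, "hexamer_orf"] <- hexamer_score(s, table, "longest_orf",
        quiet = TRUE
      )
    } else {
      n_flagged <- n_flagged + 1L
    }
  }
  if (n_flagged > 0L) {
    message(
      n_flagged, " of ", n,
      " transcripts have no ORF; ORF-dependent features set to 0"
    )
  }
  if (any(!is.finite(feats))) {
    bad <- rownames(feats)[rowSums(!is.finite(feats)) > 0]
    stop("non-finite features for: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  feats
}

# GC fraction at each codon position of an ORF sequence (N excluded).
codon_position_gc <- function(orf) {
  chars <- strsplit(orf, "", fixed = TRUE)[[1L]]
  pos <- (seq_along(chars) - 1L) %% 3L + 1L
  vapply(1:3, function(p) {
    cc <- chars[pos == p]
    cc <- cc[cc %in% c("A", "C", "G", "T")]
    if (!length(cc)) return(0)
    mean(cc %in% c("G", "C"))
  }, numeric(1))
}

# Stop-codon frequency pooled over the 3 forward frames.
stop_codon_density <- function(s) {
  n <- nchar(s)
  stops <- 0L
  total <- 0L
  for (f in 0:2) {
    if (n - f < 3L) next
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    stops <- stops + sum(codons %in% STOP_CODONS)
    total <- total + length(codons)
  }
  if (total == 0L) 0 else stops / total
}

#' Write a feature matrix as TSV
#'
#' Header = `transcript_id` + feature names, one row per transcript.
#'
#' @param feats Matrix from [featurize_corpus()].
#' @param path Output path.
#' @export
write_feature_matrix <- function(feats, path) {
  df <- data.frame(
    transcript_id = rownames(feats), feats,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
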