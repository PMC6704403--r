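#' Default codon-bias table for the coding-sequence generator
#'
#' Within each amino-acid group, G/C-ending codons are weighted 3:1 over
#' A/T-ending ones, giving generated coding ORFs a pronounced, realistic
#' codon / hexamer usage bias without tying the generator to any one
#' genome's usage table. Weights sum to 1 per amino-acid group.
#'
#' @return Named numeric vector over the 61 sense codons.
#' @export
default_codon_bias <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  w <- ifelse(substr(sense, 3, 3) %in% c("G", "C"), 3, 1)
  aa <- gc[sense]
  for (a in unique(aa)) {
    idx <- aa == a
    w[idx] <- w[idx] / sum(w[idx])
  }
  stats::setNames(w, sense)
}

# Draw one biased codon sequence of k codons (amino acids uniform over the
# 20, codons by the per-amino-acid bias weights).
sample_biased_codons <- function(k, bias) {
  gc <- Biostrings::GENETIC_CODE
  aa_of <- gc[names(bias)]
  aas <- sample(unique(aa_of), k, replace = TRUE)
  out <- character(k)
  for (a in unique(aas)) {
    idx <- which(aas == a)
    codons <- names(bias)[aa_of == a]
    out[idx] <- sample(codons, length(idx), replace = TRUE,
      prob = bias[codons])
  }
  out
}

random_nt <- function(n, prob = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
}

#' Generate a synthetic coding-transcript corpus
#'
#' Each sequence is `5'UTR + ATG + (>= 100 biased codons) + stop + 3'UTR`,
#' so the longest ORF is at least 303 nt by construction. Codons are drawn
#' from a per-amino-acid bias table (default: G/C-ending codons favoured
#' 3:1), giving the corpus a hexamer profile distinct from random sequence.
#' Deterministic for a fixed seed.
#'
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @param n_codons Integer range (min, max) of biased codons per CDS;
#'   minimum must be >= 100.
#' @param utr5,utr3 Integer ranges of UTR lengths.
#' @param bias Codon-bias weights summing to 1 per amino-acid group
#'   (default [default_codon_bias()]).
#' @return Named `DNAStringSet` (`coding_0001`, ...).
#' @export
make_coding_corpus <- function(n = 2000L, seed = 1L,
                               n_codons = c(100L, 350L),
                               utr5 = c(20L, 200L), utr3 = c(50L, 500L),
                               bias = default_codon_bias()) {
  stopifnot(n >= 0, n_codons[1] >= 100L, n_codons[1] <= n_codons[2])
  check_bias_table(bias)
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    k <- sample(n_codons[1]:n_codons[2], 1L)
    paste0(
      random_nt(sample(utr5[1]:utr5[2], 1L)),
      "ATG",
      paste(sample_biased_codons(k, bias), collapse = ""),
      sample(STOP_CODONS, 1L),
      random_nt(sample(utr3[1]:utr3[2], 1L))
    )
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(
    seqs, sprintf("coding_%04d", seq_len(n))
  ))
}

check_bias_table <- function(bias) {
  gc <- Biostrings::GENETIC_CODE
  if (!all(names(bias) %in% names(gc)) || any(gc[names(bias)] == "*")) {
    stop("bias table must cover sense codons only")
  }
  sums <- tapply(bias, gc[names(bias)], sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("codon-bias weights must sum to 1 within each amino-acid group")
  }
  invisible(bias)
}

#' Generate a synthetic non-coding transcript corpus
#'
#' Sequences are drawn from a slightly AT-rich composition and
#' rejection-sampled so that the longest forward-strand ORF is shorter than
#' `max_orf` nt, emulating transcripts without long reading frames.
#'
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @param length_range Integer range (min, max) of sequence lengths.
#' @param max_orf Longest tolerated ORF (nt, exclusive bound).
#' @param composition Base probabilities (named A/C/G/T).
#' @param max_tries Rejection budget per sequence.
#' @return Named `DNAStringSet` (`noncoding_0001`, ...).
#' @export
make_noncoding_corpus <- function(n = 2000L, seed = 2L,
                                  length_range = c(200L, 2000L),
                                  max_orf = 150L,
                                  composition = c(
                                    A = 0.30, C = 0.20, G = 0.20, T = 0.30
                                  ),
                                  max_tries = 100L) {
  stopifnot(n >= 0, max_orf >= 0, length_range[1] >= 10L)
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    len <- sample(length_range[1]:length_range[2], 1L)
    for (try in seq_len(max_tries)) {
      s <- random_nt(len, composition)
      orfs <- find_orfs(s, min_len_nt = 6L)
      if (nrow(orfs) == 0L || orfs$length_nt[1] < max_orf) return(s)
    }
    stop(
      "rejection budget exceeded while sampling a non-coding sequence; ",
      "loosen max_orf or shorten length_range"
    )
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(
    seqs, sprintf("noncoding_%04d", seq_len(n))
  ))
}

#' Build the toy genome annotation and planted filter fixture
#'
#' Emits a reference annotation (two protein-coding genes, one tRNA gene,
#' one pseudogene on a 2 x 100 kb toy genome) and a set of candidate
#' transcripts planted to exercise every sieve of [filter_candidates()],
#' together with the machine-readable expected outcome of each candidate.
#' The default scenario set plants 10 candidates: 2 clean keepers (one of
#' them exactly 201 bp, the boundary of the `> 200` gate), 2 too-short (one
#' exactly 200 bp), 2 classifier-rejected, 2 single-exon overlaps of the
#' artificial-coding mask, 1 multi-exon candidate with exactly 30% overlap,
#' and 1 tRNA-overlapping candidate. An optional `multi_exon_20` scenario
#' plants a multi-exon candidate with exactly 20% overlap (kept under the
#' `> 25%` rule). Expected overlap fractions are derived from the planted
#' geometry with `ext5 = 160`, `ext3 = 792`.
#'
#' @param scenarios Character vector of scenario names to plant (see
#'   Details in the source; default = the 10-candidate fixture).
#' @return A list with `candidates` and `reference` ([transcript_models]),
#'   `scores` (named numeric, the planted classifier scores), and `truth`
#'   (`data.frame` of expected outcome, reason and overlap fraction per
#'   candidate).
#' @export
make_toy_annotation <- function(scenarios = c(
                                  "clean_201", "clean_multi",
                                  "short_150", "short_200",
                                  "coding_low", "coding_mid",
                                  "single_exon_overlap_a",
                                  "single_exon_overlap_b",
                                  "multi_exon_30", "trna_overlap"
                                )) {
  ref_tx <- data.frame(
    transcript_id = c("PC1.1", "PC2.1", "TR1.1", "PS1.1"),
    gene_id = c("PC1", "PC2", "TR1", "PS1"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "+", "+", "+"),
    biotype = c("protein_coding", "protein_coding", "tRNA", "pseudogene"),
    cds_start = c(10501L, 30201L, NA, NA),
    cds_end = c(11500L, 30800L, NA, NA),
    stringsAsFactors = FALSE
  )
  ref_exons <- GenomicRanges::GRangesList(
    PC1.1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 12000), "+"),
    PC2.1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(30001, 31000), "+"),
    TR1.1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, 50072), "+"),
    PS1.1 = GenomicRanges::GRanges("chr2", IRanges::IRanges(40001, 41000), "+")
  )
  reference <- transcript_models(ref_tx, ref_exons)

  # Artificial coding mask for ext5=160/ext3=792 (+ strand):
  #   PC1.1: 10501..11500 -> 10341..12292
  #   PC2.1: 30201..30800 -> 30041..31592
  plant <- list(
    clean_201 = list(
      chrom = "chr2", exons = IRanges::IRanges(10001, 10201), score = 0.95,
      outcome = "kept", reason = NA, frac = 0
    ),
    clean_multi = list(
      chrom = "chr2",
      exons = IRanges::IRanges(c(60001, 61001), c(60400, 61400)),
      score = 0.95, outcome = "kept", reason = NA, frac = 0
    ),
    short_150 = list(
      chrom = "chr1", exons = IRanges::IRanges(80001, 80150), score = 0.95,
      outcome = "removed", reason = "too_short", frac = NA
    ),
    short_200 = list(
      chrom = "chr1", exons = IRanges::IRanges(80501, 80700), score = 0.95,
      outcome = "removed", reason = "too_short", frac = NA
    ),
    coding_low = list(
      chrom = "chr2", exons = IRanges::IRanges(20001, 20600), score = 0.10,
      outcome = "removed", reason = "predicted_coding", frac = NA
    ),
    coding_mid = list(
      chrom = "chr2",
      exons = IRanges::IRanges(c(25001, 26001), c(25300, 26300)),
      score = 0.40, outcome = "removed", reason = "predicted_coding", frac = NA
    ),
    single_exon_overlap_a = list(
      chrom = "chr1", exons = IRanges::IRanges(12200, 12800), score = 0.95,
      outcome = "removed", reason = "overlaps_artificial_coding",
      frac = 93 / 601
    ),
    single_exon_overlap_b = list(
      chrom = "chr1", exons = IRanges::IRanges(10200, 10400), score = 0.95,
      outcome = "removed", reason = "overlaps_artificial_coding",
      frac = 60 / 201
    ),
    multi_exon_30 = list(
      chrom = "chr1",
      exons = IRanges::IRanges(c(11993, 20001), c(12292, 20700)),
      score = 0.95, outcome = "removed",
      reason = "overlaps_artificial_coding", frac = 0.30
    ),
    multi_exon_20 = list(
      chrom = "chr1",
      exons = IRanges::IRanges(c(12093, 21001), c(12292, 21800)),
      score = 0.95, outcome = "kept", reason = NA, frac = 0.20
    ),
    trna_overlap = list(
      chrom = "chr1", exons = IRanges::IRanges(50050, 50500), score = 0.95,
      outcome = "removed", reason = "overlaps_other_ncRNA", frac = 0
    )
  )
  unknown <- setdiff(scenarios, names(plant))
  if (length(unknown)) {
    stop("unknown layout scenarios: ", paste(unknown, collapse = ", "))
  }
  plant <- plant[scenarios]

  cand_ids <- paste0("cand_", names(plant))
  cand_tx <- data.frame(
    transcript_id = cand_ids,
    gene_id = paste0("g_", names(plant)),
    chrom = vapply(plant, `[[`, character(1), "chrom"),
    strand = "+",
    biotype = "other",
    stringsAsFactors = FALSE
  )
  cand_exons <- GenomicRanges::GRangesList(stats::setNames(
    lapply(plant, function(p) {
      GenomicRanges::GRanges(p$chrom, p$exons, "+")
    }),
    cand_ids
  ))
  candidates <- transcript_models(cand_tx, cand_exons)
  truth <- data.frame(
    id = cand_ids,
    scenario = names(plant),
    score = vapply(plant, `[[`, numeric(1), "score"),
    expected_outcome = vapply(plant, `[[`, character(1), "outcome"),
    expected_reason = vapply(plant, function(p) {
      if (is.na(p$reason[1])) NA_character_ else p$reason
    }, character(1)),
    expected_fraction = vapply(plant, function(p) {
      as.numeric(p$frac)
    }, numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(
    candidates = candidates,
    reference = reference,
    scores = stats::setNames(truth$score, truth$id),
    truth = truth
  )
}

#' Generate an expression matrix with planted specificity patterns
#'
#' Transcripts are assigned one of five patterns: `pure_a` (expressed only
#' in organ A), `pure_b` (only organ B), `shared_ab` (equally in both
#' organs), `broad` (uniform across all tissues) and `silent` (all zero).
#' Per-sample values are the pattern mean multiplied by lognormal noise
#' (`exp(rnorm(0, sigma))` on the natural-log scale, multiplicative on the
#' linear TPM scale, matching the `log2(x + 1)` analysis scale); zeros stay
#' exactly zero. The returned truth table records the preference group each
#' pattern is designed to produce (`pure_a` -> A-preferential, `pure_b` ->
#' B, `shared_ab` -> joint, `broad`/`silent` -> none).
#'
#' @param n Number of transcripts.
#' @param seed Integer seed.
#' @param tissues Tissue names; the first two are the organs of interest.
#' @param organ_a,organ_b Organ tissue labels (must be in `tissues`).
#' @param reps Samples per tissue.
#' @param proportions Named pattern proportions summing to <= 1 (remainder
#'   goes to `broad`).
#' @param sigma Log-scale noise standard deviation.
#' @param on_mean,shared_mean,broad_mean Pattern mean TPM values.
#' @return List with `em` (an [expression_matrix]) and `truth`
#'   (`data.frame` of transcript id, pattern and expected preference group).
#' @export
make_expression_matrix <- function(n = 1000L, seed = 1L,
                                   tissues = c(
                                     "VNO", "MOE", "brain", "cerebellum",
                                     "cortex", "heart", "kidney", "liver"
                                   ),
                                   organ_a = "VNO", organ_b = "MOE",
                                   reps = 3L,
                                   proportions = c(
                                     pure_a = 0.2, pure_b = 0.2,
                                     shared_ab = 0.2, broad = 0.3,
                                     silent = 0.1
                                   ),
                                   sigma = 0.1, on_mean = 100,
                                   shared_mean = 50, broad_mean = 20) {
  stopifnot(
    length(tissues) >= 2L, all(c(organ_a, organ_b) %in% tissues),
    sum(proportions) <= 1 + 1e-9, sigma >= 0
  )
  set.seed(seed)
  counts <- floor(proportions * n + 0.5)
  counts["broad"] <- counts["broad"] + (n - sum(counts))
  pattern <- rep(names(counts), counts)

  means <- matrix(0, nrow = n, ncol = length(tissues),
    dimnames = list(NULL, tissues)
  )
  means[pattern == "pure_a", organ_a] <- on_mean
  means[pattern == "pure_b", organ_b] <- on_mean
  means[pattern == "shared_ab", organ_a] <- shared_mean
  means[pattern == "shared_ab", organ_b] <- shared_mean
  means[pattern == "broad", ] <- broad_mean

  samples <- paste0(rep(tissues, each = reps), "_", seq_len(reps))
  tissue_map <- stats::setNames(rep(tissues, each = reps), samples)
  vals <- matrix(0, nrow = n, ncol = length(samples),
    dimnames = list(sprintf("tx_%04d", seq_len(n)), samples)
  )
  for (j in seq_along(samples)) {
    mu <- means[, tissue_map[samples[j]]]
    noise <- exp(stats::rnorm(n, mean = 0, sd = sigma))
    vals[, j] <- mu * noise
  }
  expected <- c(
    pure_a = paste0(organ_a, "_pref"),
    pure_b = paste0(organ_b, "_pref"),
    shared_ab = paste0(organ_a, "+", organ_b, "_pref"),
    broad = "none", silent = "none"
  )
  list(
    em = expression_matrix(vals, tissue_map),
    truth = data.frame(
      transcript_id = rownames(vals),
      pattern = pattern,
      expected_group = unname(expected[pattern]),
      stringsAsFactors = FALSE
    )
  )
}

#' Write an expression matrix and tissue map as TSV files
#'
#' @param em An [expression_matrix].
#' @param matrix_path Abundance TSV path (rows = transcripts, columns =
#'   samples).
#' @param tissues_path Two-column sample-to-tissue TSV path.
#' @export
write_expression_tsv <- function(em, matrix_path, tissues_path) {
  df <- data.frame(
    transcript_id = rownames(em$values), em$values,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, matrix_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(sample = names(em$tissues), tissue = unname(em$tissues)),
    tissues_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(matrix_path)
}

#' Read an expression matrix and tissue map from TSV files
#'
#' @param matrix_path Abundance TSV (first column = transcript id).
#' @param tissues_path Two-column sample/tissue TSV.
#' @param tx2gene_path Optional two-column transcript/gene TSV.
#' @return An [expression_matrix].
#' @export
read_expression_tsv <- function(matrix_path, tissues_path,
                                tx2gene_path = NULL) {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
    stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  tdf <- utils::read.delim(tissues_path, stringsAsFactors = FALSE)
  tissues <- stats::setNames(tdf[[2]], tdf[[1]])
  tx2gene <- NULL
  if (!is.null(tx2gene_path)) {
    gdf <- utils::read.delim(tx2gene_path, stringsAsFactors = FALSE)
    tx2gene <- stats::setNames(gdf[[2]], gdf[[1]])
  }
  expression_matrix(vals, tissues, tx2gene)
}
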