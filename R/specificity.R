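#' Construct an expression matrix with a tissue map
#'
#' @param values Nonnegative finite numeric matrix of TPM abundances, rows =
#'   transcripts, columns = samples (both named).
#' @param tissues Character vector mapping each sample (column) to exactly
#'   one tissue; named by sample id or given in column order.
#' @param tx2gene Optional named character vector mapping transcript ids to
#'   gene ids.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, tissues, tx2gene = NULL) {
  stopifnot(
    is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)),
    all(is.finite(values)), all(values >= 0)
  )
  if (!is.null(names(tissues))) {
    missing <- setdiff(colnames(values), names(tissues))
    if (length(missing)) {
      stop("samples missing from tissue map: ", paste(missing, collapse = ", "))
    }
    tissues <- tissues[colnames(values)]
  } else {
    stopifnot(length(tissues) == ncol(values))
    names(tissues) <- colnames(values)
  }
  structure(
    list(values = values, tissues = tissues, tx2gene = tx2gene),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(
    "expression_matrix:", nrow(x$values), "transcripts x",
    ncol(x$values), "samples,", length(unique(x$tissues)), "tissues\n"
  )
  invisible(x)
}

#' Median-of-ratios library size factors
#'
#' For each sample, the median over reference transcripts (those positive in
#' every sample) of the ratio between the sample's abundance and the
#' transcript's geometric mean across samples. Normalized abundance is the
#' raw value divided by the sample's factor.
#'
#' @param em An [expression_matrix] with >= 2 samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(em) {
  stopifnot(inherits(em, "expression_matrix"), ncol(em$values) >= 2L)
  ref <- rowSums(em$values > 0) == ncol(em$values)
  if (!any(ref)) {
    stop(
      "no transcript is positive in every sample; ",
      "filter low-abundance transcripts before normalization"
    )
  }
  m <- em$values[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  apply(m / geo, 2L, stats::median)
}

#' Divide an expression matrix by its size factors
#'
#' @param em An [expression_matrix].
#' @param factors Optional precomputed factors (defaults to
#'   [size_factors()]).
#' @return A normalized `expression_matrix`.
#' @export
normalize_expression <- function(em, factors = size_factors(em)) {
  stopifnot(all(factors > 0), length(factors) == ncol(em$values))
  expression_matrix(
    sweep(em$values, 2L, factors, "/"), em$tissues, em$tx2gene
  )
}

#' Sum isoform abundances to gene level
#'
#' Gene abundance per sample is the sum of its isoforms' (normalized)
#' abundances; the transcript-level matrix is left untouched.
#'
#' @param em An [expression_matrix].
#' @param tx2gene Named character vector transcript -> gene covering every
#'   transcript (defaults to the map stored in `em`).
#' @return A gene-level `expression_matrix`.
#' @export
gene_abundance <- function(em, tx2gene = em$tx2gene) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(tx2gene)) stop("no transcript-to-gene map supplied")
  missing <- setdiff(rownames(em$values), names(tx2gene))
  if (length(missing)) {
    stop(
      "transcripts missing from tx2gene map: ",
      paste(utils::head(missing, 5), collapse = ", ")
    )
  }
  g <- rowsum(em$values, group = tx2gene[rownames(em$values)])
  expression_matrix(g, em$tissues)
}

#' Collapse samples to tissue means and log-transform
#'
#' Replicates of each tissue are collapsed by arithmetic mean of the
#' (normalized) abundances, then transformed as `log2(x + 1)`.
#'
#' @param em An [expression_matrix] (normalize first).
#' @return Numeric matrix, rows = transcripts, columns = tissues.
#' @export
collapse_and_transform <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  tissues <- unique(em$tissues)
  out <- vapply(tissues, function(t) {
    cols <- names(em$tissues)[em$tissues == t]
    if (!length(cols)) stop("tissue with zero samples: ", t)
    rowMeans(em$values[, cols, drop = FALSE])
  }, numeric(nrow(em$values)))
  if (nrow(em$values) == 1L) out <- matrix(out, nrow = 1L,
    dimnames = list(rownames(em$values), tissues))
  log2(out + 1)
}

#' SPM tissue-specificity metric
#'
#' For a nonnegative expression vector over tissues, `SPM_i = x_i /
#' sqrt(sum_j x_j^2)` — the cosine between the expression vector and tissue
#' i's unit vector. Squared SPM values sum to 1 for any nonzero vector; an
#' all-zero vector yields all-zero SPM. SPM is invariant to positive
#' rescaling of the vector.
#'
#' @param x A nonnegative numeric vector over >= 2 tissues, or a matrix
#'   (rows = transcripts, columns = tissues) processed row-wise.
#' @return Vector or matrix of per-tissue SPM values in `[0, 1]`.
#' @export
spm <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) >= 2L, all(is.finite(x)))
    if (any(x < 0)) stop("SPM requires nonnegative expression values")
    norms <- sqrt(rowSums(x^2))
    out <- x / ifelse(norms > 0, norms, 1)
    return(out)
  }
  stopifnot(length(x) >= 2L, all(is.finite(x)))
  if (any(x < 0)) stop("SPM requires nonnegative expression values")
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) return(x * 0)
  x / nrm
}

#' Call preferential-expression groups from SPM profiles
#'
#' A transcript is `<organ_a>_pref` when its SPM in organ A is `>=
#' c_single`; otherwise `<organ_b>_pref` when organ B's SPM is `>=
#' c_single`; otherwise `<organ_a>+<organ_b>_pref` when the *minimum* of the
#' two organ SPMs is `>= c_joint`; otherwise `none`. With the default
#' cut-offs (0.9, 0.9, 0.55) the three groups are pairwise disjoint by the
#' cosine identity: `0.9^2 + 0.55^2 > 1`, so no profile can satisfy two
#' calls at once.
#'
#' @param spm_profile Matrix of SPM values (rows = transcripts, columns =
#'   tissues) or a named per-tissue vector for a single transcript.
#' @param organ_a,organ_b Tissue column names of the two organs of interest
#'   (defaults `"VNO"` and `"MOE"`).
#' @param c_single Cut-off for single-organ preference.
#' @param c_joint Cut-off for joint preference.
#' @return Character vector of group labels, one per transcript.
#' @export
assign_preference <- function(spm_profile, organ_a = "VNO", organ_b = "MOE",
                              c_single = 0.9, c_joint = 0.55) {
  if (!is.matrix(spm_profile)) {
    spm_profile <- matrix(spm_profile,
      nrow = 1L,
      dimnames = list(NULL, names(spm_profile))
    )
  }
  if (!all(c(organ_a, organ_b) %in% colnames(spm_profile))) {
    stop("organ columns absent from SPM profile: ", organ_a, " / ", organ_b)
  }
  a <- spm_profile[, organ_a]
  b <- spm_profile[, organ_b]
  labels <- preference_levels(organ_a, organ_b)
  out <- rep(labels[["none"]], length(a))
  out[pmin(a, b) >= c_joint] <- labels[["joint"]]
  out[b >= c_single] <- labels[["b"]]
  out[a >= c_single] <- labels[["a"]]
  out
}

preference_levels <- function(organ_a = "VNO", organ_b = "MOE") {
  c(
    a = paste0(organ_a, "_pref"),
    b = paste0(organ_b, "_pref"),
    joint = paste0(organ_a, "+", organ_b, "_pref"),
    none = "none"
  )
}

#' Expression-level quartile groups
#'
#' Within a preference group, transcripts above the third quartile of
#' abundance are `high`, below the first quartile `low`, and the inclusive
#' interquartile range is `medium`. Quartiles are computed within the group
#' itself; with all-equal values Q1 = Q3 and everything is `medium`.
#'
#' @param values Numeric TPM abundances of the transcripts in one
#'   preference group.
#' @return Character vector over `{"high", "medium", "low"}`.
#' @export
expression_groups <- function(values) {
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  ifelse(values > q[2], "high", ifelse(values < q[1], "low", "medium"))
}

#' OMP positivity of single cells
#'
#' A cell is OMP-positive when the absolute abundance of the Omp transcript
#' (estimated RNA molecules per cell) is strictly greater than 100.
#'
#' @param abundance Nonnegative absolute abundance value(s).
#' @return Logical vector.
#' @export
label_omp_positive <- function(abundance) {
  stopifnot(all(abundance >= 0))
  abundance > 100
}

#' Full specificity profile of an expression matrix
#'
#' Convenience wrapper running size-factor normalization, tissue collapsing
#' with `log2(x + 1)`, SPM, preference calls, and within-group expression
#' quartile groups (quartiles of the mean abundance over the organ(s)
#' defining each preference group, on the normalized linear scale).
#'
#' @param em An [expression_matrix] of raw TPM.
#' @inheritParams assign_preference
#' @return A `data.frame` with one row per transcript: per-tissue SPM
#'   columns (`spm_<tissue>`), `preference`, `abundance` (organ-mean TPM
#'   used for grouping) and `expression_group`.
#' @export
specificity_profile <- function(em, organ_a = "VNO", organ_b = "MOE",
                                c_single = 0.9, c_joint = 0.55) {
  norm <- normalize_expression(em)
  tis <- collapse_and_transform(norm)
  if (!all(c(organ_a, organ_b) %in% colnames(tis))) {
    stop("tissue map lacks organ: ", organ_a, " / ", organ_b)
  }
  s <- spm(tis)
  pref <- assign_preference(s, organ_a, organ_b, c_single, c_joint)
  # linear-scale tissue means for expression grouping
  lin <- 2^tis - 1
  levels <- preference_levels(organ_a, organ_b)
  abundance <- ifelse(
    pref == levels[["a"]], lin[, organ_a],
    ifelse(pref == levels[["b"]], lin[, organ_b],
      (lin[, organ_a] + lin[, organ_b]) / 2
    )
  )
  grp <- rep(NA_character_, nrow(tis))
  for (g in setdiff(unique(pref), "none")) {
    idx <- pref == g
    grp[idx] <- expression_groups(abundance[idx])
  }
  out <- data.frame(
    transcript_id = rownames(tis), s,
    preference = pref, abundance = abundance, expression_group = grp,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(out)[2:(1 + ncol(s))] <- paste0("spm_", colnames(s))
  rownames(out) <- NULL
  out
}
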