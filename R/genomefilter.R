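#' Upper-quartile UTR lengths from an annotation
#'
#' Computes, per side, the exonic UTR length of every protein-coding
#' transcript carrying a CDS span (exonic bases genomically outside the CDS,
#' assigned to the 5' or 3' side strand-awareness), and returns the upper
#' quartile (Q3) of each length distribution. Zero-length sides are treated
#' as absent UTRs and excluded, so the distributions describe annotated
#' UTRs. The quartile uses linear interpolation between closest ranks
#' (`quantile` type 6) by default; the method is configuration, not
#' hard-coded. When no annotation is available, the pipeline defaults are
#' `ext5 = 160`, `ext3 = 792` nt.
#'
#' @param annotation A [transcript_models] object containing protein-coding
#'   transcripts with CDS spans.
#' @param quantile_type `type` argument passed to [stats::quantile()].
#' @return Named numeric `c(ext5 = ..., ext3 = ...)`.
#' @export
utr_extension_lengths <- function(annotation, quantile_type = 6) {
  stopifnot(inherits(annotation, "transcript_models"))
  tx <- annotation$tx
  sel <- tx$biotype == "protein_coding" & !is.na(tx$cds_start)
  if (!any(sel)) {
    stop(
      "annotation has no protein-coding transcripts with a CDS; ",
      "use the package defaults ext5 = 160, ext3 = 792"
    )
  }
  utr5 <- numeric(0)
  utr3 <- numeric(0)
  for (i in which(sel)) {
    e <- annotation$exons[[tx$transcript_id[i]]]
    before <- exonic_bases_outside(e, upstream = TRUE, tx$cds_start[i])
    after <- exonic_bases_outside(e, upstream = FALSE, tx$cds_end[i])
    if (tx$strand[i] == "-") {
      u5 <- after
      u3 <- before
    } else {
      u5 <- before
      u3 <- after
    }
    utr5 <- c(utr5, u5)
    utr3 <- c(utr3, u3)
  }
  utr5 <- utr5[utr5 > 0]
  utr3 <- utr3[utr3 > 0]
  if (!length(utr5) && !length(utr3)) {
    stop(
      "no UTR-bearing transcripts in the annotation; ",
      "use the package defaults ext5 = 160, ext3 = 792"
    )
  }
  q3 <- function(v) {
    if (!length(v)) return(0)
    unname(stats::quantile(v, 0.75, type = quantile_type))
  }
  c(ext5 = q3(utr5), ext3 = q3(utr3))
}

# Exonic bases strictly before cds_start (upstream) / after cds_end.
exonic_bases_outside <- function(exons, upstream, bound) {
  if (upstream) {
    sum(pmax(0L, pmin(GenomicRanges::end(exons), bound - 1L) -
      GenomicRanges::start(exons) + 1L))
  } else {
    sum(pmax(0L, GenomicRanges::end(exons) -
      pmax(GenomicRanges::start(exons), bound + 1L) + 1L))
  }
}

#' Build artificial coding transcript intervals
#'
#' For each protein-coding transcript carrying a CDS span: take its
#' CDS-overlapping exonic intervals (exons intersected with the CDS span),
#' extend the CDS-side boundaries by `ext5` upstream of the CDS start and
#' `ext3` downstream of the CDS end *in genomic space* (strand-aware: on the
#' minus strand "upstream" is the larger coordinate), clamp at position 1,
#' and merge the resulting intervals per chromosome into an unstranded
#' exclusion mask. Extension happens from the genomic CDS span endpoints,
#' not walked along spliced exon chains; this is a documented approximation
#' that matches how UTR-fragment exclusion zones are defined around
#' annotated coding regions.
#'
#' @param annotation A [transcript_models] object.
#' @param ext5,ext3 Extension lengths in nt (defaults are the packaged
#'   upper-quartile UTR lengths 160 and 792).
#' @return A reduced, unstranded `GRanges` exclusion mask.
#' @export
build_artificial_coding <- function(annotation, ext5 = 160, ext3 = 792) {
  stopifnot(inherits(annotation, "transcript_models"))
  tx <- annotation$tx
  sel <- which(tx$biotype == "protein_coding")
  skipped <- character(0)
  pieces <- list()
  for (i in sel) {
    if (is.na(tx$cds_start[i])) {
      skipped <- c(skipped, tx$transcript_id[i])
      next
    }
    e <- annotation$exons[[tx$transcript_id[i]]]
    span <- GenomicRanges::GRanges(
      tx$chrom[i], IRanges::IRanges(tx$cds_start[i], tx$cds_end[i])
    )
    chunks <- GenomicRanges::intersect(e, span, ignore.strand = TRUE)
    if (length(chunks) == 0L) next
    minus <- tx$strand[i] == "-"
    lead <- if (minus) ext3 else ext5   # extension at the smaller coordinate
    trail <- if (minus) ext5 else ext3
    i_min <- which.min(GenomicRanges::start(chunks))
    i_max <- which.max(GenomicRanges::end(chunks))
    GenomicRanges::start(chunks)[i_min] <-
      max(1L, GenomicRanges::start(chunks)[i_min] - as.integer(lead))
    GenomicRanges::end(chunks)[i_max] <-
      GenomicRanges::end(chunks)[i_max] + as.integer(trail)
    pieces[[length(pieces) + 1L]] <- chunks
  }
  if (length(skipped)) {
    warning(
      "protein-coding transcripts without cds_span were skipped: ",
      paste(utils::head(skipped, 5), collapse = ", ")
    )
  }
  if (!length(pieces)) return(GenomicRanges::GRanges())
  g <- do.call(c, pieces)
  GenomicRanges::strand(g) <- "*"
  GenomicRanges::reduce(g)
}

#' Fraction of a candidate's exonic bases covered by blockers
#'
#' Strand-agnostic by default (intergenic-lncRNA practice excludes sense and
#' antisense overlap alike); `stranded = TRUE` restricts to same-strand
#' blockers. A candidate on a chromosome absent from the blocker set has
#' fraction 0.
#'
#' @param exons `GRanges` of the candidate's exons.
#' @param blockers Merged `GRanges` blocker set.
#' @param stranded Count only same-strand overlap.
#' @return Overlap fraction in `[0, 1]`.
#' @export
exonic_overlap_fraction <- function(exons, blockers, stranded = FALSE) {
  total <- sum(GenomicRanges::width(exons))
  if (total == 0L || length(blockers) == 0L) return(0)
  ov <- suppressWarnings(GenomicRanges::intersect(
    exons, blockers, ignore.strand = !stranded
  ))
  sum(GenomicRanges::width(ov)) / total
}

#' Overlap rule for one candidate
#'
#' Single-exon candidates fail on *any* overlap with the blocker set;
#' multi-exon candidates fail only when the overlap exceeds `max_fraction`
#' of their exonic length (strictly greater, so a fraction of exactly 0.25
#' passes the default rule).
#'
#' @param exons Candidate exon `GRanges`.
#' @param blockers Merged blocker `GRanges`.
#' @param max_fraction Tolerated overlap fraction for multi-exon candidates.
#' @param stranded Same-strand matching only.
#' @return `TRUE` when the candidate passes (is kept).
#' @export
passes_overlap_filter <- function(exons, blockers, max_fraction = 0.25,
                                  stranded = FALSE) {
  frac <- exonic_overlap_fraction(exons, blockers, stranded)
  if (length(exons) == 1L) frac == 0 else frac <= max_fraction
}

#' Apply the full candidate-lncRNA sieve
#'
#' Applies the three sieves in order and reports one removal reason per
#' candidate (the first failing stage wins):
#' \enumerate{
#'   \item `too_short`: exonic length must be strictly greater than
#'     `min_len` (default 200 nt).
#'   \item `predicted_coding`: the classifier's lncRNA probability must be
#'     `>= threshold`.
#'   \item genomic overlap: candidates failing the one-exon/any-overlap or
#'     multi-exon/>25% rule against the artificial-coding mask (CDS
#'     intervals with UTR-quartile extensions) pooled with pseudogene exons
#'     are `overlaps_artificial_coding`; surviving candidates with any exon
#'     overlap against rRNA/tRNA/snoRNA/miRNA/ribozyme exons are
#'     `overlaps_other_ncRNA`.
#' }
#' Candidates on chromosomes absent from the annotation pass stage 3
#' vacuously. The outcome is independent of candidate input order.
#'
#' @param candidates A [transcript_models] object of candidate transcripts.
#' @param annotation A [transcript_models] reference annotation, or `NULL`
#'   for no genomic blockers.
#' @param scores Named numeric lncRNA probabilities covering all candidates.
#' @param threshold Classifier decision threshold.
#' @param min_len Minimum exonic length (strict).
#' @param ext5,ext3 UTR extensions for the artificial-coding mask.
#' @param max_fraction Multi-exon overlap tolerance.
#' @param stranded Same-strand overlap matching only.
#' @return An object of class `filter_report`: a list with `candidates` (a
#'   `data.frame` of id, outcome, reason, overlap_fraction) and
#'   `stage_counts` (input / long / classified / clean survivors).
#' @export
filter_candidates <- function(candidates, annotation, scores,
                              threshold = 0.5, min_len = 200,
                              ext5 = 160, ext3 = 792, max_fraction = 0.25,
                              stranded = FALSE) {
  stopifnot(inherits(candidates, "transcript_models"))
  ids <- candidates$tx$transcript_id
  missing <- setdiff(ids, names(scores))
  if (length(missing)) {
    stop(
      "scores missing for candidates: ",
      paste(utils::head(missing, 5), collapse = ", ")
    )
  }
  if (is.null(annotation)) {
    coding_mask <- GenomicRanges::GRanges()
    ncrna_mask <- GenomicRanges::GRanges()
  } else {
    coding_mask <- GenomicRanges::reduce(c(
      build_artificial_coding(annotation, ext5, ext3),
      biotype_exons(annotation, "pseudogene")
    ))
    ncrna_mask <- biotype_exons(annotation, NCRNA_BIOTYPES)
  }

  n <- length(ids)
  outcome <- rep("kept", n)
  reason <- rep(NA_character_, n)
  frac <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (candidates$tx$exonic_length[i] <= min_len) {
      outcome[i] <- "removed"
      reason[i] <- "too_short"
      next
    }
    if (scores[[ids[i]]] < threshold) {
      outcome[i] <- "removed"
      reason[i] <- "predicted_coding"
      next
    }
    e <- candidates$exons[[ids[i]]]
    frac[i] <- exonic_overlap_fraction(e, coding_mask, stranded)
    if (!passes_overlap_filter(e, coding_mask, max_fraction, stranded)) {
      outcome[i] <- "removed"
      reason[i] <- "overlaps_artificial_coding"
      next
    }
    if (exonic_overlap_fraction(e, ncrna_mask, stranded) > 0) {
      outcome[i] <- "removed"
      reason[i] <- "overlaps_other_ncRNA"
    }
  }
  stage_counts <- c(
    input = n,
    long = sum(is.na(reason) | reason != "too_short"),
    classified = sum(is.na(reason) |
      !reason %in% c("too_short", "predicted_coding")),
    clean = sum(outcome == "kept")
  )
  structure(
    list(
      candidates = data.frame(
        id = ids, outcome = outcome, reason = reason,
        overlap_fraction = frac, stringsAsFactors = FALSE
      ),
      stage_counts = stage_counts
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report — sieve survivors:\n")
  print(x$stage_counts)
  if (any(x$candidates$outcome == "removed")) {
    print(table(x$candidates$reason[x$candidates$outcome == "removed"]))
  }
  invisible(x)
}

#' Write a filter report (TSV + JSON stage summary)
#'
#' @param report A `filter_report`.
#' @param tsv_path Per-candidate table path.
#' @param json_path Optional stage-summary JSON path.
#' @export
write_filter_report <- function(report, tsv_path, json_path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  utils::write.table(report$candidates, tsv_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(report$stage_counts), json_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(tsv_path)
}

#' Distance from each query locus to its nearest feature
#'
#' Genomic gap distance (0 for overlapping or adjacent-book-ended loci),
#' strand-agnostic and symmetric. Queries on chromosomes that carry no
#' feature get `Inf`.
#'
#' @param query,features `GRanges` objects.
#' @return Numeric vector of distances, one per query.
#' @export
nearest_feature_distance <- function(query, features) {
  stopifnot(length(query) > 0, length(features) > 0)
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(
    query, features,
    ignore.strand = TRUE
  ))
  out <- rep(Inf, length(query))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}
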