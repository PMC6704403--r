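ALL_HEXAMERS <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 6))[
  , 6:1
])

#' Train a hexamer usage log-likelihood table
#'
#' Builds the CPAT-style hexamer bias table: for each of the 4096 DNA
#' hexamers, the log-likelihood ratio of its pseudocount-smoothed frequency
#' in a coding corpus versus a non-coding corpus. Coding sequences are
#' counted in-frame (step 3) over each sequence's longest ORF; non-coding
#' sequences are counted in frame 0 (step 3 from position 1). Hexamers
#' containing `N` are skipped.
#'
#' @param coding,noncoding Sequence corpora (`DNAStringSet` or named
#'   character vectors); both must be non-empty.
#' @param pseudocount Positive smoothing count added to every hexamer.
#' @return An object of class `hexamer_table`: a list with `score` (named
#'   numeric of length 4096) and `pseudocount`.
#' @export
train_hexamer_table <- function(coding, noncoding, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (length(coding) == 0L) stop("coding corpus is empty")
  if (length(noncoding) == 0L) stop("noncoding corpus is empty")
  coding <- as_transcript_set(coding)
  noncoding <- as_transcript_set(noncoding)

  orfs <- vapply(
    as.character(coding),
    function(s) {
      o <- longest_orf_seq(s)
      if (is.null(o)) "" else o
    },
    character(1)
  )
  n_noorf <- sum(!nzchar(orfs))
  if (n_noorf > 0L) {
    warning(n_noorf, " coding sequences have no ORF and were skipped")
  }
  orfs <- orfs[nzchar(orfs) & nchar(orfs) >= 6L]
  if (length(orfs) == 0L) stop("no coding sequence contributed an ORF")

  cod_counts <- hexamer_counts(Biostrings::DNAStringSet(orfs), step = 3L)
  nc_counts <- hexamer_counts(noncoding[Biostrings::width(noncoding) >= 6L],
    step = 3L
  )
  score <- log((cod_counts + pseudocount) / (sum(cod_counts) + 4096 * pseudocount)) -
    log((nc_counts + pseudocount) / (sum(nc_counts) + 4096 * pseudocount))
  structure(
    list(score = score, pseudocount = pseudocount),
    class = "hexamer_table"
  )
}

hexamer_counts <- function(set, step) {
  if (length(set) == 0L) {
    return(stats::setNames(rep(0, 4096), ALL_HEXAMERS))
  }
  m <- Biostrings::oligonucleotideFrequency(set, width = 6L, step = step)
  colSums(m)[ALL_HEXAMERS]
}

#' Score a sequence against a hexamer table
#'
#' Mean table score over the region's hexamers: step-1 sliding hexamers for
#' `region = "full"`, in-frame (step 3) hexamers of the longest ORF for
#' `region = "longest_orf"`. Returns 0 (with a warning unless `quiet`) when
#' the region is absent or shorter than 6 nt, or when it contains no
#' `N`-free hexamer.
#'
#' @param seq A single sequence.
#' @param table A `hexamer_table` from [train_hexamer_table()].
#' @param region `"full"` or `"longest_orf"`.
#' @param quiet Suppress the degenerate-region warning.
#' @return Mean log-likelihood ratio over the region's hexamers.
#' @export
hexamer_score <- function(seq, table, region = c("full", "longest_orf"),
                          quiet = FALSE) {
  region <- match.arg(region)
  stopifnot(inherits(table, "hexamer_table"))
  s <- as_single_sequence(seq)
  if (region == "longest_orf") {
    s <- longest_orf_seq(s)
    step <- 3L
  } else {
    step <- 1L
  }
  if (is.null(s) || nchar(s) < 6L) {
    if (!quiet) warning("region shorter than one hexamer; score set to 0")
    return(0)
  }
  cnt <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(s),
    width = 6L, step = step
  )[ALL_HEXAMERS]
  tot <- sum(cnt)
  if (tot == 0) {
    if (!quiet) warning("no unambiguous hexamer in region; score set to 0")
    return(0)
  }
  unname(sum(cnt * table$score) / tot)
}

#' Write / read a hexamer table as TSV
#'
#' Two-column TSV (`hexamer`, `score`) preceded by a metadata comment line
#' recording the pseudocount.
#'
#' @param table A `hexamer_table`.
#' @param path File path.
#' @return `path` (writer) or a `hexamer_table` (reader).
#' @export
write_hexamer_table <- function(table, path) {
  stopifnot(inherits(table, "hexamer_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pseudocount=%.17g", table$pseudocount), con)
  writeLines("hexamer\tscore", con)
  writeLines(sprintf("%s\t%.17g", names(table$score), table$score), con)
  invisible(path)
}

#' @rdname write_hexamer_table
#' @export
read_hexamer_table <- function(path) {
  first <- readLines(path, n = 1L)
  pc <- as.numeric(sub("^# pseudocount=", "", first))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  score <- stats::setNames(df$score, df$hexamer)[ALL_HEXAMERS]
  structure(list(score = score, pseudocount = pc), class = "hexamer_table")
}
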