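STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames on the forward strand
#'
#' Scans the three forward reading frames for ORFs: an `ATG` followed by an
#' in-frame run of codons terminated by the first in-frame stop codon
#' (`TAA`/`TAG`/`TGA`). The stop codon is included in the ORF. ORFs that run
#' off the transcript end without a stop are not reported. Nested ORFs
#' (downstream in-frame `ATG`s sharing a stop) are reported individually.
#'
#' Assembled transcripts are assumed to be oriented, so only the forward
#' strand is scanned by default; set `both_strands = TRUE` for
#' strand-unknown transcripts (the reverse complement is scanned too, with
#' coordinates reported on the given sequence's reverse complement).
#'
#' @param seq A single sequence (character scalar, `DNAString`, or length-1
#'   `DNAStringSet`).
#' @param min_len_nt Minimum ORF length in nucleotides, including the stop
#'   codon; must be >= 6 and divisible by 3.
#' @param both_strands Also scan the reverse complement.
#' @return A `data.frame` with columns `start`, `end` (1-based inclusive
#'   positions on the scanned strand), `length_nt` and `strand`, sorted by
#'   decreasing length with ties broken by smaller start.
#' @export
find_orfs <- function(seq, min_len_nt = 6L, both_strands = FALSE) {
  stopifnot(length(min_len_nt) == 1L, min_len_nt >= 6L, min_len_nt %% 3L == 0L)
  s <- as_single_sequence(seq)
  out <- orf_scan(s, min_len_nt, strand = "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    out <- rbind(out, orf_scan(rc, min_len_nt, strand = "-"))
  }
  out[order(-out$length_nt, out$start), , drop = FALSE]
}

orf_scan <- function(s, min_len_nt, strand) {
  n <- nchar(s)
  empty <- data.frame(
    start = integer(0), end = integer(0), length_nt = integer(0),
    strand = character(0), stringsAsFactors = FALSE
  )
  res <- empty
  for (f in 0:2) {
    if (n - f < 6L) next
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% STOP_CODONS)
    if (!length(atg) || !length(stp)) next
    # index of first stop codon strictly downstream of each ATG
    j <- findInterval(atg, stp) + 1L
    ok <- j <= length(stp)
    if (!any(ok)) next
    atg <- atg[ok]
    stop_i <- stp[j[ok]]
    len <- 3L * (stop_i - atg + 1L)
    keep <- len >= min_len_nt
    if (!any(keep)) next
    res <- rbind(res, data.frame(
      start = f + 3L * (atg[keep] - 1L) + 1L,
      end = f + 3L * stop_i[keep],
      length_nt = len[keep],
      strand = strand,
      stringsAsFactors = FALSE
    ))
  }
  res
}

# Longest forward-strand ORF as a substring, or NULL when none exists.
longest_orf_seq <- function(s, min_len_nt = 6L) {
  orfs <- find_orfs(s, min_len_nt)
  if (nrow(orfs) == 0L) return(NULL)
  substring(s, orfs$start[1], orfs$end[1])
}

as_single_sequence <- function(seq) {
  if (methods::is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- seq[[1L]]
  }
  toupper(as.character(seq))
}
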