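#' Read transcript sequences from a FASTA file
#'
#' Reads a (possibly multi-line, CRLF-tolerant, mixed-case) FASTA file into a
#' [Biostrings::DNAStringSet] and validates the alphabet: only `A`, `C`, `G`,
#' `T` and `N` are accepted. IUPAC ambiguity codes other than `N`, and gap
#' characters, are rejected at parse time.
#'
#' @param path Path to a FASTA file of transcript sequences.
#' @return A named `DNAStringSet`; names are the transcript identifiers
#'   (first whitespace-delimited token of each header).
#' @export
read_transcript_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  validate_transcript_set(x)
  x
}

#' Coerce to a validated DNAStringSet of transcripts
#'
#' @param x A `DNAStringSet` or named character vector of sequences over
#'   `{A,C,G,T,N}` (case-insensitive).
#' @return A `DNAStringSet`.
#' @keywords internal
as_transcript_set <- function(x) {
  if (!methods::is(x, "DNAStringSet")) {
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  }
  validate_transcript_set(x)
  x
}

validate_transcript_set <- function(x) {
  if (any(Biostrings::width(x) < 1L)) {
    stop("all transcript sequences must have length >= 1")
  }
  af <- Biostrings::alphabetFrequency(x)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- af[, setdiff(colnames(af), allowed), drop = FALSE]
  if (any(bad > 0)) {
    offenders <- which(rowSums(bad) > 0)
    stop(
      "sequences contain characters outside {A,C,G,T,N}: ",
      paste(utils::head(names(x)[offenders], 5), collapse = ", ")
    )
  }
  invisible(x)
}

#' Write transcript sequences to FASTA
#'
#' @param x A `DNAStringSet` or named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(x, path) {
  Biostrings::writeXStringSet(as_transcript_set(x), path)
  invisible(path)
}
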