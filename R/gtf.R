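BIOTYPES <- c(
  "protein_coding", "pseudogene", "rRNA", "tRNA", "snoRNA", "miRNA",
  "ribozyme", "lncRNA", "other"
)
NCRNA_BIOTYPES <- c("rRNA", "tRNA", "snoRNA", "miRNA", "ribozyme")

#' Construct a set of transcript models
#'
#' A `transcript_models` object is the unit the genomic-overlap sieve works
#' on: a transcript table (id, gene, chromosome, strand, biotype, optional
#' CDS span, exonic length) plus an exon `GRangesList` indexed by transcript
#' id. Exons are sorted by start; overlapping exons within a transcript are
#' merged with a warning. All coordinates are 1-based inclusive (GRanges
#' convention, identical to GTF).
#'
#' @param tx `data.frame` with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `biotype`, and optionally `cds_start`/`cds_end` (NA when
#'   absent).
#' @param exons A `GRangesList` named by transcript id.
#' @return A `transcript_models` object.
#' @export
transcript_models <- function(tx, exons) {
  stopifnot(
    is.data.frame(tx),
    all(c("transcript_id", "gene_id", "chrom", "strand", "biotype") %in%
      names(tx)),
    !anyDuplicated(tx$transcript_id),
    setequal(names(exons), tx$transcript_id)
  )
  if (is.null(tx$cds_start)) tx$cds_start <- NA_integer_
  if (is.null(tx$cds_end)) tx$cds_end <- NA_integer_
  exons <- exons[tx$transcript_id]
  merged <- FALSE
  for (i in seq_along(exons)) {
    e <- sort(exons[[i]])
    r <- GenomicRanges::reduce(e)
    if (length(r) != length(e)) merged <- TRUE
    exons[[i]] <- r
  }
  if (merged) warning("overlapping exons within a transcript were merged")
  widths <- vapply(exons, function(e) sum(GenomicRanges::width(e)), numeric(1))
  if (any(widths <= 0)) stop("transcripts must have positive exonic length")
  tx$exonic_length <- as.integer(widths[tx$transcript_id])
  tx$n_exons <- vapply(exons, length, integer(1))[tx$transcript_id]
  rownames(tx) <- NULL
  structure(list(tx = tx, exons = exons), class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(
    "transcript_models:", nrow(x$tx), "transcripts on",
    length(unique(x$tx$chrom)), "chromosome(s)\n"
  )
  print(table(x$tx$biotype))
  invisible(x)
}

#' Parse a GTF file into transcript models
#'
#' Reads GTF2.2 `exon` and `CDS` feature lines (attributes `gene_id`,
#' `transcript_id`, and `gene_biotype`/`transcript_biotype`). Lines are
#' pre-validated: a malformed row (fewer than 9 tab-separated fields, or an
#' exon/CDS line whose attribute field lacks `gene_id`/`transcript_id`) is
#' an error naming the line number. Transcripts that have CDS lines but no
#' exon lines are rejected with a named warning. The CDS span of a
#' transcript is the min start / max end over its CDS lines. Biotypes
#' outside the recognized vocabulary map to `"other"`; any `*pseudogene*`
#' biotype maps to `"pseudogene"`.
#'
#' @param path Path to a GTF file.
#' @return A [transcript_models] object.
#' @export
parse_gtf <- function(path) {
  lines <- readLines(path)
  data_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in data_idx) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 9L) {
      stop("malformed GTF record (", length(fields), " fields) at line ", i)
    }
    if (fields[3L] %in% c("exon", "CDS") &&
      (!grepl("gene_id", fields[9L]) || !grepl("transcript_id", fields[9L]))) {
      stop("malformed attribute field (missing gene_id/transcript_id) at line ", i)
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("no exon or CDS records in ", path)

  meta <- S4Vectors::mcols(gr)
  biotype <- rep(NA_character_, length(gr))
  if ("transcript_biotype" %in% colnames(meta)) {
    biotype <- as.character(meta$transcript_biotype)
  }
  if ("gene_biotype" %in% colnames(meta)) {
    gb <- as.character(meta$gene_biotype)
    biotype[is.na(biotype)] <- gb[is.na(biotype)]
  }
  biotype <- normalize_biotype(biotype)

  txid <- as.character(meta$transcript_id)
  is_exon <- as.character(meta$type) == "exon"
  exon_tx <- unique(txid[is_exon])
  cds_only <- setdiff(unique(txid[!is_exon]), exon_tx)
  if (length(cds_only)) {
    warning(
      "transcripts with no exon lines were rejected: ",
      paste(utils::head(cds_only, 5), collapse = ", ")
    )
  }

  keep <- is_exon
  exons <- GenomicRanges::split(
    GenomicRanges::granges(gr[keep]), txid[keep]
  )
  first <- !duplicated(txid) & txid %in% exon_tx
  tx <- data.frame(
    transcript_id = txid[first],
    gene_id = as.character(meta$gene_id)[first],
    chrom = as.character(GenomicRanges::seqnames(gr))[first],
    strand = as.character(GenomicRanges::strand(gr))[first],
    biotype = biotype[first],
    stringsAsFactors = FALSE
  )
  chrom_per_tx <- tapply(
    as.character(GenomicRanges::seqnames(gr)), txid,
    function(v) length(unique(v))
  )
  if (any(chrom_per_tx > 1L)) {
    stop("transcript spans multiple chromosomes: ",
      paste(names(chrom_per_tx)[chrom_per_tx > 1L], collapse = ", "))
  }

  cds <- gr[!is_exon & txid %in% exon_tx]
  cds_tx <- txid[!is_exon & txid %in% exon_tx]
  tx$cds_start <- NA_integer_
  tx$cds_end <- NA_integer_
  if (length(cds)) {
    st <- tapply(GenomicRanges::start(cds), cds_tx, min)
    en <- tapply(GenomicRanges::end(cds), cds_tx, max)
    m <- match(names(st), tx$transcript_id)
    tx$cds_start[m] <- as.integer(st)
    tx$cds_end[m] <- as.integer(en)
  }
  tx$strand[!tx$strand %in% c("+", "-")] <- "."
  transcript_models(tx, exons)
}

normalize_biotype <- function(b) {
  b[is.na(b)] <- "other"
  b[grepl("pseudogene", b)] <- "pseudogene"
  b[grepl("lincRNA|lncRNA", b)] <- "lncRNA"
  b[!b %in% BIOTYPES] <- "other"
  b
}

#' Write transcript models to a GTF file
#'
#' Emits exon lines (and CDS lines for transcripts carrying a CDS span,
#' clipped to exons) with `gene_id`, `transcript_id` and
#' `transcript_biotype` attributes. `parse_gtf(write_gtf(x))` is the
#' identity on models.
#'
#' @param models A [transcript_models] object.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "transcript_models"))
  out <- character(0)
  for (i in seq_len(nrow(models$tx))) {
    t <- models$tx[i, ]
    e <- models$exons[[t$transcript_id]]
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
      t$gene_id, t$transcript_id, t$biotype
    )
    strand <- if (t$strand %in% c("+", "-")) t$strand else "."
    out <- c(out, sprintf(
      "%s\tlncsieve\texon\t%d\t%d\t.\t%s\t.\t%s",
      t$chrom, GenomicRanges::start(e), GenomicRanges::end(e), strand, attrs
    ))
    if (!is.na(t$cds_start)) {
      span <- GenomicRanges::GRanges(
        t$chrom, IRanges::IRanges(t$cds_start, t$cds_end)
      )
      chunks <- GenomicRanges::intersect(e, span, ignore.strand = TRUE)
      out <- c(out, sprintf(
        "%s\tlncsieve\tCDS\t%d\t%d\t.\t%s\t0\t%s",
        t$chrom, GenomicRanges::start(chunks), GenomicRanges::end(chunks),
        strand, attrs
      ))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# Pooled exon GRanges for a subset of biotypes (reduced, unstranded).
biotype_exons <- function(models, biotypes) {
  ids <- models$tx$transcript_id[models$tx$biotype %in% biotypes]
  if (!length(ids)) return(GenomicRanges::GRanges())
  g <- unlist(models$exons[ids], use.names = FALSE)
  GenomicRanges::strand(g) <- "*"
  GenomicRanges::reduce(g)
}
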