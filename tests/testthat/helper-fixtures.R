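# Builds a complete small pipeline fixture on disk: training corpora,
# candidate sequences named after the toy-annotation candidates, both GTFs
# and an expression matrix.
build_pipeline_fixture <- function(dir, n_train = 80, n_expr = 120) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    coding_fasta = file.path(dir, "coding.fa"),
    noncoding_fasta = file.path(dir, "noncoding.fa"),
    candidates_fasta = file.path(dir, "candidates.fa"),
    candidates_gtf = file.path(dir, "candidates.gtf"),
    reference_gtf = file.path(dir, "reference.gtf"),
    expression_tsv = file.path(dir, "tpm.tsv"),
    tissues_tsv = file.path(dir, "tissues.tsv")
  )
  write_transcript_fasta(make_coding_corpus(n_train, seed = 101),
    paths$coding_fasta
  )
  write_transcript_fasta(make_noncoding_corpus(n_train, seed = 102),
    paths$noncoding_fasta
  )
  fx <- make_toy_annotation()
  cand_seqs <- make_noncoding_corpus(nrow(fx$truth), seed = 103)
  names(cand_seqs) <- fx$truth$id
  write_transcript_fasta(cand_seqs, paths$candidates_fasta)
  write_gtf(fx$candidates, paths$candidates_gtf)
  write_gtf(fx$reference, paths$reference_gtf)
  gen <- make_expression_matrix(n = n_expr, seed = 104)
  write_expression_tsv(gen$em, paths$expression_tsv, paths$tissues_tsv)
  paths
}

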