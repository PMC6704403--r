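single_exon_model <- function(id, chrom, start, end, strand = "+",
                              biotype = "protein_coding",
                              cds = NULL) {
  tx <- data.frame(
    transcript_id = id, gene_id = paste0("g_", id), chrom = chrom,
    strand = strand, biotype = biotype,
    cds_start = if (is.null(cds)) NA_integer_ else cds[1],
    cds_end = if (is.null(cds)) NA_integer_ else cds[2],
    stringsAsFactors = FALSE
  )
  exons <- GenomicRanges::GRangesList(stats::setNames(
    list(GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start, end), strand
    )), id
  ))
  transcript_models(tx, exons)
}

test_that("parse_gtf converts coordinates, sorts exons and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", "301", "400", ".", "+", ".",
      'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";',
      sep = "\t"
    ),
    paste("chr1", "src", "exon", "101", "200", ".", "+", ".",
      'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";',
      sep = "\t"
    ),
    paste("chr1", "src", "CDS", "121", "180", ".", "+", "0",
      'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";',
      sep = "\t"
    )
  ), tmp)
  m <- parse_gtf(tmp)
  e <- m$exons[["t1"]]
  expect_equal(GenomicRanges::start(e), c(101L, 301L))
  expect_equal(GenomicRanges::width(e), c(100L, 100L))
  expect_equal(m$tx$exonic_length, 200L)
  expect_equal(m$tx$cds_start, 121L)
  expect_equal(m$tx$cds_end, 180L)

  # round trip is the identity on models
  fx <- make_toy_annotation()
  out <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(fx$reference, out)
  back <- parse_gtf(out)
  ord <- order(back$tx$transcript_id)
  ord0 <- order(fx$reference$tx$transcript_id)
  expect_equal(back$tx[ord, ], fx$reference$tx[ord0, ],
    ignore_attr = TRUE
  )
  for (id in fx$reference$tx$transcript_id) {
    expect_equal(
      as.data.frame(back$exons[[id]])[, 1:3],
      as.data.frame(fx$reference$exons[[id]])[, 1:3]
    )
  }
})

test_that("parse_gtf reports malformed records with line numbers", {
  tmp <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", "101", "200", ".", "+", ".",
      'gene_id "g1"; transcript_id "t1";',
      sep = "\t"
    ),
    paste("chr1", "src", "exon", "301", "400", ".", "+", ".",
      'no_attributes_here',
      sep = "\t"
    )
  ), tmp)
  expect_error(parse_gtf(tmp), "line 2")

  short <- withr::local_tempfile(fileext = ".gtf")
  writeLines("chr1\texon\t101", short)
  expect_error(parse_gtf(short), "line 1")
})

test_that("UTR upper quartiles follow the closest-ranks rule", {
  # four coding transcripts with UTR multiset {100,200,300,400} per side
  utrs <- c(100L, 200L, 300L, 400L)
  tx <- data.frame(
    transcript_id = paste0("t", 1:4), gene_id = paste0("g", 1:4),
    chrom = "chr1", strand = "+", biotype = "protein_coding",
    cds_start = 10000L + (1:4) * 100000L + utrs,
    cds_end = 10000L + (1:4) * 100000L + 1000L,
    stringsAsFactors = FALSE
  )
  exons <- GenomicRanges::GRangesList(stats::setNames(lapply(1:4, function(i) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(
      10000L + i * 100000L, 10000L + i * 100000L + 1000L + utrs[i]
    ), "+")
  }), tx$transcript_id))
  m <- transcript_models(tx, exons)
  q <- utr_extension_lengths(m)
  expect_equal(unname(q["ext5"]), 375)
  expect_equal(unname(q["ext3"]), 375)

  # all-equal UTRs give Q3 = L
  tx2 <- tx
  tx2$cds_start <- 10000L + (1:4) * 100000L + 250L
  m2 <- transcript_models(tx2, exons)
  expect_equal(unname(utr_extension_lengths(m2)["ext5"]), 250)

  # no UTR-bearing transcripts: instructed to use the packaged defaults
  bare <- single_exon_model("b1", "chr1", 1000, 1999, cds = c(1000, 1999))
  expect_error(utr_extension_lengths(bare), "160")
  expect_equal(eval(formals(filter_candidates)$ext5), 160)
  expect_equal(eval(formals(filter_candidates)$ext3), 792)
})

test_that("artificial coding intervals extend the CDS strand-awarely", {
  plus <- single_exon_model("p1", "chr1", 1001, 2000, "+", cds = c(1201, 1800))
  g <- build_artificial_coding(plus, ext5 = 160, ext3 = 792)
  expect_equal(GenomicRanges::start(g), 1041L)
  expect_equal(GenomicRanges::end(g), 2592L)

  minus <- single_exon_model("m1", "chr1", 1001, 2000, "-", cds = c(1201, 1800))
  g2 <- build_artificial_coding(minus, ext5 = 160, ext3 = 792)
  expect_equal(GenomicRanges::start(g2), 409L)
  expect_equal(GenomicRanges::end(g2), 1960L)

  # zero extensions reduce to the merged CDS-exonic intervals exactly
  g0 <- build_artificial_coding(plus, ext5 = 0, ext3 = 0)
  expect_equal(GenomicRanges::start(g0), 1201L)
  expect_equal(GenomicRanges::end(g0), 1800L)
  # ... and are idempotent under merging
  expect_equal(g0, GenomicRanges::reduce(g0))

  # extension clamps at the chromosome start
  early <- single_exon_model("e1", "chr1", 1, 500, "+", cds = c(50, 400))
  ge <- build_artificial_coding(early, ext5 = 160, ext3 = 10)
  expect_equal(GenomicRanges::start(ge), 1L)

  nocds <- single_exon_model("n1", "chr1", 1, 500)
  expect_warning(build_artificial_coding(nocds), "skipped")
})

test_that("exonic overlap fraction matches the per-base bitmap oracle", {
  expect_equal(exonic_overlap_fraction(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 199)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(300, 400))
  ), 0)
  expect_equal(exonic_overlap_fraction(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 250)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 400))
  ), 1)
  # absent chromosome in the blocker set
  expect_equal(exonic_overlap_fraction(
    GenomicRanges::GRanges("chrZ", IRanges::IRanges(150, 250)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 400))
  ), 0)

  set.seed(17)
  for (i in 1:200) {
    n_ex <- sample(1:4, 1)
    starts <- sort(sample(seq(1, 90000, by = 500), n_ex))
    ex <- data.frame(start = starts, end = starts + sample(50:400, n_ex, TRUE))
    n_bl <- sample(0:5, 1)
    bl <- if (n_bl > 0) {
      bs <- sample(1:95000, n_bl)
      data.frame(start = bs, end = bs + sample(100:3000, n_bl, TRUE))
    } else {
      data.frame(start = integer(0), end = integer(0))
    }
    blocker_gr <- if (nrow(bl)) {
      GenomicRanges::reduce(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(bl$start, bl$end))
      )
    } else {
      GenomicRanges::GRanges()
    }
    impl <- exonic_overlap_fraction(
      GenomicRanges::reduce(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(ex$start, ex$end))
      ),
      blocker_gr
    )
    expect_equal(impl, oracle_bitmap_fraction(ex, bl))
  }
})

test_that("the one-exon/any and multi-exon/25% boundary rules hold", {
  blocker <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000))
  one_bp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 2500))
  expect_false(passes_overlap_filter(one_bp, blocker))

  two_ex_20 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1801, 5000), c(2000, 5799))
  ) # 200 of 1000 covered
  expect_true(passes_overlap_filter(two_ex_20, blocker))

  two_ex_25 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1751, 5000), c(2000, 5749))
  ) # exactly 250 of 1000
  expect_equal(exonic_overlap_fraction(two_ex_25, blocker), 0.25)
  expect_true(passes_overlap_filter(two_ex_25, blocker))

  two_ex_over <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1750, 5000), c(2000, 5748))
  ) # 251 of 1000
  expect_false(passes_overlap_filter(two_ex_over, blocker))
})

test_that("filter_candidates reproduces the planted fixture and is order-stable", {
  fx <- make_toy_annotation()
  rep <- filter_candidates(fx$candidates, fx$reference, fx$scores)
  expect_equal(rep$candidates$outcome, fx$truth$expected_outcome)
  expect_equal(rep$candidates$reason, fx$truth$expected_reason)
  ok <- !is.na(fx$truth$expected_fraction)
  expect_equal(
    rep$candidates$overlap_fraction[ok], fx$truth$expected_fraction[ok]
  )
  expect_equal(
    unname(rep$stage_counts), c(10L, 8L, 6L, 2L)
  )
  # non-increasing survivors, exhaustive accounting, unique reasons
  expect_true(all(diff(rep$stage_counts) <= 0))
  expect_equal(
    sum(rep$candidates$outcome == "kept") +
      sum(rep$candidates$outcome == "removed"),
    nrow(rep$candidates)
  )
  expect_true(all(!is.na(rep$candidates$reason[
    rep$candidates$outcome == "removed"
  ])))

  # input order does not change per-candidate outcomes
  perm <- rev(seq_len(nrow(fx$candidates$tx)))
  shuffled <- transcript_models(
    fx$candidates$tx[perm, ], fx$candidates$exons[perm]
  )
  rep2 <- filter_candidates(shuffled, fx$reference, fx$scores)
  m <- match(rep$candidates$id, rep2$candidates$id)
  expect_equal(rep2$candidates$outcome[m], rep$candidates$outcome)
  expect_equal(rep2$candidates$reason[m], rep$candidates$reason)
  expect_equal(unname(rep2$stage_counts), unname(rep$stage_counts))
})

test_that("filter_candidates handles edge configurations", {
  fx <- make_toy_annotation()
  # missing scores are an error naming the candidate
  expect_error(
    filter_candidates(fx$candidates, fx$reference, fx$scores[-1]),
    fx$truth$id[1]
  )
  # threshold 0 and no annotation: stage-3 survivors = stage-1 survivors
  rep <- filter_candidates(fx$candidates, NULL, fx$scores, threshold = 0)
  expect_equal(rep$stage_counts[["clean"]], rep$stage_counts[["long"]])
  # the optional 20%-overlap scenario is kept under the strict > 25% rule
  fx20 <- make_toy_annotation(scenarios = c("multi_exon_20", "multi_exon_30"))
  rep20 <- filter_candidates(fx20$candidates, fx20$reference, fx20$scores)
  expect_equal(rep20$candidates$outcome, c("kept", "removed"))
  expect_equal(rep20$candidates$overlap_fraction, c(0.20, 0.30))
})

test_that("nearest_feature_distance matches brute-force gap arithmetic", {
  q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  f <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 400))
  expect_equal(nearest_feature_distance(q, f), 100)
  expect_equal(nearest_feature_distance(f, q), 100)

  ov <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 350))
  expect_equal(nearest_feature_distance(ov, f), 0)

  # query chromosome with no features
  q2 <- GenomicRanges::GRanges("chrM", IRanges::IRanges(1, 10))
  expect_equal(nearest_feature_distance(q2, f), Inf)

  set.seed(23)
  for (i in 1:100) {
    qs <- sample(1:90000, 1)
    qe <- qs + sample(10:500, 1)
    n_f <- sample(1:6, 1)
    fs <- sample(1:90000, n_f)
    fe <- fs + sample(10:2000, n_f, TRUE)
    impl <- nearest_feature_distance(
      GenomicRanges::GRanges("chr1", IRanges::IRanges(qs, qe)),
      GenomicRanges::GRanges("chr1", IRanges::IRanges(fs, fe))
    )
    expect_equal(impl, oracle_min_gap(qs, qe, fs, fe))
  }
})
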