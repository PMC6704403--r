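test_that("find_orfs handles minimal and degenerate sequences", {
  o <- find_orfs("ATGAAATAG")
  expect_equal(nrow(o), 1L)
  expect_equal(o$start, 1L)
  expect_equal(o$length_nt, 9L)

  expect_equal(nrow(find_orfs("CCCCCCCC")), 0L)
  expect_equal(nrow(find_orfs("NNNNNNNNNNNN")), 0L)
  # ORF running off the end (no stop) is not counted
  expect_equal(nrow(find_orfs("ATGAAAAAAAAA")), 0L)
  # nested ORFs share a stop and are reported individually
  o2 <- find_orfs("ATGATGAAATAG")
  expect_equal(o2$length_nt, c(12L, 9L))
  expect_equal(o2$start, c(1L, 4L))
})

test_that("find_orfs agrees with the exhaustive start/stop-pair oracle", {
  set.seed(42)
  for (i in 1:300) {
    s <- random_seq(sample(60:1000, 1))
    orfs <- find_orfs(s, min_len_nt = 6L)
    impl <- if (nrow(orfs)) orfs$length_nt[1] else 0L
    expect_identical(impl, oracle_longest_orf(s))
  }
})

test_that("find_orfs scans the reverse complement only when asked", {
  s <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAAAAATAG")
  ))
  expect_equal(nrow(find_orfs(s)), 0L)
  both <- find_orfs(s, both_strands = TRUE)
  expect_equal(both$strand, "-")
  expect_equal(both$length_nt, 12L)
})

test_that("fickett_score matches the published-table reference", {
  s1 <- paste(rep("ACGT", 100), collapse = "")
  expect_equal(fickett_score(s1), oracle_fickett(s1))
  s2 <- strrep("A", 400)
  expect_equal(fickett_score(s2), oracle_fickett(s2))
  set.seed(7)
  for (i in 1:50) {
    s <- random_seq(sample(50:600, 1))
    expect_equal(fickett_score(s), oracle_fickett(s))
  }
  # the statistic is position-sensitive: reverse complement generally differs
  s <- random_seq(300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_false(isTRUE(all.equal(fickett_score(s), fickett_score(rc))))
  expect_warning(fickett_score(strrep("N", 50)), "no unambiguous")
})

test_that("hexamer table training matches a naive recount", {
  set.seed(11)
  coding <- vapply(1:20, function(i) {
    paste0("ATG", paste(sample(c("GCT", "GAA", "CTG", "AAA"), 60,
      replace = TRUE
    ), collapse = ""), "TAA")
  }, character(1))
  noncoding <- vapply(1:20, function(i) random_seq(300), character(1))
  names(coding) <- paste0("c", 1:20)
  names(noncoding) <- paste0("n", 1:20)
  pc <- 1
  tab <- train_hexamer_table(coding, noncoding, pseudocount = pc)

  orfs <- vapply(coding, function(s) {
    o <- find_orfs(s)
    substring(s, o$start[1], o$end[1])
  }, character(1))
  cc <- oracle_hexamer_counts(orfs)
  nc <- oracle_hexamer_counts(noncoding)
  full_c <- full_n <- stats::setNames(rep(0L, 4096), names(tab$score))
  full_c[names(cc)] <- cc
  full_n[names(nc)] <- nc
  expected <- log((full_c + pc) / (sum(full_c) + 4096 * pc)) -
    log((full_n + pc) / (sum(full_n) + 4096 * pc))
  expect_equal(tab$score, expected)
})

test_that("hexamer table has symmetry, sign and error behaviour", {
  set.seed(3)
  seqs <- stats::setNames(
    vapply(1:10, function(i) {
      paste0("ATG", paste(rep("GCT", 40), collapse = ""), "TAA")
    }, character(1)),
    paste0("s", 1:10)
  )
  # identical corpora: ORFs of the coding side are counted, so compare a
  # corpus of pure ORFs against itself
  orfs_only <- stats::setNames(
    rep(paste0("ATG", strrep("GCT", 40), "TAA"), 5), paste0("o", 1:5)
  )
  tab0 <- train_hexamer_table(orfs_only, orfs_only)
  expect_true(all(abs(tab0$score) < 1e-12))

  rnd <- stats::setNames(
    vapply(1:10, function(i) random_seq(300), character(1)), paste0("r", 1:10)
  )
  tab <- train_hexamer_table(seqs, rnd)
  expect_gt(tab$score[["GCTGCT"]], 0)
  expect_error(
    train_hexamer_table(character(0), rnd), "coding corpus is empty"
  )
  expect_error(
    train_hexamer_table(seqs, character(0)), "noncoding corpus is empty"
  )
})

test_that("hexamer_score equals a sliding-window recomputation", {
  set.seed(5)
  cod <- make_coding_corpus(30, seed = 1)
  ncc <- make_noncoding_corpus(30, seed = 2)
  tab <- train_hexamer_table(cod, ncc)

  zero_tab <- tab
  zero_tab$score[] <- 0
  expect_equal(hexamer_score(random_seq(100), zero_tab, "full"), 0)

  one_hex <- "GCTAAA"
  expect_equal(
    hexamer_score(one_hex, tab, "full"),
    unname(tab$score[[one_hex]])
  )
  for (i in 1:50) {
    s <- random_seq(sample(30:400, 1))
    vals <- vapply(
      seq_len(nchar(s) - 5L),
      function(j) tab$score[[substring(s, j, j + 5L)]], numeric(1)
    )
    expect_equal(hexamer_score(s, tab, "full"), mean(vals))
  }
  expect_warning(hexamer_score("ACGTA", tab, "full"), "shorter")
})

test_that("featurize populates the registry and is pure", {
  cod <- make_coding_corpus(20, seed = 1)
  ncc <- make_noncoding_corpus(20, seed = 2)
  tab <- train_hexamer_table(cod, ncc)

  # perfect ORF with no UTR covers the sequence
  s <- paste0("ATG", strrep("GCTAAA", 17), "TAA")
  fv <- featurize(s, tab)
  expect_named(fv, feature_names())
  expect_equal(unname(fv["orf_coverage"]), 1.0)
  expect_equal(unname(featurize(random_seq(1000), tab)["log10_length"]), 3.0)

  # purity: bit-identical on repeated calls
  s2 <- random_seq(500)
  expect_identical(featurize(s2, tab), featurize(s2, tab))

  # all finite, bounded features on a mixed corpus including N runs
  mix <- c(cod[1:5], ncc[1:5],
    Biostrings::DNAStringSet(c(weird = paste0(strrep("N", 30), "ATGCCC")))
  )
  suppressMessages(m <- featurize_corpus(mix, tab))
  expect_true(all(is.finite(m)))
  expect_true(all(m[, "gc_content"] >= 0 & m[, "gc_content"] <= 1))
  expect_true(all(m[, "orf_coverage"] >= 0 & m[, "orf_coverage"] <= 1))
  expect_true(all(m[, "tri_entropy"] >= 0 & m[, "tri_entropy"] <= log2(64)))
})

test_that("codon-position GC recombines to the ORF GC content", {
  cod <- make_coding_corpus(30, seed = 9)
  ncc <- make_noncoding_corpus(5, seed = 2)
  tab <- train_hexamer_table(cod, ncc)
  m <- featurize_corpus(cod, tab)
  for (i in seq_along(cod)) {
    s <- as.character(cod[[i]])
    o <- find_orfs(s)
    orf <- substring(s, o$start[1], o$end[1])
    gc_direct <- {
      ch <- strsplit(orf, "")[[1]]
      mean(ch %in% c("G", "C"))
    }
    expect_equal(mean(m[i, c("gc1", "gc2", "gc3")]), gc_direct,
      tolerance = 1e-9
    )
  }
})

test_that("coding and non-coding corpora separate on ORF and hexamer features", {
  cod <- make_coding_corpus(60, seed = 7)
  ncc <- make_noncoding_corpus(60, seed = 8)
  tab <- train_hexamer_table(cod, ncc)
  mc <- featurize_corpus(cod, tab)
  suppressMessages(mn <- featurize_corpus(ncc, tab))
  expect_gt(mean(mc[, "longest_orf_len"]), mean(mn[, "longest_orf_len"]))
  expect_gt(mean(mc[, "hexamer_orf"]), 0)
})

test_that("hexamer enrichment sign is stable across pseudocounts", {
  cod <- make_coding_corpus(25, seed = 13)
  ncc <- make_noncoding_corpus(25, seed = 14)
  s <- as.character(cod[[1]])
  for (pc in c(1, 0.1)) {
    tab <- train_hexamer_table(cod, ncc, pseudocount = pc)
    expect_gt(hexamer_score(s, tab, "longest_orf"), 0)
  }
})

test_that("FASTA round trip preserves ids and rejects bad alphabets", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  x <- make_noncoding_corpus(5, seed = 1)
  write_transcript_fasta(x, tmp)
  y <- read_transcript_fasta(tmp)
  expect_equal(names(y), names(x))
  expect_equal(as.character(y), as.character(x))

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">b1", "ACGTRY"), bad)
  expect_error(read_transcript_fasta(bad), "outside")
})
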