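# Clean-read pipeline: trimming, length filtering/collapsing, exact
# mapping, ncRNA removal, length distributions — each against a brute-force
# oracle on randomized instances.

ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

reads_df <- function(seqs, qual_score = 35) {
  data.frame(id = sprintf("r%04d", seq_along(seqs)), seq = seqs,
             qual = vapply(nchar(seqs),
                           function(l) strrep(intToUtf8(qual_score + 33), l),
                           character(1)),
             stringsAsFactors = FALSE)
}

test_that("adapter trimming removes the longest >= 6 nt suffix-prefix overlap", {
  insert <- "ACGTACGTACGTACGTACGTA"
  full <- paste0(insert, ADAPTER)
  out <- trim_and_quality_filter(reads_df(c(full, insert)), ADAPTER)
  expect_identical(out$reads$seq, c(insert, insert))
  # < 6 nt of adapter present: read returned unchanged
  short <- paste0(insert, substr(ADAPTER, 1, 5))
  out2 <- trim_and_quality_filter(reads_df(short), ADAPTER)
  expect_identical(out2$reads$seq, short)
  expect_error(trim_and_quality_filter(reads_df("ACGT"), ""), "adapter")
})

test_that("quality and N filters discard with per-reason accounting", {
  good <- "ACGTACGTACGTACGTACGT"
  withN <- "ACGTACGTNNGTACGTACGT"
  reads <- reads_df(c(good, withN, good))
  reads$qual[3] <- strrep(intToUtf8(10 + 33), nchar(good))  # mean Phred 10
  out <- trim_and_quality_filter(reads, ADAPTER, min_mean_quality = 20)
  expect_identical(out$reads$seq, good)
  expect_identical(unname(out$log[c("discarded_n", "discarded_quality",
                                    "output")]), c(1L, 1L, 1L))
  bad <- reads_df("ACGT")
  bad$qual <- "II"
  expect_error(trim_and_quality_filter(bad, ADAPTER), "index 1")
})

test_that("trimming matches the exhaustive suffix-prefix oracle on random reads", {
  set.seed(71)
  seqs <- character(1200)
  for (i in seq_along(seqs)) {
    ins <- rdna(sample(15:30, 1))
    seqs[i] <- switch(sample(3, 1),
                      paste0(ins, substr(ADAPTER, 1, sample(0:21, 1))),
                      ins,
                      rdna(sample(20:36, 1)))
  }
  out <- trim_and_quality_filter(reads_df(seqs), ADAPTER)
  want <- vapply(seqs, oracle_trim, character(1), adapter = ADAPTER,
                 USE.NAMES = FALSE)
  expect_identical(out$reads$seq, want)
})

test_that("length window 18-32 is inclusive and collapsing counts reads", {
  seqs <- c(rdna(17), rdna(18), rdna(32), rdna(33))
  tab <- length_filter_and_collapse(list(A = reads_df(seqs)))
  expect_identical(sort(tab$length), c(18L, 32L))
  tag21 <- rdna(21)
  tab2 <- length_filter_and_collapse(list(A = reads_df(rep(tag21, 3)),
                                          B = reads_df(tag21)))
  expect_identical(nrow(tab2), 1L)
  expect_identical(tab2$A, 3L)
  expect_identical(tab2$B, 1L)
})

test_that("collapsed counts equal a brute-force tally of the read stream", {
  set.seed(73)
  pool <- vapply(rep(21, 30), rdna, character(1))
  seqs <- sample(pool, 1000, replace = TRUE)
  tab <- length_filter_and_collapse(list(A = reads_df(seqs)))
  want <- table(seqs)
  expect_identical(sum(tab$A), 1000L)
  expect_identical(tab$A[match(names(want), tab$tag)],
                   as.integer(want))
})

test_that("mapping equals an exhaustive scan of a small genome", {
  set.seed(79)
  genome <- c(chrA = rdna(2500), chrB = rdna(2500))
  tags <- character(0)
  for (i in 1:40) {  # planted plus-strand, minus-strand and absent tags
    chrom <- sample(names(genome), 1)
    s <- sample(2400, 1)
    w <- substr(genome[[chrom]], s, s + 20)
    tags <- c(tags, w, paste(rev(strsplit(chartr("ACGT", "TGCA", w),
                                          "")[[1]]), collapse = ""))
  }
  tags <- unique(c(tags, vapply(rep(21, 20), rdna, character(1))))
  tab <- map_tags(make_tag_table(tags, rep(1L, length(tags))), genome)
  for (i in seq_along(tags)) {
    want <- oracle_map(tags[i], genome)
    got <- if (tab$hits[i] == "") character(0) else
      sort(strsplit(tab$hits[i], ";")[[1]])
    expect_identical(got, want)
    expect_identical(tab$n_hits[i], length(want))
  }
  # the documented examples: a tag equal to genome[100:121) maps at 100 "+"
  t1 <- substr(genome[["chrA"]], 101, 121)
  row <- match(t1, tab$tag)
  if (!is.na(row)) expect_true(grepl("chrA:100:\\+", tab$hits[row]))
  expect_error(map_tags(tab, character(0)), "non-empty")
})

test_that("ncRNA removal equals an independent substring scan and is idempotent", {
  set.seed(83)
  refs <- setNames(vapply(rep(150, 4), rdna, character(1)),
                   c("rRNA_01", "tRNA_01", "snRNA_01", "snoRNA_01"))
  inref <- vapply(1:25, function(i) {
    r <- sample(refs, 1); s <- sample(120, 1)
    substr(r, s, s + sample(18:25, 1))
  }, character(1))
  outref <- vapply(rep(21, 25), rdna, character(1))
  tags <- unique(c(inref, outref))
  tab <- make_tag_table(tags, rep(2L, length(tags)))
  res <- remove_ncrna(tab, refs)
  want_removed <- vapply(tags, oracle_in_ncrna, logical(1), refs = refs)
  expect_identical(sort(res$table$tag), sort(tags[!want_removed]))
  expect_identical(sum(res$report$tags_removed), sum(want_removed))
  # idempotence
  res2 <- remove_ncrna(res$table, refs)
  expect_identical(res2$table$tag, res$table$tag)
  expect_identical(sum(res2$report$tags_removed), 0L)
  # unknown classes are rejected
  expect_error(remove_ncrna(tab, c(lncRNA_01 = rdna(100))), "class")
})

test_that("length distributions are read-weighted and sum to one", {
  tab <- make_tag_table(c(rdna(21), rdna(21), rdna(24)),
                        list(A = c(5L, 3L, 2L), B = c(0L, 0L, 4L)))
  ld <- length_distribution(tab)
  dA <- ld$distribution[ld$distribution$library == "A", ]
  expect_equal(sum(dA$fraction), 1, tolerance = 1e-9)
  expect_equal(dA$fraction[dA$length == 21], 0.8)
  expect_equal(unname(ld$frac_20_24), c(1, 1))
  # an all-21-nt library is a point mass
  one <- length_distribution(make_tag_table(rdna(21), 7L))
  expect_equal(one$distribution$fraction, 1)
  # empty library reported as missing, empty table is an error
  tab0 <- make_tag_table(rdna(21), list(A = 1L, B = 0L))
  expect_true(is.na(length_distribution(tab0)$frac_20_24[["B"]]))
  expect_error(length_distribution(make_tag_table(character(0), integer(0))),
               "empty")
})

test_that("each pipeline stage only loses read mass", {
  cfg <- small_cfg(seed = 89)
  sim <- generate_toy_genome(cfg)
  reads <- simulate_srna_libraries(sim)
  lib <- "ELS1_20DAP"
  tq <- trim_and_quality_filter(reads[[lib]], cfg$adapter)
  expect_lte(nrow(tq$reads), nrow(reads[[lib]]))
  tab <- length_filter_and_collapse(setNames(list(tq$reads), lib))
  expect_lte(sum(tab[[lib]]), nrow(tq$reads))
  tab <- map_tags(tab, sim$genome)
  res <- remove_ncrna(tab, sim$ncrna_ref)
  expect_lte(sum(res$table[[lib]]), sum(tab[[lib]]))
})
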