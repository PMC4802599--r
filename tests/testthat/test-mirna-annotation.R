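# Known-miRNA annotation (isomiR rule), precursor extraction, hairpin
# folding (vs exhaustive recursion), and the novel-locus criteria.

test_that("tags annotate references exactly and via <= 2 nt end shifts only", {
  ref <- c("zma-miR156a" = "TGACAGAAGAGAGTGAGCACA")
  tags <- c(
    exact = "TGACAGAAGAGAGTGAGCACA",
    shift3 = "TGACAGAAGAGAGTGAGCAC",     # 3' trimmed by 1
    shift5 = "ACAGAAGAGAGTGAGCACA",      # 5' trimmed by 2
    ext3 = "TGACAGAAGAGAGTGAGCACAGG",    # 3' extended by 2
    mism = "TGACAGAAGAGTGTGAGCACA",      # internal mismatch
    far = "TGACAGAAGAGAGTGAG"            # 4 nt off the 3' end
  )
  tab <- make_tag_table(unname(tags), rep(1L, length(tags)))
  rec <- annotate_known(tab, ref)
  assigned <- attr(rec, "assignment")$tag
  expect_setequal(assigned, unname(tags[c("exact", "shift3", "shift5",
                                          "ext3")]))
  expect_identical(rec$L1, 4)
  expect_identical(rec$family, "zma-miR156")
  expect_error(annotate_known(tab, c(a = "ACGT", a = "ACGT")), "duplicate")
})

test_that("the isomiR rule matches an independent trim-based formulation", {
  set.seed(97)
  for (i in 1:300) {
    ref <- rdna(21)
    tag <- switch(sample(4, 1),
                  ref,
                  substr(ref, sample(1:3, 1), 21 - sample(0:2, 1)),
                  paste0(rdna(sample(0:2, 1)), ref),
                  rdna(sample(18:24, 1)))
    got <- !is.na(senmiR:::shift_match_one(tag, ref, 2L))
    expect_identical(got, oracle_isomir(tag, ref), info = paste(tag, ref))
  }
})

test_that("precursor windows are exact slices, reverse-complemented on minus hits", {
  set.seed(101)
  genome <- c(chr1 = rdna(6000))
  # plus strand
  w <- extract_precursor("chr1", 5000, 5021, "+", genome, flank = 150)
  expect_identical(w$seq[w$orientation == "tag5p"],
                   substr(genome[["chr1"]], 5001, 5171))
  expect_identical(w$seq[w$orientation == "tag3p"],
                   substr(genome[["chr1"]], 4851, 5021))
  expect_false(any(w$truncated))
  expect_identical(substr(w$seq[1], w$tag_from[1], w$tag_to[1]),
                   substr(genome[["chr1"]], 5001, 5021))
  # minus strand: windows are reverse-complemented
  wm <- extract_precursor("chr1", 5000, 5021, "-", genome, flank = 150)
  expect_identical(wm$seq[wm$orientation == "tag5p"],
                   dna_revcomp(substr(genome[["chr1"]], 4851, 5021)))
  expect_identical(substr(wm$seq[1], wm$tag_from[1], wm$tag_to[1]),
                   dna_revcomp(substr(genome[["chr1"]], 5001, 5021)))
  # clipping at the reference end is flagged
  wt <- extract_precursor("chr1", 10, 31, "+", genome, flank = 150)
  expect_true(wt$truncated[wt$orientation == "tag3p"])
})

test_that("a perfect inverted repeat folds into a fully paired stem", {
  stem <- "GCGCATATGCGCAATTGGCCTTAACCGGAA"
  hp <- paste0(stem, "TTTTTTTT", dna_revcomp(stem))
  f <- fold_hairpin(hp)
  expect_gte(f$n_pairs, nchar(stem))
  p <- f$partner[seq_len(nchar(stem))]
  expect_true(all(p[p > 0] > nchar(stem)))
  expect_lte(f$score, -18)
})

test_that("folding handles degenerate input and rejects bad characters", {
  f <- fold_hairpin(strrep("A", 40))
  expect_identical(f$n_pairs, 0L)
  expect_identical(f$score, 0)
  expect_error(fold_hairpin("ACGTX"), "non-ACGU")
  expect_error(fold_hairpin(strrep("A", 301)), "300")
})

test_that("the folding DP matches exhaustive recursion on 1000 short sequences", {
  set.seed(103)
  for (i in 1:1000) {
    n <- sample(10:25, 1)
    s <- rdna(n)
    f <- fold_hairpin(s)
    expect_identical(f$n_pairs, oracle_max_pairs(s), info = s)
    # structural invariants: valid pairs, involution, nestedness
    p <- f$partner
    idx <- which(p > 0)
    expect_true(all(p[p[idx]] == idx))
    if (nrow(f$pairs) > 1) {
      for (a in seq_len(nrow(f$pairs) - 1)) {
        i1 <- f$pairs[a, 1]; j1 <- f$pairs[a, 2]
        others <- f$pairs[-seq_len(a), , drop = FALSE]
        crossing <- (others[, 1] > i1 & others[, 1] < j1 &
                       others[, 2] > j1) |
          (others[, 1] < i1 & others[, 2] > i1 & others[, 2] < j1)
        expect_false(any(crossing), info = s)
      }
    }
  }
})

test_that("planted novel hairpins are recovered exactly, at both arms and strands", {
  rep <- default_report()
  r <- rep$recovery
  expect_identical(r$novel_precision, 1)
  expect_identical(r$novel_recall, 1)
  # mature lengths of the calls concentrate at 20-23 nt
  novel <- rep$mirna_records[rep$mirna_records$status == "novel", ]
  expect_gt(mean(nchar(novel$mature) %in% 20:23), 0.5)
})

test_that("a tag spanning the hairpin loop is rejected", {
  stem <- "GCGCATATGCGCAATTGGCCAATTCCGGTA"
  hp <- paste0(stem, "TTTTTTTT", dna_revcomp(stem))
  seqw <- paste0(hp, rdna(100))
  # tag centered on the loop
  tf <- nchar(stem) - 6L
  ev <- senmiR:::evaluate_hairpin_window(seqw, tf, tf + 20L,
                                         novel_criteria())
  expect_null(ev)
  # the same tag placed on the 5' arm passes
  ev2 <- senmiR:::evaluate_hairpin_window(seqw, 5L, 25L, novel_criteria())
  expect_false(is.null(ev2))
  expect_lte(ev2$score, -18)
})

test_that("novel calls are pure functions of tag, genome and criteria", {
  sim <- generate_toy_genome(small_cfg(seed = 107))
  tn <- sim$truth$mirna[sim$truth$mirna$status == "novel", ]
  tab <- make_tag_table(tn$mature, rep(5L, nrow(tn)))
  tab <- map_tags(tab, sim$genome)
  n1 <- call_novel_mirnas(tab, sim$genome)
  n2 <- call_novel_mirnas(tab, sim$genome)
  expect_identical(n1, n2)
  expect_identical(nrow(n1), nrow(tn))
  expect_setequal(n1$mature, tn$mature)
  expect_identical(n1$start, sort(tn$mat_start))
})

test_that("known, novel and unclassified tags partition the candidate set", {
  rep <- default_report()
  rec <- rep$mirna_records
  known_m <- rec$mature[rec$status == "known"]
  novel_m <- rec$mature[rec$status == "novel"]
  expect_length(intersect(known_m, novel_m), 0)
})
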