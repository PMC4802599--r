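# Degradome module: duplex penalty scoring, site finding vs brute force,
# tag profiles and the 0-4 peak categories.

test_that("duplex scoring follows the stated penalty rules", {
  m <- "TGACAGAAGAGAGTGAGCACA"  # 21 nt
  site <- dna_revcomp(m)
  expect_equal(score_duplex(m, site)$score, 0)
  # a mismatch at miRNA position 1 costs 1.0, at position 10 costs 2.0;
  # setting the site base equal to the miRNA base can never pair or wobble
  mm_at <- function(k) {
    s <- strsplit(site, "")[[1]]
    i <- nchar(m) - k + 1
    s[i] <- substr(m, k, k)
    paste(s, collapse = "")
  }
  expect_equal(score_duplex(m, mm_at(1))$score, 1.0)
  expect_equal(score_duplex(m, mm_at(10))$score, 2.0)
  expect_identical(score_duplex(m, mm_at(10))$states[10], "mismatch")
  # G:U wobble at position 5 costs 0.5 x 2
  s5 <- strsplit(site, "")[[1]]
  k5 <- nchar(m) - 5 + 1
  m5 <- strsplit(m, "")[[1]][5]
  s5[k5] <- if (m5 == "G") "T" else if (m5 == "T") "G" else NA
  if (!is.na(s5[k5])) {
    expect_equal(score_duplex(m, paste(s5, collapse = ""))$score, 1.0)
  }
  # more than one gap needed: no alignment
  expect_null(score_duplex(m, substr(site, 1, 18)))
})

test_that("duplex scores match the literal-rule oracle on 1000 random duplexes", {
  set.seed(137)
  for (i in 1:1000) {
    L <- sample(18:24, 1)
    m <- rdna(L)
    site <- switch(sample(3, 1),
                   rdna(L), rdna(L - 1), rdna(L + 1))
    got <- score_duplex(m, site)$score
    expect_equal(got, oracle_duplex(m, site), info = paste(m, site))
  }
})

test_that("adding a mismatch never decreases the duplex score", {
  set.seed(139)
  for (i in 1:200) {
    m <- rdna(21)
    site <- dna_revcomp(m)
    base <- score_duplex(m, site)$score
    s <- strsplit(site, "")[[1]]
    k <- sample(21, 1)
    s[k] <- chartr("ACGT", "GTAC", s[k])
    expect_gte(score_duplex(m, paste(s, collapse = ""))$score, base)
  }
})

test_that("site finding reports every window at or below the cutoff", {
  set.seed(149)
  m <- rdna(21)
  tx <- c(T1 = paste0(rdna(60), dna_revcomp(m), rdna(40)))
  hits <- find_target_sites(m, tx, max_score = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$site_start, 61L)
  expect_equal(hits$score, 0)
  # cleavage 10 nt into the site from its 3'-pairing end
  expect_identical(hits$cleavage_pos, 61L + 21L - 10L)
  # full equivalence with exhaustive per-window scoring
  tx2 <- c(T2 = rdna(300))
  all_hits <- find_target_sites(m, tx2, max_score = 1000)
  for (gap in c("none", "mirna", "site")) {
    sub <- all_hits[all_hits$gap == gap, ]
    L <- switch(gap, none = 21L, mirna = 20L, site = 22L)
    expect_identical(nrow(sub), 300L - L + 1L)
    check <- sample(nrow(sub), 40)
    for (i in check) {
      site <- substr(tx2[["T2"]], sub$site_start[i], sub$site_end[i])
      expect_equal(sub$score[i], score_duplex(m, site)$score)
    }
  }
})

test_that("tag profiles count 5' ends with full conservation", {
  set.seed(151)
  tx <- c(TA = rdna(200), TB = rdna(200))
  tags <- c(substr(tx[["TA"]], 57, 92),        # profile[TA][57]
            substr(tx[["TA"]], 57, 92),
            substr(tx[["TB"]], 11, 46),
            rdna(36))                          # matches nothing
  prof <- build_tag_profile(tags, tx)
  expect_identical(prof$TA[57], 2L)
  expect_identical(prof$TB[11], 1L)
  expect_identical(sum(prof$TA), 2L)
  expect_identical(sum(prof$TB), 1L)
  # oracle recount by substring scan
  set.seed(152)
  tags2 <- vapply(1:60, function(i) {
    t <- sample(names(tx), 1); s <- sample(160, 1)
    substr(tx[[t]], s, s + 35)
  }, character(1))
  prof2 <- build_tag_profile(tags2, tx)
  for (t in names(tx)) {
    want <- integer(200)
    for (tag in tags2) {
      for (s in seq_len(200 - nchar(tag) + 1)) {
        if (substr(tx[[t]], s, s + nchar(tag) - 1) == tag) {
          want[s] <- want[s] + 1L
        }
      }
    }
    expect_identical(prof2[[t]], want)
  }
})

test_that("peak categories follow the 0-4 rules and match the oracle", {
  p <- integer(100); p[58] <- 10L
  expect_identical(assign_category(p, 58), 0L)
  p2 <- p; p2[58] <- 1L
  expect_identical(assign_category(p2, 58), 4L)
  p3 <- p; p3[10] <- 10L
  expect_identical(assign_category(p3, 58), 1L)
  expect_error(assign_category(p, 57), "signal")
  expect_error(assign_category(p, 0), "outside")
  set.seed(157)
  for (i in 1:1000) {
    prof <- rpois(50, 0.8)
    idx <- which(prof >= 1)
    if (length(idx) == 0) next
    pos <- idx[sample.int(length(idx), 1)]
    expect_identical(assign_category(prof, pos),
                     oracle_category(prof, pos))
  }
})

test_that("every planted cleavage site is recovered as a category-0, S=0 hit", {
  rep <- default_report()
  r <- rep$recovery
  expect_identical(r$cleavage_recovered, 1)
  expect_identical(r$cleavage_category0, 1)
  expect_identical(r$cleavage_score0, 1)
  # category partition: every reported hit has exactly one category 0-4
  expect_true(all(rep$degradome$category %in% 0:4))
})

test_that("functional classes are percentages over distinct targets", {
  hits <- data.frame(transcript_id = c("T1", "T1", "T2", "T3", "T4", "T5",
                                       "T6", "T7", "T8", "T9", "T10"),
                     stringsAsFactors = FALSE)
  ann <- data.frame(transcript_id = sprintf("T%d", 1:10),
                    class = c(rep("transcriptional regulator", 3),
                              rep("translational regulator", 2),
                              rep("metabolizer", 2), "signal transducer",
                              "stress responder", "other"),
                    stringsAsFactors = FALSE)
  out <- classify_target_function(hits, ann)
  expect_equal(sum(out$percentage), 100)
  expect_equal(out$percentage[out$class == "transcriptional regulator"], 30)
  one <- classify_target_function(hits[hits$transcript_id == "T1", ,
                                       drop = FALSE], ann)
  expect_equal(one$percentage, 100)
})
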