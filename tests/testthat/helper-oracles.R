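# Shared fixtures and independent brute-force oracles. Oracles are literal
# re-implementations kept free of the package's own code paths.

rdna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

small_cfg <- function(seed = 301, ...) {
  args <- list(seed = seed, genome_length = 40000L, n_known_mirnas = 12L,
               n_novel_mirnas = 4L, n_ncrna_loci = 6L, n_sa_mirnas = 4L,
               reads_per_library = 6000L, degradome_tags = 4000L,
               n_transcripts_background = 3L)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# one full default-scale pipeline run shared by the deeper tests
.run_cache <- new.env(parent = emptyenv())
default_report <- function() {
  if (is.null(.run_cache$report)) {
    .run_cache$report <- run_pipeline(run_config(sim = sim_config()))
  }
  .run_cache$report
}

make_tag_table <- function(tags, counts, lib = "L1") {
  df <- data.frame(tag = tags, length = nchar(tags),
                   stringsAsFactors = FALSE)
  if (is.list(counts)) {
    for (l in names(counts)) df[[l]] <- counts[[l]]
    libs <- names(counts)
  } else {
    df[[lib]] <- counts
    libs <- lib
  }
  attr(df, "libraries") <- libs
  class(df) <- c("tag_table", "data.frame")
  df
}

## longest read suffix that is an adapter prefix (>= 6 nt), checked by
## explicit enumeration of every overlap
oracle_trim <- function(seq, adapter) {
  L <- nchar(seq)
  for (k in min(L, nchar(adapter)):6) {
    if (k < 6) break
    if (substr(seq, L - k + 1, L) == substr(adapter, 1, k)) {
      return(substr(seq, 1, L - k))
    }
  }
  seq
}

## exhaustive substring scan on both strands; returns "chrom:start0:strand"
oracle_map <- function(tag, genome) {
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  hits <- character(0)
  for (chrom in names(genome)) {
    g <- genome[[chrom]]
    L <- nchar(tag)
    for (s in seq_len(nchar(g) - L + 1)) {
      w <- substr(g, s, s + L - 1)
      if (w == tag) hits <- c(hits, sprintf("%s:%d:+", chrom, s - 1))
      if (w == rc(tag)) hits <- c(hits, sprintf("%s:%d:-", chrom, s - 1))
    }
  }
  sort(hits)
}

## is `tag` an exact sense-strand subsequence of any reference entry?
oracle_in_ncrna <- function(tag, refs) {
  any(vapply(refs, function(r) grepl(tag, r, fixed = TRUE), logical(1)))
}

## memoized recursive maximum base-pairing (independent of the C++ DP)
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  can <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste0(i, ",", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- f(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (can(ch[i], ch[k])) {
        v <- 1L + f(i + 1L, k - 1L) + (if (k < j) f(k + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  f(1L, length(ch))
}

## literal transcription of the duplex penalty rules
oracle_duplex <- function(mirna, site) {
  pen1 <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return(0)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(0.5)
    1
  }
  wt <- function(k) if (k >= 2 && k <= 13) 2 else 1
  m <- strsplit(mirna, "")[[1]]
  L <- length(m)
  r <- rev(strsplit(site, "")[[1]])
  Ls <- length(r)
  if (Ls == L) {
    return(sum(vapply(seq_len(L),
                      function(k) pen1(m[k], r[k]) * wt(k), numeric(1))))
  }
  if (Ls == L - 1) {
    best <- Inf
    for (g in seq_len(L)) {
      s <- 1 * wt(g)
      for (k in seq_len(L)) {
        if (k == g) next
        ri <- if (k < g) k else k - 1
        s <- s + pen1(m[k], r[ri]) * wt(k)
      }
      best <- min(best, s)
    }
    return(best)
  }
  if (Ls == L + 1) {
    best <- Inf
    for (g in seq_len(L + 1)) {
      s <- 1 * wt(min(max(g, 1), L))
      for (k in seq_len(L)) {
        ri <- if (k < g) k else k + 1
        s <- s + pen1(m[k], r[ri]) * wt(k)
      }
      best <- min(best, s)
    }
    return(best)
  }
  NULL
}

## literal transcription of the category rules
oracle_category <- function(profile, pos) {
  count <- profile[pos]
  if (count == 1) return(4L)
  mx <- max(profile)
  if (count == mx && sum(profile == mx) == 1) return(0L)
  if (count == mx) return(1L)
  if (count > median(profile[profile >= 1])) return(2L)
  3L
}

## independent isomiR rule: tag and reference match when both can be end-
## trimmed by at most 2 nt per end (never both at the same end) into the
## same string
oracle_isomir <- function(tag, ref, max_shift = 2) {
  lt <- nchar(tag); lr <- nchar(ref)
  for (a in 0:max_shift) for (b in 0:max_shift) {
    for (cc in 0:max_shift) for (d in 0:max_shift) {
      if (a > 0 && cc > 0) next
      if (b > 0 && d > 0) next
      t2 <- substr(tag, 1 + a, lt - b)
      r2 <- substr(ref, 1 + cc, lr - d)
      if (nchar(t2) > 0 && t2 == r2) return(TRUE)
    }
  }
  FALSE
}
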