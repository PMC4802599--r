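# Degradome (PARE) target calling: plant-style complementarity penalty
# scoring of miRNA/transcript duplexes, 5'-end tag profiles, and 0-4
# cleavage-site categories.

PENALTY_MISMATCH <- 1.0
PENALTY_WOBBLE <- 0.5
PENALTY_GAP <- 1.0
CORE_FROM <- 2L
CORE_TO <- 13L

# penalty of pairing miRNA base m against transcript base t (both DNA
# alphabet, given in pairing orientation)
base_penalty <- function(m, t) {
  comp <- (m == "A" & t == "T") | (m == "T" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  wob <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(comp, 0, ifelse(wob, PENALTY_WOBBLE, PENALTY_MISMATCH))
}

core_weight <- function(pos) ifelse(pos >= CORE_FROM & pos <= CORE_TO, 2, 1)

#' Score a miRNA/target-site duplex
#'
#' The site is the transcript subsequence (5'->3') that base-pairs
#' antiparallel with the miRNA. Penalties: mismatch 1.0, G:U wobble 0.5,
#' gap 1.0 (at most one gap), doubled when falling at miRNA positions 2-13
#' (position 1 = miRNA 5' end). Site lengths of miRNA length - 1 / + 1 are
#' aligned with one gap on the site/miRNA side respectively; larger length
#' differences need more than one gap and return `NULL`.
#'
#' @param mirna mature miRNA sequence (18-26 nt, DNA alphabet).
#' @param site transcript subsequence.
#' @return list with `score`, `states` (per miRNA position: `match`,
#'   `mismatch`, `GU`, `gap`) and `gap` (`"none"`, `"mirna"` or `"site"`),
#'   or `NULL` when no single-gap alignment exists.
#' @export
score_duplex <- function(mirna, site) {
  mirna <- chartr("U", "T", toupper(mirna))
  site <- chartr("U", "T", toupper(site))
  L <- nchar(mirna); Ls <- nchar(site)
  if (abs(Ls - L) > 1L) return(NULL)
  m <- strsplit(mirna, "")[[1]]
  r <- rev(strsplit(site, "")[[1]])  # r[k] pairs miRNA position k (gapless)

  state_of <- function(pen, gap_at = 0L) {
    st <- ifelse(pen == 0, "match", ifelse(pen == PENALTY_WOBBLE, "GU",
                                           "mismatch"))
    if (gap_at > 0L) st[gap_at] <- "gap"
    st
  }

  if (Ls == L) {
    pen <- base_penalty(m, r)
    score <- sum(pen * core_weight(seq_len(L)))
    return(list(score = score, states = state_of(pen), gap = "none"))
  }
  if (Ls == L - 1L) {
    # one miRNA base bulged (gap on the site side), try every placement
    best <- NULL
    for (g in seq_len(L)) {
      idx <- c(seq_len(g - 1L), NA, seq_len(L - g) + g - 1L)  # r index per k
      pen <- numeric(L)
      ks <- setdiff(seq_len(L), g)
      pen[ks] <- base_penalty(m[ks], r[idx[ks]])
      pen[g] <- PENALTY_GAP
      score <- sum(pen * core_weight(seq_len(L)))
      if (is.null(best) || score < best$score) {
        best <- list(score = score, states = state_of(pen, g), gap = "mirna",
                     gap_at = g)
      }
    }
    return(best)
  }
  # Ls == L + 1: one site base bulged
  best <- NULL
  for (g in seq_len(L + 1L)) {
    # site base at reversed index g is skipped
    idx <- ifelse(seq_len(L) < g, seq_len(L), seq_len(L) + 1L)
    pen <- base_penalty(m, r[idx])
    wpos <- min(max(g, 1L), L)
    score <- sum(pen * core_weight(seq_len(L))) +
      PENALTY_GAP * core_weight(wpos)
    if (is.null(best) || score < best$score) {
      st <- state_of(pen)
      best <- list(score = score, states = st, gap = "site", gap_at = g)
    }
  }
  best
}

# penalty matrix P[k, pos]: miRNA position k against transcript position pos
penalty_matrix <- function(m, tchars) {
  P <- matrix(0, nrow = length(m), ncol = length(tchars))
  for (k in seq_along(m)) {
    P[k, ] <- base_penalty(m[k], tchars)
  }
  P
}

#' Find candidate target sites for a miRNA across transcripts
#'
#' Every window whose duplex score is at most `max_score` is reported
#' (gapless windows plus single-gap variants). The predicted cleavage
#' position is the transcript base pairing miRNA position 10, reported
#' 1-based; results are ordered by (transcript id, position).
#'
#' @param mirna mature miRNA sequence.
#' @param transcripts named character vector of transcript sequences.
#' @param max_score maximum penalty score (default 4).
#' @param mirna_id id echoed into the result.
#' @return data.frame with `mirna_id`, `transcript_id`, `site_start`,
#'   `site_end` (1-based inclusive), `score`, `cleavage_pos`, `gap`.
#' @export
find_target_sites <- function(mirna, transcripts, max_score = 4,
                              mirna_id = "miRNA") {
  mirna <- chartr("U", "T", toupper(mirna))
  L <- nchar(mirna)
  m <- strsplit(mirna, "")[[1]]
  w <- core_weight(seq_len(L))
  out <- list()
  for (tx in names(transcripts)) {
    tseq <- chartr("U", "T", toupper(transcripts[[tx]]))
    Tn <- nchar(tseq)
    if (Tn < L - 1L) next
    tchars <- strsplit(tseq, "")[[1]]
    P <- penalty_matrix(m, tchars)

    add_hits <- function(starts, scores, site_len, gap, cleave) {
      ok <- which(scores <= max_score)
      if (length(ok) == 0) return()
      out[[length(out) + 1L]] <<- data.frame(
        mirna_id = mirna_id, transcript_id = tx,
        site_start = starts[ok], site_end = starts[ok] + site_len - 1L,
        score = scores[ok], cleavage_pos = cleave[ok], gap = gap,
        stringsAsFactors = FALSE)
    }

    ## gapless: site [s, s+L-1], miRNA k pairs transcript s+L-k
    if (Tn >= L) {
      starts <- seq_len(Tn - L + 1L)
      sc <- numeric(length(starts))
      for (k in seq_len(L)) {
        sc <- sc + w[k] * P[k, starts + L - k]
      }
      add_hits(starts, sc, L, "none", starts + L - 10L)
    }

    ## one miRNA base bulged (gap on the site side): site length L - 1.
    ## miRNA k pairs transcript s+(L-1)-k for k < g, s+L-k for k > g.
    if (Tn >= L - 1L && L >= 2L) {
      starts <- seq_len(Tn - (L - 1L) + 1L)
      best <- rep(Inf, length(starts))
      gbest <- rep(1L, length(starts))
      for (g in seq_len(L)) {
        sc <- rep(PENALTY_GAP * w[g], length(starts))
        for (k in seq_len(L)) {
          if (k == g) next
          off <- if (k < g) (L - 1L) - k else L - k
          sc <- sc + w[k] * P[k, starts + off]
        }
        better <- sc < best
        best[better] <- sc[better]
        gbest[better] <- g
      }
      # miRNA position 10 pairs s+(L-1)-10 when the bulge lies 3' of it,
      # s+L-10 when 5' of it; a bulge at position 10 leaves the site base
      # adjacent to position 11 as the cut coordinate
      cleave <- ifelse(gbest > 10L, starts + L - 10L, starts + (L - 1L) - 10L)
      add_hits(starts, best, L - 1L, "mirna", cleave)
    }

    ## one site base bulged: site length L + 1.
    ## miRNA k pairs transcript s+(L+1)-k for k < g, s+L-k for k >= g.
    if (Tn >= L + 1L) {
      starts <- seq_len(Tn - (L + 1L) + 1L)
      best <- rep(Inf, length(starts))
      gbest <- rep(1L, length(starts))
      for (g in seq_len(L + 1L)) {
        wpos <- min(max(g, 1L), L)
        sc <- rep(PENALTY_GAP * core_weight(wpos), length(starts))
        for (k in seq_len(L)) {
          off <- if (k < g) (L + 1L) - k else L - k
          sc <- sc + w[k] * P[k, starts + off]
        }
        better <- sc < best
        best[better] <- sc[better]
        gbest[better] <- g
      }
      cleave <- ifelse(gbest > 10L, starts + (L + 1L) - 10L, starts + L - 10L)
      add_hits(starts, best, L + 1L, "site", cleave)
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      score = numeric(0), cleavage_pos = integer(0),
                      gap = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$site_start, res$score), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build per-transcript 5'-end tag profiles
#'
#' Each degradome tag is exact-matched to the transcripts; every match
#' increments the count at the matching 5'-end position (1-based).
#' Tags matching several transcripts (or several positions) count at every
#' match.
#'
#' @param reads degradome read data.frame (`seq` column) or character vector
#'   of tag sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param min_len tags shorter than this are ignored (default 15 nt):
#'   exact-matching very short 3'-end-truncated tags is ambiguous and would
#'   scatter counts across unrelated transcripts.
#' @return named list of integer count vectors, one per transcript, of
#'   length `nchar(transcript)`.
#' @export
build_tag_profile <- function(reads, transcripts, min_len = 15L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  seqs <- toupper(seqs)
  seqs <- seqs[nchar(seqs) >= min_len]
  profiles <- lapply(transcripts, function(tx) integer(nchar(tx)))
  if (length(seqs) == 0) return(profiles)
  tab <- data.table::data.table(seq = seqs)[, .N, by = seq]
  tab[, len := nchar(seq)]
  for (ln in sort(unique(tab$len))) {
    sub <- tab[tab$len == ln]
    for (tx in names(transcripts)) {
      w <- substr_windows(toupper(transcripts[[tx]]), ln)
      if (length(w) == 0) next
      wdt <- data.table::data.table(seq = w, pos = seq_along(w))
      hit <- wdt[sub, on = "seq", nomatch = NULL]
      if (nrow(hit) > 0) {
        profiles[[tx]][hit$pos] <- profiles[[tx]][hit$pos] + hit$N
      }
    }
  }
  profiles
}

#' Assign the degradome peak category at a cleavage site
#'
#' Category 4: exactly one raw read at the site. Category 0: site count
#' equals the transcript maximum and the maximum is unique. Category 1:
#' equals a non-unique maximum. Category 2: above the median of positions
#' with at least one read but below the maximum. Category 3: otherwise.
#'
#' @param profile integer count vector for one transcript.
#' @param position 1-based cleavage position; must carry at least one read.
#' @return integer category 0-4.
#' @export
assign_category <- function(profile, position) {
  if (position < 1 || position > length(profile)) {
    stop("cleavage position outside transcript", call. = FALSE)
  }
  count <- profile[position]
  if (count < 1) stop("no degradome signal at the cleavage position",
                      call. = FALSE)
  if (count == 1) return(4L)
  mx <- max(profile)
  if (count == mx) {
    if (sum(profile == mx) == 1L) return(0L) else return(1L)
  }
  med <- median(profile[profile >= 1])
  if (count > med) return(2L)
  3L
}

#' Call degradome-supported target hits
#'
#' Combines [find_target_sites()], [build_tag_profile()] and
#' [assign_category()]: alignments whose predicted cleavage position carries
#' at least one degradome read become `DegradomeHit`s.
#'
#' @param mirnas data.frame with `id` and `mature` columns (miRNA records).
#' @param transcripts named character vector.
#' @param degradome_reads degradome read data.frame or tag vector.
#' @param max_score maximum duplex penalty (default 4).
#' @param annotation optional data.frame (`transcript_id`, `class`) merged
#'   into the result.
#' @return data.frame of hits: alignment columns plus `tag_count`,
#'   `profile_max`, `n_max_positions`, `median_nonzero`, `category` and
#'   (when annotated) `class`.
#' @export
degradome_hits <- function(mirnas, transcripts, degradome_reads,
                           max_score = 4, annotation = NULL) {
  profiles <- build_tag_profile(degradome_reads, transcripts)
  sites <- do.call(rbind, lapply(seq_len(nrow(mirnas)), function(i) {
    find_target_sites(mirnas$mature[i], transcripts, max_score,
                      mirna_id = mirnas$id[i])
  }))
  if (is.null(sites) || nrow(sites) == 0) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      score = numeric(0), cleavage_pos = integer(0),
                      gap = character(0), tag_count = integer(0),
                      profile_max = integer(0), n_max_positions = integer(0),
                      median_nonzero = numeric(0), category = integer(0),
                      stringsAsFactors = FALSE))
  }
  keep <- logical(nrow(sites))
  cat <- integer(nrow(sites))
  tagc <- integer(nrow(sites))
  pmx <- integer(nrow(sites)); nmx <- integer(nrow(sites))
  mnz <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    pr <- profiles[[sites$transcript_id[i]]]
    pos <- sites$cleavage_pos[i]
    if (pos < 1 || pos > length(pr) || pr[pos] < 1) next
    keep[i] <- TRUE
    tagc[i] <- pr[pos]
    cat[i] <- assign_category(pr, pos)
    pmx[i] <- max(pr)
    nmx[i] <- sum(pr == max(pr))
    mnz[i] <- median(pr[pr >= 1])
  }
  out <- sites[keep, , drop = FALSE]
  out$tag_count <- tagc[keep]
  out$profile_max <- pmx[keep]
  out$n_max_positions <- nmx[keep]
  out$median_nonzero <- mnz[keep]
  out$category <- cat[keep]
  if (!is.null(annotation)) {
    out$class <- annotation$class[match(out$transcript_id,
                                        annotation$transcript_id)]
    out$class[is.na(out$class)] <- "other"
  }
  rownames(out) <- NULL
  out
}

#' Functional-class percentages of target transcripts
#'
#' Percentages are over distinct target transcripts; unannotated transcripts
#' fall into class `"other"`.
#'
#' @param hits `DegradomeHit` data.frame.
#' @param annotation data.frame with `transcript_id` and `class`.
#' @return data.frame (`class`, `n`, `percentage`), percentages summing to
#'   100 up to rounding.
#' @export
classify_target_function <- function(hits, annotation) {
  tx <- unique(hits$transcript_id)
  if (length(tx) == 0) {
    return(data.frame(class = character(0), n = integer(0),
                      percentage = numeric(0)))
  }
  cls <- annotation$class[match(tx, annotation$transcript_id)]
  cls[is.na(cls)] <- "other"
  tab <- table(cls)
  out <- data.frame(class = names(tab), n = as.integer(tab),
                    percentage = 100 * as.integer(tab) / length(tx),
                    stringsAsFactors = FALSE)
  out[order(-out$n, out$class), , drop = FALSE]
}
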