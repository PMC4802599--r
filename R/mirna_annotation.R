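# Known-miRNA annotation (isomiR-tolerant matching against a miRBase-style
# mature reference) and novel-miRNA prediction from hairpin secondary
# structure.

#' Parse a miRNA family from a mature id
#'
#' `"zma-miR159a-3p"` -> `"zma-miR159"`.
#'
#' @param id character vector of mature miRNA ids.
#' @return character vector of family names (the id itself when no family
#'   pattern is recognized).
#' @export
mirna_family <- function(id) {
  m <- regexpr("^[A-Za-z]{3}-(miR|MIR)[0-9]+", id)
  ifelse(m > 0, substr(id, 1L, attr(m, "match.length")), id)
}

# does `tag` match `ref` allowing end shifts of at most `max_shift` nt at
# each end with no internal mismatches? Returns the total shift (|5'| + |3'|)
# or NA when there is no valid alignment.
shift_match_one <- function(tag, ref, max_shift = 2L) {
  lt <- nchar(tag); lr <- nchar(ref)
  best <- NA_integer_
  for (o in -max_shift:max_shift) {       # ref position of tag position 1, minus 1
    e <- o + lt - lr                      # 3' end shift
    if (abs(e) > max_shift) next
    i0 <- max(1L, 1L - o); i1 <- min(lt, lr - o)
    if (i1 < i0) next
    if (substr(tag, i0, i1) == substr(ref, i0 + o, i1 + o)) {
      s <- abs(o) + abs(e)
      if (is.na(best) || s < best) best <- s
    }
  }
  best
}

#' Annotate tags against a mature miRNA reference
#'
#' A tag annotates a reference mature when it is identical, or identical up
#' to a 5'/3' end shift of at most 2 nt (isomiR tolerance, no internal
#' mismatches). Each tag is assigned to at most one reference (smallest total
#' shift wins, ties broken by reference order); counts of all tags assigned
#' to one mature id are summed per library.
#'
#' @param table a `tag_table` (ideally mapped and ncRNA-free).
#' @param mature_ref named character vector of mature sequences; names are
#'   miRNA ids (duplicates are an error).
#' @param max_shift maximum end shift in nt (default 2).
#' @return data.frame of known `MiRNARecord`s: `id`, `family`, `mature`,
#'   `status`, locus columns (from the exactly-matching tag's genome hit
#'   when available) and one count column per library. The tag-to-miRNA
#'   assignment is attached as attribute `"assignment"`.
#' @export
annotate_known <- function(table, mature_ref, max_shift = 2L) {
  if (anyDuplicated(names(mature_ref))) {
    stop("duplicate reference ids: ",
         paste(unique(names(mature_ref)[duplicated(names(mature_ref))]),
               collapse = ", "), call. = FALSE)
  }
  libs <- tag_table_libraries(table)
  tags <- table$tag
  assign_id <- rep(NA_character_, length(tags))
  assign_shift <- rep(NA_integer_, length(tags))
  refs <- toupper(mature_ref)
  for (r in seq_along(refs)) {
    lr <- nchar(refs[[r]])
    cand <- which(abs(nchar(tags) - lr) <= 2L * max_shift)
    for (i in cand) {
      s <- shift_match_one(tags[i], refs[[r]], max_shift)
      if (!is.na(s) && (is.na(assign_shift[i]) || s < assign_shift[i])) {
        assign_shift[i] <- s
        assign_id[i] <- names(refs)[r]
      }
    }
  }
  assigned <- !is.na(assign_id)
  ids <- unique(assign_id[assigned])
  rows <- lapply(ids, function(id) {
    sel <- which(assign_id == id)
    counts <- if (length(libs) > 0) {
      colSums(as.matrix(table[sel, libs, drop = FALSE]))
    } else numeric(0)
    # locus from the exactly-matching tag's unique genome hit, if present
    chrom <- NA_character_; start <- NA_integer_; end <- NA_integer_
    strand <- NA_character_
    if ("hits" %in% names(table)) {
      exact <- sel[tags[sel] == refs[[id]] & table$n_hits[sel] == 1L]
      if (length(exact) >= 1) {
        h <- parse_hits(table$hits[exact[1]])
        chrom <- h$chrom[1]; start <- h$start[1]
        end <- start + nchar(tags[exact[1]]); strand <- h$strand[1]
      }
    }
    df <- data.frame(id = id, family = mirna_family(id),
                     mature = as.character(refs[[id]]), status = "known",
                     chrom = chrom, start = start, end = end, strand = strand,
                     stringsAsFactors = FALSE)
    for (lib in libs) df[[lib]] <- as.numeric(counts[[lib]])
    df
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    empty_mirna_records(libs)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assignment") <- data.frame(tag = tags[assigned],
                                        mirna_id = assign_id[assigned],
                                        shift = assign_shift[assigned],
                                        stringsAsFactors = FALSE)
  attr(out, "libraries") <- libs
  out
}

empty_mirna_records <- function(libs) {
  df <- data.frame(id = character(0), family = character(0),
                   mature = character(0), status = character(0),
                   chrom = character(0), start = integer(0), end = integer(0),
                   strand = character(0), stringsAsFactors = FALSE)
  for (lib in libs) df[[lib]] <- numeric(0)
  df
}

#' Extract candidate precursor windows around a genomic tag hit
#'
#' Two windows are returned, covering the cases where the tag sits on the 5'
#' arm (flank downstream in transcript orientation) or the 3' arm (flank
#' upstream). Minus-strand hits are reverse-complemented so the returned
#' sequences read 5'->3' with the tag in its sequenced orientation. Windows
#' clipped at reference ends are flagged `truncated`.
#'
#' @param chrom,start,end,strand the tag hit (0-based half-open, plus-strand
#'   coordinates).
#' @param genome named character vector of reference sequences.
#' @param flank flank length in nt (default 150).
#' @return data.frame with columns `orientation` (`tag5p`/`tag3p`), `seq`,
#'   `win_start`, `win_end` (genomic, 0-based half-open), `truncated`,
#'   `tag_from`, `tag_to` (1-based tag position within `seq`).
#' @export
extract_precursor <- function(chrom, start, end, strand, genome,
                              flank = 150L) {
  gseq <- genome[[chrom]]
  L <- nchar(gseq)
  taglen <- end - start
  win <- function(ws, we) {
    ws2 <- max(0L, ws); we2 <- min(L, we)
    list(ws = ws2, we = we2, trunc = (ws2 != ws) || (we2 != we),
         seq = substr(gseq, ws2 + 1L, we2))
  }
  if (strand == "+") {
    w5 <- win(start, end + flank)   # tag at 5' end of the window
    w3 <- win(start - flank, end)   # tag at 3' end
    seq5 <- w5$seq; seq3 <- w3$seq
    tag5_from <- start - w5$ws + 1L
    tag3_from <- start - w3$ws + 1L
  } else {
    # in RNA orientation the downstream flank lies genomically upstream
    w5 <- win(start - flank, end)
    w3 <- win(start, end + flank)
    seq5 <- dna_revcomp(w5$seq); seq3 <- dna_revcomp(w3$seq)
    tag5_from <- w5$we - end + 1L
    tag3_from <- w3$we - end + 1L
  }
  data.frame(
    orientation = c("tag5p", "tag3p"),
    seq = c(seq5, seq3),
    win_start = c(w5$ws, w3$ws),
    win_end = c(w5$we, w3$we),
    truncated = c(w5$trunc, w3$trunc),
    tag_from = c(tag5_from, tag3_from),
    tag_to = c(tag5_from, tag3_from) + taglen - 1L,
    stringsAsFactors = FALSE
  )
}

#' Fold a candidate precursor
#'
#' Pseudoknot-free base-pair maximization (A-U, G-C and G-U wobble pairs,
#' minimum hairpin loop of `min_loop` nt) with deterministic traceback. The
#' stability score is `-(pairs + 0.5 * stacked pairs)`, scaled so canonical
#' miRNA hairpins (stems of roughly 13 bp and longer) score below -18 units;
#' lower is more stable.
#'
#' @param seq precursor sequence (ACGU/T, at most 300 nt).
#' @param min_loop minimum hairpin loop length (default 3).
#' @return list with `partner` (integer vector, 0 = unpaired, otherwise the
#'   1-based partner), `pairs` (two-column matrix, i < j), `n_pairs`,
#'   `n_stacks`, `score` and `structure` (dot-bracket string).
#' @export
fold_hairpin <- function(seq, min_loop = 3L) {
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  if (grepl("[^ACGT]", seq)) {
    stop("precursor contains non-ACGU(T) characters", call. = FALSE)
  }
  if (nchar(seq) > 300L) {
    stop("precursor longer than 300 nt", call. = FALSE)
  }
  partner <- fold_partner_cpp(seq, min_loop)
  i <- which(partner > seq_along(partner))
  pairs <- cbind(i = i, j = partner[i])
  n_pairs <- nrow(pairs)
  n_stacks <- if (n_pairs > 0) {
    sum(partner[pmin(pairs[, 1] + 1L, length(partner))] == pairs[, 2] - 1L &
          pairs[, 1] + 1L < pairs[, 2] - 1L)
  } else 0L
  db <- rep(".", nchar(seq))
  db[pairs[, 1]] <- "("
  db[pairs[, 2]] <- ")"
  list(partner = as.integer(partner), pairs = pairs, n_pairs = n_pairs,
       n_stacks = n_stacks, score = -(n_pairs + 0.5 * n_stacks),
       structure = paste(db, collapse = ""))
}

#' Criteria for calling a novel miRNA locus
#'
#' @param min_len,max_len mature length window (18-26 nt).
#' @param max_star_mismatch maximum unpaired mature positions when paired
#'   against the star arm.
#' @param max_bulge maximum run of consecutive unpaired positions (nt) in
#'   either arm of the mature/star duplex.
#' @param max_score stability threshold in score units (call requires
#'   score <= `max_score`).
#' @param flank precursor flank in nt.
#' @param min_loop minimum loop separation between mature and star.
#' @return a named list of criteria.
#' @export
novel_criteria <- function(min_len = 18L, max_len = 26L,
                           max_star_mismatch = 4L, max_bulge = 2L,
                           max_score = -18, flank = 150L, min_loop = 3L) {
  list(min_len = min_len, max_len = max_len,
       max_star_mismatch = max_star_mismatch, max_bulge = max_bulge,
       max_score = max_score, flank = flank, min_loop = min_loop)
}

max_run <- function(x) {
  if (length(x) == 0 || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# evaluate one precursor window; tag occupies positions tag_from..tag_to
# (1-based within `seq`). Returns NULL on rejection, otherwise hairpin stats.
#
# Two stages: (1) find the star arm by direct antiparallel duplex alignment
# of the mature against every candidate window on either side (wobble pairs
# count as paired; one 1-nt bulge allowed) — a base-pair maximizing fold of
# the whole window is too opportunistic (long-range pairings) to be used
# for this; (2) fold the exact mature..star region for the stability score
# and require that the mature/star stem dominates that fold (single major
# stem).
evaluate_hairpin_window <- function(seq, tag_from, tag_to, criteria) {
  n <- nchar(seq)
  if (tag_to > n || tag_from < 1) return(NULL)
  taglen <- tag_to - tag_from + 1L
  tag_seq <- substr(seq, tag_from, tag_to)

  best <- NULL
  alt_mid <- numeric(0)    # midpoint and quality of every candidate window
  alt_mm <- integer(0)
  for (L in (taglen - 1L):(taglen + 1L)) {
    if (n < L) next
    for (s in seq_len(n - L + 1L)) {
      e <- s + L - 1L
      # the mature must sit wholly on one arm: a star overlapping the tag
      # means the tag spans the loop
      if (s <= tag_to && e >= tag_from) next
      loop_sep <- if (s > tag_to) s - tag_to - 1L else tag_from - e - 1L
      if (loop_sep < criteria$min_loop) next
      dup <- score_duplex(tag_seq, substr(seq, s, e))
      if (is.null(dup)) next
      unp <- dup$states %in% c("mismatch", "gap")
      mm <- sum(unp)
      if (mm <= criteria$max_star_mismatch) {
        alt_mid <- c(alt_mid, (s + e) / 2)
        alt_mm <- c(alt_mm, mm)
      }
      if (is.null(best) || mm < best$mm ||
          (mm == best$mm && loop_sep < best$loop_sep)) {
        best <- list(mm = mm, run = max_run(unp), s = s, e = e,
                     loop_sep = loop_sep)
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (best$mm > criteria$max_star_mismatch) return(NULL)
  if (best$run > criteria$max_bulge) return(NULL)
  # single major stem: no *competing* star (within one mismatch of the best)
  # may exist outside the chosen stem's neighborhood — that would place the
  # tag in a multi-stem, repeat-like context rather than one hairpin.
  # Windows merely under the mismatch ceiling do not compete: a single
  # bulged alignment against random flank reaches the ceiling by chance.
  competing <- alt_mm <= best$mm + 1L &
    abs(alt_mid - (best$s + best$e) / 2) > taglen + 10L
  if (any(competing)) return(NULL)

  ## fold the exact hairpin region for the stability score
  r0 <- min(tag_from, best$s); r1 <- max(tag_to, best$e)
  sub <- substr(seq, r0, r1)
  f2 <- fold_hairpin(sub, criteria$min_loop)
  if (f2$score > criteria$max_score) return(NULL)
  list(score = f2$score, n_mature_mismatches = best$mm,
       star_from = best$s, star_to = best$e, loop_sep = best$loop_sep,
       precursor = sub, precursor_from = r0, precursor_to = r1)
}

#' Predict novel miRNA loci from unannotated mapped tags
#'
#' A locus is called when the tag is 18-26 nt, lies wholly on one arm of a
#' predicted hairpin (never spanning the loop), pairs with a star region on
#' the opposite arm with at most `max_star_mismatch` unpaired positions and
#' no bulge longer than `max_bulge` nt, has no second acceptable star
#' region elsewhere in the precursor (single major stem), and the
#' mature..star region folds with a stability score of `max_score` or
#' lower. Identical tags at several loci yield one record
#' per locus; records are deduplicated by sequence + locus and numbered in
#' genomic order.
#'
#' @param table a `tag_table` of mapped, reference-unassigned tags (must
#'   carry `hits` from [map_tags()]).
#' @param genome named character vector of reference sequences.
#' @param criteria a [novel_criteria()] list.
#' @return data.frame of novel `MiRNARecord`s with the same columns as
#'   [annotate_known()] plus `score`; ids are `Predict-miR-<n>`.
#' @export
call_novel_mirnas <- function(table, genome, criteria = novel_criteria()) {
  stopifnot("hits" %in% names(table))
  libs <- tag_table_libraries(table)
  recs <- list()
  for (i in seq_len(nrow(table))) {
    tag <- table$tag[i]
    lt <- nchar(tag)
    if (lt < criteria$min_len || lt > criteria$max_len) next
    if (!table$mapped[i]) next
    hits <- parse_hits(table$hits[i])
    for (h in seq_len(nrow(hits))) {
      wins <- extract_precursor(hits$chrom[h], hits$start[h],
                                hits$start[h] + lt, hits$strand[h],
                                genome, criteria$flank)
      best <- NULL
      for (w in seq_len(nrow(wins))) {
        ev <- evaluate_hairpin_window(wins$seq[w], wins$tag_from[w],
                                      wins$tag_to[w], criteria)
        if (!is.null(ev) && (is.null(best) || ev$score < best$score)) {
          best <- ev
        }
      }
      if (is.null(best)) next
      counts <- if (length(libs) > 0) {
        as.numeric(table[i, libs, drop = FALSE])
      } else numeric(0)
      rec <- data.frame(id = NA_character_, family = NA_character_,
                        mature = tag, status = "novel",
                        chrom = hits$chrom[h], start = hits$start[h],
                        end = hits$start[h] + lt, strand = hits$strand[h],
                        score = best$score,
                        n_mature_mismatches = best$n_mature_mismatches,
                        stringsAsFactors = FALSE)
      for (k in seq_along(libs)) rec[[libs[k]]] <- counts[k]
      recs[[length(recs) + 1L]] <- rec
    }
  }
  if (length(recs) == 0) {
    out <- empty_mirna_records(libs)
    out$score <- numeric(0)
    out$n_mature_mismatches <- integer(0)
    attr(out, "libraries") <- libs
    return(out)
  }
  out <- do.call(rbind, recs)
  out <- out[!duplicated(out[, c("mature", "chrom", "start", "strand")]), ,
             drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$id <- sprintf("Predict-miR-%d", seq_len(nrow(out)))
  out$family <- out$id
  rownames(out) <- NULL
  attr(out, "libraries") <- libs
  out
}
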