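# Clean-read pipeline: adapter trimming + quality filtering, 18-32 nt tag
# collapsing, exact genome mapping on both strands, and structural-ncRNA
# removal. Coordinates are 0-based half-open internally.

#' Trim 3' adapters and drop low-quality reads
#'
#' The 3' adapter is detected as the longest read suffix that is an exact
#' prefix of the adapter, requiring at least 6 matching nt, and removed.
#' Reads containing N, reads whose mean Phred score over the trimmed insert
#' falls below `min_mean_quality`, and reads trimmed to nothing are
#' discarded; per-reason counts are reported in the log.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (see
#'   [read_fastq()]).
#' @param adapter adapter sequence (non-empty, >= 6 nt usable).
#' @param min_mean_quality mean Phred threshold (default 20).
#' @return list with `reads` (clean read data.frame) and `log` (named counts:
#'   input, adapter_trimmed, discarded_n, discarded_quality, discarded_empty,
#'   output).
#' @export
trim_and_quality_filter <- function(reads, adapter, min_mean_quality = 20) {
  if (missing(adapter) || is.null(adapter) || !nzchar(adapter)) {
    stop("adapter must be a non-empty sequence", call. = FALSE)
  }
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  bad_rec <- which(nchar(reads$seq) != nchar(reads$qual) |
                     nchar(reads$seq) == 0L)
  if (length(bad_rec) > 0) {
    stop("malformed FASTQ record at index ", bad_rec[1], call. = FALSE)
  }
  adapter <- toupper(adapter)
  n <- nrow(reads)
  seqs <- toupper(reads$seq)
  lens <- nchar(seqs)

  trim_k <- integer(n)
  kmax <- min(nchar(adapter), max(lens))
  if (kmax >= 6L) {
    for (k in kmax:6L) {
      cand <- trim_k == 0L & lens >= k
      if (!any(cand)) next
      hit <- substr(seqs[cand], lens[cand] - k + 1L, lens[cand]) ==
        substr(adapter, 1L, k)
      trim_k[cand][hit] <- k
    }
  }
  trimmed <- substr(seqs, 1L, lens - trim_k)
  trimmed_qual <- substr(reads$qual, 1L, lens - trim_k)

  empty <- nchar(trimmed) == 0L
  has_n <- !empty & grepl("N", trimmed, fixed = TRUE)
  meanq <- rep(NA_real_, n)
  rest <- !empty & !has_n
  meanq[rest] <- qual_means(trimmed_qual[rest])
  lowq <- rest & meanq < min_mean_quality

  keep <- !(empty | has_n | lowq)
  out <- data.frame(id = reads$id[keep], seq = trimmed[keep],
                    qual = trimmed_qual[keep], stringsAsFactors = FALSE)
  log <- c(input = n,
           adapter_trimmed = sum(trim_k > 0L),
           discarded_empty = sum(empty),
           discarded_n = sum(has_n),
           discarded_quality = sum(lowq),
           output = sum(keep))
  list(reads = out, log = log)
}

#' Length-filter reads and collapse identical tags
#'
#' Keeps reads of `min_len`-`max_len` nt (18-32 by default, boundaries
#' inclusive) and collapses identical sequences into unique tags with
#' per-library counts.
#'
#' @param reads_by_library named list of clean read data.frames (names are
#'   library ids).
#' @param min_len,max_len retained length window in nt.
#' @return a `tag_table`: data.frame with columns `tag`, `length` and one
#'   count column per library, plus attributes `libraries` and
#'   `length_discarded` (read-weighted per-library discard counts).
#' @export
length_filter_and_collapse <- function(reads_by_library, min_len = 18L,
                                       max_len = 32L) {
  stopifnot(is.list(reads_by_library), length(names(reads_by_library)) ==
              length(reads_by_library))
  libs <- names(reads_by_library)
  dts <- lapply(libs, function(lib) {
    df <- reads_by_library[[lib]]
    data.table::data.table(library = lib, tag = toupper(df$seq))
  })
  dt <- data.table::rbindlist(dts)
  dt[, len := nchar(tag)]
  discarded <- dt[len < min_len | len > max_len, .N, by = library]
  length_discarded <- setNames(rep(0L, length(libs)), libs)
  if (nrow(discarded) > 0) {
    length_discarded[discarded$library] <- discarded$N
  }
  dt <- dt[len >= min_len & len <= max_len]
  counts <- dt[, .N, by = .(tag, len, library)]
  wide <- data.table::dcast(counts, tag + len ~ library, value.var = "N",
                            fill = 0L)
  for (lib in setdiff(libs, names(wide))) wide[[lib]] <- 0L
  wide <- wide[order(tag)]
  out <- data.frame(tag = wide$tag, length = wide$len,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (lib in libs) out[[lib]] <- wide[[lib]]
  attr(out, "libraries") <- libs
  attr(out, "length_discarded") <- length_discarded
  class(out) <- c("tag_table", "data.frame")
  out
}

tag_table_libraries <- function(table) {
  libs <- attr(table, "libraries")
  if (is.null(libs)) {
    libs <- setdiff(names(table),
                    c("tag", "length", "n_hits", "hits", "mapped"))
  }
  libs
}

#' Map tags to a genome by exact full-length matching
#'
#' Both strands are searched (minus strand via reverse complement); all hit
#' positions are reported as 0-based starts on the plus strand. Unmapped
#' tags are flagged (`mapped = FALSE`) so they can be excluded from
#' candidate-read accounting downstream.
#'
#' @param table a `tag_table`.
#' @param genome named character vector of reference sequences.
#' @return the table with added columns `n_hits`, `hits`
#'   (`"ref:start:strand"` separated by `;`) and `mapped`.
#' @export
map_tags <- function(table, genome) {
  if (length(genome) == 0 || any(!nzchar(genome))) {
    stop("genome must be non-empty", call. = FALSE)
  }
  tags <- table$tag
  if (length(tags) == 0) {
    table$n_hits <- integer(0); table$hits <- character(0)
    table$mapped <- logical(0)
    return(table)
  }
  K <- min(nchar(tags))
  genome <- toupper(genome)

  idx <- data.table::rbindlist(lapply(names(genome), function(chrom) {
    kmers <- substr_windows(genome[[chrom]], K)
    data.table::data.table(kmer = kmers, chrom = chrom,
                           pos = seq_along(kmers))  # 1-based
  }))
  data.table::setkey(idx, kmer)

  query <- data.table::data.table(
    tag_i = rep(seq_along(tags), 2L),
    strand = rep(c("+", "-"), each = length(tags)),
    full = c(tags, dna_revcomp(tags))
  )
  query[, kmer := substr(full, 1L, K)]
  hits <- idx[query, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) > 0) {
    hits[, len := nchar(full)]
    hits[, ok := substring(genome[[chrom]], pos, pos + len - 1L) == full,
         by = .(chrom)]
    hits <- hits[ok == TRUE]
  }
  hit_str <- character(length(tags))
  n_hits <- integer(length(tags))
  if (nrow(hits) > 0) {
    hits[, start0 := pos - 1L]
    hits <- hits[order(tag_i, chrom, start0, strand)]
    agg <- hits[, .(s = paste(sprintf("%s:%d:%s", chrom, start0, strand),
                              collapse = ";"), n = .N), by = tag_i]
    hit_str[agg$tag_i] <- agg$s
    n_hits[agg$tag_i] <- agg$n
  }
  table$n_hits <- n_hits
  table$hits <- hit_str
  table$mapped <- n_hits > 0L
  table
}

#' Parse a `hits` string into a data.frame
#'
#' @param hits character vector in the `"ref:start:strand;..."` format
#'   produced by [map_tags()] (starts are 0-based).
#' @return data.frame with columns `chrom`, `start`, `strand` for the first
#'   element of `hits` split at `;` boundaries; vectorized callers should
#'   loop.
#' @export
parse_hits <- function(hits) {
  parts <- strsplit(unlist(strsplit(hits, ";", fixed = TRUE)), ":",
                    fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             start = as.integer(vapply(parts, `[`, "", 2L)),
             strand = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Remove tags matching structural ncRNAs
#'
#' A tag is removed when it occurs as an exact (sense-strand) subsequence of
#' any ncRNA reference entry. Reference entry classes are parsed from the
#' `class=` field of the FASTA header when present, otherwise from the
#' leading token of the entry name (e.g. `rRNA_03` -> `rRNA`).
#'
#' @param table a `tag_table`.
#' @param ncrna_ref named character vector of ncRNA reference sequences.
#' @return list with `table` (surviving tags, the candidate miRNA reads) and
#'   `report` (per-class removed tag and read counts).
#' @export
remove_ncrna <- function(table, ncrna_ref) {
  classes <- ncrna_classes(ncrna_ref)
  allowed <- c("rRNA", "tRNA", "snRNA", "snoRNA", "cis-reg")
  if (!all(classes %in% allowed)) {
    stop("unknown ncRNA class: ",
         paste(setdiff(classes, allowed), collapse = ", "), call. = FALSE)
  }
  libs <- tag_table_libraries(table)
  tag_class <- rep(NA_character_, nrow(table))
  if (nrow(table) > 0 && length(ncrna_ref) > 0) {
    for (len in sort(unique(table$length))) {
      subs <- data.table::rbindlist(lapply(seq_along(ncrna_ref), function(i) {
        w <- substr_windows(toupper(ncrna_ref[[i]]), len)
        if (length(w) == 0) return(NULL)
        data.table::data.table(sub = w, class = classes[i], ord = i)
      }))
      if (is.null(subs) || nrow(subs) == 0) next
      subs <- subs[order(ord)]
      first <- subs[!duplicated(sub)]
      sel <- which(table$length == len & is.na(tag_class))
      m <- match(table$tag[sel], first$sub)
      tag_class[sel[!is.na(m)]] <- first$class[m[!is.na(m)]]
    }
  }
  removed <- !is.na(tag_class)
  report <- do.call(rbind, lapply(allowed, function(cl) {
    sel <- which(tag_class == cl)
    reads <- if (length(sel) > 0 && length(libs) > 0) {
      sum(as.matrix(table[sel, libs, drop = FALSE]))
    } else 0L
    data.frame(class = cl, tags_removed = length(sel),
               reads_removed = reads, stringsAsFactors = FALSE)
  }))
  reads_removed_by_lib <- if (length(libs) > 0) {
    colSums(as.matrix(table[removed, libs, drop = FALSE]))
  } else numeric(0)
  out <- table[!removed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "libraries") <- libs
  attr(out, "length_discarded") <- attr(table, "length_discarded")
  class(out) <- class(table)
  list(table = out, report = report,
       reads_removed_by_library = reads_removed_by_lib)
}

ncrna_classes <- function(ncrna_ref) {
  desc <- attr(ncrna_ref, "description")
  nm <- names(ncrna_ref)
  cls <- character(length(ncrna_ref))
  if (!is.null(desc) && any(grepl("class=", desc))) {
    cls <- ifelse(grepl("class=", desc),
                  sub("^.*class=(\\S+).*$", "\\1", desc),
                  sub("_[0-9]+$", "", nm))
  } else {
    cls <- sub("_[0-9]+$", "", nm)
  }
  cls
}

#' Read-weighted tag length distribution
#'
#' @param table a `tag_table`.
#' @return list with `distribution` (data.frame library/length/fraction,
#'   fractions summing to 1 per non-empty library) and `frac_20_24` (named
#'   vector, the 20-24 nt aggregate fraction per library; `NA` for an empty
#'   library).
#' @export
length_distribution <- function(table) {
  if (nrow(table) == 0) stop("tag table is empty", call. = FALSE)
  libs <- tag_table_libraries(table)
  rows <- list()
  frac2024 <- setNames(rep(NA_real_, length(libs)), libs)
  for (lib in libs) {
    tot <- sum(table[[lib]])
    if (tot == 0) next
    agg <- tapply(table[[lib]], table$length, sum)
    fr <- as.numeric(agg) / tot
    rows[[lib]] <- data.frame(library = lib,
                              length = as.integer(names(agg)),
                              fraction = fr, stringsAsFactors = FALSE)
    lens <- as.integer(names(agg))
    frac2024[lib] <- sum(fr[lens >= 20 & lens <= 24])
  }
  list(distribution = if (length(rows)) do.call(rbind, rows) else
         data.frame(library = character(0), length = integer(0),
                    fraction = numeric(0)),
       frac_20_24 = frac2024)
}
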