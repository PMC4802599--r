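# Synthetic study generator: a toy genome with planted miRNA hairpins and
# structural-ncRNA loci, four sRNA libraries (2 genotypes x 2 timepoints),
# a degradome library peaked at planted cleavage sites, and qPCR/absorbance
# tables, all deterministic under one seed.

MAIZE_MIR_FAMILIES <- c(156, 159, 160, 164, 166, 167, 168, 169, 171, 172,
                        319, 390, 393, 394, 395, 396, 397, 398, 399, 408,
                        528, 529)

SENMIR_LIBRARIES <- c("ELS1_20DAP", "ELS1_30DAP", "Yu871_20DAP", "Yu871_30DAP")

#' Simulation configuration
#'
#' Study conditions for the synthetic generator: a 2 genotypes (early-senescing
#' ELS-1 vs stay-green Yu87-1) x 2 timepoints (20 and 30 days after
#' pollination) small-RNA design with planted senescence-associated (SA)
#' miRNAs, plus a degradome library and phenotype tables.
#'
#' @param seed integer; fully determines every generated artifact.
#' @param genome_length toy genome size in nt.
#' @param n_known_mirnas number of planted miRNA loci carried in the
#'   miRBase-style mature reference.
#' @param n_novel_mirnas number of planted loci absent from the reference
#'   (recoverable only through hairpin prediction).
#' @param n_ncrna_loci number of structural ncRNA loci (rRNA/tRNA/snRNA/
#'   snoRNA/cis-reg) that contaminate the libraries.
#' @param n_sa_mirnas number of planted SA-miRNAs (differential in ELS-1
#'   only); must not exceed the total miRNA count.
#' @param reads_per_library sequencing depth of each of the four libraries.
#' @param sa_fold_change linear expression ratio planted for SA-miRNAs between
#'   30 and 20 DAP in ELS-1; must exceed 2^1.5 so candidates clear the
#'   selection threshold with margin.
#' @param nb_dispersion negative-binomial dispersion of simulated counts
#'   (variance mu + dispersion * mu^2); 0 gives deterministic rounded counts.
#' @param degradome_peak_fraction fraction of a targeted transcript's
#'   degradome tags whose 5' end sits exactly at the planted cleavage site.
#' @param adapter 3' sequencing adapter appended to a fraction of reads.
#' @param adapter_fraction fraction of sRNA reads carrying the adapter.
#' @param ncrna_read_fraction nominal fraction of reads drawn from ncRNA loci
#'   (this pool also absorbs the count-noise remainder so library depth is
#'   exact).
#' @param lowq_read_fraction fraction of reads that are low-quality or
#'   N-containing and should fall to the quality filter.
#' @param read_cycles sequencer read length in cycles.
#' @param degradome_tags total degradome tag count.
#' @param degradome_tag_length degradome tag length (5'-end sequencing).
#' @param ct_sd Gaussian noise, in cycles, added to simulated Ct values.
#' @param absorbance_sd Gaussian noise added to simulated absorbances.
#' @param n_transcripts_background untargeted transcripts in the toy
#'   transcriptome.
#' @param flank precursor flank length used when planting hairpins.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 101L,
                       genome_length = 200000L,
                       n_known_mirnas = 40L,
                       n_novel_mirnas = 10L,
                       n_ncrna_loci = 20L,
                       n_sa_mirnas = 8L,
                       reads_per_library = 50000L,
                       sa_fold_change = 4,
                       nb_dispersion = 0.002,
                       degradome_peak_fraction = 0.7,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       adapter_fraction = 0.6,
                       ncrna_read_fraction = 0.15,
                       lowq_read_fraction = 0.02,
                       read_cycles = 36L,
                       degradome_tags = 20000L,
                       degradome_tag_length = 36L,
                       ct_sd = 0.15,
                       absorbance_sd = 0.005,
                       n_transcripts_background = 8L,
                       flank = 150L) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_known_mirnas = as.integer(n_known_mirnas),
              n_novel_mirnas = as.integer(n_novel_mirnas),
              n_ncrna_loci = as.integer(n_ncrna_loci),
              n_sa_mirnas = as.integer(n_sa_mirnas),
              reads_per_library = as.integer(reads_per_library),
              sa_fold_change = sa_fold_change,
              nb_dispersion = nb_dispersion,
              degradome_peak_fraction = degradome_peak_fraction,
              adapter = toupper(adapter),
              adapter_fraction = adapter_fraction,
              ncrna_read_fraction = ncrna_read_fraction,
              lowq_read_fraction = lowq_read_fraction,
              read_cycles = as.integer(read_cycles),
              degradome_tags = as.integer(degradome_tags),
              degradome_tag_length = as.integer(degradome_tag_length),
              ct_sd = ct_sd,
              absorbance_sd = absorbance_sd,
              n_transcripts_background = as.integer(n_transcripts_background),
              flank = as.integer(flank))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  n_mirna <- cfg$n_known_mirnas + cfg$n_novel_mirnas
  if (cfg$n_sa_mirnas > n_mirna) {
    stop("n_sa_mirnas (", cfg$n_sa_mirnas, ") exceeds the planted miRNA ",
         "count (", n_mirna, ")", call. = FALSE)
  }
  if (cfg$n_sa_mirnas > 0 && cfg$sa_fold_change <= 2^1.5) {
    stop("sa_fold_change must exceed 2^1.5 so planted SA-miRNAs clear the ",
         "log2 fold-change threshold of 1.5", call. = FALSE)
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$degradome_peak_fraction < 0 || cfg$degradome_peak_fraction > 1) {
    stop("degradome_peak_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (nchar(cfg$adapter) < 6) stop("adapter must be >= 6 nt", call. = FALSE)
  fr <- cfg$ncrna_read_fraction + cfg$lowq_read_fraction
  if (fr >= 1) stop("ncRNA + low-quality read fractions must be < 1",
                    call. = FALSE)
  # capacity is re-checked precisely at assembly time
  invisible(cfg)
}

rand_dna <- function(len) {
  vapply(len, function(l) paste(sample(c("A", "C", "G", "T"), l,
                                       replace = TRUE), collapse = ""),
         character(1))
}

count_occurrences <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# star arm: reverse complement of the mature with n_mm complement-breaking
# substitutions at interior positions (substitutions only, so no bulges)
make_star <- function(mature, n_mm) {
  star <- strsplit(dna_revcomp(mature), "")[[1]]
  if (n_mm > 0) {
    idx <- sample(3:(length(star) - 2), n_mm)
    for (i in idx) {
      star[i] <- sample(setdiff(c("A", "C", "G", "T"), star[i]), 1)
    }
  }
  paste(star, collapse = "")
}

#' Generate the toy genome, references and planted truth
#'
#' Assembles a random genome in which each miRNA locus is a fold-back
#' precursor (mature arm + loop + near-complementary star arm, placed on a
#' random strand) and each ncRNA locus is a contaminant reference entry, then
#' derives the planted expression matrix, SA flags, target transcripts with
#' cleavage sites, and phenotype trajectories anchored at the chlorophyll
#' values of the study design (e.g. chlorophyll a falling from 25.58 mg/L at
#' 25 DAP to 0.35 mg/L at 30 DAP in the early-senescing genotype).
#'
#' Every planted mature sequence occurs at exactly one genomic position
#' (the star arm always carries at least one mismatch, so the minus-strand
#' copy is inexact); this is verified and enforced at generation time.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `senmir_sim`: list with `genome` (named
#'   character), `features` (0-based half-open annotation data.frame),
#'   `truth` (class `planted_truth`), `mature_ref`, `ncrna_ref`,
#'   `transcripts`, `transcript_annotation` and `config`.
#' @export
generate_toy_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_known <- config$n_known_mirnas
  n_novel <- config$n_novel_mirnas
  n_mirna <- n_known + n_novel
  n_nc <- config$n_ncrna_loci

  ## ids and families
  fam_num <- rep(MAIZE_MIR_FAMILIES, length.out = max(n_known, 1L))
  known_ids <- character(n_known)
  if (n_known > 0) {
    for (f in unique(fam_num[seq_len(n_known)])) {
      idx <- which(fam_num[seq_len(n_known)] == f)
      suffix <- if (length(idx) == 1) "a" else letters[seq_along(idx)]
      known_ids[idx] <- paste0("zma-miR", f, suffix)
    }
  }
  novel_ids <- if (n_novel > 0) sprintf("novel-miR-%02d", seq_len(n_novel))
               else character(0)
  ids <- c(known_ids, novel_ids)
  families <- c(if (n_known > 0) paste0("zma-miR", fam_num[seq_len(n_known)])
                else character(0),
                novel_ids)
  status <- rep(c("known", "novel"), c(n_known, n_novel))

  ## mature lengths: knowns mostly 21-22 nt, novels 20-23 nt
  mat_len <- c(sample(20:24, n_known, replace = TRUE,
                      prob = c(.15, .40, .30, .10, .05)),
               sample(20:23, n_novel, replace = TRUE,
                      prob = c(.25, .35, .25, .15)))

  ## ncRNA loci
  nc_classes <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA", "cis-reg"),
                    length.out = max(n_nc, 1L))[seq_len(n_nc)]
  nc_seqs <- rand_dna(sample(90:200, n_nc, replace = TRUE))
  nc_ids <- sprintf("%s_%02d", nc_classes, seq_len(n_nc))

  ## genome layout
  loop_len <- sample(8:12, n_mirna, replace = TRUE)
  hp_len <- 2L * mat_len + loop_len
  widths <- c(hp_len, nchar(nc_seqs))
  n_elem <- length(widths)
  min_gap <- 40L
  need <- sum(widths) + (n_elem + 1L) * min_gap
  if (need > config$genome_length) {
    stop("infeasible config: planted loci need ", need,
         " nt but genome_length is ", config$genome_length, call. = FALSE)
  }
  spare <- config$genome_length - need
  gaps <- min_gap + as.integer(rmultinom(1, spare, rep(1, n_elem + 1L)))
  order_elem <- sample.int(n_elem)

  fillers <- rand_dna(gaps)
  filler_blob <- paste(fillers, collapse = "")
  nc_blob <- paste(nc_seqs, collapse = "")

  ## plant hairpins, rejecting matures that collide anywhere else
  matures <- character(n_mirna)
  hairpins <- character(n_mirna)
  arms <- sample(c("5p", "3p"), n_mirna, replace = TRUE)
  star_mm <- sample(1:2, n_mirna, replace = TRUE)
  context <- paste(filler_blob, nc_blob)
  for (i in seq_len(n_mirna)) {
    for (try in 1:60) {
      mat <- rand_dna(mat_len[i])
      star <- make_star(mat, star_mm[i])
      loop <- rand_dna(loop_len[i])
      hp <- if (arms[i] == "5p") paste0(mat, loop, star)
            else paste0(star, loop, mat)
      ok <- count_occurrences(mat, context) == 0L &&
        count_occurrences(dna_revcomp(mat), context) == 0L &&
        count_occurrences(mat, hp) == 1L &&
        count_occurrences(dna_revcomp(mat), hp) == 0L
      if (ok) break
      if (try == 60) stop("failed to plant a unique mature sequence")
    }
    matures[i] <- mat
    hairpins[i] <- hp
    context <- paste(context, hp, dna_revcomp(hp))
  }

  ## assemble chr1; hairpins go on a random strand
  strand <- sample(c("+", "-"), n_mirna, replace = TRUE)
  elem_seq_genomic <- c(ifelse(strand == "+", hairpins, dna_revcomp(hairpins)),
                        nc_seqs)
  elem_type <- rep(c("miRNA_hairpin", "ncRNA"), c(n_mirna, n_nc))
  elem_id <- c(ids, nc_ids)
  elem_strand <- c(strand, rep("+", n_nc))
  elem_class <- c(rep(NA_character_, n_mirna), nc_classes)

  pieces <- character(2L * n_elem + 1L)
  pieces[seq(1L, 2L * n_elem + 1L, by = 2L)] <- fillers
  pieces[seq(2L, 2L * n_elem, by = 2L)] <- elem_seq_genomic[order_elem]
  genome_seq <- paste(pieces, collapse = "")

  starts <- integer(n_elem)  # 0-based
  pos <- gaps[1L]
  for (k in seq_len(n_elem)) {
    starts[k] <- pos
    pos <- pos + widths[order_elem[k]] + gaps[k + 1L]
  }
  elem_start <- integer(n_elem)
  elem_start[order_elem] <- starts

  ## mature coordinates within the genome (0-based half-open)
  mat_off <- ifelse(arms == "5p", 0L, mat_len + loop_len)  # within hairpin RNA
  mat_start <- ifelse(strand == "+",
                      elem_start[seq_len(n_mirna)] + mat_off,
                      elem_start[seq_len(n_mirna)] +
                        (hp_len - mat_off - mat_len))
  mat_end <- mat_start + mat_len

  features <- data.frame(
    seqid = "chr1",
    type = elem_type,
    start = elem_start,
    end = elem_start + widths,
    strand = elem_strand,
    id = elem_id,
    class = elem_class,
    stringsAsFactors = FALSE
  )
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL

  genome <- c(chr1 = genome_seq)

  ## final uniqueness audit of every planted mature
  for (i in seq_len(n_mirna)) {
    hits <- count_occurrences(matures[i], genome_seq) +
      count_occurrences(dna_revcomp(matures[i]), genome_seq)
    if (hits != 1L) {
      stop("planted mature ", ids[i], " occurs ", hits,
           " times in the toy genome")
    }
  }

  ## SA assignment and expression (RPM per library)
  sa_idx <- if (config$n_sa_mirnas > 0 && n_known >= config$n_sa_mirnas) {
    sample(seq_len(n_known), config$n_sa_mirnas)
  } else {
    sample(seq_len(n_mirna), config$n_sa_mirnas)
  }
  sa <- rep(FALSE, n_mirna)
  sa[sa_idx] <- TRUE
  direction <- rep(NA_character_, n_mirna)
  if (length(sa_idx) > 0) {
    up <- sa_idx[seq_len(ceiling(length(sa_idx) / 2))]
    direction[up] <- "up"
    direction[setdiff(sa_idx, up)] <- "down"
  }

  w <- runif(n_mirna, 60, 2000)
  w[sa_idx] <- runif(length(sa_idx), 1500, 3000)
  # balance the planted effects so total read mass is unchanged at 30 DAP:
  # otherwise RPM renormalization compresses the up-regulated fold changes
  # toward the selection threshold
  up_idx <- which(direction %in% "up")
  dn_idx <- which(direction %in% "down")
  if (length(up_idx) > 0 && length(dn_idx) > 0) {
    w[dn_idx] <- w[dn_idx] *
      (config$sa_fold_change * sum(w[up_idx]) / sum(w[dn_idx]))
  }
  w30 <- w
  w30[direction %in% "up"] <- w[direction %in% "up"] * config$sa_fold_change
  w30[direction %in% "down"] <- w[direction %in% "down"] / config$sa_fold_change
  expr <- cbind(ELS1_20DAP = w, ELS1_30DAP = w30,
                Yu871_20DAP = w, Yu871_30DAP = w)
  expr <- sweep(expr, 2, colSums(expr), "/") * 1e6
  rownames(expr) <- ids

  sa_flags <- abs(log2(expr[, "ELS1_30DAP"] / expr[, "ELS1_20DAP"])) > 1.5 &
    abs(log2(expr[, "Yu871_30DAP"] / expr[, "Yu871_20DAP"])) <= 1.5
  names(sa_flags) <- ids

  ## transcripts: one target per SA miRNA plus up to two novel targets
  target_idx <- c(sa_idx, setdiff(which(status == "novel"),
                                  sa_idx)[seq_len(min(2L, n_novel))])
  target_idx <- unique(target_idx[!is.na(target_idx)])
  n_tx <- length(target_idx) + config$n_transcripts_background
  tx_ids <- sprintf("TX%04d", seq_len(max(n_tx, 1L))[seq_len(n_tx)])
  tx_seqs <- character(n_tx)
  site_start <- integer(length(target_idx))
  for (k in seq_along(target_idx)) {
    i <- target_idx[k]
    repeat {
      len <- sample(550:800, 1)
      s <- sample(100:380, 1)
      body <- rand_dna(len)
      tx <- paste0(substr(body, 1, s - 1), dna_revcomp(matures[i]),
                   substr(body, s, len - mat_len[i]))
      if (sum(vapply(matures, count_occurrences, integer(1),
                     subject = tx)) == 0L &&
          count_occurrences(dna_revcomp(matures[i]), tx) == 1L) break
    }
    tx_seqs[k] <- tx
    site_start[k] <- s
  }
  if (config$n_transcripts_background > 0) {
    bg <- rand_dna(sample(500:800, config$n_transcripts_background,
                          replace = TRUE))
    tx_seqs[length(target_idx) + seq_len(config$n_transcripts_background)] <- bg
  }
  names(tx_seqs) <- tx_ids

  cleavage_sites <- data.frame(
    mirna_id = ids[target_idx],
    transcript_id = tx_ids[seq_along(target_idx)],
    site_start = site_start,
    cleavage_pos = site_start + mat_len[target_idx] - 10L,
    stringsAsFactors = FALSE
  )

  fun_classes <- c("transcriptional regulator", "translational regulator",
                   "metabolizer", "signal transducer", "stress responder",
                   "other")
  tx_class <- c(rep(fun_classes, length.out = length(target_idx)),
                rep("other", config$n_transcripts_background))
  transcript_annotation <- data.frame(transcript_id = tx_ids,
                                      class = tx_class,
                                      stringsAsFactors = FALSE)

  ## phenotype trajectories (mg/L), anchored at the study's reported values
  phenotype <- data.frame(
    genotype = rep(c("ELS-1", "Yu87-1"), each = 4),
    dap = rep(c(10, 20, 25, 30), 2),
    chl_a = c(27.90, 26.80, 25.58, 0.35,
              28.40, 27.90, 27.41, 23.01),
    chl_b = c(13.45, 2.30, 1.75, 0.40,
              13.20, 12.60, 12.10, 10.40),
    stringsAsFactors = FALSE
  )

  ## qPCR truth: SA-miRNA expression relative to the 20 DAP ELS-1 calibrator
  qpcr_genes <- ids[sa_idx]
  qpcr <- if (length(qpcr_genes) > 0) {
    do.call(rbind, lapply(qpcr_genes, function(g) {
      data.frame(gene = g, library = SENMIR_LIBRARIES,
                 rel_expression = as.numeric(expr[g, ] / expr[g, "ELS1_20DAP"]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene = character(0), library = character(0),
               rel_expression = numeric(0))
  }

  mirna <- data.frame(
    id = ids, family = families, status = status, mature = matures,
    length = mat_len, arm = arms, chrom = rep("chr1", n_mirna),
    hp_start = elem_start[seq_len(n_mirna)],
    hp_end = elem_start[seq_len(n_mirna)] + hp_len,
    strand = strand, mat_start = mat_start, mat_end = mat_end,
    sa = sa, direction = direction,
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    mirna = mirna,
    expression = expr,
    sa_flags = sa_flags,
    cleavage_sites = cleavage_sites,
    phenotype = phenotype,
    qpcr = qpcr,
    libraries = SENMIR_LIBRARIES
  ), class = "planted_truth")

  mature_ref <- matures[status == "known"]
  names(mature_ref) <- known_ids
  ncrna_ref <- nc_seqs
  names(ncrna_ref) <- nc_ids

  structure(list(
    genome = genome,
    features = features,
    truth = truth,
    mature_ref = mature_ref,
    ncrna_ref = ncrna_ref,
    transcripts = tx_seqs,
    transcript_annotation = transcript_annotation,
    config = config
  ), class = "senmir_sim")
}

#' Simulate the four small-RNA libraries
#'
#' Reads are mature-miRNA copies with negative-binomial counts around the
#' planted RPM expectations, plus ncRNA fragments (16-34 nt) and low-quality /
#' N-containing reads. A configurable fraction of sRNA reads carries the 3'
#' adapter and is truncated at the read length, exercising the trimmer.
#' The ncRNA pool absorbs the count-noise remainder so that each library
#' holds exactly `reads_per_library` records.
#'
#' @param sim a `senmir_sim` object from [generate_toy_genome()].
#' @param config simulation config; defaults to the one stored in `sim`.
#' @param dir optional directory; when given, one FASTQ per library is
#'   written and paths are attached as attribute `"paths"`.
#' @return named list of read data.frames (`id`, `seq`, `qual`), one per
#'   library, with attribute `"composition"` giving per-library read class
#'   counts.
#' @export
simulate_srna_libraries <- function(sim, config = sim$config, dir = NULL) {
  stopifnot(inherits(sim, "senmir_sim"))
  set.seed(config$seed + 1L)
  truth <- sim$truth
  n <- config$reads_per_library
  n_lowq <- round(config$lowq_read_fraction * n)
  n_nc_nominal <- round(config$ncrna_read_fraction * n)
  n_mirna_target <- n - n_lowq - n_nc_nominal

  out <- list()
  comp <- list()
  for (lib in truth$libraries) {
    mu <- truth$expression[, lib] / 1e6 * n_mirna_target
    counts <- if (config$nb_dispersion == 0) {
      round(mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
    # the ncRNA pool absorbs the NB remainder; trim the largest counts if the
    # draw overshoots the library depth
    overshoot <- sum(counts) + n_lowq - n
    while (overshoot > 0) {
      j <- which.max(counts)
      take <- min(counts[j] - 1L, overshoot)
      counts[j] <- counts[j] - take
      overshoot <- overshoot - take
    }
    n_nc <- n - n_lowq - sum(counts)

    mirna_seq <- rep(truth$mirna$mature, counts)

    nc_seq <- character(0)
    if (n_nc > 0 && length(sim$ncrna_ref) > 0) {
      src <- sample(seq_along(sim$ncrna_ref), n_nc, replace = TRUE)
      flen <- sample(16:34, n_nc, replace = TRUE)
      ref_len <- nchar(sim$ncrna_ref)[src]
      flen <- pmin(flen, ref_len)
      fstart <- floor(runif(n_nc, 1, ref_len - flen + 1 + 1))
      nc_seq <- substring(sim$ncrna_ref[src], fstart, fstart + flen - 1)
    } else if (n_nc > 0) {
      nc_seq <- rand_dna(rep(21L, n_nc))
    }

    inserts <- c(mirna_seq, nc_seq)
    with_adapter <- runif(length(inserts)) < config$adapter_fraction
    reads <- inserts
    reads[with_adapter] <- substr(paste0(inserts[with_adapter], config$adapter),
                                  1L, config$read_cycles)
    quals <- random_quals(nchar(reads), 28:40)

    if (n_lowq > 0) {
      n_N <- floor(0.4 * n_lowq)
      n_bad <- n_lowq - n_N
      bad_seq <- rand_dna(sample(20:30, n_bad, replace = TRUE))
      bad_qual <- random_quals(nchar(bad_seq), 2:14)
      nseq <- rand_dna(sample(20:30, n_N, replace = TRUE))
      if (n_N > 0) {
        pos <- floor(runif(n_N, 2, nchar(nseq)))
        substr(nseq, pos, pos) <- "N"
      }
      n_qual <- random_quals(nchar(nseq), 28:40)
      reads <- c(reads, bad_seq, nseq)
      quals <- c(quals, bad_qual, n_qual)
    }

    ord <- sample.int(length(reads))
    df <- data.frame(
      id = sprintf("%s_r%06d", lib, seq_along(reads)),
      seq = reads[ord],
      qual = quals[ord],
      stringsAsFactors = FALSE
    )
    out[[lib]] <- df
    comp[[lib]] <- data.frame(library = lib, mirna_reads = sum(counts),
                              ncrna_reads = n_nc, lowq_reads = n_lowq,
                              total = nrow(df), stringsAsFactors = FALSE)
  }
  attr(out, "composition") <- do.call(rbind, comp)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(out), function(lib) {
      p <- file.path(dir, paste0(lib, ".fastq"))
      write_fastq(out[[lib]], p)
      p
    }, character(1))
    attr(out, "paths") <- paths
  }
  out
}

#' Simulate the degradome (PARE) library
#'
#' Tags are fixed-length transcript suffix prefixes representing uncapped
#' 5' ends. For transcripts with a planted cleavage site, a tag starts at the
#' site with probability `degradome_peak_fraction` and at a uniform position
#' otherwise; untargeted transcripts yield uniform background only. Tags
#' truncated by the transcript 3' end carry a `|trunc` marker in their id.
#'
#' @param sim a `senmir_sim` object.
#' @param config simulation config; defaults to the one stored in `sim`.
#' @param dir optional output directory for a `degradome.fastq` file.
#' @return read data.frame (`id`, `seq`, `qual`).
#' @export
simulate_degradome_library <- function(sim, config = sim$config, dir = NULL) {
  stopifnot(inherits(sim, "senmir_sim"))
  set.seed(config$seed + 2L)
  tx <- sim$transcripts
  sites <- sim$truth$cleavage_sites
  bad <- sites$cleavage_pos < 1 | sites$cleavage_pos > nchar(tx[sites$transcript_id])
  if (any(bad)) {
    stop("cleavage position outside transcript: ",
         paste(sites$transcript_id[bad], collapse = ", "))
  }
  n_tx <- length(tx)
  n_per <- max(1L, round(config$degradome_tags / n_tx))
  taglen <- config$degradome_tag_length

  rows <- lapply(seq_len(n_tx), function(k) {
    id <- names(tx)[k]
    len <- nchar(tx[[k]])
    site <- sites$cleavage_pos[match(id, sites$transcript_id)]
    if (!is.na(site)) {
      n_site <- rbinom(1, n_per, config$degradome_peak_fraction)
      pos <- c(rep(site, n_site),
               floor(runif(n_per - n_site, 1, len + 1)))
    } else {
      pos <- floor(runif(n_per, 1, len + 1))
    }
    seqs <- substring(tx[[k]], pos, pmin(len, pos + taglen - 1L))
    trunc <- nchar(seqs) < taglen
    data.frame(
      id = sprintf("deg_%s_%05d%s", id, seq_along(pos),
                   ifelse(trunc, "|trunc", "")),
      seq = seqs,
      stringsAsFactors = FALSE
    )
  })
  reads <- do.call(rbind, rows)
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  reads$qual <- random_quals(nchar(reads$seq), 30:40)
  rownames(reads) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(dir, "degradome.fastq")
    write_fastq(reads, p)
    attr(reads, "path") <- p
  }
  reads
}

#' Simulate qPCR Ct and absorbance tables
#'
#' Absorbances are obtained by inverting the chlorophyll equations from the
#' planted concentration trajectories; Ct values encode the planted relative
#' expression through the ddCt model. Three replicates per sample; Gaussian
#' noise with the configured standard deviations (zero noise gives exact
#' round-trips).
#'
#' @param sim a `senmir_sim` object.
#' @param config simulation config; defaults to the one stored in `sim`.
#' @param dir optional directory; writes `ct_table.tsv` and
#'   `absorbance_table.tsv`.
#' @return list with data.frames `ct` (sample_id, genotype, dap, gene,
#'   replicate, ct_target, ct_reference) and `absorbance` (genotype, dap,
#'   replicate, a645, a663).
#' @export
simulate_phenotype_tables <- function(sim, config = sim$config, dir = NULL) {
  stopifnot(inherits(sim, "senmir_sim"))
  set.seed(config$seed + 3L)
  truth <- sim$truth

  ph <- truth$phenotype
  ab <- absorbance_for_chlorophyll(ph$chl_a, ph$chl_b)
  absorbance <- do.call(rbind, lapply(1:3, function(r) {
    data.frame(genotype = ph$genotype, dap = ph$dap, replicate = r,
               a645 = pmax(0, ab$a645 + rnorm(nrow(ph), 0,
                                              config$absorbance_sd)),
               a663 = pmax(0, ab$a663 + rnorm(nrow(ph), 0,
                                              config$absorbance_sd)),
               stringsAsFactors = FALSE)
  }))
  absorbance <- absorbance[order(absorbance$genotype, absorbance$dap,
                                 absorbance$replicate), ]
  rownames(absorbance) <- NULL

  qp <- truth$qpcr
  ct <- NULL
  if (nrow(qp) > 0) {
    lib_geno <- c(ELS1_20DAP = "ELS-1", ELS1_30DAP = "ELS-1",
                  Yu871_20DAP = "Yu87-1", Yu871_30DAP = "Yu87-1")
    lib_dap <- c(ELS1_20DAP = 20, ELS1_30DAP = 30,
                 Yu871_20DAP = 20, Yu871_30DAP = 30)
    ct <- do.call(rbind, lapply(1:3, function(r) {
      data.frame(sample_id = qp$library,
                 genotype = lib_geno[qp$library],
                 dap = lib_dap[qp$library],
                 gene = qp$gene,
                 replicate = r,
                 ct_target = 25 - log2(qp$rel_expression) +
                   rnorm(nrow(qp), 0, config$ct_sd),
                 ct_reference = 15 + rnorm(nrow(qp), 0, config$ct_sd),
                 stringsAsFactors = FALSE)
    }))
    ct <- ct[order(ct$gene, ct$sample_id, ct$replicate), ]
    rownames(ct) <- NULL
  } else {
    ct <- data.frame(sample_id = character(0), genotype = character(0),
                     dap = numeric(0), gene = character(0),
                     replicate = integer(0), ct_target = numeric(0),
                     ct_reference = numeric(0))
  }

  out <- list(ct = ct, absorbance = absorbance)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(ct, file.path(dir, "ct_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(absorbance, file.path(dir, "absorbance_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write all simulated reference artifacts to disk
#'
#' Emits the genome, mature/ncRNA/transcript FASTA files, a GFF3 feature
#' table and the planted-truth tables; all files round-trip through the
#' package's own readers ([read_fasta()], [read_features()], etc.).
#'
#' @param sim a `senmir_sim` object.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "senmir_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    mature = file.path(dir, "mature_mirnas.fasta"),
    ncrna = file.path(dir, "ncrna.fasta"),
    transcripts = file.path(dir, "transcripts.fasta"),
    features = file.path(dir, "features.gff3"),
    annotation = file.path(dir, "transcript_annotation.tsv"),
    expression = file.path(dir, "planted_expression.tsv")
  )
  write_fasta(sim$genome, paths["genome"])
  write_fasta(sim$mature_ref, paths["mature"])
  nc <- sim$ncrna_ref
  names(nc) <- sprintf("%s class=%s", names(nc), sub("_[0-9]+$", "", names(nc)))
  write_fasta(nc, paths["ncrna"])
  write_fasta(sim$transcripts, paths["transcripts"])
  write_features(sim$features, paths["features"])
  utils::write.table(sim$transcript_annotation, paths["annotation"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- data.frame(id = rownames(sim$truth$expression),
                     sim$truth$expression, check.names = FALSE)
  utils::write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write a feature table as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 output is 1-based
#' inclusive.
#'
#' @param features feature data.frame from [generate_toy_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  attrs <- sprintf("ID=%s%s", features$id,
                   ifelse(is.na(features$class), "",
                          paste0(";class=", features$class)))
  gff <- data.frame(features$seqid, "senmiR", features$type,
                    features$start + 1L, features$end, ".",
                    features$strand, ".", attrs)
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a GFF3 feature table written by [write_features()]
#'
#' @param path GFF3 file path.
#' @return feature data.frame with 0-based half-open `start`/`end`.
#' @export
read_features <- function(path) {
  gff <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  id <- sub("^ID=([^;]+).*$", "\\1", gff$V9)
  class <- ifelse(grepl("class=", gff$V9),
                  sub("^.*class=([^;]+).*$", "\\1", gff$V9), NA_character_)
  data.frame(seqid = gff$V1, type = gff$V3, start = gff$V4 - 1L,
             end = gff$V5, strand = gff$V7, id = id, class = class,
             stringsAsFactors = FALSE)
}
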