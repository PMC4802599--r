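# One-config orchestration of the whole workflow, the packaged novel-miRNA
# abundance table, and the machine-readable run report.

#' Pipeline run configuration
#'
#' Collects every stage parameter; all randomness flows from
#' `sim$seed`.
#'
#' @param sim a [sim_config()].
#' @param min_len,max_len retained tag length window (nt).
#' @param min_qual mean Phred threshold of the quality filter.
#' @param floor RPM floor ("at least one sample" rule).
#' @param fc_threshold log2 fold-change threshold of the contrast.
#' @param pseudocount RPM pseudocount for zero-safe fold changes.
#' @param max_score maximum degradome duplex penalty.
#' @param novel a [novel_criteria()] list.
#' @param calibrator calibrator sample id for ddCt.
#' @param reference_gene reference-gene label echoed into reports.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), min_len = 18L, max_len = 32L,
                       min_qual = 20, floor = 5, fc_threshold = 1.5,
                       pseudocount = 1, max_score = 4,
                       novel = novel_criteria(), calibrator = "ELS1_20DAP",
                       reference_gene = "18S_rRNA") {
  stopifnot(inherits(sim, "sim_config"), min_len <= max_len,
            floor >= 0, fc_threshold > 0, pseudocount > 0, max_score >= 0)
  if (!calibrator %in% SENMIR_LIBRARIES) {
    stop("calibrator must be one of the four libraries: ",
         paste(SENMIR_LIBRARIES, collapse = ", "), call. = FALSE)
  }
  structure(list(sim = sim, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), min_qual = min_qual,
                 floor = floor, fc_threshold = fc_threshold,
                 pseudocount = pseudocount, max_score = max_score,
                 novel = novel, calibrator = calibrator,
                 reference_gene = reference_gene,
                 libraries = SENMIR_LIBRARIES),
            class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  plain$sim <- unclass(plain$sim)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file written by [write_run_config()].
#' @return a `run_config` equal to the one written.
#' @export
read_run_config <- function(path) {
  plain <- yaml::read_yaml(path)
  sim <- do.call(sim_config, plain$sim)
  novel <- do.call(novel_criteria, plain$novel)
  run_config(sim = sim, min_len = plain$min_len, max_len = plain$max_len,
             min_qual = plain$min_qual, floor = plain$floor,
             fc_threshold = plain$fc_threshold,
             pseudocount = plain$pseudocount, max_score = plain$max_score,
             novel = novel, calibrator = plain$calibrator,
             reference_gene = plain$reference_gene)
}

#' Load the packaged novel-miRNA abundance table
#'
#' Reads the packaged transcription of the published novel-miRNA table
#' (164 records: id, length, sequence and four per-library abundance
#' columns) and validates it: each sequence length must equal the length
#' column and abundances must be nonnegative.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return data.frame with columns `novel_mirna`, `length_nt`, `sequence`,
#'   `ELS1_20DAP`, `ELS1_30DAP`, `Yu871_20DAP`, `Yu871_30DAP`.
#' @export
load_table1_fixture <- function(path = system.file(
  "extdata", "table1_novel_mirnas.tsv", package = "senmiR")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("novel_mirna", "length_nt", "sequence",
            "ELS1_20DAP", "ELS1_30DAP", "Yu871_20DAP", "Yu871_30DAP")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("fixture lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(nchar(tab$sequence) != tab$length_nt)
  if (length(bad) > 0) {
    stop("sequence length mismatch in row ", tab$novel_mirna[bad[1]],
         call. = FALSE)
  }
  if (any(grepl("[^ACGT]", tab$sequence))) {
    stop("malformed sequence in fixture", call. = FALSE)
  }
  ab <- as.matrix(tab[, need[4:7]])
  if (any(is.na(ab)) || any(ab < 0)) {
    stop("malformed abundance values in fixture", call. = FALSE)
  }
  tab
}

#' Run the full pipeline on synthetic data
#'
#' Generates the toy study, processes the four libraries into a candidate
#' tag table, annotates known and novel miRNAs, applies the RPM floor and
#' the two-genotype contrast, calls degradome-supported cleavage sites,
#' computes the wet-lab quantities, and scores recovery against the planted
#' truth. All thresholds are echoed into the report.
#'
#' @param config a [run_config()].
#' @param dir optional directory: report tables are written there.
#' @return object of class `senmir_report` (a list; see Details in the
#'   package vignette).
#' @export
run_pipeline <- function(config = run_config(), dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- generate_toy_genome(config$sim)
  truth <- sim$truth
  reads <- simulate_srna_libraries(sim)

  clean <- list()
  qc_log <- list()
  for (lib in names(reads)) {
    tq <- trim_and_quality_filter(reads[[lib]], adapter = config$sim$adapter,
                                  min_mean_quality = config$min_qual)
    clean[[lib]] <- tq$reads
    qc_log[[lib]] <- tq$log
  }

  table <- length_filter_and_collapse(clean, config$min_len, config$max_len)
  table <- map_tags(table, sim$genome)
  nc <- remove_ncrna(table, sim$ncrna_ref)
  candidates <- nc$table
  totals <- candidate_library_totals(candidates)

  known <- annotate_known(candidates, sim$mature_ref)
  assignment <- attr(known, "assignment")
  unassigned <- candidates[candidates$mapped &
                             !(candidates$tag %in% assignment$tag), ,
                           drop = FALSE]
  attr(unassigned, "libraries") <- attr(candidates, "libraries")
  novel <- call_novel_mirnas(unassigned, sim$genome, config$novel)

  known$score <- NA_real_
  known$n_mature_mismatches <- NA_integer_
  records <- rbind(known[names(novel)], novel)
  attr(records, "libraries") <- tag_table_libraries(candidates)

  expr <- compute_rpm(records, totals)
  floored <- apply_floor(expr, config$floor)
  contrast <- select_sa_mirnas(floored, config$fc_threshold,
                               config$pseudocount)
  families <- summarize_families(contrast)

  ## degradome on candidate SA-miRNAs plus all novel calls
  deg_reads <- simulate_degradome_library(sim)
  deg_mirnas <- records[records$id %in%
                          contrast$id[contrast$sa_candidate] |
                          records$status == "novel", , drop = FALSE]
  hits <- degradome_hits(deg_mirnas, sim$transcripts, deg_reads,
                         config$max_score, sim$transcript_annotation)
  classes <- classify_target_function(hits, sim$transcript_annotation)

  ## wet-lab quantities
  ph <- simulate_phenotype_tables(sim)
  ab <- ph$absorbance
  key <- paste(ab$genotype, ab$dap, sep = "\r")
  a645 <- tapply(ab$a645, key, mean)
  a663 <- tapply(ab$a663, key, mean)
  ids <- do.call(rbind, strsplit(names(a645), "\r", fixed = TRUE))
  chl <- cbind(data.frame(genotype = ids[, 1], dap = as.numeric(ids[, 2]),
                          stringsAsFactors = FALSE),
               chlorophyll_concentrations(as.numeric(a645),
                                          as.numeric(a663)))
  chl <- chl[order(chl$genotype, chl$dap), ]
  rownames(chl) <- NULL
  senescence <- senescence_contrast(chl)

  rq <- delta_delta_ct(ph$ct, config$calibrator)
  samp <- unique(ph$ct[, c("sample_id", "genotype", "dap")])
  rq$genotype <- samp$genotype[match(rq$sample_id, samp$sample_id)]
  rq$dap <- samp$dap[match(rq$sample_id, samp$sample_id)]
  rq_els <- rq[rq$genotype == "ELS-1", , drop = FALSE]
  concordance <- direction_concordance(rq_els, contrast)

  ## read accounting (per library, must sum to the raw depth)
  accounting <- do.call(rbind, lapply(names(reads), function(lib) {
    ql <- qc_log[[lib]]
    len_disc <- attr(table, "length_discarded")[[lib]]
    ncr <- nc$reads_removed_by_library[[lib]]
    unmapped <- sum(candidates[[lib]][!candidates$mapped])
    cand <- totals[[lib]]
    data.frame(library = lib, raw = unname(ql[["input"]]),
               qc_discarded = unname(ql[["discarded_empty"]] +
                                       ql[["discarded_n"]] +
                                       ql[["discarded_quality"]]),
               length_discarded = len_disc, ncrna_removed = ncr,
               unmapped = unmapped, candidate = cand,
               stringsAsFactors = FALSE)
  }))
  accounting$total_check <- with(accounting, qc_discarded +
                                   length_discarded + ncrna_removed +
                                   unmapped + candidate)

  # length profile over all clean 18-32 nt reads (before ncRNA removal),
  # mirroring the published per-library length distributions
  lens <- length_distribution(table)

  recovery <- score_recovery(truth, records, contrast, hits)

  report <- structure(list(
    config = config,
    accounting = accounting,
    length_distribution = lens,
    mirna_records = records,
    expression = expr,
    expression_floored = floored,
    contrast = contrast,
    families = families,
    degradome = hits,
    target_classes = classes,
    chlorophyll = chl,
    senescence = senescence,
    rq = rq,
    concordance = concordance,
    recovery = recovery,
    truth = truth
  ), class = "senmir_report")
  if (!is.null(dir)) write_report(report, dir)
  report
}

# recovery of the planted truth: SA candidates, novel loci, cleavage sites.
# Predicted novel ids are matched to planted miRNAs by mature sequence.
score_recovery <- function(truth, records, contrast, hits) {
  truth_id_of <- function(pred_ids) {
    mat <- records$mature[match(pred_ids, records$id)]
    known <- pred_ids %in% truth$mirna$id
    out <- ifelse(known, pred_ids,
                  truth$mirna$id[match(mat, truth$mirna$mature)])
    out
  }
  truth_sa <- names(truth$sa_flags)[truth$sa_flags]
  pred_sa <- truth_id_of(contrast$id[contrast$sa_candidate])
  pred_sa <- pred_sa[!is.na(pred_sa)]
  sa_precision <- if (sum(contrast$sa_candidate) == 0) NA_real_ else
    length(intersect(pred_sa, truth_sa)) / sum(contrast$sa_candidate)
  sa_recall <- if (length(truth_sa) == 0) NA_real_ else
    length(intersect(pred_sa, truth_sa)) / length(truth_sa)

  tn <- truth$mirna[truth$mirna$status == "novel", , drop = FALSE]
  truth_loci <- sprintf("%s:%d:%s:%s", tn$chrom, tn$mat_start, tn$strand,
                        tn$mature)
  pn <- records[records$status == "novel", , drop = FALSE]
  pred_loci <- sprintf("%s:%d:%s:%s", pn$chrom, pn$start, pn$strand,
                       pn$mature)
  novel_precision <- if (nrow(pn) == 0) NA_real_ else
    length(intersect(pred_loci, truth_loci)) / nrow(pn)
  novel_recall <- if (nrow(tn) == 0) NA_real_ else
    length(intersect(pred_loci, truth_loci)) / nrow(tn)

  cs <- truth$cleavage_sites
  found <- logical(nrow(cs))
  cat0 <- logical(nrow(cs))
  s0 <- logical(nrow(cs))
  if (nrow(hits) > 0 && nrow(cs) > 0) {
    hit_truth_id <- truth_id_of(hits$mirna_id)
    for (i in seq_len(nrow(cs))) {
      sel <- which(hit_truth_id == cs$mirna_id[i] &
                     hits$transcript_id == cs$transcript_id[i] &
                     hits$cleavage_pos == cs$cleavage_pos[i])
      found[i] <- length(sel) > 0
      cat0[i] <- any(hits$category[sel] == 0)
      s0[i] <- any(hits$score[sel] == 0)
    }
  }
  list(sa_precision = sa_precision, sa_recall = sa_recall,
       n_sa_truth = length(truth_sa),
       n_sa_predicted = sum(contrast$sa_candidate),
       novel_precision = novel_precision, novel_recall = novel_recall,
       n_novel_truth = nrow(tn), n_novel_predicted = nrow(pn),
       cleavage_recovered = mean(found),
       cleavage_category0 = if (any(found)) mean(cat0[found]) else NA_real_,
       cleavage_score0 = if (any(found)) mean(s0[found]) else NA_real_,
       n_cleavage_truth = nrow(cs))
}

#' Write report tables and a JSON summary
#'
#' @param report a `senmir_report`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    accounting = wt(report$accounting, "read_accounting.tsv"),
    expression = wt(report$expression, "expression_rpm.tsv"),
    contrast = wt(report$contrast, "contrast.tsv"),
    degradome = wt(report$degradome, "degradome_hits.tsv"),
    chlorophyll = wt(report$chlorophyll, "chlorophyll.tsv"),
    rq = wt(report$rq, "relative_expression.tsv")
  )
  summary <- list(
    thresholds = list(
      min_len = report$config$min_len, max_len = report$config$max_len,
      min_qual = report$config$min_qual, floor = report$config$floor,
      fc_threshold = report$config$fc_threshold,
      pseudocount = report$config$pseudocount,
      max_score = report$config$max_score,
      novel = report$config$novel,
      seed = report$config$sim$seed
    ),
    frac_20_24 = as.list(report$length_distribution$frac_20_24),
    n_candidate_mirnas = report$families$n_candidates,
    n_candidate_families = report$families$n_families,
    n_retained_after_floor = nrow(report$expression_floored),
    recovery = report$recovery,
    early_senescing = report$senescence$early_senescing,
    concordant_fraction = if (nrow(report$concordance) > 0)
      mean(report$concordance$agree) else NA_real_
  )
  pj <- file.path(dir, "report.json")
  jsonlite::write_json(summary, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, json = pj))
}

#' @export
print.senmir_report <- function(x, ...) {
  cat("senmiR pipeline report\n")
  cat("  libraries:", paste(x$accounting$library, collapse = ", "), "\n")
  cat("  raw reads/library:", unique(x$accounting$raw), "\n")
  cat("  candidate reads:",
      paste(sprintf("%s=%d", x$accounting$library,
                    as.integer(x$accounting$candidate)), collapse = ", "),
      "\n")
  cat(sprintf("  20-24 nt fraction: %s\n",
              paste(sprintf("%.3f", x$length_distribution$frac_20_24),
                    collapse = ", ")))
  cat(sprintf("  miRNAs detected: %d known, %d novel\n",
              sum(x$mirna_records$status == "known"),
              sum(x$mirna_records$status == "novel")))
  cat(sprintf("  retained after %g RPM floor: %d\n", x$config$floor,
              nrow(x$expression_floored)))
  cat(sprintf("  SA candidates: %d in %d families\n",
              x$families$n_candidates, x$families$n_families))
  cat(sprintf("  degradome hits: %d (category 0: %d)\n",
              nrow(x$degradome), sum(x$degradome$category == 0)))
  cat(sprintf("  early-senescing genotype: %s\n",
              x$senescence$early_senescing))
  r <- x$recovery
  cat(sprintf("  recovery: SA precision %.2f recall %.2f; novel precision %.2f recall %.2f; cleavage sites %.2f\n",
              r$sa_precision, r$sa_recall, r$novel_precision,
              r$novel_recall, r$cleavage_recovered))
  invisible(x)
}
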