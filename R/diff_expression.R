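# RPM normalization and the two-genotype selection contrast that defines
# candidate senescence-associated miRNAs: |log2 fold change| > 1.5 between
# 30 and 20 DAP in the early-senescing line, and not in the stay-green line.

#' Compute reads-per-million expression
#'
#' RPM = count / mapped candidate reads x 10^6, per library.
#'
#' @param records miRNA record data.frame (from [annotate_known()] /
#'   [call_novel_mirnas()]) with one raw-count column per library.
#' @param library_totals named numeric vector of mapped candidate reads per
#'   library; all totals must be positive.
#' @return expression matrix data.frame: `id`, `family`, `status` and one
#'   RPM column per library.
#' @export
compute_rpm <- function(records, library_totals) {
  libs <- names(library_totals)
  if (length(libs) == 0) stop("library_totals must be named", call. = FALSE)
  zero <- libs[library_totals <= 0]
  if (length(zero) > 0) {
    stop("zero mapped candidate reads in library: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(libs, names(records))
  if (length(missing) > 0) {
    stop("records lack count columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(id = records$id,
                    family = records$family,
                    status = if ("status" %in% names(records))
                      records$status else NA_character_,
                    stringsAsFactors = FALSE)
  for (lib in libs) {
    out[[lib]] <- records[[lib]] / library_totals[[lib]] * 1e6
  }
  attr(out, "libraries") <- libs
  out
}

#' Candidate-read totals per library
#'
#' Read-weighted totals over mapped tags of a `tag_table` — the RPM
#' denominator.
#'
#' @param table a mapped, ncRNA-free `tag_table`.
#' @return named numeric vector of totals.
#' @export
candidate_library_totals <- function(table) {
  libs <- tag_table_libraries(table)
  sel <- if ("mapped" %in% names(table)) table$mapped else
    rep(TRUE, nrow(table))
  vapply(libs, function(lib) sum(table[[lib]][sel]), numeric(1))
}

#' Apply the minimum-expression floor
#'
#' Keeps rows whose maximum RPM over all libraries is at least `floor`
#' ("at least one sample" rule; default 5 RPM).
#'
#' @param matrix expression matrix from [compute_rpm()].
#' @param floor RPM floor (>= 0).
#' @return the filtered matrix.
#' @export
apply_floor <- function(matrix, floor = 5) {
  stopifnot(floor >= 0)
  libs <- attr(matrix, "libraries")
  if (is.null(libs)) libs <- setdiff(names(matrix),
                                     c("id", "family", "status"))
  if (nrow(matrix) == 0) return(matrix)
  mx <- do.call(pmax, matrix[libs])
  out <- matrix[mx >= floor, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "libraries") <- libs
  out
}

#' Pseudocount-adjusted log2 fold change
#'
#' `log2((t2 + c) / (t1 + c))`; finite for all nonnegative inputs including
#' zeros.
#'
#' @param rpm_t2,rpm_t1 nonnegative expression values (later and earlier
#'   timepoint).
#' @param pseudocount positive pseudocount in RPM units (default 1).
#' @return numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(rpm_t2, rpm_t1, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  stop_if_negative(c(rpm_t2, rpm_t1), "expression")
  log2((rpm_t2 + pseudocount) / (rpm_t1 + pseudocount))
}

#' Select candidate senescence-associated miRNAs
#'
#' A miRNA is differentially expressed in a genotype when the absolute
#' pseudocount-adjusted log2 fold change between its two timepoints is
#' strictly greater than `threshold`. Candidates are differentially
#' expressed in the early-senescing genotype and *not* in the stay-green
#' genotype (the removal rule). A sensitivity report over pseudocounts
#' 0.5/1/2 RPM is attached as attribute `"pseudocount_sensitivity"`.
#'
#' @param matrix floored expression matrix.
#' @param threshold log2 fold-change threshold (default 1.5, strict
#'   inequality).
#' @param pseudocount pseudocount in RPM (default 1).
#' @param lib_map list with elements `els` and `yu`, each `c(t1 = , t2 = )`
#'   naming the expression columns of the two genotypes' timepoints.
#' @return `ContrastResult` data.frame: `id`, `family`, `log2FC_ELS`,
#'   `log2FC_Yu`, `passed_floor`, `de_in_ELS`, `removed_by_Yu`,
#'   `sa_candidate`, `direction`.
#' @export
select_sa_mirnas <- function(matrix, threshold = 1.5, pseudocount = 1,
                             lib_map = list(
                               els = c(t1 = "ELS1_20DAP", t2 = "ELS1_30DAP"),
                               yu = c(t1 = "Yu871_20DAP", t2 = "Yu871_30DAP"))) {
  need <- unlist(lib_map, use.names = FALSE)
  missing <- setdiff(need, names(matrix))
  if (length(missing) > 0) {
    stop("expression matrix lacks required library columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  contrast_at <- function(pc) {
    fc_els <- log2_fold_change(matrix[[lib_map$els[["t2"]]]],
                               matrix[[lib_map$els[["t1"]]]], pc)
    fc_yu <- log2_fold_change(matrix[[lib_map$yu[["t2"]]]],
                              matrix[[lib_map$yu[["t1"]]]], pc)
    de_els <- abs(fc_els) > threshold
    rem_yu <- abs(fc_yu) > threshold
    data.frame(id = matrix$id, family = matrix$family,
               log2FC_ELS = fc_els, log2FC_Yu = fc_yu,
               passed_floor = TRUE,
               de_in_ELS = de_els, removed_by_Yu = rem_yu,
               sa_candidate = de_els & !rem_yu,
               direction = ifelse(fc_els >= 0, "up", "down"),
               stringsAsFactors = FALSE)
  }
  out <- contrast_at(pseudocount)
  sens <- do.call(rbind, lapply(c(0.5, 1, 2), function(pc) {
    cc <- contrast_at(pc)
    data.frame(pseudocount = pc, n_candidates = sum(cc$sa_candidate),
               candidates = paste(sort(cc$id[cc$sa_candidate]),
                                  collapse = ","),
               stringsAsFactors = FALSE)
  }))
  attr(out, "pseudocount_sensitivity") <- sens
  attr(out, "threshold") <- threshold
  out
}

#' Summarize candidate families
#'
#' @param contrast a `ContrastResult` data.frame.
#' @return list with `n_families`, `families` (sorted data.frame of family,
#'   member count and ids) and `n_candidates`.
#' @export
summarize_families <- function(contrast) {
  cand <- contrast[contrast$sa_candidate, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(n_families = 0L,
                families = data.frame(family = character(0), n = integer(0),
                                      ids = character(0)),
                n_candidates = 0L))
  }
  sp <- split(cand$id, cand$family)
  fam <- data.frame(family = names(sp),
                    n = vapply(sp, length, integer(1)),
                    ids = vapply(sp, function(x)
                      paste(sort(x), collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  fam <- fam[order(fam$family), , drop = FALSE]
  rownames(fam) <- NULL
  list(n_families = nrow(fam), families = fam, n_candidates = nrow(cand))
}
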