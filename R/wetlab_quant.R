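# Phenotype and validation arithmetic: spectrophotometric chlorophyll
# quantification (Arnon-type linear equations on A645/A663) and 2^-ddCt
# relative expression from qPCR Ct tables.

#' Chlorophyll equation coefficients
#'
#' Arnon-type coefficients for 645/663 nm absorbances of a mixed-solvent
#' extract; swap in alternative solvent coefficients here.
#'
#' @return named list of coefficients (mg/L per absorbance unit).
#' @export
chl_coefficients <- function() {
  list(ca_663 = 12.7, ca_645 = 2.69,
       cb_645 = 22.9, cb_663 = 4.68,
       ct_645 = 20.2, ct_663 = 8.02)
}

#' Chlorophyll concentrations from absorbances
#'
#' `Ca = 12.7 A663 - 2.69 A645`, `Cb = 22.9 A645 - 4.68 A663`,
#' `Ctot = 20.2 A645 + 8.02 A663` (mg/L). Negative computed concentrations
#' are clipped to zero with a warning.
#'
#' @param a645,a663 nonnegative absorbance values (vectorized).
#' @param coef coefficient list, see [chl_coefficients()].
#' @return data.frame with columns `ca`, `cb`, `ctot` in mg/L.
#' @export
chlorophyll_concentrations <- function(a645, a663,
                                       coef = chl_coefficients()) {
  if (any(a645 < 0) || any(a663 < 0)) {
    stop("absorbances must be nonnegative", call. = FALSE)
  }
  ca <- coef$ca_663 * a663 - coef$ca_645 * a645
  cb <- coef$cb_645 * a645 - coef$cb_663 * a663
  ct <- coef$ct_645 * a645 + coef$ct_663 * a663
  if (any(ca < 0) || any(cb < 0)) {
    warning("negative computed concentration clipped to 0")
    ca <- pmax(ca, 0); cb <- pmax(cb, 0)
  }
  data.frame(ca = ca, cb = cb, ctot = ct)
}

#' Absorbances that reproduce target chlorophyll a/b concentrations
#'
#' Inverts the 2x2 linear system of [chlorophyll_concentrations()].
#'
#' @param ca,cb target concentrations in mg/L (vectorized).
#' @param coef coefficient list.
#' @return data.frame with `a645`, `a663`; an error if a target requires a
#'   negative absorbance.
#' @export
absorbance_for_chlorophyll <- function(ca, cb, coef = chl_coefficients()) {
  det <- coef$ca_663 * coef$cb_645 - coef$ca_645 * coef$cb_663
  a663 <- (coef$cb_645 * ca + coef$ca_645 * cb) / det
  a645 <- (coef$cb_663 * ca + coef$ca_663 * cb) / det
  if (any(a645 < 0) || any(a663 < 0)) {
    stop("target concentrations are not representable by nonnegative ",
         "absorbances", call. = FALSE)
  }
  data.frame(a645 = a645, a663 = a663)
}

#' Per-interval chlorophyll decline rates and the early-senescence flag
#'
#' Computes `-(delta C / delta t)` (mg/L per day, positive = decline) for
#' each consecutive timepoint interval and genotype, and flags as
#' early-senescing the genotype whose maximum decline rate exceeds the other
#' genotype's maximum by at least `ratio`.
#'
#' @param samples data.frame with `genotype`, `dap` and a concentration
#'   column named by `value`.
#' @param value which concentration column to use (default `"ctot"`).
#' @param ratio decline-rate ratio needed to flag (default 2).
#' @return list with `rates` (genotype, interval, rate) and
#'   `early_senescing` (genotype name or `NA`).
#' @export
senescence_contrast <- function(samples, value = "ctot", ratio = 2) {
  stopifnot(all(c("genotype", "dap", value) %in% names(samples)))
  genos <- unique(samples$genotype)
  if (length(genos) != 2) stop("expected exactly two genotypes",
                               call. = FALSE)
  tp <- lapply(genos, function(g) sort(unique(samples$dap[samples$genotype == g])))
  if (!identical(tp[[1]], tp[[2]])) {
    stop("unmatched timepoints between genotypes", call. = FALSE)
  }
  if (length(tp[[1]]) < 2) stop("need at least two timepoints per genotype",
                                call. = FALSE)
  rates <- do.call(rbind, lapply(genos, function(g) {
    sub <- samples[samples$genotype == g, , drop = FALSE]
    agg <- tapply(sub[[value]], sub$dap, mean)
    d <- as.numeric(names(agg))
    data.frame(genotype = g,
               interval = paste0(head(d, -1), "-", d[-1], "DAP"),
               rate = -diff(as.numeric(agg)) / diff(d),
               stringsAsFactors = FALSE)
  }))
  mx <- vapply(genos, function(g) max(rates$rate[rates$genotype == g]),
               numeric(1))
  early <- NA_character_
  if (mx[1] >= ratio * mx[2] && mx[1] > 0) early <- genos[1]
  if (mx[2] >= ratio * mx[1] && mx[2] > 0) early <- genos[2]
  list(rates = rates, early_senescing = early, max_decline = mx)
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per sample x gene before differencing:
#' `dCt = mean(Ct_target) - mean(Ct_reference)`, `ddCt = dCt_sample -
#' dCt_calibrator`, `RQ = 2^-ddCt` (so the calibrator's RQ is 1 by
#' construction).
#'
#' @param records data.frame with `sample_id`, `gene`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @param calibrator sample id used as the reference condition; required for
#'   every gene.
#' @return data.frame with `sample_id`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `rq`.
#' @export
delta_delta_ct <- function(records, calibrator) {
  need <- c("sample_id", "gene", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(records)))
  if (any(is.na(records$ct_reference))) {
    bad <- unique(records$sample_id[is.na(records$ct_reference)])
    stop("missing reference-gene Ct for sample: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(records$ct_target <= 0 | records$ct_target >= 45 |
            records$ct_reference <= 0 | records$ct_reference >= 45)) {
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  }
  key <- paste(records$sample_id, records$gene, sep = "\r")
  dct <- tapply(records$ct_target, key, mean) -
    tapply(records$ct_reference, key, mean)
  ids <- do.call(rbind, strsplit(names(dct), "\r", fixed = TRUE))
  out <- data.frame(sample_id = ids[, 1], gene = ids[, 2],
                    delta_ct = as.numeric(dct), stringsAsFactors = FALSE)
  cal <- out[out$sample_id == calibrator, c("gene", "delta_ct")]
  if (nrow(cal) == 0) stop("calibrator sample '", calibrator,
                           "' absent from records", call. = FALSE)
  miss <- setdiff(unique(out$gene), cal$gene)
  if (length(miss) > 0) {
    stop("calibrator lacks measurements for gene: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out$delta_delta_ct <- out$delta_ct - cal$delta_ct[match(out$gene, cal$gene)]
  out$rq <- 2^(-out$delta_delta_ct)
  out[order(out$gene, out$sample_id), ]
}

#' Direction concordance between qRT-PCR and sequencing
#'
#' Agreement when the sign of `log2(RQ_30DAP / RQ_20DAP)` matches the sign
#' of the sequencing log2 fold change; a zero on either side agrees with
#' anything.
#'
#' @param rq data.frame from [delta_delta_ct()] restricted to one genotype,
#'   with a `dap` column (must cover 20 and 30).
#' @param contrast `ContrastResult` data.frame; matched to `rq$gene` by
#'   `id`.
#' @param fc_column which log2FC column of `contrast` to compare against.
#' @return data.frame (`gene`, `qpcr_log2`, `seq_log2fc`, `agree`).
#' @export
direction_concordance <- function(rq, contrast, fc_column = "log2FC_ELS") {
  stopifnot(all(c("gene", "dap", "rq") %in% names(rq)))
  genes <- intersect(unique(rq$gene), contrast$id)
  rows <- lapply(genes, function(g) {
    r20 <- rq$rq[rq$gene == g & rq$dap == 20]
    r30 <- rq$rq[rq$gene == g & rq$dap == 30]
    if (length(r20) == 0 || length(r30) == 0) return(NULL)
    ql <- log2(mean(r30) / mean(r20))
    sl <- contrast[[fc_column]][match(g, contrast$id)]
    data.frame(gene = g, qpcr_log2 = ql, seq_log2fc = sl,
               agree = sign(ql) == sign(sl) || ql == 0 || sl == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), qpcr_log2 = numeric(0),
                      seq_log2fc = numeric(0), agree = logical(0))
  }
  rownames(out) <- NULL
  out
}
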