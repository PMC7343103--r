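# Small in-code fixtures.

# build a DepCohort directly from per-sample repeat matrices
makeDepCohort <- function(sampleValues, freqs, arms,
                          ids = names(sampleValues)) {
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(sampleValues))
  nRep <- vapply(sampleValues, ncol, integer(1))
  resp <- do.call(cbind, sampleValues)
  colnames(resp) <- unlist(lapply(seq_along(ids), function(i)
    sprintf("%s_r%d", ids[i], seq_len(nRep[i]))))
  cd <- S4Vectors::DataFrame(
    sample_id = rep(ids, nRep), arm = rep(arms, nRep),
    repeat_index = unlist(lapply(nRep, seq_len)),
    row.names = colnames(resp))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(response = resp),
    rowData = S4Vectors::DataFrame(frequency_hz = freqs),
    colData = cd)
  new("DepCohort", se)
}

# build a ProcessedCohort directly from a median matrix (+ optional mask)
makeProcessed <- function(med, freqs, arms, mask = NULL,
                          ids = colnames(med)) {
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(ncol(med)))
  colnames(med) <- ids
  if (is.null(mask)) mask <- matrix(TRUE, nrow(med), ncol(med))
  dimnames(mask) <- dimnames(med)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(median = med, mask = mask),
    rowData = S4Vectors::DataFrame(frequency_hz = freqs),
    colData = S4Vectors::DataFrame(sample_id = ids, arm = arms,
                                   n_repeats_used = rep(1L, length(ids)),
                                   row.names = ids))
  new("ProcessedCohort", se)
}

# an MDV results table from bare vectors (for diagnostics tests)
makeResults <- function(mdv, arm, excluded = rep(FALSE, length(mdv)),
                        threshold = 0) {
  n <- length(mdv)
  S4Vectors::DataFrame(
    sample_id = sprintf("S%02d", seq_len(n)), arm = arm,
    low_mean = rep(NA_real_, n), high_mean = rep(NA_real_, n), mdv = mdv,
    spectrum_sd = rep(NA_real_, n), excluded = excluded,
    predicted = if (n) ifelse(excluded, "excluded",
                              classifyMDV(mdv, threshold)) else character(0))
}

refCell <- function() ShellParams(10e-6, 0.01, 2000, 60, 0.25)
refMedium <- function() DielectricMedium(78, 0.043)
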