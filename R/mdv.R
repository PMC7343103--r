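#' MDV analysis configuration
#'
#' Settings for the Mean Difference Value statistic and the sample-quality
#' exclusion filter. Defaults follow the published rule: 9-point low and
#' high bands, decision threshold 0.65 (cancer iff MDV < threshold),
#' exclusion when the spectrum SD across frequencies falls below 0.4, and
#' frequency-ordered band selection.
#'
#' @param nLow,nHigh points in the low/high band (default 9 each)
#' @param threshold classification threshold (default 0.65)
#' @param sdMin exclusion cutoff on the spectrum SD (default 0.4); samples
#'   with SD strictly below it are excluded
#' @param bandMode "by_frequency" (bands are the lowest/highest-frequency
#'   valid points; default) or "by_value" (the numerically smallest/largest
#'   values)
#' @param signConvention "low_minus_high" (default) or "high_minus_low"
#' @return A validated list of class \code{"MDVConfig"}.
#' @export
mdvConfig <- function(nLow = 9L, nHigh = 9L, threshold = 0.65, sdMin = 0.4,
                      bandMode = c("by_frequency", "by_value"),
                      signConvention = c("low_minus_high", "high_minus_low")) {
  bandMode <- match.arg(bandMode)
  signConvention <- match.arg(signConvention)
  stopifnot(nLow >= 1L, nHigh >= 1L, is.finite(threshold), sdMin >= 0)
  structure(list(nLow = as.integer(nLow), nHigh = as.integer(nHigh),
                 threshold = threshold, sdMin = sdMin, bandMode = bandMode,
                 signConvention = signConvention),
            class = "MDVConfig")
}

#' Spectrum standard deviation
#'
#' Sample standard deviation (n - 1 denominator) of a median spectrum's
#' valid values across frequency points. Low cell numbers collapse the
#' spectrum's low/high plateaux and hence this SD, which is why it gates
#' sample quality.
#'
#' @param values median spectrum values
#' @param mask logical, TRUE = valid (default all)
#' @return A single non-negative number.
#' @export
spectrumSD <- function(values, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  v <- values[mask]
  if (length(v) < 2L)
    stop("spectrum SD needs at least 2 valid points, got ", length(v))
  sd(v)
}

# low/high band means on the valid points of one spectrum
.bandMeans <- function(values, freqs, mask, config) {
  v <- values[mask]
  f <- freqs[mask]
  if (length(v) < config$nLow + config$nHigh)
    stop("only ", length(v), " valid points; bands need ",
         config$nLow + config$nHigh)
  ord <- if (config$bandMode == "by_frequency") order(f) else order(v)
  vs <- v[ord]
  lowMean <- mean(vs[seq_len(config$nLow)])
  highMean <- mean(vs[seq(length(vs) - config$nHigh + 1L, length(vs))])
  c(low = lowMean, high = highMean)
}

#' Mean Difference Value statistics for a processed cohort
#'
#' For each sample: the mean over the low band, the mean over the high
#' band, their difference (the MDV; default sign convention
#' low - high), the spectrum SD, the exclusion flag (SD strictly below
#' \code{sdMin}) and the predicted label (cancer iff MDV < threshold;
#' excluded samples are labelled "excluded").
#'
#' @param processed a \linkS4class{ProcessedCohort}
#' @param config an \code{\link{mdvConfig}}
#' @return An \code{S4Vectors::DataFrame} with one row per sample and
#'   columns \code{sample_id}, \code{arm}, \code{low_mean},
#'   \code{high_mean}, \code{mdv}, \code{spectrum_sd}, \code{excluded},
#'   \code{predicted}.
#' @examples
#' cohort <- simulateCohort(cohortConfig(seed = 1))
#' proc <- maskDeadPoints(medianAcrossRepeats(cohort))
#' computeMDV(proc)
#' @export
computeMDV <- function(processed, config = mdvConfig()) {
  stopifnot(is(processed, "ProcessedCohort"), inherits(config, "MDVConfig"))
  med <- medianSpectra(processed)
  mask <- validMask(processed)
  freqs <- frequencies(processed)
  ids <- colData(processed)$sample_id
  out <- lapply(seq_along(ids), function(j) {
    bm <- tryCatch(.bandMeans(med[, j], freqs, mask[, j], config),
                   error = function(e)
                     stop("sample '", ids[j], "': ", conditionMessage(e)))
    sdv <- spectrumSD(med[, j], mask[, j])
    mdv <- if (config$signConvention == "low_minus_high")
      bm[["low"]] - bm[["high"]] else bm[["high"]] - bm[["low"]]
    c(low = bm[["low"]], high = bm[["high"]], mdv = mdv, sd = sdv)
  })
  out <- do.call(rbind, out)
  excluded <- out[, "sd"] < config$sdMin
  res <- DataFrame(sample_id = as.character(ids),
                   arm = as.character(colData(processed)$arm),
                   low_mean = as.numeric(out[, "low"]),
                   high_mean = as.numeric(out[, "high"]),
                   mdv = as.numeric(out[, "mdv"]),
                   spectrum_sd = as.numeric(out[, "sd"]),
                   excluded = as.logical(excluded),
                   predicted = as.character(
                     ifelse(excluded, "excluded",
                            classifyMDV(out[, "mdv"], config$threshold))))
  rownames(res) <- res$sample_id
  res
}

#' Threshold classification of MDVs
#'
#' Cancer when MDV is strictly below the threshold, control otherwise
#' (an MDV exactly at the threshold is control).
#'
#' @param mdv numeric MDV value(s)
#' @param threshold decision threshold
#' @return Character vector of "cancer"/"control".
#' @export
classifyMDV <- function(mdv, threshold = 0.65) {
  ifelse(mdv < threshold, "cancer", "control")
}

#' Apply the exclusion filter to an MDV table
#'
#' @param results a DataFrame from \code{\link{computeMDV}}
#' @return The rows whose \code{excluded} flag is FALSE.
#' @export
includedResults <- function(results) results[!results$excluded, , drop = FALSE]
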