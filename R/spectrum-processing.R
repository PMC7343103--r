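#' Per-sample median spectra
#'
#' Collapses each sample's technical repeats to a per-frequency median,
#' the robust summary used to suppress instrument noise before any
#' statistic is computed. Even repeat counts use the midpoint of the two
#' central values (the standard sample median). The mask starts all-valid;
#' see \code{\link{maskDeadPoints}}.
#'
#' @param cohort a \linkS4class{DepCohort}
#' @return A \linkS4class{ProcessedCohort} with one column per sample.
#' @export
medianAcrossRepeats <- function(cohort) {
  stopifnot(is(cohort, "DepCohort"))
  ids <- sampleIds(cohort)
  if (length(ids) == 0L) stop("cohort contains no samples")
  resp <- depResponse(cohort)
  sampleOf <- as.character(colData(cohort)$sample_id)
  med <- vapply(ids, function(id) {
    cols <- which(sampleOf == id)
    if (length(cols) == 0L) stop("sample '", id, "' has no repeats")
    apply(resp[, cols, drop = FALSE], 1L, median)
  }, numeric(nrow(resp)))
  nRep <- vapply(ids, function(id) sum(sampleOf == id), integer(1))
  arms <- armLabels(cohort)
  se <- SummarizedExperiment(
    assays = SimpleList(median = med,
                        mask = matrix(TRUE, nrow(med), ncol(med),
                                      dimnames = dimnames(med))),
    rowData = DataFrame(frequency_hz = frequencies(cohort)),
    colData = DataFrame(sample_id = ids, arm = unname(arms[ids]),
                        n_repeats_used = unname(nRep), row.names = ids))
  metadata(se) <- metadata(cohort)
  new("ProcessedCohort", se)
}

#' Detect dead-connection points in one spectrum
#'
#' A point is flagged dead when its absolute value falls below
#' \code{deadThreshold} while the spectrum's overall median absolute value
#' is at least twice the threshold -- i.e. a near-zero outlier relative to
#' a real curve. A uniformly near-zero spectrum (a low-cell sample) is left
#' untouched: whole-sample quality is the exclusion filter's job.
#'
#' @param values median spectrum values
#' @param deadThreshold absolute-value threshold (default 0.05)
#' @return Logical vector, TRUE = dead point.
#' @export
detectDeadPoints <- function(values, deadThreshold = 0.05) {
  stopifnot(deadThreshold >= 0)
  if (median(abs(values)) < 2 * deadThreshold) return(logical(length(values)))
  abs(values) < deadThreshold
}

#' Mask dead-connection points across a processed cohort
#'
#' Applies \code{\link{detectDeadPoints}} to every sample's median spectrum
#' and records the result in the \code{mask} assay. Values are never
#' modified, only masked. At most \code{maxMasked} points are masked per
#' sample: dead connections are rare instrument faults (typically a single
#' well), whereas a spectrum genuinely passes near zero at its crossover
#' frequencies, so when the near-zero rule fires at more candidates than
#' the cap the points with the smallest absolute values -- true dead
#' connections sit far closer to zero than crossover-adjacent points --
#' are kept masked and the band statistic retains enough valid points.
#'
#' @param processed a \linkS4class{ProcessedCohort}
#' @param deadThreshold absolute-value threshold (default 0.05)
#' @param maxMasked maximum masked points per sample (default 2)
#' @return The \code{ProcessedCohort} with an updated mask.
#' @export
maskDeadPoints <- function(processed, deadThreshold = 0.05, maxMasked = 2L) {
  stopifnot(is(processed, "ProcessedCohort"), maxMasked >= 0L)
  med <- medianSpectra(processed)
  mask <- validMask(processed)
  for (j in seq_len(ncol(med))) {
    dead <- which(detectDeadPoints(med[, j], deadThreshold))
    if (length(dead) > maxMasked)
      dead <- dead[order(abs(med[dead, j]))][seq_len(maxMasked)]
    mask[dead, j] <- FALSE
  }
  assay(processed, "mask") <- mask
  processed
}

#' Rolling average of a spectrum
#'
#' Moving mean over consecutive valid points with the given window; the
#' output has \code{n_valid - window + 1} points. Used only for plotting
#' trendlines -- it never feeds the MDV statistic.
#'
#' @param values numeric values
#' @param window window width (default 2)
#' @param mask logical, TRUE = valid (default all)
#' @return Numeric vector of window means.
#' @examples
#' rollingAverage(c(1, 2, 4, 8), window = 2)  # 1.5 3 6
#' @export
rollingAverage <- function(values, window = 2L, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  v <- values[mask]
  if (window < 1L) stop("window must be >= 1")
  if (window > length(v))
    stop("window (", window, ") exceeds number of valid points (", length(v), ")")
  if (window == 1L) return(v)
  cs <- cumsum(c(0, v))
  (cs[(window + 1L):(length(v) + 1L)] - cs[1L:(length(v) - window + 1L)]) / window
}

#' Arm-average spectrum
#'
#' Per-frequency mean of the median spectra of one arm's samples, omitting
#' masked points frequency-by-frequency. A frequency masked in every sample
#' of the arm is returned as NA (masked in the output).
#'
#' @param processed a \linkS4class{ProcessedCohort}
#' @param arm "cancer" or "control"
#' @return A data.frame with columns \code{frequency_hz}, \code{mean}
#'   (NA where all samples are masked) and \code{n} (samples contributing).
#' @export
armMeanSpectrum <- function(processed, arm = c("cancer", "control")) {
  arm <- match.arg(arm)
  stopifnot(is(processed, "ProcessedCohort"))
  sel <- colData(processed)$arm == arm
  if (!any(sel)) stop("no samples in arm '", arm, "'")
  med <- medianSpectra(processed)[, sel, drop = FALSE]
  mask <- validMask(processed)[, sel, drop = FALSE]
  med[!mask] <- NA_real_
  n <- rowSums(mask)
  m <- rowMeans(med, na.rm = TRUE)
  m[n == 0L] <- NA_real_
  data.frame(frequency_hz = frequencies(processed), mean = m, n = n)
}
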