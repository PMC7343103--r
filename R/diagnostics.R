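#' Confusion matrix from MDV results
#'
#' Tabulates predicted vs true arm labels with cancer as the positive
#' class. Excluded samples never enter the matrix; count them with
#' \code{sum(results$excluded)}.
#'
#' @param results a DataFrame/data.frame with columns \code{arm} (truth),
#'   \code{predicted} and \code{excluded}
#' @return A \linkS4class{ConfusionMatrix}.
#' @export
confusionMatrix <- function(results) {
  if (is.null(results$arm) || any(is.na(results$arm)))
    stop("every result needs a true arm label")
  keep <- !results$excluded
  truth <- results$arm[keep]
  pred <- results$predicted[keep]
  if (any(!truth %in% c("cancer", "control")))
    stop("true arm labels must be 'cancer' or 'control'")
  ConfusionMatrix(tp = sum(truth == "cancer" & pred == "cancer"),
                  fn = sum(truth == "cancer" & pred == "control"),
                  tn = sum(truth == "control" & pred == "control"),
                  fp = sum(truth == "control" & pred == "cancer"))
}

#' Two-sample t-test between arm MDVs
#'
#' Classic two-tailed two-sample t-test, pooled-variance (Student) by
#' default, Welch optionally. The degenerate case of zero variance in both
#' groups with equal means is reported as t = 0, p = 1.
#'
#' @param groupA,groupB numeric MDV values (each of length >= 2)
#' @param variant "pooled" (default) or "welch"
#' @return A list with \code{statistic}, \code{pValue}, \code{df} and
#'   \code{variant}.
#' @export
mdvTTest <- function(groupA, groupB, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(statistic = 0, pValue = 1,
                  df = length(groupA) + length(groupB) - 2L,
                  variant = variant))
    return(list(statistic = Inf * sign(mean(groupA) - mean(groupB)),
                pValue = 0, df = length(groupA) + length(groupB) - 2L,
                variant = variant))
  }
  tt <- t.test(groupA, groupB, var.equal = (variant == "pooled"))
  list(statistic = unname(tt$statistic), pValue = tt$p.value,
       df = unname(tt$parameter), variant = variant)
}

#' Sensitivity/specificity sweep over decision thresholds
#'
#' Evaluates the MDV classifier at a grid of thresholds and finds the
#' optimum by the Youden index (sensitivity + specificity - 1). The
#' operating point is a step function that only changes at observed MDVs,
#' so the default candidate grid is the midpoints between consecutive
#' sorted MDVs plus one point beyond each extreme. Ties for the maximal
#' Youden index are resolved to the midpoint of the tying threshold
#' interval, which is also reported.
#'
#' @param results an MDV table (see \code{\link{computeMDV}}); excluded
#'   rows are dropped
#' @param thresholds optional explicit threshold grid
#' @return A list with \code{table} (data.frame: threshold, sensitivity,
#'   specificity, youden) and \code{optimum} (list: threshold, interval,
#'   sensitivity, specificity, youden).
#' @export
thresholdSweep <- function(results, thresholds = NULL) {
  res <- includedResults(results)
  mdv <- res$mdv
  truth <- res$arm
  if (!any(truth == "cancer") || !any(truth == "control"))
    stop("threshold sweep needs included samples in both arms")
  if (is.null(thresholds)) {
    v <- sort(unique(mdv))
    step <- if (length(v) > 1L) diff(range(v)) / length(v) else max(abs(v), 1)
    thresholds <- c(v[1] - step,
                    if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2,
                    v[length(v)] + step)
  }
  thresholds <- sort(thresholds)
  evalAt <- function(t) {
    pred <- classifyMDV(mdv, t)
    se <- sum(pred == "cancer" & truth == "cancer") / sum(truth == "cancer")
    sp <- sum(pred == "control" & truth == "control") / sum(truth == "control")
    c(sensitivity = se, specificity = sp)
  }
  tab <- t(vapply(thresholds, evalAt, numeric(2)))
  tab <- data.frame(threshold = thresholds, tab,
                    youden = tab[, 1] + tab[, 2] - 1)
  best <- max(tab$youden)
  ties <- which(tab$youden == best)
  # the operating point is constant between consecutive observed MDVs, so
  # each contiguous run of tying candidates corresponds to one interval of
  # real thresholds attaining the optimum, bounded by the flanking MDVs;
  # with several runs the widest interval is reported (first on ties)
  runs <- split(ties, cumsum(c(1, diff(ties) != 1)))
  intervals <- lapply(runs, function(run) {
    lo <- suppressWarnings(max(mdv[mdv < thresholds[run[1]]]))
    hi <- suppressWarnings(min(mdv[mdv >= thresholds[run[length(run)]]]))
    c(if (is.finite(lo)) lo else thresholds[run[1]],
      if (is.finite(hi)) hi else thresholds[run[length(run)]])
  })
  widths <- vapply(intervals, diff, numeric(1))
  interval <- intervals[[which.max(widths)]]
  opt <- mean(interval)
  at <- evalAt(opt)
  list(table = tab,
       optimum = list(threshold = opt, interval = interval,
                      sensitivity = unname(at["sensitivity"]),
                      specificity = unname(at["specificity"]),
                      youden = best))
}

# assemble one DiagnosticReport from an MDV table
.buildReport <- function(results, threshold, nExcluded) {
  res <- includedResults(results)
  res$predicted <- ifelse(res$excluded, "excluded",
                          classifyMDV(res$mdv, threshold))
  cm <- confusionMatrix(res)
  tt <- mdvTTest(res$mdv[res$arm == "cancer"], res$mdv[res$arm == "control"])
  sweep <- thresholdSweep(res)
  new("DiagnosticReport", confusion = cm,
      sensitivity = sensitivity(cm), specificity = specificity(cm),
      tStatistic = tt$statistic, pValue = tt$pValue,
      nExcluded = as.integer(nExcluded), threshold = threshold,
      sweep = sweep$table)
}

#' Full pipeline: processing, MDV, classification, diagnostics
#'
#' Runs the complete analysis twice -- once ignoring the exclusion filter
#' and once with low-SD samples excluded -- and returns both diagnostic
#' reports, mirroring the pre-/post-exclusion comparison of the assay's
#' validation. With \code{thresholdMode = "sweep"} the decision threshold
#' is calibrated on the unfiltered cohort at the Youden optimum and the
#' same threshold is applied to both passes; \code{"fixed"} uses
#' \code{config$threshold} as-is. Deterministic given the cohort.
#'
#' @param cohort a \linkS4class{DepCohort}
#' @param config an \code{\link{mdvConfig}}
#' @param deadThreshold dead-point masking threshold (default 0.05)
#' @param thresholdMode "fixed" (default) or "sweep"
#' @return A list with \code{unfiltered} and \code{filtered}
#'   \linkS4class{DiagnosticReport}s, the per-sample \code{mdv} table, the
#'   \code{processed} cohort and the \code{threshold} used.
#' @examples
#' cohort <- simulateCohort(cohortConfig(seed = 1))
#' ans <- runFullAnalysis(cohort, thresholdMode = "sweep")
#' ans$filtered
#' @export
runFullAnalysis <- function(cohort, config = mdvConfig(),
                            deadThreshold = 0.05,
                            thresholdMode = c("fixed", "sweep")) {
  thresholdMode <- match.arg(thresholdMode)
  proc <- maskDeadPoints(medianAcrossRepeats(cohort), deadThreshold)
  results <- computeMDV(proc, config)

  unfilteredResults <- results
  unfilteredResults$excluded <- rep(FALSE, nrow(results))
  threshold <- if (thresholdMode == "sweep")
    thresholdSweep(unfilteredResults)$optimum$threshold
  else config$threshold

  unfiltered <- .buildReport(unfilteredResults, threshold, nExcluded = 0L)
  filtered <- .buildReport(results, threshold,
                           nExcluded = sum(results$excluded))
  results$predicted <- ifelse(results$excluded, "excluded",
                              classifyMDV(results$mdv, threshold))
  list(unfiltered = unfiltered, filtered = filtered, mdv = results,
       processed = proc, threshold = threshold)
}
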