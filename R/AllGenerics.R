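#' Accessors for DEP cohort containers
#'
#' Small accessor layer over the \linkS4class{DepCohort} and
#' \linkS4class{ProcessedCohort} containers so downstream code never touches
#' slots or assay names directly.
#'
#' @param x a \code{DepCohort} or \code{ProcessedCohort}
#' @return \code{frequencies}: numeric vector of grid frequencies in Hz.
#'   \code{sampleIds}: character vector of unique sample ids.
#'   \code{armLabels}: arm label per unique sample, named by sample id.
#'   \code{depResponse}: the raw response matrix (frequencies x repeats).
#'   \code{medianSpectra}: the per-sample median matrix.
#'   \code{validMask}: logical matrix, TRUE = valid point.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname cohort-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname cohort-accessors
#' @export
setGeneric("armLabels", function(x) standardGeneric("armLabels"))

#' @rdname cohort-accessors
#' @export
setGeneric("depResponse", function(x) standardGeneric("depResponse"))

#' @rdname cohort-accessors
#' @export
setGeneric("medianSpectra", function(x) standardGeneric("medianSpectra"))

#' @rdname cohort-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname cohort-accessors
#' @export
setMethod("frequencies", "SummarizedExperiment",
          function(x) as.numeric(rowData(x)$frequency_hz))

#' @rdname cohort-accessors
#' @export
setMethod("sampleIds", "SummarizedExperiment",
          function(x) unique(as.character(colData(x)$sample_id)))

#' @rdname cohort-accessors
#' @export
setMethod("armLabels", "SummarizedExperiment", function(x) {
  ids <- sampleIds(x)
  setNames(as.character(colData(x)$arm[match(ids, colData(x)$sample_id)]), ids)
})

#' @rdname cohort-accessors
#' @export
setMethod("depResponse", "DepCohort", function(x) assay(x, "response"))

#' @rdname cohort-accessors
#' @export
setMethod("medianSpectra", "ProcessedCohort", function(x) assay(x, "median"))

#' @rdname cohort-accessors
#' @export
setMethod("validMask", "ProcessedCohort", function(x) assay(x, "mask"))

#' Sensitivity and specificity of a confusion matrix
#'
#' Cancer is the positive class throughout: sensitivity is tp / (tp + fn),
#' specificity is tn / (tn + fp).
#'
#' @param object a \linkS4class{ConfusionMatrix}
#' @return A single fraction in [0, 1].
#' @examples
#' sensitivity(ConfusionMatrix(tp = 6, fn = 2, tn = 7, fp = 1))  # 0.75
#' specificity(ConfusionMatrix(tp = 6, fn = 2, tn = 7, fp = 1))  # 0.875
#' @name diagnostic-rates
NULL

#' @rdname diagnostic-rates
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))

#' @rdname diagnostic-rates
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))

#' @rdname diagnostic-rates
#' @export
setMethod("sensitivity", "ConfusionMatrix", function(object) {
  if (object@tp + object@fn == 0L)
    stop("sensitivity undefined: no positive (cancer) samples in the matrix")
  object@tp / (object@tp + object@fn)
})

#' @rdname diagnostic-rates
#' @export
setMethod("specificity", "ConfusionMatrix", function(object) {
  if (object@tn + object@fp == 0L)
    stop("specificity undefined: no negative (control) samples in the matrix")
  object@tn / (object@tn + object@fp)
})
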