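#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

# vacuum permittivity, F/m
EPS0 <- 8.854e-12

#' Dielectric description of a suspending medium
#'
#' A homogeneous medium characterised by its relative permittivity and its
#' conductivity. In a DEP experiment this is the low-conductivity iso-osmotic
#' buffer the cells are suspended in.
#'
#' @slot relPermittivity dimensionless relative permittivity (> 0)
#' @slot conductivity conductivity in S/m (>= 0)
#' @export
setClass("DielectricMedium",
  representation(relPermittivity = "numeric", conductivity = "numeric"))

setValidity("DielectricMedium", function(object) {
  msg <- character()
  if (length(object@relPermittivity) != 1L || !is.finite(object@relPermittivity) ||
      object@relPermittivity <= 0)
    msg <- c(msg, "relPermittivity must be a single positive number")
  if (length(object@conductivity) != 1L || !is.finite(object@conductivity) ||
      object@conductivity < 0)
    msg <- c(msg, "conductivity must be a single non-negative number (S/m)")
  if (length(msg)) msg else TRUE
})

#' @describeIn DielectricMedium-class Constructor.
#' @param relPermittivity dimensionless relative permittivity (> 0)
#' @param conductivity conductivity in S/m (>= 0)
#' @return A \code{DielectricMedium} object.
#' @examples
#' DielectricMedium(78, 0.043)
#' @export
DielectricMedium <- function(relPermittivity, conductivity) {
  new("DielectricMedium", relPermittivity = as.numeric(relPermittivity),
      conductivity = as.numeric(conductivity))
}

setMethod("show", "DielectricMedium", function(object) {
  cat("DielectricMedium: eps_r =", object@relPermittivity,
      ", sigma =", object@conductivity, "S/m\n")
})

#' Single-shell dielectric parameters of a cell
#'
#' The standard single-shell idealisation: a conductive cytoplasm sphere
#' wrapped in a thin, poorly conducting membrane. The membrane is
#' parameterised by its specific (per-area) capacitance and conductance,
#' which avoids an unmeasurable membrane-thickness parameter.
#'
#' @slot radius cell radius in m (> 0)
#' @slot membraneCapacitance specific membrane capacitance in F/m^2 (> 0)
#' @slot membraneConductance specific membrane conductance in S/m^2 (>= 0)
#' @slot cytoplasmPermittivity relative permittivity of the cytoplasm (> 0)
#' @slot cytoplasmConductivity cytoplasm conductivity in S/m (> 0)
#' @export
setClass("ShellParams",
  representation(radius = "numeric",
                 membraneCapacitance = "numeric",
                 membraneConductance = "numeric",
                 cytoplasmPermittivity = "numeric",
                 cytoplasmConductivity = "numeric"))

setValidity("ShellParams", function(object) {
  msg <- character()
  chk1 <- function(x) length(x) == 1L && is.finite(x)
  if (!chk1(object@radius) || object@radius <= 0)
    msg <- c(msg, "radius must be a single positive number (m)")
  if (!chk1(object@membraneCapacitance) || object@membraneCapacitance <= 0)
    msg <- c(msg, "membraneCapacitance must be positive (F/m^2)")
  if (!chk1(object@membraneConductance) || object@membraneConductance < 0)
    msg <- c(msg, "membraneConductance must be non-negative (S/m^2)")
  if (!chk1(object@cytoplasmPermittivity) || object@cytoplasmPermittivity <= 0)
    msg <- c(msg, "cytoplasmPermittivity must be positive")
  if (!chk1(object@cytoplasmConductivity) || object@cytoplasmConductivity <= 0)
    msg <- c(msg, "cytoplasmConductivity must be positive (S/m)")
  if (length(msg)) msg else TRUE
})

#' @describeIn ShellParams-class Constructor.
#' @param radius cell radius, m
#' @param membraneCapacitance specific membrane capacitance, F/m^2
#' @param membraneConductance specific membrane conductance, S/m^2
#' @param cytoplasmPermittivity relative permittivity of the cytoplasm
#' @param cytoplasmConductivity cytoplasm conductivity, S/m
#' @return A \code{ShellParams} object.
#' @examples
#' ShellParams(10e-6, 0.01, 2000, 60, 0.25)
#' @export
ShellParams <- function(radius, membraneCapacitance, membraneConductance,
                        cytoplasmPermittivity, cytoplasmConductivity) {
  new("ShellParams",
      radius = as.numeric(radius),
      membraneCapacitance = as.numeric(membraneCapacitance),
      membraneConductance = as.numeric(membraneConductance),
      cytoplasmPermittivity = as.numeric(cytoplasmPermittivity),
      cytoplasmConductivity = as.numeric(cytoplasmConductivity))
}

setMethod("show", "ShellParams", function(object) {
  cat("ShellParams:\n")
  cat(sprintf("  radius                : %.4g m\n", object@radius))
  cat(sprintf("  membraneCapacitance   : %.4g F/m^2\n", object@membraneCapacitance))
  cat(sprintf("  membraneConductance   : %.4g S/m^2\n", object@membraneConductance))
  cat(sprintf("  cytoplasmPermittivity : %.4g\n", object@cytoplasmPermittivity))
  cat(sprintf("  cytoplasmConductivity : %.4g S/m\n", object@cytoplasmConductivity))
})

#' Shell-parameter distribution for one study arm
#'
#' Describes the between-participant variation of cell dielectric parameters
#' within an arm: a central \code{ShellParams} value plus per-parameter
#' log-normal coefficients of variation. Log-normal variation preserves
#' positivity of every parameter.
#'
#' @slot label arm label, one of "cancer" or "control"
#' @slot centre central (median-scale) \code{ShellParams} for the arm
#' @slot cv named numeric vector of coefficients of variation, one per
#'   shell parameter
#' @export
setClass("ArmPopulation",
  representation(label = "character", centre = "ShellParams", cv = "numeric"))

SHELL_PARAM_NAMES <- c("radius", "membraneCapacitance", "membraneConductance",
                       "cytoplasmPermittivity", "cytoplasmConductivity")

setValidity("ArmPopulation", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !object@label %in% c("cancer", "control"))
    msg <- c(msg, "label must be 'cancer' or 'control'")
  if (!identical(sort(names(object@cv)), sort(SHELL_PARAM_NAMES)))
    msg <- c(msg, "cv must be named after all five shell parameters")
  if (any(!is.finite(object@cv)) || any(object@cv < 0))
    msg <- c(msg, "cv values must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn ArmPopulation-class Constructor. A scalar \code{cv} is
#'   recycled across all five parameters.
#' @param label "cancer" or "control"
#' @param centre central \code{ShellParams}
#' @param cv coefficient(s) of variation; scalar or named vector
#' @return An \code{ArmPopulation} object.
#' @export
ArmPopulation <- function(label, centre, cv = 0.15) {
  if (length(cv) == 1L && is.null(names(cv)))
    cv <- setNames(rep(cv, 5L), SHELL_PARAM_NAMES)
  new("ArmPopulation", label = label, centre = centre, cv = cv)
}

setMethod("show", "ArmPopulation", function(object) {
  cat("ArmPopulation '", object@label, "' (log-normal, CV ",
      paste(signif(unname(object@cv), 3), collapse = "/"), "):\n", sep = "")
  show(object@centre)
})

#' Raw multi-repeat DEP cohort
#'
#' A \linkS4class{SummarizedExperiment} holding one column per technical
#' repeat (a single 3DEP-style acquisition) and one row per frequency.
#' Assay \code{"response"} is the dimensionless DEP response;
#' \code{rowData(x)$frequency_hz} carries the frequency grid and
#' \code{colData} carries \code{sample_id}, \code{arm}, \code{repeat_index}
#' and optional \code{sex}/\code{age}. Simulated cohorts additionally store
#' ground truth (low-cell flags, injected dead points) and the generating
#' configuration in \code{metadata}.
#'
#' @export
setClass("DepCohort", contains = "SummarizedExperiment")

setValidity("DepCohort", function(object) {
  msg <- character()
  if (!"response" %in% assayNames(object))
    msg <- c(msg, "assay 'response' is required")
  f <- rowData(object)$frequency_hz
  if (is.null(f))
    msg <- c(msg, "rowData must carry 'frequency_hz'")
  else if (any(f <= 0) || is.unsorted(f, strictly = TRUE))
    msg <- c(msg, "frequency_hz must be strictly increasing and positive")
  cd <- colData(object)
  for (col in c("sample_id", "arm", "repeat_index"))
    if (!col %in% colnames(cd)) msg <- c(msg, paste0("colData must carry '", col, "'"))
  if ("arm" %in% colnames(cd) && !all(cd$arm %in% c("cancer", "control")))
    msg <- c(msg, "arm labels must be 'cancer' or 'control'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DepCohort", function(object) {
  f <- rowData(object)$frequency_hz
  ids <- unique(colData(object)$sample_id)
  arms <- colData(object)$arm[match(ids, colData(object)$sample_id)]
  cat("DepCohort:", length(ids), "samples (",
      sum(arms == "cancer"), "cancer /", sum(arms == "control"), "control ),",
      ncol(object), "repeat spectra\n")
  cat(sprintf("  %d frequencies, %.3g Hz - %.3g Hz\n", length(f), min(f), max(f)))
})

#' Per-sample processed DEP spectra
#'
#' A \linkS4class{SummarizedExperiment} with one column per sample. Assay
#' \code{"median"} is the per-frequency median across that sample's
#' technical repeats; assay \code{"mask"} is logical, TRUE for valid points
#' (dead-connection points are masked, never overwritten).
#' \code{colData} carries \code{sample_id}, \code{arm} and
#' \code{n_repeats_used}.
#'
#' @export
setClass("ProcessedCohort", contains = "SummarizedExperiment")

setValidity("ProcessedCohort", function(object) {
  msg <- character()
  if (!all(c("median", "mask") %in% assayNames(object)))
    msg <- c(msg, "assays 'median' and 'mask' are required")
  if (is.null(rowData(object)$frequency_hz))
    msg <- c(msg, "rowData must carry 'frequency_hz'")
  cd <- colData(object)
  for (col in c("sample_id", "arm", "n_repeats_used"))
    if (!col %in% colnames(cd)) msg <- c(msg, paste0("colData must carry '", col, "'"))
  if ("sample_id" %in% colnames(cd) && anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_id values must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProcessedCohort", function(object) {
  cat("ProcessedCohort:", ncol(object), "samples,",
      nrow(object), "frequencies;",
      sum(!assay(object, "mask")), "masked points\n")
})

#' 2x2 diagnostic confusion matrix
#'
#' Counts of true/false positives and negatives with cancer as the positive
#' class. Excluded samples are never counted here.
#'
#' @slot tp true positives @slot fn false negatives
#' @slot tn true negatives @slot fp false positives
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fn = "integer", tn = "integer", fp = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fn, object@tn, object@fp)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0L))
    "tp, fn, tn, fp must be single non-negative counts" else TRUE
})

#' @describeIn ConfusionMatrix-class Constructor.
#' @param tp,fn,tn,fp non-negative counts; cancer is the positive class
#' @return A \code{ConfusionMatrix} object.
#' @examples
#' ConfusionMatrix(tp = 6, fn = 2, tn = 7, fp = 1)
#' @export
ConfusionMatrix <- function(tp = 0L, fn = 0L, tn = 0L, fp = 0L) {
  new("ConfusionMatrix", tp = as.integer(tp), fn = as.integer(fn),
      tn = as.integer(tn), fp = as.integer(fp))
}

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fp, object@fn, object@tn), 2, 2,
              dimnames = list(truth = c("cancer", "control"),
                              predicted = c("cancer", "control")))
  cat("ConfusionMatrix (cancer = positive):\n")
  print(m)
})

#' Diagnostic performance report
#'
#' Operating characteristics of the MDV classifier on one cohort:
#' confusion matrix, sensitivity, specificity, a two-sample t-test between
#' the arms' MDVs, the number of samples removed by the exclusion filter,
#' the decision threshold used, and a threshold sweep table.
#'
#' @slot confusion \code{ConfusionMatrix}
#' @slot sensitivity tp / (tp + fn)
#' @slot specificity tn / (tn + fp)
#' @slot tStatistic two-sample t statistic (cancer minus control)
#' @slot pValue two-tailed p-value
#' @slot nExcluded number of samples removed by the exclusion filter
#' @slot threshold decision threshold applied (cancer iff MDV < threshold)
#' @slot sweep data.frame with columns threshold, sensitivity, specificity,
#'   youden
#' @export
setClass("DiagnosticReport",
  representation(confusion = "ConfusionMatrix",
                 sensitivity = "numeric", specificity = "numeric",
                 tStatistic = "numeric", pValue = "numeric",
                 nExcluded = "integer", threshold = "numeric",
                 sweep = "data.frame"))

setMethod("show", "DiagnosticReport", function(object) {
  cat("DiagnosticReport\n")
  show(object@confusion)
  cat(sprintf("  sensitivity : %.3f\n  specificity : %.3f\n",
              object@sensitivity, object@specificity))
  cat(sprintf("  t = %.3f, two-tailed p = %.4g\n",
              object@tStatistic, object@pValue))
  cat(sprintf("  excluded    : %d sample(s)\n", object@nExcluded))
  cat(sprintf("  threshold   : MDV < %.4g => cancer\n", object@threshold))
  cat(sprintf("  sweep       : %d thresholds evaluated\n", nrow(object@sweep)))
})
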