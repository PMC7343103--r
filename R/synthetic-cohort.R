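#' Default suspending medium
#'
#' Low-conductivity iso-osmotic DEP buffer: relative permittivity 78,
#' conductivity 43 mS/m.
#'
#' @return A \linkS4class{DielectricMedium}.
#' @export
defaultMedium <- function() DielectricMedium(78, 0.043)

#' Default two-arm shell-parameter populations
#'
#' Central parameters chosen to reproduce the qualitative contrast seen
#' between bladder-cancer and healthy urothelial cells: the control arm has
#' a higher membrane conductance (raising the low-frequency response) and a
#' lower cytoplasm conductivity (lowering the high-frequency response) than
#' the cancer arm. Both arms: radius 10 um, membrane capacitance
#' 0.01 F/m^2, cytoplasm permittivity 60. Control: membrane conductance
#' 2000 S/m^2, cytoplasm conductivity 0.25 S/m; cancer: 200 S/m^2 and
#' 0.5 S/m. Between-participant variation is log-normal with CV 0.15.
#'
#' @param cv coefficient of variation for both arms (default 0.15)
#' @return Named list with \code{ArmPopulation}s \code{cancer} and
#'   \code{control}.
#' @export
defaultArms <- function(cv = 0.15) {
  list(
    cancer = ArmPopulation("cancer",
      ShellParams(10e-6, 0.01, 200, 60, 0.5), cv),
    control = ArmPopulation("control",
      ShellParams(10e-6, 0.01, 2000, 60, 0.25), cv))
}

#' Cohort simulation configuration
#'
#' Bundles the study-design knobs of the synthetic cohort generator.
#' Defaults emulate a pilot voided-urine study: 8 samples per arm, 3-5
#' technical repeats each, a 20-point log grid from 10 kHz to 45 MHz,
#' additive Gaussian instrument noise of SD 0.05, one dead instrument well
#' (near-zero values at the same frequency in every sample), and 3
#' cancer-arm samples whose cell yield is too low to produce a DEP curve
#' (spectra are pure noise).
#'
#' @param nCancer,nControl samples per arm (default 8 each)
#' @param repeatsRange inclusive range of technical repeats per sample
#'   (default 3 to 5)
#' @param frequencies measurement grid, Hz (default \code{defaultGrid()})
#' @param noiseSD SD of additive Gaussian noise per point per repeat,
#'   dimensionless response units (default 0.05)
#' @param deadWells number of instrument wells with a dead connection for
#'   the whole cohort (default 1): their positions are drawn once per
#'   cohort and the near-zero values appear at the same frequency in every
#'   sample and repeat, as a faulty well of a shared well-plate reader does
#' @param deadPointProb additional per-point probability of a dead
#'   connection drawn independently per sample (default 0)
#' @param lowCellCancer,lowCellControl number of samples per arm injected
#'   as low-cell failures (defaults 3 and 0)
#' @param lowCellProb additional per-sample probability of a low-cell
#'   failure (default 0; the injected counts above are deterministic)
#' @param gain dimensionless instrument gain mapping Re[CM] to the recorded
#'   response (default 2; see the methods vignette for the scale rationale)
#' @param seed integer RNG seed; NULL draws one and records it
#' @return A validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nCancer = 8L, nControl = 8L,
                         repeatsRange = c(3L, 5L),
                         frequencies = defaultGrid(),
                         noiseSD = 0.05, deadWells = 1L, deadPointProb = 0,
                         lowCellCancer = 3L, lowCellControl = 0L,
                         lowCellProb = 0, gain = 2, seed = NULL) {
  stopifnot(nCancer >= 1L, nControl >= 1L,
            length(repeatsRange) == 2L, repeatsRange[1] >= 1L,
            repeatsRange[2] >= repeatsRange[1],
            length(frequencies) >= 2L,
            !is.unsorted(frequencies, strictly = TRUE), all(frequencies > 0),
            noiseSD >= 0, deadPointProb >= 0, deadPointProb <= 1,
            deadWells >= 0L, deadWells <= length(frequencies),
            lowCellProb >= 0, lowCellProb <= 1,
            lowCellCancer >= 0L, lowCellCancer <= nCancer,
            lowCellControl >= 0L, lowCellControl <= nControl,
            is.finite(gain))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  structure(list(nCancer = as.integer(nCancer),
                 nControl = as.integer(nControl),
                 repeatsRange = as.integer(repeatsRange),
                 frequencies = as.numeric(frequencies),
                 noiseSD = noiseSD, deadWells = as.integer(deadWells),
                 deadPointProb = deadPointProb,
                 lowCellCancer = as.integer(lowCellCancer),
                 lowCellControl = as.integer(lowCellControl),
                 lowCellProb = lowCellProb, gain = gain,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Draw one cell's shell parameters from an arm population
#'
#' Each parameter is drawn independently from a log-normal distribution
#' whose mean equals the arm's central value and whose coefficient of
#' variation is the arm's \code{cv}. With CV 0 the central values are
#' returned exactly. Uses (and advances) the current RNG state.
#'
#' @param arm an \linkS4class{ArmPopulation}
#' @return A \linkS4class{ShellParams}.
#' @export
sampleCellParams <- function(arm) {
  stopifnot(is(arm, "ArmPopulation"))
  vals <- vapply(SHELL_PARAM_NAMES, function(p) {
    m <- slot(arm@centre, p)
    cv <- arm@cv[[p]]
    if (cv == 0) return(m)
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(1L, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }, numeric(1))
  do.call(ShellParams, as.list(vals))
}

# one sample's repeat matrix plus ground truth; deadWells are instrument
# wells dead for the whole cohort, per-point draws add sample-level deads
.simulateSampleMatrix <- function(cell, medium, config, lowCell,
                                  deadWells = integer(0)) {
  nRep <- if (config$repeatsRange[1] == config$repeatsRange[2])
    config$repeatsRange[1]
  else sample(seq(config$repeatsRange[1], config$repeatsRange[2]), 1L)
  nF <- length(config$frequencies)
  truth <- if (lowCell) rep(0, nF)
  else depSpectrum(cell, medium, config$frequencies, gain = config$gain)
  m <- truth + matrix(rnorm(nF * nRep, 0, config$noiseSD), nF, nRep)
  dead <- sort(union(deadWells, which(runif(nF) < config$deadPointProb)))
  if (length(dead))
    m[dead, ] <- rnorm(length(dead) * nRep, 0, config$noiseSD / 10)
  list(values = m, dead = dead, nRep = nRep)
}

#' Simulate one sample's technical repeats
#'
#' Each repeat is gain * Re[CM] evaluated on the configured grid plus iid
#' Gaussian noise. A low-cell sample has no underlying curve: its repeats
#' are noise around zero. Dead-connection points -- the given fixed
#' instrument wells plus per-point draws at \code{config$deadPointProb} --
#' replace the values at that frequency across all repeats with near-zero
#' noise (SD noiseSD / 10). Uses the current RNG state.
#'
#' @param cell a \linkS4class{ShellParams}
#' @param medium a \linkS4class{DielectricMedium}
#' @param config a \code{\link{cohortConfig}}
#' @param lowCell logical: simulate a low-cell failure
#' @param deadWells integer indices of instrument wells that are dead for
#'   every sample of the cohort (default none)
#' @return A list with \code{values} (frequencies x repeats matrix),
#'   \code{dead} (indices of injected dead points) and \code{nRep}.
#' @export
simulateSample <- function(cell, medium, config, lowCell = FALSE,
                           deadWells = integer(0)) {
  stopifnot(inherits(config, "CohortConfig"), is(medium, "DielectricMedium"))
  .simulateSampleMatrix(cell, medium, config, lowCell, deadWells)
}

#' Simulate a two-arm DEP cohort
#'
#' Generates the full study structure: per-sample shell parameters drawn
#' from the arm populations, 3-5 technical repeats with instrument noise,
#' injected dead-connection points and low-cell failures, and demographic
#' metadata (sex ratios 6:2 cancer, 7:1 control; ages ~N(73, 10) and
#' N(52, 17)). Fully reproducible from \code{config$seed}; ground truth
#' (low-cell flags, dead-point indices, drawn parameters) is kept in
#' \code{metadata()}.
#'
#' @param config a \code{\link{cohortConfig}}
#' @param arms named list of \code{ArmPopulation}s (default
#'   \code{defaultArms()})
#' @param medium a \linkS4class{DielectricMedium} (default
#'   \code{defaultMedium()})
#' @return A \linkS4class{DepCohort}.
#' @examples
#' cohort <- simulateCohort(cohortConfig(seed = 1))
#' cohort
#' @export
simulateCohort <- function(config = cohortConfig(),
                           arms = defaultArms(),
                           medium = defaultMedium()) {
  stopifnot(inherits(config, "CohortConfig"),
            all(c("cancer", "control") %in% names(arms)))
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(config$seed)

  armOf <- c(rep("cancer", config$nCancer), rep("control", config$nControl))
  ids <- sprintf("S%02d_%s", seq_along(armOf), armOf)
  lowCell <- logical(length(armOf))
  pick <- function(idx, n) idx[sample.int(length(idx), n)]
  if (config$lowCellCancer > 0L)
    lowCell[pick(which(armOf == "cancer"), config$lowCellCancer)] <- TRUE
  if (config$lowCellControl > 0L)
    lowCell[pick(which(armOf == "control"), config$lowCellControl)] <- TRUE
  lowCell <- lowCell | (runif(length(armOf)) < config$lowCellProb)

  sex <- ifelse(armOf == "cancer",
                ifelse(runif(length(armOf)) < 6 / 8, "M", "F"),
                ifelse(runif(length(armOf)) < 7 / 8, "M", "F"))
  age <- round(ifelse(armOf == "cancer", rnorm(length(armOf), 73, 10),
                      rnorm(length(armOf), 52, 17)))

  deadWells <- if (config$deadWells > 0L)
    sort(sample.int(length(config$frequencies), config$deadWells))
  else integer(0)

  cells <- vector("list", length(armOf))
  mats <- vector("list", length(armOf))
  deadList <- vector("list", length(armOf))
  for (i in seq_along(armOf)) {
    cells[[i]] <- sampleCellParams(arms[[armOf[i]]])
    sim <- .simulateSampleMatrix(cells[[i]], medium, config, lowCell[i],
                                 deadWells)
    mats[[i]] <- sim$values
    deadList[[i]] <- sim$dead
  }
  nRep <- vapply(mats, ncol, integer(1))
  response <- do.call(cbind, mats)
  colnames(response) <- unlist(lapply(seq_along(ids), function(i)
    sprintf("%s_r%d", ids[i], seq_len(nRep[i]))))
  cd <- DataFrame(sample_id = rep(ids, nRep),
                  arm = rep(armOf, nRep),
                  repeat_index = unlist(lapply(nRep, seq_len)),
                  sex = rep(sex, nRep), age = rep(age, nRep),
                  row.names = colnames(response))
  rd <- DataFrame(frequency_hz = config$frequencies)
  names(deadList) <- names(cells) <- ids
  se <- SummarizedExperiment(assays = SimpleList(response = response),
                             rowData = rd, colData = cd)
  metadata(se) <- list(config = config, seed = config$seed,
                       lowCell = setNames(lowCell, ids),
                       deadWells = deadWells,
                       deadPoints = deadList, cellParams = cells)
  new("DepCohort", se)
}
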