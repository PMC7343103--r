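#' @importFrom utils read.csv write.csv
NULL

.fmt <- function(x) sprintf("%.15g", x)

#' Read and write single-spectrum CSV files
#'
#' Dialect: header \code{frequency_hz,value[,mask]}; the mask column is
#' optional with 1 = valid. UTF-8, "." decimal separator.
#'
#' @param path CSV file path
#' @return \code{readSpectrum}: a list with \code{frequency_hz},
#'   \code{value} and logical \code{mask}.
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  d <- read.csv(path)
  if (!all(c("frequency_hz", "value") %in% names(d)))
    stop("spectrum CSV needs columns frequency_hz,value: ", path)
  mask <- if ("mask" %in% names(d)) d$mask == 1 else rep(TRUE, nrow(d))
  list(frequency_hz = d$frequency_hz, value = d$value, mask = mask)
}

#' @rdname readSpectrum
#' @param frequency_hz,value,mask spectrum content to write
#' @export
writeSpectrum <- function(path, frequency_hz, value, mask = NULL) {
  d <- data.frame(frequency_hz = .fmt(frequency_hz), value = .fmt(value))
  if (!is.null(mask)) d$mask <- as.integer(mask)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to disk
#'
#' One spectrum CSV per sample (\code{frequency_hz,repeat_1..repeat_k})
#' plus a \code{manifest.csv} (\code{sample_id,arm,file,sex,age}). The
#' layout round-trips losslessly through \code{\link{readCohort}}.
#'
#' @param cohort a \linkS4class{DepCohort}
#' @param dir output directory (created if needed)
#' @return Invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "DepCohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  ids <- sampleIds(cohort)
  cd <- colData(cohort)
  resp <- depResponse(cohort)
  files <- paste0(ids, ".csv")
  for (i in seq_along(ids)) {
    cols <- which(cd$sample_id == ids[i])
    m <- resp[, cols, drop = FALSE]
    d <- data.frame(frequency_hz = .fmt(frequencies(cohort)))
    for (k in seq_along(cols)) d[[paste0("repeat_", k)]] <- .fmt(m[, k])
    p <- file.path(dir, files[i])
    tryCatch(write.csv(d, p, row.names = FALSE, quote = FALSE),
             error = function(e) stop("failed writing ", p, ": ",
                                      conditionMessage(e)))
  }
  first <- match(ids, cd$sample_id)
  manifest <- data.frame(
    sample_id = ids, arm = cd$arm[first], file = files,
    sex = if ("sex" %in% colnames(cd)) cd$sex[first] else NA,
    age = if ("age" %in% colnames(cd)) cd$age[first] else NA)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Read a cohort from a manifest
#'
#' Inverse of \code{\link{writeCohort}}: reads the manifest and every
#' referenced spectrum CSV, validating arm labels, grid consistency and
#' repeat lengths.
#'
#' @param manifestPath path to \code{manifest.csv}
#' @return A \linkS4class{DepCohort}.
#' @export
readCohort <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop("manifest not found: ", manifestPath)
  man <- read.csv(manifestPath)
  for (col in c("sample_id", "arm", "file"))
    if (!col %in% names(man)) stop("manifest lacks column '", col, "'")
  if (any(!man$arm %in% c("cancer", "control")))
    stop("manifest arm labels must be 'cancer' or 'control', got: ",
         paste(setdiff(man$arm, c("cancer", "control")), collapse = ", "))
  if (anyDuplicated(man$sample_id))
    stop("duplicate sample_id in manifest")
  dir <- dirname(manifestPath)
  grid <- NULL
  mats <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- file.path(dir, man$file[i])
    if (!file.exists(p)) stop("spectrum file not found: ", p)
    d <- read.csv(p)
    if (names(d)[1] != "frequency_hz" || ncol(d) < 2L)
      stop("malformed spectrum CSV (need frequency_hz,repeat_1..): ", p)
    if (anyNA(d))
      stop("missing values (unequal repeat lengths?) in ", p)
    if (is.null(grid)) grid <- d$frequency_hz
    else if (length(grid) != length(d$frequency_hz) ||
             any(abs(grid - d$frequency_hz) > 1e-9 * pmax(grid, 1)))
      stop("frequency grid in ", p, " differs from the first sample's grid")
    mats[[i]] <- as.matrix(d[, -1, drop = FALSE])
  }
  nRep <- vapply(mats, ncol, integer(1))
  resp <- do.call(cbind, mats)
  colnames(resp) <- unlist(lapply(seq_len(nrow(man)), function(i)
    sprintf("%s_r%d", man$sample_id[i], seq_len(nRep[i]))))
  cd <- DataFrame(sample_id = rep(man$sample_id, nRep),
                  arm = rep(man$arm, nRep),
                  repeat_index = unlist(lapply(nRep, seq_len)),
                  row.names = colnames(resp))
  if ("sex" %in% names(man)) cd$sex <- rep(man$sex, nRep)
  if ("age" %in% names(man)) cd$age <- rep(man$age, nRep)
  se <- SummarizedExperiment(assays = SimpleList(response = resp),
                             rowData = DataFrame(frequency_hz = grid),
                             colData = cd)
  new("DepCohort", se)
}

#' Write an MDV results table as CSV
#'
#' Columns: \code{sample_id,arm,low_mean,high_mean,mdv,spectrum_sd,
#' excluded,predicted}.
#'
#' @param results DataFrame from \code{\link{computeMDV}}
#' @param path output CSV path
#' @return Invisibly, the path.
#' @export
writeMDVTable <- function(results, path) {
  d <- data.frame(sample_id = results$sample_id, arm = results$arm,
                  low_mean = .fmt(results$low_mean),
                  high_mean = .fmt(results$high_mean),
                  mdv = .fmt(results$mdv),
                  spectrum_sd = .fmt(results$spectrum_sd),
                  excluded = as.integer(results$excluded),
                  predicted = results$predicted)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a diagnostic report as JSON
#'
#' @param report a \linkS4class{DiagnosticReport}
#' @param path output JSON path
#' @return Invisibly, the path.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "DiagnosticReport"))
  cm <- report@confusion
  obj <- list(confusion = list(tp = cm@tp, fn = cm@fn, tn = cm@tn, fp = cm@fp),
              sensitivity = report@sensitivity,
              specificity = report@specificity,
              t_statistic = report@tStatistic,
              p_value = report@pValue,
              n_excluded = report@nExcluded,
              threshold = report@threshold,
              threshold_sweep = report@sweep)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

# flat key-value config file -> cohortConfig
.configKeys <- c("n_cancer", "n_control", "repeats_min", "repeats_max",
                 "n_frequencies", "f_min_hz", "f_max_hz", "noise_sd",
                 "dead_wells", "dead_point_prob", "low_cell_cancer",
                 "low_cell_control", "low_cell_prob", "gain", "seed")

#' Read a simulation configuration file
#'
#' Flat key-value YAML; unknown keys are rejected by name. Keys (all
#' optional, defaults in parentheses): n_cancer (8), n_control (8),
#' repeats_min (3), repeats_max (5), n_frequencies (20), f_min_hz (1e4),
#' f_max_hz (4.5e7), noise_sd (0.05), dead_wells (1), dead_point_prob (0),
#' low_cell_cancer (3), low_cell_control (0), low_cell_prob (0), gain (2),
#' seed (random).
#'
#' @param path YAML file path
#' @param seed optional seed overriding the file's
#' @return A \code{\link{cohortConfig}}.
#' @export
readSimConfig <- function(path, seed = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- setdiff(names(cfg), .configKeys)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  g <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  if (!is.null(seed)) cfg$seed <- seed
  cohortConfig(
    nCancer = g("n_cancer", 8L), nControl = g("n_control", 8L),
    repeatsRange = c(g("repeats_min", 3L), g("repeats_max", 5L)),
    frequencies = defaultGrid(g("n_frequencies", 20L),
                              g("f_min_hz", 1e4), g("f_max_hz", 4.5e7)),
    noiseSD = g("noise_sd", 0.05),
    deadWells = g("dead_wells", 1L),
    deadPointProb = g("dead_point_prob", 0),
    lowCellCancer = g("low_cell_cancer", 3L),
    lowCellControl = g("low_cell_control", 0L),
    lowCellProb = g("low_cell_prob", 0),
    gain = g("gain", 2), seed = cfg$seed)
}

#' Simulate a cohort and write it to disk
#'
#' Front-end used by the \code{depscreen.R} script's \code{simulate}
#' subcommand: reads the configuration, simulates, writes the cohort and
#' prints a short summary including the seed.
#'
#' @param configPath optional YAML configuration (see
#'   \code{\link{readSimConfig}})
#' @param outDir output directory
#' @param seed optional seed override
#' @return Invisibly, the simulated \linkS4class{DepCohort}.
#' @export
cmdSimulate <- function(configPath = NULL, outDir = ".", seed = NULL) {
  config <- readSimConfig(configPath, seed = seed)
  cohort <- simulateCohort(config)
  writeCohort(cohort, outDir)
  message("simulated ", length(sampleIds(cohort)), " samples (seed ",
          config$seed, ") -> ", outDir)
  invisible(cohort)
}

#' Analyze a cohort from disk
#'
#' Front-end used by the \code{depscreen.R} script's \code{analyze}
#' subcommand: reads the cohort, runs the full pipeline and writes
#' \code{mdv.csv}, \code{report_unfiltered.json},
#' \code{report_filtered.json} and \code{arm_means.csv} into
#' \code{outDir}.
#'
#' @param manifestPath path to the cohort manifest
#' @param outDir output directory
#' @param threshold MDV decision threshold (default 0.65)
#' @param sdMin exclusion cutoff (default 0.4)
#' @param bandMode "by_frequency" or "by_value"
#' @param thresholdMode "fixed" or "sweep"
#' @return Invisibly, the \code{\link{runFullAnalysis}} result.
#' @export
cmdAnalyze <- function(manifestPath, outDir = ".", threshold = 0.65,
                       sdMin = 0.4, bandMode = "by_frequency",
                       thresholdMode = "fixed") {
  cohort <- readCohort(manifestPath)
  config <- mdvConfig(threshold = threshold, sdMin = sdMin,
                      bandMode = bandMode)
  ans <- runFullAnalysis(cohort, config, thresholdMode = thresholdMode)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  writeMDVTable(ans$mdv, file.path(outDir, "mdv.csv"))
  writeReport(ans$unfiltered, file.path(outDir, "report_unfiltered.json"))
  writeReport(ans$filtered, file.path(outDir, "report_filtered.json"))
  am <- rbind(cbind(arm = "cancer", armMeanSpectrum(ans$processed, "cancer")),
              cbind(arm = "control", armMeanSpectrum(ans$processed, "control")))
  am$frequency_hz <- .fmt(am$frequency_hz)
  am$mean <- .fmt(am$mean)
  write.csv(am, file.path(outDir, "arm_means.csv"),
            row.names = FALSE, quote = FALSE)
  message(sum(ans$mdv$excluded), " sample(s) excluded; reports -> ", outDir)
  invisible(ans)
}
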