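#' Write germination records to delimited text
#'
#' Comma-separated, header row, long format:
#' `dish,temperature_C,time_d,tr_count,er_count,dish_size,treatment_id`.
#' Round-trips losslessly through [readGerminationCsv()].
#'
#' @param records germination records (see [simulateExperiment()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGerminationCsv <- function(records, path) {
  validateGerminationRecords(records)
  cols <- c("dish", "temperature_C", "time_d", "tr_count", "er_count",
            "dish_size", "treatment_id")
  if (!"treatment_id" %in% names(records)) records$treatment_id <- "none"
  ok <- tryCatch({
    write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to '", path, "'")
  invisible(path)
}

#' Read germination records from delimited text
#'
#' Validating reader for the long germination format.  Malformed rows and
#' count inversions (`er_count > tr_count`, counts above the dish size,
#' cumulative counts decreasing in time) raise errors naming the offending
#' file line; an empty file (header only) returns an empty table with a
#' warning.
#'
#' @param path CSV file with header
#'   `dish,temperature_C,time_d,tr_count,er_count,dish_size[,treatment_id]`.
#' @return a validated germination-record data.frame.
#' @export
readGerminationCsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: '", path, "'")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed file '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  req <- c("dish", "temperature_C", "time_d", "tr_count", "er_count", "dish_size")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s) in '", path, "': ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("'", path, "' contains no data rows")
    df$treatment_id <- character(0)
    return(df)
  }
  if (!"treatment_id" %in% names(df)) df$treatment_id <- "none"
  for (cc in setdiff(req, "dish")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad))
      stop("non-numeric '", cc, "' at line ", bad[1] + 1L, " of '", path, "'")
    df[[cc]] <- as.numeric(df[[cc]])
  }
  bad <- which(df$er_count > df$tr_count | df$tr_count > df$dish_size |
               df$er_count < 0)
  if (length(bad))
    stop("count inversion (need 0 <= er <= tr <= dish_size) at line ",
         bad[1] + 1L, " of '", path, "'")
  validateGerminationRecords(df)
  df
}

#' Run the simulate-fit-summarize pipeline from a configuration
#'
#' Reproducible umbrella over the package stages: simulates a germination
#' dataset from a packaged parameter fixture (or explicit parameters), fits
#' the thermal-time model, estimates per-temperature maximum germination,
#' and optionally writes the dataset (CSV), the fit report and the resolved
#' configuration (JSON) next to each other.  Identical configuration and
#' seed give a bit-identical bundle.
#'
#' @param config a named list (or path to a JSON file) with elements:
#'   `paramSet` (fixture name) or `params` (list of
#'   [seedPopulationParams()] arguments); optional `temperatures`,
#'   `nDishes`, `seedsPerDish`, `scoringDays`, `event`, `seed`.
#' @param outDir optional output directory (created if needed).
#' @return a list with `records`, `fit` ([ThermalTimeFit-class]), `gmax`
#'   (per-temperature table) and `config` (the resolved configuration).
#' @examples
#' bundle <- runPipeline(list(paramSet = "black_AR_1", seed = 11,
#'                            scoringDays = 30))
#' bundle$fit
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: '", config, "'")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("paramSet", "params", "temperatures", "nDishes", "seedsPerDish",
             "scoringDays", "event", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))

  params <- if (!is.null(config$paramSet)) {
    seedParamSet(config$paramSet)
  } else if (!is.null(config$params)) {
    do.call(seedPopulationParams, config$params)
  } else stop("config error: supply 'paramSet' or 'params'")

  resolved <- list(
    paramSet = config$paramSet,
    temperatures = config$temperatures %||%
      (if (!is.null(config$paramSet)) fixtureTemperatures(config$paramSet)
       else stop("config error: 'temperatures' required with explicit params")),
    nDishes = config$nDishes %||% 3,
    seedsPerDish = config$seedsPerDish %||% 30,
    scoringDays = config$scoringDays %||% length(fixtureScoringTimes()),
    event = config$event %||% "er",
    seed = config$seed %||% 1)

  design <- experimentDesign(temperatures = resolved$temperatures,
                             nDishes = resolved$nDishes,
                             seedsPerDish = resolved$seedsPerDish,
                             scoringTimes = seq_len(resolved$scoringDays),
                             rngSeed = resolved$seed)
  records <- simulateExperiment(design, params)
  fit <- tryCatch(fitThermalTime(records, event = resolved$event),
                  error = function(e) stop("stage 'fit' failed: ",
                                           conditionMessage(e), call. = FALSE))
  gmax <- estimateGmax(records, event = resolved$event)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeGerminationCsv(records, file.path(outDir, "data.csv"))
    jsonlite::write_json(fitReport(fit), file.path(outDir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write.csv(gmax, file.path(outDir, "gmax.csv"), row.names = FALSE)
    jsonlite::write_json(resolved, file.path(outDir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(records = records, fit = fit, gmax = gmax, config = resolved)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
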