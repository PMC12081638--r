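## Plate input and control normalization.

plateRequiredColumns <- c("plate_id", "well", "drug_a_conc_uM",
                          "drug_b_conc_uM", "dose_Gy", "solvent",
                          "raw_signal", "experiment_id")

#' Read a raw plate CSV
#'
#' Reads the plate dialect written by [writePlateCsv()]: one row per well
#' with columns `plate_id`, `well`, `drug_a_conc_uM`, `drug_b_conc_uM`,
#' `dose_Gy`, `solvent`, `raw_signal`, `experiment_id`. Unknown columns are
#' preserved. Solvent percentages above the assay limits (1% DMSO, 0.3%
#' Tween-20, from an optional `solvent_pct` column) trigger a warning, not an
#' error.
#'
#' @param path CSV file path.
#' @return A data.frame of well records.
#' @export
readPlate <- function(path) {
  if (!file.exists(path)) fail("plate file '%s' does not exist", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning(sprintf("plate file '%s' contains no wells", path))
    missing <- setdiff(plateRequiredColumns, names(df))
    if (length(missing))
      fail("plate file is missing required column(s): %s",
           paste(missing, collapse = ", "))
    return(df)
  }
  missing <- setdiff(plateRequiredColumns, names(df))
  if (length(missing))
    fail("plate file is missing required column(s): %s",
         paste(missing, collapse = ", "))
  raw <- suppressWarnings(as.numeric(df$raw_signal))
  if (anyNA(raw)) {
    bad <- which(is.na(raw))[1]
    fail("non-numeric raw_signal at row %d ('%s')", bad, df$raw_signal[bad])
  }
  df$raw_signal <- raw
  if (any(raw < 0)) fail("raw_signal must be >= 0")
  checkSolventLimits(df)
  df
}

## DMSO <= 1%, Tween-20 <= 0.3% (assay solvent limits); violations warn only.
checkSolventLimits <- function(df) {
  if (!"solvent_pct" %in% names(df)) return(invisible(NULL))
  lim <- c(DMSO = 1, `Tween-20` = 0.3)
  over <- !is.na(df$solvent_pct) & df$solvent %in% names(lim) &
    df$solvent_pct > lim[df$solvent]
  if (any(over))
    warning(sprintf("%d well(s) exceed the solvent limit (DMSO 1%%, Tween-20 0.3%%)",
                    sum(over)))
  invisible(NULL)
}

#' Normalize raw signals to solvent-matched untreated controls
#'
#' Each well's viability is its raw signal divided by the mean raw signal of
#' the control wells on the same plate, in the same experiment and with the
#' same solvent, so control wells average exactly 1 per plate. Viabilities
#' are not clipped at 1 (wells can outgrow controls, and clipping would bias
#' Bliss expectations). The per-condition summary pools wells across plates
#' within an experiment, which is what makes drug x radiation designs (one
#' plate per dose) comparable.
#'
#' @param wells a data.frame of well records (from [readPlate()] or
#'   [simulatePlate()]).
#' @param controlSelector predicate `function(wells) -> logical` marking
#'   control wells; the default selects untreated wells
#'   (`drug_a_conc_uM == 0 & drug_b_conc_uM == 0 & dose_Gy == 0`).
#' @return A [ViabilityTable-class] object.
#' @examples
#' plate <- simulatePlate(plateSimSpec(noiseCv = 0, seed = 1L))
#' vt <- normalizeViability(plate)
#' conditionSummary(vt)
#' @export
normalizeViability <- function(wells, controlSelector = NULL) {
  missing <- setdiff(plateRequiredColumns, names(wells))
  if (length(missing))
    fail("well table is missing required column(s): %s",
         paste(missing, collapse = ", "))
  if (nrow(wells) == 0) fail("no wells to normalize")
  if (is.null(controlSelector)) {
    controlSelector <- function(w)
      w$drug_a_conc_uM == 0 & w$drug_b_conc_uM == 0 & w$dose_Gy == 0
    desc <- "untreated (0 uM, 0 uM, 0 Gy), matched by plate/experiment/solvent"
  } else desc <- "user-supplied control selector"
  isCtrl <- controlSelector(wells)
  if (!is.logical(isCtrl) || length(isCtrl) != nrow(wells))
    fail("controlSelector must return one logical per well")

  key <- interaction(wells$plate_id, wells$experiment_id, wells$solvent,
                     drop = TRUE)
  ctrlMeans <- tapply(wells$raw_signal[isCtrl], key[isCtrl], mean)
  noCtrl <- setdiff(levels(key), names(ctrlMeans)[!is.na(ctrlMeans)])
  if (length(noCtrl))
    fail("no control wells on plate group(s): %s",
         paste(noCtrl, collapse = ", "))
  if (any(ctrlMeans <= 0))
    fail("control mean signal is <= 0 on plate group(s): %s",
         paste(names(ctrlMeans)[ctrlMeans <= 0], collapse = ", "))

  wells$viability <- wells$raw_signal / as.numeric(ctrlMeans[as.character(key)])
  conds <- aggregate(viability ~ drug_a_conc_uM + drug_b_conc_uM + dose_Gy +
                       experiment_id, data = wells, FUN = mean)
  nw <- aggregate(viability ~ drug_a_conc_uM + drug_b_conc_uM + dose_Gy +
                    experiment_id, data = wells, FUN = length)
  conds$n_wells <- nw$viability
  names(conds)[names(conds) == "viability"] <- "mean_viability"
  conds <- conds[order(conds$experiment_id, conds$drug_a_conc_uM,
                       conds$drug_b_conc_uM, conds$dose_Gy), ]
  rownames(conds) <- NULL
  new("ViabilityTable", wells = wells, conditions = conds,
      controlDescription = desc)
}

#' @describeIn ViabilityTable-class per-well records with viabilities.
#' @param object,x a `ViabilityTable`.
#' @export
wellViabilities <- function(x) {
  stopifnot(is(x, "ViabilityTable"))
  x@wells
}

#' @describeIn ViabilityTable-class per-condition mean viabilities.
#' @export
conditionSummary <- function(x) {
  stopifnot(is(x, "ViabilityTable"))
  x@conditions
}

#' @describeIn ViabilityTable-class compact display.
#' @export
setMethod("show", "ViabilityTable", function(object) {
  cat(sprintf("ViabilityTable: %d wells, %d conditions, %d experiment(s)\n",
              nrow(object@wells), nrow(object@conditions),
              length(unique(object@wells$experiment_id))))
  cat("  controls:", object@controlDescription, "\n")
})

#' Write a viability table as TSV and/or JSON
#'
#' @param x a [ViabilityTable-class] object.
#' @param tsvPath,jsonPath optional output paths (either may be `NULL`).
#' @return invisible `NULL`.
#' @export
writeViabilityTable <- function(x, tsvPath = NULL, jsonPath = NULL) {
  stopifnot(is(x, "ViabilityTable"))
  if (!is.null(tsvPath))
    utils::write.table(conditionSummary(x), tsvPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(conditions = conditionSummary(x),
                              wells = wellViabilities(x)),
                         jsonPath, digits = 12, auto_unbox = TRUE)
  invisible(NULL)
}
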