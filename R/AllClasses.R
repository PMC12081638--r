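#' @import methods
#' @importFrom stats density mad median pt quantile rnbinom rnorm runif rgamma
#'   sd setNames t.test var aggregate rbinom
#' @importFrom utils read.csv write.csv combn packageVersion
NULL

## ---------------------------------------------------------------------------
## Simulation specification objects
## ---------------------------------------------------------------------------

#' Specification of a simulated combination-screen plate
#'
#' Describes the generative model for a Bliss-null (or deliberately
#' interacting) viability plate: single-agent viabilities, a planted
#' interaction factor, multiplicative log-normal noise and the replicate /
#' experiment layout. The true combination viability before noise is
#' `drugAViability * drugBViability / interactionFactor`, so the synergy score
#' recovered downstream equals `interactionFactor` by construction.
#'
#' @slot drugAViability,drugBViability single-agent viability fractions in
#'   \[0, 1\] relative to untreated controls.
#' @slot interactionFactor positive real; the true synergy score to plant
#'   (1 = Bliss independence).
#' @slot noiseCv coefficient of variation of the multiplicative log-normal
#'   measurement noise (>= 0).
#' @slot nReplicateWells,nExperiments positive integers; wells per condition
#'   per plate and number of independent experiments (one plate each).
#' @slot seed integer seed; each call uses its own RNG stream.
#' @slot agentB `"drug"` or `"radiation"`; with `"radiation"` agent B wells
#'   are labelled by `dose_Gy` instead of `drug_b_conc_uM`.
#' @slot drugAConc,drugBConc,doseGy nominal treatment labels written to the
#'   plate table (uM and Gy).
#' @slot controlSignal expected raw luminescence of untreated control wells.
#' @slot solvent solvent label written to every well.
#' @export
setClass("PlateSimSpec",
  representation(
    drugAViability = "numeric", drugBViability = "numeric",
    interactionFactor = "numeric", noiseCv = "numeric",
    nReplicateWells = "integer", nExperiments = "integer", seed = "integer",
    agentB = "character", drugAConc = "numeric", drugBConc = "numeric",
    doseGy = "numeric", controlSignal = "numeric", solvent = "character"))

setValidity("PlateSimSpec", function(object) {
  msg <- character()
  chk01 <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      sprintf("'%s' must be a single value in [0, 1]", nm) else character()
  }
  msg <- c(msg, chk01(object@drugAViability, "drugAViability"),
           chk01(object@drugBViability, "drugBViability"))
  if (!is.finite(object@interactionFactor) || object@interactionFactor <= 0)
    msg <- c(msg, "'interactionFactor' must be > 0")
  if (!is.finite(object@noiseCv) || object@noiseCv < 0)
    msg <- c(msg, "'noiseCv' must be >= 0")
  if (object@nReplicateWells < 1L)
    msg <- c(msg, "'nReplicateWells' must be a positive integer")
  if (object@nExperiments < 1L)
    msg <- c(msg, "'nExperiments' must be a positive integer")
  if (!object@agentB %in% c("drug", "radiation"))
    msg <- c(msg, "'agentB' must be \"drug\" or \"radiation\"")
  if (!is.finite(object@controlSignal) || object@controlSignal <= 0)
    msg <- c(msg, "'controlSignal' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param drugAViability,drugBViability,interactionFactor,noiseCv,nReplicateWells,nExperiments,seed,agentB,drugAConc,drugBConc,doseGy,controlSignal,solvent
#'   see the corresponding slots.
#' @return A validated `PlateSimSpec`.
#' @rdname PlateSimSpec-class
#' @examples
#' spec <- plateSimSpec(interactionFactor = 1, noiseCv = 0, seed = 1L)
#' @export
plateSimSpec <- function(drugAViability = 0.5, drugBViability = 0.95,
                         interactionFactor = 1, noiseCv = 0.1,
                         nReplicateWells = 4L, nExperiments = 3L,
                         seed = 1L, agentB = c("drug", "radiation"),
                         drugAConc = 2, drugBConc = 20, doseGy = 4,
                         controlSignal = 1e5, solvent = "DMSO") {
  new("PlateSimSpec",
      drugAViability = drugAViability, drugBViability = drugBViability,
      interactionFactor = interactionFactor, noiseCv = noiseCv,
      nReplicateWells = as.integer(nReplicateWells),
      nExperiments = as.integer(nExperiments), seed = as.integer(seed),
      agentB = match.arg(agentB), drugAConc = drugAConc,
      drugBConc = drugBConc, doseGy = doseGy,
      controlSignal = controlSignal, solvent = solvent)
}

#' Specification of a simulated clonogenic well image
#'
#' Disk-shaped colonies of known radius and intensity are drawn on a smooth
#' background gradient with additive Gaussian noise, emulating a 4x composite
#' of a clonogenic-assay well.  The ground truth (area, circularity = 1 for
#' disks, overlap flags) travels with the image.
#'
#' @slot imageShape integer (rows, cols) in pixels.
#' @slot pixelSize physical pixel size in micrometres per pixel.
#' @slot colonies data.frame with columns `center_row`, `center_col`
#'   (pixels), `radius_um` and `intensity`.
#' @slot backgroundGradient amplitude of the linear background ramp
#'   (intensity units across the image).
#' @slot noiseSd standard deviation of the additive Gaussian noise.
#' @slot baseline constant background offset.
#' @slot seed integer RNG seed.
#' @export
setClass("ColonyImageSpec",
  representation(imageShape = "integer", pixelSize = "numeric",
                 colonies = "data.frame", backgroundGradient = "numeric",
                 noiseSd = "numeric", baseline = "numeric", seed = "integer"))

setValidity("ColonyImageSpec", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "'imageShape' must be two integers >= 8")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be > 0")
  cc <- object@colonies
  need <- c("center_row", "center_col", "radius_um", "intensity")
  if (!all(need %in% names(cc))) {
    msg <- c(msg, sprintf("'colonies' must have columns %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(cc)) {
    if (any(cc$radius_um <= 0)) msg <- c(msg, "colony radii must be > 0")
    if (any(cc$center_row < 1 | cc$center_row > object@imageShape[1] |
            cc$center_col < 1 | cc$center_col > object@imageShape[2]))
      msg <- c(msg, "colony centers must lie inside the image")
  }
  if (!is.finite(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "'noiseSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param imageShape,pixelSize,colonies,backgroundGradient,noiseSd,baseline,seed
#'   see the corresponding slots.
#' @return A validated `ColonyImageSpec`.
#' @rdname ColonyImageSpec-class
#' @export
colonyImageSpec <- function(imageShape = c(200L, 200L), pixelSize = 5,
                            colonies = data.frame(center_row = numeric(),
                                                  center_col = numeric(),
                                                  radius_um = numeric(),
                                                  intensity = numeric()),
                            backgroundGradient = 500, noiseSd = 0,
                            baseline = 1000, seed = 1L) {
  new("ColonyImageSpec", imageShape = as.integer(imageShape),
      pixelSize = pixelSize, colonies = as.data.frame(colonies),
      backgroundGradient = backgroundGradient, noiseSd = noiseSd,
      baseline = baseline, seed = as.integer(seed))
}

#' Specification of a simulated DNA-content sample
#'
#' Events are drawn from a four-component mixture: a sub-G1 component strictly
#' below the G1 (2N) mode, Gaussian G1 and G2/M peaks (G2/M centred at twice
#' the G1 mode) and a uniform S-phase bridge between them.
#'
#' @slot nEvents number of events (>= 100; landmark detection is undefined at
#'   tiny n).
#' @slot fractions numeric length 4 `(subG1, G1, S, G2M)`, nonnegative,
#'   summing to 1 within 1e-9.
#' @slot g1Mode intensity position of the 2N peak (> 0).
#' @slot cv peak coefficient of variation (width as fraction of the mode).
#' @slot seed integer RNG seed.
#' @export
setClass("DnaContentSpec",
  representation(nEvents = "integer", fractions = "numeric",
                 g1Mode = "numeric", cv = "numeric", seed = "integer"))

setValidity("DnaContentSpec", function(object) {
  msg <- character()
  f <- object@fractions
  if (length(f) != 4L || any(f < 0))
    msg <- c(msg, "'fractions' must be 4 nonnegative values (subG1, G1, S, G2M)")
  else if (abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "'fractions' must sum to 1 within 1e-9")
  if (!is.finite(object@g1Mode) || object@g1Mode <= 0)
    msg <- c(msg, "'g1Mode' must be > 0")
  if (!is.finite(object@cv) || object@cv <= 0 || object@cv > 0.2)
    msg <- c(msg, "'cv' must be in (0, 0.2]")
  if (length(msg)) msg else TRUE
})

#' @param nEvents,fractions,g1Mode,cv,seed see the corresponding slots.
#' @return A validated `DnaContentSpec`.
#' @rdname DnaContentSpec-class
#' @export
dnaContentSpec <- function(nEvents = 10000L,
                           fractions = c(0.05, 0.60, 0.10, 0.25),
                           g1Mode = 200, cv = 0.05, seed = 1L) {
  new("DnaContentSpec", nEvents = as.integer(nEvents),
      fractions = as.numeric(fractions), g1Mode = g1Mode, cv = cv,
      seed = as.integer(seed))
}

#' Specification of a simulated RNA-seq count matrix
#'
#' Negative-binomial counts for two groups (radiosensitive vs radioresistant)
#' with per-gene baseline means, per-sample library-size factors, and planted
#' gene sets whose members are shifted by a stated log2 effect in the
#' radioresistant group. Decoy sets with no effect are generated alongside.
#'
#' @slot nGenes,nSamplesPerGroup integers; genes and samples per group.
#' @slot dispersion negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @slot baselineMean mean count of a typical gene at library factor 1.
#' @slot plantedSets list of `list(id =, genes =, log2Effect =)` entries;
#'   member genes must exist and effects must be finite.
#' @slot librarySizeFactors per-sample positive multipliers of expected
#'   counts (recycled to `2 * nSamplesPerGroup`).
#' @slot nDecoySets,decoySetSize decoy gene sets (log2 effect 0) written to
#'   the GMT alongside planted sets.
#' @slot seed integer RNG seed.
#' @export
setClass("CountsSimSpec",
  representation(nGenes = "integer", nSamplesPerGroup = "integer",
                 dispersion = "numeric", baselineMean = "numeric",
                 plantedSets = "list", librarySizeFactors = "numeric",
                 nDecoySets = "integer", decoySetSize = "integer",
                 seed = "integer"))

setValidity("CountsSimSpec", function(object) {
  msg <- character()
  if (object@nGenes < 10L) msg <- c(msg, "'nGenes' must be >= 10")
  if (object@nSamplesPerGroup < 2L)
    msg <- c(msg, "'nSamplesPerGroup' must be >= 2")
  if (!is.finite(object@dispersion) || object@dispersion <= 0)
    msg <- c(msg, "'dispersion' must be > 0")
  if (!is.finite(object@baselineMean) || object@baselineMean <= 0)
    msg <- c(msg, "'baselineMean' must be > 0")
  ids <- geneIdsFor(object@nGenes)
  for (ps in object@plantedSets) {
    if (!all(c("id", "genes", "log2Effect") %in% names(ps))) {
      msg <- c(msg, "each planted set needs 'id', 'genes', 'log2Effect'")
      next
    }
    if (!all(is.finite(ps$log2Effect)))
      msg <- c(msg, sprintf("planted set '%s': effect size must be finite", ps$id))
    if (!all(ps$genes %in% ids))
      msg <- c(msg, sprintf("planted set '%s' references unknown gene ids", ps$id))
  }
  if (any(!is.finite(object@librarySizeFactors) |
          object@librarySizeFactors <= 0))
    msg <- c(msg, "'librarySizeFactors' must be positive")
  if (length(msg)) msg else TRUE
})

## canonical simulated gene identifiers
geneIdsFor <- function(n) sprintf("gene%04d", seq_len(n))

#' @param nGenes,nSamplesPerGroup,dispersion,baselineMean,plantedSets,librarySizeFactors,nDecoySets,decoySetSize,seed
#'   see the corresponding slots.
#' @return A validated `CountsSimSpec`.
#' @rdname CountsSimSpec-class
#' @export
countsSimSpec <- function(nGenes = 1000L, nSamplesPerGroup = 3L,
                          dispersion = 0.1, baselineMean = 100,
                          plantedSets = list(), librarySizeFactors = 1,
                          nDecoySets = 20L, decoySetSize = 50L, seed = 1L) {
  new("CountsSimSpec", nGenes = as.integer(nGenes),
      nSamplesPerGroup = as.integer(nSamplesPerGroup),
      dispersion = dispersion, baselineMean = baselineMean,
      plantedSets = plantedSets,
      librarySizeFactors = rep_len(librarySizeFactors,
                                   2L * as.integer(nSamplesPerGroup)),
      nDecoySets = as.integer(nDecoySets),
      decoySetSize = as.integer(decoySetSize), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Result containers
## ---------------------------------------------------------------------------

#' Normalized plate viabilities
#'
#' Per-well viability fractions (raw signal divided by the mean of matched
#' control wells on the same plate, experiment and solvent) together with a
#' per-condition summary.  Control wells average exactly 1 per plate;
#' viabilities above 1 are retained (wells can outgrow controls).
#'
#' @slot wells data.frame of well records plus a `viability` column.
#' @slot conditions per-condition summary: treatment labels, mean viability,
#'   `n_wells`, `experiment_id`.
#' @slot controlDescription human-readable description of the control
#'   selector used.
#' @export
setClass("ViabilityTable",
  representation(wells = "data.frame", conditions = "data.frame",
                 controlDescription = "character"))

setValidity("ViabilityTable", function(object) {
  msg <- character()
  if (!"viability" %in% names(object@wells))
    msg <- c(msg, "'wells' must contain a 'viability' column")
  else if (any(object@wells$viability < 0))
    msg <- c(msg, "viabilities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Bliss synergy result for one drug/drug or drug/radiation combination
#'
#' Stores single-agent and combination viabilities per independent experiment,
#' the Bliss-expected viability (the product of single-agent viabilities), the
#' per-experiment synergy scores (expected / observed), the aggregate score
#' (median with min--max range) and the combination-level classification.
#'
#' @slot combination text label, e.g. `"drugA:2uM + drugB:20uM"`.
#' @slot yA,yB,yObserved,yExpected per-experiment viability fractions.
#' @slot perExperimentScores per-experiment synergy scores.
#' @slot score median score across experiments.
#' @slot scoreRange `(min, max)` of the per-experiment scores.
#' @slot experimentLabels per-experiment classification.
#' @slot label combination-level classification (replication rule).
#' @slot nExperiments number of independent experiments.
#' @slot floored logical per experiment; TRUE where the observed viability
#'   was floored before division.
#' @export
setClass("SynergyResult",
  representation(combination = "character", yA = "numeric", yB = "numeric",
                 yObserved = "numeric", yExpected = "numeric",
                 perExperimentScores = "numeric", score = "numeric",
                 scoreRange = "numeric", experimentLabels = "character",
                 label = "character", nExperiments = "integer",
                 floored = "logical"))

setValidity("SynergyResult", function(object) {
  msg <- character()
  if (any(abs(object@yExpected - object@yA * object@yB) > 1e-12))
    msg <- c(msg, "yExpected must equal yA * yB within 1e-12")
  if (any(object@perExperimentScores <= 0))
    msg <- c(msg, "synergy scores must be > 0")
  if (length(msg)) msg else TRUE
})

#' Colony detection result
#'
#' All connected objects found in a well image, with physical-unit features
#' and a `kept` flag implementing the area (>= 5000 um^2 by default) and
#' circularity (>= 0.5 by default) filters; the colony count is the number of
#' kept objects.
#'
#' @slot features data.frame with columns `label`, `area_um2`,
#'   `perimeter_um`, `circularity`, `centroid_row`, `centroid_col`, `kept`.
#' @slot count number of kept colonies.
#' @slot pixelSize micrometres per pixel.
#' @slot params the detection parameter list used (see [colonyParams()]).
#' @export
setClass("ColonyDetection",
  representation(features = "data.frame", count = "integer",
                 pixelSize = "numeric", params = "list"))

setValidity("ColonyDetection", function(object) {
  msg <- character()
  ft <- object@features
  if (nrow(ft)) {
    if (any(ft$area_um2 <= 0)) msg <- c(msg, "areas must be > 0")
    if (any(ft$circularity <= 0 | ft$circularity > 1.1))
      msg <- c(msg, "circularity must lie in (0, 1.1]")
    keep <- ft$area_um2 >= object@params$minAreaUm2 &
      ft$circularity >= object@params$minCircularity
    if (!identical(as.logical(keep), as.logical(ft$kept)))
      msg <- c(msg, "'kept' must equal (area >= minArea & circularity >= minCircularity)")
  }
  if (object@count != sum(ft$kept))
    msg <- c(msg, "'count' must equal the number of kept objects")
  if (length(msg)) msg else TRUE
})

#' Analyzed DNA-content sample
#'
#' Event intensities with detected 2N / 4N landmarks, the sub-G1 gate
#' (gateFactor x 2N mode) and the resulting sub-G1 fraction.
#'
#' @slot events numeric DNA intensities (pre-gated singlet events).
#' @slot g1Mode,g2mMode detected 2N and 4N peak positions.
#' @slot subg1Gate upper intensity bound of the sub-G1 gate.
#' @slot subg1Fraction fraction of events below the gate.
#' @slot condition treatment label, e.g. `"0Gy"` / `"5Gy"`.
#' @slot organoidId sample identifier.
#' @export
setClass("DNAContentSample",
  representation(events = "numeric", g1Mode = "numeric", g2mMode = "numeric",
                 subg1Gate = "numeric", subg1Fraction = "numeric",
                 condition = "character", organoidId = "character"))

setValidity("DNAContentSample", function(object) {
  msg <- character()
  if (!(object@subg1Gate > 0 && object@subg1Gate < object@g1Mode &&
        object@g1Mode < object@g2mMode))
    msg <- c(msg, "must satisfy 0 < subg1Gate < g1Mode < g2mMode")
  ratio <- object@g2mMode / object@g1Mode
  if (ratio < 1.7 || ratio > 2.3)
    msg <- c(msg, "g2mMode / g1Mode must lie in [1.7, 2.3]")
  if (object@subg1Fraction < 0 || object@subg1Fraction > 1)
    msg <- c(msg, "subg1Fraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Clonogenic survival curve
#'
#' Per-dose colony counts converted to surviving fractions: the plating
#' efficiency is colonies / cells plated in the unirradiated condition, and
#' SF(d) = (colonies(d) / cells plated(d)) / plating efficiency, so SF(0) = 1.
#'
#' @slot doses radiation doses in Gy.
#' @slot cellsPlated,colonyCounts per-dose inputs.
#' @slot platingEfficiency colonies per cell plated at 0 Gy.
#' @slot survivingFraction per-dose surviving fractions.
#' @slot fit optional linear-quadratic fit (list with `alpha`, `beta`), or
#'   empty list.
#' @export
setClass("ClonogenicCurve",
  representation(doses = "numeric", cellsPlated = "numeric",
                 colonyCounts = "numeric", platingEfficiency = "numeric",
                 survivingFraction = "numeric", fit = "list"))

setValidity("ClonogenicCurve", function(object) {
  msg <- character()
  if (any(object@survivingFraction < 0))
    msg <- c(msg, "surviving fractions must be >= 0")
  i0 <- which(object@doses == 0)
  if (length(i0) && any(abs(object@survivingFraction[i0] - 1) > 1e-12))
    msg <- c(msg, "surviving fraction at 0 Gy must equal 1")
  if (length(msg)) msg else TRUE
})
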