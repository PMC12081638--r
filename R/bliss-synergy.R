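## Bliss-independence synergy scoring and classification.
##
## Under Bliss independence the expected viability of a combination is the
## product of the single-agent viabilities, Y_A * Y_B = Y_AB(E). The synergy
## score is Y_AB(E) / Y_AB(O): a score of 2 means the combination left half
## as many viable cells as expected. Per-experiment scores in [2, 5] are
## "synergistic", above 5 "strongly synergistic"; a combination is called
## synergistic only when a strict majority of independent experiments
## (2 of 3 in a triplicate design) score above 2.

synergyLevels <- c("not synergistic", "synergistic", "strongly synergistic")

#' Bliss-expected combination viability
#'
#' @param yA,yB single-agent viability fractions (>= 0; vectorized).
#' @return `yA * yB`, the expected combination viability under independence.
#' @examples
#' blissExpected(0.8, 0.5)  # 0.4
#' @export
blissExpected <- function(yA, yB) {
  if (any(!is.finite(yA)) || any(!is.finite(yB)) || any(yA < 0) || any(yB < 0))
    fail("single-agent viabilities must be finite and >= 0")
  yA * yB
}

#' Bliss synergy score
#'
#' Expected viability divided by observed viability. Observed viabilities at
#' or below `floor` (default 1e-4) are floored before division so that
#' near-complete kill yields a finite score; flooring emits a warning and is
#' flagged in the `"floored"` attribute.
#'
#' @param yExpected Bliss-expected viability (>= 0).
#' @param yObserved observed combination viability.
#' @param floor positive lower bound applied to `yObserved`.
#' @return Numeric score(s) with logical attribute `"floored"`.
#' @examples
#' synergyScore(0.40, 0.20)  # 2: twice the expected kill
#' @export
synergyScore <- function(yExpected, yObserved, floor = 1e-4) {
  if (any(!is.finite(yExpected)) || any(yExpected < 0))
    fail("'yExpected' must be finite and >= 0")
  if (any(!is.finite(yObserved))) fail("'yObserved' must be finite")
  floored <- yObserved < floor
  if (any(floored)) {
    warning(sprintf("%d observed viability value(s) below %g were floored",
                    sum(floored), floor))
    yObserved <- pmax(yObserved, floor)
  }
  structure(yExpected / yObserved, floored = floored)
}

#' Classify a per-experiment synergy score
#'
#' Scores below 2 are "not synergistic", scores in \[2, 5\] "synergistic"
#' and scores above 5 "strongly synergistic".
#'
#' @param score finite synergy score(s).
#' @return Character vector of labels.
#' @examples
#' classifyExperiment(c(1.99, 3, 6))
#' @export
classifyExperiment <- function(score) {
  if (any(!is.finite(score))) fail("synergy scores must be finite")
  ifelse(score > 5, synergyLevels[3],
         ifelse(score >= 2, synergyLevels[2], synergyLevels[1]))
}

#' Classify a combination from replicated experiments
#'
#' The combination is called synergistic only when scores strictly above 2
#' occur in a strict majority of experiments: at least `ceiling((n + 1) / 2)`
#' of `n`, which reduces to 2-of-3 for a triplicate design. It is promoted to
#' strongly synergistic when that rule passes and the median score exceeds 5.
#'
#' @param scores per-experiment synergy scores (>= 1 value).
#' @return A list with `label`, `nQualifying` (scores > 2), `nExperiments`,
#'   `median` and `range` (min, max).
#' @examples
#' classifyCombination(c(2.5, 3.1, 1.8))$label  # "synergistic"
#' @export
classifyCombination <- function(scores) {
  if (length(scores) == 0) fail("at least one synergy score is required")
  if (any(!is.finite(scores))) fail("synergy scores must be finite")
  n <- length(scores)
  q <- sum(scores > 2)
  med <- median(scores)
  label <- if (q >= ceiling((n + 1) / 2)) {
    if (med > 5) synergyLevels[3] else synergyLevels[2]
  } else synergyLevels[1]
  list(label = label, nQualifying = q, nExperiments = n, median = med,
       range = c(min(scores), max(scores)))
}

## Assemble a SynergyResult from per-experiment viabilities.
makeSynergyResult <- function(combination, yA, yB, yObserved, experiments,
                              floor = 1e-4) {
  yE <- blissExpected(yA, yB)
  sc <- suppressWarnings(synergyScore(yE, yObserved, floor = floor))
  floored <- attr(sc, "floored")
  sc <- as.numeric(sc)
  agg <- classifyCombination(sc)
  new("SynergyResult", combination = combination, yA = yA, yB = yB,
      yObserved = yObserved, yExpected = yE,
      perExperimentScores = setNames(sc, experiments),
      score = agg$median, scoreRange = agg$range,
      experimentLabels = classifyExperiment(sc), label = agg$label,
      nExperiments = length(sc), floored = floored)
}

## Look up the per-experiment mean viability of one condition; error names
## the missing condition.
lookupCondition <- function(conds, a, b, d, what) {
  sel <- conds$drug_a_conc_uM == a & conds$drug_b_conc_uM == b &
    conds$dose_Gy == d
  if (!any(sel))
    fail("missing %s condition (drug A %g uM, drug B %g uM, %g Gy)",
         what, a, b, d)
  setNames(conds$mean_viability[sel], conds$experiment_id[sel])
}

## Shared core for drug x drug and drug x radiation synergy extraction.
comboSynergyCore <- function(vt, radiation, floor) {
  stopifnot(is(vt, "ViabilityTable"))
  conds <- conditionSummary(vt)
  bcol <- if (radiation) "dose_Gy" else "drug_b_conc_uM"
  combos <- unique(conds[conds$drug_a_conc_uM > 0 & conds[[bcol]] > 0,
                         c("drug_a_conc_uM", bcol)])
  if (nrow(combos) == 0)
    fail("no combination conditions (drug A together with %s) found",
         if (radiation) "radiation" else "drug B")
  out <- list()
  for (k in seq_len(nrow(combos))) {
    a <- combos$drug_a_conc_uM[k]
    b <- combos[[bcol]][k]
    if (radiation) {
      yA <- lookupCondition(conds, a, 0, 0, "drug-A monotherapy")
      yB <- lookupCondition(conds, 0, 0, b, "radiation-alone")
      yO <- lookupCondition(conds, a, 0, b, "combination")
      lab <- sprintf("drugA:%guM + radiation:%gGy", a, b)
    } else {
      yA <- lookupCondition(conds, a, 0, 0, "drug-A monotherapy")
      yB <- lookupCondition(conds, 0, b, 0, "drug-B monotherapy")
      yO <- lookupCondition(conds, a, b, 0, "combination")
      lab <- sprintf("drugA:%guM + drugB:%guM", a, b)
    }
    exps <- Reduce(intersect, list(names(yA), names(yB), names(yO)))
    if (length(exps) == 0)
      fail("no experiment has all conditions for %s", lab)
    out[[lab]] <- makeSynergyResult(lab, unname(yA[exps]), unname(yB[exps]),
                                    unname(yO[exps]), exps, floor = floor)
  }
  out
}

#' Bliss synergy of a drug-drug combination screen
#'
#' For every (drug A dose, drug B dose) combination present in the viability
#' table, looks up the per-experiment monotherapy and combination
#' viabilities, computes Bliss-expected viabilities and synergy scores, and
#' applies the per-experiment and replication-rule classifications.
#'
#' @param vt a [ViabilityTable-class] object.
#' @param floor observed-viability floor passed to [synergyScore()].
#' @return A named list of [SynergyResult-class] objects, one per
#'   combination.
#' @examples
#' plate <- simulatePlate(plateSimSpec(interactionFactor = 3, noiseCv = 0,
#'                                     seed = 2L))
#' res <- combinationSynergy(normalizeViability(plate))
#' res[[1]]
#' @export
combinationSynergy <- function(vt, floor = 1e-4) {
  comboSynergyCore(vt, radiation = FALSE, floor = floor)
}

#' Bliss synergy of drug x radiation combinations
#'
#' Treats the radiation dose as agent B: the expected viability of (drug dose
#' a, dose d Gy) is the product of the drug-alone viability at 0 Gy and the
#' radiation-alone viability at d Gy, each normalized to the untreated 0 uM /
#' 0 Gy control.
#'
#' @inheritParams combinationSynergy
#' @return A named list of [SynergyResult-class] objects, one per
#'   (drug dose, Gy) pair.
#' @export
radiationComboBliss <- function(vt, floor = 1e-4) {
  comboSynergyCore(vt, radiation = TRUE, floor = floor)
}

#' @describeIn SynergyResult-class per-experiment synergy scores.
#' @param x,object a `SynergyResult`.
#' @export
synergyScores <- function(x) {
  stopifnot(is(x, "SynergyResult"))
  x@perExperimentScores
}

#' @describeIn SynergyResult-class combination-level classification label.
#' @export
synergyLabel <- function(x) {
  stopifnot(is(x, "SynergyResult"))
  x@label
}

#' @describeIn SynergyResult-class display in the "median \[max-min\]" style
#'   used for replicated screens.
#' @export
setMethod("show", "SynergyResult", function(object) {
  cat(sprintf("SynergyResult: %s\n", object@combination))
  cat(sprintf("  synergy score %.3g [%.3g-%.3g] over %d experiment(s)\n",
              object@score, object@scoreRange[2], object@scoreRange[1],
              object@nExperiments))
  cat(sprintf("  classification: %s (%d/%d experiments with score > 2)\n",
              object@label, sum(object@perExperimentScores > 2),
              object@nExperiments))
  if (any(object@floored))
    cat("  note: observed viability floored in",
        sum(object@floored), "experiment(s)\n")
})

#' Tidy per-experiment synergy table
#'
#' @param results a list of [SynergyResult-class] objects (or a single one).
#' @return A data.frame with one row per combination per experiment.
#' @export
synergyTable <- function(results) {
  if (is(results, "SynergyResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(combination = r@combination,
               experiment_id = names(r@perExperimentScores),
               y_a = r@yA, y_b = r@yB, y_expected = r@yExpected,
               y_observed = r@yObserved, score = unname(r@perExperimentScores),
               experiment_label = r@experimentLabels,
               combination_label = r@label, floored = r@floored,
               row.names = NULL)
  }))
}
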