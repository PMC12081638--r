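## Synthetic-data generators. Every generator takes a validated spec object
## carrying its own seed and runs in an isolated RNG stream, so repeated calls
## with the same spec are bit-identical and never disturb the caller's RNG.

#' Simulate a combination-screen viability plate
#'
#' Emits one plate per experiment with solvent-only control wells,
#' monotherapy wells for agents A and B, and combination wells. The true
#' combination viability before noise is
#' `drugAViability * drugBViability / interactionFactor`, so a downstream
#' Bliss analysis recovers `interactionFactor` as the synergy score (exactly,
#' when `noiseCv = 0`). Raw signals are the true viability times the control
#' luminescence times multiplicative log-normal noise.
#'
#' @param spec a [PlateSimSpec-class] object.
#' @return A data.frame with columns `plate_id`, `well`, `drug_a_conc_uM`,
#'   `drug_b_conc_uM`, `dose_Gy`, `solvent`, `raw_signal`, `experiment_id`,
#'   `condition`, plus a `"groundTruth"` attribute recording the true
#'   viabilities and the planted interaction factor.
#' @examples
#' plate <- simulatePlate(plateSimSpec(interactionFactor = 3, seed = 7L))
#' head(plate)
#' @export
simulatePlate <- function(spec) {
  stopifnot(is(spec, "PlateSimSpec"))
  validObject(spec)
  yA <- spec@drugAViability
  yB <- spec@drugBViability
  yAB <- yA * yB / spec@interactionFactor
  trueViab <- c(control = 1, monoA = yA, monoB = yB, combo = yAB)
  radiation <- spec@agentB == "radiation"

  perExp <- function(e) {
    nw <- spec@nReplicateWells
    cond <- rep(names(trueViab), each = nw)
    viab <- rep(unname(trueViab), each = nw)
    n <- length(viab)
    raw <- viab * spec@controlSignal * lognormalNoise(n, spec@noiseCv)
    aConc <- ifelse(cond %in% c("monoA", "combo"), spec@drugAConc, 0)
    if (radiation) {
      bConc <- rep(0, n)
      dose <- ifelse(cond %in% c("monoB", "combo"), spec@doseGy, 0)
    } else {
      bConc <- ifelse(cond %in% c("monoB", "combo"), spec@drugBConc, 0)
      dose <- rep(0, n)
    }
    data.frame(plate_id = sprintf("plate%02d", e),
               well = wellAddresses(n),
               drug_a_conc_uM = aConc, drug_b_conc_uM = bConc,
               dose_Gy = dose, solvent = spec@solvent, raw_signal = raw,
               experiment_id = sprintf("exp%02d", e), condition = cond,
               stringsAsFactors = FALSE)
  }

  wells <- withSeed(spec@seed,
                    do.call(rbind, lapply(seq_len(spec@nExperiments), perExp)))
  rownames(wells) <- NULL
  attr(wells, "groundTruth") <- list(
    trueViability = trueViab, interactionFactor = spec@interactionFactor,
    agentB = spec@agentB)
  wells
}

#' Write / read the plate CSV dialect
#'
#' @param wells a plate data.frame as returned by [simulatePlate()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePlateCsv <- function(wells, path) {
  write.csv(wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a clonogenic well image
#'
#' Draws disk-shaped colonies on a linear background ramp, adds Gaussian
#' noise, and rounds to integer grey levels (16-bit range). Ground truth
#' lists each colony's analytic area (`pi * r^2`, in um^2), circularity 1,
#' and a flag marking colonies that overlap another colony.
#'
#' @param spec a [ColonyImageSpec-class] object.
#' @return A list with elements `image` (numeric matrix) and `truth`
#'   (data.frame with `center_row`, `center_col`, `radius_um`, `area_um2`,
#'   `circularity`, `overlaps`).
#' @examples
#' spec <- randomColonySpec(nColonies = 5, seed = 3L)
#' img <- simulateColonyImage(spec)
#' dim(img$image)
#' @export
simulateColonyImage <- function(spec) {
  stopifnot(is(spec, "ColonyImageSpec"))
  validObject(spec)
  nr <- spec@imageShape[1]; nc <- spec@imageShape[2]
  rowc <- matrix(seq_len(nr), nr, nc)
  colc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img <- spec@baseline +
    spec@backgroundGradient * ((rowc - 1) / (nr - 1) + (colc - 1) / (nc - 1)) / 2
  cc <- spec@colonies
  if (nrow(cc)) {
    rpx <- cc$radius_um / spec@pixelSize
    for (k in seq_len(nrow(cc))) {
      d2 <- (rowc - cc$center_row[k])^2 + (colc - cc$center_col[k])^2
      img <- img + cc$intensity[k] * (d2 <= rpx[k]^2)
    }
  }
  img <- withSeed(spec@seed, {
    if (spec@noiseSd > 0)
      img <- img + matrix(rnorm(nr * nc, sd = spec@noiseSd), nr, nc)
    img
  })
  img <- round(pmax(img, 0))
  overlaps <- rep(FALSE, nrow(cc))
  if (nrow(cc) > 1) {
    rpx <- cc$radius_um / spec@pixelSize
    for (i in seq_len(nrow(cc) - 1)) for (j in (i + 1):nrow(cc)) {
      d <- sqrt((cc$center_row[i] - cc$center_row[j])^2 +
                (cc$center_col[i] - cc$center_col[j])^2)
      if (d < rpx[i] + rpx[j]) overlaps[c(i, j)] <- TRUE
    }
  }
  truth <- data.frame(center_row = cc$center_row, center_col = cc$center_col,
                      radius_um = cc$radius_um,
                      area_um2 = pi * cc$radius_um^2,
                      circularity = rep(1, nrow(cc)), overlaps = overlaps)
  list(image = img, truth = truth)
}

#' Random non-overlapping colony layout
#'
#' Convenience builder for [colonyImageSpec()]: places `nColonies` disks with
#' radii drawn uniformly from `radiusRangeUm`, rejected until pairwise
#' disjoint and clear of the border.
#'
#' @param nColonies number of colonies.
#' @param seed RNG seed (also used for the image noise).
#' @param imageShape,pixelSize,noiseSd,backgroundGradient passed through to
#'   [colonyImageSpec()].
#' @param radiusRangeUm colony radius range in micrometres.
#' @param intensity colony contrast over background.
#' @return A [ColonyImageSpec-class] object.
#' @export
randomColonySpec <- function(nColonies, seed, imageShape = c(200L, 200L),
                             pixelSize = 5, radiusRangeUm = c(50, 100),
                             intensity = 8000, noiseSd = 0,
                             backgroundGradient = 500) {
  cc <- withSeed(seed, {
    placed <- data.frame(center_row = numeric(), center_col = numeric(),
                         radius_um = numeric(), intensity = numeric())
    tries <- 0L
    while (nrow(placed) < nColonies && tries < 5000L) {
      tries <- tries + 1L
      r <- runif(1, radiusRangeUm[1], radiusRangeUm[2])
      rpx <- r / pixelSize
      cr <- runif(1, rpx + 3, imageShape[1] - rpx - 3)
      cl <- runif(1, rpx + 3, imageShape[2] - rpx - 3)
      ok <- TRUE
      if (nrow(placed)) {
        d <- sqrt((placed$center_row - cr)^2 + (placed$center_col - cl)^2)
        ok <- all(d > placed$radius_um / pixelSize + rpx + 4)
      }
      if (ok)
        placed <- rbind(placed, data.frame(center_row = cr, center_col = cl,
                                           radius_um = r,
                                           intensity = intensity))
    }
    if (nrow(placed) < nColonies)
      fail("could not place %d disjoint colonies; enlarge the image", nColonies)
    placed
  })
  colonyImageSpec(imageShape = imageShape, pixelSize = pixelSize,
                  colonies = cc, backgroundGradient = backgroundGradient,
                  noiseSd = noiseSd, seed = seed)
}

#' Simulate a DNA-content event list
#'
#' Events are drawn from a mixture of four components: sub-G1 (uniform on
#' `(0.05, 0.75) * g1Mode`, strictly below the 2N peak), G1 (normal at
#' `g1Mode`), S (uniform between the 2N and 4N positions) and G2/M (normal at
#' `2 * g1Mode`). Ground-truth fractions are attached as an attribute.
#'
#' @param spec a [DnaContentSpec-class] object.
#' @return Numeric vector of per-event intensities with attribute
#'   `"groundTruth"` (the component fractions).
#' @examples
#' ev <- simulateDnaContent(dnaContentSpec(fractions = c(0.1, 0.6, 0.1, 0.2)))
#' mean(ev < 0.8 * 200)
#' @export
simulateDnaContent <- function(spec) {
  stopifnot(is(spec, "DnaContentSpec"))
  validObject(spec)
  if (spec@nEvents < 100L)
    fail("'nEvents' must be >= 100 (landmark detection undefined at tiny n)")
  g1 <- spec@g1Mode
  ev <- withSeed(spec@seed, {
    comp <- sample.int(4L, spec@nEvents, replace = TRUE, prob = spec@fractions)
    x <- numeric(spec@nEvents)
    n1 <- sum(comp == 1L); n2 <- sum(comp == 2L)
    n3 <- sum(comp == 3L); n4 <- sum(comp == 4L)
    if (n1) x[comp == 1L] <- runif(n1, 0.05 * g1, 0.75 * g1)
    if (n2) x[comp == 2L] <- rnorm(n2, g1, spec@cv * g1)
    if (n3) x[comp == 3L] <- runif(n3, g1, 2 * g1)
    if (n4) x[comp == 4L] <- rnorm(n4, 2 * g1, spec@cv * 2 * g1)
    pmax(x, 1e-6 * g1)
  })
  attr(ev, "groundTruth") <- list(fractions = spec@fractions,
                                  g1Mode = g1)
  ev
}

#' Simulate a two-group RNA-seq count matrix with planted gene sets
#'
#' Per-gene baseline means are drawn log-normally around `baselineMean`;
#' counts are negative binomial with the stated dispersion, scaled by the
#' per-sample library-size factors. Genes belonging to planted sets have
#' their mean multiplied by `2^log2Effect` in the radioresistant group.
#' Decoy sets (random members, no effect) are generated alongside so
#' enrichment analyses have a null reference.
#'
#' @param spec a [CountsSimSpec-class] object.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"`, `colData` columns `group` (radiosensitive / radioresistant)
#'   and `replicate`, and metadata entries `geneSets` (named list of member
#'   genes for planted and decoy sets) and `planted` (the planted-set
#'   definitions).
#' @examples
#' sets <- list(list(id = "SET_UP", genes = sprintf("gene%04d", 1:50),
#'                   log2Effect = 2))
#' se <- simulateCounts(countsSimSpec(plantedSets = sets, seed = 11L))
#' SummarizedExperiment::assay(se)[1:3, ]
#' @export
simulateCounts <- function(spec) {
  stopifnot(is(spec, "CountsSimSpec"))
  validObject(spec)
  genes <- geneIdsFor(spec@nGenes)
  if (anyDuplicated(genes)) fail("duplicate gene ids")
  n <- 2L * spec@nSamplesPerGroup
  group <- rep(c("radiosensitive", "radioresistant"),
               each = spec@nSamplesPerGroup)
  res <- withSeed(spec@seed, {
    baseMu <- spec@baselineMean * exp(rnorm(spec@nGenes, sd = 1))
    lfc <- setNames(numeric(spec@nGenes), genes)
    for (ps in spec@plantedSets) lfc[ps$genes] <- lfc[ps$genes] + ps$log2Effect
    mu <- outer(baseMu, spec@librarySizeFactors)
    shifted <- group == "radioresistant"
    mu[, shifted] <- mu[, shifted] * 2^lfc
    counts <- matrix(rnbinom(spec@nGenes * n, mu = mu,
                             size = 1 / spec@dispersion),
                     spec@nGenes, n, dimnames = list(genes, NULL))
    decoys <- lapply(seq_len(spec@nDecoySets), function(k)
      sample(genes, min(spec@decoySetSize, spec@nGenes)))
    names(decoys) <- sprintf("DECOY_%02d", seq_along(decoys))
    list(counts = counts, decoys = decoys, lfc = lfc)
  })
  colnames(res$counts) <- sprintf("%s_rep%d", group,
                                  rep(seq_len(spec@nSamplesPerGroup), 2L))
  sets <- c(setNames(lapply(spec@plantedSets, `[[`, "genes"),
                     vapply(spec@plantedSets, `[[`, "", "id")),
            res$decoys)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = res$counts),
    colData = S4Vectors::DataFrame(
      group = group, replicate = rep(seq_len(spec@nSamplesPerGroup), 2L),
      row.names = colnames(res$counts)))
  S4Vectors::metadata(se)$geneSets <- sets
  S4Vectors::metadata(se)$planted <- spec@plantedSets
  S4Vectors::metadata(se)$trueLog2FC <- res$lfc
  se
}

#' Write a count matrix and its sample sheet as text files
#'
#' @param se a `SummarizedExperiment` from [simulateCounts()] (or any SE with
#'   a `counts` assay and a `group` column).
#' @param countsPath,samplesPath output TSV / CSV paths.
#' @return `countsPath`, invisibly.
#' @export
writeCountsTsv <- function(se, countsPath, samplesPath = NULL) {
  m <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, countsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(samplesPath)) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    write.csv(data.frame(sample_id = rownames(cd), cd), samplesPath,
              row.names = FALSE, quote = FALSE)
  }
  invisible(countsPath)
}

#' Plain-text grayscale image I/O (PGM)
#'
#' Synthetic well images are stored as ASCII portable graymaps (PGM "P2",
#' 16-bit range), a text format readable by any image tool. Intensities are
#' clamped to `[0, 65535]` and rounded on write.
#'
#' @param image numeric matrix.
#' @param path file path.
#' @return `writePgm` returns `path` invisibly; `readPgm` returns a numeric
#'   matrix.
#' @export
writePgm <- function(image, path) {
  img <- pmin(pmax(round(image), 0), 65535)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "65535"), con)
  write(t(img), file = con, ncolumns = ncol(img))
  invisible(path)
}

#' @rdname writePgm
#' @export
readPgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") fail("'%s' is not an ASCII PGM (P2) file", path)
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != nr * nc) fail("'%s': truncated pixel data", path)
  matrix(vals, nr, nc, byrow = TRUE)
}

#' Write a per-event DNA-content CSV
#'
#' @param events numeric intensities.
#' @param path output file.
#' @param condition,organoidId metadata columns repeated per event.
#' @return `path`, invisibly.
#' @export
writeEventsCsv <- function(events, path, condition = NA, organoidId = NA) {
  write.csv(data.frame(intensity = as.numeric(events),
                       condition = condition, organoid_id = organoidId),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
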