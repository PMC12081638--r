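# Synthetic-data generators: seeded determinism, validation, ground-truth
# recovery.

test_that("every generator is seed-deterministic and RNG-isolated", {
  specs <- list(
    plate = function() simulatePlate(plateSimSpec(seed = 42L)),
    image = function() simulateColonyImage(randomColonySpec(3, seed = 42L,
                                                            noiseSd = 30)),
    flow = function() simulateDnaContent(dnaContentSpec(seed = 42L)),
    counts = function() simulateCounts(countsSimSpec(nGenes = 50L,
                                                     seed = 42L)))
  for (gen in specs) {
    set.seed(999)                      # generators must not consume this
    a <- gen()
    before <- .Random.seed
    b <- gen()
    expect_identical(a, b)
    expect_identical(before, .Random.seed)
  }
})

test_that("plate spec validation names the offending field", {
  expect_error(plateSimSpec(drugAViability = 1.2), "drugAViability")
  expect_error(plateSimSpec(interactionFactor = 0), "interactionFactor")
  expect_error(plateSimSpec(noiseCv = -0.1), "noiseCv")
})

test_that("noise-free plates give the planted score exactly downstream", {
  for (sigma in c(1, 3, 113)) {
    plate <- simulatePlate(plateSimSpec(interactionFactor = sigma,
                                        noiseCv = 0, seed = 5L))
    res <- combinationSynergy(normalizeViability(plate))[[1]]
    expect_true(all(abs(synergyScores(res) - sigma) < 1e-9))
  }
})

test_that("the strongly synergistic screen scenario is recovered from noisy plates", {
  # planted interaction 113 with 10% multiplicative noise, 4 wells x 3 exps
  med <- vapply(1:10, function(s) {
    plate <- simulatePlate(plateSimSpec(interactionFactor = 113,
                                        noiseCv = 0.1, nReplicateWells = 4L,
                                        nExperiments = 3L, seed = s))
    combinationSynergy(normalizeViability(plate))[[1]]@score
  }, 0)
  expect_true(all(abs(med - 113) / 113 <= 0.25))
})

test_that("colony image ground truth matches analytic geometry", {
  blank <- simulateColonyImage(colonyImageSpec(seed = 1L))
  expect_equal(nrow(blank$truth), 0)
  expect_equal(dim(blank$image), c(200L, 200L))

  one <- colonyImageSpec(colonies = data.frame(center_row = 100,
                                               center_col = 100,
                                               radius_um = 60,
                                               intensity = 5000),
                         pixelSize = 5, seed = 2L)
  sim <- simulateColonyImage(one)
  expect_equal(sim$truth$area_um2, pi * 60^2)
  expect_equal(sim$truth$circularity, 1)
  expect_false(sim$truth$overlaps)

  # overlapping colonies are allowed but flagged
  two <- colonyImageSpec(colonies = data.frame(
    center_row = c(100, 104), center_col = c(100, 100),
    radius_um = c(60, 60), intensity = 5000), pixelSize = 5, seed = 3L)
  expect_true(all(simulateColonyImage(two)$truth$overlaps))

  expect_error(colonyImageSpec(colonies = data.frame(
    center_row = 500, center_col = 10, radius_um = 10, intensity = 1)),
    "inside the image")
})

test_that("DNA-content fractions are recovered within binomial error", {
  for (f in list(c(0.10, 0.60, 0.10, 0.20), c(0.25, 0.50, 0.10, 0.15))) {
    spec <- dnaContentSpec(nEvents = 10000L, fractions = f, seed = 8L)
    ev <- simulateDnaContent(spec)
    est <- mean(ev < 0.8 * 200)
    se3 <- 3 * sqrt(f[1] * (1 - f[1]) / 10000)
    expect_lt(abs(est - f[1]), se3 + 1e-12)
  }
  # degenerate pure-G1 population concentrates at the mode
  pure <- simulateDnaContent(dnaContentSpec(fractions = c(0, 1, 0, 0),
                                            g1Mode = 200, cv = 0.05,
                                            seed = 9L))
  expect_true(all(abs(pure - 200) < 5 * 0.05 * 200))
  expect_error(simulateDnaContent(dnaContentSpec(nEvents = 50L)), "100")
})

test_that("count simulation plants effects and validates set references", {
  expect_error(countsSimSpec(plantedSets = list(
    list(id = "BAD", genes = "nope", log2Effect = 1))), "unknown gene")

  # equal library factors: TMM factors near 1 (sampling noise shrinks with
  # the number of genes; ~1.5% at 2000 genes)
  se <- simulateCounts(countsSimSpec(nGenes = 2000L, seed = 1L))
  expect_true(all(abs(tmmFactors(se) - 1) < 0.05))

  # null: two groups exchangeable, DE count at FDR 1% near nominal
  fp <- vapply(1:10, function(s) {
    mean(differentialExpression(
      simulateCounts(countsSimSpec(nGenes = 300L, seed = s)))$significant)
  }, 0)
  expect_lte(mean(fp), 0.02)

  # planted 50-gene set, log2 effect 2: enrichment-score difference is
  # positive in the radioresistant group, across seeds
  sets <- list(list(id = "UP", genes = sprintf("gene%04d", 1:50),
                    log2Effect = 2))
  sgn <- vapply(1:20, function(s) {
    se <- simulateCounts(countsSimSpec(nGenes = 300L, plantedSets = sets,
                                       seed = s))
    sc <- enrichmentScores(se, list(UP = sets[[1]]$genes))
    grp <- SummarizedExperiment::colData(se)$group
    mean(sc[1, grp == "radioresistant"]) - mean(sc[1, grp == "radiosensitive"])
  }, 0)
  expect_true(all(sgn > 0))
})

test_that("plate and image text round trips preserve the data", {
  plate <- simulatePlate(plateSimSpec(seed = 3L))
  f <- tempfile(fileext = ".csv")
  writePlateCsv(plate, f)
  back <- readPlate(f)
  expect_equal(back$raw_signal, plate$raw_signal, tolerance = 1e-12)

  img <- simulateColonyImage(randomColonySpec(2, seed = 4L))$image
  p <- tempfile(fileext = ".pgm")
  writePgm(img, p)
  expect_equal(readPgm(p), img)
})
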