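# Transcriptomics layer: TMM, filtering, DE, BH, enrichment, response rate,
# gene-set graph.

test_that("bhAdjust equals the brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), bhOracle(p))
  }
  # adjusted >= raw, order preserved
  p <- runif(50)
  a <- bhAdjust(p)
  expect_true(all(a >= p - 1e-15))
  expect_equal(order(a[order(p)]), seq_along(p))
})

test_that("TMM factors: identity, geometric mean, and the edgeR cross-check", {
  m <- matrix(rep(c(10, 50, 200, 1000, 5), 4), ncol = 4)
  rownames(m) <- sprintf("g%d", 1:5)
  expect_equal(unname(tmmFactors(m)), rep(1, 4))   # identical libraries

  set.seed(7)
  big <- matrix(rnbinom(2000 * 6, mu = outer(rgamma(2000, 2, scale = 50),
                                             c(1, 1, 1, 3, 3, 3)),
                        size = 10), 2000, 6)
  rownames(big) <- sprintf("g%04d", 1:2000)
  f <- tmmFactors(big)
  expect_lt(abs(geomMean(f) - 1), 1e-9)
  # pure library scaling (no composition change) leaves factors at 1
  sc <- cbind(big[, 1], big[, 1] * 5)
  rownames(sc) <- rownames(big)
  expect_equal(unname(tmmFactors(sc)), c(1, 1))

  expect_error(tmmFactors(cbind(g1 = c(0, 0), g2 = c(1, 2))), "all-zero")

  skip_if_not_installed("edgeR")
  for (s in 1:10) {
    set.seed(s)
    mm <- matrix(rnbinom(300 * 4, mu = outer(rgamma(300, 2, scale = 40),
                                             c(1, 2, 0.5, 1.5)), size = 5),
                 300, 4)
    rownames(mm) <- sprintf("g%03d", 1:300)
    ref <- edgeR::calcNormFactors(edgeR::DGEList(mm))$samples$norm.factors
    expect_equal(unname(tmmFactors(mm)), ref, tolerance = 1e-10)
  }
})

test_that("low-expression filtering follows the CPM rule", {
  # libraries of 100 counts: CPM = count * 1e4. Gene rows:
  #   g1: 0 everywhere -> CPM 0, removed
  #   g2: 1 in all 4   -> CPM 1e4, kept
  #   g3: high in 2 samples only -> fails minSamples = 3
  m <- rbind(g1 = c(0, 0, 0, 0), g2 = c(1, 1, 1, 1), g3 = c(40, 40, 0, 0),
             g4 = c(30, 30, 30, 30), g5 = c(29, 29, 69, 59))
  kept <- filterLowExpression(m, minCpm = 100, minSamples = 3)
  expect_setequal(rownames(kept), c("g2", "g4", "g5"))
  expect_equal(rownames(filterLowExpression(m, minCpm = 0, minSamples = 0)),
               rownames(m))
  expect_error(filterLowExpression(m, minCpm = 1e9, minSamples = 4), "all genes")
  expect_error(filterLowExpression(m, minCpm = -1), ">= 0")
})

test_that("differential expression: antisymmetry and error control", {
  se <- simulateCounts(countsSimSpec(nGenes = 200L, seed = 31L))
  counts <- SummarizedExperiment::assay(se)
  g <- SummarizedExperiment::colData(se)$group
  de1 <- differentialExpression(counts, g)
  de2 <- differentialExpression(counts,
                                ifelse(g == "radioresistant",
                                       "radiosensitive", "radioresistant"))
  expect_equal(de1$log2FC, -de2$log2FC, tolerance = 1e-12)
  expect_equal(de1$p, de2$p, tolerance = 1e-12)
  expect_true(all(de1$padj >= de1$p - 1e-15))

  expect_error(differentialExpression(counts, rep(c("a", "b", "c"), 2)),
               "two groups")
  expect_error(differentialExpression(counts[, c(1, 2, 4, 5)],
                                      c("a", "b", "b", "b")), "at least two")

  # permuted-label null: false-positive proportion at FDR 1% stays <= 2%
  fp <- vapply(1:20, function(s) {
    se0 <- simulateCounts(countsSimSpec(nGenes = 300L, seed = 200L + s))
    perm <- withr::with_seed(s, sample(SummarizedExperiment::colData(se0)$group))
    mean(differentialExpression(SummarizedExperiment::assay(se0),
                                perm)$significant)
  }, 0)
  expect_lte(mean(fp), 0.02)
})

test_that("planted effects are recovered at the rate the oracle predicts", {
  # Unmoderated t at n = 3 vs 3 (df = 4) cannot push BH-adjusted p below 1%
  # for moderate effects; the simulation oracle puts raw-p recovery near 60%
  # and the fold-change estimates near the planted value. Those computed
  # values are what is frozen here.
  sets <- list(list(id = "UP", genes = sprintf("gene%04d", 1:50),
                    log2Effect = 2))
  stats <- vapply(1:10, function(s) {
    se <- simulateCounts(countsSimSpec(nGenes = 500L, plantedSets = sets,
                                       dispersion = 0.1, seed = s))
    de <- differentialExpression(se)
    planted <- de$gene %in% sets[[1]]$genes
    c(mean(de$p[planted] < 0.01), mean(de$log2FC[planted]))
  }, c(0, 0))
  expect_gt(mean(stats[1, ]), 0.45)            # raw-p recovery (oracle ~0.61)
  expect_equal(mean(stats[2, ]), 2, tolerance = 0.15)  # effect calibration
})

test_that("enrichment scores behave as a standardized mean rank", {
  se <- simulateCounts(countsSimSpec(nGenes = 400L, seed = 33L))
  lc <- countsPerMillion(SummarizedExperiment::assay(se), log = TRUE)

  # the top-expressed genes of a sample score strictly positive there
  top <- rownames(lc)[order(lc[, 1], decreasing = TRUE)[1:30]]
  expect_gt(enrichmentScores(lc, list(TOP = top))[1, 1], 0)

  # a set and its complement score with opposite signs
  half <- rownames(lc)[1:200]
  sc <- enrichmentScores(lc, list(A = half,
                                  B = setdiff(rownames(lc), half)))
  expect_true(all(sc[1, ] * sc[2, ] < 0))

  # null calibration: random sets have mean ~0, variance ~1
  z <- withr::with_seed(5, replicate(300, {
    enrichmentScores(lc, list(S = sample(rownames(lc), 40)))[1, 1]
  }))
  expect_lt(abs(mean(z)), 0.15)
  expect_equal(var(z), 1, tolerance = 0.25)

  # sets with too few members present are dropped with a warning
  expect_warning(
    expect_error(enrichmentScores(lc, list(GONE = c("x1", "x2", "x3"))),
                 "enough members"),
    "dropping")
  expect_warning(
    sc2 <- enrichmentScores(lc, list(OK = rownames(lc)[1:20],
                                     GONE = c("x1", "x2"))),
    "dropping")
  expect_equal(rownames(sc2), "OK")
})

test_that("differential gene sets flag planted enrichment with direction", {
  sets <- list(list(id = "UP", genes = sprintf("gene%04d", 1:50),
                    log2Effect = 2))
  se <- simulateCounts(countsSimSpec(nGenes = 300L, plantedSets = sets,
                                     seed = 34L))
  sc <- enrichmentScores(se, S4Vectors::metadata(se)$geneSets)
  dgs <- differentialGeneSets(sc, SummarizedExperiment::colData(se)$group)
  up <- dgs[dgs$set == "UP", ]
  expect_true(up$significant)
  expect_equal(up$direction, "up")

  # identical groups: zero mean difference by symmetry
  m <- matrix(rep(c(1, 2, 3), each = 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), NULL))
  dg0 <- differentialGeneSets(m, c("a", "a", "b", "b"))
  expect_equal(dg0$delta, rep(0, 3))
})

test_that("response rate multiplies evidence and effect", {
  expect_equal(responseRate(0.01, 4), 4.0)
  expect_equal(responseRate(0.5, 1), 0.0)
  expect_equal(responseRate(0.001, 0.5), -3.0)
  expect_error(responseRate(0, 2), "infinite")
  expect_error(responseRate(0.01, -1), "> 0")
  # antisymmetric in the fold change
  set.seed(3)
  p <- runif(20, 0.001, 1); f <- exp(rnorm(20))
  expect_equal(responseRate(p, f), -responseRate(p, 1 / f), tolerance = 1e-12)
})

test_that("gene-set graphs encode shared-gene counts", {
  mem <- list(S1 = sprintf("g%d", 1:20), S2 = sprintf("g%d", 11:30),
              S3 = sprintf("g%d", 100:110))
  sig <- data.frame(set = c("S1", "S2", "S3"),
                    direction = c("up", "up", "down"))
  g <- buildGeneSetGraph(sig, mem)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)           # S3 shares nothing
  e <- igraph::as_data_frame(g, "edges")
  expect_equal(e$weight, 10)                    # S1 and S2 share g11..g20
  expect_error(buildGeneSetGraph(data.frame(set = "S9", direction = "up"),
                                 mem), "S9")

  # random collections against the brute-force intersection oracle
  set.seed(9)
  for (rep in 1:20) {
    sets <- lapply(1:6, function(i) sample(sprintf("g%d", 1:60),
                                           sample(5:25, 1)))
    names(sets) <- sprintf("S%d", 1:6)
    sig <- data.frame(set = names(sets), direction = "up")
    gg <- buildGeneSetGraph(sig, sets)
    ee <- igraph::as_data_frame(gg, "edges")
    for (k in seq_len(nrow(ee)))
      expect_equal(ee$weight[k],
                   intersectOracle(sets[[ee$from[k]]], sets[[ee$to[k]]]))
    # no edge for zero-overlap pairs
    prs <- combn(names(sets), 2)
    for (k in seq_len(ncol(prs))) {
      w <- intersectOracle(sets[[prs[1, k]]], sets[[prs[2, k]]])
      has <- igraph::are_adjacent(gg, prs[1, k], prs[2, k])
      expect_equal(has, w >= 1)
    }
  }

  # GraphML serialization round trip
  f <- tempfile(fileext = ".graphml")
  writeGeneSetGraph(g, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::E(back)$weight, 10)
})

test_that("GMT files round trip", {
  sets <- list(ALPHA = c("g1", "g2", "g3"), BETA = c("g2", "g9"))
  f <- tempfile(fileext = ".gmt")
  writeGmt(sets, f)
  expect_equal(readGmt(f), sets)
  expect_error(writeGmt(list(c("a", "b")), f), "named")
  writeLines("ONLYNAME\tdesc", f)
  expect_error(readGmt(f), "malformed")
})
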