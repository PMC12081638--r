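# Colony detection pipeline and clonogenic survival arithmetic.

test_that("circularity matches analytic shapes", {
  r <- 50
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1.0)
  s <- 7
  expect_equal(circularity(s^2, 4 * s), pi / 4)
  expect_equal(circularity(20, 42), 4 * pi * 20 / 42^2)  # ~0.142
  expect_error(circularity(10, 0), "> 0")
})

test_that("Crofton perimeter of a digitized disk is close to 2*pi*r", {
  for (r in c(8, 15, 25)) {
    n <- 2L * r + 9L
    cr <- (n + 1) / 2
    mask <- outer(seq_len(n), seq_len(n),
                  function(i, j) (i - cr)^2 + (j - cr)^2 <= r^2)
    expect_lt(abs(croftonPerimeter(mask) - 2 * pi * r) / (2 * pi * r), 0.05)
  }
})

test_that("input validation: dimensionality and physical pixel size", {
  expect_error(detectColonies(array(0, c(4, 4, 2)), 5), "2-D")
  expect_error(detectColonies(matrix(0, 50, 50)), "pixelSize")
  expect_error(detectColonies(matrix(0, 50, 50), -1), "> 0")
})

test_that("noise-only and blank images yield zero colonies", {
  blank <- simulateColonyImage(colonyImageSpec(noiseSd = 0, seed = 1L))
  expect_equal(colonyCount(detectColonies(blank$image, 5)), 0L)
  noisy <- simulateColonyImage(colonyImageSpec(noiseSd = 60, seed = 2L))
  expect_equal(colonyCount(detectColonies(noisy$image, 5)), 0L)
})

test_that("disjoint disks above both thresholds are all detected", {
  spec <- randomColonySpec(12, seed = 11L, imageShape = c(320L, 320L))
  sim <- simulateColonyImage(spec)
  det <- detectColonies(sim$image, pixelSize = 5)
  expect_equal(colonyCount(det), 12L)
  ft <- colonyFeatures(det)
  expect_true(all(ft$circularity[ft$kept] > 0.8))  # disks are round
  # detected areas agree with planted areas within discretization error
  hits <- matchColonies(ft, sim$truth, 5)
  expect_equal(hits, 12L)
})

test_that("the area filter separates small from large objects", {
  # 3000 um^2 (r = 30.9 um) fails the 5000 um^2 filter; 8000 um^2 passes
  cc <- data.frame(center_row = c(60, 150), center_col = c(60, 150),
                   radius_um = sqrt(c(3000, 8000) / pi), intensity = 8000)
  sim <- simulateColonyImage(colonyImageSpec(colonies = cc, pixelSize = 5,
                                             seed = 3L))
  det <- detectColonies(sim$image, pixelSize = 5)
  ft <- colonyFeatures(det)
  expect_equal(nrow(ft), 2L)
  expect_equal(colonyCount(det), 1L)
  expect_equal(sum(!ft$kept), 1L)
})

test_that("detection is invariant to translation and constant offsets", {
  cc <- data.frame(center_row = c(60, 130), center_col = c(70, 150),
                   radius_um = c(60, 75), intensity = 8000)
  base <- simulateColonyImage(colonyImageSpec(colonies = cc, pixelSize = 5,
                                              seed = 4L, noiseSd = 100))
  n0 <- colonyCount(detectColonies(base$image, 5))
  expect_equal(n0, 2L)

  cc2 <- cc
  cc2$center_row <- cc2$center_row + 15
  cc2$center_col <- cc2$center_col + 10
  shifted <- simulateColonyImage(colonyImageSpec(colonies = cc2,
                                                 pixelSize = 5, seed = 4L,
                                                 noiseSd = 100))
  expect_equal(colonyCount(detectColonies(shifted$image, 5)), n0)

  # adding a constant changes nothing: background subtraction removes it
  det1 <- detectColonies(base$image, 5)
  det2 <- detectColonies(base$image + 500, 5)
  expect_equal(colonyFeatures(det1), colonyFeatures(det2))
})

test_that("raising the area threshold never increases the count", {
  sim <- simulateColonyImage(randomColonySpec(8, seed = 5L, noiseSd = 200))
  counts <- vapply(c(2000, 5000, 9000, 15000, 25000), function(a)
    colonyCount(detectColonies(sim$image, 5,
                               colonyParams(minAreaUm2 = a))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("a fixed threshold can replace Otsu", {
  sim <- simulateColonyImage(randomColonySpec(4, seed = 6L))
  det <- detectColonies(sim$image, 5,
                        colonyParams(threshold = "fixed",
                                     thresholdValue = 4000))
  expect_equal(colonyCount(det), 4L)
  expect_error(colonyParams(threshold = "fixed"), "thresholdValue")
})

test_that("surviving fractions follow the plating-efficiency definition", {
  cur <- survivingFraction(data.frame(dose_Gy = c(0, 4),
                                      cells_plated = c(1000, 1000),
                                      colonies = c(300, 60)))
  expect_equal(cur@platingEfficiency, 0.3)
  expect_equal(survivalTable(cur)$surviving_fraction, c(1.0, 0.2))

  # ratio invariance: proportional plating and colonies give identical SFs
  a <- survivingFraction(data.frame(dose_Gy = c(0, 2, 4),
                                    cells_plated = c(500, 500, 500),
                                    colonies = c(200, 120, 40)))
  b <- survivingFraction(data.frame(dose_Gy = c(0, 2, 4),
                                    cells_plated = c(1000, 1000, 1000),
                                    colonies = c(400, 240, 80)))
  expect_equal(a@survivingFraction, b@survivingFraction)

  expect_error(survivingFraction(data.frame(dose_Gy = c(0, 2),
                                            cells_plated = 100,
                                            colonies = c(0, 10))),
               "plating efficiency")
  expect_error(survivingFraction(data.frame(dose_Gy = c(2, 4),
                                            cells_plated = 100,
                                            colonies = c(5, 2))), "0 Gy")
})

test_that("the optional linear-quadratic fit recovers known parameters", {
  alpha <- 0.3; beta <- 0.05
  d <- c(0, 2, 4, 6, 8)
  sf <- exp(-alpha * d - beta * d^2)
  cur <- survivingFraction(data.frame(dose_Gy = d, cells_plated = 1e6,
                                      colonies = round(0.3 * 1e6 * sf)),
                           fitLQ = TRUE)
  expect_equal(cur@fit$alpha, alpha, tolerance = 0.02)
  expect_equal(cur@fit$beta, beta, tolerance = 0.02)
})
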