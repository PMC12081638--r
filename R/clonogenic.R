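## Clonogenic-assay colony detection and survival quantities.
##
## The detection pipeline mirrors the classic ImageJ macro sequence:
## rolling-ball background subtraction (ball radius 115 px by default),
## Gaussian blur (sigma 2 px), a global threshold (Otsu by default),
## 8-connected component labelling with hole filling, then area
## (>= 5000 um^2) and circularity (>= 0.5) filters in physical units.

#' Colony-detection parameters
#'
#' @param rollingBallRadiusPx rolling-ball radius in pixels.
#' @param gaussianSigmaPx Gaussian blur sigma in pixels.
#' @param minAreaUm2 minimum colony area in square micrometres.
#' @param minCircularity minimum circularity (`4 * pi * area / perimeter^2`).
#' @param threshold `"otsu"` for Otsu's global threshold or `"fixed"` to use
#'   `thresholdValue` on the blurred, background-subtracted image.
#' @param thresholdValue numeric threshold when `threshold = "fixed"`.
#' @return A parameter list for [detectColonies()].
#' @export
colonyParams <- function(rollingBallRadiusPx = 115, gaussianSigmaPx = 2,
                         minAreaUm2 = 5000, minCircularity = 0.5,
                         threshold = c("otsu", "fixed"),
                         thresholdValue = NULL) {
  threshold <- match.arg(threshold)
  if (threshold == "fixed" && (is.null(thresholdValue) ||
                               !is.finite(thresholdValue)))
    fail("'thresholdValue' must be given for a fixed threshold")
  list(rollingBallRadiusPx = rollingBallRadiusPx,
       gaussianSigmaPx = gaussianSigmaPx, minAreaUm2 = minAreaUm2,
       minCircularity = minCircularity, threshold = threshold,
       thresholdValue = thresholdValue)
}

#' Gaussian blur of a grayscale image
#'
#' Separable Gaussian convolution with edge replication; the kernel extends
#' to three sigma.
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return Blurred matrix of the same size.
#' @export
gaussianBlur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  rows <- 0 * image
  for (i in seq_along(k))
    rows <- rows + k[i] * shiftReplicate(image, 0L, i - r - 1L)
  out <- 0 * image
  for (i in seq_along(k))
    out <- out + k[i] * shiftReplicate(rows, i - r - 1L, 0L)
  out
}

## Block mean downsampling by integer factor (edge-replicated padding).
blockMean <- function(m, s) {
  if (s == 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  nR <- ceiling(nr / s); nC <- ceiling(nc / s)
  m2 <- m[pmin(seq_len(nR * s), nr), pmin(seq_len(nC * s), nc), drop = FALSE]
  rg <- rep(seq_len(nR), each = s)
  cg <- rep(seq_len(nC), each = s)
  t(rowsum(t(rowsum(m2, rg)), cg)) / (s * s)
}

## Separable bilinear upsampling of a shrunken grid back to (nr, nc); shrunk
## pixel i covers full-resolution rows (i-1)*s+1 .. i*s.
enlargeBilinear <- function(sm, nr, nc, s) {
  if (s == 1L) return(sm[seq_len(nr), seq_len(nc), drop = FALSE])
  interpIdx <- function(nFull, nSmall) {
    u <- (seq_len(nFull) - 0.5) / s + 0.5
    i0 <- pmin(pmax(floor(u), 1), nSmall)
    i1 <- pmin(i0 + 1, nSmall)
    w <- pmin(pmax(u - floor(u), 0), 1)
    w[i0 == i1] <- 0
    list(i0 = i0, i1 = i1, w = w)
  }
  ri <- interpIdx(nr, nrow(sm))
  ci <- interpIdx(nc, ncol(sm))
  rows <- sm[ri$i0, , drop = FALSE] * (1 - ri$w) +
    sm[ri$i1, , drop = FALSE] * ri$w
  t(t(rows[, ci$i0, drop = FALSE]) * (1 - ci$w) +
      t(rows[, ci$i1, drop = FALSE]) * ci$w)
}

## Grayscale opening with a (non-flat) ball structuring element of radius r.
ballOpen <- function(f, r) {
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- dr^2 + dc^2 <= r^2
  dr <- dr[keep]; dc <- dc[keep]
  h <- sqrt(r^2 - dr^2 - dc^2)
  ero <- matrix(Inf, nrow(f), ncol(f))
  for (i in seq_along(dr))
    ero <- pmin(ero, shiftReplicate(f, dr[i], dc[i]) - h[i])
  dil <- matrix(-Inf, nrow(f), ncol(f))
  for (i in seq_along(dr))
    dil <- pmax(dil, shiftReplicate(ero, dr[i], dc[i]) + h[i])
  dil
}

#' Rolling-ball background estimation
#'
#' Estimates the smooth background as the grayscale opening of the image
#' with a ball structuring element of the given radius, the classical
#' rolling-ball definition. For large radii the image is downsampled by
#' block averaging (factor up to 8, as in the ImageJ implementation), opened
#' at the reduced radius, and the background is interpolated back up.
#' Intensities are rescaled so the ball curvature is commensurate with the
#' image's dynamic range; the estimate is clipped to lie below the image.
#'
#' @param image numeric matrix.
#' @param radius ball radius in pixels (default 115).
#' @return Background matrix of the same size; subtract it from `image`.
#' @export
rollingBallBackground <- function(image, radius = 115) {
  stopifnot(radius > 0)
  shrink <- if (radius <= 16) 1L else if (radius <= 32) 2L
            else if (radius <= 64) 4L else 8L
  small <- blockMean(image, shrink)
  rb <- max(2L, as.integer(round(radius / shrink)))
  rng <- diff(range(small))
  iscale <- if (rng > 0) rng / rb else 1
  op <- ballOpen(small / iscale, rb) * iscale
  bg <- enlargeBilinear(op, nrow(image), ncol(image), shrink)
  pmin(bg, image)
}

#' Otsu's global threshold
#'
#' Maximizes the between-class variance on a 256-bin histogram of the image
#' values and returns the threshold on the intensity scale; foreground is
#' `image > threshold`.
#'
#' @param image numeric matrix or vector.
#' @param nbins number of histogram bins.
#' @return The scalar threshold.
#' @export
otsuThreshold <- function(image, nbins = 256L) {
  v <- as.numeric(image)
  mn <- min(v); mx <- max(v)
  if (mx - mn <= 0) return(mx)
  brk <- seq(mn, mx, length.out = nbins + 1L)
  h <- tabulate(findInterval(v, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  w <- cumsum(h)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  m <- cumsum(h * mids)
  mt <- m[nbins]; n <- w[nbins]
  w1 <- w[-nbins]; m1 <- m[-nbins]
  valid <- w1 > 0 & w1 < n
  bc <- rep(-Inf, nbins - 1L)
  bc[valid] <- (mt * w1[valid] / n - m1[valid])^2 /
    (w1[valid] / n * (1 - w1[valid] / n))
  brk[which.max(bc) + 1L]
}

#' Label connected foreground components
#'
#' Iterative minimum-label propagation over the 8- (or 4-) neighbourhood.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix; 0 is background, objects are labelled 1..k.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  if (!any(mask)) return(out)
  offs <- if (connectivity == 8L)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  else list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)
  repeat {
    new <- lab
    for (o in offs) new <- pmin(new, shiftFill(lab, o[1], o[2], Inf))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- lab[mask]
  out[mask] <- match(ids, sort(unique(ids)))
  out
}

## Fill interior holes of a single logical object mask (already padded by a
## FALSE border): background not reachable from the border becomes object.
fillHolesMask <- function(sub) {
  reach <- matrix(FALSE, nrow(sub), ncol(sub))
  reach[1, ] <- !sub[1, ]; reach[nrow(sub), ] <- !sub[nrow(sub), ]
  reach[, 1] <- reach[, 1] | !sub[, 1]
  reach[, ncol(sub)] <- reach[, ncol(sub)] | !sub[, ncol(sub)]
  repeat {
    grow <- reach |
      shiftFill(reach, -1L, 0L, FALSE) | shiftFill(reach, 1L, 0L, FALSE) |
      shiftFill(reach, 0L, -1L, FALSE) | shiftFill(reach, 0L, 1L, FALSE)
    grow <- grow & !sub
    if (identical(grow, reach)) break
    reach <- grow
  }
  sub | !reach
}

#' Crofton perimeter of a binary mask
#'
#' Perimeter estimate from boundary intersection counts along four line
#' directions (0, 45, 90, 135 degrees), the estimator for which digitized
#' disks come out near `2 * pi * r`.
#'
#' @param mask logical matrix (one object; outside counts as background).
#' @return Perimeter in pixel units.
#' @export
croftonPerimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  nh <- sum(p[, -1] != p[, -(nc + 2L)])
  nv <- sum(p[-1, ] != p[-(nr + 2L), ])
  d1 <- sum(p[-1, -1] != p[-(nr + 2L), -(nc + 2L)])
  d2 <- sum(p[-1, -(nc + 2L)] != p[-(nr + 2L), -1])
  pi / 8 * (nh + nv + (d1 + d2) / sqrt(2))
}

#' Circularity of a region
#'
#' `4 * pi * area / perimeter^2`: 1 for an ideal disk, `pi / 4` for a
#' square, approaching 0 for elongated shapes. Units cancel as long as area
#' and perimeter use consistent ones.
#'
#' @param area region area (e.g. um^2).
#' @param perimeter region perimeter (> 0, e.g. um).
#' @return Dimensionless circularity.
#' @examples
#' circularity(pi * 50^2, 2 * pi * 50)  # 1
#' circularity(20, 42)                  # thin 1 x 20 rectangle, ~0.14
#' @export
circularity <- function(area, perimeter) {
  if (any(perimeter <= 0)) fail("'perimeter' must be > 0")
  4 * pi * area / perimeter^2
}

#' Detect colonies in a grayscale well image
#'
#' Applies, in order: rolling-ball background subtraction, Gaussian blur,
#' global thresholding, 8-connected labelling with per-object hole filling,
#' and feature extraction. Objects are kept when their area is at least
#' `minAreaUm2` and their circularity at least `minCircularity`. With the
#' Otsu threshold, a contrast guard rejects segmentations whose threshold is
#' within three robust standard deviations (MAD) of the image median -- the
#' signature of a noise-only image with no real foreground.
#'
#' @param image 2-D numeric matrix.
#' @param pixelSize physical pixel size in micrometres per pixel (required:
#'   the area filter is in physical units).
#' @param params parameter list from [colonyParams()].
#' @return A [ColonyDetection-class] object.
#' @examples
#' sim <- simulateColonyImage(randomColonySpec(nColonies = 4, seed = 5L))
#' det <- detectColonies(sim$image, pixelSize = 5)
#' colonyCount(det)
#' @export
detectColonies <- function(image, pixelSize, params = colonyParams()) {
  if (!is.matrix(image) || !is.numeric(image))
    fail("'image' must be a 2-D numeric matrix")
  if (missing(pixelSize) || is.null(pixelSize))
    fail("'pixelSize' (um per pixel) is required: the area filter is physical")
  if (!is.finite(pixelSize) || pixelSize <= 0)
    fail("'pixelSize' must be > 0")

  sub <- image - rollingBallBackground(image, params$rollingBallRadiusPx)
  bl <- gaussianBlur(sub, params$gaussianSigmaPx)
  emptyResult <- function() new("ColonyDetection",
    features = data.frame(label = integer(), area_um2 = numeric(),
                          perimeter_um = numeric(), circularity = numeric(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          kept = logical()),
    count = 0L, pixelSize = pixelSize, params = params)

  if (params$threshold == "otsu") {
    thr <- otsuThreshold(bl)
    guard <- median(bl) + 3 * mad(bl)
    if (thr <= guard) return(emptyResult())
  } else thr <- params$thresholdValue
  mask <- bl > thr
  if (!any(mask)) return(emptyResult())

  lab <- labelComponents(mask, connectivity = 8L)
  k <- max(lab)
  feats <- vector("list", k)
  for (id in seq_len(k)) {
    w <- which(lab == id, arr.ind = TRUE)
    r0 <- range(w[, 1]); c0 <- range(w[, 2])
    sub0 <- matrix(FALSE, diff(r0) + 3L, diff(c0) + 3L)
    sub0[cbind(w[, 1] - r0[1] + 2L, w[, 2] - c0[1] + 2L)] <- TRUE
    filled <- fillHolesMask(sub0)
    wf <- which(filled, arr.ind = TRUE)
    areaPx <- nrow(wf)
    perimPx <- croftonPerimeter(filled)
    feats[[id]] <- data.frame(
      label = id,
      area_um2 = areaPx * pixelSize^2,
      perimeter_um = perimPx * pixelSize,
      circularity = min(circularity(areaPx, perimPx), 1.1),
      centroid_row = mean(wf[, 1]) + r0[1] - 2L,
      centroid_col = mean(wf[, 2]) + c0[1] - 2L)
  }
  ft <- do.call(rbind, feats)
  ft$kept <- ft$area_um2 >= params$minAreaUm2 &
    ft$circularity >= params$minCircularity
  new("ColonyDetection", features = ft, count = sum(ft$kept),
      pixelSize = pixelSize, params = params)
}

#' @describeIn ColonyDetection-class per-object feature table.
#' @param x,object a `ColonyDetection`.
#' @export
colonyFeatures <- function(x) {
  stopifnot(is(x, "ColonyDetection"))
  x@features
}

#' @describeIn ColonyDetection-class number of kept colonies.
#' @export
colonyCount <- function(x) {
  stopifnot(is(x, "ColonyDetection"))
  x@count
}

#' @describeIn ColonyDetection-class compact display.
#' @export
setMethod("show", "ColonyDetection", function(object) {
  cat(sprintf("ColonyDetection: %d colonies kept of %d objects (pixel %g um)\n",
              object@count, nrow(object@features), object@pixelSize))
})

#' Clonogenic surviving fractions
#'
#' The plating efficiency (PE) is colonies per cell plated at 0 Gy; the
#' surviving fraction at dose d is `(colonies(d) / cellsPlated(d)) / PE`, so
#' SF(0) = 1 by construction and SFs are invariant to proportional changes
#' in plating density.
#'
#' @param curveInput data.frame with columns `dose_Gy`, `cells_plated`,
#'   `colonies` (one row per dose).
#' @param fitLQ if `TRUE`, additionally fit the linear-quadratic model
#'   `SF = exp(-alpha * D - beta * D^2)` by least squares on `log(SF)`
#'   (an extension beyond the plain counting readout).
#' @return A [ClonogenicCurve-class] object.
#' @examples
#' survivingFraction(data.frame(dose_Gy = c(0, 4), cells_plated = 1000,
#'                              colonies = c(300, 60)))
#' @export
survivingFraction <- function(curveInput, fitLQ = FALSE) {
  need <- c("dose_Gy", "cells_plated", "colonies")
  if (!all(need %in% names(curveInput)))
    fail("curve input needs columns %s", paste(need, collapse = ", "))
  i0 <- which(curveInput$dose_Gy == 0)
  if (length(i0) != 1L)
    fail("exactly one 0 Gy condition is required")
  if (curveInput$colonies[i0] <= 0)
    fail("zero colonies at 0 Gy: plating efficiency is undefined")
  pe <- curveInput$colonies[i0] / curveInput$cells_plated[i0]
  sf <- (curveInput$colonies / curveInput$cells_plated) / pe
  fit <- list()
  if (fitLQ) {
    ok <- sf > 0
    if (sum(ok) >= 3) {
      d <- curveInput$dose_Gy[ok]
      co <- stats::coef(stats::lm(log(sf[ok]) ~ 0 + d + I(d^2)))
      fit <- list(alpha = -unname(co[1]), beta = -unname(co[2]))
    } else warning("too few positive surviving fractions for an LQ fit")
  }
  new("ClonogenicCurve", doses = curveInput$dose_Gy,
      cellsPlated = curveInput$cells_plated,
      colonyCounts = curveInput$colonies, platingEfficiency = pe,
      survivingFraction = sf, fit = fit)
}

#' @describeIn ClonogenicCurve-class per-dose summary table.
#' @param x,object a `ClonogenicCurve`.
#' @export
survivalTable <- function(x) {
  stopifnot(is(x, "ClonogenicCurve"))
  data.frame(dose_Gy = x@doses, cells_plated = x@cellsPlated,
             colonies = x@colonyCounts,
             surviving_fraction = x@survivingFraction)
}

#' @describeIn ClonogenicCurve-class compact display.
#' @export
setMethod("show", "ClonogenicCurve", function(object) {
  cat(sprintf("ClonogenicCurve: %d doses, plating efficiency %.3g\n",
              length(object@doses), object@platingEfficiency))
  if (length(object@fit))
    cat(sprintf("  LQ fit: alpha %.3g, beta %.3g\n",
                object@fit$alpha, object@fit$beta))
})
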