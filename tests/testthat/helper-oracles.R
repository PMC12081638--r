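# Independent oracles and small fixture builders shared across test files.

# Brute-force Benjamini-Hochberg step-up: walk the sorted p-values from the
# largest down, carrying the running minimum of p * n / rank.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  s <- p[o]
  adj <- numeric(n)
  cur <- Inf
  for (i in n:1) {
    cur <- min(cur, s[i] * n / i)
    adj[i] <- min(cur, 1)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force pairwise intersection size
intersectOracle <- function(a, b) {
  cnt <- 0L
  for (g in a) if (any(b == g)) cnt <- cnt + 1L
  cnt
}

# Closed-form pooled-variance two-sample t statistic and p-value
pooledTOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * pt(-abs(tt), df = nx + ny - 2))
}

# Minimal hand-built well table (one row per well)
makeWells <- function(plate, exp, aConc, bConc, dose, signal,
                      solvent = "DMSO") {
  n <- length(signal)
  data.frame(plate_id = rep_len(plate, n),
             well = sprintf("A%02d", seq_len(n)),
             drug_a_conc_uM = rep_len(aConc, n),
             drug_b_conc_uM = rep_len(bConc, n),
             dose_Gy = rep_len(dose, n), solvent = rep_len(solvent, n),
             raw_signal = signal, experiment_id = rep_len(exp, n),
             stringsAsFactors = FALSE)
}

# Match detected colony centroids to planted centers within one radius;
# returns the number of planted colonies recovered.
matchColonies <- function(features, truth, pixelSize) {
  kept <- features[features$kept, , drop = FALSE]
  if (nrow(truth) == 0 || nrow(kept) == 0) return(0L)
  hits <- 0L
  used <- rep(FALSE, nrow(kept))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((kept$centroid_row - truth$center_row[i])^2 +
              (kept$centroid_col - truth$center_col[i])^2)
    j <- which(!used & d < truth$radius_um[i] / pixelSize)
    if (length(j)) {
      used[j[1]] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}
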