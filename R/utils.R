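## Internal helpers shared across modules.

## Evaluate `code` under its own RNG stream without touching global RNG state.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## Multiplicative log-normal noise with E[noise] = 1 and the requested CV.
lognormalNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

## Shift a matrix by (dr, dc) with edge replication: out[i, j] = m[i+dr, j+dc],
## indices clamped to the matrix.
shiftReplicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

## Shift a matrix by (dr, dc) padding with `fill` outside.
shiftFill <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs + dr, cs + dc, drop = FALSE]
  out
}

## Well addresses "A01".."H12"-style for n wells laid out row-wise on a
## 12-column grid (purely cosmetic labels; no positional meaning downstream).
wellAddresses <- function(n) {
  row <- (seq_len(n) - 1L) %/% 12L
  col <- (seq_len(n) - 1L) %% 12L + 1L
  paste0(LETTERS[row %% 26L + 1L], sprintf("%02d", col))
}

## stop() with the call suppressed, for cleaner validation errors
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Geometric mean
geomMean <- function(x) exp(mean(log(x)))
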