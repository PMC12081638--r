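## Transcriptomic radioresistance profiling layer: TMM normalization,
## two-group differential expression with BH control at FDR 1%, per-sample
## gene-set enrichment scores, the response-rate statistic, and the
## shared-gene gene-set graph.
##
## Deliberate simplifications relative to a full voom/GSVA stack: the
## two-group test is an equal-variance t test on TMM-normalized log-CPM
## (no empirical-Bayes moderation), and the per-sample enrichment score is a
## standardized mean rank with an analytic finite-population null rather
## than a kernel KS statistic. Both are documented in the methods vignette.

## Accept either a SummarizedExperiment with a "counts" assay or a plain
## matrix; returns list(counts, groups).
countsAndGroups <- function(x, groups = NULL) {
  if (is(x, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(x, "counts")
    if (is.null(groups)) groups <- SummarizedExperiment::colData(x)$group
  } else counts <- as.matrix(x)
  if (anyDuplicated(rownames(counts))) fail("duplicate gene ids")
  if (!is.null(groups) && length(groups) != ncol(counts))
    fail("every sample needs a group label")
  list(counts = counts, groups = groups)
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample normalization robust to composition bias. The reference
#' sample is the one whose upper-quartile (of library-size-scaled counts) is
#' closest to the mean upper-quartile. For each sample, gene-wise log ratios
#' M and average abundances A against the reference are computed on
#' library-size-adjusted counts; genes in the top/bottom 30% of M or 5% of A
#' are trimmed, and the factor is `2^` the precision-weighted mean of the
#' remaining M values (delta-method binomial weights). Factors are rescaled
#' to have geometric mean 1.
#'
#' @param x count matrix (genes x samples) or `SummarizedExperiment`.
#' @param trimM,trimA two-sided trim fractions for M and A.
#' @param refColumn optional reference column index (default: automatic).
#' @return Numeric vector of per-sample normalization factors.
#' @examples
#' m <- matrix(rpois(600, 50), 100, 6)
#' rownames(m) <- sprintf("g%03d", 1:100)
#' tmmFactors(m)
#' @export
tmmFactors <- function(x, trimM = 0.3, trimA = 0.05, refColumn = NULL) {
  counts <- countsAndGroups(x)$counts
  if (ncol(counts) < 2) fail("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) fail("sample(s) with all-zero counts: %s",
                          paste(which(lib <= 0), collapse = ", "))
  uq <- vapply(seq_len(ncol(counts)),
               function(j) quantile(counts[, j] / lib[j], 0.75), 0)
  if (is.null(refColumn)) refColumn <- which.min(abs(uq - mean(uq)))
  ref <- counts[, refColumn]
  nR <- lib[refColumn]

  oneFactor <- function(obs, nO) {
    fin <- obs > 0 & ref > 0
    o <- obs[fin]; r <- ref[fin]
    M <- log2((o / nO) / (r / nR))
    A <- (log2(o / nO) + log2(r / nR)) / 2
    if (max(abs(M)) < 1e-6) return(1)
    w <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n - floor(n * trimM)
    loA <- floor(n * trimA) + 1; hiA <- n - floor(n * trimA)
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)),
              function(j) oneFactor(counts[, j], lib[j]), 0)
  f <- f / geomMean(f)
  setNames(f, colnames(counts))
}

#' Counts per million (optionally log2 with pseudocount)
#'
#' Plain CPM divides by the library size; with `normFactors`, the effective
#' library size is `libSize * factor` (TMM-normalized CPM). The log form is
#' `log2((count + 0.5) / (effLib + 1) * 1e6)`, the standard pseudocount
#' convention.
#'
#' @param x count matrix or `SummarizedExperiment`.
#' @param log return log2-CPM instead of CPM.
#' @param normFactors optional per-sample normalization factors.
#' @return Matrix of (log-)CPM values.
#' @export
countsPerMillion <- function(x, log = FALSE, normFactors = NULL) {
  counts <- countsAndGroups(x)$counts
  lib <- colSums(counts)
  if (!is.null(normFactors)) lib <- lib * normFactors
  if (log) {
    log2(t(t(counts + 0.5) / (lib + 1)) * 1e6)
  } else {
    t(t(counts) / lib) * 1e6
  }
}

#' Filter lowly expressed genes
#'
#' Keeps genes with CPM at least `minCpm` in at least `minSamples` samples
#' (defaults CPM >= 1 in >= 3 samples).
#'
#' @param x count matrix or `SummarizedExperiment`.
#' @param minCpm,minSamples thresholds (>= 0).
#' @return The input with low-expression genes removed (same class).
#' @export
filterLowExpression <- function(x, minCpm = 1, minSamples = 3) {
  if (minCpm < 0 || minSamples < 0) fail("thresholds must be >= 0")
  counts <- countsAndGroups(x)$counts
  keep <- rowSums(countsPerMillion(counts) >= minCpm) >= minSamples
  if (!any(keep)) fail("all genes were filtered out")
  if (is(x, "SummarizedExperiment")) x[keep, ] else counts[keep, , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment: sorted p-values are multiplied by
#' `n / rank` and a cumulative minimum is taken from the largest down,
#' capped at 1. Order-preserving.
#'
#' @param pvals p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric())
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    fail("p-values must lie in [0, 1]")
  n <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  adj <- pmin(1, cummin(pvals[o] * n / (n:1)))
  adj[order(o)]
}

## Contrast order: factors keep their level order; for the default labels the
## radiosensitive group is the reference, so positive effects mean "up in
## radioresistant"; anything else falls back to sorted order.
canonicalGroups <- function(groups) {
  if (is.factor(groups)) return(droplevels(groups))
  u <- sort(unique(groups))
  if (setequal(u, c("radioresistant", "radiosensitive")))
    u <- c("radiosensitive", "radioresistant")
  factor(groups, levels = u)
}

## Vectorized two-sample equal-variance t test on the rows of a matrix.
## Returns diff (mean g2 - mean g1), t, p.
rowTTest <- function(m, groups) {
  g <- canonicalGroups(groups)
  if (nlevels(g) != 2) fail("exactly two groups are required")
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (n1 < 2 || n2 < 2) fail("each group needs at least two samples")
  m1 <- rowMeans(m[, g == levels(g)[1], drop = FALSE])
  m2 <- rowMeans(m[, g == levels(g)[2], drop = FALSE])
  v1 <- apply(m[, g == levels(g)[1], drop = FALSE], 1, var)
  v2 <- apply(m[, g == levels(g)[2], drop = FALSE], 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- m2 - m1
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  p <- 2 * pt(-abs(t), df = n1 + n2 - 2)
  p[is.infinite(t)] <- 0
  list(diff = d, t = t, p = p, groupLevels = levels(g))
}

#' Two-group differential expression
#'
#' Log2 fold changes are differences of group means of TMM-normalized
#' log2-CPM (second factor level minus first; with the default labels,
#' radioresistant minus radiosensitive). Per-gene equal-variance t tests are
#' BH-adjusted and genes are flagged significant at an FDR of 1% by default.
#'
#' @param x count matrix or `SummarizedExperiment` (with `group` column).
#' @param groups group labels (taken from `colData` when `x` is an SE).
#' @param fdr significance level on the BH-adjusted p-values.
#' @return data.frame with `gene`, `log2FC`, `t`, `p`, `padj`,
#'   `significant`; attribute `"groupLevels"` records the contrast order.
#' @examples
#' se <- simulateCounts(countsSimSpec(nGenes = 200, seed = 3L))
#' head(differentialExpression(se))
#' @export
differentialExpression <- function(x, groups = NULL, fdr = 0.01) {
  cg <- countsAndGroups(x, groups)
  if (is.null(cg$groups)) fail("every sample needs a group label")
  f <- tmmFactors(cg$counts)
  lcpm <- countsPerMillion(cg$counts, log = TRUE, normFactors = f)
  tt <- rowTTest(lcpm, cg$groups)
  padj <- bhAdjust(tt$p)
  out <- data.frame(gene = rownames(cg$counts), log2FC = tt$diff, t = tt$t,
                    p = tt$p, padj = padj, significant = padj < fdr,
                    row.names = NULL)
  attr(out, "groupLevels") <- tt$groupLevels
  out
}

#' Read / write GMT gene-set collections
#'
#' GMT is tab-delimited: set name, description, then member genes.
#'
#' @param path GMT file.
#' @param sets named list of character vectors (member genes).
#' @param descriptions optional per-set description column.
#' @return `readGmt`: a named list of member-gene vectors; `writeGmt`:
#'   `path`, invisibly.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) fail("GMT file '%s' does not exist", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(tok) {
    if (length(tok) < 3)
      fail("malformed GMT line (need set, description, >= 1 gene)")
    unique(tok[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
  sets
}

#' @rdname readGmt
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    fail("'sets' must be a named list")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    ""), path)
  invisible(path)
}

#' Per-sample gene-set enrichment scores (standardized mean rank)
#'
#' For each sample, genes are ranked by expression (ascending, average
#' ties). A set's score is its members' mean rank, centred at `(G + 1) / 2`
#' and scaled by the standard deviation of a mean of `m` ranks drawn without
#' replacement from `1..G` (variance `(G + 1) (G - m) / (12 m)`), so scores
#' are approximately standard normal under the no-enrichment null. Sets with
#' fewer than `minProp` of their members present in the matrix are dropped
#' with a warning.
#'
#' @param expr expression matrix (e.g. TMM-normalized log-CPM), genes in
#'   rows; or a `SummarizedExperiment` whose counts are converted to
#'   log-CPM internally.
#' @param sets named list of member-gene vectors (e.g. from [readGmt()]).
#' @param minProp minimum fraction of a set's genes that must be present.
#' @return Matrix of scores, sets x samples.
#' @export
enrichmentScores <- function(expr, sets, minProp = 0.5) {
  if (is(expr, "SummarizedExperiment")) {
    cg <- countsAndGroups(expr)
    f <- tmmFactors(cg$counts)
    expr <- countsPerMillion(cg$counts, log = TRUE, normFactors = f)
  }
  expr <- as.matrix(expr)
  G <- nrow(expr)
  ranks <- apply(expr, 2, rank)
  keepSet <- vapply(sets, function(g)
    length(intersect(g, rownames(expr))) >= max(1, minProp * length(g)) &&
      length(intersect(g, rownames(expr))) < G, TRUE)
  if (!all(keepSet))
    warning(sprintf("dropping %d set(s) with < %g%% of members present",
                    sum(!keepSet), 100 * minProp))
  sets <- sets[keepSet]
  if (length(sets) == 0) fail("no gene set has enough members present")
  score <- matrix(NA_real_, length(sets), ncol(expr),
                  dimnames = list(names(sets), colnames(expr)))
  for (i in seq_along(sets)) {
    idx <- which(rownames(expr) %in% sets[[i]])
    m <- length(idx)
    sdNull <- sqrt((G + 1) * (G - m) / (12 * m))
    score[i, ] <- (colMeans(ranks[idx, , drop = FALSE]) - (G + 1) / 2) / sdNull
  }
  score
}

#' Differential gene-set enrichment between two groups
#'
#' Per-set equal-variance t test on the enrichment-score matrix, BH-adjusted
#' at FDR 1% by default; direction is the sign of the group mean difference
#' (second level minus first).
#'
#' @param scores set x sample enrichment-score matrix.
#' @param groups per-sample group labels (two levels, >= 2 samples each).
#' @param fdr significance level for the BH-adjusted p-values.
#' @return data.frame with `set`, `delta` (mean score difference),
#'   `direction` (`"up"` / `"down"`), `p`, `padj`, `significant`.
#' @export
differentialGeneSets <- function(scores, groups, fdr = 0.01) {
  scores <- as.matrix(scores)
  tt <- rowTTest(scores, groups)
  padj <- bhAdjust(tt$p)
  data.frame(set = rownames(scores), delta = tt$diff,
             direction = ifelse(tt$diff >= 0, "up", "down"),
             p = tt$p, padj = padj, significant = padj < fdr,
             row.names = NULL)
}

#' Transcriptional response rate
#'
#' `-log10(padj) * log2(foldChange)`: large when a change is both strong and
#' well supported; the sign follows the direction of change. `foldChange` is
#' the linear fold change (the formula applies the log2).
#'
#' @param padj BH-adjusted p-value(s) in (0, 1\].
#' @param foldChange linear fold change(s), > 0.
#' @return Numeric response rate(s).
#' @examples
#' responseRate(0.01, 4)  # 2 * 2 = 4
#' @export
responseRate <- function(padj, foldChange) {
  if (any(!is.finite(padj) | padj <= 0 | padj > 1))
    fail("'padj' must lie in (0, 1]; zero gives an infinite response rate")
  if (any(!is.finite(foldChange) | foldChange <= 0))
    fail("'foldChange' must be > 0")
  -log10(padj) * log2(foldChange)
}

#' Build the shared-gene gene-set graph
#'
#' Nodes are the significant gene sets (direction-annotated); an undirected
#' edge joins two sets when they share at least `minShared` genes, weighted
#' by the shared-gene count. Sets that share many genes therefore cluster
#' together under any force-directed layout; the layout itself is a
#' rendering concern and not part of this construction.
#'
#' @param significantSets data.frame with columns `set` and `direction`
#'   (e.g. the significant rows of [differentialGeneSets()] output).
#' @param memberships named list of member genes covering every node.
#' @param minShared minimum shared-gene count for an edge (default 1).
#' @param categories optional named list of keyword vectors; a node is
#'   tagged with the first category whose keyword matches the set name
#'   (case-insensitive), else `"other"`.
#' @return An [igraph::graph] with vertex attributes `direction` and
#'   `category` and edge attribute `weight`.
#' @export
buildGeneSetGraph <- function(significantSets, memberships, minShared = 1,
                              categories = NULL) {
  if (!all(c("set", "direction") %in% names(significantSets)))
    fail("'significantSets' needs columns 'set' and 'direction'")
  nodes <- significantSets$set
  missing <- setdiff(nodes, names(memberships))
  if (length(missing))
    fail("no membership list for set(s): %s", paste(missing, collapse = ", "))
  tagOf <- function(nm) {
    if (is.null(categories)) return("other")
    for (cat in names(categories))
      if (any(vapply(categories[[cat]],
                     function(k) grepl(k, nm, ignore.case = TRUE), TRUE)))
        return(cat)
    "other"
  }
  edges <- data.frame(from = character(), to = character(),
                      weight = integer())
  if (length(nodes) >= 2) {
    pr <- combn(nodes, 2)
    w <- apply(pr, 2, function(p)
      length(intersect(memberships[[p[1]]], memberships[[p[2]]])))
    keep <- w >= minShared & w >= 1
    edges <- data.frame(from = pr[1, keep], to = pr[2, keep],
                        weight = w[keep])
  }
  vertices <- data.frame(name = nodes,
                         direction = significantSets$direction,
                         category = vapply(nodes, tagOf, ""))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' Serialize a gene-set graph to GraphML
#'
#' @param graph an igraph object from [buildGeneSetGraph()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneSetGraph <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
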