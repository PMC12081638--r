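---
title: "Methods: synergy, clonogenic, sub-G1 and transcriptomic analysis for organoid radioresistance screens"
author: "OrganoidScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind OrganoidScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrganoidScreen)
```

# Scope

OrganoidScreen implements the computational layer of a patient-derived
organoid radioresistance study: Bliss-independence synergy scoring of
drug/drug and drug/radiation combinations measured by ATP-proxy luminescence,
automated colony counting for clonogenic survival assays, sub-G1
quantification from DNA-content event lists, and a bulk-transcriptomic
profiling layer (TMM normalization, differential expression at an FDR of 1%,
per-sample gene-set enrichment, response-rate statistics and a shared-gene
gene-set graph). Every input can be produced by a seeded synthetic-data
generator with known ground truth, so each stage is testable without any
external data.

# Viability plates and normalization

Wells are identified by plate, experiment, solvent, and treatment labels
(drug concentrations in uM, radiation dose in Gy). Viability is the raw
luminescence divided by the mean luminescence of the *matched* control wells:
same plate, same experiment, same solvent, untreated (0 uM / 0 uM / 0 Gy).
Consequences of this definition:

* control wells average exactly 1 per plate, and normalization is invariant
  to rescaling all signals on a plate by any positive constant;
* viabilities are **not clipped at 1** -- wells can outgrow controls, and
  clipping would bias Bliss expectations downward;
* controls are matched within plate rather than pooled across the plates of
  an experiment. This was a genuinely open choice; within-plate matching was
  selected because each plate is a separate luminescence read with its own
  gain, and it makes drug x radiation designs (one plate per dose) correct by
  construction. Condition summaries then pool wells across the plates of an
  experiment.

Solvent percentages above the assay limits (1% DMSO, 0.3% Tween-20) raise a
warning rather than an error: they flag a protocol deviation, not an invalid
measurement.

# Bliss synergy

Under Bliss independence, two agents that act independently leave a
combination viability equal to the product of the single-agent viabilities,

$$Y_{AB(E)} = Y_A \cdot Y_B,$$

and the synergy score is the ratio of expected to observed viability,
$S = Y_{AB(E)} / Y_{AB(O)}$. A score of 2 means the combination left half as
many viable cells as expected. Per-experiment categories are: $S < 2$ not
synergistic, $2 \le S \le 5$ synergistic, $S > 5$ strongly synergistic; the
boundary semantics follow the category definitions literally, so exactly 2
is synergistic and exactly 5 is not yet "strongly". A combination is called
synergistic only when scores **strictly above 2** occur in at least
$\lceil (n+1)/2 \rceil$ of $n$ independent experiments -- a strict majority,
which reduces to the classical 2-of-3 rule for triplicate designs; the
majority generalization for $n \neq 3$ is this package's extension.
Radiation is treated as agent B by substituting the dose for the second
concentration axis.

Numerical choices:

* **Observed-viability floor.** Near-complete eradication drives
  $Y_{AB(O)}$ toward 0 and the score toward infinity. Observed viabilities
  below $10^{-4}$ are floored there before division; floored scores are
  flagged and a warning is raised. The floor corresponds to a combination
  well at 0.01% of control signal, below the resolution of a luminescence
  read.
* **Aggregation.** The combination-level score is the median of the
  per-experiment scores, reported with the (min, max) range, matching the
  "score [high-low]" convention for replicated screens; whether such ranges
  accompany a mean or a median is conventionally ambiguous, and the median
  was chosen for its robustness at $n = 3$. Promotion to "strongly
  synergistic" at the combination level requires the replication rule to
  pass *and* the median to exceed 5 (only per-experiment categories are
  classically defined; this promotion rule is documented as a choice).

# Synthetic plates

The plate generator is the generative inverse of the Bliss analysis. True
combination viability is $Y_A Y_B / \sigma$ where $\sigma$ is the planted
interaction factor, so the downstream synergy score equals $\sigma$ by
construction -- exactly when noise is zero, in median under noise. Raw
signals are `viability x control luminescence x noise` with multiplicative
log-normal noise of a chosen CV (mean 1): luminescence error is
multiplicative and viability cannot go negative. Each generator call runs in
its own RNG stream seeded from the spec; the caller's RNG state is never
touched.

Defaults state a realistic screen: single-agent viabilities 0.5 and 0.95
(an active oxidative-stress inducer paired with a glutathione-synthesis
inhibitor that is inert alone), 4 replicate wells, 3 independent
experiments, control signal $10^5$ counts. Plate-level variance is not a
published quantity; `noiseCv = 0.1` is a free parameter documented as such
(10% CV is typical of CellTiter-Glo-style reads) and the calibration tests
exercise 0, 0.05 and 0.1.

# Clonogenic colony detection

The pipeline reproduces a macro-style sequence in physical units:

1. **Rolling-ball background subtraction**, radius 115 px. Implemented as
   grayscale opening with a ball structuring element (the classical
   rolling-ball definition). For radii above 16 px the image is downsampled
   by block averaging (factor up to 8), opened at the reduced radius, and
   the background is bilinearly interpolated back -- the standard
   large-radius approximation. Intensities are rescaled so the ball's
   curvature is commensurate with the image's dynamic range, and the
   background is clipped to lie at or below the image. Opening commutes with
   additive constants, so adding a uniform offset to an image changes
   nothing downstream.
2. **Gaussian blur**, sigma 2 px, separable kernel truncated at 3 sigma with
   edge replication.
3. **Global threshold.** The method is a configuration option; Otsu's
   parameter-free threshold is the default. A noise-only image has a
   unimodal histogram, where Otsu would split the noise itself; the
   segmentation is therefore rejected (no foreground) when the Otsu
   threshold is within three robust standard deviations (MAD) of the image
   median. The cost of this guard is that colonies with contrast below
   about three noise SDs are declared absent -- acceptable for
   well-plate imaging, where colony contrast is tens of noise SDs.
4. **8-connected labelling** (the particle-analysis convention), followed by
   per-object hole filling.
5. **Feature filters.** Area $\ge 5000\ \mu m^2$ and circularity
   $4\pi A / P^2 \ge 0.5$, both defaults exposed in `colonyParams()`. The
   perimeter is a Crofton four-direction estimate, for which digitized disks
   come out near $2\pi r$; discretization can push circularity slightly
   above 1, absorbed by a cap at 1.1. The area threshold's biological gloss
   ("roughly 50 cells") is treated as commentary, not a second filter.

Merged colonies are not split (no watershed); overlapping objects appear as
one large region and are flagged in the synthetic ground truth instead.
Surviving fractions use the standard clonogenic definition: plating
efficiency $PE = \text{colonies}(0\,\mathrm{Gy})/\text{plated}(0\,\mathrm{Gy})$ and
$SF(d) = [\text{colonies}(d)/\text{plated}(d)] / PE$. A linear-quadratic fit
($SF = e^{-\alpha D - \beta D^2}$, least squares on $\log SF$) is available
but marked as an extension: no survival-curve model is part of the core
readout.

The image generator draws hard-edged disks (circularity exactly 1 in ground
truth) on a linear background ramp with additive Gaussian noise, written as
ASCII PGM when serialized -- a deliberately simple text format, since no
TIFF writer is available in this R environment and the fixtures must remain
plain text. Real well images differ in ways the generator does not emulate:
soft colony edges, vignetting, debris, and merged colonies; a green test
establishes correctness of the measurement pipeline, not robustness to
every imaging artifact.

# Sub-G1 analysis

Inputs are pre-gated singlet event lists (debris/doublet exclusion by
scatter gating happens upstream in the cytometer software and is out of
scope). The 2N and 4N landmarks are the two dominant modes of a
kernel-density estimate (Silverman's bandwidth) whose position ratio falls
in the sanity band $[1.7, 2.3]$ around the expected doubling; if no such
pair exists (e.g. a pure G1 population) the analysis refuses and suggests
manual gates. The sub-G1 gate is `gateFactor x g1Mode` with default 0.80:
no numeric gate is conventionally published, and 0.8 places the boundary
more than four peak-SDs below the G1 mode for peak CVs up to 8%, so G1
leakage into the gate is negligible while uniform sub-G1 debris is
captured. Because the gate is derived from the detected landmarks, the
fraction is invariant to global intensity rescaling.

Fold changes are `fraction(5 Gy) / fraction(0 Gy)`; group comparisons use
the two-sided pooled-variance (Student's) t test, the classical equal-variance
form. The generator draws from a four-component mixture -- uniform sub-G1
strictly below the 2N mode, Gaussian G1 and G2/M at $\mu$ and $2\mu$,
uniform S bridge -- which emulates histogram shape but not aggregates,
partial degradation continua, or aneuploid populations.

# Transcriptomics

Counts enter as a gene x sample integer matrix (alignment and quantification
are upstream and out of scope) with a two-group design, radiosensitive vs
radioresistant; positive effects mean "up in radioresistant".

* **TMM.** The trimmed-mean-of-M-values factors are computed exactly as
  conventionally defined: reference sample with upper quartile closest to
  the mean, two-sided trims of 30% on M and 5% on A, precision weights from
  the delta-method binomial variances, factors rescaled to geometric mean 1.
  The implementation is authored here (it is part of the re-implemented
  layer) and is cross-checked in the tests against the edgeR implementation
  on random matrices, where the two agree to numerical precision.
* **Filtering.** CPM $\ge 1$ in $\ge 3$ samples by default; the thresholds
  are stated as free parameters because only the existence of a filter, not
  its values, is conventionally fixed.
* **Differential expression.** Log2 fold changes are differences of group
  means of TMM-normalized log2-CPM (pseudocount 0.5); inference is a
  per-gene pooled-variance t test with Benjamini-Hochberg adjustment and
  significance at adjusted $p < 0.01$. This deliberately replaces a
  moderated-variance pipeline with a defined, dependency-light procedure
  whose error control is testable: under permuted-label and simulated nulls
  the realized false-positive proportion stays well under the nominal 1%.
  The cost is power at small $n$: with 3 samples per group (4 degrees of
  freedom) moderate effects rarely clear BH-adjusted $p < 0.01$, so
  sensitivity claims in the tests are frozen from this package's own
  simulation oracle (raw-p recovery and effect-size calibration) rather
  than from any aspirational recovery rate.
* **Enrichment scores.** Per sample, genes are ranked by expression and a
  set's score is the standardized mean rank of its members:
  $z = (\bar r - \tfrac{G+1}{2}) / \sqrt{(G+1)(G-m)/(12m)}$, the exact
  finite-population null moments for drawing $m$ of $G$ ranks without
  replacement. Scores are mean 0, variance 1 under the null by
  construction -- verified against a permutation oracle -- and a set scores
  against its complement with opposite sign. This is a deliberate,
  analytically tractable replacement for kernel-based per-sample enrichment
  estimators and is not numerically compatible with them. Sets with fewer
  than half their members present are dropped with a warning.
* **Differential gene sets** reuse the pooled t test on score rows with BH
  at 1%; direction is the sign of the group mean difference.
* **Response rate.** $-\log_{10}(p_{adj}) \times \log_2(\text{fold change})$
  with the *linear* fold change as input (the formula applies the log2
  itself); it is antisymmetric under inverting the fold change, and
  $p_{adj} = 0$ is rejected rather than mapped to infinity.
* **Gene-set graph.** Nodes are exactly the significant sets, annotated
  with direction; an undirected edge of weight equal to the shared-gene
  count joins any two sets sharing at least one gene (`minShared`
  configurable). Layout is a rendering concern: the graph is serialized to
  GraphML and any force-directed renderer will place gene-sharing sets
  together. Category tags are user-supplied keyword lists over set names,
  since no canonical category assignment exists.

The count generator uses per-gene log-normal baseline means around
`baselineMean`, negative-binomial sampling at the stated dispersion,
per-sample library-size factors, and multiplies planted-set members by
$2^{\text{effect}}$ in the radioresistant group; decoy sets provide a null
reference. It does not emulate gene-gene correlation, batch structure, or
length bias, so null calibration results transfer to real data only to the
extent that those are absent or corrected upstream.

# Pipeline runner

`runPipeline()` executes stages in dependency order from a validated
configuration (JSON-serializable; flags in the thin
`inst/scripts/pipeline.R` wrapper override file values) and writes a
manifest with package and R versions, the seed, all parameters, and MD5
checksums of every input and output -- sufficient to re-execute a run
exactly. Seeded runs are bit-reproducible. The configuration format is JSON
rather than TOML because no TOML parser is available in this environment;
the structure is a flat field set, so the substitution is lossless.

# Known limitations

* Colony detection processes single images; tiled composites must be
  stitched upstream, and merged colonies are counted once.
* The DE layer trades power for simplicity at very small group sizes (see
  above); for cohort-scale inference a moderated pipeline is preferable.
* Sub-G1 analysis assumes a dominant diploid cycle; strongly aneuploid
  samples can defeat the ratio-band landmark search and require manual
  gates.
* Synergy scores compare means of few replicates; the floor (1e-4) bounds
  but does not remove the instability of near-zero observed viabilities.
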