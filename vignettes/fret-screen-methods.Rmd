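---
title: "Methods: FRET-based screening for respiratory chain supercomplex assembly"
author: "fretscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FRET-based screening for respiratory chain supercomplex assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscreen)
```

# The assay and its readout

Mitochondrial respiratory chain complexes I, III~2~ and IV assemble into
higher-order supercomplexes. When a GFP-class donor fluorophore is fused
to a complex I subunit and a DsRed-class acceptor to a complex IV
subunit, the two come within Förster distance only upon supercomplex
formation, so sensitized acceptor emission (FRET) reports supercomplex
abundance in living cells. An imaging cytometer records three channels
per field: the donor channel (donor excitation, donor emission), the
acceptor channel (acceptor excitation, acceptor emission), and the raw
FRET channel (donor excitation, acceptor emission), quantified over 12
regions of interest (ROIs) per 96-well plate well.

The raw FRET channel is contaminated by two spectral artifacts:
donor emission bleeding into the acceptor detection band, and direct
excitation of the acceptor at the donor wavelength. Both are removed by
the standard sensitized-emission correction

$$\mathrm{cFRET} = F_{raw} - \alpha\,F_{donor} - \beta\,F_{acceptor},$$

where $\alpha$ is estimated from cells expressing only the donor and
$\beta$ from cells expressing only the acceptor. The working statistic is
the ratio cFRET/donor, which cancels expression-level differences
(`corrected_fret()`, `aggregate_wells()`).

## Estimator choices

* $\alpha$ and $\beta$ are least-squares slopes through the origin of the
  raw FRET intensity on the donor (respectively acceptor) intensity
  across calibration ROIs. A slope is preferred over the mean of
  per-ROI ratios because ROI intensities span orders of magnitude and the
  contamination model is proportional through zero; the source assay does
  not state its estimator, so this package declares one. Estimation
  requires at least 20 ROIs (`min_rois`), and an all-zero regressor is an
  error, never a silent zero.
* Background: an optional per-channel constant background can be
  subtracted before estimation and correction; it defaults to off. The
  commercial analysis pipeline behind the original assay does not
  document its background handling, so the default here is the least
  surprising one and is explicit in the configuration.
* Negative cFRET values are retained, not clipped. Clipping would bias
  null wells upward; keeping the full distribution keeps control means
  unbiased and the normalization exact.
* ROIs with non-positive donor intensity or zero cells are flagged and
  excluded from well means rather than producing undefined ratios. Wells
  keep their exclusion counts (`n_rois`, `qc_flags`).

## Acceptor photobleaching

Bleaching the acceptor abolishes transfer and dequenches the donor; the
apparent transfer efficiency per region is $E = 1 - F_{pre}/F_{post}$
from donor intensities before and after bleaching
(`photobleach_fret_efficiency()`). The function verifies that the
acceptor actually decreased in each region and runs a paired two-sided
Student's t test on the donor intensities, mirroring the validation
design of the assay (nine paired regions).

# Screen scoring

The screen treats a 1280-compound library at a single concentration in
two replicate experiments, with DMSO vehicle wells and β-lapachone
positive-control wells on every plate. Scores are computed per compound
(`score_primary()`):

$$S = \frac{\overline{r}_{compound} - \overline{r}_{DMSO}}
           {\overline{r}_{\beta\text{-}lap} - \overline{r}_{DMSO}},
  \qquad r = \mathrm{cFRET/donor},$$

with control means computed per plate-replicate and averaged across
replicates, so each compound is normalized against its own plates'
controls. A compound is a **hit** when $S > 0.6$ (strict) and no
exclusion applies:

* **Replicate inconsistency**: the two replicate raw mean cFRET/donor
  values differ by more than 0.15 (strict; a difference of exactly 0.15
  is retained). The rule is applied to raw per-replicate means, not
  normalized scores, following the wording of the published criterion;
  this is configurable.
* **Cytotoxicity**: mean well cell count below half the plate's DMSO
  mean cell count. The published screen excluded compounds by visual
  inspection of cell death and morphology; a cell-count fraction is the
  computable proxy, and the 0.5 default is declared, not inferred.

The secondary screen uses the unnormalized difference
$\Delta = \overline{r}_{compound} - \overline{r}_{DMSO}$
(`score_secondary()`), ranking compounds by descending $\Delta$ with
lexicographic tie-breaks so ranking is deterministic.

Assay quality is summarized by the screening-window statistic

$$Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} - \mu_{neg}|}$$

on control wells (`z_prime()`), the standard formula of the
high-throughput screening literature; 0.5 and above is industry grade,
and the original assay reports roughly 0.2.

# Dose-response fitting

Concentration-response data are fitted with the four-parameter logistic
$y = d + (a-d)/[1 + (x/c)^b]$ by Levenberg–Marquardt nonlinear least
squares (`fit_four_pl()`, wrapping `minpack.lm::nlsLM`). Choices that
matter:

* Initialization: $d$ = mean response at the lowest dose, $a$ = mean at
  the highest, $c$ = geometric mean of the dose range, $b = 1$.
* Bounds: $c \in (\min x/10,\ \max x \times 10)$; $|b| \le 50$ (steeper
  curves are numerically step functions, and unbounded slopes overflow
  the power term inside the optimizer).
* Convergence tolerance $10^{-8}$ on parameters; non-convergence is
  reported, never silently accepted.
* Canonical orientation: the parameterization has an exact degeneracy —
  swapping $(a, d)$ and negating $b$ leaves the curve unchanged — so
  fits are canonicalized to $b > 0$ with $a$ as the $x \to 0$ asymptote,
  making the EC50 ($= c$) unique.
* Zero-dose (vehicle) rows are excluded from the fit because $x$ enters
  through a power; they belong in the data as baseline anchors, not in
  the likelihood. At least four distinct positive concentrations are
  required, and constant responses are an explicit under-determined
  error.
* Unweighted least squares by default (the source protocol does not
  state weights); inverse-variance weights can be passed.

# Respirometry and expression assays

A Mito Stress Test trace measures oxygen consumption rate (OCR, pmol
O~2~/min) in three cycles at baseline and after each sequential injection
of oligomycin (ATP-synthase inhibitor), FCCP (uncoupler), and
rotenone/antimycin A (complex I/III inhibitors). `segment_phases()`
assigns cycles to phases from the injection annotations;
`respiration_metrics()` then computes, with phase means as the default
summary (the protocol says "OCR before/after injection" without picking
a cycle; `summary = "vendor"` reproduces the common last-baseline /
min / max vendor convention):

* non-mitochondrial = rotenone/antimycin phase,
* basal = baseline − non-mitochondrial,
* ATP-linked = baseline − oligomycin,
* proton leak = oligomycin − non-mitochondrial,
* maximal = FCCP − non-mitochondrial,
* spare capacity = maximal − basal.

The identities basal = ATP-linked + proton leak and spare = maximal −
basal hold by construction and are asserted in the tests. qPCR fold
changes use the standard $2^{-\Delta\Delta C_T}$ method
(`ddct_fold_change()`).

# The synthetic-data generator

All tests and the acceptance analysis run on simulated data with known
ground truth, because the screen's raw tables are not deposited. The
generator (`sim_config()`, `gen_*()`) emulates the screen's statistical
structure with an explicit spectral mixing model. Per cell, with donor
abundance $D$ and acceptor abundance $A$ drawn from lognormals and an
engaged-donor fraction $f = f_0(1+\theta)$ at per-engagement efficiency
$E_0$:

$$F_{donor} = g_D D (1 - fE_0), \quad F_{acceptor} = g_A A, \quad
F_{raw} = g_F D f E_0 + \alpha F_{donor}^{sig} + \beta F_{acceptor}^{sig},$$

plus a constant background offset and Gaussian noise with standard
deviation $\sigma_{bg} + k\sqrt{\mathrm{signal}}$ (camera plus shot
noise; means stay unbiased, and intensities are clipped at zero as on a
detector). Donor quenching — the $(1 - fE_0)$ factor — is included so
that acceptor photobleaching recovers a positive transfer efficiency.
ROI values are means over the cells in the field. In the zero-background
limit the expected ratio has the closed form
$\mathbb{E}[\mathrm{cFRET/donor}] = g_F f E_0 / (g_D(1 - fE_0))$
(`expected_cfret_per_donor()`), which the tests use as an analytic
oracle.

## Default study conditions

Defaults are fixed once as the simulated screen's study conditions:
1280 compounds, two replicate screens, 12 ROIs/well, 80 compounds per
96-well plate with one DMSO column and one β-lapachone column. Where the
source assay states a number it is used directly (library size,
replicates, ROIs/well, 0.6 and 0.15 thresholds, triplicate respirometry
cycles, nine photobleach regions); where it does not, values are chosen
once at field-realistic magnitudes and documented here:

* $f_0 = 0.25$, $E_0 = 0.3$: a modest baseline engaged fraction with
  transfer efficiency typical of GFP–RFP pairs, giving a baseline ratio
  of about 0.08.
* Positive-control effect $\theta = 1$ (β-lapachone doubles the engaged
  fraction); planted hits draw $\theta$ uniformly from 0.7–1.3 times the
  positive-control effect, 20 hits per 1280 compounds; 2% of compounds
  are cytotoxic with a 60% cell-count loss.
* $\alpha = 0.2$, $\beta = 0.1$: the source does not report coefficient
  magnitudes; these are declared placeholders at plausible magnitudes.
* Lognormal abundances (meanlog $\log 1000$ and $\log 800$, sdlog 0.3),
  50 cells per ROI, background offsets 0, background SD 5 AU, shot
  factor 1.
* Dose series: 8 log-spaced doses over 0.025–5 µM (the β-lapachone dose
  range of the source assay) with true EC50 0.6 µM (matching the
  magnitude of the reported MNS estimate), slope 1.5, 5% CV, 3
  replicates.
* OCR phase means 100/40/150/20 pmol O~2~/min, SD 5, three cycles per
  phase.

Cytotoxicity is modeled **only** as reduced cell count; the published
morphology criterion is visual and not computable from intensity tables.
The image generator renders disjoint elliptical cells — not filamentous
mitochondrial networks — so segmentation results speak to the pipeline's
bookkeeping, not to real-image difficulty. There is no optics model (no
PSF, no photobleaching kinetics beyond the pre/post pair). Passing tests
therefore demonstrate correctness of the estimators and scoring rules
under a faithful statistical emulation, not performance on real
microscope images.

## Imaging path

`segment_rois()` thresholds the donor channel with Otsu's method
(cells express the donor constitutively), labels connected components,
and removes components under 50 px — the simplest defensible stand-in
for the unpublished commercial segmentation. `fret_efficiency_map()`
renders per-pixel cFRET/donor inside the foreground with low-donor
pixels masked rather than divided; the commercial "FRET efficiency"
pseudo-color statistic is proprietary and unspecified, so this package
renders its own declared ratio.

# Problem sizes and determinism

Every generator is deterministic given (configuration, seed), and the
pipeline is deterministic given its inputs, which the tests verify by
byte comparison. The test suite runs full-size screens (1280 compounds,
two replicates, five seeds) for hit recovery, 200-ROI calibrations for
coefficient recovery, 50-seed dose-response recovery studies, and
100-trace respirometry Monte-Carlo checks; these sizes match the
emulated study design while keeping the suite fast.

# Known limitations

* The spectral coefficients and background levels of the original
  instrument are unpublished; recovery results are relative to the
  simulator's declared truth.
* The replicate-difference rule is applied to raw per-replicate means;
  if the original screen applied it to normalized scores the excluded
  set could differ near the boundary (configurable).
* The published screen's compound tables are not redistributable, so the
  recount of its published funnel (222 compounds above threshold, top
  secondary delta 1.65) runs only when a user supplies the deposited
  tables as CSV under `inst/extdata/supplementary/`.
* No spatial plate-effect correction (B-score/median polish) and no
  multiple-testing machinery: the screen's published decision rules are
  thresholds, and this package implements exactly those.
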