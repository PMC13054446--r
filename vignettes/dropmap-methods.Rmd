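---
title: "Models and methods behind dropmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dropmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropmapr)
```

## The assay being modelled

dropmapr analyses droplet-microfluidic single-cell secretion assays of the
DropMap family. Single cells are encapsulated in ~10 pL water-in-oil
droplets together with streptavidin paramagnetic nanobeads coated with an
anti-kappa light chain nanobody, a green-labelled antigen
(glucose-6-phosphate isomerase, GPI, 30 nM in-droplet), and a red-labelled
anti-IgG F(ab')2 detector (75 nM in-droplet). Under a magnetic field the
beads align into an elongated "beadline". IgG secreted by the cell is
captured on the beadline; the red detector and, if the IgG binds the
antigen, the green antigen relocate there with it. Droplets are imaged in
both channels every 7.5 minutes over 37.5 minutes (6 frames).

The measured quantity per droplet, channel and frame is the *relocation*:
the mean beadline intensity divided by the mean intensity of the rest of
the droplet. Relocation kinetics in the red channel report how fast the
cell secretes; the green:red relationship reports the affinity (K_D) of
the secreted IgG for the antigen.

## Forward binding model

For a cell secreting at rate $s$ (molecules/s) in a droplet of volume $V$,
the number of secreted molecules after $t$ seconds is $N(t) = s t$, all
captured on the beadline (capture is treated as instantaneous relative to
the 7.5-minute frame interval; nanobody capture on nanobeads is fast
compared with secretion accumulation). Captured IgG presents binding sites
at molar concentration $B(t) = N(t) / (N_A V)$.

Within each frame the two reporters equilibrate independently with the
captured sites by 1:1 binding (30/75 nM reagents and nM-scale analyte
equilibrate in minutes, so equilibrium rather than kinetic binding is
assumed within a frame):

$$(B - x)(L - x) = K_D\, x,$$

solved for the complex concentration $x$ by the conservation quadratic in
its numerically stable form $x = 2BL / (B + L + K_D + \sqrt{(B + L +
K_D)^2 - 4BL})$, which avoids catastrophic cancellation when $x \ll B, L$
(`bound_1to1()`; it agrees with a brute-force bisection root to 1e-9
relative error in the test suite). For the red channel $L$ is the detector
concentration and $K_D$ the detector affinity (1 nM by default; the assay
itself does not resolve detector kinetics, and a near-saturating detector
makes red relocation track the captured IgG amount). For the green channel
$L$ is the antigen concentration and $K_D$ the cell's own affinity.

The relocation in channel $c$ is

$$R_c(t) = 1 + \kappa_c \frac{\mathrm{bound}_c(t)}{\mathrm{free}_c(t)},$$

with dimensionless channel gains $\kappa_c$. $R_c(0) = 1$ and $R_c$ is
non-decreasing in time. IgG is treated as monovalent for both reporters
(a single 1:1 constant is what the assay reports; bivalency is ignored).

## Synthetic data generator

The generator exists so that every downstream stage is testable with known
ground truth. Its defaults are the study conditions of the assay:

* Poisson cell loading at 0.3 cells/droplet — the occupancy implied by a
  30e6 cells/mL suspension in 10 pL droplets. The droplet volume itself is
  derived from those two numbers (0.3 / 3e7 mL = 10 pL), giving a 13.4 um
  spherical radius.
* 6 frames at 7.5-minute spacing; 30 nM antigen and 75 nM detector.
* Default ground-truth distributions emulate an arthritic-mouse spleen
  cohort: half the cells secrete; rates are log-normal (meanlog 3.317,
  sdlog 0.6; mean ~33 molecules/s) truncated to the 4-800 molecules/s
  assay window; 40% of secretors are antigen-specific, with K_D mostly in
  the low-affinity 10-100 nM decade (88%), some at 1-10 nM (10%) and a
  small 0.1-1 nM high-affinity tail (2%); nonspecific secretors get K_D
  log-uniform on 0.3-30 uM, far above the 100 nM detection limit.

Rendering conventions: droplets are disks on a jittered grid (never
overlapping); the background intensity is proportional to the free
fluorophore fraction (fluorophore is conserved in the closed droplet, so
the background dims as label relocates); the beadline is a horizontal bar
of 3 px by 0.6 droplet diameters whose intensity is background times
$R_c(t)$; cells are small dark disks placed at least 5 px apart and away
from the beadline; images are 16-bit with a 2000-count base background.
Optional imperfections: Poisson shot noise, Gaussian read noise, 3 px
droplet jitter between frames, and transient bright specks.

At most one cell per droplet secretes in the generator: two secretors in
one droplet would superpose their signals with no single ground-truth
(rate, K_D), and the real assay likewise excludes ambiguous droplets.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: optics (point-spread function, z-structure),
droplet polydispersity, photobleaching, autofluorescence, illumination
gradients, cells that move or divide, and secretion rates that vary over
the acquisition. Recovery results on synthetic stacks demonstrate the
correctness of the inversion chain, not robustness to every real-world
artifact.

## Imaging front-end

Droplets are segmented by thresholding (0.2 times the 99.9th intensity
percentile of the frame) plus connected-component labelling, with a
circularity filter ($4\pi A / P^2 \ge 0.8$) and an EDGE flag for
border-touching regions — simpler and fully deterministic for monodisperse
emulsions than a Hough transform. The beadline is found by sliding a 3-row
window over the central rows of each droplet and keeping the
highest-contrast window, falling back to the geometric center bar when
there is no contrast (pre-secretion frames); the field axis is horizontal
and known from the chamber geometry.

The background of a droplet is its disk minus the beadline mask *and*
minus detected cell pixels: the dark cell body would otherwise deflate the
background mean and inflate relocation by about 2%. Two guard choices make
the extraction robust to sub-pixel centroid error: the beadline mean is
taken on the bar shrunk by one column at each end, and the bar dilated by
one row/two columns is excluded from the background, so bright bar pixels
can never leak into the background or trip the artifact detector.

QC flags follow the assay's exclusion rules: MOVED for center displacement
above 2 px between consecutive frames (the assay requires "no movement";
2 px is our operationalisation, the original analysis gives no number),
MULTI_CELL for more than two detected cells, ARTIFACT for bright specks
off the beadline, EDGE, and BG_NONPOS for a non-positive background.
Background is computed per droplet (not per image), matching the
per-droplet wording of the assay description. Cell counting is automated
with a dark-disk detector; the original analysis counted cells visually,
and the flag-based design accepts detector imperfection.

## Secretor calling

A QC-passing droplet with one or two cells is called IgG-secreting when
its red relocation trace passes all three filters: maximum > 1.2, net
last-minus-first difference > 0.025, and least-squares slope >= 0.004 per
frame interval. Two interpretation choices are deliberate:

* "minimum relocation > 1.2" is read as a floor on the *achieved*
  relocation (the trace maximum must exceed 1.2), since every trace starts
  at 1.0 by construction and a literal minimum-over-trace could never
  exceed 1.2.
* The slope unit is relocation per 7.5-minute frame interval: 0.004 over
  5 intervals is 0.02, commensurate with the 0.025 net-difference
  threshold, whereas per-minute units would make the slope criterion
  dominate by about 6-fold.

## Calibration and inversion

The gains $\kappa_c$ are estimated from a panel of anchor mAbs of known
affinity encapsulated at known concentrations (clones at 0.1, 1, 10 and
100 nM spanning the working window — the published panel's affinities are
not public, so the synthetic panel spans the window). Because
$R - 1 = \kappa \cdot \mathrm{ratio}$, the fit is a through-origin least
squares of observed $R - 1$ on the model-predicted bound:free ratio,
pooled over anchors and frames; this parametric forward-model fit stands
in for the unpublished per-concentration calibration curves.

Inversion exactly reverses the forward model:

* *Rate*: each red relocation value gives the bound:free detector ratio,
  hence the captured-site concentration through the detector isotherm,
  hence molecules $N_k$. The rate is the mean of $(N_k - N_1)/(t_k - t_1)$
  over frames 2..6 (first frame as baseline), which damps any capture-lag
  transient. Estimates outside 4-800 molecules/s are *censored to the
  boundary* and flagged, not dropped — measured cohorts include values
  beyond the calibration window, so it is a validity window, not a filter.
* *K_D*: the green channel gives bound and free antigen; combined with the
  red-derived site concentration, $K_D = (B - \mathrm{bound}_g)\,
  \mathrm{free}_g / \mathrm{bound}_g$ per frame (depletion-corrected), and
  the estimate is the median over frames 2..6 for robustness. Values below
  2.3 nM are algebraic extrapolations of the same formula, kept and
  flagged `EXTRAPOLATED_LT_2.3`; values at or above 100 nM mean the cell
  is not antigen-specific; an absent green signal is `NO_GREEN_SIGNAL`
  (nonspecific). For summaries, extrapolated values below 10 pM are
  floored at 10 pM (plotting-parity rule); per-timepoint means use the
  floored values, and the floor only matters for the rare sub-10 pM
  extrapolations.

Specificity and classes: specific iff computed K_D < 100 nM; LOW if
K_D >= 10 nM, HIGH if K_D < 1 nM, MEDIUM otherwise.

## Serology

* `fit_steady_state()` fits $R_{eq}(C) = R_{max} C / (K_D + C)$ by
  Levenberg-Marquardt least squares on the five-point analyte series
  (2000, 667, 222, 74, 25 nM by default). When the largest injected
  concentration is below the fitted K_D the curve never approaches
  saturation and the fit is flagged `extrapolated` (e.g. a 4 uM serum
  affinity measured with a 2 uM top concentration).
* `percent_anti_gpi()` implements the mass-ratio formula
  $\% = R_{max}/\mathrm{capture} \times M_{antigen}/M_{IgG} \times 100$
  with defaults $M_{antigen} = 63$ kDa (GPI monomer; the dimer would halve
  the molar ratio — monomer is the default and the mass is configurable)
  and $M_{IgG} = 150$ kDa.
* `fit_ed50()` fits a four-parameter logistic to OD versus dilution and
  censors the ED50 to the threefold assay window 300..218,700 with
  `LT_300` / `GT_218700` flags; flat series are censored by level without
  a fit, and a series whose OD rises with dilution fails an orientation
  check.

## Cohort statistics

Aggregation is censoring-aware: censored rates contribute at their
boundary value, extrapolated affinities at their floored value, and every
record carries exactly one rate flag and one K_D flag so tallies reconcile
with cohort totals. Mean affinity is the arithmetic mean on the nM scale
(matching how mean affinities are quoted alongside log-scale plots); a
geometric-mean option exists but is off by default. The inferential layer
is standard plumbing: two-sided Mann-Whitney tests between consecutive
timepoints and Kruskal-Wallis across the 6-12 / 23-35 / 54-87 week age
groups with Dunn's pairwise follow-up (implemented with the standard
tie-corrected rank z statistic and Bonferroni adjustment), significance at
p <= 0.05, strata under n = 3 skipped with a notice.

## Numerical choices and problem sizes

Degenerate inputs fail fast with named errors: chambers too small to place
the emulsion, single-concentration calibration panels, all-nonpositive SPR
responses, inverted ELISA series. Ties in the beadline contrast search
resolve to the first (centered) window; the contrast threshold is 5%.
Determinism: every stochastic stage derives from one integer seed, and a
fixed seed reproduces image stacks and master tables byte for byte (the
global RNG state is saved and restored around seeded sections).

The packaged simulations are sized for a laptop-scale single CPU: the
default demo cohort is 2,000 droplets (a full acquisition is 60,000-80,000,
of which only ~20,000 one-or-two-cell droplets are analyzable — about
0.07% of a 30-million-cell spleen per acquisition); recovery cohorts use
500-1,000 rendered droplets, which already pin the pipeline means to a few
percent. Occupancy statistics are checked on 1e5 droplets, where
rendering is not needed.

## Known limitations

Rates are assumed constant over the 37.5-minute window; the inversion
returns a time-averaged rate for cells that ramp up. Affinity resolution
degrades outside 2.3-100 nM by design of the reagent concentrations:
below ~0.1 nM the green background approaches zero and the extrapolated
K_D is ordinal rather than quantitative (the HIGH class boundary at 1 nM
remains reliable). Kappa-negative (lambda light chain) secretors are
invisible to the capture design and are out of scope, as are IgM/IgA
secretors. The Dunn implementation uses the normal approximation, adequate
for the cohort sizes here but not for very small strata.
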