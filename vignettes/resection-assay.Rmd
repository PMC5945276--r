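---
title: "Measuring long-range DSB end resection in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring long-range DSB end resection in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectr)
```

## The assay and its model

A site-specific DNA double-strand break (DSB) is induced by HO endonuclease
in fission yeast carrying two fluorescent reporters near the cut site: a
10.3 kb LacO repeat array bound by LacI-GFP, whose proximal edge sits
3.57 kb from the cut, and Rad52-mCherry, which loads onto the
single-stranded DNA produced once resection has initiated. As 5' end
resection proceeds away from the break it converts the LacO array to
ssDNA, displacing LacI-GFP; the GFP focus dims in proportion to the
resected fraction of the array and finally disappears when the front
passes the distal array end, 13.87 kb from the cut.

The per-cell statistic is simple: the interval from the first frame with
an on-target Rad52 focus to the first frame with total loss of the GFP
focus spans resection of the full 13.87 kb, so

rate (kb/hr) = 13.87 / (duration / 60).

Two assumptions matter. First, the Rad52 focus appears when only a few
hundred nucleotides have been resected, so the interval effectively clocks
the *long-range* phase over the full reporter distance; the 30–60 min lag
between resection initiation (measured biochemically at a site 168 nt from
the cut) and Rad52 focus visibility is attributed to the slow initiation
phase plus RPA-to-Rad52 exchange, during which the front has moved a
negligible fraction of 13.87 kb. Second, each cell is assigned a single
constant rate; within-cell rate variation is not modeled, because one
duration per cell cannot resolve it.

Cells whose GFP focus persists to the end of acquisition are *censored*:
the event yields only an upper bound, distance / observed window
(≈2.8 kb/hr for a 5 hr window). Censored events never enter medians or
t-tests; a genotype in which most events censor is reported "N.D.".

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| spacer, array length | 3.57, 10.3 | kb | reporter geometry; sets the rate conversion |
| frame interval | 10 | min | acquisition cadence; quantizes durations |
| acquisition window | 31 frames (5 hr) | — | sets the censoring bound (2.8 kb/hr) |
| z sampling | 25 × 0.26 | slices × µm | full-volume photometry, no projections |
| cylinder radius / half-height | 2.5 px / 3 slices | — | aperture ≈1.5× the Rayleigh radius (1.22λ/2NA ≈ 1.6 px at 0.16 µm pixels); half-height spans the elongated axial PSF |
| shell gap / width | 1 / 2 px | — | local background annulus, same z extent |
| detection threshold | 5 | robust SDs | of the band-passed volume; transfers across noise levels |
| co-localization | ≤3 px for ≥2 frames | — | on-target filter against spontaneous Rad52 foci |
| onset persistence | 2 | frames | suppresses single-frame detections |
| loss threshold k | 3 | noise floors | see "Numerical choices" |

## What the simulator emulates — and what it does not

`simulate_events()` + `render_stack()` generate ground-truth-annotated
movies with the statistical structure the analysis assumes: ~15% of cells
cut within a 2 hr induction window (uniform cut times), a 30–60 min
uniform delay to Rad52 visibility, per-genotype log-normal rate
distributions (medians 7.6 wild-type-like, 13.9 crb2∆-like, 10.4
rev7∆-like, 1.4 exo1∆-like kb/hr), linear GFP focus loss across the array,
a Rad52 focus that appears at 40% of its plateau intensity and grows with
the resected tract up to 6 kb, multiplicative photobleaching (1.2% per
exposure, identical in cut and uncut cells so the photobleach control has
a defined null), Gaussian-PSF rendering, Poisson shot noise, Gaussian read
noise and a camera offset.

Choices the data do not pin down, made once: log-normal dispersion
(sdlog 0.25 — single-cell scatter is only shown graphically in the source
assay); the Rad52 floor/plateau shape (only monotone gain is observed;
the 40% floor makes the focus detectable from its first frame, which the
onset-calling accuracy relies on); the exo1∆-like median of 1.4 kb/hr
(consistent with all events censoring in 5 hr, i.e. rates below the
2.8 kb/hr bound); a GFP focus intensity of 12000 integrated counts over a
background of ~120 counts/voxel, giving the bright-array SNR regime in
which loss timing, not detection, limits accuracy.

Deliberately not emulated: cell division and mitotic GFP dips (cells are
static discs; the loss criterion's irreversibility guard is what would
absorb a transient dip), cell motility and drift, off-target Rad52 foci,
spectral bleed-through, and vectorial PSF structure. Passing recovery
tests on this simulator therefore validates the *pipeline's* logic —
photometry, event calling, censoring, statistics — under the assay's
stated noise model; it does not validate robustness to segmentation or
tracking failures in real movies, which are out of scope (ROIs come from
the experimenter or the simulator truth).

The simulated qPCR plate inverts the ΔΔCq protection model exactly as the
analysis assumes (efficiency 2.0, mock digests and a control locus
normalizing digestion efficiency, shared per-sample plate offsets,
Gaussian Cq noise, 3% background protection from incomplete digestion),
with the resection front reaching a site `d` kb from the cut at
`cut_time + delay + 60·(d − 0.168)/rate` (the initiation phase creeps to
the first ApoI site during the delay).

## Numerical choices

- **Photometry membership.** Voxels belong to the cylinder/shell by the
  distance of their center to the (subpixel) axis — no partial-voxel
  integration. This is exactly reproducible by brute-force enumeration,
  which the tests exploit; at 0.16 µm sampling the sub-voxel error is far
  below shot noise. The shell statistic is the *median*, robust to a
  neighboring focus intruding into the annulus; the shell spans the same
  z range as the cylinder (volumetric, not per-slice).
- **Border policy.** An aperture crossing the image border invalidates the
  measurement (`valid = FALSE`) rather than silently clipping it.
- **Loss threshold.** "Total loss" is operationalized as the
  background-subtracted intensity falling below `k = 3` times the noise
  floor of the integrated measurement and staying below it for every later
  frame. The noise floor combines the cylinder-sum noise
  (`√n_cyl · σ`) and the propagated error of the subtracted background
  (`n_cyl · √(π/2/n_shell) · σ`) in quadrature, with σ the robust (MAD)
  per-voxel shell SD. Omitting the second term makes the threshold ~2.4σ
  in practice and lets rare late noise excursions defer the called loss
  frame.
- **Irreversibility guard.** A loss call is revoked only by later
  *evidence of a focus*: a frame that is both detected (the 5-robust-SD
  criterion) and at or above the loss threshold. Single-frame dropouts
  before the true loss (and recovering mitotic dips, where a detectable
  focus returns) therefore do not trigger a call, while a post-loss
  photometric excursion above threshold without a detected focus does not
  defer one — with ~30 frames per movie, even a 3σ threshold is crossed
  by pure noise in a few percent of cells, which would otherwise be the
  dominant duration error.
- **Onset call.** First frame of a ≥2-frame detection run, replacing the
  human "first visible frame" judgment with the automated detection
  criterion plus persistence.
- **t50 interpolation** for population qPCR kinetics is linear between the
  bracketing timepoints; no kinetic model is fitted. Degenerate inputs
  (identical t50s → infinite rate; a curve never crossing half-max) are
  flagged or excluded, and fewer than two usable sites is an error.
- **Bonferroni family.** `m` is the number of pairs actually tested in the
  invocation, matching per-figure families; Welch's t-test is the default
  (the variances of genotype rate distributions differ visibly), Student's
  by flag.
- **Determinism.** All stochastic stages consume a single configured seed;
  identical seed + configuration reproduces truth tables, stacks and Cq
  values bit for bit.

## Problem sizes used in validation

The recovery experiments run 50–55 rendered cells per genotype at the
default acquisition geometry (31 frames × 2 channels × 25 z × 24 × 24 px
per cell), the scale at which median recovery within 15% is comfortably
resolvable given the log-normal dispersion (the median's SE is ≈
1.25·sdlog/√n ≈ 4% at n = 55); the photobleach control uses 100 uncut
cells. Population qPCR checks use 20000–30000 virtual chromosomes so the
Monte-Carlo error of true fractions is negligible against the 10%
tolerance.

## Worked example

```{r example}
geom <- cassette_geometry()
round(duration_to_rate(c(150, 140), geom), 2)   # the two daughter cells
round(censored_upper_bound(300, geom), 1)       # 5 hr censoring bound

events <- data.frame(
  cell_id = c("cell1", "cell2"), genotype = "WT", on_target = TRUE,
  duration_min = c(150, 140), censored = FALSE, observed_window_min = 300)
fit <- resection_fit(events, geom)
fit
```

## Known limitations

- The conversion assumes the Rad52-onset frame marks a front position of
  ~0 kb; if a genotype decouples Rad52 loading from initiation, its rates
  inherit that offset.
- Blinding utilities randomize and relabel manifests but cannot enforce
  that upstream file metadata is scrubbed outside what they write.
- Censored events are summarized as bounds only; no survival-analysis
  treatment of the duration distribution is attempted.
- Molecule-count calibration propagates only the reference-stoichiometry
  interval (450–1030 copies); chromophore maturation and channel
  cross-calibration are assumed away, and a mismatch in imaging metadata
  is a hard error rather than a correction.
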