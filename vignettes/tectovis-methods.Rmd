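---
title: "Models and methods behind tectovis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tectovis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tectovis` quantifies how strongly visual responses in mouse cortical areas
depend on the superior colliculus (SC) and its tecto-pulvinar projection,
and whether those areas prefer externally generated over self-generated
visual motion. This vignette documents the models, the tunable parameters,
the synthetic world used to validate every stage, and the design decisions
taken where the underlying experimental procedures leave the analysis
under-specified.

## 1. The widefield model

A widefield movie is modelled per pixel as

$$F(t) = F_0\,\bigl(1 + r(t)\bigr)\,\bigl(1 + h(t)\bigr) + \varepsilon(t),$$

where $r(t)$ is the evoked calcium signal, $h(t)$ a shared, slow
(< 1 Hz) hemodynamic modulation, and $\varepsilon$ white pixel noise. The
isosbestic channel carries $F_0(1+h) + \varepsilon'$ — the artifact but
never the evoked term. The artifact is **multiplicative**: absorption
changes scale the emitted fluorescence rather than adding to it, which is
also why the correction is a fitted rescaling of the isosbestic channel
rather than a raw subtraction.

Inside an area's mask the evoked term is a kernel pulse per trial,

$$r(t) = A\,(1 - g\,[\text{silenced}])\,(1 + \gamma\,v_{run})\,
        (1 + s_{pos}[\text{pos. VMD}] + s_{neg}[\text{neg. VMD}])\,k(t-t_{on}),$$

with $k$ a difference of exponentials ($\tau_{rise}$ = 0.1 s,
$\tau_{decay}$ = 0.8 s, rescaled so its largest *sample* is exactly 1 — a
noiseless single-trial movie therefore peaks at exactly $A$, which the
tests exploit as a closed form).

Key parameters and defaults:

| parameter | meaning | default | rationale |
|---|---|---|---|
| `A` | evoked peak ΔF/F | 0.05 | typical widefield GCaMP6s response |
| `g` | SC-dependence per area | 0 | set per experiment; 0–0.85 spans the lateromedial gradient |
| `F0` | baseline fluorescence | 1000 a.u. | arbitrary scale |
| `sigma_noise` | pixel noise SD | 10 a.u. (1% of `F0`) | single-pixel, single-frame SNR ≈ 5 for a full response |
| `h_amp` | hemodynamic amplitude | 0.01 | ~1% fluctuations, the regime where correction matters |
| `gamma` | running gain, per cm/s | 0 | see §4 |
| `frame_rate` | per channel | 10 Hz | long-exposure widefield regime |

## 2. ΔF/F, correction, delineation

* **ΔF/F** is computed per trial: $F_0$ is the pixelwise mean over the 1 s
  before onset; the analysis window runs from onset to 0.5 s after offset.
* **Hemodynamic correction** fits the isosbestic channel to the signal
  channel pixelwise by least squares over non-stimulus frames (stimulus
  windows plus 2 s of kernel tail are excluded so evoked signal is not
  absorbed) and subtracts the scaled fluctuation. A zero-variance
  isosbestic channel skips the correction with a warning rather than
  failing — the correction is known to have little impact on response
  magnitudes, so an uncorrected analysis is still meaningful.
  *Numerical caveat:* with a noisy isosbestic regressor the least-squares
  slope is attenuated by $\sigma^2_\varepsilon/\sigma^2_{h}$
  (errors-in-variables), leaving a small artifact residual; the acceptance
  check for artifact removal therefore runs near the noiseless limit,
  where the criterion's "corrected trace decorrelates from the artifact"
  statement is well defined.
* **Area delineation** binarises each of the five patch-map responses at a
  fraction (default 0.5, config-exposed — the underlying protocol does not
  state its threshold) of that map's own maximum, overlays them, splits
  the union into 4-connected components and names components by a template
  of expected area centres (greedy nearest-centre, each name used once).
  Pixels claimed by several maps go to the larger response; exact ties to
  the lower patch index. Both tie rules are package decisions made for
  reproducibility.

## 3. Silencing effect sizes

Intra-hemispheric: reduction $= (1 - \text{treated}/\text{control})\times100$,
computed on trial-mean responses from the top 50% of responding pixels,
ranked on the *average* of the control and treated mean images so the
selection cannot favour either condition. Negative treated responses are
not clipped; reductions beyond 100% are reported as computed. Note that
ranking pixels on the same trials used for measurement adds a small shared
selection bias to both conditions, compressing large reductions by roughly
one point — visible but harmless at the ±10-point recovery tolerance.

Inter-hemispheric (chronic TeLC): each area is first normalised to
same-hemisphere V1, cancelling any global gain difference between
hemispheres (expression, optics); the relative response is the ratio of
normalised values and the comparison across animals is unpaired. Areas
unresponsive under control conditions (mean below baseline mean + 2
baseline SDs) are excluded.

## 4. Visuo-motor divergence

For an uncoupled (replay) trial,
$\mathrm{VMD} = (\bar{v}_{stim} - G\bar{v}_{run}) / (G\bar{v}_{run})$
averaged over the presentation; $\ge +0.25$ is *positive* (stimulus faster
than the animal), $\le -0.25$ *negative*, otherwise *matched*. A zero mean
running speed yields a flagged $+\infty$ sentinel classified positive.
A coupled trial scored against its own running trace gives exactly 0 by
the replay identity. (The source protocol's text labels both tails
"positive" — a manifest typo; the sign convention here follows the results
and figures.)

Time courses are normalised by one scalar per mouse — the mean V1 response
over all coupled trials — truncated at 1.7 s (half-open window, so 17
samples at 10 Hz), and accompanied by the fraction of trials whose
stimulus is still on screen at each time point. All statistics aggregate
per mouse first (each mouse contributes equally), use paired two-sided
t tests per time point, and control FDR across time points with an
in-package Benjamini–Hochberg step-up. Time points where a mouse retains
no trials are reported as `NA` and excluded from the BH family rather than
imputed.

**Why `gamma` defaults to 0.** Running speed modulates visual responses,
but only as a trend in this preparation. In the generator a nonzero
`gamma` interacts with the *selection* implicit in VMD labels: positive
trials are, by construction, trials where the animal ran slower than its
replayed past self, so running gain alone would push V1's
coupled/uncoupled comparison away from the null — contradicting the
observed V1 behaviour the synthetic world is meant to emulate. The default
world therefore sets `gamma = 0`; `running_gain_check()` demonstrations
enable it explicitly. When measuring the running-gain trend itself, use a
fixed-window peak response: a window tied to trial duration correlates
with speed mechanically (faster runs make shorter trials), which would
fabricate a gain.

## 5. Electrophysiology

Spikes are absolute-value crossings of 4 trace SDs, merged within 1 ms and
timed at the trough. A crossing must persist for at least two samples
(80 µs): a single-sample rule on white noise would fire every few hundred
milliseconds at 4 SD, which no usable detector does. RS/FS classification
runs k-means (k = 2) on z-scored trough-to-peak duration and
repolarisation slope, initialised deterministically at the extreme
trough-to-peak units; the shorter-t2p cluster is FS. PSTHs use 50 ms bins
tiling the window exactly, so bin rates conserve spike counts; per-unit
normalisation is by the unit's own control maximum, and opto PSTHs are
normalised by that same control maximum. Responsiveness uses mean evoked
rate above baseline mean + k·SD with k = 2 for 0.9 s stimuli (700 ms
baseline) and k = 1 for 1.5 s stimuli (300 ms baseline). Percent reduction
is $(1 - \text{laser}/\text{control})\times100$ on baseline-subtracted
rates at each unit's preferred direction (ties to the lowest index);
population p-values use the exact Wilcoxon signed-rank test for small n.

## 6. Anatomy

Depth profiles average fluorescence across the tangential axis of a
bounding box whose depth axis is normalised to [0, 1] (pia → white
matter), so sections of different thickness align. Autofluorescence is
interpolated piecewise-linearly from label-free sample points (which must
span at least half the depth range) and subtracted; negative corrected
densities are retained, since clipping would bias totals. Profiles are
normalised per mouse and fluorophore by the maximum across sections;
multi-section areas are assembled from 10 equal bins, each taken from the
section with the greatest mean density in that bin (ties to the lowest
section id). Fractions of total fluorescence are computed on
baseline-corrected sums by default (config-switchable — whether the
original totals were corrected is not stated).

## 7. Photometry

The 405 nm channel is least-squares-fitted to the 470 nm channel over
inter-trial intervals only, subtracted, and the residual expressed as
ΔF/F against the fitted baseline. Trial responses are normalised by the
mean raw coupled response per mouse and then baseline-corrected by the 1 s
pre-onset mean (that order; the two differ only by the normaliser). The
coupled/uncoupled machinery is shared with the widefield VMD analysis,
including the divergence-binned difference curve under replay-source
pairing.

## 8. What the synthetic world does and does not establish

The generator reproduces the *structure* of the experiments — trial
timing, channel contracts, selection effects, label statistics, Poisson
spiking, laminar bands — with known effect sizes, so a green suite
establishes that the pipeline recovers what it claims to recover at
realistic SNR. It does not emulate indicator nonlinearity, eye movements
beyond a per-trial position table, spatially structured vasculature,
electrode drift, or within-trial divergence events; effect sizes for VMD
sensitivity are free parameters of the world, not estimates of biology.
Uncoupled trials inherit genuine divergence statistics (~30% positive,
~30% negative at the 25% threshold under the default running process),
rather than having labels imposed.

Degenerate inputs are handled explicitly rather than silently: zero
baseline SD excludes an area/unit with a warning; zero-variance control
channels skip correction with a warning; empty divergence bins are
reported missing, not zero; a zero control PSTH maximum drops the unit.

## 9. Known limitations

* The minimal TIFF codec writes uncompressed single-sample floats —
  adequate for the package's contracts, not a general TIFF library.
* Registration is integer-pixel rigid translation only.
* The BH family for time courses treats time points as the full family;
  no hierarchical correction across areas.
* Inter-hemispheric statistics treat hemispheres as independent samples
  (unpaired), mirroring the source convention, although both hemispheres
  come from the same animals.
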