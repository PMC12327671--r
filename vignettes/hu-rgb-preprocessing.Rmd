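---
title: "Multi-component HU-to-RGB preprocessing of brain CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-component HU-to-RGB preprocessing of brain CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hurgb)
```

## The problem

On non-contrast head CT every pixel is a Hounsfield unit (HU): air is
about -1000, cerebrospinal fluid (CSF) 0--15, white matter around 25,
gray matter around 35, fresh-to-clotted blood roughly 40--90, and bone
well above 100. A display *window* — a width `ww` and level `wl`
defining the range `[wl - ww/2, wl + ww/2]` — maps a chosen HU band to
screen intensities. No single window shows hemorrhage well: the right
band depends on clot age and patient, which is why radiologists cycle
through several windows. This package automates that cycling: it sweeps
a family of narrow windows over a slice, picks the one that isolates
blood, separates the remaining brain components by mask exclusion, and
renders everything as one RGB image with blood in adaptive red.

## Intensity transfer

Two HU-to-intensity transfers are provided. The traditional transfer
clamps: HU below the window range maps to 0, above to 255, and linearly
in between. The default transfer is a sigmoid,

$$ f(h) = \frac{U}{1 + \exp\!\big(-\tfrac{2(h - l)}{w}\,
  \ln(U/\epsilon - 1)\big)}, $$

which maps the lower window edge to $\epsilon$, the level to $U/2$ and
the upper edge to $U - \epsilon$. Out-of-range HU keeps a strictly
monotone (if tiny) response instead of being truncated, so information
survives for downstream consumers even outside the window. Defaults are
$U = 255$ and $\epsilon = 1$ intensity unit; both are configurable
(`transfer.U`, `transfer.eps`). Quantization to 8 bits uses
round-half-up followed by clamping — fixed explicitly because the
choice of rounding rule otherwise silently changes binarization at the
threshold.

A useful analytic fact, and a test anchor: as $\epsilon \to 0$ the
sigmoid tends to a *step* at the level. It therefore agrees with the
traditional transfer outside the window, at both window edges and at
the level itself, but not at other interior points, where the limit is
the step rather than the linear ramp.

## Component extraction

Masks are built by binarizing transformed slices at intensity
threshold 128, *strictly* greater-than — the sigmoid maps the level
itself to exactly 127.5, which quantizes to 128 and is excluded, so a
mask contains precisely the pixels above its window level.

1. **Initial hemorrhage candidates.** A sweep of narrow windows, width
   10 HU at levels {30, 35, ..., 75}, gives masks $H_l$. Because the
   transfer is monotone in $h - l$, the masks shrink as the level
   rises.
2. **Skull and matter masks.** $K$ from window (100, 135) captures
   skull and calcifications; $M$ from the standard brain window
   (80, 40) is used as an excluder below.
3. **Suspect regions.** For each level,
   $\hat H_l = |K - H_l| \cdot f(P)$ with $f(P) = P$ for
   $P \le 110$ HU and 0 otherwise: pixels flagged in both the candidate
   and the skull mask are excluded, and HU above 110 cannot be blood.
   The absolute difference is implemented literally (exclusive-or
   semantics); a `strict_containment` option replaces it with
   $H_l \wedge \neg K$, which differs only on skull-only pixels that
   the 110-HU cap removes anyway for real bone.
4. **Window selection.** For each $\hat H_l$ the largest 8-connected
   component is traced and its boundary points counted. Scanning
   consecutive levels, the largest *decrease* in boundary count marks
   the level at which a big low-HU structure falls out of the
   candidate mask; the region just after that drop is the hemorrhage
   ROI $\hat H$, and $H'$ is its nonzero support. Ties break to the
   earliest pair; if no pair decreases, the slice is declared
   hemorrhage-free ($H'$ empty, and the matter anchor falls back to
   `fallback_b = 40` HU, the upper edge of normal parenchyma).
5. **CSF and matter regions.** With $b = \min(\hat H)$ over positive
   entries and $a = 15$ HU:
   $\hat C = |M - H'| \cdot P\,[P \le 15]$,
   $\hat M = |M - H'| \cdot P\,[a \le P \le b/2]$,
   $\hat G = |M - H'| \cdot P\,[b/2 < P \le b]$.

### Boundary tracing

The tracer must only be *consistent across the sweep* — selection uses
differences of counts, not their absolute values. The default is the
level-0.5 iso-contour (marching squares) of the largest component,
padded by one background ring; the count is the number of vertices of
the longest closed contour, i.e. the outer boundary. This is
deterministic and parameter-free. A morphological active-contour mode
(`boundary.method = "morph_acwe"`) refines the component against the
region's HU values with a few Chan–Vese-style morphological iterations
before tracing; it exists because active contours are the natural
alternative here, and on clean convex regions the two agree exactly.
Component ties (equal areas) resolve to the component whose first
pixel in row-major order comes first.

## Rendering

Skull pixels draw as gray (155, 155, 155), CSF as (25, 25, 145), white
and gray matter share (0, 145, 0) (a `distinct_matter` palette option
separates them). Hemorrhage pixels get an adaptive red channel

$$ r = H'(i,j)\,\Big|\,255 - \tfrac{200}{110 - \min(\hat H)}
   \big(P(i,j) - \min(\hat H)\big)\Big|, $$

so the freshest (lowest-HU) blood in the region renders at full red 255
and blood at the 110-HU cap at 55 — dark red kept clear of black. The
outer $|\cdot|$ is read as absolute value; for HU inside
$[\min(\hat H), 110]$ absolute value and clamping coincide, so the
ambiguity is immaterial and the in-range property is asserted rather
than clamped. Overlap precedence is hemorrhage > skull > CSF > gray
matter > white matter — fixed so that blood, the whole point of the
preprocessing, is never occluded. Three views are composed: the full
multi-component view, a skull-plus-hemorrhage view for classifier
input, and a hemorrhage overlay on the brain-window grayscale for
human review.

## The head phantom

`generate_phantom()` emulates a 2D axial head slice so the pipeline is
testable end to end without clinical data: an elliptical skull ring
(HU uniform in [700, 1200]), a white-matter core at 25 HU, a cortical
gray-matter band at 35 HU, two ventricular CSF ellipses (per-pixel
uniform in [0, 15]), one 60-HU bleed of radius 8 by default, optional
calcified nodules above 110 HU, and additive Gaussian noise
(default sd 0, i.e. noise-free). The default grid is 128×128 — large
enough for a skull ring, cortical band and distinct blobs, small
enough that a full extraction runs in tens of milliseconds, which
keeps the 20-seed robustness checks cheap. The bleed HU of 60 sits
mid-sweep so window selection is exercised non-trivially. Ground-truth
masks are painted in a fixed order with later layers overwriting
earlier ones, so they are pairwise disjoint by construction, and the
generator is deterministic given its seed.

What the phantom does *not* emulate: partial-volume blending at tissue
interfaces, beam hardening and streak artifacts, anatomic asymmetry,
and 3D continuity across slices. Passing its tests shows the method's
logic is implemented correctly under idealized piecewise-constant
anatomy; it does not certify clinical performance.

```{r phantom-run}
ph <- generate_phantom(phantom_spec())
comp <- extract_components(ph$hu)
comp
dice(comp$Hp, ph$truth$bleed)
```

## Numerical and design choices

* **Rounding** is round-half-up throughout; base R's round-half-even
  would move the binarization boundary.
* **Sweep set**: ten levels {30..75 step 5} by default, configurable
  (`sweep.wl_list`).
* **Skull window** (100, 135) is interpreted as (width, level),
  consistent with the (80, 40) brain window; configurable if a
  different convention is needed.
* **$\min(\hat H)$** is taken over strictly positive entries — zeros
  are background, not 0 HU — and an empty selected region falls back
  to $b = 40$ HU.
* **Indexing** is R-native 1-based (row, col) everywhere; the selected
  sweep index is a 1-based position in the level list.
* **Ablation**: `thresholds_enabled = FALSE` (CLI `--no-threshold`)
  removes the HU caps from all four region equations, which admits
  calcifications above 110 HU into $H'$; the adaptive red then uses
  the raw absolute-value formula clamped to [0, 255] for display
  validity.

## Known limitations

* **The CSF and matter regions are provably empty on clean inputs
  under the default configuration.** $\hat C > 0$ requires
  $P \le 15$ together with disagreement between $M$ (which requires
  $P > 40$) and $H'$ (whose pixels exceed the lowest sweep level, 30);
  both are impossible, and the white/gray-matter ranges
  $[15, b/2]$, $(b/2, b]$ conflict with $M$'s support the same way.
  The exclusion equations are implemented exactly as specified; the
  consequence is that on the phantom (and on any slice without
  mask-boundary artifacts) only skull and hemorrhage render. The
  module-level functions accept arbitrary masks, so the regions behave
  as documented when driven directly.
* **Noise sensitivity of take-all selection.** $H'$ takes every
  nonzero pixel of the selected suspect region. With noise sd 3 HU,
  the cortical band (35 HU, exactly a sweep level) keeps roughly half
  its pixels above level 35, and they all enter $H'$: bleed recall
  stays at 1.0 (median over 20 seeds) but Dice against the bleed falls
  to about 0.27. Denoising or per-component filtering would mitigate
  this but is deliberately out of scope.
* **Boundary counts are tracer-specific.** Only differences between
  consecutive counts matter; absolute counts from other tracers are
  not comparable.
* Single-slice (2D) processing only; no volume aggregation,
  registration or atlas skull stripping. The DICOM reader handles
  uncompressed little-endian single-frame CT objects only.

## Problem sizes

The test suite runs the full pipeline on 128×128 phantoms (single
extraction ≈ 25 ms), the per-pixel equivalence oracle on one hundred
32×32 random grids, and the noise study over 20 seeds; the whole suite
completes in a few seconds.
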