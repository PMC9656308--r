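---
title: "From color-coded Doppler captures to quantitative flow maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From color-coded Doppler captures to quantitative flow maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvflow)
```

## The measurement problem

Microvascular Doppler ("MicroV") modes on intraoperative ultrasound scanners
display slow blood flow as a color overlay inside a rectangular box on the
B-mode frame. The scanner exports the *rendered* frame — an RGB secondary
capture — not the underlying flow estimates. The display scale is ordinal:
the color bar beside the image is divided into levels running from the
highest displayed flow down to no flow. To analyse vascularization
quantitatively (texture statistics, histograms), the display step has to be
inverted: every rendered color must be mapped back to the scale position it
encodes.

`microvflow` implements that inversion and the downstream first-order
radiomic analysis:

1. **Inverse LUT construction** (`build_colormap_from_strip()`): the color
   bar is partitioned into 256 equal segments; segment $i$ (counting from
   the highest-flow end, $i = 0,\dots,255$) is assigned the flow intensity
   $g_i = 255 - i$, so higher flow is always whiter in the output. Each
   segment's representative color is the per-channel mean of its pixels
   (transverse average first). The result is a 256-entry table
   $\{(c_i, g_i)\}$ with $g$ running 255 down to 0.
2. **Retro-conversion** (`retroconvert_mv0()`): a captured pixel with color
   $p$ receives the flow value of the nearest table entry,
   $\hat g(p) = g_{\arg\min_i \lVert p - c_i \rVert^2}$, with distance taken
   in raw 8-bit sRGB channel space.
3. **Grayscale passthrough** (`passthrough_mv2()`): captures made with the
   grayscale display map (MV2: white = 255 = highest flow, black = 0 = no
   flow) are already quantitative and pass through unchanged; chromatic
   input is rejected rather than silently matched.
4. **First-order features** (`extract_roi()`, `first_order_features()`):
   area, mean, standard deviation, minimum, maximum, mode with count, and
   the full 256-bin histogram over a rectangular selection.

## Design choices where the procedure is underdetermined

Several details of the inversion are not fixed by the procedure itself; the
package makes each one explicit and configurable.

**Color distance.** Squared Euclidean distance in raw sRGB channel values.
The LUT is defined by the display's raw RGB values, so matching happens in
the same space; a perceptually uniform space (CIELAB etc.) would change
results without a justification grounded in the rendering chain.

**Tie-breaking.** An exact distance tie resolves to the *larger* gray value
(higher flow). Any fixed rule would do; this one is deterministic and
conservative toward detecting flow, and it falls out of the storage order
(entries sorted gray-descending, first minimum wins). Because all inputs and
table entries are integer-valued, tie comparisons are exact in double
arithmetic, never approximate.

**Segment representative.** Mean of the segment's pixels, which is robust to
the antialiasing present along real scale bars; `stat = "median"` is
available. When the strip length is not divisible by 256, segment boundaries
are placed at $\lfloor nL/256 \rfloor$ so segment lengths differ by at most
one pixel.

**Scale orientation.** Always an explicit parameter (`high =` in
`scale_strip()`). Auto-detecting which end of the bar is the highest flow
would silently flip the entire flow semantics on an unfamiliar colormap.

**Background handling.** The overlay sits on an achromatic B-mode
background. Chroma — $\max(R,G,B)-\min(R,G,B)$ — is 0 for gray pixels, so a
threshold on chroma classifies overlay vs background. Two policies are
offered: `"nearest"` (default) pushes every pixel through the LUT, which
reproduces an unconditional whole-frame LUT application; `"zero"` assigns
flow 0 to achromatic pixels, which is the physically interpretable choice
because background pixels carry no Doppler information. Neither is claimed
to be *the* canonical behavior; the chroma mask is returned either way so
the caller can condition statistics on it. Note that pure white and pure
black are achromatic by this definition, so under `"zero"` a map whose
extreme entries are white/black will have those levels zeroed; the
packaged maps only expose this at flow 255.

**Statistics conventions.** The standard deviation uses the population
convention ($\div N$) by default, with `stdev = "sample"` exposed; the
difference is material only for tiny ROIs. Mode ties resolve to the lowest
intensity and are flagged in the record (`mode_tie`), a deterministic rule
conservative toward low flow. All ROI pixels enter the statistics; the
chroma mask is *not* applied implicitly. Area is reported in px² and
additionally in mm² when pixel spacing is available (e.g. from DICOM
calibration); no attempt is made to reproduce any vendor-specific area
formatting.

**ROI geometry.** Pixel coordinates are 0-based, row-major, origin top-left,
and every box is the half-open region $[x_0,x_1)\times[y_0,y_1)$; `inset`
shrinks the box symmetrically, which is how the one-pixel outline the
scanner draws around the color box is excluded from analysis.

## The MV0 fixture is synthetic

The chromatic (MV0-style) color table of any given machine is
vendor-specific and not published in a form this package could ship.
`builtin_colormap("MV0")` therefore rebuilds its LUT from a *synthetic*
scale strip bundled at `inst/extdata/mv0_synthetic_strip.csv`: a 512-pixel
"hot"-style ramp (black → red → yellow → white) whose 256 rounded colors are
pairwise distinct. Injectivity is what makes encode → retroconvert the exact
identity, which the tests rely on. For bit-exact work on real captures,
rebuild the LUT from your own machine's scale bar with
`build_colormap_from_strip()` — the whole point of the strip-based
constructor is that any machine's displayed scale defines its own inverse
LUT.

## What the phantom generator emulates

`generate_phantom()` produces a frame with the geometry the pipeline
expects: an achromatic speckle background (Gaussian gray, clipped to 0–255,
chroma exactly 0), a rectangular color box whose interior is a known flow
field encoded through a colormap, a one-pixel achromatic outline on the box
border, and a 256-pixel color-scale bar along the right edge (highest flow
at the top) that reproduces the encoding map exactly when cropped with
`crop_scale_bar()`.

The flow field inside the box is built from vessels drawn as random-walk
polylines with Gaussian transverse profiles: vessel $k$ has a peak amplitude
$a_k \sim U(a_{\min}, a_{\max})$ and thickness $t_k \sim U(t_{\min},
t_{\max})$ (the Gaussian $\sigma = t/2$, stamped to $3\sigma$); the field is
the pixelwise maximum over vessels, and centreline pixels carry exactly
$a_k$ so peak recovery can be asserted without tolerance. A connected
necrotic region, grown by randomized flood fill to the requested fraction of
the box, forces flow to 0 — emulating the avascular core of a necrotic
tumor, with the hypervascular tissue around it.

Defaults: 512 × 384 frame, a 220 × 172 px box (≈38k analysed pixels, the
order of magnitude of a clinical ROI), 8 vessels, amplitudes 40–254,
thickness 2–6 px, speckle mean 60 / sd 18, necrotic fraction 0.15. All
randomness derives from `spec$seed` through one generator whose state is
saved and restored, so the same spec is bit-reproducible and never perturbs
the caller's RNG.

**What the phantom does not emulate** — and hence what passing tests do and
do not show. It contains no Doppler physics (no aliasing, wall filter,
angle dependence, PRF effects), no scan-conversion geometry, no compression
artifacts, and its background chroma is exactly 0 rather than the small
nonzero chroma of video-compressed clinical captures
(`speckle_chroma_jitter` exists to stress the threshold logic, not to model
it). Tests passing on phantoms therefore demonstrate that the *software
inversion chain is lossless and correct*, not that retro-converted clinical
intensities are calibrated flow velocities — the scale is ordinal 0–255 by
construction.

## Numerical notes

- Nearest-color matching is vectorised as
  $\lVert p-c\rVert^2 = \lVert p\rVert^2 - 2\,p\!\cdot\!c + \lVert
  c\rVert^2$ over unique pixel colors in chunks of 16,384, so whole frames
  convert in milliseconds and memory stays bounded; all quantities are
  integer-valued doubles, so the arithmetic (and therefore tie detection) is
  exact.
- 8-bit TIFF I/O goes through values in $[0,1]$; `round(x \cdot 255)`
  recovers the stored integers exactly, which the round-trip tests assert.
- Degenerate inputs error early with the violated constraint in the message:
  strips shorter than 256 px, ROIs empty after insetting, chromatic input to
  the grayscale passthrough (reporting the offending pixel fraction),
  non-256-entry maps.

## Validation harness and problem sizes

`recover_parameters_check()` runs the full pipeline — retro-conversion, ROI
extraction at inset 1, first-order features — and compares every statistic
against the same statistics on the ground-truth grid over the pixels
classified as colored; for injective integer maps every discrepancy is
exactly zero. The test suite asserts this over multiple seeds, checks the
nearest-entry and statistics implementations against brute-force oracles
(exhaustive 256-entry search; direct summation), and exercises round trips
over all 256 flow levels. The bundled validation runs use 10,000 random
colors for the matching oracle, 100 random ROIs up to 32 × 32 for the
statistics oracle, 50 random 32 × 32 images plus the full level ramp for
round trips, and 20 default-sized phantoms for end-to-end recovery.

## Known limitations

- Multi-frame (cine-loop) DICOM clips are not read; export single frames.
- The DICOM reader covers uncompressed 8-bit explicit/implicit-VR
  little-endian secondary captures (RGB, YBR_FULL, MONOCHROME2); compressed
  transfer syntaxes are rejected with a clear error.
- Retro-converted intensities are ordinal display levels, not velocities;
  comparisons across machines or depth settings require identical display
  settings.
- Off-scale colors (annotations, measurement calipers burned into the
  capture) are matched to the nearest scale color like any pixel; the
  reported matching distance is the tool for filtering them.
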