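---
title: "Methods: simulating and quantifying a three-species microbial community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying a three-species microbial community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microswarm)
```

# The system and the measurement problem

`microswarm` quantifies the motion of a three-member synthetic microbial
community — *Phytophthora* zoospores, *Vorticella* ciliates and enteric
bacteria — filmed in a shallow microfluidic chamber while a potassium
gradient spreads from a lateral point source. The three species differ
strongly in size and behavior:

* **zoospores** (equivalent radius ~5–9 µm) swim fast (the dominant mode
  of their mean-speed distribution is 100–200 µm/s), avoid high
  potassium (negative chemotaxis), and **encyst** — shed their flagella
  and stop permanently — where the concentration is too high;
* ***Vorticella*** (radius ~11–18 µm) occur as sessile stalked
  trophonts, whose oral cilia drive a feeding vortex that drags nearby
  bacteria, and as fast free-swimming telotrochs (mostly above
  400 µm/s) with an elongated (~2:1) body;
* **bacteria** (radius ~1–2 µm) move slowly (up to ~28 µm/s) by a noisy
  run, and are advected by the *Vorticella* feeding currents.

The measurement pipeline is the classic mask-detector/tracker chain:
binarize each 8-bit frame, detect spots as connected components with
morphometrics, assign each spot to a species by its equivalent radius,
link spots of one species across consecutive frames with a
nearest-neighbor tracker under a per-species maximal linking distance,
compute per-track motion metrics, and compare named grid-cell
microenvironments with one-way ANOVA plus Sidak post hoc tests.

Because the raw movies are not distributable, the package includes an
agent-based scene generator that emulates the three behaviors and
renders 8-bit grayscale stacks with exact ground truth, so that every
pipeline stage can be verified end to end.

# The synthetic scene generator

## Chamber, gradient, and units

The imaged field defaults to 1000 × 800 µm at 1.3 µm/pixel, with frames
0.0735 s apart and 143 frames per sequence. All user-facing coordinates
are micrometres with the origin at the top-left corner and y pointing
down; frames are numbered from 1.

The potassium bolus is modeled by the closed-form planar point-source
kernel

$$C(\mathbf{x}, t) = \frac{M}{4\pi D\,t_\mathrm{eff}}
  \exp\!\left(-\frac{\lVert\mathbf{x}-\mathbf{x}_0\rVert^2}
  {4 D\,t_\mathrm{eff}}\right),
  \qquad t_\mathrm{eff} = t + t_0,$$

with the source at the mid-point of the top edge. Since imaging starts
five minutes after the bolus, the pre-diffusion offset defaults to
$t_0 = 300$ s (which also keeps the kernel regular at $t = 0$). The
diffusion coefficient ($D = 1000$ µm²/s by default) and the released
amount ($M$, arbitrary units) are not known quantitatively for the
original experiment; only the qualitative gradient behavior matters, so
both are exposed as configuration with documented defaults.
Concentrations and gradients are evaluated analytically at agent
positions — no grid interpolation error enters the dynamics.

## Agents

Agent counts are drawn from the community calibration of 200 : 10 :
2000 cells/µl (zoospores : *Vorticella* : bacteria), converted to
per-field counts through the imaged volume (field area × 400 µm chamber
depth; the default field holds 0.32 µl, hence 64, 3 and 640 agents).
Speeds and body radii are drawn uniformly from per-species ranges;
positions and headings are uniform.

* **Zoospores** follow a run-and-tumble walk: baseline tumbles at 0.5/s
  draw a fresh uniform heading; chemotactic reorientations fire at rate
  `chemotaxis_strength` × max(0, alignment with the up-gradient
  direction) and point the cell *down*-gradient (plus 0.4 rad of
  heading noise), so with strength 0 the walk is exactly unbiased — a
  property the tests exploit. Where the local concentration exceeds the
  encystment threshold the cell switches permanently to an immobile
  encysted state. The threshold defaults to the concentration contour
  that encloses the top 20% of the field area at the start of the
  sequence, since no dose–response is available; the bias strength
  (default 2/s) is likewise a free parameter chosen to give a clear but
  not caricatured avoidance drift.
* **Free *Vorticella*** swim ballistically at 400–600 µm/s with a
  sinusoidal heading perturbation (amplitude 1.5 rad/s, period 1.2 s,
  random phase), ignoring the gradient, and are rendered as 2:1
  ellipses aligned with the heading.
* **Bacteria** combine self-propulsion at 2–18 µm/s with rotational
  diffusion (2 rad²/s) and the local vortex advection. Each sessile
  *Vorticella* generates a solid-body-rotation core (radius 30 µm)
  with 1/r decay outside it, truncated at a 450 µm influence radius —
  the simplest flow reproducing closed circular trajectories around the
  trophont; the circulation scale (540 µm²/s, peak tangential speed
  18 µm/s) is deliberately conservative relative to published feeding
  current speeds. The advection term is integrated with a midpoint
  rule so that passive tracers orbit at constant radius instead of
  spiralling outward under forward Euler.

Walls reflect (a closed chamber), sessile and encysted agents never
move, and a single seeded RNG drives every stochastic choice, so a
configuration reproduces its stack bit for bit.

## Rendering

Bodies are drawn dark (intensity 40) on a bright background (200),
matching the bright-field convention the binarization expects; Gaussian
noise (default SD 8) is added and clipped to [0, 255]. At the default
noise level and thresholds the noise never flips a body/background
pixel (the margin is ~19 SD), which is intentional: it makes
segmentation effectively deterministic while still exercising the
8-bit pathway. Bodies smaller than one pixel (possible for the smallest
bacteria at 1.3 µm/px) are clamped to one pixel. Overlapping bodies
merge into single blobs — deliberately so, since merged detections are
a real feature of the imaging being emulated; their effect is
quantified, not hidden (see *Evaluation conventions*).

# Segmentation and morphometrics

Frames are thresholded (working band 100–118, values outside it warn),
and spots are connected components under 8-connectivity (diagonal
pixels merge, the mask-detector convention; 4-connectivity is
available). Morphometrics per spot:

* area = pixel count × pixel size²; equivalent radius = √(area/π);
* perimeter by the 4-direction Crofton estimator,
  $P = \tfrac{\pi}{8}\left(h + v + (d_1 + d_2)/\sqrt{2}\right)$,
  counting boundary transitions along rows, columns and both diagonals
  — raster perimeters are estimator-dependent, so tests use tolerances
  rather than exact equality;
* circularity = 4π·area/perimeter², clipped to ≤ 1 (≈1 for disks,
  < 0.5 for 5:1 ellipses, separating sessile from telotroch
  morphologies);
* quality = pixel count, a monotone stand-in for detector confidence;
  the permissive default threshold of 1 keeps single-pixel bacteria.

No contour simplification is applied anywhere, and border-touching
components are kept but flagged; whether the original analysis excluded
them is unknown, so exclusion is left to the caller.

# Species partition

Spots are classified purely by equivalent radius. The published filter
scheme gives threshold *ranges* (bacteria below 2–4.5 µm, *Vorticella*
above 10–13.5 µm, zoospores between); a pipeline needs one resolved
value per boundary, so the defaults are 4.5 µm and 10 µm with upper
bounds inclusive (a 4.5 µm spot is a bacterium, a 10 µm spot a
zoospore) and everything configurable. Radii falling in a configured
gap map to an explicit `unassigned` bucket rather than being silently
dropped, and the partition is checked to be exhaustive and exclusive.
Partition precedes tracking, so each species is tracked with its own
maximal linking distance.

# Tracking

Within one species, spots of consecutive frames are linked by greedy
nearest-neighbor assignment: candidate pairs closer than the species'
maximal linking distance (defaults 15 µm for zoospores, 60 µm for
*Vorticella*, 2 µm for bacteria) are accepted in ascending distance
order, ties broken by the lower spot id, yielding a deterministic
one-to-one matching. On sparse instances this equals the exhaustive
minimum-sum assignment (tested); in general a greedy maximal matching
can differ from the global optimum, which is the accepted behavior of
classic nearest-neighbor trackers. There is no gap closing, splitting
or merging. Note the feasibility identity: a species' maximal linking
distance divided by the frame interval caps the measurable speed
(15/0.0735 ≈ 204 µm/s for zoospores, just above their fastest observed
mean speeds).

Unlinked spots become singleton tracks — retained and counted as
non-motile candidates, but excluded from metric analysis.

# Motion metrics

For a track with $n$ links and positions $\mathbf{p}_1 \dots
\mathbf{p}_{n+1}$:
total path $L = \sum \lVert \mathbf{p}_{i+1}-\mathbf{p}_i \rVert$, net
displacement $N = \lVert \mathbf{p}_{n+1}-\mathbf{p}_1 \rVert$, mean
speed $L/(n\,\Delta t)$ (total path over elapsed time — identical to
the mean of instantaneous speeds at uniform $\Delta t$), confinement
ratio $N/L \in [0,1]$, defined as 0 for a zero-length path (the
degenerate limit of "confined"). Motility classes: zoospores below
10 µm/s are non-motile (encysted/deflagellated); *Vorticella* below
20 µm/s are sessile, otherwise telotrochs, with strict `<` on the slow
side; bacteria have no established dichotomy.

# Microenvironment statistics

A square grid (default 170 µm cells) is labeled letter-row ×
number-column from the top-left (A1, A2, …, B1, …). A microenvironment
is a named set of cells, an inclusive 1-based frame range, and a
species. A track belongs to it when its species matches, its frame span
intersects the range, and its mean position falls in the cells (an
any-spot membership rule is available; the mean-position rule makes the
assignment a partition). The statistical unit is the track, with no
correction for repeated cells or agents — a documented simplification
shared with the original analysis.

Comparisons use fixed-effects one-way ANOVA (F = between/within mean
squares via `stats::oneway.test` with equal variances) followed by
pairwise t tests with Sidak adjustment $1-(1-p)^m$ (computed via
`expm1`/`log1p` for accuracy, clipped to [0, 1]). Each condition pair
is treated as its own comparison family, the way replicate-wise pairs
are reported. Degenerate inputs are handled explicitly: groups below 2
observations are refused (ANOVA is unreliable for very small samples),
identical values everywhere are refused, and zero within-group variance
with distinct means yields F = ∞, p = 0.

# Evaluation conventions

Because the generator knows the truth, the package ships explicit
evaluators with carefully chosen denominators:

* **Partition agreement** is measured per detected spot (label vs the
  species of the nearest ground-truth agent). Agents occluded inside a
  merged blob are missed detections, not label errors, and are counted
  separately — conflating the two would charge the classifier for the
  detector's merges.
* **Link recovery** is reported two ways: over *detectable* links
  (both endpoints detected as distinct same-species spots — the
  tracker's own performance, ≳99% at the default densities) and
  *strict* (over all ground-truth links, ~92%, the difference being
  segmentation merge losses). Both numbers are returned; quoting only
  one would either hide the detector's losses or blame them on the
  tracker.
* **Speed recovery** compares the mean reconstructed track speed per
  species against the configured mean. The scene used for this check
  disables chemotaxis, encystment and sessile forms so that measured
  speeds reflect locomotion alone; with encystment on, the recovered
  zoospore mean would mix the stationary encysted mode into the
  comparison, and vortex advection would likewise inflate bacterial
  speeds.

# What the simulator does and does not emulate

It emulates: the three size classes and their radius bands, the
bimodal zoospore speed distribution (swimming vs encysted), negative
chemotaxis with encystment near the source, the sessile/telotroch
dichotomy including body elongation, vortex advection of bacteria with
its 450 µm influence range, merged-blob detections, 8-bit quantization
and background noise.

It does not emulate: 3-D motion and defocus, optical point-spread
functions, illumination gradients, agent–agent hydrodynamics beyond
the vortex advection, flagellar mechanics, cell division or death, or
stalk contraction of sessile *Vorticella* (they are held fixed between
frames). Passing tests therefore validate the *pipeline* — detection,
partition, linking, metrics, statistics — under controlled conditions;
they do not certify segmentation performance on real bright-field
movies, where illumination and focus artifacts dominate.

# Problem sizes and reproducibility

The shipped tests run the full chain on a quarter-scale community scene
(510 × 340 µm, 30 frames), a full-field scene (1000 × 800 µm, 80
frames), a 150-frame locomotion-only scene for speed recovery, and a
143-frame feeding-vortex scene, sizes chosen to keep the whole suite
within a few minutes on one core while leaving thousands of spots and
links per check. Every stochastic stage flows from an explicit seed;
identical configurations reproduce identical stacks, tables and CSVs
byte for byte, and every output table carries a provenance header
(package version, configuration hash, seed).

```{r example, eval = FALSE}
cfg <- chamber_config(field_width = 510, field_height = 340,
                      n_frames = 40, rng_seed = 42)
scene <- simulate_scene(cfg)
spots <- segment_stack(scene$stack, threshold = 110,
                       pixel_size = cfg$pixel_size)
part <- partition_spots(spots)
tracks <- build_all_tracks(part)
metrics <- track_metrics(tracks$zoospore, dt = cfg$frame_interval)
plot_metric_hist(metrics)
```

# Known limitations

* The chemotaxis dose–response and encystment threshold are free
  parameters; only the *directions* of the behavioral effects are
  meaningful, not their magnitudes.
* Greedy nearest-neighbor linking is near-optimal, not optimal, on
  crowded frames; bacteria above ~27 µm/s (step > 2 µm) are by
  construction untrackable at the default linking distance, mirroring
  the real pipeline's feasibility cap.
* Track-level statistics ignore the nesting of tracks within agents
  and cells; p-values on simulated comparisons are anti-conservative
  in proportion to that dependence.
* The quality score is a pixel-count proxy, not a likelihood; it
  exists so the permissive "quality ≥ 1" convention has a concrete
  meaning.
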