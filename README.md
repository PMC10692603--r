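# microswarm

Image-based motion analysis of a three-species synthetic microbial
community — *Phytophthora* zoospores, *Vorticella* ciliates and enteric
bacteria — responding to a potassium gradient in a shallow microfluidic
chamber.

Communities like this are a minimal model of microbially driven soil
processes: a plant pathogen dispersing by chemotactic zoospores, a
suspension-feeding ciliate whose feeding vortex drags bacteria, and the
bacteria themselves. Time-lapse bright-field movies of such a community
contain all three behaviors at once, and the analysis problem is to
take an 8-bit image stack apart into per-species motion statistics.

`microswarm` implements the full measurement chain plus an agent-based
scene generator, so that every stage can be validated against exact
ground truth:

1. **simulate** — agents with species-specific motion models (negative
   chemotaxis + encystment for zoospores; ballistic swimming for free
   *Vorticella*; rotational-diffusion walk plus feeding-vortex
   advection for bacteria) in a diffusing point-source gradient
   `C(x,t) = M/(4πDt)·exp(−|x−x₀|²/4Dt)`, rendered to 8-bit grayscale
   TIFF stacks with ground truth;
2. **segment** — threshold binarization (working band 100–118) and
   connected-component spot detection (8-connectivity) with
   morphometrics: area, Crofton perimeter, circularity
   `4π·area/perimeter²`, equivalent radius `√(area/π)`;
3. **partition** — species assignment by equivalent radius (bacteria
   ≤ 4.5 µm < zoospores ≤ 10 µm < *Vorticella*);
4. **track** — per-species greedy nearest-neighbor linking across
   consecutive frames under maximal linking distances of 15 / 60 / 2 µm
   (zoospore / *Vorticella* / bacterium);
5. **metrics** — per-track mean speed `L/(nΔt)` and confinement ratio
   `net displacement / total path ∈ [0,1]`, with motility classes
   (zoospore non-motile < 10 µm/s; *Vorticella* sessile < 20 µm/s);
6. **microenvironment statistics** — a 170 µm labeled grid (A1, A2, …),
   named cell/frame-range microenvironments, and one-way ANOVA with
   Sidak-adjusted post hoc comparisons between them.

The methods vignette (`vignettes/microswarm-methods.Rmd`) documents the
models, parameter choices and evaluation conventions in detail.

## Worked example

Simulate a quarter-scale community scene at the study densities
(200:10:2000 cells/µl scaled to the imaged volume), run the chain, and
look at the zoospore motility split:

```r
library(microswarm)

cfg <- chamber_config(field_width = 510, field_height = 340,
                      n_frames = 40, rng_seed = 42)
scene <- simulate_scene(cfg)
scene
#> <microswarm_scene> 40 frames, 154 agents (bacterium: 139, vorticella: 1,
#>   zoospore: 14), stack 262 x 392 px

spots <- segment_stack(scene$stack, threshold = 110,
                       pixel_size = cfg$pixel_size)
part <- partition_spots(spots)
part$counts
#>  bacterium   zoospore vorticella unassigned
#>       5277        470         75          0

tracks <- build_all_tracks(part)
m <- track_metrics(tracks$zoospore, dt = cfg$frame_interval)
m$motility <- classify_motility(m)
head(as.data.frame(m)[c("track_id", "n_links", "mean_speed_ums",
                        "confinement_ratio", "motility")], 5)
#>   track_id n_links mean_speed_ums confinement_ratio   motility
#> 1        1      39        122.404             0.206     motile
#> 2        2      24          0.722             0.000 non_motile
#> 3        3      26        190.275             0.407     motile
#> 4        4       8          0.000             0.000 non_motile
#> 5        7      39        159.506             0.409     motile

table(m$motility)
#>     motile non_motile
#>         22          3
```

The mean-speed column shows the characteristic bimodality: swimming
zoospores near their configured 100–200 µm/s band, and stationary
(encysted) cells below the 10 µm/s non-motile threshold with
confinement ratio 0.

A complete run — simulation through microenvironment comparison, with
provenance-stamped CSV outputs — is one call with a YAML configuration
(see `inst/extdata/demo_config.yaml`):

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "microswarm"), "out")
```

or from a shell via the thin CLI wrapper:

```sh
Rscript inst/scripts/microswarm.R run --config inst/extdata/demo_config.yaml --out out
```

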