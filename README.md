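# phasetrack

Automated tracking of migrating cells in **label-free phase-contrast
time-lapse image series**, for biologists quantifying random single-cell
migration, wound-healing (scratch) assays, cells in collagen, and
proliferation — without fluorescent labels and without manual clicking.

Phase-contrast nuclei appear as the darkest structures on a bright
background. `phasetrack` exploits exactly that: it

1. **registers** each frame to its predecessor with sub-pixel precision
   (integer grid search minimising the mean absolute grey difference,
   refined by a 1-D parabola through the cost profile), because incubator
   microscopes revisit well positions with a few pixels of jitter that
   would otherwise masquerade as cell motion;
2. **segments** nuclei by a single grey-level limit after wide Gaussian
   smoothing — either `mean(g) + z·sd(g)` with a user z-score, or an
   automatic background-peak rule — then **cuts touching cells** at paired
   concave boundary points and gates regions by equivalent circular
   diameter `d = 2·sqrt(area/π)`;
3. **links** detections frame-to-frame by greedy least-displacement
   matching (most certain matches first, up to `v_max·Δt`), repairs
   one-frame detection gaps by midpoint insertion, and keeps tracks with at
   least the configured minimum number of observations;
4. **measures** migration per track and per time step:
   - mean step velocity `= accumulated distance / duration` (µm/min)
   - accumulated distance `d_acc = Σ‖xᵢ₊₁ − xᵢ‖` and Euclidean distance
     `d_euc = ‖x_N − x₁‖`
   - directness `D = d_euc / d_acc ∈ [0, 1]`
   - forward migration index `FMIy = Δy / d_acc` (sign-flipped below the
     wound midline in wound mode, so positive always means *into* the wound)
   - the *velocity sum per cell* `‖mean displacement vector‖ / Δt`, a
     misalignment diagnostic that should stay below ~0.1 µm/min in a
     well-aligned series.

A seeded **synthetic video generator** renders Incucyte-like frames (bright
background, dark elliptical nuclei, optional static cross and speckle
artefacts, global jitter, pixel noise) with exact ground-truth
trajectories, so every stage of the pipeline is verifiable without external
data. A **comparison module** matches track sets between methods (15 µm
first-position rule), builds 1 µm-binned distance distributions with a
parabola-vertex mode, and computes Bland–Altman velocity agreement.

Image series are read and written as multi-page TIFF (lossless); results as
plain CSV; figures as ggplot2 objects / PNG.

## Worked example

```r
library(phasetrack)

spec <- synthetic_spec(width_px = 400, height_px = 400, n_frames = 12,
                       n_cells = 30, sigma_step = 2, dt = 10, seed = 42)
gv <- generate_video(spec)

s <- settings(gaussian_radius = 3, segmentation_limit = -1.5,
              shift_correction = FALSE)
run <- track_video(gv$stack, s)
run
#> <phasetrack run: 12 frames, 30 tracks (30 valid), mean velocity 0.238 um/min>

tidy(run)[1:4, c("track", "n_steps", "mean_step_velocity",
                 "accumulated_distance", "euclidean_distance")]
#> # A tibble: 4 × 5
#>   track n_steps mean_step_velocity accumulated_distance euclidean_distance
#> 1     1      11              0.235                 25.8               9.19
#> 2     2      11              0.230                 25.3               4.73
#> 3     3      11              0.178                 19.6               5.53
#> 4     4      11              0.274                 30.1               7.55

evaluate_tracking(run$valid_tracks, gv$truth)
#> switches: 0, mean position error: 0.056 um, full-length: 100%
```

All 30 simulated cells are recovered as full-length tracks with no identity
switches; the population mean velocity, 0.238 µm/min, sits at the Rayleigh
mean of the simulated Brownian motion (σ√(π/2)/Δt = 0.251 µm/min for
σ = 2 µm per 10-min step) up to sampling noise. `glance(run)` returns the
one-row video summary (cell counts, track counts, mean/mode/median
velocity, directness, FMI, the misalignment diagnostic);
`autoplot(run$valid_tracks)` draws trajectories in place or from a common
origin; `write_tables(run, dir)` emits the per-track / per-step / per-frame
/ overall CSVs.

Real series are analysed the same way via
`run_batch(c("well1.tif", ...), load_settings("settings.txt"))`, which
processes every video with identical settings, writes one results folder
per video (including the settings actually used) and a cross-video summary
with one row per video. A thin command-line wrapper lives at
`inst/cli/phasetrack.R` (`run` and `tune` subcommands; `tune` renders one
frame with identified-cell outlines for threshold inspection).

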