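# skelfit

Markerless 3D motion capture for a freely moving macaque, from multi-view
depth cameras to behavioral statistics — with a built-in synthetic test bed
so the whole pipeline runs and validates without hardware.

Attaching tracking markers to a monkey stresses it and distorts exactly the
spontaneous behaviors one wants to measure. The markerless alternative
implemented here reconstructs the animal's surface as a 3D point cloud (a
"hull") by merging four calibrated depth cameras around the cage, and fits
an articulated skeleton model — 23 spheres $S_1 \dots S_{23}$ connected by
22 joints with anatomical bend limits — into the hull in every video frame
by a physics-style force simulation run to steady state:

* attraction toward unclaimed nearby surface points,
  $f^a_i = \alpha\, m_i \sum_j a_j\,(P_j - S_i)$, where $a_j$ gates on the
  attraction region $A_i$ and on every other sphere's claim region $B_k$;
* repulsion confining spheres inside the hull,
  $f^r_i = \beta\, m_i \sum_j r_j\,(S_i - P_j)/\lVert S_i - P_j\rVert$,
  gated on proximity $C_i$ and the camera-oriented surface normal
  ($N_j \cdot (P_j - S_i) > 0$);
* a face-color attraction pinning the jaw sphere to the red face patch,
  $f^{ah} = \gamma\, m_1 \sum_j f_j\,(P_j - S_1)$, gated on an HSV red
  window and a ball around the head sphere.

Each frame's converged pose initializes the next (with a reproducible
file/callback correction interface replacing interactive fixes), traces are
loess-smoothed (0.5 s window), and the trajectories feed rule-based
detectors for bar-crossing, jumping and crawling plus kinematic parameters
(path length, walking speed, head-rotation speed while crouching). A
virtual four-camera rig and an articulated phantom with scripted gaits
generate ground-truthed depth/color video for testing everything above.

## A worked example

Render a two-second stand-then-walk clip through the virtual rig, track it,
and summarize:

```r
library(skelfit)
library(dplyr)

model   <- default_model()
phantom <- skf_phantom(model)
script  <- motion_script(list(seg_stand(1), seg_walk(1, speed = 0.3)),
                         start_x = -0.3)
seq1 <- render_sequence(phantom, script, default_cameras(),
                        noise_sd_mm = 5, seed = 1)
#> <skf_sequence> 54 frames (2.0 s at 26.7 fps), 4 cameras, depth noise 5.0 mm

traj   <- track_sequence(seq1, model, init = filter(seq1$gt, frame == 1))
smooth <- smooth_trajectory(traj, window = 0.5)

glance(traj)
#> # A tibble: 1 x 6
#>   n_frames duration_s   fps fraction_converged n_corrected_frames ...
#> 1       54       1.99  26.7                  1                  0

kinematic_summary(smooth)
#> # A tibble: 1 x 9
#>   total_path_length_cm mean_walking_speed_cm_s mean_walking_speed_cm_min ...
#> 1                 28.7                    14.4                      865.

estimation_error(smooth, seq1$gt)
#> # A tibble: 24 x 6
#>   part       sphere metric    mean    sd unit
#> 1 jaw             1 position  3.18 0.186 cm
#> 2 neck            2 position  3.97 0.195 cm
#> 3 head            3 position  3.54 0.291 cm
#> ...
```

Every frame converged with no manual corrections; the chest traveled
28.7 cm (the walk covers 0.3 m at 0.3 m/s with posture blending), and the
tracked landmarks sit 2.5 cm (mean over all spheres) from the scripted
ground truth under 5 mm depth noise. `autoplot(smooth)` draws the part
heights against the behavioral thresholds, `plot_events()` draws detected
event chronograms, and `plot_pose()` shows a fitted skeleton inside its
cloud.

For file-based workflows, `write_sequence()` materializes a rendered
sequence as 16-bit depth TIFFs + color PNGs + JSON manifest,
`run_pipeline()` executes track → smooth → detect → summarize with run
metadata (config hash, seed, convergence and correction statistics), and
`inst/cli/mocap.R` exposes `simulate` / `fit` / `track` / `analyze`
subcommands.

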