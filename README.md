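# sptseg — diffusion-mode segmentation of single-particle trajectories

`sptseg` segments 2-D single-particle-tracking (SPT) trajectories into
**Brownian**, **confined** and **directed** portions and reports each
portion's diffusion parameters. It is aimed at membrane biophysicists who
track single molecules or particles (proteins, viruses, quantum dots) in
live-cell movies and need per-segment — not per-trajectory — motion
analysis of hundreds of tracks at a time.

## Method in brief

The local motion mode is read off the *shape* of the mean square
displacement (MSD) curve. For a 2-D track sampled at interval $\delta t$,

$$\mathrm{MSD}(n\,\delta t) = \frac{1}{N-1-n}\sum_{j=1}^{N-1-n}
\left[x((j{+}n)\delta t)-x(j\delta t)\right]^2 +
\left[y((j{+}n)\delta t)-y(j\delta t)\right]^2,$$

which is linear in lag for free diffusion ($4D\Delta t$), gains an upward
curvature under drift ($4D\Delta t + V^2\Delta t^2$) and saturates under
confinement ($\tfrac13 L^2[1-e^{-12D\Delta t/L^2}]$).

A sliding window of $S_1 = 31$ frames is moved one frame at a time; each
window's normalized MSD curve (29 lags, scaled to $[0,1]$) is classified
by a three-layer back-propagation neural network (29–5–3 nodes, sigmoid
activations) trained on simulated single-mode windows, and the three
outputs $(O_B, O_C, O_D)$ are averaged over all windows covering each
frame. Detection thresholds $Y_C(k), Y_D(k)$ are calibrated on 100 pure
Brownian null trajectories so that falsely flagged frames stay below 5%
per mode for every run length $k \in [5, 45]$; a confined or directed
segment is a run of consecutive frames exceeding the calibrated
threshold for its length. Reported segments are finally re-fitted with
the matching MSD model to give per-segment $D$, plus $L$ (confinement
diameter) or $V$ (drift speed).

Everything runs on synthetic data: the package ships the trajectory
simulator used for training, calibration and validation (Brownian walks
with steps $\mathcal N(0, 2D\tau)$ per axis, circular-domain confinement,
constant drift, optional static localization noise, and labelled
composites).

## Worked example

Simulate a 30-second track (100 ms/frame, $D = 0.25\,\mu m^2/s$) that is
freely diffusing except for a 5-second confinement in a 1-µm domain, then
segment it with the packaged pre-trained model:

```r
library(sptseg)

traj <- simulate_composite(list(
  list(mode = "Brownian", length = 125),
  list(mode = "confined", length = 50, L = 1.0),
  list(mode = "Brownian", length = 125)), D = 0.25, tau = 0.1, seed = 3)

result <- segment_trajectory(traj, default_model(), default_thresholds())
print(result)
```

```
<spt_segmentation> 300 frames -> 3 segments (mixed)
      mode start_frame end_frame n_frames duration_s  V         L         D
1 Brownian           0       123      124       12.4 NA        NA 0.2693375
2 confined         124       165       42        4.2 NA 0.7764423 0.3512718
3 Brownian         166       299      134       13.4 NA        NA 0.2580578
```

The confinement (true frames 125–174) is reported between 12.4 s and
16.5 s with a fitted diameter of 0.78 µm, and the Brownian flanks recover
apparent diffusion coefficients ($D_{1\text{–}4}$) of 0.27 and
0.26 µm²/s against the simulated 0.25. The trajectory is classified
`mixed` (more than one mode present). `result$probs` holds the per-frame
mode probabilities if you want to plot the decision trace.

To retrain from scratch instead of using the packaged model:

```r
dat <- build_training_data(1000, window = 31, seed = 11)
net <- bpnn_train(bpnn_new(29, 5, 3, seed = 12), dat$train, dat$validation,
                  seed = 13)
th  <- calibrate_thresholds(net, seed = 14)
```

A command-line front end with `simulate`, `train`, `calibrate`, `segment`
and `experiment` subcommands lives at `inst/cli/sptseg.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","sptseg.R",package="sptseg"))') simulate --help`).

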