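# gaitfuse

Skeleton-based pathological gait recognition in R. `gaitfuse` takes
per-frame 3-D joint positions of a walking person (an Azure-Kinect
style skeleton) and classifies the walk as normal or as one of five
simulated pathological patterns (antalgic, steppage, lurching,
stiff-legged, Trendelenburg), or as healthy vs. vestibular-disorder-
like in a binary setting. It is aimed at movement-analysis
researchers who want a fully inspectable, dependency-light reference
implementation of a hybrid multi-input gait classifier, together with
a kinematic simulator that makes every stage testable without
clinical data.

## The model

One walk is represented three ways, each encoded by an architecture
suited to it, and the features are fused:

* raw skeleton sequence `X ∈ R^{3×T×N}` → spatial-temporal graph
  convolutional network (ST-GCN; 10 blocks, kernel (9, 3), 3-subset
  spatial partitioning rooted at the pelvis) → `f_S ∈ R^64`;
* 25 per-frame joint angles (6 bending angles θ_α by the law of
  cosines at hips/knees/ankles; link angles φ_l = ∠(v_m − v_n, u_axis)
  for thigh/shank/foot about x, y, z and the trunk about x) →
  4-layer LSTM (hidden 128) → `f_A ∈ R^16`;
* 26 gait parameters x_P (step length, asymmetry 2|L−R|/(L+R), step
  width, speed; stance/swing times per leg from coordinate-based
  heel-strike/toe-off detection; mean/min/max of spine and lower-limb
  angles, divided by 100) → one ReLU layer → `f_P ∈ R^16`.

`y = softmax(W_y · [f_S; f_A; f_P] + b_y)` after batch norm and
dropout 0.5; training minimizes cross-entropy + (λ/2)‖W‖² with Adam
(batch 50, early stopping). The whole network — graph/temporal
convolutions, LSTM backpropagation through time, batch norm, Adam —
is implemented in the package (C++ kernels via RcppArmadillo), with
gradients verified against numeric differentiation in the tests.

## Worked example

```r
library(gaitfuse)

# simulate one antalgic walk (left side affected) and recover its
# gait parameters
walk <- simulate_walk(gait_style("antalgic", affected_side = "L"),
                      subject_profile("S01", seed = 1),
                      n_frames = 110, fps = 30, seed = 42)
round(extract_gait_parameters(walk$sequence)[1:8], 3)
#>       avg_step_length step_length_asymmetry            step_width
#>                 0.430                 0.221                 0.121
#>         walking_speed         stance_time_L         stance_time_R
#>                 0.830                 0.533                 0.683
#>          swing_time_L          swing_time_R
#>                 0.600                 0.467
```

The left (affected) leg shows the antalgic signature: shorter stance
(0.53 s vs 0.68 s), a shorter step on the affected side (asymmetry
0.22), and the commanded walking speed (0.831 m/s) is recovered to
0.1 %. Binary metrics come straight from confusion
counts:

```r
round_display(binary_metrics(TP = 231, FP = 11, TN = 53, FN = 17))
#>    accuracy sensitivity specificity   precision
#>       91.03       93.15       82.81       95.45
```

The standard benchmark — 6 subjects × 6 gait classes × 5 walks,
mirrored to 360 examples, leave-one-subject-out, reduced model,
30 epochs — trains each branch alone and all three together:

```r
res <- standard_benchmark(seed = 1)
res$table
#>                   inputs n_inputs accuracy mean_fold_acc sd_fold_acc
#> 1                 params        1 93.61111      93.61111    14.07980
#> 2                 angles        1 44.72222      44.72222    12.08381
#> 3               skeleton        1 86.66667      86.66667    15.74096
#> 4 params+angles+skeleton        3 96.38889      96.38889     8.84538
```

Fusing the three inputs beats every single-input configuration
(96.4 % pooled LOSO accuracy), the direction the model is designed to
demonstrate.

## Command line

```sh
Rscript -e 'gaitfuse::gaitfuse_cli()' simulate --out data/ --subjects 12 --walks 20 --seed 1
Rscript -e 'gaitfuse::gaitfuse_cli()' extract  --manifest data/manifest.csv --out features/
Rscript -e 'gaitfuse::gaitfuse_cli()' train    --manifest data/manifest.csv --small --epochs 30 --out model.json
Rscript -e 'gaitfuse::gaitfuse_cli()' evaluate --manifest data/manifest.csv --small --protocol loso --epochs 30
Rscript -e 'gaitfuse::gaitfuse_cli()' metrics  --tp 231 --fp 11 --tn 53 --fn 17
```

## Documentation

The methods vignette (`vignettes/gaitfuse-methods.Rmd`) documents the
model, the gait-parameter definitions, the simulator's stated world
and its limits, and every numerical choice.
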