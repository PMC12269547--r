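# difftrack

Pointwise inference of heterogeneous protein diffusion from 2-D
single-particle-tracking trajectories.

Proteins imaged in cells rarely diffuse homogeneously: they bind and
unbind, enter compartments, get trapped, and dimerize. A single
diffusion coefficient fitted to a whole track hides all of that.
difftrack targets the per-frame view: given noisy coordinates
$x(t), y(t)$ of one particle (20–200 frames), it infers at **every
frame** the generalised diffusion coefficient $K$, the anomalous
exponent $\alpha$, and a discrete behavioural state
$s \in \{$immobile, confined, free, directed$\}$, and then detects the
changepoints where any of them switch. It is aimed at single-molecule
biophysicists who want segment-resolved diffusion parameters without
hand-tuned MSD thresholding.

## The model in brief

Trajectories are fractional Brownian motion with piecewise-constant
parameters and mean square displacement

$$\mathrm{MSD}(t) = 4Kt^{\alpha}, \qquad H = \alpha/2 ,$$

simulated exactly via Davies–Harte synthesis of fractional Gaussian
noise under five biological scenarios (single-state, multi-state
Markov switching, quenched traps, transient confinement, dimerization).
Ten per-frame features (normalised coordinates, displacement from the
origin, step lengths, turning angle, two straightness measures, and
log-differences) feed three stacked bidirectional LSTM blocks with skip
connections and layer normalisation (~514k parameters per variable,
implemented natively in RcppArmadillo with full backpropagation — no
external deep-learning runtime). One network is trained per variable
with masked per-trajectory losses (MAE for $\alpha$; MAE in
$\log_{10}(K{+}1)$ space for $K$; class-weighted NLL for $s$).
Predicted series are smoothed and segmented by exact penalized
least-squares changepoint detection (PELT, penalty 0.3, minimum
segment 3 frames); per-variable changepoint sets are merged around the
$K$-derived anchors. Detection quality is scored by a tolerance-gated
Hungarian pairing: Jaccard index $TP/(TP{+}FN{+}FP)$ and the RMSE of
paired changepoints. The methods vignette
(`vignettes/difftrack-methods.Rmd`) covers every design choice.

## Worked example

```r
library(difftrack)
set.seed(7)

# train a small K labeller on single-state tracks (desk scale)
train <- lapply(1:800, function(i)
  simulate_ssm(sim_config("SSM", T = sample(20:60, 1),
                          K_range = c(0.01, 1e3))))
m <- train_model(train[1:700], train[701:800], "K",
                 config = train_config(epochs = 2), verbose = TRUE)
#> epoch 1: train 0.9070 val 0.4804 lr 1.0e-03
#> epoch 2: train 0.3529 val 0.2984 lr 1.0e-03

# a 200-frame trajectory whose diffusivity jumps 40-fold at frame 100
tr <- simulate_two_segment(alpha1 = 1, K1 = 0.5, alpha2 = 1, K2 = 20,
                           T = 200)
tr$changepoints
#> [1] 100
round(k_to_log(unique(tr$K)), 3)     # true log10(K+1) levels
#> [1] 0.176 1.322

# per-frame inference + smoothing + PELT changepoint detection
pred <- infer_tracks(list(K = m), list(tr), seg_params(cp_vars = "K"))[[1]]
round(c(mean(pred$logK[1:100]), mean(pred$logK[101:200])), 2)
#> [1] 0.52 1.87
pred$changepoints
#> [1]  69 103 133 155

pr <- pair_changepoints(tr$changepoints, pred$changepoints)
c(jaccard = jaccard(pr), rmse = cp_rmse(pr))
#> jaccard    rmse
#>    0.25    3.00
```

After two epochs the labeller separates the two diffusivity levels
(predicted segment means 0.52 vs 1.87 in log10(K+1) space, true levels
0.176 and 1.322) and PELT recovers the switch 3 frames off its true
position — a true positive under the 5-frame tolerance, so the
changepoint RMSE is 3. The three spurious detections are what drag the
Jaccard index to 1/(1+0+3) = 0.25; they shrink with training, as the
predicted series flattens within segments (see the methods vignette).

## Command line

A thin CLI over the same functions lives at `inst/scripts/difftrack`
(installed under `system.file("scripts", "difftrack")`):

```sh
difftrack simulate --out data --scale-factor 2e-4 --seed 1
difftrack train    --data data --variable alpha --out alpha.rds
difftrack predict  --data data --checkpoint-alpha alpha.rds --out preds
difftrack evaluate --data data --checkpoint-alpha alpha.rds --out metrics.json
```

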