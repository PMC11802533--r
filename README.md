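# perfdiff

Conditional diffusion super-resolution for dynamic contrast-enhanced
(first-pass) myocardial perfusion MRI.

## The problem

Perfusion MRI must balance spatial resolution, temporal resolution and
slice coverage: every extra phase-encoding line costs acquisition time
inside a narrow cardiac window. Acquiring only the central 30–50% of
phase-encoding lines is 2–3× faster — enabling more slices per heartbeat
and finer temporal sampling — but yields blurred images with
Gibbs-ringing artifacts along the phase-encoding axis. `perfdiff`
restores the lost spatial detail generatively: a denoising diffusion
probabilistic model (DDPM), conditioned on the low-resolution (LR)
frame, samples a high-resolution (HR) frame from the learned conditional
distribution *p(y | x)*. Each frame is processed independently, so frame
timing — and with it the signal–time curves used for perfusion
assessment — passes through unchanged.

The package is aimed at MR-physics and image-reconstruction researchers
who want a fully inspectable, CPU-runnable implementation of the whole
pipeline: data synthesis, degradation modelling, training, sampling and
evaluation.

## The model

Forward (noising) process with retention schedule $\alpha_t$,
$\gamma_t = \prod_{i\le t}\alpha_i$:

$$q(y_t \mid y_0) = N\big(\sqrt{\gamma_t}\,y_0,\ (1-\gamma_t) I\big)$$

A conditional U-Net $f_\theta(x, y_t, \gamma_t)$ (two input channels: LR
frame + noisy frame) is trained to predict the injected noise with an L1
objective, and sampling iterates

$$y_{t-1} = \tfrac{1}{\sqrt{\alpha_t}}\Big[y_t -
\tfrac{1-\alpha_t}{\sqrt{1-\gamma_t}}\,f_\theta(x, y_t, \gamma_t)\Big] +
\sqrt{1-\alpha_t}\,\epsilon_t$$

from pure noise $y_T$ down to $t=1$. LR/HR training pairs are
synthesized by k-space phase-line truncation (FFT → keep the central
`round(fraction × N_pe)` lines → zero-pad → inverse FFT → magnitude).
The full-scale network (five levels, channels 64–128–256–512–512,
bottleneck self-attention) has 91M parameters; since no deep-learning
framework exists for R, forward, backprop and AdamW are implemented
directly in C++ (single precision, im2col + GEMM), with analytic
gradients verified against finite differences in the test suite.

Because clinical perfusion data are private, the package ships a
synthetic short-axis phantom (RV pool, LV pool, myocardial annulus, each
following a gamma-variate bolus with physiological peak ordering
RV → LV → myocardium) that stands in for patient data in every test and
experiment. See `vignettes/perfdiff-methods.Rmd` for the full method
description and its limitations.

## Worked example

```r
library(perfdiff)

# a dynamic phantom series and a paired training example
ser  <- generate_series(phantom_config(matrix_size = 32L, n_frames = 40L))
pair <- make_lr_hr_pair(ser$frames[20, , ], fraction = 0.35,
                        crop_size = 32L, norm_max = max(ser$frames))
round(c(nrmse_pct = 100 * nrmse(pair$x, pair$y0),
        psnr_db   = psnr(pair$x, pair$y0),
        ssim      = as.numeric(ssim(pair$x, pair$y0))), 2)
#> nrmse_pct   psnr_db      ssim
#>      5.89     24.59      0.93

# protocol arithmetic: nominal acceleration of a 35% phase-resolution
# acquisition combined with parallel imaging
nominal_acceleration(3, 0.35)   # GRAPPA-3 -> 8.571429-fold
nominal_acceleration(2, 0.35)   # GRAPPA-2 -> 5.714286-fold
```

At 35% phase resolution the degraded frame sits at ~6% nRMSE / 25 dB
PSNR relative to its reference; the GRAPPA-2/3 combinations give nominal
5.7-/8.6-fold accelerations, and `1/0.35 ≈ 2.86` is the
temporal-resolution gain over a full-phase protocol.

Training and super-resolving (desk scale, ~15 min on one CPU):

```r
ex <- desk_experiment(seed = 1)   # simulate, degrade, train, sample, evaluate
ex$summary                        # PSNR/nRMSE/SSIM for SR vs zero-padded LR
plot(ex$fit)                      # loss history
```

A thin command-line front end with `simulate | degrade | train | sample |
evaluate` subcommands is installed at `inst/cli/perfdiff`.

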