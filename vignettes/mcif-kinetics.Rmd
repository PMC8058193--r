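---
title: "Model-corrected input functions and cerebral FDG uptake rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-corrected input functions and cerebral FDG uptake rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcifki)
```

## The problem

Quantifying the cerebral FDG uptake rate constant $K_i$ from a dynamic PET
scan requires the arterial input function — the tracer concentration in
arterial blood over time. Serial arterial sampling in rats and mice is
invasive, terminal in practice, and hard to time around the first-pass
bolus. An image-derived input function (IDIF) read from the left-ventricular
blood pool avoids sampling, but at rodent scale the blood pool is only a few
millimetres across: the measured blood curve is depressed by partial-volume
loss (recovery coefficient $r_b < 1$) and inflated by spillover of
myocardial activity ($S_{mb}$), while the myocardial curve is conversely
contaminated by blood spillover ($S_{bm}$) and recovered at $r_m < 1$.

`mcifki` implements the dual-output solution: model both contaminated
curves simultaneously, sharing one latent arterial curve, and read the
uncontaminated input — the model-corrected input function (MCIF) — off the
fitted model. The MCIF then drives a four-parameter regional brain model
that yields $K_i$ per region.

## The dual-output model

The arterial curve is the seven-parameter Feng form
$$C_a(t) = (A_1 u - A_2 - A_3)e^{-\lambda_1 u} + A_2 e^{-\lambda_2 u} +
  A_3 e^{-\lambda_3 u}, \qquad u = t - \tau,$$
zero before the appearance delay $\tau$ and continuous at it. Myocardial
tissue follows the two-tissue compartment model
$$\dot C_1 = K_1 C_a - (k_2 + k_3) C_1 + k_4 C_2, \qquad
  \dot C_2 = k_3 C_1 - k_4 C_2, \qquad C_T = C_1 + C_2 .$$
The two measured curves are frame averages of cross-contaminated mixtures:
$$\mathrm{Model}_{IDIF,i} = \frac{1}{t_e - t_b}\int_{t_b}^{t_e}
  \left[S_{mb}\,C_T(t) + r_b\,C_a(t)\right] dt, \qquad
  \mathrm{Model}_{myo,i} = \frac{1}{t_e - t_b}\int_{t_b}^{t_e}
  \left[r_m\,C_T(t) + S_{bm}\,C_a(t)\right] dt .$$
That is 7 input + 4 kinetic + 4 contamination = 15 parameters. The fit
minimizes $O = O_1 + O_2$: $O_1$ is the unweighted residual sum of squares
over all frames of both outputs, and $O_2$ adds the squared mismatch of the
peak values (model vs data maxima of the frame-wise curves; blood over the
full scan, myocardium within the first 10 min). $O_2$ exists because under
equal weighting the single peak frame is outvoted by the many late frames,
and first-pass fidelity is exactly what an input function is for.

The regional brain model couples partial volume and spillover into one
parameter, the tissue blood-volume fraction TBV:
$$C_m(t) = \frac{1}{t_2 - t_1}\int_{t_1}^{t_2}\Big\{(1 - TBV)\,C_T(T)
  + TBV\,C_p(T)\Big\}\,dT,$$
with $C_T$ the irreversible ($k_4 = 0$) tissue solution driven by
$C_p$ (the MCIF), four parameters $(K_1, k_2, k_3, TBV)$, uptake rate
$K_i = K_1 k_3/(k_2+k_3)$ and recovery coefficient $RC = 1 - TBV$. The
model assumes spillover and partial volume complement each other exactly
(TBV and $1-TBV$); treating them independently would add a parameter and is
deliberately not done here. Note the $TBV \cdot C_p(T)$ term uses the
continuous input — the outer frame integral handles discretization.

## Numerical design

Every model output is a frame average of linear functionals of $C_a$: its
running integral, and its convolution with decaying exponentials. For a
Feng input all of these have closed forms, so frame averages are computed
from exact antiderivatives (differences of the cumulative integrals at the
frame edges) rather than quadrature. Near-degenerate exponents
($|\beta - \lambda| \to 0$, $\lambda \to 0$) switch to series branches at a
relative threshold of $10^{-3}$, keeping values accurate to machine
precision; a repeated kinetic eigenvalue (possible only at $k_3 = 0$,
$k_2 = k_4$) is split by a $10^{-6}$ relative nudge of $k_4$. The generic
`frame_average()` exposed to users integrates arbitrary functions
adaptively (absolute tolerance $10^{-8}$) and is used in the test suite to
cross-check the closed forms; a stiff ODE oracle (deSolve, rtol $10^{-10}$,
atol $10^{-12}$) independently verifies the tissue solutions.

All fits are bounded Levenberg–Marquardt least squares (`minpack.lm`), with
rates ordered by construction ($\lambda_3$, then positive increments to
$\lambda_2$ and $\lambda_1$) to break permutation symmetry. Multi-starts
are Latin-hypercube draws under a fixed seed; ties within $10^{-12}$ go to
the smaller parameter norm. Given identical inputs and seed every fit is
bit-reproducible.

## Identifiability and the estimator

Two structural facts shape the defaults, both visible analytically:

**Amplitude scale.** Scaling $C_a \mapsto c\,C_a$ while dividing $K_1$,
$r_b$ and $S_{bm}$ by $c$ leaves both model outputs unchanged. The absolute
MCIF scale is therefore carried entirely by the recovery coefficients.
Scanner recovery coefficients are measurable once, by imaging a phantom of
known activity, and `fit_mcif(recovery = c(r_b =, r_m =))` accepts such
calibration values and holds them fixed — the recommended mode, used
throughout the validation suite (the digital phantom records its generating
$r_b, r_m$ as that calibration). Without calibration, both coefficients are
fitted inside `r_bounds` (default $[0.3, 1]$) and the MCIF is determined
only up to the residual scale freedom.

**Tail degeneracy.** With wide-open bounds the unweighted objective admits
solutions that push the slowly-decaying blood tail ($A_3, \lambda_3$) into
the slowly-rising trapped-tissue spillover term ($S_{mb} C_T$) and fit
noisy data *better* than the generating parameters. The default bounds
therefore bracket rodent FDG physiology rather than all admissible rates:
$\lambda_3 \in [0.004, 0.025]$ min$^{-1}$ (whole-blood clearance half-life
of roughly 0.5–3 h), $K_1 \le 1.5$, $k_2 \le 1.5$, $k_3 \le 0.6$
min$^{-1}$; spillover fractions stay open on $[0, 1]$. For the same reason
the default estimator is a single deterministic local descent from a staged
informed start — a Feng fit to the blood TAC pins the input, a cheap
multi-started pre-fit sets kinetics and spillover with the input held
fixed, then everything is refined jointly. Latin-hypercube multi-start
(`n_starts > 0`) selects the lowest objective found, which on noiseless
data is the generating solution but on noisy data is the overfitted one;
use it for validation-grade data, and the informed local fit for measured
curves.

$k_4$ defaults to free within $[0, 0.1]$ min$^{-1}$ in the heart model
(completing the 15 parameters); `fix_k4 = TRUE` pins it at zero, which is
standard for FDG over a 60-min scan and is what the phantom generates.

Peak forcing in `fit_feng()` (used when arterial draws missed the bolus
peak and the early myocardial maximum stands in for it) is a quadratic
penalty, initial weight $10^4 \times$ the mean-squared-residual scale,
escalated tenfold until the fitted maximum agrees with the target to 0.5%,
so the optimizer surface stays smooth while the constraint is met.

## The digital-rat phantom

`generate_truth()` draws a complete ground truth per seed: regional
$K_1 \in [0.05, 0.2]$, $k_2 \in [0.1, 0.4]$, $k_3 \in [0.02, 0.12]$
min$^{-1}$, $TBV \in [0, 0.03]$ — implying cerebral $K_i$ centred on the
0.02–0.03 min$^{-1}$ range typical of fasted rats and $RC \in [0.97, 1]$ —
plus heart kinetics, spillover fractions $\in [0.1, 0.4]$, recovery
coefficients $r_b \in [0.85, 0.98]$, $r_m \in [0.75, 0.95]$, and a bolus
input peaking at a few hundred kBq/cc (the regime of a 200–300 µCi
tail-vein injection; the absolute kBq/cc scale is arbitrary). The default
layout is 35 VOIs binned into four super regions (cerebellum, frontal
cortex, hippocampus, striatum), combined as volume-weighted TAC means.

`simulate_study()` evaluates the exact forward model on the standard
23-frame/60-min schedule (11×8 s, 1×12 s, 2×60 s, 1×180 s, 8×400 s) and the
twelve-sample arterial timetable, then adds zero-mean Gaussian frame noise
with $SD_i = \sigma_0\sqrt{v_i/\Delta t_i}$ — the standard surrogate for
reconstructed-PET frame statistics — and proportional sample noise
(gamma-counter repeatability, 3% CV typical). Negative noisy values are
retained: clipping would bias low-activity frames upward. What the phantom
does *not* emulate: reconstruction artifacts, correlated frame noise,
motion, decay-correction residuals, or any image-space effect — it lives at
TAC level, where this computation begins. Passing tests therefore validate
the estimation machinery, not the upstream image processing.

## What the validation runs compute

The acceptance suite (and `scripts/acceptance.R`) checks, at sizes chosen
to keep the full run in a few minutes on one core: closed forms against the
ODE oracle (100 random parameter sets, $\le 10^{-6}$ relative); the
regional model against nested quadrature (20 sets, $\le 10^{-5}$); Patlak
slopes at $t^* = 20$ min against $K_i$ (within 2%); input-fit recovery at
the twelve sample times ($\le 0.5$% of peak, peak forcing $\le 0.5$%); MCIF
AUC recovery (within 2% noiseless; median within 10% over 20 replicates at
5% peak-relative noise); regional $K_i$ recovery (within 1% noiseless;
median within 5% at 5% proportional noise, 20 replicates per region); a
paired sign test that the peak objective does not worsen — and in fact
improves — blood-peak fits over 20 noisy replicates; exact agreement of the
Bland–Altman/paired-t outputs with hand computation; and an end-to-end
5-rat × 4-super-region study at zero noise whose computed-vs-true $K_i$
bias must sit within 2 standard errors of zero.

## Limitations

The method stands or falls with the recovery-coefficient calibration; an
error in $r_b$ propagates multiplicatively into the MCIF amplitude, AUC and
every downstream $K_i$. The unweighted objective is the method as defined,
but it is statistically inefficient for the blood tail, which dominates the
AUC — tail-rate uncertainty is the main contributor to the ~10% noisy AUC
spread seen in validation. Cerebral metabolic rate of glucose is out of
scope (it needs plasma glucose and a lumped constant), as are reversible
(Logan) analyses and any image-space processing.
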