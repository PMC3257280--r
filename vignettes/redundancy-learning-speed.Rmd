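---
title: "Neuronal redundancy and the speed of motor adaptation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuronal redundancy and the speed of motor adaptation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redmotor)
```

## The model

`redmotor` studies a deliberately minimal question: the motor cortex has
vastly more neurons (N) than there are constrained outputs (a planar reach
endpoint, M = 2), so many activity patterns produce identical movements.
Does this *neuronal redundancy* do anything for learning?

The model is a linear rate network adapted trial by trial. On trial $t$ a
movement direction $\theta$ is encoded as an input vector $x(\theta)$
(2-D cosine tuning by default), neural activities are
$u_t = W_t x + \sigma_u \xi$, a decoder turns them into a planar force
$f_t = D u_t$, and the realized hand coordinate is $y_t = R(\phi) f_t$,
where $R(\phi)$ is a fixed rotation standing in for a visuomotor rotation
or curl force field. Only the endpoint is modelled, so $y$ is "the motor
command". The squared error is $E_t = \tfrac12\lVert y^* - y_t\rVert^2$
(the $\tfrac12$ is a package convention that keeps the gradient free of a
stray factor 2; it only rescales the effective learning rate). Weights
follow gradient descent with decay $\lambda_d$, rate $\eta$ and drift
$\sigma_w$:

$$W_{t+1} = (1-\lambda_d) W_t + N\eta\, D^\top R^\top (y^*-y_t)\, x^\top
  + \sigma_w \Xi .$$

The decoder's column for neuron $i$ is its force vector
$\hat d_i / N$: a unit vector at a uniformly random force direction in
the homogeneous family, or a Gaussian(-mixture) draw in the
non-homogeneous families. The $1/N$ scaling and the explicit $N$ in the
update make both the output and the per-neuron trial-to-trial variation
independent of $N$, so changing the population size changes *only* the
redundancy, not the gain of the loop.

Substituting the update into the error gives the whole story in one
matrix. With unit-self-overlap inputs,

$$e_{t+1} = \bigl(I - \eta\, R A R^\top\bigr) e_t, \qquad
  A = \frac1N \sum_{i=1}^N \hat d_i \hat d_i^\top,$$

so each eigenmode of the *learning operator* $A$ contracts by
$(1-\eta\lambda_k)^2$ per trial and the slowest mode — $\lambda_{\min}$ —
limits learning speed. For unit-norm force vectors
$\operatorname{tr} A = 1$ exactly, hence $\lambda_{\min} \le \tfrac12$,
with equality iff the empirical second moments of the force vectors are
isotropic. That is a self-averaging property: a finite sample of
directions approximates its distribution's (isotropic) second moments
with error of order $N^{-1/2}$, so $\lambda_{\min} \to \tfrac12$ — and
learning speed is maximized — precisely when the population is redundant
($N \gg M$). `build_A()`, `eigensystem_2x2()`,
`self_averaging_residual()` and `learning_speed_bound()` expose this
chain; `analytic_curve()` is the closed-form learning curve, and
`run_repetition()` reproduces it to $10^{-10}$ relative error in the
noise-free single-target regime (a test asserts this).

## Parameters that matter

* `learning_rate` ($\eta$, default 0.2): the quasi-optimal operating
  point. The closed-form optimal rate is
  $\eta^* = 2/(\lambda_{\min}+\lambda_{\max})$
  (`optimal_learning_rate()`); every redundancy ranking in the package is
  invariant to choosing $\eta \in \{0.05, 0.2, \eta^*\}$ (tested).
* `decay` ($\lambda_d$, per-trial multiplicative shrinkage toward zero
  weights): with ongoing errors it leaves a residual floor
  $\tfrac12\sum_k (\lambda_d y_k /(\lambda_d+\eta\lambda_k))^2$ plus a
  drift variance term; `residual_error_with_decay()` returns the fixed
  point, which matches 5000-trial simulated tails within 2%. Because the
  floor falls as $\lambda_k$ rises, redundancy also minimizes residual
  error.
* `activity_sd` / `plasticity_sd` ($\sigma_u$, $\sigma_w$): both reach
  the output through the decoder, attenuated as $\operatorname{tr}A/N$
  and $\lambda_k/N$ — redundancy therefore buys noise robustness. The
  noise sweeps use $\sigma_u = 1$ and $\sigma_w = 1$, which at $N = 10$
  put the noise floor at the same order as the perturbation error (a
  visible, physiologically plausible regime) and at $N = 1000$ make it
  negligible.
* Task geometry: K = 8 center-out targets, radius 1, rotation
  $\phi = 45^\circ$, 100 baseline + 100 learning trials, one seeded
  target sequence shared by all conditions of a comparison. K, $\phi$
  and the radius are conventional center-out values (the speed results
  are scale-free in the radius); the trial counts and the shared-sequence
  design follow the standard adaptation protocol.
* Encoding: `cosine2d` gives the classical cosine generalization
  $g(\delta)=\cos\delta$. `von_mises` uses M = 100 tuned input units —
  M is held at 100 throughout — with free precision $\kappa$;
  normalization is per-direction, $x(\theta) = v(\theta)/\lVert
  v(\theta)\rVert$, so $g(0)=1$ holds exactly for every $\kappa$ (a
  single scalar normalizer cannot achieve this; the residual ripple of a
  shared constant is what the per-direction form removes).

## Decoder families and tuning histograms

The Gaussian families default to second moments
$\mathbb E[dd^\top] = \tfrac12 I$, the same operator as the homogeneous
family: unimodal with mean $(0.65, 0)$ and covariance
$\mathrm{diag}(0.5-0.65^2,\,0.5)$, bimodal as the mirrored pair
$\pm(0.65,0)$ with the same covariance. The mirror construction means the
*empirical* second-moment matrix has the identical sampling distribution
in both families, so learning speeds agree in distribution exactly, while
the force-direction histogram is clearly bimodal and the force-amplitude
histogram right-skewed — the regime where skewed-bimodal preferred
directions coexist with maximal learning speed. Preferred directions and
modulation depths are read from *post-baseline* weight rows
(`tuning_summary()`); after the learning phase the rows compensate the
rotation and every PD is shifted by $-\phi$, so tuning histograms should
always be taken from a baseline-only run.

A note on what these defaults replace: antipodal means at distance 3 with
unit isotropic covariance produce $\mathbb E[dd^\top] = I + 9 e_x
e_x^\top$, a maximally anisotropic operator whose $\lambda_{\min}$ is an
order of magnitude below the bound — that network is *slow*, bimodal or
not. The second-moment conditions, not the histogram shape, are what the
theory needs, and the defaults are calibrated to satisfy them exactly.

## Fitting learning speed

`fit_speed()` fits $a e^{-st} + c$ with $a, s, c \ge 0$, by least squares
on $\log E_t$. The log-domain criterion is the substantive choice:
squared-error curves span three or more decades, and an absolute-scale
fit is dominated by the first few trials, where the curve decays at a
*trace*-weighted mixture of mode rates. Since
$\operatorname{tr} A \equiv 1$ for every homogeneous sample, that early
mixture is nearly independent of $N$; the redundancy effect lives in the
$\lambda_{\min}$-governed tail, which log-domain residuals weight fairly.
(We verified the failure mode directly: with absolute-scale fitting the
population-size orderings under narrow generalization and in the
high-dimensional task grids invert or vanish.) The optimizer is
multi-start — an absolute-scale profile fit and two log-slope estimates
seed L-BFGS-B, with a Nelder-Mead polish — so results are
starting-value-free; exact synthetic curves are recovered to $10^{-12}$.

Relatedly, `theory_table()` reports the slowest-mode rate
$-2\log\max_k\lvert 1-\eta\lambda_k\rvert$ as the predicted speed. Over a
finite window a single-exponential fit of a genuinely two-mode curve sits
between the two mode rates, so simulated fits are compared to
`fit_speed(analytic_curve(...))` — the like-for-like check — rather than
to the asymptotic rate.

## Protocol choices in the experiments module

* **High-dimensional task sets** (`mode = "highdim"`): T tasks are T
  fixed unit-norm inputs with planar targets under a common rotation, and
  a Gaussian decoder scaled by $1/\sqrt N$. The inputs form a random
  orthonormal frame. Independently drawn unit Gaussians in dimension T
  are frequently near-collinear (at T = 2 the overlap is a raw cosine of
  a random angle), which silently merges nominal tasks and produces
  non-converging modes; orthonormality makes T nominal constraints T
  effective ones while keeping the inputs random and unit-norm. Tasks
  beyond the input dimension fall back to unit Gaussians with a
  rank-deficiency warning.
* **Generalization sweep**: broad vs narrow conditions use
  $\kappa = 2$ and $\kappa = 50$. The first Fourier coefficient of
  $g$ — which sets the multi-target learning rate of the (first-harmonic)
  rotation error — is near its maximum at $\kappa \approx 2\!-\!3$ and
  about three times smaller at $\kappa = 50$, giving the "narrower is
  slower" contrast a solid margin. Note the broad limit is not fastest:
  as $\kappa \to 0$, $g$ flattens and transfers corrections
  indiscriminately, so the differential component of the error stops
  being learnable. This sweep runs 300 learning trials instead of 100:
  with near-delta generalization each of 8 targets receives only ~12
  updates in 100 trials, too few for any rate estimate to see the slow
  modes; the default protocol elsewhere remains 100 + 100.
* **Saturating activation** (`activation = "saturating"`, odd
  slope-1 sigmoid): $\lvert\tanh\rvert < 1$ caps the reachable command at
  $2/\pi$ of the linear range, so these conditions use target radius 0.3
  to keep the task solvable. The exact sigmoid used in the original
  nonlinear variant is not pinned down; a slope-1 odd sigmoid is the
  package's choice, and the small-signal regime provably reduces to the
  linear model (tested).
* **Rectified muscles** (`n_muscles`): pull-only muscles in equally
  spaced antagonist pairs, drives from a random $1/N$-scaled matrix plus
  a tonic baseline (`tone = 1`). The tone is load-bearing: from zero
  weights all rectifier gates would otherwise be closed (zero force *and*
  zero gradient), and with equally spaced pull directions the tonic
  contributions cancel exactly, so rest force stays zero.
* **Recurrent connections**: fixed random matrices scaled to a requested
  spectral radius, solved exactly at the linear fixed point
  $u = Wx + Ku$ with gradients through $(I-K)^{-\top}$. An *adaptable*
  recurrent rule is deliberately out of scope; the fixed-point reading is
  a stated reconstruction, not a claim about the original iterative
  variant.
* **Stochastic rules**: weight and node perturbation follow the standard
  stochastic-gradient formulations, probing with Gaussian perturbations
  ($\sigma_p = 0.01$, small enough for bias $O(\sigma_p^2)$ with bounded
  estimator variance) and moving against the measured error change,
  including the $\times N$ rate scaling of the gradient rule. That
  scaling matters: without it the perturbation-rule speed scales as
  $\lambda_{\min}/N$ and the redundancy ordering reverses; with it the
  $1/N$ decoder cancels the parameter-dimension penalty (the per-trial
  second moment of the error is $1 - 2\eta\lambda + \eta^2\lambda(1 +
  \lambda + \dots)$, independent of $N$). Both rules are verified to be
  unbiased gradient estimators by $10^5$-draw Monte Carlo.
* **Pairing and exclusions**: conditions being compared share decoder
  seeds and one target sequence, so Wilcoxon signed-rank contrasts are
  maximally powered; repetitions whose error exceeds $10^6\times$ the
  initial learning-phase error are flagged divergent, excluded from
  speed averages and counted in `n_excluded`. Sweeps in the test and
  acceptance protocols use 50–200 repetitions (the headline contrasts
  reach $p < 10^{-12}$ at 100), with 1000 remaining the default for
  production use.

## What the generator emulates — and what it does not

The synthetic conditions reproduce the study's structure: uniform,
unimodal- and bimodal-Gaussian force-vector populations, rotational
perturbations, shared target sequences, activity/plasticity noise, decay
and drift. They do not emulate real motor-cortex data: no trial-to-trial
correlations beyond the model's own, no heterogeneous per-neuron learning
rates, no time-continuous trajectories (endpoints only), and decoder
distributions are not fits to recorded tuning. Passing tests therefore
demonstrate the *model's* claims — that redundancy maximizes learning
speed robustly across these variants — not claims about any particular
dataset.

## Numerical choices and degenerate inputs

Angles are radians everywhere (config files accept a `deg` suffix).
Von Mises profiles are computed as $\exp(\kappa(\cos(\cdot)-1))$ to avoid
overflow at large $\kappa$. The 2×2 eigensolver is the closed-form
quadratic with a guarded diagonal branch; asymmetric input is an error,
as are non-finite angles, non-SPD covariances, recurrent spectral radius
$\ge 1$, perturbation rules with $\sigma_p = 0$, and decoder updates on
fixed-decoder states. `self_averaging_residual()` is the normalized
spectral gap $(\lambda_1-\lambda_2)/(2\operatorname{tr}A)$ — zero iff
the sample is second-moment isotropic, exactly $\tfrac12$ for any single
neuron, and rotation-invariant (a componentwise moment deviation is not).
A flat or rising curve fits to speed 0 by convention; a curve flagged
divergent returns `NA` with `converged = FALSE`.

## A small worked example

```{r example}
dec <- sample_decoder(decoder_distribution("homogeneous_uniform"),
                      n_neurons = 1000, seed = 1)
A <- build_A(dec)
eigensystem_2x2(A)$values          # both close to 1/2: near-maximal speed
learning_speed_bound(dec)

task <- task_spec(n_targets = 1, n_baseline_trials = 0,
                  n_learning_trials = 50)
cv <- run_repetition(experiment_condition("demo", 1000, task = task), 1)
fit_speed(cv)$speed      # inside the band set by the two mode rates
-2 * log(1 - 0.2 * eigensystem_2x2(A)$values)   # the band
```

## Known limitations

The closed-form theory covers the linear fixed-decoder model; adaptable
decoders, nonlinear activation and rectified muscles are simulation-only
(the adaptable-decoder dynamics are analytically intractable here, as in
the original analysis). The high-dimensional "N = T = 2" cell is only
loosely comparable to the planar base model — Gaussian decoder columns
are not unit-norm, so the speed distributions differ in shape even though
the scales agree. Node perturbation's weight update assumes linear
activation between perturbation site and weights; with saturating
activation it remains a descent direction but not an exact gradient
estimator. Statistical summaries report all p-values; no
multiple-comparison correction is applied.
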