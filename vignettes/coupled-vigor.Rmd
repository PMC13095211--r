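---
title: "Vigor, cost of time, and coordination in coupled wrist reaching: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vigor, cost of time, and coordination in coupled wrist reaching: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical design choices, and what the
test suite does and does not establish.

# The scientific setting

Self-paced reaching durations grow affinely with amplitude,
$T(A) = aA + b$, and the slope of that law differs stably between people:
some are systematically vigorous, some systematically slow. When two
people are coupled through an elastic band (stiffness $\kappa$) and reach
together without timing instructions, the pair behaves like a single unit
with its own *dyadic vigor*. The package implements the machinery needed
to quantify this (vigor scores, variance decomposition, a mixed model of
dyadic vigor) and to simulate four candidate coordination mechanisms over
the coupled dynamics, of which the *interactive adaptation* model — a
stochastic free-final-time optimal control in which the partner's timing
uncertainty penalizes slow movements — is the scientifically interesting
one.

# Solo model and inverse optimal control

The wrist plus exoskeleton is a single rotational joint,
$I\ddot q = \tau - D\dot q - \nu\dot q$ with $I = 9.2\cdot10^{-3}$ Nm s²,
$D = 0.03$ Nm s, and commanded viscous load
$\nu \in \{0, 0.075, 0.15\}$ Nm s/rad. On the state $x = (q, \dot q, \tau)$
with control $u = \dot\tau$, effort is
$\int_0^T (x_e - x)' Q_k (x_e - x) + \beta u^2\,dt$ with
$Q_k = \mathrm{diag}(15.5/A_k, 0, 0)$ and $\beta = 0.95$ — minimum torque
change with an amplitude-normalized pull toward the target. All angles are
radians internally: the affine laws only produce plausible sub-second
durations when $A$ is in radians; degrees appear only at I/O boundaries.

Because dynamics are linear and the running cost quadratic, the
trapezoidal transcription of the fixed-duration problem is a convex QP;
`solve_fixed_time_oc()` solves its sparse KKT system exactly (no NLP
iterations, no convergence failures), with a 2 ms default node spacing
(at least 101 nodes) and the costate read off the dynamics multipliers.
Boundary conditions are full rest-to-rest, $(0,0,0) \to (A, 0, 0)$: the
terminal torque is the steady-state torque holding the posture, which is
zero for this plant. The problem is autonomous, so the Hamiltonian
$H = L + \lambda' f$ is constant along the optimum and equals $dV/dT$,
the marginal effort of allotting more time — both facts are asserted by
the tests against finite differences and an independent mesh-refinement
oracle.

**Identification.** `identify_cost_of_time()` evaluates $-H$ at the five
durations prescribed by an amplitude–duration law and fits the derivative
$g(t;p)$ of the sigmoid $G(t) = p_1(1-[1+(t/p_3)^{p_2}]^{-p_4})$ through
the pairs $(T_k, -H_k)$ by multi-start Levenberg–Marquardt in
log-parameters ($p_4 \in [10^{-6}, 10]$; 20 seeded random starts plus a
data-driven one). Two choices deserve comment:

* *Plain least squares, not log-scale residuals.* The $-H_k$ span several
  decades, which superficially argues for a log-scale fit. But the
  near-zero values arise on the *effort plateau* (below), carry almost no
  information about $G$, and a log fit chases them into a pathologically
  steep tail. Natural-scale least squares reproduces the behaviour of the
  published parameter sets.
* *Replay selection among local optima.* With five points and four
  parameters the fit is nearly degenerate: local optima with similar
  residuals differ wildly in the tail exponent $p_2 p_4$, which the data
  barely constrain but which governs the forward free-final-time
  behaviour. The transversality residual is only the first-order surrogate
  of the inverse problem, so among the distinct local optima the estimator
  returns the one whose forward replay best reproduces the input law.

**The effort plateau.** $V(T)$, the minimum effort at fixed duration,
falls steeply and then flattens: beyond a comfortable duration the
marginal value of time is numerically zero, and at large amplitudes the
curve develops a shallow secondary dip (a submovement regime — the
optimal long-duration trajectory splits its approach). Two consequences,
both verified against an exact matrix-exponential solution of the
Hamiltonian boundary-value problem and therefore properties of the
continuous problem rather than solver artifacts:

* the total cost $G(T) + V(T)$ can have several near-degenerate minima.
  `solve_free_time_oc()` therefore refines *every* grid-local minimum
  (log-spaced 60-point grid on $[0.01, 10]$ s, Brent refinement) and,
  among candidates within 0.5% relative cost of the best — five times the
  transcription accuracy bound — returns the smallest duration and sets a
  tie flag;
* forward self-consistency of the identification is exact below the
  plateau and degrades at the largest amplitude, where the preferred
  duration sits at the plateau edge and is not a stationary point of any
  smooth sigmoid's total cost. The tests assert per-target closure for
  the first four targets and closure of the mean; the acceptance checks
  report the affine fit of the five forward durations for each published
  parameter set, including the ones this analysis predicts will deviate.
  For the slow-group parameter set ($p_1 \approx 10^7$,
  $p_4 \approx 10^{-5}$, a boundary solution of the original fit) the
  forward loop cannot recover the slow law at all: its time-cost
  derivative at the slow 18° duration is $\sim 10^{-4}$ while the effort
  Hamiltonian there is $\sim 3$, so no nearby stationary point exists.

# Dyadic models

**Co-activity.** Each partner plans a minimum-jerk trajectory with their
own group's duration; the fast reference is held at the target after
completion (literal zero-padding of the position would teleport the
reference). Both are tracked by a finite-horizon, time-varying LQR on the
coupled state $(q^f, \dot q^f, q^s, \dot q^s)$ with
$Q = \mathrm{diag}(100, 0.1, 100, 0.1)$, $R = I_2$, realized as an affine
backward Riccati recursion on the Euler-discretized dynamics at 1 kHz with
terminal weight equal to the running $Q$. The reported statistic is the
mean absolute band torque $\kappa|q^f - q^s|$ over the slow partner's
movement.

**Interactive adaptation.** The slow partner is a family of minimum-jerk
trajectories with random duration $\xi_k$ of mean $\mu_k$ (slow-group law)
and sd $\sigma_k$; no distributional assumption is needed beyond the two
moments, because linearizing the slow velocity in $\xi$ around $\mu_k$ and
dropping cross-covariances gives a deterministic-equivalent cost: the fast
partner's solo cost plus
$Q_\tau \kappa^2 \int [\dot q^f - \dot q^s(\mu)]^2 + P_{\dot q} +
(\partial \dot q^s/\partial\xi|_\mu)^2 \sigma^2\,dt$, with $Q_\tau = 3$
for every amplitude and condition. $\sigma_k$ is linearly spaced over the
five targets within $[0.15, 0.25]$ s (no load), $[0.2, 0.3]$ s (light
load) and $[0.32, 0.4]$ s (heavy load). The process-noise contribution
$P_{\dot q}$ is a configuration knob (`ia_config(process_noise = )`)
defaulting to zero, since the state-covariance propagation of the original
stochastic open-loop framework is not constrained by the data used here.
The sampling oracle (`monte_carlo_expected_cost()`, truncated-normal
$\xi > 0.05$ s with the *exact*, non-linearized slow velocity) brackets
the deterministic form to first order in $\sigma/\mu$; the test computes
an a-posteriori remainder bound from the sampled linearization error
rather than assuming an $O(\sigma^2)$ rate, because the hold extension
makes the velocity non-smooth in $\xi$ near the movement end.

Fixed-duration inner problems remain convex QPs (the coupling adds a
known time-varying forcing); the free duration is searched exactly as in
the solo case. One deliberate asymmetry: the interactive-adaptation
transcription constrains terminal position and velocity but leaves the
terminal torque free, whereas the solo problems constrain full rest. The
solo convention is forced by the identification (the Hamiltonian data
match the published sigmoid fits only under full rest), while the
free-torque convention is the natural one for the coupled problem — the
hold torque against the band depends on where the slow reference is at
$T$ — and it is the convention under which the model's sensitivity to the
fast partner's cost of time comes out at the published order (≈10 ms at
18°, ≈35 ms at 90° for a 30% scaling of $p_1$). The κ→0 reduction test
compares against the solo solver run under the matching convention.

The sensitivity sweep over the slow partner's mean timing uses scalings
$\{1.0, 0.9, 0.8\}$ of $\mu_k$ — the empirically plausible range of
coupled speedups; pushed far below that, the optimum saturates at the
fast partner's own preferred pace and the monotone decrease levels off,
which is expected behaviour rather than a defect.

**Baselines.** Leader–follower baselines are the respective group's solo
free-final-time durations; weighted adaptation mixes the two leader
durations with weight $\alpha$ (default 0.5; $\alpha \in \{0,1\}$
recovers the leaders). The comparison stage computes, per hypothesis, the
median absolute duration error split by stiffness family and a qualitative
checklist derived only from computed tables: interaction force below the
0.1 Nm level that coupled humans actually stay under (no-load mean), and
whether the model predicts the dyad faster than the fast leader in the
majority of the larger no-load targets.

# The synthetic-data generator

The generator emulates the session structure of the experiment: 100-trial
blocks (10 per target per direction) in a seed-fixed pseudo-random order,
2 ± 0.15 s uniform onset jitter, Gaussian reaction times (mean 225 ms),
300 Hz sampling, additive sensor noise and 6400-count encoder
quantization. Trial-level duration jitter is log-normal with mean 1
(durations are positive and right-skewed); its coefficient of variation is
a free parameter of the generator — the experiment constrains population
structure, not trial-level noise — with default 0.08, a realistic
trial-to-trial CV for self-paced reaching, chosen once.

Two calibrations keep the generator consistent with the measurement chain
and the forward model:

* *Threshold-span calibration.* A 5%-of-peak-velocity segmentation spans
  only a fraction (analytically 0.8811) of a minimum-jerk movement, and
  the 5 Hz zero-phase filter perturbs that fraction slightly. Since
  amplitude–duration laws are laws of *measured* durations, the generator
  measures the span of clean probe movements through its own pipeline
  once, fits the affine map span(ξ), and inverts it when converting a
  drawn duration into a plan duration. Segmenting generated cohorts then
  recovers the generating slopes to well within 3% (noise-free bias
  ≈ 0.2%).
* *Load inflation.* Durations under viscous load are inflated by the
  ratio of loaded to null-field free-final-time predictions with the
  average cost of time, so synthetic loaded data slow down exactly as the
  forward model says they should, rather than by a free parameter.

Dyadic trials integrate the coupled dynamics with explicit Euler at the
sample rate while each partner tracks their hypothesis-assigned reference
with a PD servo plus inertia/damping feedforward (the LQR realization
belongs to the co-activity model; the generator only needs tight,
physically consistent tracking). The recorded interaction torque is
$\kappa(q^f - q^s)$ recomputed from the stored (noisy, quantized)
channels, so the identity holds exactly on the recorded data.

What the generator does *not* emulate: submovements and terminal
corrections of real large-amplitude reaches, EMG, cursor/screen geometry,
trial-by-trial learning, or feedback corrections during movement. Passing
round-trip tests on this generator therefore establishes the correctness
of the pipeline's bookkeeping and estimators under the stated statistical
structure — not that real data meet that structure.

# Statistical components

The vigor score uses the relevant null-field reference per condition
family (NF1 for solo loads; the KL or KH block for the corresponding
loaded coupled conditions). The variance decomposition is the one-way
sum-of-squares split (computed through `lm`/`anova`), with the degenerate
zero-variance case reported as 0% with a flag rather than NaN. The dyadic
vigor model $v^d \sim \gamma^f v^f + \gamma^s v^s$ is fit per condition
with a random intercept per dyad (the minimal structure consistent with
repeated conditions per dyad) by maximum likelihood via
`lmerTest::lmer`, with Holm correction across conditions per predictor;
the model is fit without an intercept by default — the model formula has
none — and `intercept = TRUE` adds per-condition intercepts for
comparison. Exactly collinear partner vigors are flagged
non-identifiable; exactly noiseless inputs fall back to the fixed-effects
regression with a singular-fit flag.

Smoothness is the spectral arc length of the amplitude-normalized speed
spectrum with an adaptive band cutoff (highest frequency with normalized
magnitude ≥ 0.05, capped at 10 Hz, axis normalized by the cutoff,
zero-padded FFT at ≥ 4× the segment length): the adaptive cutoff is what
makes the score insensitive to duration rescaling, which the fixed-band
variant is not.

# Problem sizes and determinism

Default test and pipeline runs use reduced problem sizes — typically one
or two repetitions per target per direction, five dyads, and a coarse
duration grid of 40 points on $[0.05, 3]$ s — chosen so the full chain
exercises every code path at comfortable cost; the solvers' defaults (60
grid points on $[0.01, 10]$ s, 2 ms collocation) are used wherever a
published quantity is recomputed. Every stochastic component draws from
an explicit seed (session configs, the pipeline master seed, the
identification multi-start), and generators restore the caller's RNG
state, so identical configurations reproduce byte-identical outputs.

# Known limitations

* The solo model carries no accuracy/variance cost and no feedback
  control; it predicts average timing, not endpoint statistics.
* The free-final-time landscape is nearly flat past the effort plateau;
  durations returned in that regime (large amplitudes with weak time
  costs, and most slow-group forward solves) are tie-broken to the
  fastest near-optimal candidate and flagged — they should be read as
  "the model is indifferent over this range", not as sharp predictions.
* The interactive-adaptation model is a single-agent deterministic
  equivalent: no two-agent game, no replanning, cross-covariances
  dropped, and the realized (as opposed to expected) interaction torque
  of a shared plan is not simulated by the optimizer itself.
* Group-level parameter sets are treated as given constants of the
  reference population; the package re-identifies costs of time from
  data-driven fits but does not attempt to re-derive those constants from
  raw recordings.
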