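# dyadvigor

Movement **vigor** — the idiosyncratic pace at which a person performs
goal-directed movements — shapes not only solo behaviour but also what
happens when two people are physically coupled, e.g. moving a table
together. `dyadvigor` implements, as a tested R package, the full analysis
chain for studying vigor in solo and dyadic wrist reaching:

* a **synthetic-data generator** emulating a wrist-reaching experiment
  (targets at 18–90°, affine per-subject amplitude–duration laws,
  reaction-time and onset jitter, viscous loads, an elastic coupling
  "band", sensor noise and encoder quantization);
* a **kinematics pipeline**: zero-phase 5 Hz Butterworth filtering,
  numerical differentiation, 5%-of-peak-velocity segmentation, reaction
  times, amplitude–duration regression, spectral arc-length smoothness;
* **vigor statistics**: the vigor score, dyadic vigor, inter- vs
  intra-individual variance decomposition, and a linear mixed model of
  dyadic vigor;
* **inverse optimal control**: identification of an individual *cost of
  time* from an amplitude–duration law via minimum-torque-change optimal
  control;
* **forward models of dyadic coordination**: co-activity (independent
  plans realized through a tracking LQR), leader–follower and weighted
  baselines, and an *interactive adaptation* model — a stochastic
  free-final-time optimal control in which the dyad minimizes the fast
  partner's solo cost plus the expected variation of the interaction
  torque against a distribution of the slow partner's trajectories.

## The models in brief

**Vigor score.** For per-target durations \(T_i(A_k)\) against population
means \(\bar T(A_k)\),

\[ v_i = \frac{\sum_k \bar T(A_k)^2}{\sum_k T_i(A_k)\,\bar T(A_k)}, \]

so \(v = 1\) means moving at the population pace and \(v = 0.5\) means
uniformly twice as slow. Dyadic vigor applies the same ratio to the
per-target mean of the two partners' durations.

**Solo reaching as optimal control.** The wrist obeys
\(I\ddot q = \tau - (D+\nu)\dot q\) with state \(x=(q,\dot q,\tau)\) and
control \(u=\dot\tau\) (minimum torque change). Effort is
\(\int (x_e-x)'Q_k(x_e-x) + \beta u^2\,dt\) with
\(Q_k=\mathrm{diag}(15.5/A_k,0,0)\), \(\beta=0.95\). A movement's duration
trades this effort against a sigmoidal **cost of time**
\(G(t)=p_1(1-[1+(t/p_3)^{p_2}]^{-p_4})\). At a freely chosen duration the
transversality condition \(dG/dt(T^\*) = -H(T^\*)\) links \(G\) to the
Hamiltonian of the fixed-time problem, which is how
`identify_cost_of_time()` recovers \(G\) from an observed affine law
\(T(A)=aA+b\).

**Interactive adaptation.** The slow partner is a distribution of
minimum-jerk trajectories with random duration \(\xi_k\) (mean \(\mu_k\),
sd \(\sigma_k\)); the dyad minimizes, in free final time,

\[ \bar V^f_k + Q_\tau \kappa^2 \int_0^{T_k}
   \big[\dot q^f - \dot q^s(\mu_k)\big]^2 + P_{\dot q} +
   \Big[\tfrac{\partial \dot q^s}{\partial \xi}\Big|_{\mu_k}\Big]^2
   \sigma_k^2 \, dt , \]

the fast partner's solo cost plus the expected interaction-torque
variation, with \(Q_\tau = 3\) across all 30 conditions (5 targets × 2
stiffness × 3 loads). The timing-uncertainty integral grows with movement
time, which is why coupled dyads are predicted to move *faster* than the
fast partner when no load is present.

## Worked example

```r
library(dyadvigor)

# identify the average participant's cost of time from the population law
cot <- identify_cost_of_time(list(slope = 0.314, intercept = 0.298))
cot
#> Identified cost of time (inverse optimal control)
#>   amplitude-duration law: T(A) = 0.314 A + 0.298
#>   p = (1.4008, 30, 0.40234, 0.14958)   relative RMS residual = 0.0471

# forward predictions: viscous loads slow the optimal movement
predict_loaded_durations(cot$cost_of_time,
                         amplitudes = target_amplitudes()[c(1, 3, 5)])
#>   viscosity amplitude duration   work
#> 1     0.000    0.3142   0.3966 0.0106
#> 3     0.000    1.5708   0.7215 0.1522
#> 6     0.075    1.5708   0.8590 0.4463
#> 9     0.150    1.5708   1.0605 0.6218   # (rows abridged)

# what independent plans would cost a coupled dyad (co-activity)
simulate_co_activity(list(slope = 0.235, intercept = 0.285),
                     list(slope = 0.35, intercept = 0.323),
                     coupling_params(0.5), amplitude = pi / 2)
#> Dyad prediction [co_activity, KL, target NA]: T = 0.873 s, mean |tau_i| = 0.0975 Nm

# the interactive-adaptation prediction for the far target, low stiffness
solve_interactive_adaptation(ia_config(),
                             slow_partner_distribution(sigma = sigma_schedule(0)),
                             coupling_params(0.5), target_index = 5)
#> Dyad prediction [interactive_adaptation, KL, target 5]: T = 0.584 s, mean |tau_i| = 0.1507 Nm
```

Reading the numbers: the null-field forward solve reproduces the input law
(0.3966 s at 18° is exactly `0.314*A1 + 0.298`); the heavy load slows the
90° reach from 0.72 to 1.06 s; independent plans would stretch the elastic
band to a mean torque of ~0.1 Nm at low stiffness (far more than coupled
humans actually produce); and the interactive-adaptation dyad at 90° moves
in 0.584 s — faster than the fast group's own 0.654 s solo pace.

A full synthetic-cohort run — generate, segment, score vigor, identify,
predict all 30 conditions under the five hypotheses, compare — is
`run_pipeline(run_config(seed = 1, out_dir = "runs/demo"))`.

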