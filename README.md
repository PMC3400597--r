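# dnifield

Closed-loop simulation of a **dynamic bidirectional neural interface**: a
pair of concurrently calibrated maps — sensory (position → electrical
stimulation pattern) and motor (evoked spike-count response → planar
force) — that together make a piece of cortex act as the controller of a
simulated point mass, shaping a desired force field around an equilibrium
point. The design emulates the spinal cord's role as the interface between
brain and limb: a repertoire of automatic force responses that volitional
commands can ride on.

The package is aimed at neural-engineering and computational-neuroscience
work on bidirectional brain–machine interfaces: it provides the full
calibration algebra, the closed-loop plant, a stimulus-conditioned
spike-count generator to stand in for recordings, trajectory metrics, and
the information-theoretic evaluation machinery with limited-sampling bias
correction.

## The method in brief

With $S$ stimulation patterns, each repeated $R$ times, the per-stimulus
mean responses $\bar r_1,\dots,\bar r_S$ ($N$ units × $T$ bins) form a set
of *basis fields*. A single-trial response $r$ is represented by the
coefficients $d(r)$ solving the Gram system $G d = g$,
$G_{ij} = \langle \bar r_i, \bar r_j\rangle$,
$g_i = \langle r, \bar r_i\rangle$. The motor interface is the affine
filter

$$F(r) = \Gamma\,\Phi\,(d(r) - \bar d),$$

with $\Phi$ the (2 × S) projection onto the principal plane of the stimulus
means, and the diagonal gain $\Gamma$ scaling the projected calibration
cloud to the force range of the desired field
$F(x) = -K(x - x_0)$ over the workspace. The sensory interface assigns each
stimulus the *calibration site* $x_i = x_0 - K^{-1}F(\bar r_i)$ and selects,
at run time, the stimulus of the nearest site — so the decoded field is
exact at the sites by construction. The point mass
($M\ddot x + B\dot x = F$, defaults $M = 10$ kg, $B = 15$ N·s/m,
$K = 4$ N/m, slightly over-damped: $\zeta = B/2\sqrt{MK} \approx 1.19$)
integrates each decoded force exactly under a 1 s zero-order hold.

Evaluation uses the convergence rate, steps to convergence, mean integrated
distance to target (MIDT), RMSE against the ideal continuous-field
trajectory, and the mutual information between stimulus (template force)
and single-trial decoded force, estimated on 5-bin equipopulated
discretizations with an analytic + shuffle + bootstrap bias-correction
cascade.

## Worked example

```r
library(dnifield)

cfg <- generator_config(seed = 1)           # 4 stimuli, 14 units, 5 ms bins
session <- generate_session(cfg)            # 400 calibration + 400 test trials
field <- desired_field()                    # F = -4 (x - 0), workspace [-1,1]^2
motor <- fit_motor_map(session$calibration, field)
sensory <- fit_sensory_map(motor, session$calibration, field)
sensory
#> sensory_map: 4 calibration sites, tie rule lowest-index
#>         [,1]    [,2]
#> [1,] -0.6748  0.0000
#> [2,]  0.0000 -0.6029
#> [3,]  0.6748  0.0000
#> [4,]  0.0000  0.6029
```

The four sites are the positions whose desired-field force equals each
stimulus's decoded template force; they partition the workspace into four
sensory regions. Driving the mass from a corner with single-trial responses
drawn from the test pool:

```r
traj <- run_closed_loop(c(1, -1), motor, sensory,
                        pool_responder(session$test_pool))
attr(traj, "converged"); steps_to_convergence(traj)
#> TRUE            # reached the equilibrium region
#> 14              # control steps (= seconds at the 1 s hold)

trajs <- run_offline_trajectories(as.matrix(expand.grid(c(-1,0,1), c(-1,0,1))),
                                  motor, sensory, session$test_pool, seed = 2)
metric_report(trajs, plant_params(), field)
#> metric_report over 9 trajectories
#>   convergence rate : 1.000
#>   mean steps       : 9.78
#>   mean RMSE        : 0.2163 m
#>   mean MIDT        : 0.5516 m
```

All nine starts converge, in ~10 steps on average, deviating ~0.22 m RMS
from the ideal continuous-field trajectory. How much information the
decoded forces carry about the stimulus:

```r
forces <- t(sapply(unlist(session$test_pool, recursive = FALSE),
                   function(r) decode_force(motor, r)))
correct_bias(rep(1:4, each = 100), forces, seed = 3)
#> mi_estimate: plugin 1.9128 bits, corrected 1.9006 bits
#>   bias: analytic 0.0018, shuffle 0.0104; bootstrap null -0.0066
```

1.9 of the maximal 2 bits: at 5 ms resolution the latency-coded population
nearly identifies the stimulus on single trials. `parameter_sweep()`
repeats this over bin widths, windows, offsets and population fractions,
and `info_performance_correlation()` relates information to closed-loop
performance.

A command-line surface wrapping the same functions
(`generate | calibrate | run-online | run-offline | sweep | report`) is
installed at `system.file("cli", "dni.R", package = "dnifield")`.

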