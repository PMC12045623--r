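# neurorbit

Analysis of how target motion modulates reach-direction coding in motor
cortex populations during flexible manual interception — single-neuron
mixed-selectivity statistics, PCA "orbital" neural-state geometry, population
decoding, and a task-trained recurrent network — together with a synthetic
data generator that makes the entire chain testable against known ground
truth.

The package is written for systems/computational neuroscientists who study
population coding in motor areas: it works on generic trial-labelled rate
tensors (neurons x trials x time bins plus per-trial labels), so recorded
sessions and simulated populations run through identical code.

## The science in brief

In the interception task a target moves on a circle of radius 15 cm at a
signed angular velocity in {-240, -120, 0, 120, 240} deg/s and the reach
ends where the target will be at touch. Around movement onset (MO), a
neuron's cosine direction tuning

    FR = offset + depth/2 * cos(theta - PD)

can be modulated by target velocity in three ways, modelled with a shared
sigmoidal velocity dependence (vc = vel/120):

* gain — `FR = (a1*sig(a2*vc) + c2) * cos(theta - pd) + c1`
* PD shift — `FR = a1 * cos(theta - pd - a5*sig(a2*vc)) + c1`
* addition — `FR = a1 * cos(theta - pd) + a3*sig(a2*vc) + c1`

At the population level, single-trial neural states (window-averaged,
z-scored rates projected on the first three PCs) form rings ordered by
reach direction — one ring per velocity condition. The rings are fitted as
3D ellipses; the tilting angle between each moving-condition ring and the
static ring grows linearly with signed velocity (CCW positive), the
geometric signature of gain-like modulation, while additive modulation
layers rings vertically and PD-shift modulation rotates the direction
clusters. A 200-unit rectified-tanh rate network trained to produce
minimum-jerk interception movements reproduces the same orbital geometry
from its node population.

## Worked example

Simulate the standard pure-gain population (300 model neurons, 5 velocity
codes x 64 reach directions), extract MO-window neural states, and measure
the orbital geometry:

```r
library(neurorbit)

pop <- build_model_population(c(gain = 300), seed = 1)
ns  <- neural_states(pop, window = c(50, 150), n_pcs = 3)
round(ns$explained_variance[1:3], 2)
#> [1] 49.06 48.95  1.05

geometry_summary(ns)
#> Orbital geometry summary
#>  target_velocity   tilt rotation shift shift_vertical r2_ellipse
#>             -240 -19.65        0 7.269              0          1
#>             -120  -9.27        0 4.029              0          1
#>                0   0.00        0 0.000              0          1
#>              120   5.99        0 4.029              0          1
#>              240   8.77        0 7.267              0          1
#> tilt = 0.0601 * vel -2.83 (R^2 = 0.95)
```

The first two PCs carry ~98% of the variance (the direction-coding plane);
the per-condition rings are perfect ellipses (R² = 1) whose tilt against
the static ring is monotone in velocity and antisymmetric in rotation
direction, while the vertical shift stays zero — the fingerprint of pure
gain modulation. Running the same pipeline on a pure-additive population
gives zero tilt and a vertical shift growing with |velocity|.

A noisy synthetic session with known per-neuron ground truth validates the
modulation classifier:

```r
gt   <- synth_ground_truth(c(gain = 6, pd_shift = 6, additive = 6),
                           rate_scale = 2, seed = 3)
sess <- generate_noisy_session(gt, trials_per_cell = 8, noise = 0, seed = 4)
classify_modulation(sess, neuron = 1, seed = 5)
#> Modulation: gain
```

On a deterministic session every neuron classifies exactly as its
generating kind. Training an interception network and measuring its node
geometry uses the same downstream code:

```r
net <- train_rnn(n_steps = 1500, seed = 21)      # ~minutes on one core
validate_rnn(net, rnn_validation_set(200))$mean  # endpoint error, a.u.
#> [1] 0.0095                                      # target radius = 0.15
node_geometry(net, trials_per_cell = 5, seed = 12)$tilt_fit
#> $slope      0.259
#> $intercept  5.24
#> $r2         0.992
```

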