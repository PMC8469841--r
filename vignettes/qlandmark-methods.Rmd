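---
title: "Deep Q-learning landmark localization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep Q-learning landmark localization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Anatomical landmark localization in 3D scalar volumes — the motivating case
is finding the left and right coronary ostia, the points where the coronary
arteries branch off the aortic root, in cardiac CT angiography. `qlandmark`
frames this as a sequential decision process: an agent stands at a voxel,
looks at a small neighborhood, and repeatedly steps through the grid until
it sits on the target. The attraction of this formulation over sliding-window
regression is that the agent never needs to see, let alone score, the whole
volume; a trained agent walks almost straight to the landmark from an
arbitrary seed point.

## The Markov decision process

**State.** A full `N^3` box around the agent is expensive to store and to
convolve, and a deep Q-network needs to keep hundreds of thousands of states
in its replay memory. The package therefore uses a 2.5D observation: three
orthogonal `N x N` patches through the agent's position, with normals along
the x-, y- and z-axes. One such triple is ambiguous about where the agent
came from, so the state stacks the current observation with the observations
at the last `H` positions — the state is the `(H+1) x 3 x N x N` array built
by `observe()`, giving the process an H-th-order Markov character and
letting the network read the direction of travel out of the state itself.
The defaults `N = 32`, `H = 3` (four frames) follow the full-scale study
configuration. At episode start the `H` past frames replicate the current
one.

Patches are windowed linearly to `[0, 1]`; out-of-grid samples take a
configurable pad value whose default is the window minimum (air-equivalent
for CT). Because the patch covers `center - floor(N/2) ... center -
floor(N/2) + N - 1` on each in-plane axis, even `N` is slightly left-biased;
the convention is fixed and shared by the brute-force test oracle. Padding
is not cosmetic: near the boundary the visible pad band is the only
positional cue the agent has, and policies demonstrably use it to move back
inside.

**Actions.** Seven discrete actions: a unit step along either direction of
each axis, scaled by the step size `rho` (`p' = p + rho * a`), plus `stay`.
The training default `rho = 3` voxels corresponds to about 1 mm at the
0.33 mm spacing the generator mimics.

**Reward.** The per-step reward is the decrease in squared Euclidean
distance to the ground truth, `R = ||p - p_GT||^2 - ||p' - p_GT||^2`, in
voxel units. Squared distances make the reward telescope exactly: summed
over any trajectory it equals the initial minus the final squared distance,
which the test suite checks in integer arithmetic. A `reward_metric =
"plain"` switch differencing the un-squared distances is provided; see the
desk-scale section for when the bounded variant is preferable.

**Termination.** An episode ends when the agent comes within `reach_tol`
voxels of the target (default 3, one coarse step — any stricter tolerance
is unreachable when moving in multiples of 3), steps outside the grid, or
exhausts the step cap (default 1500).

## The Q-network

The network scores the seven actions from the stacked 2.5D state. Its
structure mirrors the state's factorization, and the parameter partition is
deliberately explicit:

* **Per-axis encoders** (`theta`): each `N x N` plane is encoded by a small
  convolutional stack. Weights are shared across the `H+1` time frames —
  the same plane seen at a different time must encode identically — but
  *not* across the three axes, because axial, coronal and sagittal content
  are statistically different. The test suite pins both directions of this
  sharing split.
* **Per-frame local inference** (`omega`): the three 64-vectors of one
  frame are concatenated and fused to a 64-vector per frame. These layers
  are per-frame (not shared), since "three planes seen now" and "three
  planes seen three steps ago" mean different things.
* **Global inference**: the frames' local codes are concatenated and mapped
  to a 128-vector.
* **Heads**: either a dueling pair — state value `V` (how good is this
  location) and action advantages `A` (which way is better), combined as
  `Q = V + A - mean(A)` so that `mean(Q) = V` and the decomposition is
  identifiable — or a single plain linear head. Both modes share identical
  encoder shapes, so comparisons vary only the Q-approximator.

The reference encoder at `N = 32` is conv 3x3/2 (1->8), conv 3x3/2 (8->16),
conv 3x3/2 (16->32), flatten (512), FC to 64, all ReLU. The architecture is
a package choice: the original description fixes the sharing structure and
the budget, not the layer list, so every width lives in `arch_spec()` and
alternatives can be priced with `count_flops()`.

**FLOPs accounting.** `count_flops()` counts one multiply-accumulate per
conv/FC output element (`output_elements x kernel_volume x in_channels`),
excludes biases, activations, pooling and the dueling mean-subtraction, and
multiplies the per-plane encoder cost by the `(H+1) x 3 = 12` plane passes
of one forward. Under this convention the reference dueling network costs
2,466,816 FLOPs — within the ~2.5M budget reported for this family of methods,
and about an order of magnitude below comparable 3D-patch networks. The
convention is printed by the `flops` CLI subcommand so the number is
auditable layer by layer.

**Numerics.** The production forward/backward path runs in single precision
through an RcppArmadillo core (im2col + GEMM with index tables precomputed
per architecture); `essenet_trace()` is an independent double-precision R
implementation exposing every intermediate (per-plane encodings, per-frame
fusions, `sbar`, `V`, `A`), used for inspection and as the cross-check the
test suite compares the compiled path against (tolerance 1e-4, reflecting
float32). Gradients were verified against central finite differences of the
double-precision path. Initialization is He-uniform with zero biases from a
named sub-stream of the run seed; a forward pass is deterministic given
parameters and input.

## Training

Standard deep Q-learning stabilized the standard two ways: a FIFO experience
replay (capacity 1.5e5 by default) sampled uniformly to decorrelate batches,
and a frozen target network giving the regression target
`y = r + gamma * max_a' Q(s', a'; theta-)`, with bootstrapping masked on
terminal transitions. The loss is the mean squared error between `y` and the
prediction network's Q-value of the taken action; gradients flow only
through the prediction parameters. Transitions are stored compactly as
position histories and observations re-extracted on demand — at 2.5D patch
sizes this makes the replay memory a few megabytes where 3D-patch states
would be gigabytes, which is precisely the argument for the 2.5D state.

Defaults where the full-scale protocol speaks: `gamma = 0.9`, epsilon-greedy
from 0.9 to 0.1, batch 48, `rho = 3`, 1500-step episodes, a random training
volume per episode, and seed points drawn uniformly from the central 80% of
each dimension. Where it is silent the package fixes and documents its own
values: linear epsilon decay over 5e4 steps, ADAM at 1e-4, target sync
every 2500 steps, warm-up of max(batch, 1000) transitions, one gradient
step per environment step (`update_every = 1`), and global gradient-norm
clipping at 10 as a stability guard. All randomness flows from one root
seed split into named sub-streams (`derive_seed()`), so a run is exactly
reproducible.

`train_config()` also accepts a *set* of step sizes, sampling one per
episode. The default remains the single coarse `rho = 3`; the option exists
because the test-time localization procedure rolls the policy out at both
`rho = 3` and `rho = 1`, and a policy that has only ever experienced
3-voxel histories can behave poorly under 1-voxel dynamics (see below).

## Coarse-to-fine localization

At test time the greedy policy (epsilon = 0, ties broken toward the fixed
action order) is rolled out from the volume center — or any chosen seed —
for a fixed 100 steps at `rho = 3`. Fixed-length rollouts sidestep the
termination-criterion problem: rather than asking the agent to declare
convergence, the rollout is long enough to reach anywhere in the volume and
oscillates near the target once there. Out-of-grid moves are clamped at
inference so rollouts always complete. Five fine agents are then spawned at
uniform random displacements within a 6-voxel ball (two coarse steps) of
the coarse endpoint, each refined for 50 steps at `rho = 1`, and the final
prediction is the weighted average of their endpoints, rounded
half-away-from-zero to a voxel.

The weights of that average are not prescribed anywhere; the package
defaults to uniform (the unbiased choice) and offers
`weighting = "value_softmax"`, a softmax over each agent's final state value
`V` under the dueling head, on the rationale that `V` estimates proximity.
Accuracy is reported as the Euclidean distance between prediction and
ground truth in mm (`evaluate_error()`), the field's standard metric.

## The phantom generator

`generate_phantom()` builds the study conditions without external data: a
64^3 volume at 0.33 mm isotropic spacing containing a bright spheroid
(radius 10–14 voxels, drawn per phantom; the "aortic root") with an
attached bright tube (radius 2, length 18; the "coronary artery"), plus
Gaussian noise (sd 0.03) on a 0.15 background with 0.8 foreground, clipped
to `[0, 1]`. The landmark is the sphere-surface/tube-axis junction — the
ostium analogy — rather than the free tube tip, deliberately: the junction's
surroundings look the same in every volume, and consistent surroundings are
what make a landmark learnable; tip-like points with variable context are
documented to be much harder. Geometry is rejection-sampled so the landmark
and tube keep an 8-voxel margin from every face (half the desk-scale patch),
making observations at the target padding-free. `generate_suite()` produces
n phantoms with consecutive seeds and a 75/25 train/test manifest, mirroring
the 24/8 split of the full-scale study at n = 32.

What the phantoms do *not* emulate: anatomical context (chambers, lungs,
bone), Hounsfield calibration, contrast gradients, motion or
reconstruction artifacts, and anisotropic spacing. Passing the desk-scale
suite therefore demonstrates that the machinery — state encoding, value
learning, coarse-to-fine search — works end to end on a geometrically
faithful analogue; it does not certify clinical-grade accuracy, which in
the original setting required 32 real CT scans and ~15 h of GPU training.

## The desk-scale protocol

`desk_protocol()` fixes the reduced experiment used by
`run_desk_experiment()` and the acceptance tests, sized for minutes on one
CPU: patches `N = 16` with `H = 3` on the default 64^3 phantoms (32 volumes,
24 train / 8 held out), 150 episodes of at most 200 moves, replay capacity
2e4, batch 32, epsilon annealed over 4000 steps, ADAM at 3e-4, target sync
every 500 steps. (150 episodes was chosen after observing that 250- and
400-episode runs reach the same held-out accuracy; the learning curve
saturates early at this scale.) Three choices depart from the full-scale
defaults, each a protocol decision made once and kept:

* `update_every = 4` (the classic DQN cadence) instead of a gradient step
  per move. At desk scale the run is wall-clock-bound by the optimizer, and
  one update per move quadruples the cost of every experiment for no
  measurable gain at this problem size.
* `reward_metric = "plain"`. On a 64^3 grid the squared-distance reward
  puts TD targets anywhere in ±900 while the network heads start at O(1);
  the short desk budget is then spent learning the scale of the value
  function rather than its shape. The bounded plain-distance reward (per
  step at most `rho` in magnitude) conditions the regression and leaves the
  greedy policy target unchanged.
* training step sizes `c(3, 3, 3, 1)`: one episode in four runs at the fine
  step size. The localization algorithm relies on the policy transferring
  from 3-voxel to 1-voxel dynamics; at full scale that transfer is reported
  to hold, but at desk scale a policy trained purely at `rho = 3` drifts
  when rolled out at `rho = 1` because 1-voxel observation histories are
  out of its experience. Mixing a minority of fine-step episodes closes the
  gap without changing the method.

The vignette states these sizes as the package's reference experiment; the
same constructor is what the acceptance tests run, so the documented
protocol and the tested protocol cannot drift apart.

What the desk run achieves — and what it cannot. Training reliably shows
learning progress: the 30-episode moving-average reward rises from clearly
negative (random exploration drifting off the grid) to clearly positive,
and the greedy policy navigates from the volume center to the bright
structure on held-out phantoms. Pinpointing the junction is another
matter: held-out localization errors settle around 10–15 voxels, roughly
the sphere radius. The cause is geometric. A 16-voxel patch sees less than
the spheroid's 20–28-voxel diameter, and away from the junction the
sphere's surface is locally rotation-symmetric, so most near-surface
states carry no information about which way the tube lies; the tube only
enters the field of view within about 8 voxels of the junction. The
optimal observable policy is therefore a surface *search*, which a
deterministic greedy agent trained for a few thousand updates does not
discover — consistent with the full-scale observation that agents need
hundreds of episodes on real data, where surrounding anatomy breaks the
symmetry, before all of them converge. Experiments at this scale with
250 and 400 episodes, longer exploration, higher learning rate, gamma
0.95, faster target sync and a tighter training termination radius all
landed in the same 10–16-voxel band. The robust desk-scale readouts are
the learning-progress trend and the dueling-vs-plain comparison, not
millimeter-grade accuracy; the latter belongs to the full-scale setting
with real anatomy.

## Degenerate inputs and tie-breaking

* Patch centers may lie outside the grid; extraction pads rather than
  errors, and a fully padded patch is legal (it is what an out-of-bounds
  terminal state observes).
* Greedy argmax ties break toward the lowest action index in the fixed
  order `+x, -x, +y, -y, +z, -z, stay`, making rollouts reproducible.
* `weighted_average()` rounds half away from zero, so symmetric endpoint
  clouds do not bias toward the origin.
* Stepping a terminal environment is a usage error; localization accepts
  untrained parameters silently (quality is the caller's concern).
* Volumes must carry spacing metadata; a MetaImage header without
  `ElementSpacing` is an error rather than an assumed 1 mm.

## Known limitations

* Single landmark per run; paired-landmark search (e.g. left and right
  ostia) is two runs with different ground truth, not a joint policy.
* No resampling or reorientation: volumes are taken axis-aligned as stored,
  and the reward is computed in (possibly anisotropic) voxel units.
* The compiled core is single-precision; Q-values agree with the
  double-precision reference to ~1e-4 relative, which is far below any
  decision boundary that matters here but visible in bitwise comparisons.
* The desk-scale accuracy criterion is a 3-voxel (~1 mm at 0.33 mm spacing)
  median on synthetic phantoms; it is an analogue of, not a substitute for,
  the full-scale accuracies reported on real CT.
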