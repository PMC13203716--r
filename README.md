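# squatsim

Predictive, quasi-static simulation of barbell-squat posture under load,
for biomechanists, strength coaches and movement modellers who want to ask
*"what posture becomes mechanically necessary as the bar gets heavier?"*
rather than *"what moments did an observed posture require?"*.

## The model in one paragraph

The body is a rigid-segment chain (fixed feet, shanks, thighs, pelvis,
rigid torso) whose global posture is reduced to five generalized
coordinates `q = (xp, zp, ψp, φp, θt)`: pelvis position in the sagittal
plane, pelvis yaw, pelvic obliquity and torso pitch.  Knees follow from
planar two-link inverse kinematics in each leg's own vertical plane.  An
intended squat is generated as a smooth reference trajectory
(`f(s) = 3s² − 2s³` scaling of drop, backshift and rotations over 40
frames).  Each of the seven joints (L/R ankle, knee, hip; torso) resists
deviation `Δθ` from its reference angle with a bounded moment

    M = My · tanh(k Δθ / My),      Π = (My² / k) · ln cosh(k Δθ / My),

and yields — a permanent stiffness drop `ke → kp ≈ 0.075 ke` — once
`|M| ≥ 0.95 My`.  At every frame the corrected posture minimizes

    Π(q) = ½ (q − q_ref)ᵀ K (q − q_ref)  +  Σⱼ Πⱼ(Δθⱼ)  +  (Wb/2)(zSL + zSR)

(tracking + joint energy + barbell potential, `Wb = m g` through the
shoulders) subject to coordinate bounds and leg-reachability constraints,
warm-started from the previous frame.  Load-dependent technique changes —
posterior pelvis shift, forward lean, demand redistribution, yielding —
emerge from this competition; nothing is prescribed.

## Worked example

```r
library(squatsim)

cfg <- squat_config()              # packaged published parameter set
sim <- run_simulation(cfg, mass = 100)
sim
#> <squat_sim> 40 frames, barbell 100 kg
#>   max pelvis backshift 0.177 m, drop 0.607 m, torso pitch 71.2 deg
#>   peak |moment| (N m): ankle 43.0, knee 104.1, hip 119.5, torso 243.7
#>   max utilization: demand 2.18, bounded 0.97; 1 yield event(s)

sim$yield_log
#> # A tibble: 1 × 6
#>   joint frame     s moment k_before k_after
#>   <chr> <int> <dbl>  <dbl>    <dbl>   <dbl>
#> 1 torso    29 0.718   244.     5000     375
```

Reading this: under a 100 kg bar the lifter still reaches the intended
0.60 m depth (plus ~7 mm of gravity-driven sag) but the pelvis stops 3 mm
short of the intended 0.18 m backshift, and the torso — intended to pitch
30° — is driven to 71°: at frame 29 the torso joint's moment (244 N·m)
reached 95 % of its 250 N·m capacity, it yielded, its stiffness dropped
permanently from 5000 to 375 N·m/rad, and the posture reorganized around
the softened joint.  The demand utilization of 2.18 (> 1) flags the
yielding; the bounded utilization stays below 1 by construction of the
saturating law.

Load sweeps, tidy accessors and plots:

```r
sweep <- sweep_loads(cfg)          # masses 0, 60, 100, 140 kg
glance(sweep$sims[["0kg"]])        # zero load: backshift 0.180 m, drop 0.600 m, pitch 30.0 deg
tidy(sim)                          # per-frame per-joint moments/utilizations
autoplot(sim, type = "moments")    # ggplot joint-moment histories
write_outputs(sweep, "out/")       # trajectory/moments/utilization/summary CSVs + manifest.json
```

At 0 kg the corrected motion coincides with the reference exactly (every
objective term vanishes there), so the summary reproduces the reference
amplitudes; with rising mass the pitch increases strictly and joint demand
grows.  A command-line wrapper ships at `inst/cli/squatsim.R`
(`simulate`, `sweep`, `reference` subcommands).

Configurations are plain JSON using the published parameter names
(`L_shank`, `pelvis_drop_max`, `nSteps`, ...); `read_config()` loads them,
unknown keys are rejected, and every run's `manifest.json` reproduces the
run bit-identically via `read_manifest()`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the packaged defaults, the peak-response
quantities of the four-load sweep: the maximum pelvis drop common to all
load cases (t1, metres), and the bodyweight-case maximum pelvis backshift
(t2, metres) and maximum torso pitch (t3, degrees), writing them as JSON.
The pipeline is deterministic; `--seed` is honoured for completeness.
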