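---
title: "Modelling cardiac-to-coronary coupling with coroflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiac-to-coronary coupling with coroflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coroflow)
```

## What the model is

`coroflow` simulates the human circulation as a closed loop of lumped and
single-element distributed compartments, beat by beat, with a mechanistic
coronary circulation embedded in it. The point of the model is
*cardiac-to-coronary coupling*: myocardial contraction does not only drive
aortic pressure (which perfuses the coronaries), it also squeezes the
intramural coronary vessels and impedes their flow, most strongly in the
subendocardium. Because both effects come from the same myofiber mechanics,
the model can ask how changes in the heart (here: severe aortic valve
stenosis) propagate into coronary flow waveforms.

The parts, from inside out:

* **Ventricular mechanics — one-fiber walls and three-wall interaction.**
  Each wall (LV free wall, septum, RV free wall) is a thick spherical cap
  with fixed wall volume `Vw`, midwall area `Am` and curvature `Cm`.
  Myofiber tension is assumed homogeneous across a wall; the representative
  natural fiber strain is
  `eps = 0.5*log(Am/Am_ref) - z^2/12 - 0.019*z^4` with `z = 3*Cm*Vw/(2*Am)`.
  Total fiber stress is the sum of an active part
  (`sig_act * activation(t) * f_len(Ls) * f_v(dLs/dt)`, with a linear
  length dependence above slack length and a linear force-velocity
  de-rating of shortening) and an exponential passive part. Wall tension
  is `Tm = (Vw*sigma/(2*Am)) * g(z)` with `g(z) = atanh(z)/z`; for a
  closed sphere this reproduces the thick-wall Laplace relation
  `p = (sigma/3) * log(1 + Vw/Vcav)` *exactly*, which the tests use as an
  independent oracle. The three ventricular walls meet in a junction
  ring; a damped Newton iteration finds the septal cap volume and
  junction radius at which the axial and radial tension components
  balance. Atria are single-wall spherical chambers with the same
  constitutive law and an earlier activation onset. A non-linearly
  compliant pericardium (`p = s*((V/Vref)^k - 1)`) surrounds the
  chambers, walls and epicardial coronary blood volume.

* **Conduit vessels.** Large systemic, pulmonary and coronary vessels
  are non-linear elastic tubes of fixed length with one volume state
  each. Their pressure-area law is the same collapsible-tube law as the
  microcirculation (below); their ends present the characteristic wave
  impedance `Z = rho*c/A` with `c = sqrt((A/rho) dp/dA)`, and junction
  flows are driven by internal pressure differences across the summed
  end impedances. A single element per vessel resolves the flow
  distribution and the impedance seen by its neighbours, not intra-vessel
  wave profiles; this is a deliberate scope decision (see Limitations).
  The coronary tree is the left main bifurcating into LAD and LCx, plus
  the RCA, all from the ascending aorta; three coronary veins drain via
  the distal coronary sinus (left branches) and proximal coronary sinus
  (joined by the right) into the right atrium. "Distal coronary sinus
  flow" therefore carries the left coronary venous return, which is why
  its reference mean is the sum of the LAD and LCx target flows.

* **Coronary microcirculation.** Each branch perfuses a bed with an
  epicardial arterial compartment, three transmural layers (subepi, mid,
  subendo, radial positions 1/6, 3/6, 5/6), each with an arteriolar and
  a venular compartment, and an epicardial venous compartment. Every
  compartment obeys the pressure-area law

  `p_trans = p0*[((A+0.5*Aw)/(A0+0.5*Aw))^(k/3-1) - max(0, (A/A0)^-0.7 * (Aw/A0)^0.4 - 1)^2]`

  whose first factor anchors `p_trans(A0) = p0` (the exponent is read as
  `k/3 - 1`; the alternative reading fails this anchor) and whose second,
  collapse, term makes transmural pressure progressively negative as the
  lumen empties. Compartment resistances follow Poiseuille scaling with
  volume, `R = R0 * V0^2 / V^2`; the shared middle resistance `Rm`
  represents the capillaries, which have no volume state, and therefore
  keeps its reference value. Reference resistances derive from the
  branch target flow and the mean perfusion pressure drop
  (`R0 = dp0/q0`), split 28:65:7 over epicardial arterial,
  intramyocardial and epicardial venous compartments and 60:30:10 within
  the intramyocardial block. Layer target flows honour the
  subendo-to-subepi flow ratio of 1.11 with the mid layer halfway.

* **Coupling.** Tissue pressure in layer `r` of a branch is the
  mass-weighted territory average (Table-driven: RV wall 100% RCA;
  septum 60% LAD / 40% RCA; LV free wall 42% LCx / 33% LAD / 25% RCA) of
  `IMP = CEP + VE` per wall, with `CEP = r*P1 + (1-r)*P2` (cavity
  pressure transmitted linearly across the wall; for the septum the two
  bounding pressures are LV and RV, with `r` measured from the RV side)
  and `VE = gamma*sigma_f` with `gamma = 0.06` shared by all walls,
  sized so that peak VE is about 20% of peak LV pressure. `sigma_f` is
  the wall's total (active + passive) fiber stress. IMP acts as external
  pressure on the six intramyocardial compartments; the epicardial
  compartments feel pericardial pressure instead.

* **Valves and control.** Valves are orifice-Bernoulli flow channels
  with blood inertance; flow is clamped at zero when closed. Between
  beats, a homeostatic controller nudges circulating volume toward the
  mean-arterial-pressure target and the systemic peripheral resistance
  toward the value that carries the systemic share of the target cardiac
  output at that pressure (measured venous pressure and coronary flow
  feed this update). Coronary autoregulation tuning then rescales each
  layer's reference arteriolar resistance (a damped secant update,
  re-running to periodic steady state between iterations) until every
  layer's beat-averaged flow is within 1% of target. The aortic-stenosis
  scenario reuses the tuned coronary parameters unchanged and alters
  only the aortic orifice area (4.8 to 0.8 cm^2).

## Reference conditions and parameters that matter

The reference simulation encodes: heart rate 71 bpm, cardiac output
5.1 L/min, mean arterial pressure 91 mmHg, systolic duration 41% of the
cycle, branch target flows RCA/LAD/LCx = 112/83/60 mL/min, endo-to-epi
ratio 1.11, wall volumes LV/S/RV = 108/45/39 mL (myocardial density
1.055 g/mL, so territory masses are 88.3/65.8/47.9 g), aortic orifice
4.8 cm^2, integration step 1 ms. These are fixed study conditions, not
tuning knobs.

A second group of parameters is structural but not observable at this
scale, and is calibrated once against the reference hemodynamics (the
calibration script ships in `scripts/calibrate.R`):

* One-fiber constants (`sig_act_kpa = 85`, length dependence with slack
  at 1.55 um, `v_max = 3 /s`, exponential passive stress, wall reference
  midwall areas). Calibrated so the converged reference beat ejects the
  target stroke volume at the target pressure with peak LV pressure near
  110 mmHg and peak fiber stress such that VE peaks near 20% of peak LV
  pressure.
* Vessel geometry (lengths, reference areas). Coronary artery reference
  areas set the velocity scale (about 15 cm/s mean) relative to the
  tuned flows; stiffness exponents k = 13 for coronary conduit arteries,
  10 for veins, 8/10 for the systemic/pulmonary tubes.
* Microcirculatory volumes and wall laws (per-gram compartment volumes,
  `k` and `Aw/A0` per compartment class, operating reference pressures
  85/70/22/5 mmHg). These control the depth of systolic squeezing, the
  refill time constants, and hence the diastolic-dominant arterial and
  systolic-dominant venular waveforms. Two sub-decisions deserve
  emphasis: the epicardial arterial compartment is small and stiff, so
  that blood displaced from the arterioles in systole raises its
  pressure enough to throttle (and briefly reverse) inlet flow - this is
  what produces the high peak diastolic-to-systolic velocity ratio - and
  compartment `p0` values are anchored at typical operating pressures
  rather than at the ideal resistor-chain node pressures, so compartments
  sit near `V0` (hence near `R0`) in vivo; the autoregulation tuning
  absorbs the residual mismatch in the arteriolar reference resistance.
  A `p0_mode = "chain"` variant anchors the chain exactly and is used by
  the isolated-bed consistency tests.

## Numerical choices

* Explicit Euler at the stated 1 ms step, with two local refinements:
  the valves' quadratic orifice drag is treated implicitly in the flow
  update (the drag time scale approaches the step under severe
  stenosis), and valve flow cannot drain its upstream chamber below
  about 1 mL in a step. An RK4 option exists for step-halving
  (Richardson) checks; the scheme is first order and the tests verify
  the error scales accordingly.
* The TriSeg junction Newton iteration uses a finite-difference
  Jacobian, damped line search, warm starts from the previous step and
  a multi-start fallback; tolerance 1e-8 relative, with stalls accepted
  below 1e-4 relative (force residuals at that level correspond to
  pressure errors well below 0.01 mmHg).
* Compartment and tube volumes are smoothly floored at 1% of reference
  (softplus clamp) so the collapse regime stays finite; the floor is
  exact (no perturbation) away from collapse.
* Periodicity is declared when the beat-to-beat relative change of every
  state falls below 1e-3 and the controller targets are met within 1%.
  From a cold start the reference needs roughly 100-150 beats plus some
  tens of autoregulation iterations of a few beats each; the stenosis
  rerun warm-starts from the tuned reference state. Deterministic
  throughout: no random numbers are used anywhere.

## What the synthetic fixtures emulate

Unit tests drive a single coronary bed with analytic half-sinusoid
cavity-pressure and fiber-stress waveforms (`make_driven_bed_fixture`),
which isolates the microcirculation and coupling from the heart. The
fixture reproduces the qualitative physiology (early-systolic
subendocardial retrograde flow, systolic venular dominance, monotone
suppression of subendocardial systolic flow as gamma grows) but not the
aortic pressure pulse, wave timing, or pericardial feedback - so passing
fixture tests demonstrates mechanism, not closed-loop quantitative
agreement, which the scenario-level acceptance tests cover.

## Known limitations

* Single-element tubes do not resolve intra-vessel wave propagation or
  dispersion; wave impedance enters only through junction coupling.
* No autoregulatory vasodilation or flow reserve: the stenosis case
  deliberately freezes coronary parameters, and chronic adaptation
  (hypertrophy, increased demand) is out of scope.
* The shortening-induced intracellular pressure mechanism is
  deliberately excluded from IMP; IMP is CEP plus stress-proportional VE
  only.
* Under severe aortic stenosis with output and pressure maintained, the
  mean coronary flow reduction the model produces (about a fifth of the
  LAD flow, with the subendo/subepi ratio falling to about 0.9) is
  weaker than the reductions reported from comparable modelling; a
  periodic tissue pressure can depress mean flow only through the
  volume-resistance and collapse non-linearities, and in this
  single-compartment-per-layer realization that pathway saturates. The
  early-systolic retrograde flow and all qualitative stenosis signatures
  are reproduced.
* The RCA bed's subendocardial squeeze is governed by its
  territory-mass-weighted tissue pressure, over half of which comes from
  septal and LV segments; its diameter change therefore lands nearer 60%
  of the left-branch value than the ~33% reported from per-segment
  anatomical assignments.
* Atrial coronary supply is not modelled; territory assignment is the
  standard population-level mapping, carried as wall-mass fractions.
* Segment subdivision of the LV free wall (12) and septum (5) is
  carried structurally (labels and mass fractions) but the default
  material parameters are uniform per wall, so all segments of a wall
  share one stress trajectory unless the user overrides per-segment
  properties.

## Reading results

```{r example}
fit <- coroflow() # tuned reference simulation
summary(fit) # metrics table
plot(fit) # pressure, coronary velocity, layer flow, diameter panels
sten <- coroflow(scenario = "aortic_stenosis")
summary(sten)
```

`summary()` reports, per branch: mean flow (mL/min), endo-to-epi flow
ratio, peak diastolic-to-systolic velocity ratio (pDSVR), the diastolic
fraction of the velocity-time integral (DTVi, antegrade-clipped
convention with retrograde flow reported separately), peak systolic
velocity (m/s), and the end-diastole to end-systole subendocardial
arteriolar diameter change (%, diameter proportional to the square root
of compartment volume). Global rows give cardiac output, mean arterial
pressure, peak LV pressure, the mean transvalvular gradient over the
ejection period, the peak aortic jet velocity (valve flow over effective
orifice area), and mean distal coronary sinus flow. Phase windows
bracket systole by LV ejection (aortic valve open to closed); diastole
is everything else including both isovolumic phases, with an
`isovolumic_in_systole` variant available.
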