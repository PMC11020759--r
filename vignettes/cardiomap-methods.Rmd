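---
title: "cardiomap: models, measurement conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardiomap: models, measurement conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(cardiomap)
```

`cardiomap` analyzes dual-channel cardiac optical-mapping recordings —
membrane potential (V~m~) and intracellular calcium (Ca~i~) movies acquired
at 2 ms/frame and 0.25 mm/pixel — and ships a ground-truthed synthetic
tissue generator so that every stage of the analysis can be verified
without animal data. This vignette documents the science inside the
package: the tissue and calcium models, the measurement conventions, the
statistical machinery, and the design decisions that were genuinely open.

## The excitable tissue model

The generator integrates a two-variable excitable membrane model (a fast
inward current balanced by a slow outward current, with a single recovery
gate) on a 2-D sheet:

$$\partial_t v = h\,v^2(1-v)/\tau_{in} - v/\tau_{out} + D\nabla^2 v + I_{stim},$$
$$\partial_t h = \begin{cases}(1-h)/\tau_{open} & v < v_{gate}\\
-h/\tau_{close}(x,y) & v \ge v_{gate}\end{cases}$$

This class of model was chosen because its action-potential-duration (APD)
restitution is analytically tractable, which lets the alternans machinery
be validated against closed-form results. Integration is forward Euler
with a 5-point Laplacian, no-flux outer boundaries, and an internal step of
0.1 ms (stability requires $D\,\Delta t/\Delta x^2 \le 1/4$; the default
$D = 0.1\ \mathrm{mm^2/ms}$, $\Delta x = 0.25$ mm gives 0.16). The infarct
scar is an internal unexcitable no-flux region; its pixels emit baseline
fluorescence plus noise only. `tau_close` is a per-cell map, which carries
both the peri-infarct border-zone APD prolongation (default factor 1.1)
and the drug effect.

Default membrane constants ($\tau_{in} = 0.3$, $\tau_{out} = 6$,
$\tau_{open} = 30$, $\tau_{close} = 60$ ms, $v_{gate} = 0.13$) were
calibrated once, on a paced strip, so that the paced sheet reproduces the
emulated study's baseline working point: APD80 $\approx 123$ ms at a
pacing cycle length (PCL) of 300 ms, ventricular effective refractory
period (VERP) $\approx 135$ ms, and conduction velocity
$\approx 0.33$ mm/ms. The drug condition is purely parametric:
`drug_apd_factor` (default 1.09) multiplies `tau_close`, prolonging APD
and ERP; `drug_ca_factor` (default 0.95) multiplies the calcium decay
constant. No kinetics or washout are modelled.

## The calcium subsystem

Calcium is a driven relaxation equation with an explicit release gate:

$$\partial_t [Ca] = g\,S(w)\,s(v) - [Ca]/\tau_{Ca},$$

where $s(v)$ gates release on depolarisation and $S(w)$ is a sharp
sigmoid of a release gate $w$ that inactivates with its own constant
(`tau_ca_release`, default 80 ms, i.e. release shuts off roughly
$80\ln 2 \approx 55$ ms after the upstroke). Two properties motivated the
explicit gate:

* after release terminates the decay is a clean monoexponential with the
  *known* constant $\tau_{Ca}$, so the decay-fitting stage has exact
  ground truth (a release source that lingered through the plateau biased
  fitted decay constants upward by 40% in early experiments);
* the release duration is independent of `tau_close`, so the drug
  prolongs APD without materially changing the calcium transient
  duration, as observed in the emulated study.

## Fluorescence and noise model

The camera model is $F_{Vm} = 1 - 0.8\,V + \varepsilon$ (inverted
polarity, the voltage-dye convention) and $F_{Ca} = 0.1 + 0.8\,[Ca] +
\varepsilon$, with i.i.d. Gaussian pixel-frame noise. The signal-to-noise
ratio is defined as the median peak-to-peak signal of non-scar pixels over
the noise standard deviation; the study default is 20 dB. An optional slow
exponential drift (`bleach_tau_ms`) emulates photobleaching, and the
`detrend = "linear"`/`"exponential"` preprocessing options remove it.

## Measurement conventions

* **Activation** is the time of maximal upstroke velocity (max dF/dt),
  refined by parabolic sub-frame interpolation; derivatives are centred
  differences (a one-sided derivative biases times by half a frame). A
  50%-crossing detector is available (`method = "midpoint"`), and a
  stimulus-anchored variant (`anchor = "stimulus"`) serves the calcium
  channel, whose upstroke is too slow for derivative detection under
  noise.
* **APD80/CaTD80** run from activation to the first downward crossing of
  `peak - 0.8 * (peak - baseline)`, linearly interpolated between frames;
  the per-beat baseline is the median of the 20 ms window before the
  upstroke (robust to drift). Failure to repolarise before the next beat
  flags the beat invalid rather than erroring.
* **Calcium decay tau** is a least-squares monoexponential
  $A e^{-(t-t_0)/\tau} + C$ starting at the 20%-repolarization crossing of
  the fitted beat. The window runs to the end of the beat's diastole (next
  activation or trace end) rather than stopping at deep repolarization:
  with a free offset, a truncated window leaves $(\tau, C)$
  ill-conditioned, which Monte-Carlo showed to inflate $\tau$ by ~8% with
  a 40% spread at 20 dB; the full-diastole window brings recovery to
  within 2% of truth. Window landmarks are located on a lightly smoothed
  copy of the trace while the fit itself uses raw samples, because
  crossing detection on noisy samples is conditionally biased. Fits with
  $\tau \notin (1, 1000)$ ms are flagged invalid.
* **Quality mask**: per-pixel SNR is the variance of the temporally
  smoothed trace over the first-difference residual variance, in dB
  (threshold 6 dB by default). The mask is built on the *unsmoothed*
  normalized movie: spatial smoothing bleeds signal into the scar and
  inflates its apparent SNR. Fewer than 25 analyzable sites is an explicit
  error, mirroring the minimum-sites rule of the emulated protocol.
* **Alternans**: per site, the signed mean over consecutive beat pairs of
  (first − second); APD alternans are significant when the difference
  exceeds 10 ms, calcium-amplitude alternans when it exceeds 5% of the
  pair mean (the denominator is a package choice; the source protocol does
  not state one). Beat parity is aligned across sites on the stimulus
  index, so a missed beat at one site cannot flip its apparent phase.
  Discordance requires significant regions of both signs of at least 10
  connected pixels (suppressing noise speckle); the nodal line is the
  zero contour of the 3x3-smoothed signed map.
* **Alternans threshold**: PCLs are scanned downward (default 300 to 80 ms
  in 10 ms steps) with the cable state carried across steps like a real
  decremental protocol; the threshold is the longest PCL with a
  significant site, and the scan stops at loss of 1:1 capture. At the
  shortest PCLs the last 1:1 beats before capture loss are evaluated even
  when fewer than four remain, since alternans there are largest.
* **Phase** is the analytic-signal (Hilbert) phase of the mean-subtracted
  trace (delay embedding available); singularities are plaquettes of
  winding number $\pm 2\pi$ on 2x2 loops — the smallest loop, hence
  maximal spatial resolution — linked across frames within 3 px and kept
  when they survive 2 frames.
* **Conduction block**: edges between activated neighbours with more than
  4 ms/px activation-time difference, plus boundaries of
  unactivated-but-valid regions (functional block) and of activated tissue
  against the excluded scar (fixed block).
* **Rhythm**: beats are envelope peaks above median + 8 robust SDs with a
  refractory guard; "rapid" means a coupling interval below 80% of the
  baseline cycle; "organized" means the sliding 5-beat coefficient of
  variation of cycle lengths stays at or below 0.15; three or more
  consecutive rapid organized beats are VT, rapid disorganized beats VF,
  episodes of 30 s or more are sustained. A premature ventricular beat is
  a non-paced beat with coupling below 85% of the running median cycle;
  the beat after an ectopic is never itself counted. These numeric
  thresholds operationalise qualitative definitions and are configurable
  and echoed into every report.

## The restitution cable

The fast surrogate for paced tissue iterates
$APD_{n+1} = APD_{max} - a\,e^{-DI_n/\tau_r}$ with $DI_n = PCL - APD_n$.
Its slope at diastolic interval DI is $(a/\tau_r)e^{-DI/\tau_r}$, and the
slope-1 period-doubling cycle length is
$APD_{max} - \tau_r + \tau_r\ln(a/\tau_r)$
(`restitution_bifurcation_pcl()`), the analytic oracle for the threshold
scan. With several sites, conduction-velocity restitution
$CV(DI) = cv_0(1 - b\,e^{-DI/\tau_{cv}})$ produces spatially discordant
alternans with a nodal line, the classical mechanism, and a premature
stimulus delivered after a train blocks at the node — the fixture used to
verify nodal-line/conduction-block co-localization. Baseline cable shape
$(a = 50, \tau_r = 12)$ puts the analytic onset near 132 ms so the
detected (>10 ms) threshold sits near 127 ms; the drug shape
$(a = 45, \tau_r = 26)$ flattens restitution and lowers the onset toward
115–120 ms while keeping a wide enough diastolic margin that the >10 ms
criterion is reached before 1:1 capture is lost (steeper drug shapes left
the threshold unmeasurable in a sizeable fraction of hearts).

## The synthetic study

`run_study()` examines `n_hearts` (default 14) hearts under baseline and
drug conditions. Per heart, between-heart variability is drawn once:
target APD80 $\sim N(123.1, 7^2)$ ms, calcium decay
$\tau \sim N(50.3, 4.5^2)$ ms, an ectopy burden from a gamma distribution
with mean 0.55/min and SD 0.55, and an anatomical reentry-circuit ratio
$\sim N(0.97, 0.035^2)$ (see below). Each examination runs the full
pipeline on simulated movies: burst pacing at PCL 300 ms with 6
conditioning beats and 8 recorded beats (the deterministic model reaches
its fixed point within a few beats at this cycle length, so the long
conditioning trains used experimentally are unnecessary), signal
conditioning, quality masking, feature extraction on a grid subsample of
analyzable sites, aggregation under the 25-site rule, decay fits on the
final beat, an S1–S2 scan for ERP on the tissue model with snapshot reuse,
and a decremental threshold scan on the heart's calibrated cable
(`apd_max` tracks the heart's *measured* APD80 + 4 ms).

**Inducibility** uses a mechanistic surrogate rather than full
reaction–diffusion reentry induction: a heart/condition is induced when
(i) the extrastimulus protocol on its CV-restitution cable with a
border-zone APD step produces unidirectional block — a premature beat
captured proximally but blocked at the step — and (ii) the reentrant
circuit can sustain, i.e. its cycle length lies at or below the
restitution map's period-doubling PCL, the regime in which the functional
block anchoring the circuit persists (the restitution hypothesis). The
circuit cycle length is an anatomical per-heart fraction of baseline
refractoriness, constant across conditions, so the drug acts on
inducibility only through its electrophysiological effects. Induced
episodes are emitted as beat trains (organized cycles near the circuit
length, degrading to disorganized cycles deep in the unstable regime) and
classified by the rhythm module like any recording.

**Ectopy monitoring** synthesises a 20-minute pseudo-ECG of sinus rhythm
(cycle 400 ms) with Poisson focal ectopy from the border zone, thinned by
a 100 ms refractory window. The candidate rate is analytically compensated
for the two loss mechanisms — refractory thinning and late-diastolic
events that fail the 85% prematurity rule — so the *detected* burden
matches the heart's programmed burden.

The report compares conditions with paired Student's t-tests (continuous
metrics) and Fisher's exact test (inducibility), both implemented from
first principles (`paired_t_test()`, `fisher_exact()`; the Fisher p-value
uses the point-probability two-sided convention, the most common one). No
multiple-testing correction is applied, matching the emulated analysis.
For the 10/14 vs 2/14 inducibility counts the exact two-sided p is
0.00633; published values for such counts sometimes differ because the
two-sided convention or an underlying pairing structure is not printed —
the package reports its own exact convention.

## What the generator does and does not emulate

Emulated: paced propagating action potentials with upstroke, plateau and
repolarization; calcium transients that follow voltage with tunable decay;
restitution-driven concordant and spatially discordant alternans with a
nodal line; an unexcitable scar emitting only noise; a border zone with
prolonged APD; focal ectopy with refractory suppression; pseudo-ECG far
fields; and a parametric drug effect. Not emulated: motion artifacts (the
experiments used an excitation–contraction uncoupler), dual-camera
registration, dye spectra, spatially correlated noise, pacing-electrode
artifacts, full reaction–diffusion reentry (see the inducibility
surrogate above), and drug pharmacokinetics. Passing tests therefore
demonstrate correctness of the measurement pipeline against a model with
known truth, not performance on raw experimental video.

## Numerical choices and problem sizes

Integration step 0.1 ms; movies down-sampled to 2 ms frames. Robust
normalization uses the 2nd/98th percentiles per pixel; zero-range pixels
are invalidated, never divided by zero. Level crossings are linearly
interpolated (2 ms frames are coarse relative to the 10 ms alternans
rule). Tie-breaks in beat detection keep the larger envelope peak. The
test suite exercises the pipeline on 16–30 px tissues with 3–8 recorded
beats and a 3-heart miniature study; the acceptance script runs the full
14-heart study on a 50 x 50 px tissue (about 8 minutes on one CPU) and
the 200-seed decay-constant Monte-Carlo. The emulated field of view is
100 x 100 px; all algorithms are resolution-independent and the default
`tissue_geometry()` remains 100 x 100.

## Known limitations

The membrane model has no explicit ionic currents, so drug mechanisms are
phenomenological; CaTD80 depends on the release-gate constant and sits
somewhat below the emulated study's values; the inducibility surrogate
captures the restitution mechanism but not all routes to reentry (e.g.
triggered activity); and the alternans threshold is quantized to the
10 ms scan grid, which contributes most of its between-heart variance at
fixed parameters.
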