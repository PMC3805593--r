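---
title: "Phase-synchronization network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchronization network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synchnet)
```

## What this package computes

`synchnet` analyses event-related multichannel EEG as a sequence of
weighted functional networks. The chain is:

1. **Trial selection and filtering.** Only correctly answered trials are
   kept. Each 1200 ms post-stimulus trial is band-pass filtered into the
   beta band (13–30 Hz), the band most associated with motor cognition.
2. **Instantaneous phase.** The analytic signal
   \(z(t) = x(t) + i\,\mathcal{H}[x](t)\) (Hilbert transform
   \(\mathcal{H}\)) yields the instantaneous phase
   \(\varphi(t) = \arg z(t)\) per channel.
3. **Mean phase coherence (MPC / PSI).** For two channels with phases
   \(\varphi_1, \varphi_2\),
   \(R = \lvert \langle e^{i(\varphi_1(t) - \varphi_2(t))} \rangle_t \rvert
   \in [0, 1]\): 1 means a perfectly constant phase difference (1:1 phase
   locking), values near 0 mean no locking. MPC is computed per trial
   over each of three cognitive sub-stage windows — Beginning
   \([0, 300)\) ms (stimulus encoding), Middle \([300, 800)\) ms (mental
   rotation), End \([800, 1200)\) ms (response) — for every channel pair,
   then averaged within each of the 12 stimulus types (2 hands × 6
   rotation angles), giving 12 association matrices per subject per
   sub-stage.
4. **Networks.** Each 28×28 association matrix is thresholded by
   retaining its \(k\) largest edges at their original weights
   (\(k = 90\) by default). Nodal clustering uses the Onnela
   geometric-mean form on weights scaled by the network maximum; the
   global coefficient \(C\) is the mean over all nodes. Path lengths use
   reciprocal weights; \(L\) is the mean shortest path over reachable
   pairs. Betweenness counts fractional shortest-path traffic through
   each node. Small-worldness is
   \(\sigma = (C / C_{rand}) / (L / L_{rand})\) against the means of 20
   size-matched random surrogates.
5. **Statistics.** Mixed-design repeated-measures ANOVA with GROUP
   (control vs patient) between subjects and HEMISPHERE / ANGLE / HAND
   (or CHANNEL, for nodal measures) within subjects; per-threshold and
   per-channel two-sample t-tests; Benjamini–Hochberg FDR at
   \(q = 0.05\).

## The synthetic cohort generator

No public recording accompanies the study design this package targets,
so the generator is a first-class, tested module. Channel \(i\) carries

\[
s_i(t) = \sin\!\big(2\pi f t + \theta(t) + \delta_{h(i)}(t)
          + \varepsilon_i(t)\big) + \eta_i(t)
\]

* \(f\): beta carrier, default 20 Hz with ±0.5 Hz uniform per-subject
  jitter, keeping energy mid-band after filtering.
* \(\theta(t)\): a slow shared random-walk phase drift (default
  1 rad/\(\sqrt{s}\)); common to all channels, so it cancels in every
  pairwise coherence.
* \(\delta_{h}(t)\): a per-hemisphere phase offset, von Mises with
  concentration `inter_hemi_kappa` redrawn every jitter block. It makes
  inter-hemispheric pairs less coherent than intra-hemispheric pairs —
  the dominant HEMISPHERE effect in real data. Midline channels carry no
  offset and are excluded from the hemispheric pair classes anyway.
* \(\varepsilon_i(t)\): independent per-channel von Mises jitter,
  piecewise constant over 20 ms blocks, with concentration
  \(\kappa_{\mathrm{eff}} = \kappa_{s} \cdot g_{\mathrm{angle}}(a) \cdot
  g_{\mathrm{group}}(g, s)\) for sub-stage \(s\); the profile is blended
  across sub-stage boundaries with a 20 ms raised-cosine ramp because
  real phase dynamics are continuous and hard steps would ring through
  the narrowband filter.
* \(\eta_i(t)\): white noise, default SD 0.3 (moderate SNR against the
  unit-amplitude carrier).

The jitter model was chosen because its expected coherence has a
closed/integrable form: for two channels with concentrations
\(\kappa_1, \kappa_2\), the asymptotic MPC is
\(A(\kappa_1) A(\kappa_2)\) with \(A(\kappa) = I_1(\kappa)/I_0(\kappa)\)
(times \(A(\kappa_{inter})^2\) across hemispheres), and the expectation
of the finite-sample estimator over \(n\) independent blocks follows
from the CLT for the complex mean. The test suite's recovery oracle
integrates exactly that, independently of the generator code.

### Default presets (the stated world)

| parameter | control | patient | why |
|---|---|---|---|
| \(\kappa\) (Beginning, Middle, End) | 1.5, 2.0, 1.5 | same | coherence rises during mental rotation |
| group gain | 1, 1, 1 | 1, **0.6**, 1 | the group deficit is confined to the Middle (rotation) window |
| angle gain | \(1 + 0.15(1-\cos a)/2\), peak at 180° | same | the "angle effect": PSI maximal at 180° |
| `inter_hemi_kappa` | 1.5 | 1.5 | inter < intra hemispheric PSI |
| blocks per subject | 6 | 2 | patients tolerate shorter sessions |
| accuracy | 0.97 | 0.90 | realistic mental-rotation error rates; the paper's companion behavioural data are not printed, so these are fixed once |
| subjects | 11 | 11 | two cohorts of eleven |

Each block is an exact multiset of 96 stimuli — angles 0° and 180° at
25%, the four oblique angles at 12.5%, hands balanced within every angle
— randomly permuted; only the order is random. All randomness derives
from one cohort seed through a documented per-subject / per-trial seed
derivation, so identical seeds give byte-identical cohorts.

### What the generator does *not* emulate

No volume conduction or forward model, no ocular/muscle artifacts, no
reaction times, no 1/f background spectrum. A green test therefore
establishes that the pipeline recovers *phase-coupling structure it is
pointed at*, with correct statistics under the stated design — not that
it is robust to every pathology of scalp EEG.

## Numerical choices

* **Zero-phase filtering.** The filter family and order are not fixed by
  the source design, and phases are the analysis target, so zero phase
  distortion is mandatory. We apply the *squared magnitude response* of a
  4th-order Butterworth band-pass (bilinear-prewarped edges) in the
  frequency domain, over trials padded by odd reflection. This has the
  identical magnitude characteristic of a forward–backward ("filtfilt")
  pass — effective order 8, −6 dB at 13 and 30 Hz — and exactly zero
  phase, while avoiding the transient-initialisation machinery of a
  recursive implementation (no filter-design package is assumed).
  Measured: < 0.1% attenuation at 20 Hz, ≈ −100 dB at 5 Hz.
* **Hilbert on the full trial.** Phases are extracted over the whole
  1200 ms (with reflection padding in the batched path) and then sliced
  into sub-stage windows; the transform's edge artifacts would otherwise
  load on the 300-sample Beginning window. Filtering likewise precedes
  segmentation; the test suite shows segment-interior agreement between
  the two orders and much larger segment-edge transients.
* **Per-trial MPC, then averaging.** MPC is computed per trial per
  window and matrices of the same stimulus type are averaged
  (element-wise mean), rather than concatenating trials before MPC —
  consistent with "averaging all matrices of the same stimulus type".
* **Diagonal fixed at 0**, excluded from averages and from top-k
  selection; self-synchrony is uninformative and would eat threshold
  slots.
* **Top-k ties** at the k-th weight break by lexicographic (row, column)
  order of the upper-triangle pair — deterministic and documented. Ties
  have probability zero for continuous data.
* **Unreachable pairs** are excluded from \(L\) and their count is
  reported (`n_unreachable_pairs`). A 90-edge network on 28 nodes is
  often disconnected; substituting infinity would make \(L\) undefined
  and substituting a constant would invent scale.
* **Zero-degree nodes** enter the global clustering mean with value 0
  (the definition averages over all nodes).
* **Betweenness is unnormalised** over unordered pairs; group contrasts
  are unaffected by a common scale factor.
* **Random ensemble**: "size-matched" is read as the stricter standard —
  degree-preserving (Maslov–Sneppen) rewiring with the original weight
  multiset permuted onto the rewired edges; an Erdős–Rényi null is
  selectable (`null = "er"`), and is also the automatic fallback if
  rewiring is infeasible.
* **ANOVA**: closed-form balanced sums of squares (identical to
  `aov()`'s `Error(subject/(...))` partition, verified in the tests, but
  orders of magnitude faster for the 28-level CHANNEL factor). No
  sphericity correction by default — the reference design reports plain
  integer df. Subjects missing any within-cell are excluded from that
  ANOVA with a logged message; imputation would invent data.
* **Midline channels** (Fz, Cz, Pz, Oz) belong to none of the three
  hemispheric pair classes, keeping left/right/inter disjoint; the
  reference design never assigns them.

## Desk-scaling in the test suite

Heavy validation criteria are scaled in *problem size only*, never in
model parameters, thresholds, or tolerances:

* power and design-reproduction tests run cohorts at 250 Hz sampling
  with one 96-stimulus block per subject — the 20 ms jitter blocks mean
  the per-window count of independent coupling draws (what MPC
  statistics depend on) is unchanged by the sampling-rate scaling;
* surrogate ensembles use 5 networks where \(\sigma\) is not itself the
  quantity under test (it is 20 wherever it is);
* the type-I calibration permutes group labels on a *null* cohort (both
  groups from the control preset): with a real effect present,
  relabelling produces two-component mixtures in each pseudo-group and
  the nominal level of the F-test is not guaranteed, so the exchangeable
  null is the correct setting for a 5% ± 3% band.

## Known limitations

* 1:1 phase locking only; no \(n\!:\!m\) locking, no surrogate-based
  PSI significance, no amplitude-based connectivity.
* The 28-channel montage is a reconstruction (a 32-electrode 10–20 cap
  minus reference, mastoids and EOG); every function accepts a
  user-supplied montage.
* EDF I/O is not provided; recordings enter as plain delimited
  channel × sample matrices plus a trial-metadata table
  (`write_epochs()` / `read_epochs_dir()` document the layout).
* The per-channel-pair coupling surface is parameterised per channel
  (plus hemisphere offsets), not per pair: under the independent-jitter
  model, pairwise coherence is the product of per-channel resultants,
  so arbitrary per-pair targets are not realizable in this model class.
* `generate_cohort()` at the full default design holds ~2 GB in memory;
  the pipeline streams subject by subject instead.
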