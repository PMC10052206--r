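---
title: "Entropy-based complexity trends for beat-to-beat hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based complexity trends for beat-to-beat hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(qctrends)
```

## Motivation

During a head-up tilt test (HUTT), a patient is passively tilted upright
while heart rate and blood pressure are monitored, in the hope of provoking
— and thereby diagnosing — a vasovagal response. The clinically dangerous
moment, syncope, is conventionally announced by a fall in mean blood
pressure (MBP) and/or heart rate (HR). By the time those thresholds are
crossed, however, the collapse is already under way.

`qctrends` monitors something different: how *organized* the cardiovascular
control system is. Each beat yields a vector of hemodynamic variables; over
a sliding window we ask which pairs of variables move together in a
statistically demonstrable way, how many bits of information those couplings
carry, and we condense the answer into a single bounded quantity, the
complexity `C`, measured in bits. The working hypothesis is that a failing
regulation loop becomes transiently *more* coupled — extra compensatory
feedback is recruited — before pressure ever drops, so a surge in `C` above
its own baseline can precede the conventional alarms.

## The beat-to-beat state vector

The pipeline consumes beat-by-beat records with six primitive channels — HR,
SBP, DBP, MBP, left-ventricular ejection time (LVET), pre-ejection period
(PEP) — plus the raw impedance-cardiography (ICG) quantities `z0`, `dzmax`
and `trc`. From these, `assemble_state_matrix()` derives five more variables
per beat:

* stroke volume `SV = VEPT * dzmax * LVET / z0` (Kubicek-type ICG formula),
  where the volume of electrically participating tissue `VEPT` comes from
  the subject's weight, height and sex via `compute_vept()`;
* cardiac output `CO = SV * HR / 1000` (L/min);
* the Heather contractility index `HI = dzmax / trc`;
* total arterial compliance `TAC = SV / (SBP - DBP)`;
* systemic vascular resistance `SVR = 80 * (MBP - CVP) / CO`, with an
  assumed central venous pressure carried on the `qct_subject`.

Missingness is propagated honestly: if a primitive is absent on a beat, every
variable derived from it (and only those) is masked. Beats with `SBP <= DBP`
mask the pulse-pressure-derived cells with a warning rather than aborting.

## Detecting a dependency: rank pixelation

Pearson correlation would miss nonlinear couplings and be distorted by the
heavy-tailed, drifting distributions typical of physiological data. Instead,
each pair of variables in a window of `M` beats is turned into a small
image:

1. Both series are converted to ranks (ties broken by position, so the
   procedure is fully deterministic).
2. Ranks are cut into `b = mesh_side(M) = floor(sqrt(M))` equal-frequency
   bins; for the canonical 100-beat window this is a 10 × 10 mesh with
   exactly 10 points per row and per column.
3. The joint histogram of the bin pair is the "pixelated" image.

Because only ranks enter, the statistic is invariant under any strictly
monotone transformation of either variable — units, offsets and sensor
nonlinearities drop out. The equal-frequency margins mean the marginal
entropy of each variable on the mesh is exactly `log2(b)` bits when no data
are missing, which is what makes the bounds below tractable.

The strength of a coupling is the mutual information of the image in bits.
Significance is judged against permutation surrogates: one series is
repeatedly re-paired with a permuted copy of the other, and the exact
p-value `(1 + #{surrogate MI >= observed}) / (n_surrogates + 1)` is compared
to `alpha` (default 0.05 with 200 surrogates). The surrogate permutations
are generated by a dedicated counter-based generator keyed on
`(seed, window, pair)`, so results are reproducible bit for bit and R's
global random-number state is never touched.

## From dependencies to complexity

For a window with `N` usable variables, the dependency engine produces:

* `S`: an `N × N` 0/1 adjacency matrix (unit diagonal) marking the pairs
  whose coupling passed the surrogate test;
* `E`: an entropy matrix whose diagonal holds the marginal entropies and
  whose off-diagonal entries hold the *joint* entropy of each structured
  pair (zero where no dependency was established).

The complexity is the spectral norm (largest singular value) of the Hadamard
product:

```
C = || S ∘ E ||_2   (bits)
```

A fully decoupled system contributes only its diagonal, so `C` collapses to
the largest marginal entropy; each established coupling adds off-diagonal
mass and pushes `C` up. Two companions make the number interpretable:

* `complexity_bounds()` returns `C_min` (all off-diagonal couplings absent)
  and `C_critical` (every pair maximally coupled at the mesh resolution),
  so each trend point can be read as a position inside a feasibility
  corridor;
* `complexity_profile()` attributes the total to individual variables,
  normalized to sum to 100, either by leave-one-out deletion (default) or
  from the dominant eigenvector. A symmetric two-variable system splits
  exactly 50/50.

`dependency_map()` exposes the same window as a graph (optionally as an
`igraph` object, GraphML or JSON) for inspection of *which* couplings drive
a surge.

## The sliding-window trend and event detection

`qct(records, subject, window = 100, step = 10)` slides the canonical
100-beat window across the recording. Each window is timestamped by its
*last* beat, so the trend is strictly causal: appending future data never
changes past values, which is a prerequisite for any online warning claim.

`detect_surge()` implements the alert rule: from a user-chosen baseline
interval it takes the median and MAD of `C` and fires at the first run of at
least `s = 5` consecutive trend points exceeding `median + k * MAD`
(`k = 6`; a 5 % floor protects against a degenerate MAD of zero). For tilt
protocols the baseline should be a *settled head-up* interval — the tilt
transition itself produces a legitimate, transient complexity spike that
would otherwise be read as an alert. `reference_events()` supplies the
conventional comparators (sustained MBP and HR drops), and `lead_time()`
reports how far ahead of them the complexity alert fired.

## The synthetic tilt-test generator

Real HUTT recordings with annotated ground truth are scarce, so the package
ships a physiologically structured generator (`simulate_hutt()` plus
`scenario_presets()`). It is built on four latent autonomic states —
venous return, sympathetic tone, vagal tone and vasomotor tone — each
following a smoothed AR(1) trajectory between phase-dependent targets.
Observable channels are algebraic functions of the latents plus measurement
noise, and the stored ICG primitives are constructed by *inverting* the SV
formula, so derived values recompute exactly from the primitives.

Three design choices matter for realism:

* a **baroreflex** couples MBP back to cardiac output, buffering beat-level
  noise so that resting couplings are decisive rather than borderline;
* a **low-frequency vasomotor oscillation** (period ≈ 22 s, the classic
  Mayer-wave band) is switched on during orthostatic stress and during the
  pre-syncopal prodrome, with the vagal latent in antiphase. This is what
  transiently synchronizes the channels and produces both the tilt-induced
  complexity spike and the pre-syncopal surge;
* the **vasovagal collapse** presets follow the mixed-type sequence: MBP
  decline begins first, HR depression follows, syncope is declared when MBP
  crosses the syncopal threshold. The `type1_mixed_with_warning` preset adds
  a prodromal phase in which the oscillation ramps up well before either
  conventional threshold is reached.

Four presets cover the study arms used throughout the tests: a supine
baseline, a tilt-negative protocol with a nitroglycerin provocation, and two
mixed-type collapse scenarios (abrupt and with prodrome). `inject_gaps()`
adds bursty per-channel dropouts for robustness studies.

## Choice of window and mesh sizes

The defaults — 100-beat windows on a 10 × 10 mesh, step 10, `alpha = 0.05`,
200 surrogates — balance three pressures: the mesh needs roughly `b^2`
points for the joint histogram to be informative (`M = b^2` exactly, by
construction); shorter windows react faster but have noisier `C` (the test
suite verifies that 50-beat windows have at least the variance of 125-beat
windows on stationary data); and at ~1 beat/s a 100-beat window spans under
two minutes, short enough to be clinically useful during a tilt protocol.

## Limitations

* The surrogate test controls the per-pair false-positive rate, not the
  family-wise rate across the 55 pairs of an 11-variable window; `C` is
  therefore best read as a *trend* against its own baseline rather than an
  absolute scale.
* `C` is a thresholded-edge statistic: couplings sitting near the
  significance boundary can flip between adjacent windows, which is the
  dominant source of trend noise and of sensitivity to channel dropouts.
* The generator is a caricature — useful because its ground truth is exact,
  but its parameter values are tuned for plausibility, not fitted to
  patient data. Claims about real recordings require real recordings.

## A minimal end-to-end run

```{r, eval = FALSE}
scn <- scenario_presets(seed = 1)$type1_mixed_with_warning
sim <- simulate_hutt(scn)
fit <- qct(sim$records, scn$subject, window = 100, step = 5)

alert <- detect_surge(fit, baseline = c(380, 650))
refs <- reference_events(sim$records, baseline = c(380, 650))
lead_time(alert, refs$mbp_drop)       # > 0: the alert came first
sim$truth$events$syncope - alert$time # seconds of warning before syncope
```
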