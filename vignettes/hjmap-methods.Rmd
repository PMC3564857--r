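---
title: "Mapping single-base DNA differences from Holliday-junction nanomechanics: models and methods"
author: "hjmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single-base DNA differences from Holliday-junction nanomechanics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hjmap)
```

## The measurement principle

A nearly palindromic DNA construct is tethered between a surface and a
magnetic bead. Unwinding the bead extrudes a four-way (Holliday) junction
at the center of symmetry; every bead turn feeds half a helical repeat
(`hr_dna / 2 = 5.225` bases at 10.45 bp/turn) into each lateral arm, so a
junction positioned `b` bases from the center corresponds to a rotation

$$R = -\frac{2b}{\mathrm{HR}_\mathrm{DNA}}.$$

In a magnesium-containing buffer the junction migrates freely through
homologous sequence but cannot advance past a mismatch between the two
recombining strands: the mismatch acts as a ratchet (retraction and
mismatch resorption remain easy). Once blocked, further unwinding is
stored as plectonemes and the extension-versus-rotation curve traces a
rescaled, shifted copy of the plectoneme formation curve. Fitting each
such "plectoneme curve-segment" for its rotation offset `Ri`, and
converting rotations back to bases, maps the sequence differences — with
sub-helical-repeat precision — without sequencing.

Three models underlie the analysis:

* **Migration line.** While the junction migrates, the extension falls
  linearly, $h = H_0 (1 - |R| / N_0)$. Its zero-height intercept defines
  `N0`, the effective helical turns of the relaxed tether
  (`estimate_N0()`).
* **Reference curve.** Near zero rotation (no junction), the extension
  follows a bell-shaped plectoneme formation curve. Normalized by `H0`
  and `N0` it becomes a function of the relative winding
  $\sigma = R / N_0$, fitted once per molecule (`fit_reference()`).
* **Blocked segments.** A blockage at rotation `Ri` with `Ni` effective
  turns remaining in the tether follows
  $h = H_0 \frac{N_i}{N_0}\, C\!\left(\frac{R - R_i}{N_i}\right)$,
  where $C$ is the normalized reference curve. With
  $N_i = N_0 - |R_i|$ the apexes of successive segments are collinear
  with the migration line (`blocked_height()`, `fit_blockage()`).

## The forward simulator

The study's raw traces are not publicly deposited, so the package carries
a forward model (`simulate_protocol_run()`) that generates the same kind
of data the instrument records, plus ground truth for testing. It
emulates:

* the exact turn bookkeeping of the junction (ratchet state machine
  `step_hj()`: conservation of applied turns between migration and stored
  plectonemes is exact);
* the go-and-return measurement protocol: 1-turn steps, fast-mode probe
  descents of 14 turns (2.5 s/cycle), slow-mode re-acquisitions of 25
  turns (10 s/cycle) when a new blockage is met, and restarts 2 turns
  above the previous start. The decision to re-acquire is driven by the
  generator's ground truth — it emulates an attentive experimenter — while
  noise-based detection is left to the analysis-side detector, which is
  tested against the truth labels;
* Gaussian height noise per acquisition mode, and optional "rotation
  skids" (persistent shifts of the rotation reference from transient
  anchoring loss), at most one per run by default.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `N0` | 1200 turns | effective turns of the ~13-kb construct between anchors |
| `H0` | 2.76 um | maximum extension at the working force |
| `hr_dna` | 10.45 bp/turn | B-DNA helical repeat |
| `plecto_width` | 0.025 | mid-height half-width of the bell in sigma; ~30 turns at `N0 = 1200`, the observed tens-of-turns scale of extension loss at 0.2-0.4 pN |
| `noise_sd_slow` | 0.035 um | calibrated so the bootstrap SD of `Ri` on default runs falls in 0.5-0.6 turns (see below) |
| `noise_sd_fast` | 3 x slow | fast mode is the quick, noisier probe |
| fast/slow cycle | 2.5 / 10 s | protocol timing |

The bell itself is a power of a half-cosine,
$C(\sigma) = \cos(\pi\sigma/2)^p$, with $p$ set by `plecto_width`; it is
smooth, even, 1 at zero and 0 at $|\sigma| = 1$. Only the simulator knows
this form — the analysis side must recover the shape from data through
the spline fit, so any smooth even unimodal family would do.

What the simulator does **not** model: no worm-like-chain or twist
elasticity of the extension curve (the bell is phenomenological), no
Brownian bead dynamics, no force dependence beyond its phenomenological
entry through `H0`, `plecto_width` and the noise levels, no open-junction
physics of the magnesium-free buffer beyond "migration unblocked", and
drift-free noise (independent Gaussians). Passing tests therefore show
that the analysis chain inverts this class of data correctly — not that
it is robust to instrument drift or force miscalibration in real traces.

## Reference-curve estimation

`fit_reference()` normalizes the reference trace by `H0` (apex height)
and `N0`, folds the data to $|\sigma|$, and fits a least-squares
piecewise cubic (B-spline basis, `n_pieces = 8` uniform knot intervals)
with the derivative clamped to zero at $\sigma = 0$, then reflects it.
Evenness is thus exact by construction, not approximate. The apex
rotation — which defines $R = 0$ — is located by a local quadratic fit
around the coarse maximum rather than by the literal noisy maximum. If a
re-acquired end-of-run reference is supplied, the apex shift between the
two is reported as a rotation-skid offset. Eight pieces are enough that
doubling `n_pieces` changes the fit by less than the noise SD (tested);
the fit needs at least `2 * n_pieces + 4` points. Points outside the
fitted $|\sigma|$ domain are excluded by downstream consumers, never
extrapolated.

## Segment detection

`detect_segments()` works from the recorded trace alone:

1. descents = maximal runs of decreasing rotation;
2. per-mode noise SDs from second differences within descents (robust to
   the local trend), floored at 0.1% of the typical extension so
   thresholds remain meaningful on noiseless synthetic data;
3. the migration line by an iterative trimmed linear fit — blocked points
   lie below the line and are trimmed away;
4. a descent carries a blockage when it runs at least `k = 3` noise SDs
   below the line for 3 consecutive points (the persistence rule, not the
   threshold, controls false positives); it contributes its curve-segment
   cut just above the apex, located by a local quadratic fit;
5. curve-segments from different descents merge when they agree where
   they overlap (threshold accounting for both segments' noise); a
   segment whose apex lies above the previous segment's top opens a new
   blockage. When a slow-mode re-acquisition exists it alone carries the
   segment — the fast mode only probes, as in the protocol itself.

## Blockage fitting

`fit_blockage()` minimizes the weighted residuals of a segment against
the rescaled reference curve with the Levenberg-Marquardt algorithm
(minpack.lm). Following the original scheme, each point's residual in
relative-height units is multiplied by the weight

$$w = e^{3(h_\mathrm{rel} - 1)},$$

which makes the fit stringent at the top of the curve and tolerant of the
lower part (where bead proximity distorts real data; the simulator offers
this distortion only as an optional sag, off by default, and the weight
is kept regardless). One numerical choice matters: the residuals are
minimized on the **measurement scale** (multiplied by $H_0 N_i / N_0$)
rather than in relative units. The two agree exactly on noiseless data,
but relative residuals carry a noise scale proportional to $1/N_i$, so a
noisy fit can lower its objective simply by inflating `Ni` — in practice
dragging `Ri` to its bound. The measurement-scale form removes that
spurious gradient while preserving the published weighting. Initial
values are the apex rotation and the collinearity relation
$N_i = N_0 - |R_i|$; bounds are $N_i \in (0, N_0]$ and `Ri` within the
segment span plus or minus 5 turns; convergence at a relative parameter
step below 1e-8 or 200 iterations (non-convergence is flagged, with
parameters still reported). Because `N0` enters the reference
normalization and the residual scaling identically, the fitted `Ri` is
invariant under a change of `N0` (tested at 1200 versus 1000; `Ni`
absorbs the rescaling exactly).

`bootstrap_fits()` estimates errors by residual resampling: un-weighted
residuals from the upper half of the curves (fitted relative height at or
above 0.5 — thresholds 0.4/0.6 give similar spreads, tested) are pooled
across all segments of the run; each replicate adds resampled residuals
to the fitted curves and refits with the same weighted objective (the
original description leaves the replicate objective unstated; using the
main fit's objective is the natural reading). The replicate SD of `Ri`
is `boot_sd`, the mean shift `boot_bias`. The generator's slow-mode noise
default (0.035 um) was calibrated once so that `boot_sd` on default runs
lands in the 0.5-0.6-turn range; with symmetric Gaussian noise the
resulting `boot_bias` is small and positive but not a sharp prediction.

## Matching and calibration

`merge_unresolvable()` encodes the protocol's resolution limit: expected
blockages within 2 turns (about 10 bases) of a neighbor — transitively —
cannot be separated unless a descent starts between them, and are
replaced by their middle member (lower median on ties), flagged as
merged. `match_and_calibrate()` then pairs fitted and expected rotations
by an order-preserving dynamic-programming assignment (squared-error
cost about a trial offset; skips cost `skip_cost^2` with a 3-turn
default; a mild `1e-4 * offset^2` regularization prefers the smaller
common shift among near-equal assignments). On the matched pairs a line
of fixed slope one, $y = A + x$, is fitted: `A` is the mean residual and
absorbs any global rotation-skid (flagged above 1 turn), `sd_turns` the
residual SD, and `sd_bases = sd_turns * hr_dna / 2` its conversion to
bases (0.5 turns = 2.6 bases). Unmatched entries on either side are
reported, never dropped. `signature_gap()` returns the widest
blockage-free rotation interval, a fingerprint of the construct that
survives absolute-reference loss.

## Bypass kinetics

Blockage bypass under high mechanical stress is exponential in time:
`fit_exponential()` provides both the MLE (sample mean, with the exact
chi-squared interval) and a histogram least-squares fit
(Freedman-Diaconis bins) since the original fit style is not specified.
Two characteristic times at two temperatures give the activation
enthalpy through the Arrhenius law,

$$\frac{E_a}{k_b} = \frac{\ln(\tau_1/\tau_2)}{1/T_1 - 1/T_2},$$

reported both in units of $k_b T$ at a 300 K reference and in kJ/mol
(19 s at 30 C versus 3 s at 37 C gives ~83 kbT, ~206 kJ/mol). The torque
stored by `dR` turns beyond a blockage in a tether of contour length `L1`
under linear twist elasticity is
$\Gamma = k_b T \cdot 2\pi\, |\Delta R|\, C / L_1$ with the twist
persistence length `C` defaulting to 95 nm (midpoint of 90-100 nm);
estimates beyond the ~10 pN nm critical torque are flagged as outside the
linear regime. Tether lengths come from the construct arithmetic — a
junction at `b` bases from the center sequesters `2 b` bases in its side
arms — with a configurable helical rise (0.30 nm/bp by default, which
matches an 8.4-kb tether to ~2.5 um; 0.34 nm/bp is selectable since the
published conversion is internally loose).

## Sequence handling

`make_synthetic_homologs()` generates a diverged homolog pair (the tested
construct used two natural beta-lactamase variants at ~5% divergence;
those exact sequences are optional user input, not packaged data).
`find_differences()` compares the arms position-wise (equal lengths) or
after a global Biostrings alignment, warning below 80% identity. For the
fold-back construct, arm-a base $X$ opposite arm-b base $Y$ forms the
heteroduplex mismatches $X/\overline{Y}$ and $\overline{X}/Y$ (one per
recombined arm), reported alphabetically — an A/C difference gives
"A/G+C/T", G/C gives "C/C+G/G". A 1-bp indel becomes a pair of base
bulges at a single blockage locus; the data show such an indel blocks,
but give no finer rule.

## Problem sizes and determinism in the tests

The test suite simulates runs of eight well-separated blockages over
R = -465 to -545 (about 700 trace records each), uses 100-200 bootstrap
replicates per segment, 20 random instances for the grid-search oracle of
the Levenberg-Marquardt fit, and 1e5 draws for the law-of-large-numbers
check of the waiting-time generator; the full suite runs in well under a
minute. All stochastic tests fix their seeds; the end-to-end recovery
check asserts the calibrated bootstrap band (mean SD in 0.5-0.6 turns),
slope-one calibration with `sd_turns` at or below 0.6, and every matched
locus within three bootstrap SDs.

## Known limitations

* The resolution rule (2-turn default) and the detector constants
  (`k = 3`, 3-point persistence) are package choices; the source protocol
  gives none. Both are configurable.
* Composite segments from mismatches a few turns apart fit a single
  effective blockage with inflated bootstrap SD rather than being split.
* The matcher assumes at most a global rotation offset; piecewise skids
  within a single run (several skid events) are simulated but only the
  net offset is diagnosed.
* Real-data effects outside the noise model — drift, bead-size
  distortion of the lower curve (beyond the weight-factor mitigation),
  anchoring breakage — are not exercised by the synthetic tests.
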