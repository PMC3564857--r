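# hjmap

Locating single-base differences between two homologous DNA sequences
from magnetic-tweezers measurements of a Holliday-junction construct —
no sequencing, no probes, just DNA mechanics.

## The problem and the method

A nearly palindromic construct carrying the two sequences to be compared
(in opposite orientations) is held between a surface and a magnetic
bead. Unwinding the bead extrudes a Holliday junction at the center of
symmetry and drives its branch migration: each bead turn moves the
junction HR<sub>DNA</sub>/2 = 5.225 bases into each arm (helical repeat
10.45 bp/turn). Where the two sequences agree, migration is free and the
extension falls along the migration line *h* = *H₀*(1 − |R|/*N₀*). A
single-base difference forms a pair of mismatches that act as a ratchet:
the junction cannot advance past them, further unwinding is stored as
plectonemes, and the rotation–extension curve traces a rescaled, shifted
copy of the plectoneme formation curve,

> *h*(R) = *H₀* (*Nᵢ*/*N₀*) · C((R − *Rᵢ*)/*Nᵢ*),

whose offset *Rᵢ* marks the blockage. Fitting every such
"plectoneme curve-segment" (weighted Levenberg–Marquardt against a
mirror-symmetric segmented cubic-spline reference curve C, with a
residual-resampling bootstrap for errors) and converting rotations to
bases through base = −*Rᵢ*·HR<sub>DNA</sub>/2 maps the sequence
differences to a few bases. The package implements the complete chain —
a forward simulator of the traces (the raw experimental data are not
deposited), sequence comparison and blockage prediction, reference-curve
and blockage fitting, matching/calibration, and the Arrhenius/torque
analysis of blockage-bypass kinetics. See the methods vignette
(`vignettes/hjmap-methods.Rmd`) for the models and numerical choices.

Audience: single-molecule biophysicists analyzing rotation–extension
data, and anyone wanting a tested, self-contained reimplementation of
this mismatch-mapping analysis.

## Worked example

Simulate a mapping run over eight known loci, fit it blind, and compare:

```r
library(hjmap)
p   <- sim_params(seed = 3)                      # N0 = 1200, H0 = 2.76 um
mis <- c(2455, 2500, 2560, 2610, 2655, 2700, 2760, 2800)  # bases from center
tr  <- simulate_protocol_run(p, mis, R_start = -465, R_stop = -545)

n0  <- estimate_N0(tr[tr$segment_id == 0, ])     # migration-line intercept
ref <- fit_reference(simulate_reference_trace(p), N0 = n0$N0)
fits <- fit_blockages(tr, ref, n_boot = 200, seed = 3)
fits[[1]]
#> Blockage curve-segment fit: Ri = -535.832 turns, Ni = 630.3 turns
#>   24 points (0 excluded), weighted RSS 0.00886, converged
#>   bootstrap (200 reps): SD 0.316 turns, bias +0.043 turns

m <- match_and_calibrate(fits, expected_rotations(data.frame(base_index = mis)))
summary(m)
#> Blockage map: 8 matched pairs, A = +0.140 turns, SD = 0.340 turns (1.77 bases)
#>
#>   fitted_Ri expected_rotation base_index boot_sd residual
#> 1    -535.8            -535.9       2800  0.3157 -0.08644
#> 2    -528.6            -528.2       2760  0.4834 -0.46928
#> ...
```

All eight blockages are recovered on a slope-one line `y = A + x`: the
intercept `A` absorbs any global rotation offset, the residual SD of
0.34 turns corresponds to 0.34·10.45/2 ≈ 1.8 bases of mapping precision,
and each locus lands within its bootstrap error. (`estimate_N0`
extrapolates a long lever arm, so its value is loose — by design the
fitted `Ri` are invariant to the choice of `N0`.)

Sequence-side, the expected blockages come from the construct itself:

```r
arms <- make_synthetic_homologs(800, divergence = 0.01, seed = 3)
find_differences(arms, offset_to_center = 2200)
#> Mismatch table: 6 loci
#>   base_index         kind mismatch_pair expected_rotation
#> 1       2295 substitution       A/C+G/T         -439.2344
#> 2       2383 substitution       C/C+G/G         -456.0766
#> ...
```

Kinetics of forced blockage bypass:

```r
arrhenius_enthalpy(tau1 = 19, T1 = 30, tau2 = 3, T2 = 37)
#> Arrhenius activation enthalpy: 82.6 kbT (at 300 K) = 206 kJ/mol
torque_estimate(delta_R = 20, C = 95, L1 = tether_length(13200, 2386)$tether_nm)$gamma
#> [1] 19.55  # pN nm, flagged beyond the ~10 pN nm critical torque
```

A thin command-line surface wraps the same functions
(`exec/hjmap {simulate|design|fit-reference|fit-blockages|map|kinetics|run-all}`);
`run-all` on the default JSON configuration writes every stage's TSV/JSON
artifact, each stamped with the seed and a configuration hash.

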