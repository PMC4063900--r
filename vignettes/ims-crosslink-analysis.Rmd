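---
title: "Characterising di-tyrosine cross-linked peptide oligomers by IMS-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising di-tyrosine cross-linked peptide oligomers by IMS-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dityrims)
```

## The problem

Soluble oligomers of the amyloid-beta peptide are leading candidates
for the neurotoxic agent in Alzheimer's disease, and oligomers from
biological sources are far more stable (and more toxic) than those
assembled in vitro. One proposed stabiliser is a covalent di-tyrosine
bond: oxidative radical coupling of the single Tyr10 side chains of two
Aβ1-40 chains. Such a bond has two measurable signatures in ion
mobility mass spectrometry:

1. a **mass loss of a nominal 2 Da per bond** (two hydrogens leave when
   the C–C bond forms), so a covalent dimer is ~2 Da lighter than two
   intact monomers and a doubly linked trimer ~4 Da lighter than three;
2. a change in the **arrival-time distribution**: oligomers of one
   order and charge usually populate both compact and extended
   gas-phase conformers, and cross-linking re-weights that equilibrium
   rather than creating new shapes.

The package turns both signatures into a tested, seeded pipeline:
simulate or load a 2D (m/z × drift time) spectrum, identify species,
quantify cross-link stoichiometry and conformer population shifts, and
convert drift times to collisional cross-sections (Ω).

## Mass accounting

A linear peptide's elemental composition is the residue sum plus one
water; `composition_from_sequence()` covers the 20 canonical residues
over C, H, N, O, S. The packaged default sequence is canonical human
Aβ1-40 (APP residues 672–711), C₁₉₄H₂₉₅N₅₃O₅₈S, average mass 4329.81 Da
from the packaged isotope table. A cross-linked oligomer of order $n$
with $k$ Tyr–Tyr bonds ($0 \le k \le n-1$) has composition

$$n \times \text{monomer} - 2k \times \mathrm{H},$$

i.e. an average-mass deficit of $2k \times 1.008\,\mathrm{Da}$. The
chemistry is tracked purely as $-2\mathrm{H}$ per bond, with no
positional bookkeeping — mass is the only observable used downstream.

Two m/z conventions are implemented. The default `"physical"` carrier
is the proton (1.00728 Da). The `"paper"` convention uses exactly
1.000 Da per charge: the packaged reference table of dimer/trimer
measurements is arithmetically exact under
$M = z\,(m/z) - z\cdot 1.000$ on every row, so that convention is used
when auditing it (`reproduce_table1()`). Which carrier a published
table used is rarely stated; here it was inferred from the table's own
arithmetic. Bond-count inference is unaffected by the choice, because
the carrier term cancels in a before/after difference at fixed charge.

Two cells of the reference table (both 7+ trimer rows after reaction)
disagree with the recomputed mass by up to 0.28 Da; in both cases the
row's own printed m/z *and* its printed mass-change column agree with
the recomputation, identifying those cells as printed typos. The audit
reports them rather than hiding or "correcting" them.

## Isotopic envelopes and charge assignment

`isotopic_distribution()` convolves natural per-element isotope
distributions (packaged CIAAW/NIST-representative masses and
abundances), aggregating isotopologues into extra-neutron bins whose
masses are abundance-weighted means. Per-element powers use binary
exponentiation of the convolution, so the Aβ trimer (~1800 atoms) is
instant; the test suite checks the result against an independent naive
atom-by-atom convolution oracle to total-variation distance < 1e-9.

At charge $z$ envelope peaks are spaced ≈ $1.0033/z$ Th.
`infer_charge()` takes the **median** adjacent-centroid spacing (robust
to one missed or merged peak; the mean is deliberately not used),
scans $z = 1..12$, and accepts the best match only within 20% relative
deviation. Centroids come from local maxima above a relative threshold
(default 5% of the window maximum), refined by three-point parabolic
interpolation; peaks closer than one grid step merge — the honest
resolution limit of the grid. Drift gating precedes the m/z analysis,
mirroring how envelopes are extracted at the arrival time of one
conformer to untangle co-migrating species (e.g. 4+ monomer and 8+
dimer at the same m/z but different drift times).

Species assignment searches $(n \le n_\text{max}, k \le n-1)$ for the
candidate mass closest to the measurement (default tolerance 1 Da, ties
toward fewer bonds) and works on **average** masses by default, since
envelope-averaged m/z values are what the workflow measures; a
monoisotopic mode exists but is off by default.

## CCS calibration

Travelling-wave mobility cells need empirical calibration. The model is
the power law

$$\Omega = c \, q \, t_D^{\,X}$$

with charge $q$, drift time $t_D$ (ms), scale $c$ and exponent $X$.
`fit_calibration()` initialises from the exact least-squares line of
$\log(\Omega/q)$ on $\log t_D$ — the model is log-linear, so noiseless
data are recovered at machine precision already at this step — and
refines by Levenberg–Marquardt on the Ω scale. Two calibrants give the
closed-form determined solution. The calibrated span (observed
drift-time range) is stored; conversions outside it are flagged
`in_range = FALSE` but not refused.

Reference Ω values for the classical protein calibrants (myoglobin,
cytochrome c, ubiquitin) are instrument-database values not shipped
here, so the packaged demonstration calibrants are *synthetic*, drawn
exactly from $c = 53.1$, $X = 0.652$ over 6–17 ms — parameters typical
of a travelling-wave setup and the ones under which the packaged
reference table's printed Ω values reproduce within 0.1% on every row
(the worst row is reported by `reproduce_table1()`, consistent with
rounding of the printed drift times). Under 1% multiplicative noise on
15 calibrants, $X$ is recovered within ±0.02 in ≥ 95 of 100 seeded
replicates (a test in the suite).

## Shared-center drift decomposition

If cross-linking only re-populates existing conformers, the before and
after arrival-time distributions should be describable by **one** set
of Gaussian components — same centers, same widths — with only the
amplitudes differing. `fit_shared_mixture()` fits exactly that model:

- objective: summed squared residual of the **max-normalised** profiles
  of both conditions, so a 10× more intense condition does not absorb
  the shared parameters;
- constraints: amplitudes ≥ 0 (box bounds), centers inside the grid,
  widths bounded below by the grid step;
- optimisation: `L-BFGS-B` from 10 seeded starts (profile local maxima
  plus jitter), tie-broken by lowest objective;
- widths are tied across conditions by default — the stricter reading
  of "the same set of curves" — and can be freed (`tie_widths =
  FALSE`); `shared = FALSE` drops all tying for the
  constrained-vs-unconstrained residual comparison.

Component *fractions* are amplitude × width shares (Gaussian areas), so
they are invariant to joint intensity rescaling.
`population_shift_report()` labels each component as gaining or losing
population and summarises the overall move ("toward compact" when the
fraction-weighted mean drift time decreases). `select_n_components()`
scores $J = 1..J_\text{max}$ by a BIC-style penalised residual
$(\mathrm{RSS}/N)\,N^{p/N}$ (floored at numerical precision of the
normalised profiles so that near-perfect fits of different $J$ tie) and
takes the smallest $J$ within 1% of the best; pure-noise input selects
one component flagged ill-conditioned (fit $R^2 < 0.5$, overlapping
centers, or an all-zero condition).

## The synthetic-data generator

`render_spectrum()` emulates the features the analysis actually
consumes: isotopic envelopes at the correct m/z spacings and
abundances, the 2 Da-per-bond mass shifts, uni- or bimodal Gaussian
drift profiles per species, and additive zero-truncated Gaussian noise
scaled to the noiseless maximum. Peaks are Gaussian in both dimensions.
Defaults: m/z step 0.02 Th and drift step 0.05 ms (resolving envelope
spacings to charge ~10 and the 6–17 ms drift range of the reference
oligomers); peak width `mz_sigma` 0.02 Th is a free simulator
parameter, not a measured instrument resolution.

It deliberately does **not** model instrument physics: T-wave velocity
and amplitude effects, ion transmission, detector saturation, Poisson
counting noise, or chemical background. Passing tests on synthetic
spectra therefore demonstrate the correctness of the *analysis logic*
(charge inference, mass accounting, mixture decomposition), not
robustness to every artefact of real instrument data.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: simulated
windows a few Th wide (grids of order 300 × 100), the full
charge-inference grid $n \le 3$, $z \le 10$, 100 seeded calibration
replicates, and drift profiles of 161 points — everything completes in
well under a minute. Every stochastic step (noise, calibrant sampling,
multi-start jitter) flows from an explicit integer seed through an
RNG-state-restoring wrapper, and the pipeline writes byte-identical
outputs when re-run with the same seed.

## Limitations

- Windows are analyst-specified, as in manual practice; there is no
  untargeted full-spectrum deconvolution or joint fitting of
  overlapping envelopes.
- Mixed oligomers (e.g. a covalent dimer plus a non-covalently attached
  monomer) are represented only by their bond count $(n = 3, k = 1)$;
  no topology is tracked.
- The calibrant fit that produced $c = 53.1$, $X = 0.652$ on the
  original instrument cannot be reproduced without the reference Ω
  values of the protein standards; the packaged calibrants are labelled
  synthetic accordingly.
- Drift-profile decomposition assumes Gaussian components; strongly
  tailed arrival-time distributions would bias the amplitude shares.
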