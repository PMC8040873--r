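---
title: "Models and methods behind ion4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ion4d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ion4d)
```

ion4d implements the quantitative workflow by which divalent-metal
stabilization of a protein is established and explained structurally:
thermal-inactivation kinetics, binding-site analysis from EPR-style
titrations, irreversible differential scanning calorimetry (DSC) with
activation thermodynamics, and a chirality-aware structural search for the
four-carboxylate ("4D") metal-binding pocket. This vignette explains each
model, its assumptions, the tunable parameters, the synthetic-data
generators used for testing, and the numerical choices made where the
design was genuinely open.

## Thermal-inactivation kinetics

Loss of enzymatic activity during incubation at an elevated temperature is
modeled as a first-order process,

$$A(t) = A_0 \, e^{-k_\mathrm{obs} t},$$

fitted by nonlinear least squares (`fit_exponential_decay()`). Start
values are deterministic: $A_0$ from the first activity and $k$ from a
log-linear regression restricted to points above 5% of $A_0$ (points near
zero would otherwise dominate the log fit). The half-life is
$t_{1/2} = \ln 2 / k_\mathrm{obs}$, and `fold_stabilization()` is the
ratio of fitted half-lives of a treated condition over a reference — a
ratio of rate constants, not of single-timepoint residual activities,
which is far less sensitive to assay noise. Activities may be in any
relative unit; the rate is scale-free.

A plateau term ($A(t) = A_0 e^{-kt} + c$) is available but off by
default: the standard protocol follows the decay over more than two
half-lives with no evidence of a nonzero floor, and an unnecessary
plateau parameter degrades the conditioning of the rate estimate.

Michaelis–Menten fits (`fit_michaelis_menten()`) take substrate in mM and
rates in min$^{-1}$ (already normalized per enzyme). Start values come
from the Lineweaver–Burk linearization, which is exact on noise-free data
under any design — including all-saturating designs where a half-maximum
heuristic has no information to work with. The specificity constant
$k_{cat}/K_m$ is reported in M$^{-1}$min$^{-1}$ (i.e. $k_{cat}/(K_m
\times 10^{-3})$), the convention of the kinetics literature.

## Binding analysis from titration signals

A titration of protein (catalytic-subunit concentration $P$) with a
paramagnetic ligand is observed through a signal linear in the free-ion
concentration; the bound ion retains a fraction $\alpha$ of the free-ion
amplitude (about 5% for a protein-immobilized divalent ion):

$$I = \gamma \,(c_\mathrm{free} + \alpha\, c_\mathrm{bound}), \qquad
  c_\mathrm{free} + c_\mathrm{bound} = L_\mathrm{total}.$$

`bound_from_signal()` inverts this linear system exactly. Tiny negative
concentrations produced by noise near the fully-bound or fully-free ends
are clamped to zero with a warning; violations beyond a relative
tolerance (default 2% of the total at that point) are treated as data
errors rather than silently repaired.

The binding isotherm is the classical independent-site-class model

$$\nu(c) = \sum_i \frac{n_i K_i c}{1 + K_i c},$$

with $\nu$ the ligand bound per catalytic subunit. `scatchard_points()`
forms the linearization $\nu/c$ versus $\nu$; for a single class the
points fall on a line with slope $-K$ and x-intercept $n$.
`fit_scatchard_segment()` performs the classical windowed linear
regression (default window $\nu \in [0.4, 0.9]$, the high-affinity
segment); `fit_multisite()` fits the full one- or two-class model by
nonlinear least squares, parameterized in $\log_{10} K$ for conditioning
and seeded from a segment fit on the lower-$\nu$ half of the data. When a
weaker site class is present, the segment method's x-intercept
systematically overestimates the strong-site count — the package keeps
both methods so this bias can be demonstrated rather than hidden, and the
tests assert its direction.

The default synthetic titration (`gen_titration()`) emulates the standard
design: 20 µM catalytic subunits titrated with 4–280 µM divalent ion,
$\alpha = 0.05$, multiplicative signal noise. Ligand additions are spaced
geometrically (roughly constant-ratio additions, the usual titration
practice), which is what places several points inside the 0.4–0.9
high-affinity window; a linear grid would waste almost all points on the
weak-site tail. Per point the free concentration solves the mass balance
$c + P\,\nu(c) = L$ with a bracketed monotone root-finder.

## Irreversible two-state DSC

Thermal denaturation that is calorimetrically irreversible and
scan-rate-dependent is modeled as a kinetically controlled two-state
process N $\rightarrow$ D with a first-order rate constant in the
one-parameter-exponent Arrhenius form

$$k(T) = \exp\!\left[\frac{E_A}{R}\left(\frac{1}{T^*} -
\frac{1}{T}\right)\right],$$

where $T^*$ is the temperature at which $k = 1\ \mathrm{min}^{-1}$. The
excess molar heat capacity at scan rate $\nu = dT/dt$ is

$$C_p^{ex}(T) = \frac{\Delta H}{\nu}\, k(T)\,
  \exp\!\left[-\frac{1}{\nu}\int_{T_0}^{T} k(T')\,dT'\right],$$

with $\Delta H$ the (temperature-independent) calorimetric enthalpy. The
curve integrates to $\Delta H$, and its maximum satisfies the closed-form
peak condition $k(T_m) = \nu E_A / (R\,T_m^2)$, which
`peak_temperature()` solves directly and the simulator reproduces.

Numerical choices:

* The inner integral is a cumulative trapezoid with an Euler–Maclaurin
  endpoint correction built from the analytic derivative
  $k' = k\,E_A/(R T^2)$. Plain trapezoid on a 0.1 K grid is only
  accurate to about $2\times 10^{-4}$ (relative) for protein-sized
  activation energies; the corrected rule is $O(h^4)$ and comfortably
  exceeds the $10^{-4}$ accuracy the analysis assumes. Grids coarser
  than 0.5 K trigger a warning.
* `fit_thermogram()` fits $(E_A, T^*, \Delta H)$ by nonlinear least
  squares with deterministic initialization: $\Delta H$ from the
  trapezoid area, $E_A$ from the half-height width, and $T^*$ by
  inverting the peak condition at the observed maximum. Fit quality is
  reported as $r = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$.
* The model is *exactly degenerate* under scan-rate misspecification:
  a thermogram recorded at scan rate $\nu$ but fitted assuming $\nu'$
  is reproduced perfectly with the same $E_A$ and $\Delta H$ and with
  $T^*$ shifted to $1/T^{*\prime} = 1/T^* + (R/E_A)\ln(\nu'/\nu)$. An
  incorrectly recorded scan rate therefore corrupts $T^*$ (and
  everything derived from it) while leaving the fit statistics and
  $E_A$ flawless — worth knowing when comparing instruments.
* An optional linear baseline (`subtract_baseline()`) is fitted to
  user-marked pre- and post-transition flanks; vendor "chemical
  baseline" algorithms are instrument-specific and not reproduced. The
  flanks must carry negligible transition signal for the subtraction to
  be unbiased.

Activation thermodynamics (`eyring_parameters()`) follow transition-state
theory, $k = (k_B T/h)\, e^{\Delta S^\ddagger/R} e^{-\Delta
H^\ddagger/RT}$: $\Delta H^\ddagger = E_A - R T_\mathrm{ref}$, $\Delta
S^\ddagger$ solved from the $k(T^*) = 1$ condition evaluated at $T^*$,
and $\Delta G^\ddagger = \Delta H^\ddagger - T_\mathrm{ref}\Delta
S^\ddagger$. There is a genuine unit subtlety: the Arrhenius convention
defines $T^*$ at $k = 1\ \mathrm{min}^{-1}$, but activation entropies in
the calorimetry literature derived this way back-calculate only if the
Eyring condition uses $k(T^*) = 1\ \mathrm{s}^{-1}$. Both conventions are
selectable via `rate_unit`; `per_second` is the default (it reproduces
the published activation tables) and the choice is recorded in the
returned object — the two differ by exactly $R \ln 60 \approx 8.1$ cal
K$^{-1}$ mol$^{-1}$ in $\Delta S^\ddagger$. Constants: $R = 1.9872\times
10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, $k_B = 1.380649\times 10^{-23}$ J
K$^{-1}$, $h = 6.62607015\times 10^{-34}$ J s; energies in kcal
mol$^{-1}$, entropies in cal K$^{-1}$ mol$^{-1}$.

## The 4D motif search

The structural search reduces each acidic side chain to a two-point
pseudo-atom vector: for aspartate from C$\beta$ to the midpoint of
O$\delta1$/O$\delta2$, and — by analogy, for DEDD/3D1E variant pockets —
for glutamate from C$\gamma$ to the midpoint of
O$\epsilon1$/O$\epsilon2$. This deliberately ignores main-chain geometry:
two pockets match when their carboxylates align, however different their
backbones. Vectors shorter than 1.0 Å or longer than 3.5 Å (broken or
mislabeled side chains) are skipped with a warning.

`search_motif()` enumerates candidate residue assignments of the query's
types, pruning on pairwise base-atom distances (default tolerance
±3.5 Å), superposes the $2N$ pseudo-atoms of each surviving pairing onto
the query by least squares, and keeps hits at or below the RMSD cutoff
(default 2.5 Å). Design points:

* **Chirality.** A 3D arrangement of vectors and its mirror image are
  not related by any proper rotation, so left-handed matches are found
  by running the identical search against the mirrored query
  ($x \to -x$). The superposition itself permits proper rotations only
  (the SVD solution is determinant-corrected); left-handed hits carry an
  explicit flag rather than a silently improper transform.
* **Pairing order.** All type-consistent permutations are tried and the
  best-RMSD pairing is kept per residue set — real pockets are known to
  match queries with residues in a different order than the query lists
  them.
* **Pruning completeness.** After superposition at RMSD $r$, a single
  pairwise base distance can deviate from the query's by at most
  $\sqrt{4N}\, r$ (4$\times$ for a four-residue motif). Pruning is
  therefore guaranteed lossless only when the tolerance is at least
  $\sqrt{4N}$ times the cutoff; the tests verify exact equality with
  brute-force enumeration at that bound. The 3.5 Å default cannot miss
  near-exact motif copies (anything under $\approx$ 0.9 Å) and keeps the
  combinatorics bounded; the search aborts with advice if more than
  $10^6$ candidate assignments survive pruning.
* **RMSD metric.** The reported RMSD is over the $2N$ superposed
  pseudo-atom positions. Some structure-comparison services may instead
  report statistics over the side-chain vectors themselves; both are
  available in `overlay_motifs()` (`metric = "pseudoatom"` or
  `"vector"`), and on real overlays the two can differ — comparisons
  against published RMSDs should state the metric rather than assume
  agreement.

`annotate_pocket()` inventories the matched pocket: ions are hetero atoms
of known mono-/divalent elements within 3.0 Å of any motif carboxylate
oxygen, or bridged to one by a water within 3.5 Å of both; waters are
counted when within 3.5 Å of at least one carboxylate oxygen; the
occupancy class is `unoccupied`, `monovalent`, `divalent`, or
`multi_ion`. The divalent element set is {MG, CA, MN, ZN, FE, NI, CO, CU,
CD, SR, BA, U (uranyl)}, monovalent {NA, K, LI, RB, CS}. A plain
atom–atom distance utility (`atom_distance()`) supports spot checks such
as the metal-to-catalytic-serine O$\gamma$ distance.

`alignment_motif_scan()` handles the sequence side: it maps residue
positions of a reference sequence (in its own ungapped numbering) to
alignment columns and reports, per sequence, the residues at those
columns and whether they match a pattern such as DDDD or DEDD.

## Synthetic data: what it emulates, and what it does not

Every analysis input can be generated deterministically
(`gen_decay()`, `gen_titration()`, `gen_thermogram()`,
`gen_structure()`); each generator is a pure function of its arguments
and a seed. Noise models follow each instrument's dominant error:
multiplicative for activity assays (constant CV) and titration signals,
additive for DSC traces. Defaults encode the study conditions the
analyses assume: decays sampled over three half-lives (20 points, 2%
noise), titrations of 20 µM subunits with 4–280 µM ligand at
$\alpha = 0.05$, thermograms on 0.1 K grids at 1 K/min, and planted 4D
pockets with full aspartate side chains rebuilt around each vector (ideal
bond geometry: C–C 1.52 Å, C–O 1.25 Å, O–C–O 123°) among at least 30
randomly oriented decoy Asp/Glu residues placed at least 8 Å apart.

The built-in `default_4d_template()` is a synthetic pocket whose geometry
was chosen (and frozen) to be strongly chiral: its mirror image cannot be
proper-superposed onto it below 3.2 Å under any residue pairing, so
chirality tests have a clean margin around the 2.5 Å search cutoff.

What the generators do *not* emulate — and hence what passing tests do
not demonstrate about real data: temperature equilibration transients and
instrument response smearing in DSC (synthetic thermograms are
ideal-instrument); EPR lineshapes and baseline drifts (the titration
model is already reduced to intensities); cooperative or competing
binding; real protein backbones, crystallographic disorder, or lattice
contacts in structures (decoys are isolated side chains). Recovery rates
measured on synthetic data are therefore upper bounds on what identical
settings achieve on experimental traces.

## Study orchestration

`run_study()` runs any subset of stages from one JSON config, validating
all inputs before any stage executes, and returns a typed report with
provenance (inputs, package version, timestamp); `table_check()`
tabulates computed values against user-supplied expectations with
absolute and relative deltas, reporting one-sided keys as missing rather
than dropping them. All numeric output is serialized at full double
precision; rounding happens only in printed summaries. The package's
interface is its functions and this document; the pipeline is run from R
(or `Rscript -e`) rather than through a separate shell tool.

## Test problem sizes

The test suite verifies parameter recovery at the sizes the analyses are
designed for while staying quick to run: decay-rate recovery and
planted-motif retrieval use 100 seeds; DSC and binding recovery-under-
noise properties use 30 seeds each (medians are stable well below that);
brute-force search equivalence uses small structures with 9–10 acidic
residues, where exhaustive enumeration is exact and fast.

## Known limitations

* The DSC model assumes a temperature-independent $\Delta H$ and a
  single irreversible step; Lumry–Eyring or multi-domain extensions are
  out of scope, as is equilibrium (van 't Hoff) analysis, which is
  invalid for scan-rate-dependent transitions.
* The Eyring $\Delta S^\ddagger$/$\Delta G^\ddagger$ values inherit the
  $k(T^*)$ unit convention; always report which convention was used.
* The segment Scatchard method is biased in the presence of additional
  site classes (demonstrably so; see the tests) — prefer the full
  isotherm fit and use the segment fit for comparability with the
  classical literature.
* The motif search scales combinatorially with the number of acidic
  residues of each query type; the distance pruning makes typical
  single-chain searches instantaneous, but pathological inputs (hundreds
  of clustered carboxylates with a loose tolerance) hit the candidate
  cap by design.
* Hydrogens are ignored throughout; contact cutoffs are heavy-atom
  distances.
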