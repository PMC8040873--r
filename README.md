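# ion4d

Quantitative analysis of divalent-metal-ion stabilization of proteins,
built around the workflow used for acetylcholinesterase: a divalent
cation (Mg²⁺, Ca²⁺, Mn²⁺) binds a surface pocket formed by four
aspartate side chains — the **4D motif** — and dramatically slows both
thermal inactivation and thermal denaturation. The package is for
biophysicists and structural bioinformaticians who need to quantify such
stabilization and locate the pocket responsible.

Four analysis stages, each usable on its own:

* **Inactivation kinetics** — mono-exponential decay fits
  A(t) = A₀·e^(−kt), half-lives t₁/₂ = ln 2 / k, fold stabilization as
  the ratio of fitted half-lives, Michaelis–Menten fits and specificity
  constants k_cat/K_m.
* **Binding titrations** — inversion of an EPR-style signal
  I = γ(c_free + α·c_bound) into bound/free ligand, Scatchard plots
  (ν/c = (n − ν)K), classical windowed segment fits, and full
  independent-site-class isotherm fits ν(c) = Σ nᵢKᵢc/(1 + Kᵢc).
* **Irreversible DSC** — the kinetically controlled two-state model
  Cp_ex(T) = (ΔH/ν)·k(T)·exp[−(1/ν)∫k dT'] with Arrhenius rate
  k(T) = exp[(E_A/R)(1/T* − 1/T)]; simulation, nonlinear fitting, the
  closed-form peak condition k(T_m) = νE_A/(RT_m²), and Eyring
  activation thermodynamics (ΔH‡, ΔS‡, ΔG‡) at a reference temperature.
* **4D motif search** — chirality-aware matching of side-chain
  pseudo-atom vectors (Asp: Cβ → midpoint Oδ1/Oδ2; Glu analog for
  DEDD/3D1E variants) in PDB/mmCIF structures, with least-squares
  superposition RMSD, pocket ion/water occupancy annotation, and
  aligned-FASTA motif scanning.

Deterministic synthetic-data generators (`gen_decay`, `gen_titration`,
`gen_thermogram`, `gen_structure`) produce every input class with the
statistical structure the analyses assume, so the whole pipeline is
testable without downloads. `run_study()` orchestrates any subset of
stages from a JSON config into a single provenance-carrying report.

## Worked example

```r
library(ion4d)

## 1. thermal inactivation: apo vs +10 mM MgCl2 at 39 C (synthetic, 2% noise)
ref <- fit_exponential_decay(gen_decay(0.1386,  noise_rel = 0.02, seed = 11,
                                       label = "apo, 39 C"))
trt <- fit_exponential_decay(gen_decay(9.24e-4, noise_rel = 0.02, seed = 12,
                                       label = "+10 mM MgCl2, 39 C"))
ref; trt
fold_stabilization(ref, trt)

## 2. DSC: simulate the apo transition, refit, derive activation parameters
tg  <- gen_thermogram(arrhenius_params(111.1, 315.6, 250),
                      noise_abs = 0.05, seed = 13)
fit <- fit_thermogram(tg)
fit$params
eyring_parameters(fit$params)

## 3. find a planted 4D pocket among 30 decoy acidic residues
q   <- default_4d_template()
pdb <- gen_structure(q, n_decoys = 30, jitter_sigma = 0.3, seed = 14,
                     ions = data.frame(element = "MG", x = -1.2, y = -2.8, z = 0.5))
search_motif(parse_structure(pdb), q, rmsd_cutoff = 2.5, handedness = "both")
```

Output:

```
Mono-exponential decay fit [apo, 39 C]:
  k_obs  = 0.137874 min^-1
  t_half = 5.02741 min
  sse    = 0.001531 (n = 20)
Mono-exponential decay fit [+10 mM MgCl2, 39 C]:
  k_obs  = 0.000920938 min^-1
  t_half = 752.653 min
  sse    = 0.002381 (n = 20)
[1] 149.7165
Arrhenius parameters (two-state irreversible model):
  E_A = 111.1 kcal mol^-1, T* = 315.6 K (k = 1 min^-1), dH = 249.9 kcal mol^-1
Eyring activation parameters at 298.15 K (k(T*) = 1 s^-1):
  dH_act = 110.5 kcal mol^-1
  dS_act = 291.4 cal K^-1 mol^-1
  dG_act = 23.6 kcal mol^-1
1 motif hit(s)
   1. rmsd  0.477 A  right  A:ASP326 A:ASP389 A:ASP392 A:ASP393
```

Reading it: the apo enzyme loses half its activity in ~5 min while the
Mg²⁺-protected enzyme takes ~750 min — a ~150-fold stabilization. The
DSC refit recovers the generating Arrhenius parameters (E_A = 111.1
kcal/mol, T* = 315.6 K) from the noisy trace, and transition-state
analysis at 25 °C gives ΔG‡ ≈ 23.6 kcal/mol. The structural search
retrieves the planted, jittered 4-aspartate pocket as a right-handed hit
at 0.48 Å RMSD over its eight side-chain pseudo-atoms.

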