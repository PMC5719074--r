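---
title: "Allosteric gating kinetics of the 20S proteasome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allosteric gating kinetics of the 20S proteasome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatekin)
```

## The system and the questions

The 20S core particle (CP) of the proteasome is a barrel of four stacked
heptameric rings. The outer alpha-rings carry the substrate gate — the
N-terminal tails of the alpha subunits — and the docking surface for
regulatory particles (RPs) such as PA28, PA200 and the 19S complex. RPs
anchor largely through salt bridges: acidic residues (Asp/Glu) on the CP
alpha-surface pair with basic residues (Lys/Arg) of the RP, and this
anchoring biases the spontaneous equilibrium between a "closed"
(proteolytically quiet) and an "open" (active) gate conformation.

Tetra-cationic porphyrins exploit the same electrostatics: four positive
charges held at fixed mutual distances by a rigid scaffold can occupy the
acidic clusters that RPs use, and thereby act as allosteric modulators of
gating rather than as catalytic-site blockers. `gatekin` implements the
quantitative workflow for this system:

1. map CP–RP ionic contacts on structures and score acidic-cluster
   geometry against a ligand's charge spacing (`find_ionic_contacts()`,
   `site_geometry()`, `match_ligand_geometry()`);
2. compute the idealized charge spacing of porphyrin scaffolds
   (`adjacent_charge_spacing()`);
3. discriminate steady-state inhibition mechanisms on rate grids
   (`fit_inhibition()`, `lineweaver_burk()`, `fit_ic50()`);
4. decompose stopped-flow Soret-band traces into exponential phases and
   assemble k_obs series (`fit_exponentials()`, `select_n_phases()`,
   `collect_kobs()`);
5. fit the two-state cooperative binding law to k_obs series
   (`populations()`, `kobs_model()`, `fit_kobs()`, `compare_modes()`).

A synthetic-data module (`gen_*`, `simulate_fixture()`) generates every
input with known ground truth, so the full pipeline runs and is tested
without any external data.

## The two-state concerted binding model

The core model treats one cluster of `n` equivalent porphyrin sites on a
CP that interconverts, as a whole, between closed and open conformations
(a concerted, MWC-type scheme). With per-site association constants `K_c`
and `K_o` for the two conformations and a zero-ligand equilibrium
`L = [open]/[closed]`, the open fraction at free ligand concentration `x`
is

    f_o(x) = L (1 + K_o x)^n / [ (1 + K_c x)^n + L (1 + K_o x)^n ],

and `f_c = 1 - f_o`. Two conventions matter and are fixed throughout the
package: `L` multiplies the *open* term, so `f_o(0) = L/(1+L)` and a small
`L` means the ligand-free particle is closed; and `n` is a *fixed small
integer*, never a continuous exponent — cooperativity here counts physical
sites, and fits are compared across `n` by information criterion instead
of letting `n` float.

The observed pseudo-first-order rate constant of a binding phase is the
population-weighted mixture of the state-specific association rate
constants,

    k_obs(x) = ( k_c f_c(x) + k_o f_o(x) ) x + k_off,

which reduces exactly to the classical bimolecular line
`k_obs = k_on x + k_off` when the two states bind identically
(`K_o = K_c`, `k_o = k_c`) — a degeneracy the test suite checks
numerically. Populations are evaluated in log space (`log1p`), so extreme
concentrations or constants cannot overflow.

The reference parameter sets (`fixture_params()`) encode the first-cluster
constants for the human and yeast wild-type particles and for the
permanently open yeast alpha-3ΔN mutant, which loses cooperativity
entirely and serves as the bimolecular control: deleting the alpha-3
N-terminal tail removes the closed state, so `k_obs` becomes linear in
ligand. `consistency_report()` checks these sets for thermodynamic sanity:
for one-step binding `k_on/k_off` must equal the association constant, and
the open-state constants agree to within a factor ~1.4 (0.99 for the
mutant), while discrepancies beyond 3-fold are flagged.

### Parameters, units, defaults

| parameter | units | meaning | human reference value |
|---|---|---|---|
| `K_o`, `K_c` | M^-1 | per-site association constants, open/closed | 1.8e7, 7.0e3 |
| `k_o`, `k_c` | M^-1 s^-1 | association rate constants, open/closed | 2.8e6, 1.3e2 |
| `k_off` | s^-1 | dissociation rate constant | 0.22 |
| `L` | — | [open]/[closed] at zero ligand | 4.0e-6 |
| `n` | sites | cluster size, fixed integer | 3 |

With these values the model places the open/closed crossover
(`population_curves()`) near 3.5 µM and predicts `k_obs(5 µM) ≈ 10.5 s^-1`
for the fast phase.

### Fitting k_obs series and what the data can identify

`fit_kobs()` performs nonlinear least squares in log-parameter space
(positivity by construction, box bounds at ±15 decades to prevent
underflow), with ≥16 data-driven multi-starts: `k_off` is seeded from the
low-concentration plateau, `k_o` from the terminal slope, the transition
midpoint seeds a ladder of `K_o` values, and `L` is chosen so each start
crosses at the apparent midpoint.

Residuals are weighted `1/k_obs` by default. This is deliberate: rate
constants from stopped-flow phases carry roughly constant *relative*
error, and on a 0.2–100 µM grid `k_obs` spans 0.22 to ~280 s^-1 — under
unweighted least squares the intercept `k_off` would be invisible next to
the top-of-curve residuals. Per-point standard errors (`weights = "se"`)
or unweighted fitting are available as options.

A structural caveat that any user of this model should know: on grids
where the sigmoid transition happens at `K_o x >> 1` (true for the
reference constants: `K_o x ≈ 63` at the midpoint), the data pin `k_o`,
`k_off` and the *compound* `L·K_o^n` (which fixes the transition
position), but not `L` and `K_o` individually — the likelihood has a flat
ridge along `log L + n log K_o = const`, and `k_c`/`K_c` contribute at
most ~0.01 s^-1 anywhere on the grid. Consequently point estimates of
`L`, `K_o`, `K_c`, `k_c` from a single series are not trustworthy;
`fit_kobs()` reports 95% intervals that are honestly wide (often
unbounded) along the ridge, and the test suite asserts coverage only for
the identifiable parameters. Resolving the ridge requires independent
information, e.g. equilibrium titrations or grids extending into the
`K_o x ~ 1` regime with the transition still visible.

What *is* robust from a single series: the site number. `fit_kobs(...,
n = 1:3)` refits at each `n` and compares by AICc; data simulated with
`n = 3` select 3 decisively (ΔAICc > 10 against `n ≤ 2` in the reference
conditions) because lower `n` cannot reproduce the slope steepness of the
transition. Likewise `compare_modes()` reliably separates cooperative
(wild-type) from bimolecular (alpha-3ΔN) series by AICc, with a
lack-of-fit F-test of the straight line reported alongside; selection is
refused below 8 points (insufficient residual degrees of freedom for the
6-parameter model), with both fits still reported.

## Steady-state inhibition analysis

`rate_law()` implements the four textbook reversible-inhibition laws
(competitive, uncompetitive, mixed with interaction factor α, and
non-competitive ≡ mixed at α = 1). `fit_inhibition()` fits each law
globally across all inhibitor levels on *untransformed* rates — the
double-reciprocal transform distorts the error structure and is kept only
as the classical diagnostic (`lineweaver_burk()`, whose line-intersection
pattern gives the textbook classification hint: common y-intercept →
competitive, common x-intercept → non-competitive, parallel →
uncompetitive). Residuals are relative (`1/v` weighting), matching the
multiplicative error of initial-rate assays.

Model selection combines the two documented criteria: AICc is primary;
the extra-sum-of-squares F-test (α = 0.01) guards the boundary between
mixed and its nested special cases. The fourth parameter must earn its
keep — when mixed wins AICc but a nested 3-parameter law is not rejected
by the F-test, the parsimonious law is reported. Without this rule, pure
non-competitive data at 5% noise are labelled "mixed" (with α ≈ 1, i.e.
the same mechanism, overparameterized) in roughly one replicate in five;
with it, the generating mechanism is recovered in 99/100 replicates while
genuinely mixed (α = 4) and competitive grids still select correctly.

`fit_ic50()` fits `a = 1/(1 + (I/IC50)^h)` with the Hill slope fixed at 1
by default (`hill_free` to release it); it refuses data with no visible
transition (all activities > 0.8 or < 0.2), where an IC50 would be pure
extrapolation.

## Stopped-flow phase analysis

Binding is monitored at the porphyrin Soret band (421 nm), and traces are
modelled as a sum of exponential relaxations plus offset,
`A(t) = A_inf + Σ a_i exp(-k_i t)`. `fit_exponentials()` profiles the
linear parameters (amplitudes, offset) out by variable projection and
optimizes only the log-rates, from a ladder of log-spaced multi-starts
spanning the observable window `1/t_max` to `10/t_min`; the best solution
is then refined with all parameters free to obtain a covariance matrix.

The sign convention — the single most error-prone choice in this analysis
— is defined from the trace direction: the offset is the *final*
absorbance, so a negative amplitude is a phase in which absorbance rises
toward the end value (hyperchromic) and a positive amplitude a falling,
hypochromic phase. `classify_phases()` returns the labels in temporal
order (descending rate). The reference trace fixture encodes the
characteristic signature of the phenyl-extended porphyrin: a fast
hyperchromic event followed by a slower hypochromic one.

`select_n_phases()` fits `n = 1..max_n` and selects by AICc, with two
pruning rules that prevent noise from being dressed as an extra phase: a
candidate is ineligible if any two of its rates are within a factor 1.05
(degenerate, ill-conditioned) or if any amplitude lies within 2 standard
errors of zero. On the two-phase reference fixture the selector returns 2
(not 3) in every tested replicate; on pure noise it returns 1.

`collect_kobs()` assembles per-phase `(x, k_obs, SE)` series across
concentrations, matching phases by *rate rank* rather than amplitude
(rates vary smoothly with concentration; amplitudes need not), excluding
stray extra phases with a warning. The pseudo-first-order assumption
(ligand in large excess over enzyme, ~µM vs ~nM) underlies the whole
analysis.

## Interface mapping and ligand geometry

`find_ionic_contacts()` uses the standard salt-bridge convention: Glu
OE1/OE2, Asp OD1/OD2 (and terminal OXT) versus Lys NZ and Arg NE/NH1/NH2,
at a default 4.0 Å cutoff between charged atoms; His and N-terminal
charges are off by default but available. Contacts are deduplicated at
the residue-pair level keeping the closest atom pair, because residues,
not atom pairs, are the biological currency. Candidate generation uses a
uniform cell grid of cell size equal to the cutoff; the test suite proves
it equivalent to the all-pairs scan. Swapping the two chain groups
returns the same contacts with roles re-assigned (the negative partner is
always listed first).

Homolog transfer (`align_and_map()`, `transfer_contacts()`) uses global
Needleman–Wunsch alignment (BLOSUM62, gap open 10, extend 0.5 — orthologous
proteasome subunits are highly similar, so gaps should be rare and
expensive) and drops, with counts, contacts whose acidic residue lands on
a gap or a non-acidic target residue. Residue numbering is taken from the
files as-is (author numbering, insertion codes preserved); groove labels
come from user-supplied chain→subunit annotations, with no hard-coded
proteasome topology.

`site_geometry()` reduces each acidic residue to its carboxylate-oxygen
centroid; `match_ligand_geometry()` scores every 4-subset of centroids
against an ideal square of side `s` by the RMS deviation of its six
sorted pairwise distances from the multiset {s, s, s, s, s√2, s√2}. The
score uses only internal distances, hence is rigid-motion invariant.
Subsets containing any distance outside `[s - 3·tol, s√2 + 3·tol]` are
pruned first; tests prove pruning leaves the exhaustive result unchanged.

The ligand side of the comparison is an idealized calculator. The
scaffold design argument is about *design distances*, not conformer
ensembles, so `radial_charge_distance()` sums documented standard bond
lengths along one meso arm of a planar, four-fold-symmetric scaffold —
centre→meso carbon 3.45 Å, biaryl link 1.49 Å, para-phenylene span 2.78 Å,
inner biaryl link 1.48 Å, pyridine ipso-C→para-N 2.79 Å — and
`adjacent_charge_spacing()` converts to the square's edge (`r√2`) and
diagonal (`2r`). This yields 10.93 Å ≈ 11 Å between adjacent cations with
no spacer and 16.96 Å ≈ 17 Å with one para-phenylene spacer per arm: the
difference that converts a gate-channel binder into a groove-spanning
allosteric ligand, since the acidic clusters edging the alpha-ring
grooves sit ~17 Å apart.

## The synthetic-data module

Every generator takes an explicit `seed` and restores the caller's RNG
state; identical arguments and seed give byte-identical output (text) or
exactly identical arrays. Noise models follow the physics of each
measurement: multiplicative Gaussian (CV-parameterized) for rates and
activities, whose error is proportional to signal; additive Gaussian for
absorbance traces, whose error is detector noise; lognormal relative
noise for k_obs values, which are positive by construction. Noise levels
in properties about trace fitting are quoted relative to the total
kinetic amplitude (the SNR convention for relaxation traces), not the
static absorbance offset.

Structural fixtures are built, not downloaded: `gen_toy_complex()` plants
Asp/Glu–Lys/Arg pairs at exact distances (the nearest charged-atom
distance equals the requested value by construction, so detection has a
construction oracle) plus decoys guaranteed farther than 8 Å from any
opposite charge; `gen_pseudo_ring()` builds a ring of pseudo-subunits
with scattered carboxylate centroids and one planted exact square in an
inter-subunit groove. Both emit standard fixed-width PDB ATOM text that
round-trips through `parse_structure()`.

What the generators deliberately do *not* emulate: real structures'
side-chain rotamer ensembles, crystallographic noise, or missing atoms;
correlated/systematic assay errors (pipetting drifts, enzyme
inactivation); stopped-flow dead time and photobleaching; and the
time-domain absorbance of the full two-cluster binding scheme, which
would require the extinction coefficients of partially bound
intermediates. Passing tests therefore demonstrate correctness of the
estimators under the stated error models, not robustness to every
systematic error of real instruments.

Fixture constants not fixed by the reference analysis were chosen once at
field-typical values and left alone: the Suc-LLVY-AMC grid uses
Km = 70 µM, normalized Vmax = 1 and Ki = 2 µM (equal to the IC50, as it
must be for pure non-competitive inhibition); the stopped-flow fixture
uses phases (−0.05 AU, 10.4 s^-1) and (+0.03 AU, 1.0 s^-1) on an offset
of 1.0 AU with 0.002 AU detector noise; k_obs series use a 15-point
log-spaced 0.2–100 µM concentration grid at 5% CV.

## Numerical choices and problem sizes

AICc is computed from residual sums of squares with the error variance
counted as a parameter, making comparisons valid across models fitted to
the same data. Exponential fits flag rate ratios below 1.05 as
degenerate. Optimizers: Levenberg–Marquardt (`minpack.lm`) for all
nonlinear refinements, Brent/Nelder–Mead over log-rates for the
variable-projection stage. Replicated stochastic checks in the test suite
use 10–40 replicates per property (e.g. 40 grids for mechanism-selection
reliability, 20 traces for rate recovery, 11–12 series for k_obs fits),
sizes at which the suite completes in well under a minute while the
binomial thresholds retain power.

## Known limitations

- Only the first binding cluster is modelled quantitatively; the second,
  lower-affinity cluster (which returns the particle to a "closed-bound"
  state) is a qualitative narrative in this system, as no parameter set
  exists for it.
- The `L`/`K_o` ridge discussed above: single k_obs series cannot
  separate these parameters in the reference regime.
- Distance-based electrostatics only: no Poisson–Boltzmann, no pKa, no
  docking. The square-matching score is a pharmacophore-style geometric
  filter, not an energy.
- The mmCIF reader accepts standard coordinate blocks via `bio3d`; exotic
  categories are ignored.
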