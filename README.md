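# gatekin

Allosteric gating kinetics of the 20S proteasome and cationic porphyrin
ligands.

## What this package is for

The 20S proteasome core particle spontaneously interconverts between a
"closed" and an "open" gate conformation. Regulatory particles open the
gate by docking onto acidic residues (Asp/Glu) of the alpha-ring surface
through salt bridges, and tetra-cationic porphyrins can occupy the same
acidic clusters, acting as *allosteric* inhibitors that shift the
open/closed equilibrium rather than blocking the catalytic sites. For
researchers characterizing such ligands, `gatekin` provides the full
quantitative workflow:

- **Interface mapping** — detect core-particle/regulator ionic contacts
  on PDB/mmCIF structures (4 Å salt-bridge convention), transfer them to
  homologs by global alignment, group them by inter-subunit groove, and
  score acidic-cluster geometry against a ligand's charge spacing.
- **Ligand geometry** — idealized charge spacings of porphyrin scaffolds:
  ~11 Å between adjacent cations without a spacer ring, ~17 Å with one
  para-phenylene spacer per arm.
- **Steady-state kinetics** — IC50 fitting and discrimination of
  competitive / uncompetitive / mixed / non-competitive inhibition on
  substrate-by-inhibitor rate grids, with Lineweaver–Burk diagnostics.
- **Stopped-flow analysis** — multi-exponential decomposition of
  Soret-band (421 nm) progress curves, AICc phase-number selection,
  hyper/hypochromic classification, and assembly of k_obs series.
- **Allosteric gating model** — the two-state concerted (MWC-type)
  cooperative binding law for observed rate constants, population curves,
  model comparison against simple bimolecular binding, and
  detailed-balance consistency checks.
- **Synthetic data** — generators with known ground truth for every input
  above, so the entire pipeline runs and is tested with no downloads.

## The core model

For a cluster of `n` equivalent sites on a particle that switches
conformation as a whole, with per-site association constants `K_o`
(open) and `K_c` (closed) and zero-ligand equilibrium
`L = [open]/[closed]`:

    f_o(x) = L (1 + K_o x)^n / [ (1 + K_c x)^n + L (1 + K_o x)^n ]

    k_obs(x) = ( k_c (1 - f_o) + k_o f_o ) x + k_off

The second law reduces to the classical `k_obs = k_on x + k_off` when the
two conformations bind identically — which is exactly what happens for
the permanently open alpha-3ΔN mutant, the package's bimolecular control.

## Worked example

```r
library(gatekin)

hp <- fixture_params("human-20s")
hp
#> Two-state binding parameters [human]
#>   K_o = 1.8e+07 M^-1   K_c = 7e+03 M^-1   L = 4e-06   n = 3
#>   k_o = 2.8e+06 M^-1 s^-1   k_c = 130 M^-1 s^-1   k_off = 0.22 s^-1

# Where does the ligand flip the gate equilibrium?
population_curves(hp, exp(seq(log(1e-7), log(1e-4), length.out = 60)))
#> Population curve over [1e-07, 0.0001] M (60 points)
#>   open/closed crossover (f_open = 0.5) at 3.53e-06 M

# Simulate a 15-point k_obs series (5% noise) and ask: cooperative or simple?
ser <- simulate_fixture("human-20s", seed = 2)
compare_modes(ser)
#> Selected mode: cooperative (delta AICc, bimolecular - cooperative = 59.02)
#> Lack-of-fit F(4,9) = 490, p = 1.61e-10

# How many sites per cluster? Sweep n and compare by AICc.
fit_kobs(ser, mode = "cooperative", n = 1:3)$sweep
#>   n       aicc delta_aicc
#> 1 1  -6.859194   55.91993
#> 2 2 -33.516643   29.26248
#> 3 3 -62.779123    0.00000

# Steady-state mechanism on a simulated Suc-LLVY-AMC rate grid
fit_inhibition(simulate_fixture("sucllvy-inhibition", seed = 4))
#> Inhibition mechanism fit on 36 rates; selected: noncompetitive
#>       mechanism        ssr       aicc  delta_aicc
#>     competitive 3.33093787  -76.39922 183.0941476
#>   uncompetitive 7.80046536  -45.76576 213.7276091
#>  noncompetitive 0.02059525 -259.49337   0.0000000
#>           mixed 0.01954906 -258.66050   0.8328679
#> selected-model parameters:
#>      Vmax        Km        Ki
#>  1.033581 72.104721  1.980175

# Ligand design distances: one phenylene spacer pushes adjacent cations to ~17 A
adjacent_charge_spacing(arm_spec(1))
#>   radial adjacent diagonal
#> 11.99000 16.95642 23.98000
```

Reading the output: the gate equilibrium crosses 50/50 near 3.5 µM
ligand; the k_obs series is decisively cooperative (ΔAICc ≈ 59 against a
straight line) with three sites per cluster ranked best; the rate grid is
non-competitive (Vmax falls, Km unchanged) with Ki ≈ 2 µM recovered from
3%-noise data; and the spacer-extended scaffold holds adjacent charges
16.96 Å apart, matching the ~17 Å spacing of the acidic clusters that
line the alpha-ring grooves.

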