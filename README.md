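# hydroshell

Structured hydration-shell analysis for collagen-mimetic, triplet-periodic
peptides, with the analytical equidistant-bead chain model and a
ground-truth synthetic-trajectory generator.

## The scientific problem

The collagen-mimetic peptide [(PPG)<sub>10</sub>]<sub>3</sub> — three chains
of ten Pro-Pro-Gly triplets wound into a triple helix — binds water in a
strikingly regular way: each backbone carbonyl oxygen is a potential binding
site, and the three triplet positions behave differently. The X-position
proline carbonyl binds no water (its space is taken by the inter-chain
Gly-NH hydrogen bond), the Y-position proline binds about two waters, and
glycine binds one: the **0-2-1 hydration pattern**, softening to roughly
0-1.7-1 in room-temperature liquid water. Although individual waters
exchange on the 25–80 ps timescale, a departing ligand is replaced
essentially instantly (a substitution reaction), so the pattern persists.

This package implements the full analysis chain needed to quantify that
picture, for real coordinate sets (multi-model PDB, XYZ) or for synthetic
trajectories with known ground truth:

* **Chain shape** — radius of gyration R<sub>g</sub>, end-to-end distance
  R<sub>ee</sub>, Kabsch superposition, RMSD/RMSF, and the analytical
  *equidistant-bead model*: n equal masses spaced l apart give

  R<sub>g</sub>²/R<sub>ee</sub>² = (1/6)(k+1)(2k+1)/(2k)²  (odd n = 2k+1),
  (1/12)(2k+1)/(2k−1)  (even n = 2k),

  R<sub>g</sub>² = (l²/12)(n+1)n (odd) or (l²/12)(n+1)(n−1) (even),

  both branches converging to R<sub>g</sub>/R<sub>ee</sub> = 1/√12 = 0.2887,
  the rigid-rod signature — against 1/√6 = 0.408 for an ideal
  (freely-jointed) chain and the compact-globule law
  R<sub>g</sub> = 0.395 N<sup>3/5</sup> + 7.257 Å.
* **Hydration shells** — radial distribution functions g(r) with running
  coordination integral n(r), extrema detection (first maximum 2.65 Å,
  first minimum 3.225 Å, second minimum 5.61 Å), per-site/per-role
  first-shell occupancy, and second-shell coordination both by shell
  integration and by hydrogen-bonded two-hop counting.
* **SASA** — rolling-probe (1.4 Å) solvent-accessible surface area on a
  deterministic golden-spiral lattice, Bondi radii, plus the
  SASA-versus-occupancy correlation that shows the pattern is chiefly
  geometric.
* **Residence kinetics** — per-identity occupancy traces at the 3.5 Å
  cutoff, sojourn extraction with the *single-frame grace rule* (a water
  that leaves for one time step and returns has not ended its episode),
  residence histograms f(t), mono-exponential fits f(t) = A·e^(−t/⟨τ⟩),
  and substitution-fraction classification of departures.
* **Synthetic data** — a rigid triplet-periodic scaffold, programmable
  X-Y-G occupancy patterns with exponential exchange kinetics, bulk water
  at a stated density, and freely-jointed-chain ensembles; every generator
  returns its ground truth so each analysis is tested against known
  answers.

## Worked example

```r
library(hydroshell)

# a (PPG)10 triple-helix scaffold with 0-2-1 hydration exchanging at the
# Gly/Pro(Y) timescales
sc  <- generate_scaffold(scaffold_config(10, spacing_l = 8.85, chains = 3))
hy  <- generate_hydration_trajectory(sc, exchange_config(
         n_frames = 150, pattern = c(X = 0, Y = 2, G = 1),
         mean_sojourn = c(X = 25.68, Y = 25.68, G = 81.72), seed = 1))

site_occupancy(hy$trajectory, hy$sites, cutoff = 3.225)$per_role
#>  G X Y
#>  1 0 2

bead_model(10, 8.85)
#> <bead model> n = 10 (even, k = 5), l = 8.85 A: Rg = 25.4197 A,
#>              Ree = 79.6500 A, Rg/Ree = 0.3191

trace <- occupancy_trace(hy$trajectory, hy$sites, cutoff = 3.5)
fit_exponential(residence_histogram(
  sojourns(trace)[sojourns(trace)$role == "Y", ], bin_width = 5))
#> <exp fit> f(t) = 65.24 * exp(-t / 24.07 ps), R^2 = 0.9656
```

The per-role table recovers the exact 0-2-1 pattern built into the
generator; the even-branch bead model reproduces
R<sub>g</sub> = 25.42 Å at n = 10 and l = 8.85 Å; and the fitted residence
time returns the generator's 25.68 ps scale to within sampling error.

The numbered drivers under `analysis/` run the whole workflow and narrate
their findings (`Rscript analysis/01_simulate.R`, then 02–05), writing
tables under `results/`. `run_report()` produces the same bundle — chain
metrics, per-residue occupancy and SASA, RDF extrema, second shell,
residence fits, and a seed-stamped manifest — in one call.

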