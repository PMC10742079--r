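---
title: "Models and methods behind hydroshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hydroshell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`hydroshell` quantifies the ordered hydration of triplet-periodic,
collagen-mimetic peptides. This vignette is the package's own account of
the models it implements, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open. It states no empirical result that the test
suite and the analysis drivers do not themselves compute.

## 1. The equidistant-bead chain model

A (PPG)$_n$ triple helix is, to a good approximation, a rigid linear array
of $n$ equal-mass triplet centres separated by a fixed spacing $l$. Let
$k = \lfloor n/2 \rfloor$. For odd $n = 2k+1$ the centre of mass sits on
the central bead and the non-central beads lie at distances
$l, 2l, \dots, kl$ on either side, so with the square pyramidal number
$P_k = \sum_{i=1}^k i^2 = k(k+1)(2k+1)/6$,

$$\frac{R_g^2}{R_{ee}^2} = \frac{1}{6}\frac{(k+1)(2k+1)}{(2k)^2}
\quad (\text{odd}), \qquad
\frac{R_g^2}{R_{ee}^2} = \frac{1}{12}\frac{2k+1}{2k-1}
\quad (\text{even } n = 2k),$$

with $R_{ee} = 2kl$ (odd) or $(2k-1)l$ (even), and equivalently

$$R_g^2 = \frac{l^2}{12}(n+1)n \;(\text{odd}), \qquad
R_g^2 = \frac{l^2}{12}(n+1)(n-1) \;(\text{even}).$$

Both parity branches converge to $R_g/R_{ee} = 1/\sqrt{12} \approx 0.2887$,
the rigid-rod signature, with the odd curve always above the even one. The
contrasting references are the ideal freely-jointed chain,
$R_g/R_{ee} = 1/\sqrt{6} \approx 0.408$ (implemented as a Monte-Carlo
ensemble in `generate_ideal_chain()`), and the compact-globule scaling law
$R_g = 0.395\,N^{3/5} + 7.257$ Å for $N$ residues (`globular_rg()`).

**A normalisation subtlety.** The odd-branch average runs over the $2k$
*non-central* beads — the central bead, sitting exactly at the centre of
mass, is excluded from the normalisation. This differs from the all-points
radius of gyration, which divides by $n$. The package deliberately exposes
both: `bead_rg()`/`bead_ratio_squared()` implement the closed forms
above, while `rg_points()`/`radius_of_gyration()` compute the
conventional all-points quantity. The consistency test
(`bead Rg == numerical Rg of the generated bead set to 1e-9 relative`)
therefore drops the central bead for odd $n$ rather than silently choosing
one convention for the user.

The spacing $l$ is recoverable from end-to-end distances of chains of
different length, $R_{ee}(n) = (n-1)l$: `estimate_spacing()` fits the
least-squares slope of $R_{ee}$ against $n$, which for two consecutive $n$
reduces to the plain difference.

## 2. Hydration shells

Every carbonyl oxygen is a candidate binding site; roles X/Y/G are assigned
from residue position within the chain modulo the repeat
(`select_carbonyl_sites()`). All distance logic uses only the water
*oxygen*: hydrogen positions can interchange without the water leaving its
bound position, so consulting them would create spurious exchange events.

Three equivalent routes count first-shell waters, and the package
implements all three because each suits a different input:

* a single frame or crystal structure: direct counting at a **3.5 Å**
  cutoff (slightly wider than the ensemble first minimum, appropriate when
  there is no thermal averaging);
* an ensemble: counting at **3.225 Å**, the first minimum of the
  water-oxygen g(r) in bulk water (the commonly quoted 3.25 Å is treated as a
  rounded display form of the same quantity; computations standardise on
  3.225);
* the radial distribution function itself: $n(r)$, the running integral of
  $g(r)$, evaluated at the first minimum. A test asserts route-equivalence
  of the cutoff count and the interpolated $n(r)$ on identical input.

The RDF normalises per spherical shell by the others' number density
computed per frame from the box volume (bin width default 0.05 Å, range
8 Å, minimum-image distances; an error is raised when the requested range
exceeds half the smallest box width). Extrema are located on a
moving-average-smoothed profile (default 5 bins) by an alternating
max/min scan; absent extrema are reported as `NA`, never invented.

Second-shell coordination has two inequivalent definitions, both provided:
(a) the shell integral of $g(r)$ between the first and second minima
(defaults 3.225 and 5.61 Å) counts *all* second neighbours; (b)
`second_shell_hbonded()` counts only waters hydrogen-bonded to a
first-shell ligand — the distinct *other* water oxygens within the cutoff
of any first-shell oxygen of that site. Distinct-count semantics were
chosen (a water bonded to two ligands of one site counts once) because the
quantity of interest is a second-layer population, not a bond count.

Whether per-role summaries should exclude chain termini (where fraying
and dangling ends distort counts) is a matter of convention;
`site_occupancy()` therefore carries an
`exclude_termini` flag (first and last triplet per chain) and the report
emits both variants.

## 3. Solvent-accessible surface area

`atom_sasa()` uses the rolling-probe point-sampling construction: each
target's sphere of radius $r_{vdw} + 1.4$ Å is sampled on a deterministic
golden-spiral lattice (default 960 points; reproducibility is why the
lattice is deterministic rather than random), and a point is accessible
iff it lies outside every other occluder's expanded sphere. Radii are
Bondi values (C 1.70, N 1.55, O 1.52, H 1.20, S 1.80 Å), configurable per
call since no single table is canonical. Waters and ions are excluded from
the occluder set by default — the quantity of interest is the peptide
surface a water could reach. Tests pin the construction to the analytic
isolated-sphere and two-sphere-cap areas, monotonicity under added
occluders, per-residue additivity, rigid invariance, and <1% change from
960 to 3840 points.

## 4. Residence kinetics and the grace rule

A water's sojourn at a site is a maximal run of frames in which that
identity stays within the 3.5 Å cutoff, where absences of up to one frame
are bridged and the bridged frame counts toward the duration. The grace
window is one *frame*, not one picosecond — the rule is about the sampling
grid, so it scales with the save interval; it is exposed as a parameter
(`grace`, 0 disables). The rule is applied per gap and hence transitively:
the pattern present/absent/present/absent/present is one five-frame
episode, since each gap individually satisfies the rule. The transitive
reading is a package decision — the rule is naturally stated for a single
gap — and the parameter lets a user tighten it.

Sojourns touching either trajectory end are flagged censored and excluded
from means and histograms by default (including them would bias short).
Durations are binned (default bin = frame interval) and fitted to
$f(t) = A e^{-t/\langle\tau\rangle}$ by Levenberg–Marquardt least squares
started from a log-linear regression, zero-count bins excluded, unweighted
(semi-log-straight data make weighting immaterial); a direct
SSE-minimisation fallback handles degenerate (e.g. flat) histograms so a
poor $R^2$ is reported instead of an error. `mean_residence()` and the
fitted $\langle\tau\rangle$ are two estimators of the same quantity and a
test holds them to 10% agreement on $10^4$ synthetic sojourns.

`substitution_fraction()` classifies each uncensored departure by whether
the site's occupant count in the following frame stayed at or above the
site's modal count: 1.0 means pure substitution (no vacancy ever opens),
0.0 means every departure leaves a transient hole.

## 5. The synthetic generator: what it emulates, and what it does not

`generate_scaffold()` builds a rigid scaffold: beads on the axis at exact
spacing $l$ (default 8.85 Å, the per-triplet rise implied by the
end-to-end difference between the 9- and 10-triplet helices), and for each
chain a helical arrangement of residues (PRO, PRO, GLY repeating) carrying
a CA and a carbonyl O per residue. Two deliberate departures from
collagen realism:

* the twist is 60°/residue at site radius 5 Å rather than the realistic
  ~108°/residue, because with three phase-shifted chains the realistic
  twist brings cross-chain carbonyl oxygens within ~3 Å of one another and
  a first-shell water could then be attributed to two sites at once; the
  generator's job is unambiguous ground truth, and helix realism beyond
  site placement is out of scope;
* each X-site oxygen carries a cluster of blocker pseudo-atoms capping its
  outward face (the geometric stand-in for the inter-chain amide that
  occupies the space above the X carbonyl) and each G site a partial
  shade, so carbonyl accessibility is ordered Y > G > X ≈ 0 by
  construction and the SASA–occupancy correlation is positive, mirroring
  the real system's geometry-driven pattern.

`generate_hydration_trajectory()` gives every site `pattern[role]`
bound-water slots (default 0-2-1). Slot occupants persist for sojourns
drawn in continuous time from an exponential of mean `mean_sojourn[role]`
(defaults 25.68 ps for Y, 81.72 ps for G — the liquid-water timescales of
the two hydrated roles) and discretised to frames by ceiling with a
1-frame minimum, mirroring how a trajectory saved every 1–10 ps samples
continuous kinetics; a configuration warning fires when the frame interval
approaches half the sojourn mean, where discretisation bias becomes
material. Departing occupants are replaced instantly (substitution), with
probability `vacancy_prob` of a single-frame hole; how often a real
departure leaves a transient vacancy is not established, so this is an
exposed parameter defaulting to 0 rather than a fixed constant. Bound
waters sit at 2.65 Å (the first-shell g(r) maximum) in a direction drawn
on the outward spherical cap (half-angle 60°), which keeps them inside
both cutoffs of their own site and outside every other site's; unbound
waters are parked on a distant grid. Waters are single points (oxygen
only) — sufficient because every implemented criterion is distance-based
on the oxygen.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no force-field energetics or water geometry, no
thermal vibration of the scaffold, no diffusive approach/escape paths
(waters teleport between bound and parked positions), no correlation
between neighbouring sites' exchange events, and no temperature
dependence beyond what the user encodes in the sojourn means. Tests
against this generator validate the *bookkeeping* — counting, identity
tracking, bridging, fitting — not the physics of any particular peptide.

`generate_bulk_water()` provides the ideal-gas reference (default density
0.0334 Å⁻³, liquid water at ambient conditions; count = density × volume,
rounded) used to verify RDF normalisation ($g \equiv 1$) and analytic
shell integrals. `generate_ideal_chain()` draws unit steps uniformly on
the sphere; per-chain $R_g^2$ uses the walk's vertices including the
origin.

## 6. Problem sizes, determinism, degenerate inputs

The test suite and drivers use desk-scale problem sizes chosen to give
comfortable statistical margins: occupancy recovery on 90 sites × 120–400
frames; sojourn statistics on ≥10⁴ draws (Kolmogorov–Smirnov at
α = 0.01, fits held to 10%); the ideal-chain acceptance ensemble at 10⁵
chains × 10³ steps (ratio held to ±0.005); RDF flatness on four pooled
902-molecule frames. All generators are seeded and bit-reproducible;
`run_report()` stamps its seed and config into a manifest with per-file
checksums so a bundle can be verified against a rerun.

Degenerate inputs are contracts, not afterthoughts: empty atom subsets,
chains lacking the terminal atom, zero-volume boxes, RDF ranges beyond
minimum-image validity, all-censored sojourn sets, monotone g(r) (extrema
reported absent), unknown elements (mass 0 with a warning, excluded from
weighted sums; SASA refuses elements without a radius), and partial
triplets (roles still assigned, with a warning) all have tested behaviour.

## 7. Known limitations

* The PDB reader handles the coordinate dialect the analyses need
  (ATOM/HETATM/MODEL/CRYST1); it does not parse insertion codes, altLocs,
  or multi-character chain ids, and binary trajectory formats are out of
  scope.
* Hydrogen-bond criteria are distance-only throughout; no angular terms.
* The SASA reference values of any specific force-field-equilibrated
  structure depend on the radii table used; the package exposes the table
  rather than asserting absolute areas for real peptides.
* `second_shell_hbonded()` is O(sites × first-shell × waters) per frame;
  it is intended for the structured systems generated here, not for
  ~10⁵-water production boxes.
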