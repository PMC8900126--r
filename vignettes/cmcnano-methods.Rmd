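---
title: "Modelling CMC-8 nanovehicles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CMC-8 nanovehicles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The system

Carboxymethyl cellulose (CMC) is cellulose whose hydroxyls at ring positions
2, 3 and 6 are partially substituted by carboxymethyl (CM) groups, each
carrying −1e at neutral pH. Converting a fraction of the CM groups to
N-octyl amides (CM8) yields the amphiphilic derivative CMC-8: the octyl
tails drive self-assembly above a critical aggregation concentration (CAC),
and multi-chain carboxylate clusters close to the alkyl clusters act as
Zn²⁺ binding sites. `cmcnano` models this system end to end at the
coarse-grained level: chain composition statistics, bead conformers,
screened electrostatics, periodic packing with cluster detection, and the
two bench computations (CAC from pyrene I3/I1 titration; amide degree of
substitution from elemental C/N).

Everything runs on synthetic inputs with known ground truth; no external
data are required.

# Chain composition

## The monomer state space

Each glucose unit carries one of {OH, CM, CM8} at each of positions 2, 3
and 6 — 27 monomer types in total (`build_monomer_library()`). Charge is
−1e per CM; CM8 is neutral and carries one alkyl tail. Masses are the
anhydroglucose residue (162.14 g/mol) plus per-substituent increments under
a declared convention: `sodium_salt` (-CH₂COONa, +80.02; the form CMC is
supplied in — the default) or `free_acid` (-CH₂COOH, +58.04). The octyl
amide increment (+169.27) is convention-independent. The convention only
affects masses and densities, never counts or charges.

## Reconciling the published substitution statistics

For DS ≈ 0.9 CMC the experimental literature gives two summaries of a
1000-mer: positional substitution counts (360–370 at position 2, 160–170 at
3, 350–360 at 6) and class counts (330–340 / 440–450 / 190–200 / 20–30
un-/mono-/di-/tri-substituted monomers). These are mutually inconsistent:
the positional ranges cap the total CM content at 0.900 per monomer while
the class midpoints imply 0.910. No distribution can satisfy both
midpoints, so `fit_pattern_distribution()` reconciles them:

1. The total CM content is pinned to the positionally feasible value
   closest to the class-implied one — 0.900 at the defaults, which also
   honours the "900 CM per 1000-mer" construction. The inconsistency is
   recorded in the fit's provenance, not silently absorbed.
2. The three positional marginals are the least-squares projection of the
   range midpoints onto that total; for the default ranges this lands
   exactly on the upper bounds, p = (0.370, 0.170, 0.360).
3. A single probability law over the eight {OH, CM}³ patterns is then found
   by an equality-constrained weighted least-squares (KKT) solve against
   both midpoint sets, with an active-set pass for nonnegativity.

The marginal constraints leave a two-dimensional family of feasible pattern
laws; a small ridge (1e-4) pulls the solution toward the independence
product of the fitted positional marginals, a neutral tie-break that adds
no correlation structure the data do not demand. The resulting class point
is f ≈ (0.338, 0.446, 0.194, 0.022) — the constrained least-squares
optimum, which sits inside all four printed ranges. (A nearby boundary
point such as (0.335, 0.450, 0.195, 0.020) is also feasible; we report the
optimum rather than a hand-picked vertex.)

For any distribution the identity p₂+p₃+p₆ = f₁+2f₂+3f₃ holds by
construction; the tests check it to 1e−12.

## Chain generation and amidation

`generate_chain()` draws patterns i.i.d. from the fitted law. With
`enforce_exact_counts = TRUE` (default) a repair pass redraws single
monomers from the law conditioned on a CM count one step closer to the
target until the chain carries exactly `round(ds_cm · N)` CM groups — the
deterministic bookkeeping the published counts use (900 per 1000-mer, −90e
per 100-mer). Amidation then converts `round(a · n_CM)` CM groups to CM8,
chosen uniformly per group (not per monomer), because the modification
chemistry targets carboxyl groups.

The default amide fraction is **200/900 ≈ 22.2%**, not 0.22: the printed
"200 amide groups per 1000-mer" and "−70e per 100-mer" are then both exact,
whereas a literal 22% reproduces neither (198 groups; −70.2e). Whether the
original generator enforced exact counts per chain is unstated; both modes
are provided, and the statistical tests use the pure i.i.d. mode.

## Negative-site counting

Negative potential concentrates at 2,3,6-tri-CM monomers (−3e). The
published per-chain site counts (~29–30 for CMC, ~22 for CMC-8 per
1000-mer) come from potential maps with an unstated threshold and slightly
exceed the 20–30 tri-substituted monomers the class template itself allows,
so no counting rule can reproduce them from the stated composition.
`count_negative_sites()` therefore exposes the rule instead of asserting
the numbers: `tri_full` (all three positions charged CM) and `tri_ge2`
(tri-substituted with ≥ 2 charged positions retained after amidation). Both
are validated against closed-form binomial expectations, not against the
printed counts.

# Coarse-grained structure

`embed_chain()` realizes a chain as a freely rotating chain: one backbone
bead per monomer, fixed virtual bond b = 0.515 nm (half the ~1.03 nm
cellobiose repeat), fixed bond angle, uniform dihedrals. The bond angle is
set either directly or through a target persistence length via
cos θ = exp(−b/Lp). One charge bead per CM group (offset 0.35 nm) and one
alkyl bead per CM8 group (offset 0.55 nm) are placed in random directions
normal to the local tangent; the offsets only set length scales for the
electrostatics and clustering stages. Hard-sphere self-avoidance is
available by rejection but off by default, so that ideal-chain statistics
hold exactly in the estimator round-trip tests.

`estimate_persistence_length()` fits log C(k) = −(b/Lp)·k through the
origin (C(0) = 1) on the pooled tangent autocorrelation, using only the
first ~2 decay lengths (C(k) > e⁻²): beyond that the log of a noisy, nearly
zero correlation dominates the regression and biases the slope. A rod
(no decay) is reported as Lp = ∞ with a flag. Recovery of generating
Lp ∈ {2, 5, 10} nm is within 15% with 200 conformers of a 100-mer. No
numeric persistence lengths were published for this system; only the
procedure is reproduced.

# Screened electrostatics

The original study solved the nonlinear Poisson–Boltzmann equation; at desk
scale we substitute the linearized Debye–Hückel superposition in a uniform
dielectric:

φ(r) = Σᵢ k·qᵢ·exp(−|r−rᵢ|/λD) / (εr·|r−rᵢ|),  k = e/(4πε₀) = 1.440 V·nm,

with εr = 80 and I = 0.1 M (λD = 0.304/√I nm ≈ 0.96 nm at 298 K) as stated
for the original calculation. A unit charge 1 nm away in εr = 80
contributes ≈18 mV unscreened, ≈6.4 mV screened. The linearization keeps
the qualitative claims that matter — potential concentrates at tri-CM
sites, and aggregation deepens wells by superposition — while providing an
exact analytic oracle, which the tests use at 100 random probes to 1e−9
relative error. The potential is capped at its value one grid spacing from
each charge; grids default to 0.2 nm spacing and export to APBS-compatible
OpenDX. Hotspots are face-connected components below a threshold (default
−10 mV, ≥5 voxels); Zn²⁺ ions are placed greedily at successive minima
subject to a 0.4 nm separation. The published site counts (29–30/22) and Zn
occupancies (7–8) are NLPB-derived and are compared only qualitatively.

# Packing and cluster detection

`pack_chains()` replaces the original packing optimizer with seeded
rejection packing: random rigid-body placement with minimum-image overlap
rejection. This is deterministic and testable, and packing quality is not
load-bearing for cluster statistics at ~0.6 g/cm³. One caveat follows from
the physics: at bulk density random insertion cannot satisfy a full 3 Å
contact rejection (that is precisely what an optimizer is for), so dense
mechanism tests relax the contact floor to 1 Å — enough to forbid
coincident beads.

Bulk density is pure composition arithmetic: Σ chain masses / (N_A · V).
For the published geometry (2700 × 100-mers, 600 Å box) this gives
0.523 g/cm³ under sodium-salt bookkeeping and 0.491 under free-acid, not
the printed ~0.6; the mass convention behind that figure (counter-ions?
hydration water?) is unstated, so `packed_density_report()` reports both
and the discrepancy is logged rather than forced.

Hydrophobic clusters are connected components of alkyl beads within 6 Å
(minimum image); acidic clusters of carboxylate beads within 8 Å. An acidic
cluster is flagged as a candidate Zn site when its centroid lies 10–15 Å
from an alkyl-cluster centroid — the observed binding-site geometry (a
5-alkyl cluster from 3 chains with a 9-carboxylate cluster nearby). Only
the 10–15 Å proximity is published; the 6/8/3 Å cutoffs are documented
defaults. Detection is verified against a brute-force O(n²) union-find
oracle including periodic images, and against planted fixtures. The
mechanism-level restatement of the central claim — packed unmodified CMC
yields zero flagged Zn sites (it has no alkyl beads at all), packed CMC-8
yields at least one — is tested on a scaled-down system (60 × 20-mers in a
100 Å box, same ~0.5 g/cm³ bulk density) to fit the test budget.

# Assay computations

**CAC.** `fit_cac()` scans every split of the concentration-sorted I3/I1
points into two segments of ≥3 points, fits least-squares lines to each,
keeps the split with minimal total RSS, and intersects the lines; parallel
segments are an error, as is a curve of fewer than 6 points. The abscissa
is linear concentration by default (no transform is stated for the original
analysis); a log10 mode is provided. Uncertainty comes from the delta
method on the two fits' covariances. The fit is exactly scale-equivariant
in linear mode.

**Amide DS.** The original DS equation is only available as an unreadable
figure, so the relation is re-derived from stoichiometry: per monomer there
are 6 ring carbons, 2 per CM and 8 extra per octyl amide, and 1 nitrogen
per amide, hence molar N/C = ds·a / (6 + 2ds + 8ds·a), inverted as
a = r(6+2ds) / (ds(1−8r)). Mass-to-molar conversion uses 12.011 and
14.007 g/mol. The ratio is invertible for r ∈ [0, ds/(6+10ds)); readings
outside that range are an out-of-model error. The published 22% is treated
as a round-trip anchor (forward model at a = 0.22 inverts to 22% exactly),
not as a recomputable value.

# Synthetic data: what a green test establishes

Every generator is seed-deterministic and writes its ground truth to a
sidecar; recovery tests read truth only from the sidecar.

* `gen_pyrene_curve()`: piecewise-linear I3/I1 over a factor-2 dilution
  series (12 points from 5 mg/mL), kink at 0.62 mg/mL, additive Gaussian
  noise σ = 0.01 — the measured CAC and protocol structure, with noise
  chosen to make recovery meaningfully stochastic yet reliable (the
  measured CAC had uncertainty ±0.12). Baseline 0.60 with slopes 0.02/0.5
  are typical pyrene-scale values; no raw spectra are emulated.
* `gen_elemental_readings()`: forward C/N model at 0.2 mg/mL sample
  concentration with multiplicative noise (default 0 in exact tests, 2% in
  Monte-Carlo bias tests).
* `gen_planted_system()`: bead geometries with known cluster answers;
  planted beads scatter within 0.15 nm of their centroid so that a planted
  cluster is guaranteed connected at the 6 Å alkyl cutoff (0.15 nm cube
  half-width bounds the diameter by 0.52 nm).

These generators emulate the *structure* of the real inputs, not their
physics: no instrument drift, no correlated noise, no real conformational
ensembles. A green recovery test establishes that the estimators invert
their own forward models at realistic noise — not that they would
reproduce the wet-lab numbers from raw instrument output.

# Numerical choices and limitations

* RNG: every public function takes a `seed` and restores the caller's RNG
  state; identical seeds give bit-identical outputs.
* The KKT fit uses a 1e−4 ridge and 1e−9 feasibility tolerance; the
  active-set loop is capped at 8 iterations (at most 8 variables can pin).
* Potential singularities are capped at one grid spacing; hotspot
  connectivity is 6-neighbour (face) connectivity.
* Cluster centroids are computed after minimum-image unwrapping relative to
  the first member, correct for clusters smaller than half the box.
* Not modelled: all-atom MD and force fields, nonlinear PB, heterogeneous
  dielectric, Zn²⁺ binding free energies, aggregation kinetics, micelle
  size distributions, block/correlated substitution along the chain
  (i.i.d. patterns only).
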