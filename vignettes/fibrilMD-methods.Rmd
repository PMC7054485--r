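---
title: "Models and methods behind fibrilMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibrilMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fibrilMD simulates a coarse-grained micellar hydrogel under rate-controlled
uniaxial stretching and quantifies how the deformation rate decides between
two fates of the network: recovery of the micellar structure after slow
stretching, versus formation of persistent fibrillar bundles after fast
stretching. This vignette documents the model, its parameters, the numerical
choices, and what the desk-scale defaults can and cannot show.

## The network model

The system is a periodic cubic box containing linear coarse-grained chains
with the repeat unit **AA-(CH2, CH2, O)x3**: one acrylic-acid bead followed
by three PEG monomers of three beads each (10 beads per repeat). AA beads
attract each other strongly and aggregate into micelle cores ("physical
clusters", PCLs); the PEG spacers form the flexible shells and the bridges
between cores. The reference composition is 8 chains of 200 beads solvated
by 2,447 single-bead waters in a 5 nm box; `build_network()` reproduces it
with its default arguments. The chain portion between two consecutive AA
beads is a **short flexible chain (SFC)** of 11 beads; a chain of 200 beads
carries 19 SFCs, the default network 152.

The Hamiltonian is

$$H = \sum_{n_b} U_b + \sum_{n_a} U_a + \sum_{n_p} U_{el} + \sum_{n_p} U_{LJ}$$

with harmonic bonds $U_b = k_b (r - r_0)^2/2$, harmonic angles
$U_a = k_a(\theta - \theta_0)^2/2$, 12-6 Lennard-Jones pair interactions and
Coulomb interactions between partial charges. Nonbonded terms use the
minimum-image convention, a cutoff, Lorentz-Berthelot combination, and 1-2 /
1-3 exclusions. The Lennard-Jones potential is shifted to zero at the
cutoff; electrostatics use a reaction-field-style form whose potential *and*
force vanish at the cutoff, so cutoff artifacts do not pump energy into the
system.

### Force-field constants

The parameter values are this package's own and are deliberately simple;
they are documented here once and shipped as `default_forcefield()`:

| parameter | value | why |
|---|---|---|
| bond $k_b$, $r_0$ | 4000 kJ/mol/nm², 0.15 nm | near-atomistic backbone spacing; soft enough for a 2-8 fs timestep |
| angle $k_a$, $\theta_0$ | 50 kJ/mol/rad², 109.47° | freely-rotating-chain stiffness |
| AA $\varepsilon$, $\sigma$ | 5.0 kJ/mol, 0.45 nm | $\approx 2\,k_BT$ self-attraction: AA beads aggregate into distinct micelle cores that still exchange members at accessible times. Much weaker and no micelles form; much stronger (e.g. 8 kJ/mol) and every AA bead condenses into one immobile core, which destroys the bridging-chain population the analysis is about |
| CH2 / O $\varepsilon$, $\sigma$ | 0.40 / 0.60 kJ/mol, 0.39 / 0.30 nm | weakly interacting spacer beads; raising PEG-PEG attraction to even 0.55/0.75 collapses the solvated network into a single dense globule |
| W $\varepsilon$, $\sigma$ | 0.65 kJ/mol, 0.3166 nm | single-bead water at liquid-like density |
| charges | AA $-0.2\,e$, water countercharge | "moderate" chain-water electrostactics; the water charge is computed at build time to neutralise the box |
| cutoff | 1.2 nm (1.0 nm in the reduced configuration) | half the smallest box edge under the deformation protocols used |

Masses are the chemical group masses (AA 72.06, CH2 14.03, O 16.00, W 18.02
g/mol). Units everywhere: nm, ps, kJ/mol, K, e.

### Dynamics and deformation

`run_protocol()` integrates with velocity Verlet in the BAOAB Langevin
splitting (friction default 1 ps⁻¹; friction 0 gives NVE dynamics, used by
the energy-conservation tests). The default timestep is 2 fs; the reduced
desk-scale protocols use 5-8 fs, which the soft bonds tolerate under the
thermostat. Uniaxial stretching is volume-conserving: every step, $L_z$ is
multiplied by an increment and $L_x, L_y$ by its inverse square root, with
all coordinates remapped affinely. Increments are chosen so the engineering
strain grows *linearly* in time, hence a 100% stretch at rate $r$ takes
exactly $1/r$: 10 ns for the quick rate (0.1 ns⁻¹) and 100 ns for the slow
rate (0.01 ns⁻¹). The protocol is ramp → hold → optional reverse (same rate,
opposite sign). Neighbour handling is a Verlet list with a 0.3 nm skin
rebuilt on a displacement criterion; positions are wrapped at every rebuild
so a single-correction minimum image is exact.

## Structural analysis

**Physical clusters** are single-linkage components of the AA-AA
minimum-image distance graph. The linkage cutoff is not stated in the
source material for this model family; we default to 0.65 nm, the boundary
between loop2 and unstretched SFC classes, and expose it as a parameter.
Cluster identity is tracked across frames by maximal member overlap with
ties broken by the lowest shared index.

**Cluster volume fraction / damage.** The AA positions (plus periodic
images within one threshold of the box faces) are tetrahedralized by a 3D
Delaunay construction (an in-package Bowyer-Watson implementation with
extended-precision predicates and a distant enclosing simplex; an
independent scipy triangulation is used as a cross-check in the tests).
$V_{PCL}$ sums the volumes of tetrahedra whose six edges all lie below the
edge threshold and whose centroid falls in the primary box (the
deduplication rule for periodic images), divided by the box volume. Damage
is $1/V_{PCL}$. On the reduced desk-scale system the micelle cores are
small and string-like, and at the 0.65 nm threshold the tetrahedra census
is usually empty (damage formally infinite); the reduced-system damage
curves therefore use a 0.9 nm edge threshold, where the census is
well-populated. Both thresholds are parameters, not claims.

**SFC classes.** Each SFC is classified by its end-to-end distance $r_e$
with half-open boundaries assigned to the lower class — loop1
($r_e \le 0.42$ nm), loop2 ($0.42 < r_e \le 0.65$), unstretched
($0.65 < r_e \le 0.85$), stretched ($r_e > 0.85$) — and by its cluster
connectivity (loops close on one cluster; unstretched/stretched chains
bridge two). When distance and connectivity disagree the class follows the
distance and the record is flagged, so the class partition is always total.
`transition_matrix()` counts class changes between consecutive frames and
reports the neighbour-transition fraction and the number of skip
transitions.

**Bundles.** A bundle is at least three SFCs that each exceed 0.65 nm
end-to-end, bridge the *same* unordered cluster pair, and are mutually
aligned: every pair of end-to-end vectors (taken as undirected, folded to
≤ 90°) encloses at most 30°, the angle below which fibril formation is
observed in the four-chains analysis. Detection enumerates the maximal
cliques of the pairwise alignment graph within each cluster-pair group,
which is deterministic and provably identical to exhaustive subset
enumeration — the tests verify this equality against an independent
`combn`-based oracle. Bundle endpoints $M_1, M_2$ are the centres of mass
of the member chain-end AA beads on each side; the fiber vector is the unit
vector $M_1 \to M_2$. Per-end rotation is the mean signed angular
displacement of the end beads about the frame-of-reference fiber axis
(right-hand rule); twist is the difference of the two end rotations, so a
synchronously rotating bundle has zero twist. A bundle that persists over a
configurable trajectory window (default 10 ns at full scale) is promoted,
conceptually, from transient bundle to fibril; `match_bundles()` implements
the persistence matching (same cluster pair, ≥ 2 shared members).

**Orientational order.** $P_2 = (3\langle\cos^2\theta\rangle - 1)/2$ over
next-nearest-neighbour segment vectors $v_i = A_{i+2} - A_i$, with $\theta$
measured against a fiber vector (for the network, the stretch axis +z; for
the four-chains model, the normalized sum of the four end-to-end vectors).
$P_2 = 1$ parallel, $-0.5$ perpendicular, 0 isotropic.

**Layer profile.** `concentration_profile()` histograms one species along z
(periodic bins). A bin is a significant peak when it is a periodic local
maximum exceeding the mean count by `prominence` Poisson standard
deviations (default 3), which keeps uniform distributions peak-free without
a tuned absolute threshold; peak centres are 3-bin count-weighted
centroids, and the layer spacing is the mean gap between adjacent sorted
centres (no wrap-around gap, so $n$ layers yield $n-1$ gaps).

## Relaxation analysis

`autocorrelation()` computes $f(t) = \langle x(0)\cdot x(t)\rangle$
averaged over entities and sliding time origins (origin averaging is the
default; a single-origin estimate is available via the origin stride).
Unit-vector observables are normalized first; $f(0) = 1$ exactly after
normalization. The five standard observables and their windows: particle
velocities (1 ps window, 1 fs sampling at full scale), bond vectors and
next-nearest-neighbour conformation vectors (100 ps / 0.1 ps), continued
presence of each AA bead in its initial physical cluster (an indicator;
100 ns / 0.1 ns) and bundle axis orientation (100 ns / 0.1 ns), with every
window rescalable for desk-scale runs. A dissolved bundle keeps its last
axis in the series, which biases the bundle observable toward *slower*
apparent decay; in practice unstable bundle populations are reported as
unusable by the fit rather than given a spurious relaxation time.

`fit_exponential()` performs a nonlinear least-squares fit of
$A e^{-t/\tau}$ over lags with $f$ above a noise floor (default 0.05,
seeded by a log-linear fit). A fit is *unusable* when it fails, when the
series does not decay, or when $\tau$ exceeds ten times the observation
window — the criterion that marks bundle orientation as unanalyzable when
bundles are not stable. The reported half-time is $\tau \ln 2$.

The Weissenberg number is $Wi = \dot\gamma \tau$. Regimes: viscous below
$Wi = 0.5$, elastic above $Wi = 10$, viscoelastic between. The nominal
viscoelastic band is 0.5-2, but the reference classification tags
$Wi = 2.03$ as viscoelastic while reserving "elastic" for $Wi \gg 1$; we
therefore read the elastic boundary as an order of magnitude above unity
and make both thresholds arguments of `weissenberg()`. One published row
multiplies to 1.776 but prints 1.773; the package always reports the
computed product.

## The four-chains model and the stable twist

`build_four_chains()` places four freely rotating 60-bead PEG chains on a
single physical crosslink (four AA anchor beads, 0.28 nm from the common
axis), with the free ends pinned on a cone such that adjacent end-to-end
vectors enclose exactly the requested mutual angle. Anchors and pinned ends
are positionally restrained; the slack of each chain (contour length minus
end-to-end distance) is laid out as a smooth bulged arc so every bond
starts near its rest length. "Unstretched class" for these long chains
means an end-to-end distance of half the contour length (the same relative
extension as the middle of the 11-bead SFC unstretched band); the mutual
angle default is 10°, the fibril-forming geometry.

`stable_twist()` measures the energy-minimizing end twist: rotate the four
pinned ends rigidly by $\phi$ about the fiber axis, relax the interior
deterministically by steepest descent, and record the potential energy.
Because a single thermal snapshot is chiral, one replicate may prefer
either twist sense; the estimator therefore scans both signs, folds each
replicate's curve into $|\phi|$ relative to its untwisted energy, averages
the folded curves over independently built replicates, and reports the
parabola vertex around the discrete minimum of the mean curve. Energy
differences along $\phi$ are a few kJ/mol for a ~240-bead system — the
same order as the spread between the conformational basins the relaxation
lands in — so deep deterministic relaxation (thousands of steepest-descent
steps) and replicate averaging are both needed, and even then the resolved
structure is weak: with the shipped force field the replicate-mean curve
is shallow near zero twist and rises toward large imposed twists, so the
located minimizer is a small angle whose exact value is seed- and
force-field-dependent. Read it as "the stable twist of this model is
small", not as a transferable constant.

## Desk-scale study conditions

The full reference system (8×200 beads, 2,447 waters, 10-100 ns protocols)
is beyond a desk-scale test budget. The shipped reduced configuration
(`default_run_config("reduced")`) uses 2 chains × 100 beads with 300 waters
in a 3 nm box; the rate-dependence study in the acceptance tests uses 4
chains × 100 beads with 400 waters in a 3.4 nm box (40 AA beads, 36 SFCs),
a 1.0 nm cutoff, an 8 fs timestep, a 0.4 ns equilibration, 75% stretch at
3 ns⁻¹ (fast) versus 0.3 ns⁻¹ (slow), and 1 ns holds. These sizes were
chosen so a full fast-versus-slow comparison integrates a few hundred
thousand steps; at this scale bundle counts are small (a handful of SFCs
participate, matching the scaled-down expectation from ~9 bundles among
152 SFCs at full scale), so the fast/slow comparison is evaluated on
hold-phase averages, not instantaneous counts.

What the reduced runs demonstrate: micelle formation, the SFC class
machinery, strain-induced class flux, a populated damage curve with
stretch-induced rise and hold-phase recovery, and transient bundle
formation. What they cannot demonstrate: *persistent* bundles. At this
scale and with the shipped force field, detected bundles are thermal
flickers around the alignment and end-to-end thresholds — the same SFCs
recur in bundles intermittently, but no bundle survives between 20 ps
analysis frames under either fast or slow stretching, so the
rate-dependence of bundle *persistence* (the hallmark of fibril formation
at full scale) is not reproduced; stabilizing aligned chains requires
interchain cohesion that, at desk density, collapses the whole network
instead. Likewise out of reach: the full-scale bundle census (9 ± 2), the
22% participation fraction, the ~1.17 nm layer spacing of the fully
stretched large network, and 100 ns relaxation spectra — those depend on
the original force field and system size. The layer-spacing and relaxation analyses are
therefore validated against synthetic fixtures with planted ground truth
(layered point sets; spherical rotational diffusion with a known
correlation time, for which $\langle u(0)\cdot u(t)\rangle = e^{-t/\tau}$
exactly), not against reduced MD.

## Numerical notes and limitations

- Deterministic seeding throughout: builders, thermostat noise and fixtures
  consume an isolated RNG stream derived from the `seed` argument, and
  identical calls are bit-identical.
- The Bowyer-Watson triangulation handles its enclosing simplex at 10⁴
  times the cloud extent; hull-adjacent slivers with circumradii beyond
  that scale would be lost, but such simplices always fail the edge filter
  long before.
- The steepest-descent minimizer is intentionally simple (adaptive step,
  reject-on-increase); it is used to remove bad contacts and for the
  twist-energy relaxations, where determinism matters more than speed.
- The stress tensor is not computed; mechanical response is out of scope.
- Forces are cut off, not Ewald-summed; with the small partial charges used
  here the Coulomb term is a minor perturbation, consistent with a solvent
  that has only minor influence on the mechanics.
- At the reduced scale, cluster and bundle censuses are small-number
  statistics; single-seed curves are noisy and the package's experiment
  driver supports multi-seed aggregation (`n_replicates`) for mean ± sd
  tables.
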