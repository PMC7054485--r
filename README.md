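# fibrilMD

Coarse-grained molecular dynamics of strain-induced fibril formation in
micellar hydrogel networks.

Hydrogels built from chains of alternating sticky groups (acrylic acid, AA)
and flexible PEG spacers self-assemble into micellar networks: AA beads
aggregate into micelle cores ("physical clusters") that act as non-covalent
crosslinks, bridged by short flexible chains (SFCs). Stretched *quickly*,
such a network reorganizes its bridging chains into aligned bundles that
persist as fibrils — the mechanism believed to underlie fiber formation in
materials like spider silk. Stretched *slowly*, the same network relaxes and
recovers its micellar structure. fibrilMD is for researchers who want to
simulate and quantify this rate-dependent fibrillogenesis at desk scale: it
builds the network and a minimal four-chains model, integrates
rate-controlled constant-volume uniaxial stretching with a Langevin
thermostat, and ships the complete structural and relaxation analysis
machinery.

The Hamiltonian is

    H = Σ U_bond + Σ U_angle + Σ U_Coulomb + Σ U_LJ

with harmonic bonds and angles, shifted Lennard-Jones and reaction-field
Coulomb nonbonded terms. The analyses include:

- **physical clusters** — single-linkage AA aggregates, identity-tracked
  across frames; network damage as the inverse Delaunay volume fraction
  1/V_PCL of the cluster phase;
- **SFC taxonomy** — loop1 / loop2 / unstretched / stretched classes by
  end-to-end distance and cluster connectivity, with class-transition
  bookkeeping;
- **bundles and fibrils** — maximal sets of ≥3 mutually aligned (≤30°)
  bridging SFCs spanning the same cluster pair, with fiber vectors, per-end
  rotation and twist tracking;
- **orientational order** — P2 = (3⟨cos²θ⟩ − 1)/2 of chain segments against
  a fiber vector; z-axis layer profiles with peak spacing;
- **relaxation** — time-autocorrelation functions of velocities, bond and
  conformation vectors, cluster membership and bundle orientation, fitted to
  exponential decays; Weissenberg numbers Wi = γ̇·τ with
  viscous/viscoelastic/elastic regime labels.

## Worked example

Build and deform a reduced network (2 chains × 100 beads, 300 waters, 3 nm
box — a desk-scale stand-in for the reference 8 × 200 / 2,447-water / 5 nm
system), then analyze its structure:

```r
library(fibrilMD)

sys <- build_network(n_chains = 2, groups_per_chain = 100, box_edge = 3,
                     n_water = 300, seed = 1,
                     ff = default_forcefield(cutoff = 1.0))
sys
#> particle_system: 500 particles
#>   box: 3 x 3 x 3 nm
#>   species: AA:20  CH2:120  O:60  W:300
#>   bonds: 198  angles: 196  SFCs: 18
#>   force field: assigned

sys <- minimize_system(sys, 400)
sys <- equilibrate(sys, 200, dt = 0.005, seed = 1)$system
identify_clusters(sys)
#> physical_clusters: 7 clusters over 20 AA groups (cutoff 0.65 nm)
#>   sizes: 11 3 2 1 1 1 1

prot <- deformation_protocol(rate = 1, target_ratio = 0.5, hold = 0.1,
                             dt = 0.005, stride = 2000)
run <- run_protocol(sys, prot, seed = 1)
tab <- analyze_structure(run$trajectory, edge_threshold = 0.9)
tail(tab[, c("time", "strain", "n_clusters", "damage", "stretched",
             "n_bundles", "p2_z")], 3)
```

Each row reports, per analysis frame: the engineering strain, the number of
physical clusters, the damage 1/V_PCL (large when the micellar phase is
disrupted), the stretched-SFC census, the bundle count and the global P2 of
all chain segments against the stretch axis. The four-chains model is
available through `build_four_chains()` / `twist_energy_scan()` /
`stable_twist()`, and `relaxation_suite()` assembles the τ / Wi / regime
summary from recorded trajectories.

A thin command-line wrapper is installed as `exec/fibrilmd` with
subcommands `build`, `run`, `analyze-structure` and `analyze-relaxation`
operating on extended-XYZ trajectories plus a plain-text topology sidecar.

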