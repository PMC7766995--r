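# dendritraj

Trajectory analysis of charged peptide dendrimers: structure,
double-layer electrostatics, hydrogen bonding, and NMR spin-lattice
relaxation observables, computed from MD coordinates in R.

## The problem

Lysine-based peptide dendrimers with charged dipeptide spacers (Lys-2Arg,
Lys-2Lys) are gene-delivery candidates. A second-generation molecule
carries 16 protonated terminal amines plus 28 charged spacer side groups
(bare charge +44 e), neutralized by counterions. The puzzle these systems
pose is that two such dendrimers can be essentially identical in size,
shape and electrostatics, yet clearly distinguishable by proton NMR: the
orientational mobility of the spacer side CH2 groups differs strongly, and
the controlling variable is the *topological distance* — the number of
chemical bonds from a CH2 carbon to the end of its side segment — not the
spacer chemistry.

`dendritraj` gives an analyst everything needed to quantify that story
from a trajectory:

- **structure** — per-frame radius of gyration
  `Rg² = (1/M) Σᵢ mᵢ rᵢ²`, gyration-tensor asphericity
  `α = 1 − 3(IxIy + IxIz + IyIz)/(Ix+Iy+Iz)²`, Kirkwood hydrodynamic
  radius `Rh⁻¹ = ⟨rᵢⱼ⁻¹⟩`, terminal-group radius `Re`, radial profiles
  `ρ(r)`, `nt(r)`, angular congregation coefficient `k45`;
- **electrostatics** — radial charge `q(r)` and cumulative charge `Q(r)`,
  effective charge `Q*` at `Rmax`, charge renormalization `Q*/Qbare`,
  surface charge density `σ = Q*/(4πRmax²)`, the spherically symmetric
  Poisson potential driven by the Bjerrum length
  `λB = e²/(4πϵϵ₀kBT)`, zeta potential `ζ = ψ(Rmax)·kBT/e`, ion pairs
  from `g(r)` and osmotic ions from `⟨n_osm⟩ = Qbare − Q* − ⟨n_pairs⟩`;
- **hydrogen bonds** — geometric detection (D–A < 0.35 nm, H-D-A
  deviation angle < 30°), per-class counts, continuous lifetimes with
  cubic-spline sub-frame refinement;
- **NMR relaxation** — orientational ACFs `P1(t)`, `P2(t)`, the identity
  check `P2 = P1³`, spectral density `J(ω) = 2∫P2(t)cos(ωt)dt`, reduced
  rate `ω[J(ω) + 4J(2ω)]` and physical `1/T1H = (A0/ωH)·ω[J + 4J(2ω)]`,
  pooled by topological-distance class;
- **synthetic data** — generators with closed-form ground truth
  (rotational diffusion, Ornstein-Uhlenbeck size pulsation, double-layer
  charge clouds, telegraph bond processes, a Brownian-dynamics
  coarse-grained toy dendrimer) standing in for microsecond atomistic
  runs.

Formats: PDB/GRO structures, multi-frame GRO and DCD trajectories;
CSV result tables and JSON run manifests.

## Worked example

Generate a coarse-grained generation-2 Lys-2Arg trajectory with the
package's Brownian toy integrator and push it through every stage:

```r
library(dendritraj)
run <- gen_toy_dendrimer_trajectory(2, "2Arg", n_steps = 2e4,
                                    save_every = 20, seed = 1)
structure_summary(run$traj, run$system, temperature = 310)
#>   temperature alpha    Rg Rg_sd    Rh Rh_over_Rg R_sphere    Re   k45
#> 1         310 0.176 1.673 0.141 1.649      0.986     2.16 2.091 0.013

electrostatics_summary(run$traj, run$system, temperature = 310)
#>   temperature Q_star renorm sigma Rmax zeta_mV n_ion_pairs n_ion_osmotic
#> 1         310 13.889  0.316 0.157 2.65  22.237      15.454        14.657

nmr_relaxation_summary(run$traj, run$system, temperature = 310)$table
#>      class tau_ps censored n_instances temperature reduced_rate t1h_rate
#> 1   side_3 0.0277    FALSE          28         310     0.002042  0.00455
#> 2   side_4 0.0297    FALSE          28         310     0.003120  0.00695
#> 3   side_5 0.0368    FALSE          28         310     0.004717  0.01051
#> 4    inner 0.0331    FALSE           6         310     0.020008  0.04458
#> 5 terminal 0.0193    FALSE           8         310     0.000912  0.00203
```

Reading the output: the toy macroion is compact and nearly spherical
(`alpha` 0.18, `Rg` 1.7 nm), its effective charge is renormalized to
about a third of the bare +44 e by condensed counterions (`renorm` 0.32),
and the zeta potential at the slip-plane proxy `Rmax` is ~22 mV. In the
mobility table the side-CH2 correlation times order strictly by
topological distance (`side_3 < side_4 < side_5`) with the terminal
groups fastest — the mechanism that makes chemically similar dendrimers
distinguishable by NMR. (Toy-model numbers; absolute values are not those
of the atomistic system.)

`run_full_analysis()` assembles the same tables across a temperature
series and writes CSVs plus a JSON manifest from which
`rerun_from_manifest()` reproduces the run exactly.

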