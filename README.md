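# glyccs

Gas-phase structure assignment for glycan ions from ion-mobility
collision cross sections.

## The problem

Drift-tube ion-mobility mass spectrometry (DTIMS) separates isobaric
glycans — anomers, linkage isomers, epimers — by their nitrogen collision
cross section (CCS, Ω, in Å²). Going the other way, from a measured CCS
back to a molecular structure, needs a computational pipeline: a glycan
ion `[M + H]⁺` or `[M − H]⁻` can carry its proton (or lose one) at any of
many hydroxyl, carbonyl, ring-oxygen or amine sites, each charge site
shapes a different conformational ensemble, and each ensemble projects to
a different CCS. `glyccs` implements that pipeline for singly charged
glycan ions, plus the scoring framework used to judge assignments against
experimental reference CCS compilations.

The stages, in workflow order:

1. **Charge-site enumeration** — every titratable site of a seed
   structure (explicit hydrogens required) generates one charge model:
   deprotonation removes the site's O–H/N–H proton; protonation places a
   new H on the lone-pair bisector.
2. **Energy ranking** — each charge model is relaxed with the built-in
   classical surrogate backend (harmonic bonds/angles, cosine torsions,
   12-6 + Coulomb nonbonded over electronegativity-equalisation charges);
   models within **10 kcal/mol** of the global-minimum model (RE ≤ 10,
   inclusive) are retained as candidates.
3. **Conformer ensembles** — up to 1000 conformers per candidate from
   stochastic torsion sampling (60° grid ± 15° jitter) with clash-relief
   minimisation; ensembles above 50 conformers are reduced to
   representative centers by deterministic community clustering on the
   pairwise heavy-atom RMSD matrix (each center = its cluster's
   lowest-energy member).
4. **CCS computation** — per optimized center, by the projection
   approximation (PA; orientation-averaged union-of-disks area) or the
   trajectory method (TM; momentum-transfer collision integral Ω(1,1)
   from classical scattering in a Lennard-Jones + charge-induced-dipole
   potential, N₂ buffer at 298 K, 10 cycles × 20 velocity points × 500
   impact-parameter samples by default). Mason–Schamp conversion between
   reduced mobility K₀ and Ω is included.
5. **Boltzmann-weighted assignment** — conformer populations
   `P_i = exp(−RE_i/kT) / Σ_j exp(−RE_j/kT)` (k = 1.987204×10⁻³
   kcal·mol⁻¹·K⁻¹, T = 298 K) weight the center CCS values over the
   ≈3 kcal/mol populated window; the report compares computed CCS with
   stepped-field/single-field references via
   `%error = |calc − ref|/ref × 100`, flags success at ≤ 3%, and the
   discrepancy between the two experimental methods is quantified by
   `%Δ = |a − b|/mean(a,b) × 100`.

Three reference tables (experimental stepped- and single-field N₂ DTIMS
CCS values and previously computed CCS values for 27 glycan ion systems)
ship as plain CSV under `inst/extdata/`.

## Worked example

```r
library(glyccs)

mz <- read_structure(system.file("extdata", "melezitose.sdf", package = "glyccs"))
mz
#> <glyccs_molecule> melezitose: 66 atoms (32 H), 68 bonds, net charge +0
#>   formula C18H32O16, monoisotopic mass 504.1690 Da
#>   ...

mods <- enumerate_charge_models(mz, "neg")
length(mods)        # 11 deprotonation models, one per hydroxyl (I ... XI)
#> [1] 11

res  <- lapply(mods, evaluate_energy)
cand <- rank_and_filter(res, window = 10)   # RE <= 10 kcal/mol retained
```

End-to-end on the bundled synthetic disaccharide-like fixture:

```r
rep <- run_pipeline(pipeline_config(
  input = "disaccharide_like", seed = 42,
  conformers = list(target = 60)))
rep
#> <assignment report> 4 system(s), policy averaged, threshold 3.0%
#>             analyte mode enum_label      site_class n_conformers n_centers
#> 1 disaccharide_like  neg          I      hydroxyl_O           53         3
#> 2 disaccharide_like  pos          I ether_or_ring_O           49        49
#> ...
#>   ccs_method ccs_globalmin ccs_weighted
#> 1         PA        99.742       99.725
```

Here the negative-mode ensemble exceeded 50 conformers and was clustered
to 3 representative centers; the positive-mode ensembles passed through
unclustered. `ccs_weighted` is the Boltzmann-weighted PA CCS in Å² over
the populated (RE ≤ 3 kcal/mol) centers.

Scoring against the bundled compilations:

```r
t3 <- glyccs_reference("table3")
success_rate(t3)$count                                   # 14 of 27 systems <= 3%
success_rate(t3, reference_policy = "best_of_methods")   # ~70%
```

A thin CLI ships in `inst/exec/glyccs`
(`glyccs run -c config.yaml`, `glyccs ccs --method tm file.sdf`, ...).

## Limitations

The energy backend is a classical surrogate with a clearly labelled
charge scheme, not an electronic-structure method: relative energies and
charge-site rankings are qualitative, and no attempt is made to
reproduce published quantum-chemistry CCS values. The N₂ buffer gas is a
single-site isotropic pseudo-atom (no quadrupole). See the methods
vignette (`vignettes/glyccs-methods.Rmd`) for the model, parameter and
design discussion.
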