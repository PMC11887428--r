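---
title: "Methods: models, parameters and design choices in glyccs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in glyccs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what each stage models, which parameters matter, where the design was
genuinely open and what was decided, and what the tests do and do not
demonstrate about real data.

## The assignment problem

A glycan ion observed in drift-tube ion-mobility mass spectrometry is
characterised by one number, its nitrogen collision cross section
$\Omega$ (Å$^2$). Assigning a structure to that number requires modelling
three nested unknowns: *where the charge sits* (each hydroxyl, carbonyl,
ring oxygen or amine of the molecule is a candidate protonation or
deprotonation site), *which conformations the resulting ion populates*
(glycosidic $\varphi/\psi$ torsions, hydroxyl rotors, exocyclic
CH$_2$OH), and *what CCS that populated ensemble presents*. The pipeline
treats these in sequence, pruning aggressively at each stage, because the
cost per structure rises steeply from graph enumeration (free) through
force-field relaxation (cheap) to trajectory-method CCS (expensive).

Two structural facts about carbohydrates license the pruning. First, the
anomeric configuration is fixed under ion-mobility conditions — the
barrier to rotation about the acetal carbon is far above thermal — so
anomers are distinct inputs, never interconverted by sampling; the
stereo-preservation assertions throughout the package enforce exactly
this. Second, glycans have few rotatable bonds for their size (rings are
locked), so the charge site can be ranked on the seed conformation alone
before any ensemble is generated.

## Charge models

`find_titratable_sites()` perceives site classes from local graph
patterns only (an O with one H and one heavy neighbour is a hydroxyl; an
O with two heavy neighbours and no H is an ether/ring oxygen; an N
adjacent to a carbonyl carbon is an amide). Negative mode enumerates
every O–H/N–H site; positive mode enumerates hydroxyl, carbonyl and
ether/ring oxygens and amine nitrogens.

Open choices, and what was decided:

* **Ring/ether oxygens as protonation sites.** Both behaviours are
  defensible; the package includes them by default
  (`include_ether_o = TRUE`) because excluding them silently would hide
  genuine low-energy charge states; the flag restricts enumeration to
  hydroxyl-type sites when a user wants the narrower census.
* **Amide nitrogens** are excluded from protonation by default
  (O-protonation of amides is strongly preferred chemically);
  `include_amide_n = TRUE` overrides.
* **Proton placement.** The new H is placed at 0.96 Å from O (1.01 Å
  from N) along the negative of the sum of unit vectors to the site's
  bonded neighbours — the lone-pair bisector. Any reasonable placement
  works because the surrogate relaxation immediately follows; the
  bisector avoids clashes deterministically.
* **Symmetry.** Graph-equivalent sites (e.g. the two hydroxyls of a
  symmetric diol) produce isomorphic models; `deduplicate_models()`
  removes them by VF2 isomorphism on element/charge vertex colours,
  keeping the lowest enumeration index.

## The surrogate energy backend

The pipeline's contract with its energy provider is narrow: a
single-point energy, a locally relaxed geometry, and per-atom partial
charges, deterministic for a fixed input. The built-in backend is a
classical surrogate potential:

* harmonic bonds, $k_b = 700/r_0$ kcal·mol$^{-1}$Å$^{-2}$ with $r_0$ the
  covalent-radius sum; harmonic angles (60 kcal·mol$^{-1}$rad$^{-2}$,
  109.47° default, 120° at sp$^2$-like centers);
* threefold cosine torsions over single bonds (0.6 kcal/mol split over
  the torsion paths of each bond; twofold, 25 kcal/mol for double
  bonds);
* 12-6 van der Waals (Bondi radii, small element well depths) and
  Coulomb terms over all pairs three or more bonds apart, 1-4 pairs
  scaled by 0.5;
* partial charges from electronegativity equalisation with the shielded
  kernel $A_{ij} = 332.0637/\sqrt{r_{ij}^2 + d_i d_j}$,
  $d_i = 332.0637/(2\eta_i)$, whose diagonal equals twice the Mulliken
  hardness. The shielded form is what makes the linear system
  well-posed; a bare distance-damped kernel is not positive definite
  against these hardnesses and produces unbounded charge transfer.
  Charges are computed once at the input geometry and held fixed during
  relaxation (and reused when already present on a molecule), which
  makes re-evaluation of a relaxed structure an exact fixed point. The
  scheme is a labelled stand-in for quantum-mechanical population
  charges; its outputs are tagged `surrogate` everywhere.

The minimiser is a deterministic limited-memory quasi-Newton (L-BFGS,
history 8) with Armijo backtracking, run to a maximum-gradient tolerance
of 10$^{-4}$ kcal·mol$^{-1}$Å$^{-1}$ within 2000 steps. Plain steepest
descent does not reach that tolerance on sugar-sized molecules in any
reasonable step budget; L-BFGS does so in a few hundred steps and is
still a line-search gradient method.

The 10 kcal/mol retention window is applied to relative energies
computed **after** per-model relaxation (applying it to single-point
energies of unrelaxed models is also supported by calling
`rank_and_filter()` on unrelaxed evaluations, but relaxation-first is
the default: unrelaxed proton placements carry arbitrary strain). The
boundary is inclusive — a model at exactly RE = 10 is retained — and
widening the window can only grow the retained set; both properties are
asserted in the test suite.

What the surrogate does *not* claim: its relative energies are
qualitative. Published computed-CCS tables built on density-functional
energetics are not reproducible with it, and the package does not try;
the backend is validated by its own invariants (rigid-motion invariance,
exact charge-sum conservation, fixed-point minimisation, window
monotonicity), not by matching any electronic-structure number.

## Conformer ensembles and clustering

`generate_conformers()` samples every rotatable bond uniformly on a 60°
grid with ±15° jitter (covering the sp$^3$ rotamer wells without grid
artefacts), relieves clashes by a short minimisation, and removes
duplicates below 0.1 Å heavy-atom aligned RMSD. The target count is
1000; systems with few degrees of freedom saturate early (butane
collapses to its three torsional wells; a ring with no rotatable bonds
yields a single-conformer ensemble, logged, not an error). Rotatable
means: single, acyclic, both endpoints bearing further neighbours, with
torsionally degenerate symmetric tops (methyl-like groups) excluded —
so hydroxyl C–OH rotors, exocyclic CH$_2$OH bonds and the glycosidic
$\varphi/\psi$ torsions all count, while ethane counts zero and butane
one.

Ensembles above 50 conformers are clustered; at or below 50 every
conformer is its own center (the pass-through is recorded and visible
in the run manifest). The clustering is a deterministic community
detection (Louvain, internally seeded) on a Gaussian affinity
$w_{ij} = \exp(-d_{ij}^2/2\sigma^2)$ of the pairwise aligned heavy-atom
RMSD matrix. Two numerical choices matter and were frozen after
calibration on synthetic fixtures: the bandwidth $\sigma$ is the lower
quartile of the off-diagonal RMSDs (a median bandwidth is inflated by
inter-family distances and merges well-separated conformer families),
and the resolution parameter is 1, at which a three-bundle calibration
fixture yields exactly three clusters and a two-bundle fixture two.
Each cluster's representative center is its lowest-energy member, so
the global minimum is a center by construction. Clustering happens
before center re-optimisation: generate → cluster → optimize centers →
score.

Hydrogens are excluded from all RMSD computations; their positions are
minimisation noise.

## CCS engines

**Projection approximation.** $\Omega_{PA}$ is the orientation-averaged
projected area of the union of atom-centred disks of radius (Bondi vdW
radius + probe radius, default 1.5 Å for N$_2$). The average is Monte
Carlo over uniform random rotations (Shoemake quaternions) with
stratified dart sampling of the projected box. PA is the pipeline's
default screen: it is three orders of magnitude cheaper than the
trajectory method and monotone under adding atoms, but systematically
underestimates the momentum-transfer cross section of ions because it
carries no long-range attraction.

**Trajectory method.** $\Omega_{TM}$ is the momentum-transfer collision
integral
$\Omega^{(1,1)}(T) = \langle Q(g) \rangle_{MB}$, with
$Q(g) = \int_0^{b_{max}} (1 - \cos\chi)\, 2\pi b\, db$ and the
deflection $\chi$ from classical trajectories of an N$_2$ pseudo-atom in
the solute–gas potential

$$V(\mathbf r) = \sum_i 4\epsilon_i\left[\left(\frac{\sigma_i}{r_i}\right)^{12}
  - \left(\frac{\sigma_i}{r_i}\right)^{6}\right]
  - \frac{\alpha}{2}\,|\mathbf E(\mathbf r)|^2,$$

where $\mathbf E$ is the electric field of the solute partial charges
and $\alpha = 1.710$ Å$^3$ the N$_2$ polarizability. Numerical choices:

* **Velocity integration**: the Maxwell–Boltzmann speed average is a
  Gauss–Legendre quadrature (20 nodes by default) on the transformed
  integrand $x^2 e^{-x}$, $x = \mu g^2/2kT$; "velocity integration
  points" are quadrature nodes, not Monte-Carlo samples, and the count
  is exposed in `tm_settings()`.
* **Impact parameter**: stratified sampling of $b^2$ up to a $b_{max}$
  chosen adaptively per velocity node so the deflection at $b_{max}$
  falls below $10^{-3}$ rad; $\Omega$ is sensitive to this bound, which
  is why it is scanned rather than fixed.
* **Integrator**: velocity Verlet with per-step energy-change control
  (halve on drift, grow when negligible, displacement capped at 1 Å)
  and a per-trajectory cumulative energy-conservation tolerance of
  $10^{-4}$ relative; trajectories violating it are excluded, counted
  and reported. The per-step tolerance is deliberately two orders
  tighter than the cumulative budget: low-energy orbiting collisions
  spend thousands of steps near the repulsive wall, and a looser
  per-step tolerance silently discards exactly the collisions with the
  largest momentum transfer, biasing $\Omega$.
* **Statistics**: the default 10 cycles are independent repeats; the
  reported standard error is their spread over $\sqrt{n}$.

The engine is validated against a closed-form chain: for a single
neutral Lennard-Jones site, $\Omega$ must equal
$\pi\sigma^2\,\Omega^{*(1,1)}(T^*)$ with the tabulated reduced collision
integral (Neufeld correlation), and the tests assert 2% agreement at
$T^* = 1$ (deep in the orbiting regime) and $T^* = 3$. The default
solute–N$_2$ Lennard-Jones table (H 0.0309/2.22, C 0.1072/3.50,
N 0.1183/3.32, O 0.1259/3.25 kcal·mol$^{-1}$/Å) is of the magnitude used
by published nitrogen-buffer trajectory parametrizations; it is the
package's declared compatibility surface, shipped as data and fully
overridable per run. The N$_2$ quadrupole moment and orientation
anisotropy are outside the single-site model; this shifts absolute TM
values for strongly charge-localised ions and is a stated limitation.

**Mason–Schamp.** Conversion between reduced mobility and CCS uses the
low-field relation with the ion–gas reduced mass and the Loschmidt
number density; `ccs_to_mobility()` is its exact inverse.

## Boltzmann weighting and scoring

Populations are $P_i = e^{-RE_i/kT}/\sum_j e^{-RE_j/kT}$ with
$k = 1.987204\times10^{-3}$ kcal·mol$^{-1}$K$^{-1}$ and $T = 298$ K
exactly. The weighted-average CCS restricts to conformers within 3
kcal/mol of the global minimum (inclusive; configurable) and
renormalizes the weights over that subset — the alternative, weighting
over all conformers without renormalization, changes nothing when the
excluded tail is unpopulated and understates the populated states when
it is not, so renormalization is the default.

Assignment statistics: per-system percent error
$|{\rm calc} - {\rm ref}|/{\rm ref}\times100$ against single-field,
stepped-field or averaged references; success at error ≤ 3% (a margin
covering instrument calibration error and inter-laboratory spread);
inter-method discrepancy $\%\Delta = |a-b|/{\rm mean}(a,b)\times100$.
Table reproduction uses half-up rounding (2 d.p. per row, integers for
aggregate means), matching the printed style of the bundled tables.

Two inconsistencies in the bundled compilation are flagged in the CSVs
rather than corrected: the mannohexaose row of the post-sampling table
prints mutually inconsistent stepped (14.52) and averaged (10.32) errors
against the same stepped-only reference, and the xylitol row of the
pre-sampling table prints a calculated CCS (124) inconsistent with all
three of its printed errors (which imply ≈123.4). Aggregate statistics
use the printed error columns verbatim, so the flags do not alter any
reproduced count or mean. More generally, printed per-row errors were
clearly computed from unrounded calculated CCS values: recomputing them
from the printed columns agrees only to within half a printing unit of
the calculated value, which for integer-printed entries is up to ≈0.4
percentage points — the tests therefore use a precision-aware tolerance
rather than a blanket one.

## The synthetic fixtures, and what the tests show

`make_fixture()` builds deterministic toy molecules: a single carbon
(analytic PA CCS), a dumbbell, n-alkanes, chair cyclohexane (zero
rotatable bonds), and a "disaccharide-like" bicyclic — two oxane rings
joined by a C–O–C bridge with one hydroxyl each — that exercises
glycosidic torsions, titratable-site enumeration and the full pipeline
in seconds. These fixtures emulate the *structural motifs* the pipeline
must handle (rings, rotors, bridges, H-bearing heteroatoms), not real
sugar energetics: passing tests demonstrate that the machinery is
correct and reproducible, not that a real glycan's charge site or CCS
would be predicted accurately. That accuracy question belongs to the
energy backend, which is a surrogate by design.

Problem sizes in the default test and acceptance runs are scaled to the
package's own smoke-test conventions: conformer targets of 40–100 on the
fixtures (the 1000-conformer default remains the production setting),
PA with 10$^3$–10$^4$ orientations, TM with 3 cycles on single-site
systems and reduced impact-parameter counts on molecular ones. The
statistics asserted at those sizes (0.5% PA agreement, 2% TM agreement,
2× standard-error rotation invariance) were chosen to be meaningful at
exactly those sizes.

## Reproducibility

One global seed in the pipeline config is fanned out to each stochastic
stage by fixed offsets, every stage records its seed in the manifest,
and all randomness (R and C++ alike) draws from R's RNG — so a rerun
with the same config and seed is byte-identical, including the report
JSON, and any single stage can be replayed in isolation. Wall-clock
times live only in the manifest, never in the report.

## Known limitations

* The surrogate backend's charge-site rankings are qualitative; an
  external quantum-chemistry engine can replace it behind the same
  evaluate/rank contract, and its file-based adapter is the natural
  extension point.
* Single-site N$_2$ (no quadrupole, no anisotropy) and a fixed
  per-element Lennard-Jones table bound the absolute accuracy of TM
  values.
* No multiply charged species, adducts, zwitterions or proton-migration
  dynamics: one static site per model, as enumerated.
* No ring-pucker enumeration or anomerization; conformational sampling
  is torsional only.
* PDB input relies on distance-based bond perception (CONECT records
  are not consumed) and assumes explicit hydrogens; structures without
  them must be protonated upstream, and the package will not add
  hydrogens implicitly.
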