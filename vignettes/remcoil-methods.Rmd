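---
title: "Methods: coiled-coil interface statistics and density-biased adaptive sampling"
author: "remcoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coiled-coil interface statistics and density-biased adaptive sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remcoil)
```

# Scope and model

Remorins are plant plasma-membrane proteins whose C-terminal region — a
coiled-coil homo-oligomerisation domain plus a short membrane anchor — is
believed to pre-structure in the cytosol as an antiparallel dimer before the
protein ever touches the membrane. The evidence for that picture rests on a
small set of quantitative analyses, which this package implements as
reusable, tested components:

1. **Ensemble statistics** for multi-model NMR bundles: optimal rigid-body
   superposition, mean pairwise RMSD over stated residue selections,
   per-residue RMSF of trajectories, and NOE restraint bookkeeping
   (classification by sequence separation, violation statistics).
2. **Interface contact analysis**: per-residue counts of intermolecular
   atomic contacts below a distance cutoff, minimal-distance maps across a
   trajectory within a 3–10 Å band, and distance time series for chosen
   residue pairs.
3. **Cross-homolog motif extraction**: a centre-anchored ("inverse")
   alignment of homologs around the conserved central hydrophobic residue of
   the zipper, cumulative contact/conservation profiles per signed offset,
   and extraction of the symmetric motif pattern (e.g. `HX11HcX11H`).
4. **Secondary structure**: backbone dihedrals, dihedral-region assignment,
   ensemble propensities with optional reweighting, and the chemical shift
   index (CSI) on Hα shifts.
5. **Density-biased adaptive sampling**: PCA projection of the
   conformational landscape, Gaussian kernel density estimation, seed
   selection with probability inversely proportional to density, and the
   unbiasing weights that correct observables computed from the biased seed
   set.

Synthetic generators supply every input class with known ground truth, so
each stage is testable without external structure downloads.

# Ensemble statistics

Superposition uses the Kabsch algorithm (SVD of the 3×3 covariance of the
centred point sets, determinant-corrected to a proper rotation). Pairwise
RMSD fits and evaluates on the *same* atom selection — the standard
self-consistent convention when a deposition reports "pairwise RMSD over
residues X–Y". Selections use a compact chain:ranges syntax
(`"A:173-186,190-194,197"`) with atom sets `backbone` (N, CA, C, O),
`heavy`, `CA` or `all`. The mean and sd are taken over the strict upper
triangle of the model×model matrix with denominator `n_pairs − 1`.

RMSF superposes all frames iteratively onto the (weighted) mean structure
until the mean moves by less than 10⁻⁴ Å, then reports the per-residue root
weighted mean squared deviation. Two numerical properties of this standard
estimator are worth knowing when interpreting tests: the rigid-body fit
absorbs six degrees of freedom, deflating a flat planted amplitude by about
`sqrt(1 − 6/(3·N_atoms))`; and for strongly *graded* amplitude profiles the
fit couples residues, biasing the low-amplitude end up by several percent.
The parameter-recovery tests therefore assert tight (5%) recovery for flat
profiles and ordering plus a looser envelope for graded ones.

Restraint classification follows the CNS convention: intra-residue
(|i−j| = 0), sequential (= 1), medium-range (2–4), long-range (≥ 5). These
four categories partition the total by construction; published tables
occasionally print the medium/long boundaries with non-partitioning labels,
but only a 2–4/≥5 split reproduces category sums equal to the printed
totals. Violation statistics (`max(0, d − upper, lower − d)` per restraint
per model) can be pooled over all restraint-model pairs or over violated
ones only — depositions rarely state which convention they used, so both
are provided and neither is asserted.

# Contact maps and the symmetric zipper motif

Contact counts use a strict `<` at the cutoff (default 3 Å): the boundary
case is measure-zero in real coordinates and the strict reading matches how
"contacts < 3 Å" is conventionally written. Two atom pairings reconcile the
two descriptions in circulation for coiled-coil interface maps: `ca_vs_all`
(Cα of one monomer against all atoms of the other) and
`ca_vs_sidechain_carbon` (Cα against side-chain carbons); `all_heavy` is the
symmetric default for counting. The pairing is stamped in the result so
downstream reports are unambiguous.

The cross-homolog profile is built on signed offsets from the central
conserved hydrophobic residue H~C~ (L137 in StREM1.3), not on a gapped
multiple alignment: coiled-coil cores of this family are indel-poor, the
centre residue is the natural anchor, and in an antiparallel dimer position
+k of one monomer faces −k of the other, which is exactly what the offset
convention encodes. Cumulative counts sum, by default, over both monomers of
each homolog dimer and over all homologs (`monomer_mode` offers `first` and
`max` alternatives, since accumulation conventions differ between studies).

`extract_symmetric_motif()` keeps offsets whose cumulative count reaches a
threshold and whose consensus residue is hydrophobic
({A, C, F, I, L, M, V, W, Y} by default), then writes the spacing pattern:
`H` at each conserved offset, `Hc` at 0, `Xk` for k unspecified residues in
between — offsets {−12, 0, +12} give `HX11HcX11H`. The threshold default of
35 is the convention for *atomic contact counts* accumulated over a
19-homolog family, where per-residue counts reach tens per monomer. For the
sequence-only synthetic route (`hydrophobic_profile_counts()`), the profile
is a conservation indicator with attainable maximum 2 × n_homologs = 38, so
the tests use the scale-appropriate majority threshold of `n_homologs`
(half the maximum), chosen a priori from the profile's construction. The
mirror-symmetry score is the Pearson correlation between the profile and
its reflection about offset 0, clipped to [0, 1].

# Secondary structure

Per-frame assignment uses dihedral regions rather than a DSSP/STRIDE
re-implementation: H for φ ∈ [−100, −30] and ψ ∈ [−80, −5], E for
φ ∈ [−180, −90] with ψ ∈ [90, 180] or ψ ∈ [−180, −150], C otherwise,
with the region bounds configurable for sensitivity checks. This matches
the visualisation-level use of per-frame secondary structure in trajectory
propensity plots; it does not reproduce hydrogen-bond-based bridge
detection, so sparse β-bridge frames may classify as coil. Terminal
residues with undefined φ or ψ are coil. Propensities are (optionally
weighted) frame fractions per residue and always sum to 1.

CSI classification uses the canonical Hα rule: secondary shift
Δδ = δ_obs − δ_rc, state −1 below −0.1 ppm, +1 above +0.1 ppm; a helix
needs ≥ 4 consecutive −1, a strand ≥ 3 consecutive +1. The packaged
random-coil reference (`RANDOM_COIL_HA`) is the standard published Hα
table (DSS-referenced); a user table can be substituted.

`build_backbone_from_dihedrals()` constructs poly-Ala N/CA/C chains from
exact target torsions (standard bond lengths/angles, ω = 180°); it is the
geometric inverse of the dihedral reader and provides noise-free fixtures
whose interior helix propensity is exactly 1.

# Density-biased adaptive sampling

The sampling scheme restarts short simulations from low-density regions of
a projected conformational space. With M~k~ configurations projected to
x_i on the first n principal modes (n = 4 retained of 10 computed, both
configurable):

$$\rho_k(x_i) = \frac{1}{(2\pi\sigma^2)^{n/2} M_k} \sum_{j=1}^{M_k}
  e^{-|x_i - x_j|^2 / 2\sigma^2}$$

$$P(i) = \frac{\rho_k^{-1}(x_i)}{\sum_j \rho_k^{-1}(x_j)}, \qquad
  \alpha_i = \frac{1}{M_k P(i)}, \qquad
  \omega_i = \frac{\alpha_i}{\sum_j \alpha_j}$$

The kernel sum runs over all M~k~ points including the evaluation point
(the self-term is kept, as the formula is written), and is computed in
compiled code so that the replicate studies below stay fast. The Scott
bandwidth is realised as whitening by the sample covariance followed by the
scalar factor M^(−1/(n+4))^ — the behaviour of the reference KDE
implementation the formula's scalar σ abbreviates; densities are then
relative to the whitened space, which changes nothing downstream because
P(i) is invariant to any constant rescaling of ρ. An explicit scalar σ can
be supplied instead. Zero-variance dimensions are an error that advises an
explicit bandwidth.

Seed selection samples without replacement by default (a physical seed is a
distinct structure), renormalising after each draw; replacement is
available. `unbias_weights()` implements the identities exactly:
α_i M_k P(i) = 1 and, when P came from `seed_probabilities()`, ω ∝ ρ — both
are tested to 10⁻¹². `adaptive_round()` composes the stages and supports
iterated rounds on the cumulative point set; the reference protocol's seed
counts are 8 for the first round and 16 thereafter. Running dynamics from
the selected seeds is out of scope — the round returns indices for an
external engine.

## What the two-state study shows

`simulate_two_state_cloud()` draws a 0.9/0.1 two-component Gaussian mixture
(defaults: 2-D, unit component sd, means 4 sd apart) as a minimal stand-in
for a major/minor conformational basin pair. On 10⁴ points with 64 seeds,
inverse-density selection raises the minor-state fraction among seeds from
0.1 to roughly 0.35–0.45 (enrichment of undiscovered states), and the
ω-reweighted minor-state indicator returns an estimate close to the true
0.1, beating the unweighted seed fraction in essentially every replicate.
The tests run 200 replicates and require enrichment at a one-sided binomial
p < 0.01 and a reweighting win rate ≥ 90%.

# Synthetic generators and what they do not emulate

* `build_coiled_coil_dimer()` is a Crick-style parameterisation: helix axes
  wound at radius 4.9 Å about a common superhelical axis (pitch 150 Å,
  left-handed), a minor helix of radius 2.26 Å with 3.62 residues per turn
  and 1.51 Å rise, giving consecutive Cα–Cα distances of 3.8 ± 0.3 Å. The
  topology is a Cα trace plus one CB pseudo side-chain atom 1.53 Å from the
  Cα — enough for every contact/RMSD/RMSF test; full-backbone fixtures for
  dihedral work come from `build_backbone_from_dihedrals()`. Zipper
  residues (Leu, at chosen offsets from the helix centre) point their CB
  into the interface; all others point away from the dimer axis. No
  side-chain rotamers, no knob-into-hole packing optimisation, no
  physically realistic energetics.
* `perturb_ensemble()` adds i.i.d. Gaussian displacements per atom and
  coordinate with per-residue sd = amplitude/√3, so the planted amplitude
  *is* the target RMSF — which makes parameter recovery a direct test. Real
  ensembles have correlated, anisotropic fluctuations; passing these tests
  shows estimator correctness, not realism.
* `generate_motif_family()` plants hydrophobic residues at symmetric
  offsets on otherwise polar sequences and corrupts positions independently
  with a substitution probability. The 19-homolog default matches the size
  of a typical remorin family panel; real homolog families additionally
  contain indels (the stated reason spacings like "40/41" vary), which the
  ungapped offset convention cannot represent — a pre-computed gapped
  alignment can be supplied to `center_alignment()` callers in that case.
* All four generators are deterministic under a fixed seed.

# Problem sizes and numerical choices

The test-suite problem sizes were chosen so each statistical assertion has
comfortable power while the whole suite remains quick to run: 2000-model
ensembles for 5% RMSF recovery, 100 seeded replicates for the ≥95% motif
recovery bound, 200 replicates × 10⁴ points × 64 seeds for the
adaptive-sampling study, brute-force oracles on ≤200-atom fixtures where
exact agreement is asserted. Superposition degeneracy (< 3 points,
collinear sets) is an error; KDE on a single point is an error by contract;
restraint files with inverted bounds fail with the offending line number;
topology mismatches across models name the first divergent atom. Ties in
consensus residues resolve alphabetically; ties in altloc occupancy keep
the first variant encountered.

# Known limitations

* The dihedral-region secondary-structure rule is not STRIDE/DSSP; bridge
  and turn classes are absorbed into coil.
* CSI is Hα-only; no ¹³C/¹⁵N consensus.
* The PDB writer emits a fixed-column subset (no SEQRES/CONECT, single-char
  chain ids, occupancy/B-factor placeholders).
* `pairwise_rmsd` on very large bundles is O(models² × atoms); the intended
  inputs are ten-model NMR bundles and trajectory subsamples.
* Published ensemble statistics can be reproduced only when the deposited
  bundles/restraints are placed under `inst/extdata/paper_data/`; the suite
  otherwise validates the identical code paths on synthetic stand-ins.
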