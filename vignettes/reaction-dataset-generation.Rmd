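---
title: "Generating and curating elementary-reaction datasets with rxnforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and curating elementary-reaction datasets with rxnforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnforge)
```

## The problem

Quantitative reaction data — activation energies and reaction enthalpies for
atom-mapped elementary reactions — are scarce in the large reaction
databases, yet they are exactly what kinetic modelling and machine-learned
reaction prediction need. One productive way to build such data is automated
potential-energy-surface exploration: start from a stable reactant, propose
many search directions as small sets of bond changes, let a string-path
optimizer relax each guess to a minimum-energy path with a transition-state
(TS) candidate, re-optimize the endpoints and the TS with a
quantum-chemistry engine, and then filter hard, because automated TS
searches produce many artifacts.

`rxnforge` implements everything around the engine: the combinatorial
proposal stage, the file interfaces, the verification filters, the
energetics, the curation rules and the dataset layout. The quantum-chemistry
and path-search software itself enters only through an executor contract; a
seeded mock executor synthesizes physically shaped outputs so the whole
pipeline runs, deterministically, at desk scale. Gas-phase molecules over H,
C, N and O with explicit hydrogens are the domain.

## The molecular model

A molecule is an element-labeled connectivity graph (`mol_graph`): atoms
with stable indices, bonds as unordered index pairs with no bond orders.
This deliberately impoverished model is the right identity carrier for
reaction discovery, where "a bond changed" means connectivity changed.

Three derived notions matter:

* **Symmetry classes** (`symmetry_classes()`): iterated neighborhood color
  refinement on element labels. Two hydrogens in one methyl group land in
  one class; the enumerator uses this to drop redundant search directions.
  Refinement is this package's choice of mechanism for "equivalent
  hydrogens"; for H/C/N/O graphs of the sizes in scope it coincides with
  automorphism orbits, which the test suite verifies by brute force on
  small fixtures.
* **Connectivity isomorphism** (`connectivity_isomorphism()`): an
  element/charge-preserving adjacency-preserving bijection, delegated to
  igraph's VF2. Among several valid maps the lexicographically smallest
  image sequence is returned, a tie-break fixed so atom-map reconstruction
  is deterministic.
* **Identity keys** (`identity_key()`): a canonical serialization of the
  (element, charge)-colored graph in BLISS canonical order. Because
  hydrogens are explicit atoms, tautomers (which differ in hydrogen
  placement) receive different keys, while resonance forms with the same
  fixed-H skeleton collapse — bond orders are excluded from the key. This
  is the package's fixed-hydrogen identity convention; a unit test checks
  that the induced equivalence classes agree with fixed-H InChI from Open
  Babel on a fixture set.

## Driving-coordinate enumeration

`enumerate_driving_coordinates()` proposes search directions as sets of
bonds to break plus non-bonded pairs to form, under the constraints:

* at most 2 breaks, at most 2 formations, 2–3 total changes (single
  changes are excluded as likely barrierless),
* the *formal product* — the reactant graph with the changes applied — must
  be valence-feasible: H exactly 1 bond, C 2–4, N 1–3, O 1–2,
* sets differing only by substitution of symmetry-equivalent hydrogens
  collapse to one canonical representative.

Valence screening applies to the formal product only; downstream of path
optimization no screening is applied, because the real path may add changes
beyond the driving coordinates. Equivalence pruning is implemented as
signature dedup: each set's signature replaces every hydrogen index by its
symmetry class, and equal signatures keep the lexicographically smallest
member. Pruning applies to hydrogens only by default; a switch
(`prune_all_equivalent`) extends it to all atoms for users who want fewer
duplicates. Output order is a canonical sort of index tuples, so runs are
reproducible without a seed.

A deliberately naive mirror, `driving_oracle()`, iterates over all subsets
with post-hoc filtering through `apply_changes()` and
`is_valence_feasible()`. The two implementations share only the rule
definitions; their exact agreement over the fixture corpus is a core test.

A consequence of the valence rules worth knowing: very small hydrides can
have *empty* enumerations. Water is the cleanest example — breaking one O–H
while forming H–H leaves the oxygen-bound hydrogen with two bonds, and
breaking both O–H strands the oxygen — so no candidate survives. Methane,
by contrast, has exactly one class: break two C–H, form H–H.

## Engine I/O and the mock executor

The pipeline consumes five quantities from any optimization + frequency
calculation: final energy (hartree), converged geometry, harmonic
frequencies (imaginary printed negative), unit-normalized Cartesian normal
modes, and a convergence flag. These travel in a minimal versioned log
dialect (`make_mock_optfreq_log()` / `parse_optfreq_log()`); string-path
outputs (node energies, TS-node and endpoint geometries) use a parallel
dialect. Parsers never default a missing physical quantity — absence is an
error or an explicit flag. Normal modes are stored as unit Cartesian
vectors without mass weighting (see the verification metric below), and
energies stay in hartree until the energetics layer.

`mock_executor()` supplies planted ground truth: species energies drawn per
(identity, level-of-theory), path barriers drawn per reaction with a small
per-path "TS conformer" jitter (so duplicate discoveries differ slightly in
barrier, which is what the retention and dedup rules act on), seeded
frequencies, and TS imaginary modes constructed so that verification is
decidable by construction (next section). Everything derives from one seed
through stable per-job keys, making campaigns bit-reproducible.

Geometries come from the package's own seeded distance-geometry embedder
(`embed_geometry()`): random starts relaxed by BFGS against covalent-radius
bond-length targets with a repulsive floor between non-bonded pairs, the
lowest-stress "conformer" selected, and the result accepted only if
perception recovers the input connectivity. It makes no claim of
thermochemical realism — it exists to give the pipeline geometries whose
perceived connectivity is exact, which is the property the tests rely on.
Disconnected fragments are embedded independently and offset so they never
perceive as bonded.

## Verification filters

`verify_reaction()` aggregates five booleans; `passed` is their
conjunction, and a failing check is data, never an exception:

1. exactly one imaginary TS frequency,
2. its magnitude at least 100 cm⁻¹ (smaller saddles typically correspond
   to conformational changes),
3. TS-optimization energy within 3 kcal/mol of the highest string-path
   node,
4. the imaginary mode matches the bond changes,
5. both endpoints are true minima (no imaginary frequencies; an atom with
   no modes passes).

Boundary semantics are literal: a drift of exactly 3 kcal/mol passes
("more than" fails), an imaginary magnitude of exactly 100 passes ("less
than" fails). By default any negative frequency counts as imaginary; a
`zero_threshold` window exists for noisy inputs but ships at 0.

The mode-match metric is a design decision of this package: with u the
unit-normalized imaginary mode, each atom pair scores
|(u_i − u_j) · ê_ij|, the relative displacement projected on the TS-frame
bond direction — pure bond-stretch character, invariant under rigid
rotations/translations and mode sign flips. The check passes iff the
minimum score over changing bonds strictly exceeds the maximum over all
other *bonded* pairs (union of reactant and product bonds; non-bonded pairs
are not "bonds" and do not compete). Ties reject, which is the conservative
reading. No mass weighting is applied; the metric is exposed as its own
function (`check_mode_match()`) so an alternative weighting could be swapped
in without touching the filter stack.

The mock TS mode is built by translating the rigid components of the
unchanged-bond graph against each other: unchanged-pair scores vanish
identically, changing pairs bridge components and score positively. The
defect-injection suite (`make_verification_suite()`) plants one flaw per
class — a second imaginary mode, a sub-100 cm⁻¹ magnitude, a >3 kcal/mol
drift, a spectator-localized mode — and the filter stack must recover the
planted labels exactly.

## Energetics

Zero-point energy is ½ Σ ν̃ over strictly positive frequencies times
0.0028591 kcal/mol per cm⁻¹; imaginary modes are excluded, frequencies are
used unscaled. The 0 K energy is e0 = E_elec × 627.5095 + ZPE; activation
energy and reaction enthalpy are e0 differences (TS − reactant;
products − reactant). There are no thermal corrections anywhere — these are
0 K ZPE-corrected electronic energies, which is also why "enthalpy" here is
the 0 K convention. Negative activation energies are retained with a
warning; no rejection rule applies to them. Mixing levels of theory is a
hard error enforced through level tags.

## Pipeline and curation

`run_generation()` chains: reactant preparation (embedding + opt job) →
enumeration → string jobs → product optimization and perception → duplicate
retention → TS optimization → mapped-SMILES extraction → verification →
energetics → final dedup → dataset.

Curation rules:

* **Retention:** duplicates of one reaction (same reactant key + sorted
  product fragment keys) are not all discarded; the `retain_k = 4`
  lowest-provisional-barrier candidates survive to TS optimization, in case
  some optimizations fail. Ties break by discovery order.
* **Final dedup:** one record per reaction key, the lowest activation
  energy; idempotent; stable order.
* **Direction:** a reaction is stored in the direction discovered; forward
  and reverse are distinct records.
* **Indices** are assigned after dedup, zero-based, zero-padded to six
  digits in the layout (`rxn000000/…`), with CSV rows
  (`idx,rsmi,psmi,ea,dh`) in directory order.
* Failed executor jobs mark their candidate failed and the campaign
  continues; failure is bookkeeping, not an exception.

Stage results cache to `state_dir` as `.rds` files, so a killed campaign
resumes from the last completed stage to a bit-identical result.
`refine_pass()` re-runs the engine-facing stages for the first pass's
candidates (pre-dedup, so retention still pays off) at a second level of
theory and re-extracts, re-verifies and re-dedups.

Atom maps are reconstructed, not remembered: the perceived molecule is
matched to the original graph by connectivity isomorphism and map numbers
follow the original indices (+0; the SMILES writer owns the 1-based shift).
The SMILES dialect is fully explicit — every atom a bracket atom with a map
number — written and parsed by the package itself; `mapped_graph()` sorts
atoms by map to recover the shared index space.

## Analyses

Two change definitions coexist deliberately, mirroring how such datasets
are usually summarized: `count_bond_changes()` counts connectivity changes
only, while `bond_change_types()` additionally counts a perceived
bond-order change between a pair that stays bonded (so ethane → ethene +
H₂ has three connectivity changes but four typed changes, the C–C order
change included). Templates (`extract_template()`) serialize the induced
center subgraphs of both sides using only element, charge, aromatic flag
and bond type, with canonical atom ranking inside each fragment so the
string is label- and spectator-invariant. Aromaticity is a minimal
Kekulé-alternation rule (even cycles with alternating single/double
perceived orders), which covers the rings reachable in this chemical space
without a full aromaticity model.

`kde2d_reactions()` is a product-Gaussian KDE over (ΔH, Ea) with Scott's
factor per dimension (sd · n^(−1/6)) unless a bandwidth is given; a single
point at bandwidth h has density 1/(2πh²) at its center, which the tests
assert in closed form. Grouped activation-energy densities are renormalized
to unit area on their grids (equal-area scaling); single-reaction groups
use a fixed 1 kcal/mol kernel width since data-driven bandwidths need two
points.

## Numerical and scale choices

* Perception: bond iff distance ≤ 1.2 × (r_cov sums), radii H 0.31 /
  C 0.76 / N 0.71 / O 0.66 Å; below 0.4 Å is a geometry error. The
  tolerance is configurable and recorded in the campaign config.
* Bond orders: branch-and-bound maximization of valence saturation over
  the unsaturated subgraph; leftover unsaturation is radical character;
  among maximal assignments the lexicographically smallest is returned.
  Adjacent "radical" atoms therefore always pair into a higher bond order,
  which is the repair for the classic perception artifact.
* Embedding: bonded-pair targets at covalent-radius sums, non-bonded floor
  at 1.6 × sums (comfortably above the 1.2 perception cutoff), BFGS with
  analytic gradients, up to 12 seeded starts.
* Test and validation problem sizes: the enumeration oracle corpus uses
  ~25 molecules of ≤4 heavy atoms; relabeling invariance uses 100
  permutations per molecule; perception round-trips use ~45 molecules up
  to 7 heavy atoms with 1000 relabelings each; campaigns in tests use
  3–5 reactants. These sizes were chosen so the full validation protocol
  runs in minutes on one core while still exercising rings, multiple
  heteroatoms, disconnected products and duplicate-rich enumerations.

## What the mock data do and do not show

The synthetic executor emulates the *shape* of engine output — energies
with consistent species identities, barriers above endpoints, one-imaginary
TS spectra, modes aligned with planted bond changes, string paths with a
highest node — under the same file contracts as a real engine adapter. It
does not emulate electronic structure: energies are draws, not physics, so
absolute Ea/ΔH values in mock campaigns mean nothing chemically. What
passing tests demonstrate is that the combinatorics, identity logic,
filters, curation rules, file formats and determinism of the pipeline are
correct — exactly the properties that transfer unchanged when a real
quantum-chemistry executor is plugged in. They say nothing about DFT
accuracy, conformer coverage on real surfaces, or how often real string
searches fail, all of which live on the engine side of the contract.

## Known limitations

* Stereochemistry is absent throughout; SMILES are constitutional.
* Aromaticity is the minimal alternation rule described above.
* The WL symmetry refinement could in principle merge non-equivalent atoms
  on pathological regular graphs; no such molecule exists in the H/C/N/O
  space at these sizes, and the brute-force orbit tests guard the fixtures.
* The signature-based equivalent-hydrogen pruning collapses two sets whose
  hydrogens share classes even when no single automorphism relates the
  sets; this matches the stated mechanism and is mirrored by the oracle,
  but it is a stronger collapse than orbit equality in rare geminal/vicinal
  situations.
* Charged species are carried through the data model but the generators
  only produce neutral molecules.
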