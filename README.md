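# rxnforge

Automated generation and curation of gas-phase elementary-reaction datasets
over H, C, N and O — the combinatorial, verification and bookkeeping layers
of a transition-state discovery campaign, with the quantum-chemistry engine
and string-path optimizer behind a pluggable executor contract so that the
entire pipeline runs and is testable without any external software.

## Who this is for

Researchers building quantitative reaction datasets (activation energies
E<sub>a</sub> and reaction enthalpies ΔH for atom-mapped reactions) by
automated potential-energy-surface exploration, and anyone who needs the
pieces individually: exhaustive driving-coordinate enumeration, normal-mode
TS verification, 3D-geometry-to-reaction-SMILES perception, ZPE-corrected
energetics, or duplicate-aware curation.

## The method in brief

Starting from a reactant connectivity graph (hydrogens explicit, bonds =
connectivity only), the package enumerates every driving-coordinate set —
bonds to break plus non-bonded pairs to form — subject to: ≤ 2 breaks, ≤ 2
formations, 2–3 total changes, a valence-feasible formal product
(H exactly 1 bond, C 2–4, N 1–3, O 1–2), and collapse of sets that differ
only by symmetry-equivalent hydrogens. Each set seeds one string-path
search; endpoints are re-optimized, perceived back to molecules
(covalent-radius connectivity, saturation-maximizing bond orders,
fixed-hydrogen canonical identity keys), and up to 4 duplicates per
reaction are retained for TS optimization. A proposed reaction survives
only if

1. the TS has exactly one imaginary frequency,
2. of magnitude ≥ 100 cm⁻¹,
3. the TS optimization drifted ≤ 3 kcal/mol from the highest string node,
4. the imaginary-mode displacement score |(u<sub>i</sub> − u<sub>j</sub>) ·
   ê<sub>ij</sub>| is strictly larger on every changing bond than on any
   unchanged bond, and
5. both endpoints are true minima.

Energetics are 0 K ZPE-corrected electronic energies:
E₀ = E<sub>elec</sub> · 627.5095 + ½ Σ ν̃ · 0.0028591 (kcal/mol, positive
modes only), E<sub>a</sub> = E₀(TS) − E₀(reactant), ΔH = Σ E₀(products) −
E₀(reactant). Duplicates resolve to the lowest barrier; records are written
as a CSV (`idx,rsmi,psmi,ea,dh`) plus one `rxn%06d/` directory per reaction
holding `r/p/ts%06d.log`.

## Worked example

```r
library(rxnforge)

cfg <- generation_config(seed = 7)                 # B97-D3/def2-mSVP tags
res <- run_generation(c("C", "CC", "CO"), cfg, mock_executor(7))
print(res)
#> <generation_result> B97-D3/def2-mSVP
#>  n_reactants n_reactants_ok n_driving_sets n_paths_ok n_products_ok n_retained
#>            3              3              9          9             9          9
#>  n_ts_ok n_extracted n_verified n_final
#>        9           9          9       7
```

Three reactants yield nine driving-coordinate sets, all nine paths and TS
optimizations succeed under the mock engine, and final dedup keeps seven
unique reactions. The curated table is tidy and atom-mapped:

```r
res$dataset[1:2, c("idx", "rsmi", "psmi", "ea", "dh")]
#>     idx rsmi                              psmi                            ea    dh
#> 1     0 [C:1]([H:2])([H:3])([H:4])[H:5]   [C:1]([H:4])[H:5].[H:2][H:3]  74.3 -13.4
#> 2     1 [C:1]([C:2]([H:6])([H:7])[H:8]).. [C:1]([H:4])[H:5].[C:2]([H:.. 17.3 -12.2
```

Row 0 is methane → methylene + H₂ (break two C–H, form H–H): under the
planted mock energies its barrier is 74.3 kcal/mol and it is exothermic by
13.4 — numbers that exercise the machinery, not chemistry. Downstream
analyses chain directly:

```r
template_ranking(res$dataset)
#> # A tibble: 5 × 2
#>   template                           n
#> 1 [C]([H])[H]>>[C].[H][H]            3
#> 2 [C]([C][H])[H]>>[C]=[C].[H][H]     1
#> 3 [C]([H])[O]>>[C].[H][O]            1
```

The top template — an H₂ elimination center — covers three of the seven
reactions; `autoplot(kde2d_reactions(res$dataset))` renders the (ΔH, Eₐ)
density. `write_dataset(res$dataset, "out/")` materializes the published
layout, byte-identically across runs with the same seed.

A command-line wrapper `exec/rxnforge` exposes
`enumerate | generate | verify | analyze` over the same functions, e.g.
`rxnforge generate --smiles-file inst/extdata/example_reactants.smi
--out-dir out --seed 7`.

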