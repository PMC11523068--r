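# tabstrings

Torsion angular bin strings (TABS) and conformer-ensemble size bounds
(nTABS) for small molecules, in base R.

## The problem

Most molecules at room temperature are ensembles of conformers, and most
computational workflows need to reduce such an ensemble to a set of
meaningful representatives. The usual tool — pairwise heavy-atom RMSD with
a hand-picked threshold — is size-dependent and expensive (quadratic in
the number of conformers). `tabstrings` implements a discrete alternative:

* **TABS** — each conformer is reduced to a vector of binned torsion
  states, one digit per torsion bond. Bins come from the minima/maxima of
  empirical torsion potentials expressed as truncated Fourier series

  `V(φ) = Σᵢ₌₁⁶ Kᵢ (1 + sᵢ cos iφ),  sᵢ ∈ {−1, +1}`,

  matched to bonds via a SMARTS-keyed profile library; uncovered bonds get
  a default 6-state binning cut at 30°, 90°, 150°, 210°, 270°, 330°.
  Labels are canonicalized under the digit permutations induced by
  chirality-aware graph automorphisms ("the arrangement with the lowest
  integer value"). Labelling an ensemble is linear in the number of
  conformers.

* **nTABS** — an upper bound on the number of distinct TABS a molecule
  can realize, i.e. on the size of its conformational space. Naively the
  product of all torsion multiplicities (`nTABS_naive = Πₜ mₜ`), it is
  corrected in two ways: every aliphatic ring is collapsed to a single
  position carrying a literature state count (sizes 3–11 from cycloalkane
  conformer counts, e.g. 15 for a six-ring; sizes 12–16 from corrected
  macrocycle bounds, e.g. 16 549 for a 12-ring), and topological symmetry
  is divided out by counting orbits of the state space under the induced
  position-permutation group with Burnside's lemma:

  `nTABS = (1/|G|) Σ_g Π_{cycles c of g} m_c`.

  Flexibility classes: low (nTABS < 500), medium (500 ≤ nTABS < 10 000),
  high (nTABS ≥ 10 000).

The package also ships the evaluation protocol that compares TABS
grouping against RMSD grouping — confusion matrices over conformer pairs
with RMSD as ground truth, PPV/NPV scanned over thresholds 0.2–2.4 Å —
and the comparison descriptors rotatable-bond count and Kier ϕ.

There is no cheminformatics toolkit in this R stack, so the package
carries its own minimal heavy-atom molecule model: a restricted SMILES
parser, an SDF V2000 reader/writer, SSSR ring perception, a backtracking
graph-automorphism search (cross-checked against igraph in the tests) and
a restricted torsion-SMARTS matcher. These cover the organic subset well
enough for desk-scale work; they are not a general-purpose toolkit.

## Worked example

```r
library(tabstrings)
lib <- builtin_profile_library()

# chair + boat cyclohexane, built from idealized ring torsion patterns
cb <- build_fixture("cyclohexane_chair_boat")
group_ensemble(cb, lib)
#> <tabs_grouping: 2 conformer(s) in 2 group(s); nTABS 15; coverage 0.133>
#>   1-1-3-1-3-3: 2
#>   1-3-3-1-3-1: 1
```

The chair shows the alternating two-state ring pattern (canonical label
`1-3-3-1-3-1`), the boat a different pattern — the two are distinguished
by TABS even though their heavy-atom RMSD (`best_rmsd(cb, 1, 2)` ≈ 0.41 Å
for this idealized build) is below the conventional 0.5 Å threshold that
would merge them.

```r
ntabs(parse_smiles("C1CCCCC1"), lib)
#> <ntabs: 15 (naive 15), 1 position(s), group order 1, low flexibility>

ntabs(parse_smiles("CCCCC"), lib)      # pentane: 3 x 3 states, end-swap symmetry
#> <ntabs: 6 (naive 9), 2 position(s), group order 2, low flexibility>

kier_phi(parse_smiles("CCCCCC"))$phi   # n-hexane
#> [1] 5
```

The pentane case shows the symmetry reduction at work: two equivalent
3-state torsions give 9 raw labels but only 6 orbits (m(m+1)/2) under the
end-to-end swap.

A thin command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "tabs", package = "tabstrings"))') \
    ntabs --in mols.smi --out ntabs.csv
```

with subcommands `label`, `group`, `ntabs`, `evaluate` and `fixtures`.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package: the nTABS of cyclohexane and of cyclododecane (ring-table
wiring), the best-fit heavy-atom RMSD between the idealized chair and
boat fixtures, and the canonical label of a two-equivalent-torsion
conformer measured in states (2,1). Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

Torsion profiles shipped here are a small curated archetype set (alkane,
amide-like, biaryl, in-ring alkane); users with a full crystallographic
torsion hierarchy can supply it as a JSON library via
`load_profile_library()`. Local symmetry (symmetry-equivalent substituents
around one bond) is deliberately not folded into the bins; see the
methods vignette (`vignettes/tabstrings-methods.Rmd`) for the reasoning
and for all numerical and design choices.
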