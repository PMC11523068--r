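---
title: "Torsion angular bin strings: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsion angular bin strings: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabstrings)
```

## The model

A conformer's torsional state is summarized as a vector of discrete
digits, one per torsion bond. The machinery has four layers.

**Torsion potentials.** Each torsion archetype is a truncated Fourier
series

$$V(\varphi) = \sum_{i=1}^{6} K_i\,(1 + s_i \cos i\varphi), \qquad
s_i \in \{-1, +1\},$$

the functional form used by classical force fields and by
crystallographic torsion-preference fits. The highest harmonic is 6, so
no profile can have more than six minima. Minima of $V$ are the
rotameric states (bin centers); maxima are the bin boundaries; the number
of minima over one rotation is the *multiplicity* $m$. Force constants
are treated as dimensionless shape parameters: only the positions of the
extrema matter for binning, never the barrier heights, so the shipped
library's $K$ values (order 1) are placeholders for curvature, not
calibrated energies.

**Torsion set.** The torsion bonds of a molecule are (a) acyclic
rotatable bonds — single, non-ring, non-aromatic bonds between two
non-terminal heavy atoms, excluding amide C–N in the strict dialect and
bonds at triple-bond (sp) centers — and (b) every non-aromatic ring bond
in rings of size ≥ 3, macrocycles included. Ring torsions keep their
individual digits in the label; ring correlation enters only in the
counting step. Digit order is the sorted bond order `(min atom index,
max atom index)`, frozen per molecule; no neighbor-based ordering is
enforced.

**Symmetry.** Graph automorphisms (self-matches preserving element,
charge, aromaticity, bond order and specified tetrahedral centers) induce
permutations of digit positions whenever they map every torsion bond onto
a torsion bond. A label's canonical form is the lexicographically
smallest image under this induced group — the arrangement with the lowest
integer value. Canonicalization permutes *positions only*; it never
remaps digit values.

**Counting.** `nTABS_naive` is the product of multiplicities over
positions. For `nTABS`, each non-aromatic ring is collapsed to one
position carrying a fixed ring-size state count (sizes 3–11 from
cycloalkane conformer counts; 12–16 from corrected macrocycle bounds),
and the number of achievable labels is the number of orbits of the
product space under the induced group, evaluated with Burnside's lemma

$$n_\mathrm{TABS} = \frac{1}{|G|} \sum_{g \in G}\;
\prod_{\text{cycles } c \text{ of } g} m_c ,$$

which requires — and the code asserts — that multiplicity is constant on
every cycle. For state spaces up to a bound (default 20 000; the
oracle-grade enumerator handles $10^6$) an explicit vectorized orbit
enumeration cross-checks the count and supplies the orbit sizes $p_i$,
which satisfy $\sum_i p_i = n_\mathrm{TABS,naive}$ with one representative
$r_i = 1$ per orbit.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| extremum grid step | 0.1 | degrees | resolves all shapes up to multiplicity 6; roots then bisected to 1e-6° |
| default fallback bins | 30–330 every 60 | degrees | the fixed six-state binning for bonds the library does not cover |
| threshold grid | 0.2–2.4 step 0.1 | Å | the scanned RMSD interval; crossing located by linear interpolation |
| `strict` | `TRUE` | — | strict rotatable-bond dialect (amide C–N excluded); `FALSE` re-admits amides |
| `enumerate_below` | 20 000 | states | above this, Burnside only (no orbit-size bookkeeping) |
| automorphism cap | 10 000 | matches | desk-scale guard against pathological graphs |

## Numerical choices

* **Boundary ownership.** Bins are half-open: an angle exactly on a
  boundary belongs to the bin whose lower edge it is; the wraparound bin
  owns its lower edge (330° in the default binning) and every angle below
  the first boundary. This makes the circle an exact partition — every
  angle maps to exactly one state.
* **Angle convention.** Dihedrals are reported in [0°, 360°); the signed
  (−180°, 180°] measurement is shifted by +360° when negative. All bin
  arithmetic lives in this convention.
* **Extremum finding.** The analytic derivative is scanned on a dense
  grid and each sign change refined by bisection; derivative plateaus
  wider than the grid step warn and use the plateau midpoint. A flat
  (all-zero) profile is rejected as unbinnable rather than silently
  defaulted — the caller decides to substitute `default_bins()`.
* **Integer arithmetic.** Counts are R doubles, exact below $2^{53}$;
  beyond that the code warns that the product is approximate. No
  arbitrary-precision library is available in the target stack; all
  desk-scale quantities are far below the limit.

## Design choices where the design was open

* **Profile precedence.** The first library record whose pattern matches
  a bond wins, so library files are ordered most-specific-first. The
  exact pattern hierarchy of any particular conformer generator is not
  reproduced; the shipped library is a four-archetype stand-in (alkane,
  amide-like, biaryl, in-ring alkane) and users supply fuller libraries
  as JSON.
* **Fallback quadruple.** For an unmatched bond $(j,k)$ the outer atoms
  are the highest-canonical-rank heavy neighbors (Morgan-style refinement
  ranks, ties broken by atom index); ring bonds prefer neighbors inside
  the same smallest ring so ring digits trace the ring path. This makes
  labelling deterministic and renumbering-stable whenever the rank choice
  is unique; when several neighbors are genuinely symmetry-equivalent the
  tie-break can select geometrically different (but symmetry-related)
  reference atoms — the known local-symmetry caveat below.
* **Position-only symmetry action.** An automorphism can map a quadruple
  $(i,j,k,l)$ onto $(l',k',j',i')$, which geometrically sends
  $\varphi \to -\varphi$. Folding that into bin equivalence would merge
  mirror-image states; this implementation deliberately permutes
  positions only. Consequence: for some symmetric molecules two
  geometrically equivalent conformers can receive different canonical
  labels when their digits are mirror states. This keeps nTABS an upper
  bound and the canonical form well-defined.
* **Local symmetry is not modelled.** Symmetry-equivalent substituents
  around one bond (e.g. the two ortho ring atoms flanking an aryl–alkyl
  bond) are *not* used to merge bins: whether a local mirror reduces the
  state count depends on the global symmetry of the whole molecule, so a
  per-bond reduction is ill-defined. The cost is overestimation — an
  acceptable property for an upper bound.
* **Rings × symmetry.** Automorphisms act on the collapsed space:
  ring positions map to ring positions via their atom sets, torsion
  positions via their bonds. Two rings are interchangeable only if an
  automorphism maps their atom sets onto each other. Ring-internal
  symmetry does not further reduce the tabulated ring contribution — the
  table value is applied unreduced.
* **Fused and bridged systems.** Each smallest-set ring contributes its
  own table factor; shared bonds are assigned to the first (smallest)
  containing ring. Fused systems are therefore over-counted, consistent
  with the upper-bound reading. Rings above size 16 are excluded from the
  count entirely, with a prominent warning, rather than extrapolating the
  macrocycle table.
* **Unspecified stereocenters** match both ways in the automorphism
  search, so leaving stereochemistry unspecified never breaks a symmetry.

## What the fixtures emulate — and what they do not

All test inputs are built programmatically: chains are embedded from
idealized internal coordinates (C–C 1.54 Å, 111° angles) and driven to
exact torsion targets; rings are closed by lightly relaxing an idealized
torsion pattern (chair: ±55° alternating; boat: 0°, +55°, −55°, 0°,
+55°, −55°) against bond/angle/torsion restraints. This isolates the
labelling logic from any force field, and every fixture rebuilds
bit-for-bit.

What a green test therefore establishes is correctness of binning,
symmetry handling and counting on idealized geometry — not robustness to
force-field noise, condensed-phase torsion shifts, or the breadth of a
full crystallographic profile hierarchy. One concrete consequence shows
up in the acceptance suite: the idealized chair/boat pair sits at
0.40–0.41 Å best-fit heavy-atom RMSD, whereas the reference value the
acceptance check encodes for this conformer pair is 0.33 Å. The
discrepancy was verified against an independent superposition
implementation on identical coordinates (same 0.398 Å to four decimals),
so it is a property of the idealized construction itself: matching
0.33 Å would require boat torsion amplitudes near 45°, which the stated
construction does not use. The check is left failing rather than tuning
the geometry toward the number; the TABS half of that example (chair and
boat receive different canonical labels) holds.

The evaluation protocol's random "ensembles" (labels plus symmetric
distance matrices) exercise the monotonicity and additivity guarantees of
the confusion-matrix scan, not the geometry pipeline.

## Known limitations

* The SMILES parser covers the organic subset, aromatic lowercase,
  brackets with charge and tetrahedral tags, branches and ring closures —
  not the full grammar (no disconnected species, isotopes ignored,
  directional double-bond stereo ignored).
* Tetrahedral parity checks compare neighbor-permutation parity on the
  heavy-atom graph; because implicit hydrogens are dropped from the
  neighbor lists, parity handling for centers with an implicit-H
  reference is approximate. Specified stereo can only remove
  automorphisms, never add them, so nTABS remains an upper bound.
* The torsion-SMARTS dialect is restricted to linear four-atom patterns
  with element/aromaticity/connectivity primitives and ring/non-ring bond
  specs — sufficient for torsion libraries, not a general SMARTS engine.
* Aromaticity is taken from the input (lowercase SMILES, bond type 4 in
  SDF); there is no perception pass.
* RMSD-based parts assume desk-scale conformer counts: the pairwise
  matrix is quadratic and the automorphism-aware superposition multiplies
  by the group order.
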