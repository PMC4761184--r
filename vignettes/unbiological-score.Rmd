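---
title: "The UnBiological score: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The UnBiological score: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

unbio quantifies how far a small molecule lies outside the chemical space
that core metabolism occupies, and provides the statistical machinery to
relate that distance to non-specific, low-potency toxicity. This vignette
is the package's account of its model, its conventions, and the design
choices that were genuinely open.

## The molecular graph model

All matching operates on hydrogen-suppressed 2-D molecular graphs: atoms
carry an element label, bonds an order in {1, 2, 3}, and every valence
not used by an explicit bond is assumed filled with hydrogen. Allowed
valences are C 4, Si 4, N 3, O 2, P {3, 5}, S {2, 4, 6}, halogens and
alkali metals 1. The model is deliberately topological:

* **No charges, stereochemistry or isotopes.** Charged input is
  normalized to the neutral graph (a carboxylate parses to the acid);
  stereo marks are read and discarded. Molecules whose neutral form
  violates valence (e.g. nitro groups written with N^+^) are rejected
  rather than approximated.
* **One kekulized canonical form per aromatic system.** Lower-case
  aromatic SMILES is resolved to alternating single/double bonds by a
  perfect-matching search; matching then compares drawn 2-D structure.
  There is no aromaticity perception layer, so a benzene written
  kekulized and one written aromatic are identical, but matching a
  "half-rotated" kekulé pattern against the other rotation will fail.
  This is accepted: the score compares structures as a chemist would
  draw them, and the reference and test sets pass through the same
  canonicalizer.
* **Fragments are molecules with open valences.** A fragment uses the
  same representation; matching never constrains hydrogens, so the
  distinction needs no separate type.

A *substructure* (monomorphism) match maps all atoms and bonds of the
pattern onto the target injectively, preserving element and bond order;
extra bonds among matched target atoms are allowed, so a three-carbon
chain matches cyclopropane. Embedding *counts* are per distinct matched
atom-plus-bond subset: automorphic re-mappings onto the same atoms count
once, which is the convention that makes a descriptor "the number of
occurrences of a fragment in a molecule" rather than a symmetry-inflated
quantity.

Canonical identity is delegated to a BLISS canonical labeling (igraph)
of a vertex-coloured encoding in which every bond is subdivided through
an auxiliary vertex coloured by bond order. Two graphs are equal iff
their canonical SMILES agree; the test suite cross-checks the induced
equality classes against OpenBabel's canonical SMILES.

The maximum common subgraph is required to be **connected**, found by
enumerating connected subgraphs of the smaller argument in decreasing
size and testing embedding into the larger; ties at the maximal size are
broken by canonical-SMILES order so the result is reproducible. The
approach is exponential in the worst case but exact, and molecules in
this package's scope (fragment pools over small structures, reference
sets of modest size) keep it fast; enumeration refuses structures beyond
30 bonds.

## The Ub score

`Ub_N` of a test molecule against a metabolite reference set is the
heavy-atom count of the largest connected region of the molecule that
contains no connected N-atom fragment occurring anywhere in the
reference. A *region* is a connected subgraph — atoms plus a chosen
subset of bonds, exactly the fragment-matching semantics — so a region
may omit a ring-closing bond that the molecule has.

Two conventions needed fixing:

* **Regions smaller than N score 0, not N−1.** A region with no N-atom
  subgraph satisfies the defining condition vacuously; admitting such
  regions would give every molecule a floor of N−1 and metabolites
  themselves would not score 0. unbio requires |region| ≥ N, so
  metabolites score 0 and molecules smaller than N score 0.
* **The reference fragment set is *all* N-atom fragments of the
  metabolites**, computed by direct enumeration — not the ≥2-occurrence
  fragment pool. The pool's occurrence cut-off is a convenience for
  descriptor generation, and a pool-based variant of the score can be
  emulated with `generate_fragment_pool()` + `describe_molecules()`,
  but the defining quantity needs every metabolite fragment.

The production scorer decides "is this N-subgraph biological?" by
testing embedding into each metabolite directly (equivalent to
membership in the enumerated fragment set, but cheaper), then finds the
largest clean region by branch-and-bound over bond removals: whenever
the current subgraph still contains a biological N-subgraph, the search
branches on deleting each of that subgraph's bonds. `ub_score_oracle()`
answers the same question by brute force — every connected subgraph of
the molecule enumerated and checked against the canonical fragment set —
and the two are held equal on hundreds of randomized study conditions in
the tests. Mixtures must be split upstream (`parse_structure(component =
"largest")` scores the largest component, matching the screening
filter's salt handling); metabolites smaller than N contribute no
fragments but remain legal reference members.

The study-scale choice of N = 5 and 6 reflects where observed and
expected fragment coverage separate most for a ~611-molecule metabolome;
the toy reference sets used throughout the tests (tens of molecules of
up to 6 atoms) pair naturally with N = 3, which keeps every quantity in
the same regime at desk scale.

## Enumerating chemical space

`enumerate_space()` generates every connected valence-legal molecule
over a configurable element alphabet: graphs are grown one atom at a
time (each new atom bonded to an existing one), each size level is
closed under single-bond additions between existing atoms, and
everything is de-duplicated by canonical SMILES. Every connected legal
graph has a spanning tree reachable by leaf removal and regains its
remaining bonds one at a time without ever violating a valence maximum,
so the enumeration is exhaustive for the configured rules — including
quaternary carbon centres, which string-growing generators tend to
under-represent. Filters (ring policy, element states, banned patterns)
are applied to the final list only, so they cannot prune intermediates
that larger legal molecules grow through.

Choices a user can override:

* **Element states.** Phosphorus defaults to P(V) only; sulfur to S(II)
  plus a sulfate/sulfone-like S(VI) that must be fully substituted with
  at least two double-bonded oxygens. These mirror the oxidation states
  metabolism actually uses.
* **Ring policy.** Up to two fused-ring systems (connected components of
  cycle bonds); `min_ring_size` defaults to 3 — biology avoids very
  small rings, but they are legal chemistry and are left in the space by
  default.
* **Banned patterns.** The shipped instability list (`O-O-O` chains,
  N-halogen bonds; see `inst/extdata/banned_patterns.smi`) is an
  explicit, documented extension point, not a complete stability theory;
  tests pin their own lists.
* **Safety cap.** Full enumeration refuses beyond 8 heavy atoms;
  `sample_space()` serves larger specs through a random-growth rejection
  sampler that is documented as approximately, not exactly, uniform.
  For enumerable specs sampling is exactly uniform over the space.

## Coverage statistics

For a fragment f with probability p~f~ of occurring in one random
molecule from a space, the chance that a collection of M independent
draws misses f is (1 − p~f~)^M^; the expected unfound fraction is the
mean over fragments. Match probabilities are estimated by seeded Monte
Carlo over `sample_space()` draws with binomial standard errors (exact
enumeration is available for small spaces). An analytic match-frequency
algorithm would be preferable; the Monte-Carlo estimator is the
documented substitute and its error is propagated to the expected
fraction by the delta method. A metabolome drawn uniformly from its own
space reproduces the null within Monte-Carlo error; a structured subset
(e.g. saturated molecules only) leaves substantially more of fragment
space unoccupied — that contrast is the qualitative signature the
coverage module exists to measure.

## The statistical layer

* **Rank correlation** is Spearman with average ranks for ties; the
  two-sided p-value uses the large-sample t approximation
  t = ρ√((n−2)/(1−ρ²)). Constant input is flagged as undefined rather
  than erroring, so batch drivers can report it.
* **Significance tiers** default to \* < 0.05, \*\* < 0.01 and
  \*\*\* < 0.05/(35×2) ≈ 7.14×10⁻⁴ — the Bonferroni level for a family
  of 35 endpoints × 2 Ub measures. `family_wise_prob()` gives the
  family-level false-positive chance 1 − (1 − α\*)^n^; at n = 70 it is
  0.0488, i.e. about one in twenty repeat studies would show a single
  \*\*\*-level correlation by chance.
* **Potency bands** are half-open [lo, hi) intervals in log10 molar with
  open-ended extremes, defaulting to round log-unit edges. The per-band
  confidence interval is Fisher-z with half-width 1.96/√(n−3) — the CI
  method is not dictated by the problem, and Fisher-z is the common
  default; bands with n < 4 report no statistics.
* **EC50** from raw inhibition curves is log-linear interpolation
  between the two tested concentrations bracketing the first upward
  crossing of 50%; an exact 50% at a tested concentration returns it.
  Four-parameter logistic fitting would use more of the curve but
  requires convergence policy; the interpolation rule is transparent,
  and it is isolated behind one function if a user wants to swap it.
* **Units.** Half-effect concentrations are log10 molar; mammalian
  whole-organism endpoints are mol/kg body mass. The unit is a property
  of the endpoint and is never mixed within one correlation.
* The screening filter (`yeast_filter()`) applies, in order:
  organometallic exclusion (any carbon-metal bond), mixture/salt
  exclusion unless every counter-ion is a single halide or alkali-metal
  atom (the largest organic component is then scored), the
  "below 50% at the top concentration" and "above 50% at the bottom
  concentration" exclusions evaluated on the strain-averaged curve, and
  a cross-strain spread exclusion (max−min)/mean > 1 over per-strain
  EC50s. Exclusions are rows in the output with the rule named, never
  errors.

## The synthetic study generator

The generator exists so that every stage — scoring, correlation, band
analysis — can be exercised against data whose ground truth is known.

* **Metabolome.** `n_metabolites = 25` molecules drawn without
  replacement from the enumerated space of acyclic C/N/O molecules of 2
  to 6 heavy atoms with single and double bonds, with peroxide, N-N and
  the default unstable motifs excluded. This is a "biological-looking"
  corner of chemical space at toy scale: halogen-free, modestly
  unsaturated, small. Rings are left out of the toy metabolome space to
  keep the enumeration small; ring-bearing *test* compounds are still
  exercised through the cyclopropane decoration.
* **Compounds.** 400 compounds: three quarters are metabolome scaffolds
  carrying 0–3 grafted decorations (Cl, F, Br, N-N, cyclopropyl,
  peroxide), one quarter (`p_exotic = 0.25`) are assembled from
  decoration fragments alone. The exotic fraction matters: it produces
  molecules whose unbiological region is their whole extent (normalized
  Ub near 1), the analogue of a wholly non-biological test chemical,
  and without it the library's Ub spread collapses into a narrow band.
* **Toxicity.** A two-population mixture: with probability q = 0.15 a
  compound is a specific-mechanism toxin, log10 EC50 ~ N(−6, 0.5²)
  independent of Ub; otherwise log10 EC50 ~ N(−2 + β·Ub/size, 0.5²)
  with β = −0.8. This is the minimal mechanism that reproduces a
  potency-threshold phenomenon: among potent toxins the specific
  population dominates and Ub carries little signal, while in the
  low-potency band the planted negative slope shows through. Normalizing
  Ub by heavy-atom count decouples the planted effect from molecular
  size.
* **Problem sizes.** Recovery experiments use 400 compounds per seed and
  20 replicate seeds; the toy metabolome space (≈4,500 molecules) is
  enumerated once per session and cached. These sizes give stable
  recovery statistics while keeping a full run in minutes on one core.

All randomness flows from one integer seed per study; runs are
bit-for-bit reproducible.

## What the synthetic tests do and do not show

Passing recovery tests show that the pipeline — scoring, joining,
correlating, banding — faithfully extracts a planted effect of realistic
size from data with realistic noise and a contaminating potent
subpopulation. They do not show that real toxicity data contains such an
effect: the toy metabolome is two orders of magnitude smaller than a
real core-metabolism set, its chemistry is far narrower (no rings, no
sulfur or phosphorus, no aromatic systems), and real endpoint data
carries measurement heterogeneity, chemical-series bias and reporting
censoring that the generator deliberately omits. The package ships
loaders for real structure and endpoint tables (SDF/SMILES + CSV) so the
same pipeline runs unchanged on downloaded data.

## Known limitations

* Exact matching only: no tautomer awareness, no charge states, no
  3-D geometry or conformers.
* MCS and the Ub oracle are exponential-time algorithms with explicit
  size guards (30 bonds; 14 atoms for the oracle). The production Ub
  scorer's branch-and-bound handles typical drug-sized molecules but
  inherits the worst case.
* The instability rule list is a small, explicit starting set; spaces
  enumerated with it still contain chemically exotic members (cumulated
  dienes, for instance), which is acceptable for a space meant to
  over-cover plausible chemistry.
* `sample_space()` beyond the enumeration cap is approximately uniform
  only; coverage statistics at that scale inherit the approximation.
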