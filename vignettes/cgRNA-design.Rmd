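---
title: "Designing and screening circular guide RNA cassettes"
author: "circguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and screening circular guide RNA cassettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Guide RNAs expressed from Pol III cassettes are rapidly degraded, which
limits the durability of CRISPR activation and cleavage. Circularizing
the guide solves this: the expression cassette places the guide between
two self-cleaving Twister ribozymes (P3 U2A upstream, P1 downstream);
after autocatalytic cleavage the ends carry the chemistry that the
ubiquitous endogenous ligase RtcB joins, so the cell itself produces a
circular guide. Because Cas12a and CasRx self-process their own guides
out of longer transcripts, the circle remains functional — provided its
secondary structure is right. Two structural elements are
non-negotiable: the ribozymes must fold correctly (or no circle forms at
all) and the scaffold/direct-repeat hairpin must fold correctly (or the
effector neither processes nor loads the guide). The flexible linkers
inserted between the ligation sequences and the guide are the free
design variables, and the package's screening module is the digital
search over them.

# The cassette model

`GuideCassette` stores a DNA cassette as a sequence plus an ordered,
gap-free feature annotation, one feature per part. Features are kept as
`IRanges` (1-based, inclusive) — the natural convention of the R/
Bioconductor ecosystem this package lives in — and
`featureTable(x, zeroBased = TRUE)` plus the GenBank writer expose the
0-based half-open and GenBank conventions for interoperability. Validity
methods enforce the two invariants everything else relies on: features
tile the sequence without gaps or overlaps, and each feature's
subsequence is exactly its part's sequence.

The variant grammars follow the published architecture:

* `U6+27` — promoter, scaffold, spacer. The promoter part carries a
  27-nt leader as its trailing `leaderLength` nucleotides; the leader is
  retained on the transcript. Modelling the leader inside the promoter
  part (rather than as a separate feature) keeps the published feature
  orders literal — `Pre` is exactly
  `[promoter, scaffold, spacer, scaffold]` — and makes the `-d27`
  relationship exact: the `-d27` cassette is the base cassette minus the
  27 leader nucleotides, nothing else changed.
* `L-Sp1[-F30]` / `C-Sp1[-F30]` — 5' ligation sequence, 42-nt inert 5'
  region, linker, (F30 three-way junction + Broccoli aptamer in the
  `-F30` forms), scaffold–spacer–scaffold, linker, 41-nt inert 3'
  region, 3' ligation sequence; the circular forms add the two flanking
  ribozymes. The 42/41-nt regions are modelled as inert features
  distinct from the linkers, since the architecture lists them
  separately.
* `C-L<k>` — as `C-Sp1` but with the candidate `LinkerPair` substituted
  for the registry's Sp1 linkers. `gRNA+9`, `gRNA+59` and `gRNA+T4AT4`
  are built on the leaderless U6 promoter, matching how the extended
  constructs were cloned.
* Multiplex arrays repeat a (scaffold, spacer) unit per guide; linear
  `Pre`-style arrays close with a trailing scaffold, circular arrays
  wrap the units in the ribozyme/ligation/linker shell.

`predictCircle()` models cleavage at each ribozyme's boundary with its
ligation sequence, shifted by the part-level `cleavageOffset` (default
0, i.e. the cut falls on the boundary — the exact nucleotide chemistry
is delegated to configuration because it is a property of the ribozyme
parts, not of this package). Circles are canonicalised to start at the
5' ligation junction; `rotateSeq()`/`sameCircle()` express rotational
equivalence. Whether the leader is present on the precursor is moot for
the circle: it sits upstream of the 5' ribozyme and leaves with that
fragment.

Spacer lengths default to 20–23 nt (configurable per Cas system); the
published guides in this architecture are 21-mers and the bound is a
sanity check, not biology the package claims to know.

# Folding engines

Screening needs a deterministic, offline structure predictor; assessing
a published design needs production-grade energies. The package
therefore ships three engines behind one interface:

* **`fold()` (primary, "energy")** — dynamic-programming minimisation
  under a deliberately simple nearest-neighbour model: each stack of
  adjacent pairs contributes a negative energy from a 6×6 table over the
  ordered pair types (defaults derived from per-pair strengths GC 3,
  AU 2, GU 1, scaled so a GC-on-GC stack is −3.3 kcal/mol); a hairpin of
  loop size *s* costs `4.5 + log(s/3)` kcal/mol; a pair closing any
  other loop (interior, bulge, multibranch) costs a flat
  `closePenalty = 4` kcal/mol. The closure penalty matters: without it,
  long-range pairings that replace a hairpin by a penalty-free interior
  loop are spuriously favoured — concretely, the two identical scaffold
  copies of a guide would pair arm-for-arm across the spacer instead of
  folding as two hairpins. The model makes no claim to Turner-rule
  accuracy (no dangles, no coaxial stacking, no tetraloop bonuses, no
  loop-closing-pair terms) and every parameter is editable via
  `energyModel()`.
* **`foldMaxpair()` ("maxpair")** — Nussinov base-pair maximisation with
  the same minimum-loop constraint; its `dG` is the negative pair count
  in pseudo-units. It exists as a structurally different second
  predictor and as the quantity the enumeration oracle can check
  exactly.
* **`foldVienna()` ("vienna")** — a thin adapter around an external
  `RNAfold` binary (engine name and version recorded in `engineId`).
  An absent binary is a loud capability error, never a silent fallback.

Shared numerical choices: minimum hairpin loop 3 nt; wobble pairs
allowed; pseudoknots excluded (neither thermodynamic predictor in
common use reports them); alphabet strictly {A,C,G,U}; the open chain
has energy 0 and reported energies are never positive. Determinism: the
tables are filled in a fixed order and the traceback always pairs the
leftmost free base with its smallest admissible partner (inside a closed
pair: stack, then inner substructure, then hairpin), so identical input
gives byte-identical dot-brackets across runs and platforms.

Circular folding uses the doubled-sequence reduction: tables are filled
for every window of length *n* on the doubled string, the best cut
point is taken (smallest index on ties), and traceback indices map back
mod *n*. The window at cut 0 is exactly the linear problem, so the
circular optimum can never be worse than the linear one — a property
the tests assert. A structure whose helix crosses the origin renders as
a bracket string that balances only under rotation; `SecondaryStructure`
validity accounts for that, and the CT/dot-bracket readers reconstruct
the nesting via the cycle lemma.

The test oracle, `enumerateStructures()`, exhaustively lists all nested
minimum-loop structures (guarded to 16 nt) and `scoreStructure()`
evaluates any pair set under the energy model by direct loop
decomposition — two independent routes against which both DP engines
are checked exhaustively (all sequences to length 8) and on random
sequences to length 16.

# The linker screen

`runScreen()` composes: generate (or accept) a library of linker pairs →
assemble each candidate precursor → fold its transcript with the primary
engine → filter by motif correctness → rank the survivors by ΔG
ascending → keep the top `topN` (default 20, the upper end of the
screened 10–20 window) → group by structural similarity → fold the
grouped candidates with the confirmation engine → select, per group, the
most stable member that is also correct under the confirmation engine.

Design decisions where the workflow description is silent:

* **"Correct structure"** is operationalised per motif as (i) the
  fraction of template base pairs reproduced inside the feature
  footprint, threshold `minPairRecovery = 1.0`, and (ii) the number of
  predicted pairs with exactly one end inside the footprint, threshold
  `maxCrossPairs = 0`. These are the strictest readings and both are
  configurable per motif. When a motif's part occurs several times
  (multiplexed scaffolds), every copy must pass.
* **Ranking** uses the primary engine's full-precursor ΔG; ties break
  lexicographically on the linker sequences, and incorrect candidates
  are excluded from ranking entirely, so ranks are a permutation of
  1..N over the correct ones.
* **"Structural similarity"** defaults to coarse-shape equality:
  `shapeString()` collapses every maximal helix to `[]` and drops
  unpaired stretches, which is robust to the 5–7-nt length differences
  between candidates. A base-pair-set mode (single-linkage clustering on
  symmetric-difference distance over feature-relative coordinates, cut
  at a threshold) is provided for finer grouping. Group labels are
  assigned from canonically sorted shapes, so grouping — like every
  other stage — is independent of library order.
* **Engines.** The primary engine is the bundled energy model. The
  confirmation engine defaults to the `RNAfold` adapter, mirroring the
  original two-thermodynamic-predictor scheme, and confirmation is a
  correctness check only (it never re-ranks). A pair-maximisation
  confirmation is deliberately not the default: maximising pair count
  saturates every G with one of the many background C partners (the
  prescribed polyAC cores guarantee such partners), so its optima always
  contain boundary-crossing pairs and the strict filter would reject
  every candidate — a property of the objective, not of the candidates.
* **Libraries.** Extensions are drawn uniformly over the four bases with
  no composition constraint; the core is the literal AC repeat
  (`ACACACACAC`), overridable. Exhaustive mode is refused above 10^6
  pairs (the full 5–7-nt pair space has ~4.6×10^8 members); sampled
  libraries are drawn without replacement by indexing the pair space
  directly, so they are unique and reproducible from the seed alone.
* The screen folds the **precursor transcript** by default — the
  correctness requirement includes the ribozymes, which only exist
  before cleavage — with `foldCircular = TRUE` available to fold the
  post-ligation circle instead.

Every report carries a manifest (seed, engines and versions, config
hash, counts) and the TSV/JSON writers contain no timestamps, so a rerun
from the same configuration is byte-identical.

# The synthetic fixtures

The real part sequences (Twister P3 U2A and P1, ligation sequences,
scaffolds, the Sp1 and L1–L8 linkers) are supplied by users as a YAML
registry; the package ships no claimed biology. Its bundled
`fixtureParts()` registry instead emulates the *architecture*: correct
roles and the stated lengths (27-nt leader, 42/41-nt inert regions,
10-nt polyAC cores, 5–7-nt extensions, the TTTTATTTT 3' extension), with
structured parts built as stem-loops whose stems are pure G/C and whose
loops are GAAA tetraloops, over an A/C background containing no CC run.
That construction is what makes the fixtures *testable*: the background
can neither stack against the stems nor pair with itself, so every
engine — including an external Turner-rule predictor — reproduces the
annotated motifs exactly, and the bundled invading linker (reverse
complement of the scaffold's 5' arm plus one flanking and one loop base)
reliably out-competes the scaffold's own stem under both engine
families. What the fixtures do **not** emulate: real sequences have
partial self-complementarity everywhere, spacers are not inert, and real
screens will legitimately reject many random extensions. Passing the
fixture-based tests therefore demonstrates that the pipeline's logic and
bookkeeping are right, not that any particular real linker is good; for
real designs the external engine and the user's own part sequences do
the work.

Fixture quantification tables are Poisson/log-normal toys generated from
a seed, sized like the published assays (a handful of sites with
thousands of on-target reads, FACS samples of ~10^4 events, a five-point
actinomycin-D time course at 1, 3, 6, 9, 18 h).

# Quantification

* Specificity index: SI = Σ on-target / (Σ on-target + Σ off-target)
  reads, summing across a condition's sites before dividing; a per-site
  mode is exposed as well. SI is scale-invariant and strictly decreasing
  in off-target reads.
* Cleavage efficiency: E = (mNeonGreen⁻ ∩ mCherry⁺) / mCherry⁺, the
  mNeonGreen-negative fraction of transfected reporter cells.
* Fold change: ratio of means against the control condition, with a
  2^−ΔΔCt helper for Ct-scale input.
* Decay: ln(abundance) is regressed on time by OLS; k = −slope,
  t½ = ln 2 / k. The log-linear route is closed-form and exactly correct
  on noiseless exponentials (asserted to 10⁻⁹); k ≤ 0 is reported as a
  stable species (t½ = ∞) rather than an error, because that is the
  expected signature of a circularised guide in such an assay.
  Normalisation of the input series (to t = 0 or to a reference gene) is
  left to the caller; both produce the same slope.

Replicate-level hypothesis testing (ANOVA, t-tests) on wet-lab data is
out of scope; the package computes the defined ratios and fits only.

# Validation sizes and limitations

The shipped tests exercise: exhaustive oracle equivalence over all 4^n
sequences to n = 8 plus 500 random sequences to n = 16; ~10^3 random
structures for the bracket/loop invariants; 100 random libraries of 50
candidates for filter monotonicity, with full-screen
permutation-invariance on shuffled libraries; 1,000 random tables for
the statistics; and 100 noisy replicates (5% multiplicative noise) for
half-life recovery, whose median must land within 5% of truth. These
sizes keep the whole suite in the minutes range on one core while still
being exhaustive where exhaustiveness is feasible.

Known limitations: the bundled energy model is simplified (see above)
and should not be quoted as a ΔG in kcal/mol for real molecules; no
partition function, suboptimal sampling or pseudoknots; GenBank I/O
covers the subset the package writes; the CLI is a thin wrapper, not a
workflow manager; and nothing here predicts editing efficiency from
structure — the screen reproduces a rank-filter-group-confirm selection
scheme, and wet-lab validation remains the arbiter.
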