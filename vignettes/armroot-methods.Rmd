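---
title: "armroot: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{armroot: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armroot)
```

# The problem

Some cellular machines exist in two analogous, non-homologous versions
that are distributed across the eukaryotic tree in a strikingly
anti-correlated way: most species carry one or the other, few carry both.
The kinetochore couplers Dam1-C (a ten-subunit ring in fungi and many
protists) and Ska-C (three subunits, in animals and plants) are the
motivating case. Two histories can produce such a pattern: both complexes
were present in the last eukaryotic common ancestor (LECA) and were
repeatedly, reciprocally lost; or one complex arose late and spread by
horizontal gene transfer (HGT). The two histories make different,
testable predictions, and `armroot` implements the full set of analyses
that discriminate them, plus a synthetic-data module that generates data
under the ancestral-origin scenario so every analysis can be exercised
and calibrated end to end.

This vignette documents the models behind each stage, the tunable
parameters and their defaults, the numerical choices, and what the tests
do and do not establish.

# Presence/absence profiling

A `presence_matrix` stores species-by-gene cells in three states:
`present`, `absent`, `unknown`. `unknown` exists because absence from a
*transcriptome* is weak evidence — a gene may simply not be expressed in
the sampled condition. Unknown cells never enter numerators, are excluded
from per-group denominators in `taxon_completeness`, and are reported
separately by `call_complex_presence`.

Two presence rules are deliberately distinct:

* display/profile presence: at least 1 subunit (`min_subunits = 1`);
* dataset inclusion for transcriptome-derived proteomes: at least 4
  subunits detected below E-value 1e-3 (`analysis_config`'s
  `min_subunits_for_species_inclusion` and
  `evalue_inclusion_threshold`).

`cooccurrence_summary` restricts all denominators to species carrying a
conditioning gene (default `Ndc80`, a kinetochore protein expected in any
informative proteome), so genomes that would fail to show anything are
not counted as "neither". Published "percentage with either complex"
figures are ambiguous between the inclusive (A or B) and exclusive
(exactly one) readings, and the two can differ by several points; the
summary therefore reports both and the printout labels them explicitly.

`mutual_exclusivity_test` formalizes the qualitative claim that the two
complexes avoid each other. The default null permutes complex-A presence
labels among conditioning species, with
`p = (1 + #{n_both* <= n_both}) / (1 + B)`, one-sided toward exclusivity.
Because species are phylogenetically dependent, a label-permutation null
is anti-conservative when losses are clumped on the tree; passing a
rooted tree switches to a null that replants the *observed minimal loss
counts* of both complexes on branch-length-weighted edges (never nested,
matching the single-loss-per-lineage structure of a Dollo history) and
recomputes the overlap. Internally species are put in a canonical
(sorted) order before permuting, which makes the p-value exactly
invariant to row order of the input.

# Dollo loss reconstruction

Under a single-gain (Dollo) model a complex is gained once — at the root
under the ancestral-origin hypothesis (`gain_policy = "fixed_root"`), or
at the most recent common ancestor of the present species
(`"mrca_of_present"`) for a later-origin scenario — and can only be lost
thereafter. The minimal reconstruction places one loss on the edge above
each maximal subtree, below the gain node, that contains no present leaf.
This rootmost-greedy placement is provably minimal (each such subtree
needs at least one loss; one suffices) and deterministic. The test suite
verifies minimality against exhaustive enumeration of all valid loss
sets on 1000 random trees of up to 10 leaves.

`unknown` leaves are treated as absent by default but flagged, mirroring
the practice of manually investigating "suspicious absences"; the
`unknown = "free"` mode instead assigns them whichever state minimizes
the loss count (a subtree of only unknowns then never forces a loss).
When both complexes are simulated with dropout = 0, the reconstructed
count can be *below* the planted event count: two planted losses in
sister clades are indistinguishable from one loss on their shared stem.
The reconstruction is reported as what it is — a minimum compatible with
the data — and the acceptance script reports planted and reconstructed
counts side by side.

# Paralogy and structure

`reciprocal_best_matches` consumes asymmetric query-by-target E-value
matrices (as produced by external profile-vs-profile HMM tools, which are
out of scope to run here). Both directions must independently pass the
threshold; ties for "best hit" break toward the lexicographically
smallest label and the tie rule is part of the documented contract.
`homology_components` collapses direction by the minimum E-value and
reports connected components, so two subunits that miss each other
directly but both hit an intermediate profile land in one component with
path length 2 — the transitive-homology argument. E-value thresholds are
parameters surfaced in every report, not constants: profile-search
E-values near the permissive threshold (default 10) are a gray zone, and
fixing a constant would hide that sensitivity.

`kabsch_superpose` minimizes unweighted C-alpha RMSD over proper
rotations and translations (SVD of the cross-covariance with sign
correction of the smallest singular component; reflections are excluded
because proteins are chiral). There is no outlier trimming: trimmed
variants change RMSD values unpredictably, and published superposition
protocols rarely state their trimming, so reported RMSDs should be read
as magnitude/ordering evidence rather than exact targets. Correspondence
between paralog chains is built either one-to-one (equal lengths) or from
gap-free columns of a global BLOSUM62 alignment of the two sequences.
The implementation is checked against an independent quaternion
(eigenvalue) formulation to 1e-9 on 1000 random point sets.

# The arm supermatrix and duplication rooting

A symmetric complex whose two halves ("arms") are related by ancient
intracomplex duplication admits outgroup-free rooting: concatenate each
arm's subunits separately, let every species contribute one pseudo-taxon
per arm (`<species>__arm1`, `<species>__arm2`; the double underscore is
reserved and validated), and the branch separating the arm clusters is
the pre-LECA duplication — the root. The pipeline:

1. per paralog pair, merge the two subunit alignments with
   `profile_merge_align` — a profile–profile global alignment (affine
   gaps, open 10 / extend 0.5, expected BLOSUM62 column scores) whose
   output provably preserves each input sub-alignment: columns are only
   interleaved with all-gap columns, never split or reordered. Deleting
   one side's rows and dropping all-gap columns recovers the other input
   byte-for-byte, and the column pairing is verified against an
   exhaustive alignment enumeration for short profiles;
2. trim merged columns by residue fraction (`trim_columns`): a column is
   kept iff its non-gap fraction is at least `gt` (default 0.05 — the
   permissive setting appropriate when most columns of a deep merge are
   sparse). The semantics "keep when fraction >= gt" are pinned by a
   vendored fixture with hand-computed column fractions either side of
   the boundary (1/30 removed, 2/30 kept);
3. admit a species only if it has at least `min_per_arm = 2` present,
   non-excluded subunits in *each* arm — short subunit genes make
   single-gene rows mostly gap noise;
4. concatenate pair blocks in paralog-map order (the order is recorded in
   the partition table; nothing downstream depends on it).

Subunits without credible cross-arm homology are excluded via the
`paralog_map` (`Spc19`/`Spc34` in the default map) rather than silently
dropped.

`root_split_report` checks whether the unrooted tree displays the
arm1/arm2 bipartition, roots on it when present, and reports RELL support:
the proportion of RELL replicates in which the arm-split topology beats
its NNI rearrangements across that branch. Support scoring uses a single
branch-length optimization pass per alternative — enough for comparable
likelihoods, and it keeps the computation inside interactive time.

# Likelihood machinery

`site_loglik` implements Felsenstein pruning for 20-state amino-acid
models: POISSON (uniform exchangeabilities) or LG, with model or
empirical (+F) frequencies and uniform or discrete-gamma(k) rates (equal
class weights, class rates from the mean-of-quantile construction).
Transition matrices come from the eigendecomposition of the
pi-symmetrized rate matrix, normalized to one expected substitution per
unit branch length. Gaps and ambiguous residues (B, Z, X, `?`, `*`) are
missing data (partial likelihood 1 in every state). Per-node rescaling
keeps long concatenations from underflowing. The implementation is
verified three ways: exhaustive internal-state summation on quartets
(1e-10), rerooting invariance (1e-8), and agreement with an independent
likelihood implementation (phangorn) to 1e-8 under POISSON, LG and
LG+Γ4.

The published analyses this pipeline mirrors used free-rate models
(R5/R7) and ultrafast bootstrap in external software; both are features
of that software rather than of the hypotheses being tested. Here the
executed model is the configured substitution matrix with discrete-gamma
rates, and branch support/topology comparison is RELL-based. The
configured model names are what appear in provenance output; this
substitution is deliberate and recorded.

Tree search is NJ (on model-corrected ML pairwise distances; the Poisson
distance has the closed form −(19/20)·log(1 − 20p/19)) followed by
hill-climbing over NNI rearrangements, accepting strict log-likelihood
improvements. No SPR moves: at the problem sizes this package targets
(tens of pseudo-taxa), NNI from an NJ start is adequate and keeps the
search deterministic and fast; this is a documented limitation for large
trees. A constraint tree (e.g. the consensus species tree restricted to
representative taxa) vetoes any move whose induced subtree breaks a
constraint bipartition — constrained and unconstrained fits feed the
topology tests.

## RELL, KH and AU tests

RELL resamples site indices with replacement (scale r draws
⌈r·n⌉ sites) and sums stored per-site log-likelihoods — no
re-optimization. KH compares the observed log-likelihood deficit of each
topology with the centered replicate distribution of that deficit. The AU
test computes bootstrap proportions BP(r) across scales (default 0.5–1.4
step 0.1; the set must contain 1), fits
Φ⁻¹(1 − BP(r)) = d·√r + c/√r by weighted least squares (weights from the
delta-method variance of the probit), and reports
p_AU = 1 − Φ(d − c). Numerical choices: BP is clamped to
[1/(2B), 1 − 1/(2B)] before the probit; exact replicate ties are broken
uniformly at random so exactly tied topologies remain exchangeable; a
topology that wins no replicate at any scale is reported p = 0 (and a
topology that wins all of them p = 1) with a degeneracy flag rather than
through the regression. All tests are bit-reproducible under a fixed
seed. Calibration is tested, not assumed: under an exchangeable null the
suite requires the 5% rejection rate to hold within 3 standard errors
over 500 datasets at 1000 replicates.

# The synthetic-data generator

The generator defines the study conditions for all tests:

* `simulate_species_tree`: forward Gillespie birth–death from one
  lineage, stopped at the n-th extant lineage (retrying on extinction),
  so trees are exactly ultrametric with n leaves. The unconditioned
  engine is exported (`simulate_birth_death`) and its extant-count mean
  is tested against the analytic expectation e^{(b−d)t}.
* `simulate_coupled_dollo`: both complexes present at the root; loss is
  the first arrival of a per-lineage Poisson process (at most one loss
  per root-to-leaf path). Coupling multiplies the other complex's loss
  rate by (1 + coupling), clipped at zero, once one complex is lost on a
  lineage — the simplest mechanism with one interpretable knob that
  produces the observed anti-correlation (coupling −1 forbids double
  loss). No quantitative loss-rate estimates exist to copy from the
  literature, so defaults (rates ~1–1.6 per unit height on a height-1
  tree, coupling −0.9 to −0.95, dropout 0.05–0.1) are chosen to produce
  the qualitative regime the real screen shows: most species with
  exactly one complex, a small both/neither fringe, and a handful of
  independent losses per complex. Dropout records a failed observation
  as `absent` — that is what a missed transcript looks like in a
  presence screen — and truth objects always carry the un-dropped
  states.
* `simulate_complex_sequences`: the duplication history (proto-subunit →
  two arm ancestors → stepwise within-arm duplications, all before the
  species root) is grafted above the species tree, one species-tree copy
  per subunit, pruned by loss edges; sequences evolve by exact
  continuous-time Markov simulation (per-branch transition matrices via
  eigendecomposition, not Gillespie). No indels and no among-lineage
  rate variation are simulated: rooting tests depend on topology and
  divergence, not alignment ambiguity. Subfunctionalization is a
  scenario, not a fitted model — it is represented only by divergence
  time.
* `simulate_loci`: clustered layouts place all genes on one scaffold
  with exponential intergenic gaps; unclustered layouts assign scaffolds
  uniformly. Occupancy statistics are tested against closed forms
  (birthday problem; exponential mean).

What passing tests show — and what they do not: the suite demonstrates
correctness of the algorithms (oracle equivalence, contract properties),
statistical calibration under the generator's assumptions, and
recoverability of planted signal. Real screens add ortholog-detection
error, alignment error, lineage-specific rates, and non-random taxon
sampling, none of which the generator emulates; conclusions about real
complexes still require the external search/alignment tools whose
outputs this package consumes as tables.

# Problem sizes

The shipped tests run at desk scale, chosen to finish in minutes on one
core while leaving no property under-sampled: 1000-case oracle sweeps for
Dollo/likelihood/merge/superposition; 500 datasets at 1000 RELL
replicates for test calibration; 100 seeds (6 species, 8 subunits,
150 sites) for planted-root recovery, with 30-seed grids at reduced
divergence for the degradation trend; 165 species for exclusivity
calibration. The acceptance script uses the same scales.

# Known limitations

* NNI-only topology search; no SPR/TBR, no model selection.
* The internal profile merge is a desk-scale aligner; externally produced
  merged alignments are accepted as-is (`premerged = TRUE`) and are the
  right choice for production alignments.
* The Dollo count is a minimum; it cannot distinguish one stem loss from
  coordinated sister losses.
* The tree-aware exclusivity null conditions on the observed loss counts
  rather than integrating over loss-rate uncertainty.
* Free-rate models and ultrafast bootstrap are intentionally out of
  scope (see above).
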