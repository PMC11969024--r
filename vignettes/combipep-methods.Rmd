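---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, what the synthetic-data generators
do and do not emulate, and the design choices made where the design was
genuinely open.

# The pipeline in one paragraph

A parent hexadecapeptide is saturation-mutagenised (NNK codons, so every
position can become any of the 20 amino acids), displayed on phage, and
selected for three rounds against a panel of immobilised chemokines from
the CC and CXC/CX3C ("CXnC") classes, with a C5A-like control to flag
non-specific binders. Amplicon sequencing of the input library and of each
selected population yields per-variant counts; enrichment summarises
binding; improving point mutations are selected per chemokine class and
combined exhaustively into a second-generation combinatorial library;
winners are characterised by chemotaxis dose-response against single
chemokines and disease-mimetic chemokine pools; and structural models of
peptide–chemokine complexes are analysed for contacts and binding-site
occlusion.

# Amplicon processing

Reads carry, in forward orientation: an 8-nt forward demultiplexing motif,
a 26-nt forward constant region, the 48-nt variable insert (3 × 16
codons), a 116-nt reverse constant region and the reverse complement of
the 8-nt reverse demultiplexing motif. `extract_inserts()` normalises both
mates to forward orientation and recovers the insert independently from
each as the sequence between the forward and reverse constant regions.

Open choices and how they were fixed:

* **Motif matching is exact**, first occurrence, no mismatches: the
  published filtering rules state no tolerance, and an exact rule is
  conservative and deterministic. Base qualities are carried but never
  used, for the same reason.
* **Both mates must independently yield the same insert** ("non-identical
  inserts excluded" is read as a mate-concordance requirement), and
  any `N` in the insert is an "ambiguous" rejection.
* Coordinates are 0-based half-open internally and never exposed.
* Classification is exhaustive and exclusive: every pair ends in exactly
  one of `accepted`, `reject_missing_motif`, `reject_discordant`,
  `reject_size`, `reject_ambiguous`, so rejection tallies plus accepted
  (plus the off-library tally at the counting stage) always sum to the
  number of read pairs.

# Enrichment

Two frequency dialects are implemented because both appear in the
workflow's history: the NNK-library analysis imputed unobserved variants
with the **lowest observed proportion** of that sample, while the
combinatorial-library analysis **added one** to every raw count. The
add-one dialect is the package default: it has total support over the
designed library and needs no special cases. "Lowest proportion in the
experiment" is read as the per-sample minimum over observed variants, not
a global minimum across samples; the alternative would couple unrelated
samples through one sparse observation.

`log2E` is the log2 ratio of output to input frequency; `Δlog2E` subtracts
the parent's `log2E` per target, which cancels any per-target constant —
a property the tests assert directly. Control exclusion (variants with
control `log2E > 0`, strictly) is applied after the delta computation and
before any ranking.

A consequence of the strict `> 0` rule worth knowing: for a variant with
no real control affinity the control `log2E` is centred on zero, so
sampling noise alone sends roughly half of all null variants over the
threshold. That is faithful to the published rule; the package therefore
reports the removal list, and the simulator-based recovery checks run on
panels without a control so that they measure ranking accuracy, not the
aggressiveness of the exclusion rule.

Only one output sample per target per run is accepted (round 3 is the
sequenced round); no variance model or shrinkage is applied to the raw
ratios, deliberately.

# Mutation selection

For each class scope the per-position best mutation by mean and by peak
Δlog2E enters the candidate set. The published phrase "arranged by mean
and peak" is ambiguous; the implementation uses **mean as the primary key
and peak as the secondary** (the order in which they are written), with
position and replacement residue as deterministic tie-breaks. The two
thresholds (peak ≥ 5, mean ≥ 0.55) are combined as **OR** — they encode
two different goals, breadth (peak on at least one target) and overall
affinity (mean) — with an AND option available. The 0.55 mean threshold is
applied to the per-class mean, since it feeds per-class pools. Pool sizes
default to 10 (CC) and 12 (CXnC).

Combinatorial mutants are ranked by **median** Δlog2E (over all targets
and per class); the median of an even number of targets is the midpoint of
the central pair. CM groups are the top/bottom five by the relevant
median, ties broken by (median, mean, sequence). Chemokine type labels
(inflammatory/dual/homeostatic) are carried into reports but never used in
ranking.

# Library design

Combinations are all subsets of size ≥ 2 of each pool whose mutations sit
at pairwise distinct positions. Subsets containing two alternative
substitutions at one position are **excluded at enumeration time** rather
than applied-then-deduplicated: applying two substitutions to one site is
undefined (the sequence type rejects it), and the observed maximum of
simultaneous substitutions equalling the number of mutated residues says
conflicting pairs never co-occur. For this reason the apply-then-dedupe
variant mentioned as a sensitivity option is not implemented.

Reverse translation uses a bundled E. coli K-12 relative codon-usage
table (the expression host); `most_frequent` mode is deterministic,
`weighted` mode samples codons by usage under a seed, and a `gc_bias`
flag restricts choice to each residue's two highest-GC codons. Codon
choice cannot affect any peptide-level result; round-trip identity
(translate ∘ reverse-translate) is asserted over random peptides. Oligos
are emitted as 18-nt arm + 48-nt insert + 15-nt arm (81-mer layout).

The parent sequence is a required input for real runs: the package's
`synthetic_parent()` ("EEDDYTAQAPLTCGFT") is a documented stand-in whose
positions 8 and 14 are placeholders, consistent with the canonical
mutation labels (Y5W, T6D, A7D, L11I, ...) used in examples. The scrambled
control for real runs is likewise a required input; simulations draw a
seeded permutation.

# Dose-response and potency

The curve is the standard log-logistic
`f(x) = c + (d − c) / (1 + exp(b (ln x − ln e)))` with `e` in molar units.
"3-parameter" means one asymptote is fixed: agonist (EC) fits fix the top
at `d = 100` %, inhibition (IC) fits fix the bottom at `c = 0`; three
parameters remain free either way. Agonist data are cleaned first by the
desensitisation rule: doses above the peak-mean dose whose mean response
falls below the peak are dropped (the peak and any plateau at the peak are
always kept). EC fits require percent scale; raw cell counts are
normalised to percent of the maximal observed mean response, a convention
the fit records (the source protocol does not state one). Replicates are
fitted raw, not averaged — also an undocumented point fixed here.

Numerics: least squares via Levenberg–Marquardt (`minpack.lm`), fitting
`ln e` to keep the midpoint positive, multi-started over both slope signs
(±0.5, ±1, ±2) and a five-point log-spaced midpoint grid spanning the dose
range; the lowest-deviance converged start wins; tolerances 1e-12 on the
relative decrease. Non-convergence is flagged, never silently replaced.
Derived doses use the closed form `x = e ((100 − f)/f)^(1/b)`; potency is
`−log10` of the molar value.

Chemokine pools take molar fractions proportional to mean tissue TPM of
the user-chosen chemokine list — no expression filtering beyond the mean.

Dunnett comparisons are computed directly on the equal-variance one-way
ANOVA model: pooled variance on `N − k` degrees of freedom, and
familywise-adjusted two-sided p-values from the (k−1)-dimensional
multivariate t with correlations `sqrt(n_i n_j / ((n_i+n_0)(n_j+n_0)))`
via `mvtnorm::pmvt` (exact in one dimension, quasi-Monte-Carlo above it;
`multcomp::glht` serves as an independent cross-check in the test suite,
not as the implementation). Stars follow the usual legend bins (0.05,
0.01, 0.001, 0.0001).

# Structure contacts and occlusion

Models are read from mmCIF or PDB (bio3d), hydrogens dropped, altlocs
resolved to highest occupancy. The 5 Å binding-site rule is
**residue-level**: a residue contacts the partner chain if any heavy-atom
pair is within 5 Å. Interaction typing is a deliberately simple,
fully-documented geometric classifier — not a re-implementation of a
SIFT-style tool: per-class heavy-atom cutoffs (hydrophobic apolar C···C
≤ 4.5 Å; hydrogen donor···acceptor ≤ 3.5 Å; ionic opposite formal charges
≤ 4.0 Å; polar uncharged N/O pair ≤ 3.5 Å; carbonyl C···O ≤ 3.6 Å;
aromatic C···C ≤ 4.0 Å; van der Waals at radii sum + 0.5 Å) with formal
charges from residue templates at physiological pH (Asp/Glu −, Lys/Arg +,
His neutral). Ring-centroid (π) geometry is intentionally out of scope.
A residue pair's classes are the union over its atom pairs, and may be
empty (proximity without a typed interaction). Unknown residue names fall
back to element-only typing, with a message.

Occlusion compares two models sharing the chemokine chain: site residues
from the chemokine:partner model, blocked residues as the subset also
within 5 Å of the peptide in the chemokine:peptide model. Residue
numbering is reconciled by an identity check on shared residue ids
(mismatches are an error listing the residues); the peptide chain
defaults to the shortest chain of the probe model, overridable. Distances
use a dense Euclidean cross-distance matrix — exact, and fast enough for
complex models of a few thousand heavy atoms; the tests pin it to a naive
double-loop oracle at 1e-9 Å.

# What the simulators emulate — and what they do not

* **Selection** is weight-proportional retention: after each round a
  variant's proportion is multiplied by its latent weight and
  renormalised, so expected `Δlog2E` is exactly
  `rounds × log2(w_variant/w_parent)` — the log-linear behaviour the
  enrichment statistic assumes. Sequencing is multinomial at the
  configured depth. Not modelled: bead-binding kinetics, phage
  growth-competition, PCR bias, chimeras, index hopping. Amplification
  between rounds is treated as unbiased. Passing recovery tests therefore
  demonstrates the *analysis* is correct under its own assumptions, not
  that real selections are this clean.
* **Reads** embed the exact scaffold around each variant's oligo with
  independent per-base substitution errors per mate; no quality-score
  structure or indels.
* **Chemotaxis** draws Gaussian (percent scale) or negative-binomial
  (count scale) replicates around the true log-logistic curve.
* **TPM tables** provide uniform, sparse-dominant or log-normal profiles.
* **Toy complexes** place single-residue "beads" (two heavy atoms each) on
  a line so that the binding site and its blocked subset are exact by
  construction, verified by brute force before writing. They exercise the
  geometry, not protein chemistry.
* The latent affinity model supports additive per-mutation log2 effects
  plus optional pairwise epistasis, so both cooperative and antagonistic
  combinations can be planted and looked for in the CM rankings.

# Problem sizes used in the validation suite

The shipped tests and the acceptance script use: the full 305-member NNK
library at sequencing depth 1e5 and 3 rounds for recovery checks; 100
seeded noisy dose-response simulations (5 % Gaussian noise, 3 replicates,
7 doses) for pIC50 recovery; 1e4 replicates for the Dunnett familywise
error simulation (6 groups of 3); random 30–60-residue chains (≤ 500
atoms) for contact-oracle equivalence; and pools of up to 12 mutations for
enumeration oracles. These sizes make the whole suite run in well under a
minute per module while leaving Monte-Carlo error far below the asserted
tolerances.

# Known limitations

* The strict control-exclusion rule is noise-sensitive at low depth (see
  above); a margin or count-aware test would be a natural extension but
  would depart from the published rule.
* Exact reproduction of the published combinatorial library size requires
  the per-pool mutation composition, which is not available in
  machine-readable form; `enumerate_combinations()` exposes its count so
  the check is a one-liner once the pools are transcribed.
* The contact classifier is geometric and template-based; it does not
  kekulise rings, perceive protonation, or model π interactions.
* Dose-response fits assume independent homoscedastic errors; no
  mixed-effects structure across biological replicates.
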