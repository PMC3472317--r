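---
title: "Profile-based two-tier classification of DNA-binding protein families: methods and design"
author: "profam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based two-tier classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

DNA-binding proteins are classically organised in a two-tier hierarchy:
*groups* collect proteins sharing a DNA-binding structural motif
(helix-turn-helix, zinc-coordinating, β-propeller, ...; the Enzyme group
instead collects proteins with catalytic activity upon DNA binding), and
*families* within a group collect proteins sharing a biological function.
`profam` implements a purely sequence-based machinery for maintaining such a
classification as new DNA-protein complex structures accumulate: filtering a
complex manifest, choosing family *representatives* whose profiles stand for
whole families, triaging new sequences against the representative-profile
database, and clustering whatever is left into candidate new families.

Everything runs on plain protein sequences; no structure, DNA or live
database access is involved. A seeded synthetic-family generator stands in
for curated structure-derived datasets, so every stage is testable
end-to-end offline.

## Dataset filtering

A complex manifest row carries resolution, nucleic-acid type, a nucleosomal
flag and a previously-classified flag. The filter keeps entries with
resolution strictly below 3 Å ("better than 3 Å" reads as strict; ties are
rejected), bound to double-stranded DNA, non-nucleosomal and not previously
classified. Rules are applied in the fixed order previously-classified →
nucleic-acid type → nucleosomal → resolution, and the first failing rule
becomes the machine-readable rejection reason, so rejection reports are
deterministic and mutually exclusive. Malformed rows yield per-entry error
records rather than aborting a run.

## Profiles and E-values

Family profiles are position-specific score matrices (PSSMs). A *star
alignment* anchors all members to a seed sequence by pairwise global
alignment (Needleman–Wunsch, BLOSUM62, affine gaps costing
`open + L·extend` with open 11, extend 1); member residues aligned to each
seed position form the columns, and insertions relative to the seed are
dropped. This is a deliberate, documented simplification — the package does
not re-implement a progressive multiple-alignment optimiser, and profile
length always equals the seed length, which keeps candidate profiles
comparable during jack-knifing.

Column frequencies use position-based (Henikoff) sequence weights and are
mixed with background pseudocounts at weight `β/(Neff + β)`, where `Neff`
is the mean number of distinct residues per column and `β = 10` by default;
scores are log-odds in bits against a standard background composition.
With `β = 0` zero frequencies are floored at 1e-8 so scores stay finite.
All-gap columns are dropped with a warning. Profile construction is fully
deterministic.

Searches align a sequence to a PSSM by local (Smith–Waterman) dynamic
programming with the same affine gap model, in compiled code. Statistical
significance is calibrated *empirically per profile*: at least 100 unrelated
decoy sequences are scored, and the extreme-value tail model
`E = K·m·n·exp(−λS)` (m profile length, n database residues) is fitted to
the per-decoy maximal scores by Gumbel moment matching
(`λ = π/(sd·√6)`, `K` from the fitted location). The constants are cached
with the profile, making E-values engine-independent and reproducible. The
natural sanity check — the *expected* number of decoy hits with `E ≤ 1` per
database scan should be about one — is asserted on fresh decoy scans,
averaged over ten scans, because the count on any single scan is a small
integer with Poisson-level noise.

Iterative refinement mirrors jump-start profile searching: the seed
alignment defines the first matrix directly, then each iteration searches a
corpus, absorbs hits at the stringent inclusion E-value 1e-10 into the
alignment, rebuilds and recalibrates, stopping at convergence or after 20
iterations. The corpus is an explicit argument, with the run's own sequence
set as the default background; profiles refined against different corpora
are not bit-comparable, which is why the corpus used is always recorded
with a run.

## Representative selection

Coverage of candidate representative *i* for family *F* is the fraction of
members of *F* whose search against *i*'s profile scores at or below the
assignment E-value (1e-3); the candidate counts itself, since it always
picks its own profile. Jack-knifing gives every member a turn as candidate.

Candidate profiles during jack-knifing are grown from the candidate's *own*
single-sequence seed by iterative inclusion over the family corpus. Growing
them jump-start from the full-family alignment instead would hand every
candidate essentially the same averaged matrix and erase the coverage
differences the jack-knife is meant to measure; with single-seed growth a
candidate inside a tight clade absorbs only its clade and its coverage
honestly reflects its reach. Final database profiles for chosen
representatives *are* built jump-start from the full-family alignment
anchored on the representative: a database profile should summarise the
whole family, not one member's reach.

Selection dispatches on family size and identity spread:

* size 1 — the member is its own representative;
* size 2 — both members are trialled, one with full coverage is kept
  (lexicographically first on ties);
* multi-member, *narrow* spread — the lexicographically first member is
  trialled and accepted at full coverage ("any one member", since narrow
  families are near-identical); if it unexpectedly fails, selection falls
  through to jack-knifing rather than failing;
* multi-member, *wide*, fewer than 50 members — full jack-knife, then
  greedy set cover over the pick sets: repeatedly add the candidate
  covering most uncovered members until coverage is complete or no
  candidate adds anything. Ties break by higher mean bit score, then
  lexicographic id. The greedy set never contains a zero-gain member;
  exact minimum set cover is out of scope (NP-hard);
* 50 members or more — the family is first clustered (single-linkage over
  pairwise profile associations), one seed per cluster (the member with the
  highest within-cluster mean identity) is assessed singly and in greedy
  combination, extending over any still-uncovered members.

*Narrow* versus *wide* is the off-diagonal range of the family's pairwise
identity matrix against a threshold of 20 percentage points. The threshold
is a declared parameter rather than a fitted constant — near-identical
families span well under 20 points in practice — and it is exposed in the
configuration rather than hard-coded.

Because each member always covers at least itself, greedy combination can
always complete, which realises the design guarantee that selected sets
reach 100% combined coverage on coherent synthetic families.

Chosen sets are optionally validated against a *dummy database* of
completely unrelated sequences: each representative's profile is rebuilt
with the dummy corpus as the iteration background, and the set is confirmed
when combined coverage stays at 100%, showing the profile is not propped up
by extraneous homologs. When the classification is updated, previously
chosen representatives are retained whenever they still achieve full
coverage on the enlarged family; otherwise selection runs afresh and the
change is logged.

## Classifying new complexes

Each kept complex is triaged against the representative database at E-value
1e-3 and lands in one of three categories: *single* (exactly one family
hit, possibly via several representatives of that family, which collapse),
*multiple*, or *none*. Ternary complexes — two distinct proteins (pairwise
identity below 95%) on one DNA — are split and re-triaged chain by chain
regardless of their entry-level category, with each routing decision
logged: uniform splitting leaves no routing case silent or
category-dependent. Genuinely
ambiguous non-ternary multi-family hits are assigned to the lowest-E family
with a persistent ambiguity flag, never silently.

No-hit sequences go to all-vs-all pairwise association: two sequences
associate when either single-sequence profile finds the other at 1e-3 (the
decision is symmetric). Connected components of the association graph —
single linkage, matching the edge-based "pairwise association" language —
of size two or more become candidate new families; singletons are *loners*,
each promoted to a single-member family. Family names and group attribution
for new families are consumed from an annotation table: attributing a
motif or a biological function is curatorial judgement, and the pipeline
refuses to guess it. Provenance (`legacy`,
`representative_association`, `pairwise_association`, `loner`) is recorded
per member, and the classification invariant — every member in exactly one
family — is re-validated after every edit.

## The synthetic generator

`make_family()` draws an ancestor from a stated background composition and
evolves each member independently: substitutions are placed uniformly at a
rate set by the member's target identity, substitution partners are drawn
from a BLOSUM-derived exchange distribution, and indels arrive at a per-site
rate with geometric(0.5) lengths. Because identity is measured over gap-free
columns, realised identities track targets within a few points. Each
family's stream is derived by hashing the family name with the seed, so
adding a family to a benchmark never perturbs the others.

`make_benchmark()` assembles the full planted-truth study: families whose
first members seed a legacy classification, held-out members as queries,
unrelated loners, a ternary complex with chains evolved from two different
families, and a dummy database; generation asserts the separation invariant
(minimum within-family identity strictly above the maximum
family-to-background identity). Default conditions are three 5-member
families at 65–95% target identity, four loners, one ternary and a
five-sequence dummy set.

What the generator does *not* emulate: real domain architecture (multi-domain
chains, repeats), composition bias, realistic indel hotspots, or the
ragged chain boundaries of crystallographic entries. Passing tests therefore
demonstrate the machinery's correctness and the method's internal guarantees
on homology-structured data, not expected accuracy on any particular
real-world corpus.

## Numerical and policy choices

* Gap convention everywhere: a gap of length L costs `open + L·extend`.
* Alignment traceback ties prefer diagonal, then gap-in-subject, then
  gap-in-query; all orderings (hits, clusters, reports) are explicitly
  sorted, so outputs are invariant to input order.
* E-values are floored at the smallest positive double; they scale linearly
  in the database size `n`, with the calibration decoy volume as the
  default `n`.
* The jack-knife E-value cutoff reuses the assignment cutoff 1e-3 by
  default; it is a separate configuration key.
* The all-vs-all clustering cutoff defaults to the association value 1e-3
  but is a separate configuration key.
* Single-member "loner" families and retained representatives are marked
  with dedicated strategy labels (`self`, `retained`) in selection reports.
* Unknown taxa and fold labels are carried as `"unknown"`/`NA`, never
  dropped silently.

## Problem sizes

The shipped validation exercises use desk-scale regimes chosen to finish
comfortably on one CPU: 20 families of 5–30 members for
representative-selection soundness, 10 six-member narrow families for the
narrow shortcut, a 60-member two-clade family for the clustering path,
200-decoy calibrations, and the default three-family benchmark for the
end-to-end pipeline. These sizes are the package's own validation choices;
the method itself has no intrinsic size limits beyond the quadratic cost of
jack-knifing, which is why families of 50 or more members switch to
cluster seeding.

## Known limitations

* Star alignments discard insertions relative to the seed; profiles cannot
  model member-specific inserted domains.
* Empirical calibration needs a decoy set of at least 100 sequences; E-values
  from different decoy sets differ slightly (deterministically per set).
* The greedy cover is minimal only in the greedy sense; a smaller exact
  cover may exist for adversarial pick sets.
* Ambiguous multi-family assignment is a flagged heuristic (lowest E), not
  a resolution.
* Tallies reported for any particular historical structure corpus depend
  on that corpus and the search engine of the day; the package validates
  the method's guarantees on synthetic data rather than reproducing
  corpus-specific counts.
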