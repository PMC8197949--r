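---
title: "Methods: from urinary peptides to degradome signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from urinary peptides to degradome signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
the package, in the order the pipeline applies them.

## The data model

A disease–peptide association table holds one row per (peptide, condition)
association. A peptide is identified by the quadruple *(sequence, parent
accession, start, end)* — not by sequence alone — because the same sequence
can occur at two loci or in two parent proteins and the degradome stage
needs the coordinates. Coordinates are 1-based inclusive (the UniProt
convention) everywhere; every coordinate computation in the package is
written against that convention. Condition labels are case-normalised and
trimmed before keying; each condition maps to one of nine disease classes
(autoimmune, bowel, cancer, cardiovascular, infection, mental, metabolic,
renal, respiratory) or to `health`.

Sequences are restricted to the 20 canonical residues. Records containing
B/Z/U/O/X are rejected with a distinct error class rather than silently
remapped: hydropathy and pKa scales, residue masses and specificity
matching are undefined for ambiguity codes, and silent coercion would bias
every downstream descriptor. Peptides whose parent protein is absent from
the supplied proteome stay in the network and descriptor stages but are
excluded (with a warning) from the degradome stage, which cannot
reconstruct their cleavage windows.

## Signature peptides

The disease–peptide network is bipartite: conditions are source nodes,
peptides target nodes, one edge per distinct association. A peptide's
degree is its number of distinct conditions; degree-1 peptides are the
*signature peptides* of their single condition. Degree is counted over
conditions, not classes; class-level statements are derived afterwards by
mapping. Health peptides never enter the network — health is a reference
set, not a condition. Peptide node identity defaults to the full
coordinate key; sequence-only identity is available
(`build_network(..., peptide_identity = "sequence")`) and can merge loci,
which changes degree and signature counts — the choice is therefore
explicit, not automatic.

## Physicochemical descriptors

* **GRAVY** is the mean Kyte–Doolittle hydropathy index over residues; the
  scale ships as a data file and is swappable.
* **Molecular weight** sums average residue masses plus one water per
  chain (18.01528 Da); average rather than monoisotopic masses match
  conventional peptidome reporting, and monoisotopic masses are available
  by flag. Mass additivity (`mw(s1 + s2) = mw(s1) + mw(s2) − water`) is a
  tested invariant.
* **Net charge** at a given pH is the Henderson–Hasselbalch sum over
  ionisable groups: `+1/(1+10^(pH−pKa))` for the N-terminus, K, R, H and
  `−1/(1+10^(pKa−pH))` for the C-terminus, D, E, C, Y. It is strictly
  decreasing in pH, so the **isoelectric point** is the unique root,
  found by bisection on [0, 14] to |charge| < 1e-6 or 100 iterations —
  deterministic, no starting-point sensitivity.
* **pKa values** default to the EMBOSS set, with Lehninger and Bjellqvist
  selectable; published pI values differ across these sets, so descriptor
  output records which scale was used in its metadata. Absolute pI and
  mass values are validated by their defining identities (charge zero at
  pI, additivity, hand-summed GRAVY), not against any external table,
  because the conventions behind published values vary.
* The **nine amino-acid groups** (acidic, aromatic, basic, charged,
  hydrophobic, polar-and-charged, polar-non-charged, small, tiny) are a
  data file, not code; the bundled membership follows the conventional
  grouping (e.g. acidic {D,E}, tiny {A,C,G,S,T}), sets may overlap, and
  alternative schemes are drop-in.
* The **antimicrobial-activity probability** is a pluggable predictor
  hook with a no-op default, because the upstream predictor is an
  external web service that cannot be bundled or called offline.

Per-class distribution summaries require at least 20 unique peptides per
class by default; smaller classes are excluded with a logged notice, since
density summaries over a handful of peptides invite over-reading.

## Degradome prediction

An observed peptide evidences up to two proteolytic events: an N-terminal
cleavage between parent residues `start−1` and `start`, and a C-terminal
one between `end` and `end+1`. A peptide terminus coinciding with the
intact protein terminus is *not* an event — no protease action is
evidenced there. Each event's Schechter–Berger window covers P4…P1 | P1′…P4′
(8 symbols); positions beyond the protein termini hold the gap symbol `-`.

A specificity rule gives, per position, either a wildcard or an allowed
residue set; a site matches a rule iff every non-wildcard position holds
an allowed residue. A gap never satisfies a residue set; by default it
does satisfy a wildcard (the conservative reading — the rule expresses no
preference there), and a strict mode (`gap_satisfies_wildcard = FALSE`)
is available. Non-human rules are excluded before matching. Prediction
counts are *event* counts — one per (peptide, terminus, protease), per
group — so a peptide listed under two conditions contributes to both
condition groups but once to the pooled count.

## Enrichment over the health reference

The health set's predictions form the reference library: `N` total events,
`K` per protease. For a disease group with `n` events and `k` for a
protease, fold-enrichment is `(k/n)/(K/N)` and the p-value is the
upper-tail hypergeometric probability `P(X ≥ k)` with population `N`,
successes `K`, draws `n` — the standard annotation-enrichment urn, with
the reference library as the population. Bonferroni's `m` is the number
of tests actually performed in the call (pairs with `K > 0`), recorded in
the output metadata. Proteases with `K = 0` and `k > 0` are flagged
`disease_only` and reported without a fold or p-value — no pseudocounts.
`k = 0` rows carry `p_raw = 1`. Results order deterministically by
(p_adj, −fold, protease).

This urn is only approximately valid when the tested group is small
relative to the reference (`n ≪ N`): the disease events are not literally
a subset of the health library, and for `n` comparable to `N` the test
becomes anti-conservative. The synthetic defaults therefore keep the
reference an order of magnitude larger than any single condition, which
is also the regime of real pooled meta-analyses, where the health library
holds tens of thousands of events against condition groups of hundreds.

## Minimal degradome signatures

From the binary (condition × protease) significance matrix, the minimal
signature of a condition is found by exhaustive search in increasing
cardinality over subsets of its enriched proteases: a subset identifies
the condition iff no other condition's enriched set contains it. All
identifying subsets at the first cardinality `k*` are returned; the
search stops at `kmax = 3` by default because larger combinations stop
being useful as practical marker panels (the search itself is exhaustive
and accepts larger `kmax`). Uniqueness is tested against all conditions
across classes; a restricted universe is available via `against=`.
Rendering uses `or` between singleton alternatives, `+` within a set, and
factors an exact cross-product of per-slot alternatives into
parenthesised `or`-groups; the factoring is lossless, and
`parse_signature()` inverts it.

## The synthetic-study generator

The generator emulates the statistical structure the analysis assumes —
not real urinary biology (no collagen-fragment composition, no real
MEROPS specificities). Defaults: 20 parent proteins of 200–400 uniform
residues; 30 rules with per-position wildcard probability 0.5 and allowed
sets of 4–6 residues, catalytic classes round-robin over
aspartic/cysteine/metallo/serine, all human; 5 conditions × 100 peptides
(the per-condition scale of a pooled meta-analysis); a 3000-peptide
health reference (large relative to any condition, see above); peptide
lengths 6–40 (the LMW band); signature fraction 0.2 (roughly the fraction
observed in curated disease tables); 5 planted proteases per condition at
activity multiplier 5.

Generation of each peptide terminus is a three-way mixture: with
probability `q = 0.9` the cut is protease-generated (peptidome termini
are overwhelmingly proteolytic), else uniform background. For a condition
with `a` planted proteases of `t` and multiplier `m`, the planted share
of termini is `min(1, m·q·a/t)` — proportional to `m` — with the
remaining mass split between non-planted rules and background in baseline
proportions. At `m = 1` this reduces *exactly* to the health process, so
the null configuration is an exact null. A protease-generated terminus is
anchored on a genuine match site of its protease, drawn uniformly over
the proteome (which selects the parent protein); when both termini are
protease-generated the sampler retries anchoring (8 attempts, sides
alternating at random) until the second terminus also lands on a matching
site within the 6–40-residue window, falling back to anchor-only.

Two structural guards keep the planted inference well-posed:

* **Substrate diversity** (`min_rule_sites`, default 20): a generated
  rule must match at least 20 distinct sites in the proteome, otherwise
  it is resampled. A rule whose entire repertoire is one or two sites
  would re-use the same cut site across many peptides; the resulting
  clustered counts violate the exchangeability the enrichment urn
  assumes and destroy calibration in small groups.
* **Planted informativeness** (`max_planted_promiscuity`, default 0.05):
  planted sets are drawn from rules matching at most 5% of random sites.
  Enrichment of a near-indiscriminate protease is capped close to 1
  regardless of true activity (the coincidental-match floor enters both
  `k/n` and `K/N`, and the planted excess inflates `n` itself), so its
  activity is not attributable from event counts at realistic study
  sizes. Promiscuous rules remain in the registry; they are just not
  planted.

Degree structure is explicit: a configured fraction of each condition's
peptides is condition-specific (the planted degree-1 signatures); every
other peptide is assigned to at least two conditions, so the network's
degree-1 set equals the planted signature set exactly and recovery can be
scored without slack. With a single condition every peptide is trivially
degree 1. All sampling flows through one seeded RNG; identical seeds give
byte-identical artefacts.

## What the tests show — and what they do not

The verification suite checks, among others: exact equivalence of the
minimal-signature search with exhaustive subset enumeration (200 random
8 × 12 matrices); exact equivalence of degradome prediction with a
brute-force matcher (100 random toy studies); agreement of the
hypergeometric tail with explicit combinatorial sums for every instance
with N ≤ 40 at 1e-12 relative tolerance; the descriptor identities; and
parameter recovery — at 3 conditions × 500 peptides with multiplier 5,
all planted proteases significant after Bonferroni in ≥ 90% of 50 seeds
and exact signature recovery in all of them, with the family-wise
false-positive rate over 200 null seeds within α + 3·SE. Problem sizes
(50 power seeds, 200 null seeds, 10-seed replication in the acceptance
script) were chosen as the smallest giving stable rate estimates.

Passing these tests shows the machinery is correct and calibrated *under
the generator's assumptions*: uniform-composition proteins, independent
termini, exchangeable background cuts, a health set drawn from the same
baseline as disease. Real urinary data violate several of these —
collagen-derived peptide ladders share termini (the very clustering the
generator's substrate-diversity guard suppresses), compositions are far
from uniform, and study heterogeneity adds batch structure — so
calibration on real tables should be checked, for example by permuting
condition labels. The published prediction totals of the source datasets
also depend on the specificity-database version and are not reproduction
targets here.

## Known limitations

* The enrichment urn treats events as exchangeable; heavily laddered real
  peptidomes overdisperse the counts and the Bonferroni-adjusted p-values
  become optimistic (see above).
* Only Bonferroni is implemented for multiple testing in this version;
  the output metadata records `m` so other corrections can be applied
  downstream.
* The pI solver assumes the standard side-chain pKa model; post-
  translational modifications are outside the data model.
* Minimal-signature search reports only the smallest cardinality, as a
  marker panel would; inclusion-minimal sets of larger size are not
  enumerated.
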