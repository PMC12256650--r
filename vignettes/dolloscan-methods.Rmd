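---
title: "Hierarchical loss mapping and piRNA cluster signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical loss mapping and piRNA cluster signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dolloscan)
```

## The scientific problem

Syndermata — monogonont and bdelloid rotifers, the epibiotic Seisonidea and
the endoparasitic Acanthocephala — span the full transition from free-living
to host-bound lifestyles. A recurring question in parasite genomics is
whether the morphological simplification of parasites is mirrored by
regression of their genomes: loss of conserved microRNA families, loss of
near-universal single-copy orthologs (metazoan BUSCO genes), and loss of
small-RNA defence pathways such as the piRNA system.

`dolloscan` packages the comparative machinery this question needs:

1. **Dollo loss/gain mapping.** Binary presence/absence characters
   (microRNA families, core genes, morphological traits) are mapped onto a
   fixed rooted tree under the irreversibility assumption: a complex
   character, once lost, is not regained.
2. **Complement accounting.** Expected repertoires by phylogenetic node of
   origin, loss percentages, precursor hairpin-length summaries.
3. **Cross-layer association statistics.** OLS regression with $R^2$,
   Spearman partial rank correlation controlling assembly contiguity (N50),
   and hypergeometric over-representation with BH adjustment.
4. **piRNA signatures.** Length classification (27–32 nt), the 10-nt
   ping-pong 5′-overlap profile, 2-kb window densities, cumulative coverage
   and a permutation clustering-ratio statistic.
5. **Seeded synthetic generators** that emulate the statistical structure of
   every input, so the entire pipeline is testable offline.

## Dollo reconstruction

For a character that is ancestrally present, each internal node is scored
present iff at least one descendant tip is *definitely* present; the root is
forced present. A loss is counted on a branch whose parent is present and
whose child is absent. This places one loss at the root of every maximal
all-absent subtree, which is the minimal number of loss events consistent
with the tip states under irreversibility; the test suite verifies this
against exhaustive enumeration of all internal-state assignments on trees of
up to six tips (≥500 random characters).

For a character that is ancestrally absent, a single gain is placed at the
most recent common ancestor of the possessing tips (single-origin
assumption; independent parallel gains are not modelled), with Dollo losses
below. Polarity comes from a `polarity_spec()`: conserved microRNA families
and core genes are root-present by construction; morphological characters
can be polarised from outgroups, and if the outgroups disagree (or are all
unknown) the character is **excluded** from counting and logged. The source
analyses do not state a tie rule; exclusion is the conservative choice made
here.

**Unknown cells** (`?` in the TSV dialect) are carried as a third state.
They neither generate events nor rescue presence: a node with only unknown
and absent descendants is scored absent, but no event is counted on the
terminal branch into an unknown tip. Note a deliberate asymmetry: the
unconstrained minimum over unknown tip states could sometimes save an event
by declaring an unknown tip present. We do not take that minimum — absence
of evidence is not treated as evidence of presence, and event counts with
unknowns are therefore conservative upper bounds (the tests assert they
never fall below the unconstrained minimum).

## The synthetic fixtures as a stated world

`gen_matrix_from_branch_events()` plants losses on named branches: a
character lost on branch $b$ is absent in exactly the tips below $b$. Two
presets encode the published syndermatan loss structure:

* `paper_busco` — 954 core genes; stem losses 54 (Syndermata), 61
  (Hemirotifera), 165 (Pararotatoria), terminal losses 76 (Seisonidea) and
  148 (Acanthocephala). The two Pararotatoria tips then collectively lack
  $54+61+165 = 280$ genes.
* `paper_mirna` — 44 conserved families; stem decomposition 9/2/16 with
  terminal residuals 5 (Monogononta), 3 (Seisonidea), 10 (Acanthocephala),
  reproducing cumulative tip totals 14, 30 and 37. This needs 45 loss
  events over 44 families, so five families carry losses on two
  *path-disjoint* branches (Seisonidea+Monogononta ×3,
  Acanthocephala+Monogononta ×2). Multi-branch planting is validated for
  *Dollo-stability*: planted branches must be pairwise tip-disjoint and each
  must leave a present tip under its parent, so the reconstruction recovers
  the planted counts exactly — a strict round-trip oracle. The bdelloid
  cumulative total under this decomposition is 11, whereas the published
  group total is 10; the two cannot be reconciled from the printed numbers
  and no bdelloid residual is planted.

`gen_read_set()` emulates a mapped small-RNA library as intervals (no
nucleotides): a length mixture (default: 22-nt miRNA-like class at 0.4,
uniform 27–32 nt piRNA-like class at 0.6 — a deliberately piRNA-rich
library, chosen once as typical for a small-RNA lane of a piRNA-positive
species), uniform placement except a `cluster_fraction` confined to
`n_clusters` 2-kb windows, and a `pingpong_fraction` of piRNA-length reads
converted into opposite-strand partners by explicit coordinate arithmetic
(minus-partner 5′ = plus 5′ + 9), so the planted overlap mode is exactly
10 nt rather than merely enriched. What the generator does **not** emulate:
sequence composition (1U/10A bias), multimapping, expression levels, and
chromosome-scale heterogeneity — a green test establishes the statistics'
correctness on interval structure, not biological discovery power.

`gen_species_summary()` plants a linear relation between microRNA losses
(spread over 0–37, the span of the six species used in the published
regressions) and a response, with Gaussian noise and rounding to nonnegative
integers; N50 is drawn independently (log-uniform over $10^5$–$10^{7.5}$ bp,
a realistic draft-assembly range) so it is uncorrelated with losses by
construction.

## piRNA statistics: conventions

* **Coordinates** are BED 0-based half-open throughout. A plus-strand read's
  5′ end is `start`; a minus-strand read's 5′ end is `end − 1`.
* **Ping-pong overlap** for an intersecting plus/minus pair is
  `(minus 5′) − (plus 5′) + 1`, tabulated over 1–25 nt; every intersecting
  pair is counted (not first-match). The upstream description does not fix
  the arithmetic; this convention reproduces the canonical 10-nt offset.
  Note it is a 5′-to-5′ distance, not the width of the span intersection,
  and it is *not* invariant under globally swapping strand labels: a pair
  with lengths $L_1, L_2$ and overlap $o$ maps to $L_1 + L_2 − o$ under the
  swap. The tests assert that corrected symmetry.
* **Windows** tile each contig from 0 in 2-kb steps (final partial window
  included); reads are assigned by start coordinate (midpoint assignment was
  the other candidate; start was chosen as it matches the BED record
  directly and the difference is immaterial at 2-kb scale).
* **Clustering ratio** = (mean over shuffles of windows needed to hold 90%
  of reads after randomising positions) / (windows needed for the observed
  positions). Shuffling redraws each read's start uniformly on its own
  contig, preserving length, strand and per-contig counts — "positions were
  randomized" upstream leaves this open; preserving per-contig counts
  isolates within-contig clustering from contig-assignment effects. Ten
  shuffles with the mean is the default. Ties in the window sort are broken
  by contig then window index for determinism.

## Statistical choices

* `ols_fit()` wraps `stats::lm` and reports signed slope plus magnitude
  ($R^2$ and residual SE computed from residual sums directly — the
  noiseless fixtures would otherwise trigger perfect-fit warnings). The
  tests cross-check the closed-form normal equations at $10^{-10}$ relative
  tolerance.
* `spearman_partial()` rank-transforms (average ranks for ties), applies the
  first-order partial-correlation formula, and takes the p-value from a t
  statistic with $n-3$ df — the behaviour of the SPSS procedure the
  upstream Methods used. A constant covariate after ranking falls back to
  plain Spearman with a warning.
* `hypergeom_enrich()` computes upper-tail probabilities $P(X \ge k)$ via
  `stats::phyper` (exact combinatorics in the tests) and adjusts with a
  hand-implemented BH step-up (cross-checked against `stats::p.adjust`).
  The "significantly enriched" cut defaults to $q < 0.05$; the upstream
  analysis does not name its adjustment, so the enriched-term *counts* of
  the published GO analysis are not acceptance targets.

## Degenerate inputs and numerical edges

Empty BED files warn and return an empty read set; a character that is
ancestrally absent with zero possessing tips warns and produces no events;
`windows_to_cover` refuses a zero total; `clustering_ratio` refuses an empty
read set; percentages are reported at full precision with a separately
rounded display value (the published "67%"/"85%" round 30/44 = 68.2% and
37/44 = 84.1% under the printed denominator — exact arithmetic is kept and
the rounded figures are never asserted).

## Known limitations

* Probabilistic ancestral-state reconstruction, branch lengths, rates and
  tree inference are out of scope; the tree is an input.
* Gains are single-origin; convergent gains would be misplaced at an MRCA.
* The read generator plants at most one partner per selected piRNA read, so
  planted ping-pong pair counts are approximately half the selected reads.
* Reported loss percentages depend on the expected-complement denominator;
  where the upstream rounding is ambiguous the exact value is reported.
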