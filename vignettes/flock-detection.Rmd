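---
title: "Detecting species flocks and candidate endemics in OTU metabarcoding data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting species flocks and candidate endemics in OTU metabarcoding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Communities in old, confined habitats — ancient lakes are the canonical
case — assemble through a mix of immigration and in-situ diversification.
With a single marker gene (here the ~380 bp V4 region of 18S rDNA,
clustered into OTUs at 99% similarity) one cannot observe speciation
directly, but three sequence-level signatures are informative:

* **Species flocks**: a monophyletic burst of closely related but distinct
  OTUs, the expected footprint of a radiation within the habitat.
* **Deep divergence from everything known**: an OTU more than 10% away from
  every reference sequence has no close relative anywhere in the reference
  corpus and is a candidate endemic.
* **Lack of supported placement**: an OTU with a decent nearest reference
  that nevertheless refuses to attach to any reference clade with bootstrap
  support may represent an unrecognized local lineage.

This package operationalizes those signatures as explicit, parameterized
decision rules, and ships a synthetic-community generator with planted
ground truth so that each rule can be validated end to end.

## Decision rules and their parameters

### Divergence bands

Divergence is `1 - identity` to the best reference hit that passes the hit
filter (query coverage > 0.70, at least 200 aligned residue pairs; both
configurable via `hit_filter()`). The bands, from `classify_params()`:

| band | rule | default |
|---|---|---|
| `similar` | d ≤ `similar_max_divergence` | 1% |
| `unclear` | d ≤ `unclear_max_divergence` | 10% |
| `potential_endemic` | d above that, or no passing hit | — |

Both thresholds are inclusive on their band. An OTU in the `unclear` band
could be a widespread organism that simply lacks a close reference, or an
endemic — the data cannot tell, which is exactly what the label says.

### Flock criteria

From `flock_params()`: a candidate clade has bootstrap support strictly
above `min_support` (60) and at least `min_focal` (3) focal OTUs;
non-focal tips inside the clade are allowed. A candidate is a **flock**
when

1. the mean pairwise divergence of its focal OTUs (sequence-based, not
   patristic) is strictly below `max_mean_divergence` (3%), and
2. at least `min_abundance_set` (3) members have read totals whose
   max/min ratio is strictly below `max_abundance_ratio` (100), with the
   compatible set required to contain the clade's most abundant member.

Rule 2 is the intragenomic screen. Organisms with many rRNA gene copies per
genome (dinoflagellates are the textbook case) shed divergent copies into
the OTU table: one dominant OTU carrying the organism's real abundance plus
a halo of trace satellites at 95–99% identity. Such clades fail rule 2 —
there is no 3-member comparable-abundance set containing the dominant —
and are labeled `intragenomic_candidate`. Requiring the dominant in the set
is the only reading under which a clade of one 30,958-read OTU plus
satellites at 2–86 reads (mutually comparable!) is flagged, which is what
the pattern means biologically; `require_dominant_in_set = FALSE` gives
the literal reading. Candidates passing rule 2 but failing rule 1 are
`divergent_clade`: flock-like support and abundances but deeper splits —
possibly older radiations, not called flocks.

### Nested clades

Candidate clades nest: a flock's internal nodes may themselves be
supported, and a flock usually sits inside its parent taxon's (also
supported) clade. Every candidate node is classified first; then a call is
dropped when its clade is nested inside a *same-label* call (a radiation is
counted once, at its maximal extent, not once per internal node) or inside
an `intragenomic_candidate` call (subsets of a variant cloud's satellites
belong to the cloud). A flock nested inside a larger *divergent* clade is
kept — that is the normal situation of a radiation inside its parent taxon.
The alternative — collapsing nested candidates before classification — was
rejected because any supported higher-taxon clade would then absorb every
flock below it and the procedure could never find anything. Threshold
monotonicity (raising the support cutoff never adds candidates; relaxing
the divergence cutoff never removes flock labels) holds exactly on the
per-node view (`collapse_nested = FALSE`); the label-aware collapse can
merge two sibling flocks into one call when the divergence cutoff is
relaxed enough to make their parent a flock too.

### Endemism typology

Per OTU, with precedence Type 1 > 2 > 3: **Type 1** — member of a called
flock (radiation products count as flock members first, however far they
are from references); **Type 2** — best passing hit below
`type2_identity_ceiling` (90%), or no passing hit; **Type 3** — identity at
or above the ceiling but no ancestor clade with support > 60 containing a
reference tip. The 80–90% identity band is reported alongside and is
half-open at 90 so band membership is consistent with the strict `< 90%`
Type 2 rule.

## Alignment conventions

All identities come from one aligner: global Needleman–Wunsch
(match 2, mismatch −3, gap open 5, gap extend 2, via Biostrings), with
statistics computed on the end-gap-trimmed span. Fixed conventions, chosen
for bit-exact reproducibility where common practice is silent:

* identity denominator = all span columns, so internal gaps count against
  identity; `N` never counts as a match;
* `aligned_length` for the hit filter counts residue–residue columns, so a
  150 bp query can never pass a 200 bp length filter via gap padding;
* coverage for the filter is query coverage;
* divergence of gap-free equal-length pairs equals the p-distance exactly,
  which is what makes the generator's planted divergences assertable
  without tolerance inflation.

An e-value threshold exists as a hook for externally computed hit tables
but is off by default: e-value statistics are meaningless against the small
curated reference sets this pipeline searches.

## The synthetic world

`generate_dataset()` emits the post-clustering state of a metabarcoding
study — sequences, counts, truth labels — under these commitments:

* **Flocks are star radiations**: each tip receives ~half the target
  divergence in substitutions from a common ancestor, so realized mean
  pairwise divergence lands within ±20% (relative) of target. A star is the
  fewest-parameter encoding of "short branches, rapid origin". Substitution
  *counts* (not per-site probabilities) make divergences exact by
  construction. No indels, so alignment identity and p-distance coincide.
* **Flock members share a base abundance** (lognormal spread, sdlog 0.4,
  around a common draw): comparable abundances are part of the flock
  definition being planted. Independent abundances would let a "planted
  flock" fail its own defining criterion.
* **Endemics** are evolved from a random reference at a distance drawn from
  `distance_range` (default 12–18%), and the generator verifies by
  brute-force scan that every endemic is > 10% from *every* reference,
  failing hard otherwise.
* **Background OTUs** sit 3–9% from their source reference: within the 10%
  radius (so they classify `unclear`), but never able to satisfy the < 3%
  flock criterion among themselves. The floor is a modeling commitment that
  background diversity is not flock-like; real data may contain true
  borderline radiations, and a green recovery test says nothing about them.
* **Counts**: per-OTU lognormal weights (meanlog 0, sdlog 1.5), per-sample
  Dirichlet perturbation with higher concentration for 25–50 m samples
  (so deep communities cluster, as observed in stratified lakes), then a
  multinomial draw at a depth uniform on 47,195–142,260 reads. Row totals
  equal the drawn depths exactly.
* **A dedicated outgroup** (`REF_OUT`, an isolated random sequence) is
  emitted for rooting. Rooting on an in-cluster reference converts real
  splits near the root into spuriously supported giant "clades"; an
  isolated outgroup's attachment is unstable across bootstrap replicates,
  which keeps near-root clades unsupported — mirroring good outgroup
  practice.

The generator does **not** simulate raw reads, PCR or chimera artifacts,
sequencing error, indels, or taxonomic structure among references. Green
tests on this world establish that the decision rules recover planted
structure under clean separation (≤ 2% within flocks, ≥ 15% between
groups); they do not establish robustness to borderline divergences,
alignment ambiguity, or reference databases with close relatives of the
flocks.

## Numerical and procedural choices

* Bootstrap supports are percentages of replicates containing the same
  unrooted tip bipartition (invariant to rooting), from column resampling
  plus neighbor-joining on p-distances; the root never carries a support.
  Trees are consumed as rooted-as-read; NJ + bootstrap here is a fixture
  builder and a reduced-scale analog of 1000-replicate ML bootstrapping,
  not a replacement for it.
* Absent supports mean "unevaluated", never 0, and make a node ineligible
  as a candidate.
* Rarefaction is a single draw without replacement per sample (classic
  `rrarefy` behavior), seed-logged; samples below the target depth are
  dropped with a warning, never up-sampled. A repeated-draw mean is
  available (`mean_of`) but is not the default because it breaks exact
  depth conservation.
* Summary percentages are rounded half-up to integers, matching how such
  results are reported ("about 7%", "16%").
* All randomness descends from one master seed; stage streams use fixed
  offsets, so a single integer reproduces every report byte for byte.
* Tie-breaks: best hits by identity, then longer alignment, then
  lexicographic reference id; flock calls ordered by clade size then first
  member id.

## Known limitations

* The flock criteria are necessary signatures, not proof of radiation:
  phenotype–environment correlation and trait utility cannot be checked
  from a marker gene.
* Divergence is computed on OTU representatives' pairwise alignments, not
  on a multiple alignment or patristic distances; for < 3% divergent V4
  amplicons these agree closely, but they are not identical estimators.
* The intragenomic screen is abundance-based and cannot distinguish true
  rare sister species from rRNA variants of an abundant one — it flags, it
  does not prove.
* Monte-Carlo checks in the test suite (rarefaction expectation) run at
  reduced draw counts to fit the test-time budget; tolerances are set
  accordingly (3 standard errors).
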