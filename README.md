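# otuflock

Post-clustering analysis of marker-gene metabarcoding data (18S rDNA V4,
~380 bp amplicons) for questions about *where a community's taxa came
from*: which OTUs look like products of in-situ evolutionary radiation
(**species flocks**), which are candidate **endemics** of the habitat, and
which apparent radiations are artifacts of **intragenomic rRNA variation**.
The motivating setting is an ancient lake whose protist plankton mixes
cosmopolitan taxa, marine-derived relicts, and lineages that diversified in
place — but the machinery applies to any confined habitat sampled with a
99%-similarity OTU table, a reference sequence set, and bootstrap-supported
phylogenies.

## What it computes

Given OTU representative sequences, a sample × OTU count table, a reference
FASTA, and Newick trees whose internal-node labels are bootstrap supports:

1. **Divergence-band classification.** Each OTU is aligned against every
   reference (global Needleman–Wunsch; identity = matches over alignment
   columns) and its divergence *d* = 1 − identity to the best passing hit
   (coverage > 70%, ≥ 200 aligned bp) maps to a band: *d* ≤ 1% `similar`,
   1% < *d* ≤ 10% `unclear`, *d* > 10% `potential_endemic`. The 80–90%
   identity band is tracked separately.
2. **Species-flock detection.** A candidate clade has bootstrap support
   > 60 and ≥ 3 focal OTUs. A candidate is a **flock** when its focal OTUs
   have mean pairwise identity > 97% (divergence < 3%) *and* at least three
   members have read counts within 100× of each other, including the
   clade's most abundant member. Failing the abundance rule marks the clade
   as putative **intragenomic variation** (one dominant rRNA variant with
   trace satellites); passing it at ≥ 3% divergence marks a **divergent
   clade**. Nested calls of the same kind collapse to the maximal clade.
3. **Endemism typing.** Type 1: flock members (radiation products);
   Type 2: identity < 90% to every known sequence (or no passing hit);
   Type 3: decent best hit but no bootstrap-supported placement with any
   reference tip. Precedence 1 > 2 > 3.
4. **Community statistics.** Single-draw rarefaction to a common depth,
   Bray–Curtis dissimilarity BC(u,v) = 1 − 2·Σᵢmin(uᵢ,vᵢ)/(Σuᵢ+Σvᵢ),
   per-sample richness, exact rarefaction curves
   E[S(n)] = Σᵢ(1 − C(N−Nᵢ,n)/C(N,n)), and shared-OTU (Venn) partitions
   across basins.
5. **Synthetic communities with planted truth.** A generator plants star-
   radiation flocks at controlled divergence, endemics > 10% from every
   reference, dominant-plus-satellite variant clouds, and lognormal /
   Dirichlet / multinomial counts at realistic depths (47,195–142,260 reads
   per sample), so the whole pipeline is testable without raw reads.

## Worked example

```r
library(otuflock)

gen <- generator_config(
  n_references = 6, n_background_otus = 10,
  flocks  = list(list(n_tips = 5, target_divergence = 0.02),
                 list(n_tips = 4, target_divergence = 0.02)),
  clouds  = list(list(n_satellites = 5, identity_range = c(0.95, 0.99),
                      dominant_reads = 30958)),
  endemic_otus = list(n = 3, distance_range = c(0.12, 0.18)),
  n_samples = 12, depth_range = c(47195, 142260), seed = 42)

res <- run_all(run_config(out_dir = "demo", seed = 42, generator = gen))
res$flocks[, c("call_id", "label", "support", "n_focal", "mean_divergence")]
```

```
  call_id                  label support n_focal mean_divergence
1 clade01 intragenomic_candidate     100       6      0.05789474
2 clade02        divergent_clade     100       4      0.12500000
3 clade03                  flock     100       5      0.02078947
4 clade04 intragenomic_candidate     100       3      0.07105263
5 clade05        divergent_clade     100       3      0.13596491
6 clade06        divergent_clade     100       3      0.07543860
7 clade07                  flock     100       4      0.02105263
```

Both planted flocks come back as the only two `flock` calls (5 and 4
members at ~2.1% realized divergence); the planted variant cloud is
`clade01` — six co-clustered OTUs whose read counts span a >100× gap, the
signature of one abundant organism with divergent rRNA gene copies.
`divergent_clade` rows are deeper (> 3%) but otherwise flock-like groups.
The summary rolls this up:

```r
res$summary$clade_counts
#> $flock [1] 2   $divergent_clade [1] 3
#> $intragenomic_candidate [1] 2   $rejected [1] 0
res$summary$flock_otus_percent
#> [1] 32            # 9 of 28 focal OTUs sit in flocks
res$summary$endemism_counts
#> $type1_flock [1] 9  $type2_divergent [1] 3  $type3_unplaced [1] 0  $none [1] 16
```

`run_all()` also writes `classify.tsv`, `flocks.tsv`, `endemism.tsv`,
`bray_curtis.tsv`, `richness.tsv`, `venn.tsv`, `summary.json` and a
`manifest.json` (config echo, seed, input digests) under `out_dir`.
Identical config + seed reproduce the reports byte for byte.

A command-line wrapper lives at `inst/cli/otuflock.R`
(`simulate | classify | clades | flocks | stats | run-all`, each taking
`--config cfg.json --out dir --seed int`).

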