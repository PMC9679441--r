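# coipipe

COI metabarcoding of bulk community samples, from raw paired reads to
named species: inline-tag demultiplexing, quality filtering, primer
trimming and read merging; **abundance-aware clustering of unique
sequences at a single nucleotide difference into OTUs**; single-threshold
**GMYC** species delimitation on an ultrametric tree; and percent-identity
taxonomy assignment against tabular best-hit files. Built for the
workflow used on riverine benthic communities sequenced with the 313 bp
Leray COI fragment (2 × 300 MiSeq reads, 8-nt inline sample tags), and
for anyone who wants that pipeline reusable and testable at desk scale —
both simulators (mock communities with ground truth, Yule-over-coalescent
trees with known species membership) are first-class, tested code.

## The two core methods

**Single-mismatch OTU clustering.** Valid 313 bp amplicons are collapsed
into unique sequences with read counts; groups of fewer than 3 reads are
discarded; groups at Hamming distance 1 are then merged, visiting groups
in descending abundance so each group joins its most abundant
already-assigned neighbour (or founds an OTU). Chains merge transitively
but only downhill in abundance — sequencing-error satellites are absorbed
by their parents, co-abundant genuine haplotypes are not. Neighbour search
is by masked-position hashing (no all-pairs scan); a pure
connected-components mode is available for comparison.

**Single-threshold GMYC.** On an ultrametric tree with branching-time
intervals indexed by `i`, the event rate is

    r_i = λ_div · k_i^p_div + λ_coal · Σ_j ( m_ij (m_ij − 1) )^p_coal

where `k_i` counts between-species lineages (every lineage above the
threshold `T`; below `T`, the species stems crossing it) and `m_ij` the
lineages of within-species cluster `j`. The log-likelihood is
`Σ_i [ log r_event(i) − r_i x_i ]` with the event term taken from the
component that produced the event. `T` is chosen by profile maximum
likelihood over midpoints between branching times; the fit is compared to
a one-process null by a likelihood-ratio test (χ², df = 3 by default), and
cutting the tree at `T` yields the GMYC species (clusters and singletons).

## Worked example

```r
library(coipipe)

## a mock community with known truth: 5 haplotypes, 400 read pairs
sim <- generate_community(community_spec(n_haplotypes = 5,
                                         n_read_pairs = 400, seed = 42))
res <- run_pipeline(sim$pairs)
res$funnel
#>             stage reads
#>  total_read_pairs   400
#>     demultiplexed   395
#>    quality_passed   395
#>    primer_trimmed   395
#>            merged   395
#>       valid_reads   376
#>     unique_groups    55
#>   filtered_groups     5
#>              otus     5
```

400 simulated pairs lose 5 to tag-hitting sequencing errors, 19 to
off-length contaminant templates; the surviving 376 reads dereplicate
into 55 unique sequences, of which 50 are sub-3-read error satellites.
The 5 OTUs recover the 5 true haplotypes exactly
(`setequal(res$otus$otus$representative, sim$haplotypes$seq)` is `TRUE`).

```r
## GMYC on a simulated tree: 5 species x 6 tips, barcode gap 50x
tr <- generate_tree(tree_spec(n_species = 5, tips_per_species = 6,
                              depth_ratio = 50, seed = 42))
fit <- gmyc(tr$tree)
fit
#> Single-threshold GMYC fit
#>   tips:          30
#>   threshold:     0.0202346 (time before present)
#>   GMYC species:  5 (5 clusters, 0 singletons)
#>   logL:          256.51235  (null 240.95831)
#>   LR = 31.108, p = 8.067e-07 (chi-square, df = 3)
```

The fitted threshold falls inside the simulated barcode gap, the 5
entities equal the true species membership, and the mixed model beats the
single-process null decisively.

```r
## taxonomy: the bundled riverine survey's best-hit table (369 GMYC species)
rep <- summarize_hits(riverine_best_hits())
rep$counts
#>    species unassigned
#>        137        232
```

137 of 369 GMYC species clear the strict >95% identity bar for a
species-level name — the remainder await reference barcodes.

A thin CLI wrapper with `run`, `simulate`, `gmyc` and `assign`
subcommands ships in `inst/cli/coipipe.R`.

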