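---
title: "Methods: single-mismatch OTU clustering and GMYC delimitation for COI metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-mismatch OTU clustering and GMYC delimitation for COI metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coipipe)
```

# Scope

`coipipe` processes paired-end COI amplicon libraries from bulk community
samples (benthic invertebrates and whatever else a kick net collects)
through four stages: read preprocessing, OTU clustering, GMYC species
delimitation on a user-supplied ultrametric tree, and percent-identity
taxonomy assignment. Tree *inference* is deliberately out of scope — the
package consumes clock-like trees (e.g. from a Bayesian relaxed/strict
clock analysis) and only ships `hamming_upgma()` as labelled demo
plumbing, not as a phylogenetic method. BLAST execution is likewise out of
scope: taxonomy works from tabular best-hit files, because live databases
drift and a frozen table is the reproducible object.

# Read model and preprocessing

Libraries follow a 2-step tailed-PCR layout. After the second PCR the
biological part of a forward read is

```
[8-nt sample tag][forward primer site][insert ...]
```

and a reverse read starts with the reverse primer site followed by the
reverse-complemented insert. Demultiplexing matches the first 8 bases of
the forward read against the manifest **exactly** (tags differ by several
substitutions, and with a single 8-nt tag per run there is no printed
mismatch tolerance to honour); a read pair whose tag was hit by a
sequencing error lands in the unassigned bin, which simply costs coverage.

Quality filtering interprets "Phred below 20" per mate with a configurable
policy: `mean` (default), `min`, or a sliding `window` (width 25). The
default is the mean because a per-base minimum at Q20 would discard most
genuine 2 x 300 MiSeq pairs, while the mean reproduces a read-level
"quality score" cutoff; both other readings remain available in
`filter_config()`.

Primer trimming is IUPAC-aware (the metazoan COI primers are heavily
degenerate) and anchored: the forward primer is a prefix of the forward
mate, the reverse primer a prefix of the reverse mate, each allowing at
most `max_primer_mismatch = 2` mismatches — degenerate primers tolerate
template variation, and two further substitutions cover sequencing error
without letting random sequence pass. Trimming precedes merging so the
overlap search never has to align primer bases.

Merging considers every ungapped overlap of at least `min_overlap = 20`
bases, scores it by the number of matching positions, and keeps the best
(ties to the longer overlap). Substitutions only, no indels: the target is
a fixed-length 313 bp fragment, and keeping coordinates rigid is what
makes the later Hamming-distance clustering well defined. In the overlap
the base with the higher Phred wins (ties favour the forward mate) and the
consensus quality is the maximum of the two — with one mate near-always
high quality, the max is the honest confidence of the kept base.
Amplicons are then filtered to **exactly** 313 bp (a single stated net
length, not a range) and any amplicon still containing an N is dropped,
because 100%-identity dereplication is ill-defined over ambiguity codes.

# OTU clustering

Valid amplicons are dereplicated at 100% identity with per-sample counts;
groups with fewer than 3 reads are discarded (`min_group_count = 3`).
Samples are pooled before clustering — the study design this emulates
clusters all runs jointly — with per-sample counts carried along for the
OTU table.

Hamming-1 neighbours are found by masked-position hashing: for each of the
313 positions, sequences are bucketed by the string with that position
deleted; a pair at distance exactly 1 shares exactly one bucket. This is
O(n L) strings hashed instead of an O(n^2) scan, and the all-pairs scan
survives as the test oracle.

The merge rule is the abundance-aware greedy policy: visit groups in
descending read count (ties lexicographic by sequence); each group joins
the OTU of its most abundant already-assigned Hamming-1 neighbour (whose
count is by construction at least its own), or founds a new OTU.
Transitive chains therefore merge, but only downhill in abundance: a
sequencing-error satellite (always rarer than its parent) is absorbed,
while two co-abundant genuine haplotypes that happen to share a rare
intermediate neighbour still merge only through that intermediate — and
keep their own OTUs when no such bridge survives the 3-read filter. A
pure `connected_components` mode is provided as the structural
alternative; the greedy partition provably refines it, and the test suite
checks both against brute force. Representatives are the most abundant
member, ties broken lexicographically, so output is bit-for-bit
reproducible.

# GMYC delimitation

The single-threshold Generalised Mixed Yule Coalescent model places a
threshold height `T` on an ultrametric tree. Nodes older than `T` are
speciation events of a generalised pure-birth process with rate
`lambda_div * k^p_div`; nodes younger than `T` are coalescences within the
delimited species, with combined rate
`lambda_coal * sum_j (m_j (m_j - 1))^p_coal` over clusters `j`. The
exponents (searched in `[0, 2]`) generalise the linear/quadratic lineage
dependence of the pure Yule and Kingman processes.

Two conventions matter and are worth stating precisely:

* **Between-species lineages persist below the threshold.** In an
  interval younger than `T`, `k` counts the species stems crossing `T`
  (all delimited entities), not zero: species continue to exist, so the
  diversification process keeps accruing waiting-time exposure even where
  all observed events are coalescences. Dropping this survival term makes
  sub-threshold singleton regions rate-free and biases the fitted
  threshold deep into the tree. At `T` = root height no lineage is older
  than `T`, so the term vanishes and the model collapses exactly to the
  single-process null — the identity the acceptance tests check to 1e-9.
* **Each event contributes the log rate of the component that produced
  it** (competing-risks form), and the exposure integral uses the total
  rate.

The likelihood is evaluated piecewise on the intervals between branching
events, additionally split at `T`; zero-length intervals from simultaneous
branching collapse away (their events keep their log-rate terms, which
avoids `log 0`). Candidate thresholds are the midpoints between
consecutive distinct branching times, plus one just below the shallowest
branching (every tip a species) and one at the root height. The root
candidate *is* the null model, which guarantees `LR >= 0` without any
numerical grace.

At each candidate both `lambda`s are profiled out analytically
(`lambda_hat = events / exposure(p)`), leaving two separable 1-D
optimisations over the exponents, solved by a deterministic coarse grid
(step 0.1) plus `stats::optimize` refinement. This replaces a stochastic
multi-start: the profile objective is low-dimensional and the grid covers
the multimodality the multi-start would have addressed, with no RNG in
the fit.

The LR test against the null uses a chi-square reference with `df = 3` by
default (threshold plus the extra rate class; published usage varies, so
it is configurable). Note the threshold parameter is unidentifiable under
the null, so the chi-square reference is an approximation; in our
simulations under a 1-species coalescent the test is, if anything,
conservative (about 1-7% rejections at the 5% level across seeds). On
homogeneous pure-birth trees the single-process family can mimic the Yule
rate curve (exponent near 0.5), so the fit occasionally collapses to one
species — always without claiming significance.

`delimit()` cuts all branches crossing `T`; subtree tip sets are the
entities, reported as clusters (>= 2 tips) or singletons, and both are
counted as GMYC species.

# Taxonomy assignment

Percent identity is `100 * identical_sites / query_size`, rounded
half-away-from-zero to one decimal — the rounding that reproduces every
printed score in the bundled survey table (e.g. 296/311 -> 95.2).
Species-level assignment requires identity **strictly** greater than 95
(no printed row sits exactly at 95.0, so the boundary is a package
contract, documented as such). Thresholds for coarser ranks (genus,
family, order) are configuration with no defaults, since critical
similarity scores are survey-specific. The package ships the transcribed
best-hit table of a riverine benthic COI survey (369 GMYC species; DDBJ
SRA DRA012522) as `riverine_best_hits()`; applying the rule to it yields
137 species-level assignments.

# Simulators, and what they do not show

`generate_community()` emulates: uniform-random 313-nt haplotypes with an
enforced minimum pairwise distance (default 5, so error satellites at
distance 1 are unambiguous); log-normal abundance skew (`sdlog = 1` by
default — real bulk samples are heavily skewed); substitution errors at a
per-base rate (default 0.002) with honest Phred scores (erroneous bases
Q3-15, clean bases Q30-40, so the Q20 filter is exercisable); the full
tag + primer + insert read layout; and a 5% fraction of off-length
(single-deletion) templates standing in for the off-target length
variation a real run shows. It does **not** model indel sequencing
errors, chimeras, quality-by-cycle decay, or cross-talk between tags —
passing tests therefore say nothing about chimera handling, and the
fixed-length selection step is what shields the downstream algorithm from
indel-type artefacts.

`generate_tree()` grows a Yule species tree (`ape::rphylo`), then grafts
a Kingman coalescent into each species' pendant branch, scaling the
coalescent rate so the expected within-species depth is the *shallowest*
species divergence divided by `depth_ratio` (default 50). Scaling to the
shallowest divergence — not the root — is what makes the ratio an actual
barcode gap for every species pair. Coalescent draws that would overrun
their pendant branch are redrawn up to 50 times, then rescaled into 90%
of the branch; with the default ratio this is vanishingly rare. Branch
lengths are written with 15 significant digits so emitted trees validate
as ultrametric at 1e-9 relative tolerance.

Test problem sizes were chosen to keep the whole suite at desk scale:
denoising acceptance uses 100 communities of 1200 read pairs over 10
haplotypes with `sdlog = 0.5` — the milder skew guarantees every parent
haplotype is sampled far above the 3-read floor, so the check isolates
clustering behaviour from detection limits, which the acceptance
criterion's own precondition (parent at least 10x its error satellites)
presupposes; GMYC acceptance uses 100 trees of 5 species x 6 tips plus
100 single-species 30-tip null trees; parameter-recovery checks use
200-tip trees (25 species x 8 tips, exponents fixed at their generative
value 1), where both rates come back within 25% relative error in the
median.

# Numerical and degenerate-input choices

* Ultrametricity is validated against the *median* root-to-tip depth
  (relative tolerance 1e-6 by default), so a few aberrant tips are
  reported rather than the conforming majority.
* All orderings that affect output are total: count descending then
  sequence lexicographic (dereplication, greedy clustering,
  representative ties), candidate order for thresholds, tip order for
  entity ids. Reruns are byte-identical.
* Empty inputs flow through every stage (empty FASTQ -> empty OTU set ->
  empty tables) rather than erroring.
* `cluster_otus()` refuses input containing groups below
  `min_group_count` — a violated precondition is a caller bug, not
  something to silently repair.
* Merging rejects pairs whose best overlap is shorter than 20 nt or has
  more than 10% mismatches; both knobs sit in `filter_config()`.

# Known limitations

* Single-threshold GMYC only; multiple-threshold variants are out of
  scope.
* The LR test's chi-square reference is approximate (boundary
  non-identifiability); treat p-values near 0.05 with care.
* Clustering is Hamming-1 by design; it is not a general-radius OTU
  clusterer and makes no attempt at 97%-identity style clustering.
* Taxonomy is best-hit based; no lowest-common-ancestor logic.
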