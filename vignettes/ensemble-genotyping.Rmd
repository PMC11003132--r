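---
title: "Ensemble genotyping: merging, consensus and benchmarking methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble genotyping: merging, consensus and benchmarking methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensemblevar)
```

# Scope and model

`ensemblevar` implements the computational core of an ensemble genotyping
workflow: given one population VCF (the variants to be genotyped — the
*anchors*) and K per-genotyper output VCFs for a single diploid sample, it
produces one consensus genotype per anchor, and it can benchmark any call
set against a truth set. It deliberately does *not* run read alignment or
the external genotypers; the genotyper-selection module emits an advisory
plan, and the merge consumes whatever VCFs the user supplies.

The underlying assumptions are the ones this family of pipelines makes:

* all genomes are diploid (haploid calls are promoted to homozygous
  diploid; phase is ignored);
* variants are biallelic after normalization — multiallelic records are
  split at parse time, with allele *k* mapping to 1 and everything else
  (REF or another ALT) to 0 in the split record for ALT *k*;
* variant classes partition by allele-length difference: SNP (0, single
  base), indel (1–49 bp), SV (≥ 50 bp, or inversion/duplication by type —
  an inversion has signed length 0);
* the anchor variant owns its cluster's coordinates: different genotypers
  report shifted coordinates for the same SV, and the merge's job is to
  map every call back onto the input variant it corresponds to.

# Clustering and consensus

## Thresholds

| parameter | default | unit | applies to | comparison |
|---|---|---|---|---|
| `sv_pos_tol` | 200 | bp | SV start positions | strict `<` |
| `sv_len_ratio` | 0.25 | fraction | SVs and indels | strict `<` |
| `indel_pos_tol` | 10 | bp | indel positions | strict `<` |
| `snp_pos_tol` | 0 | bp | SNP positions | inclusive `<=` |

The length-ratio denominator is the anchor's length: the anchor is the
reference truth for its cluster, so `|len_call − len_anchor| /
|len_anchor| < 0.25`. Insertions and deletions compare allele-length
magnitudes; inversions (signed length 0) and duplications compare their
reference span `end − pos + 1`, since the signed definition would make
every inversion pair trivially equal. A zero-length anchor admits only
zero-length calls.

Assignment is deterministic: among admissible anchors a call takes the
nearest by start position; ties fall to the smaller length difference,
then the lower anchor position. Each genotyper contributes at most one
call per anchor (the best-matching one); surplus calls are returned
unassigned, as data rather than errors.

## Depth normalization

Tools report depth on different scales, so depths enter the consensus
only after per-tool Z-scoring, `D' = (D − μ)/σ` with the *population*
standard deviation (divisor N) over all of one tool's depth-bearing
calls. Two degenerate cases are fixed by convention: `σ = 0` maps every
`D'` of that tool to 0 (the depth carries no information), and a call
without DP has no `D'` and loses any depth tie-break to a call that has
one. A tool with no depth-bearing calls simply has no depth statistics.

## Consensus rules

The consensus genotype is the one supported by most genotypers, counting
genotypes as unordered allele pairs and never counting missing genotypes.
For SNPs and indels, a variant whose best genotype has support 1 is
skipped — a single opinion on a small variant is not evidence. For SVs,
when every distinct genotype has support exactly 1, the call with the
smallest `|D'|` decides. Two deliberate extensions cover cases the rules
above leave open: ties among equally supported genotypes (support ≥ 2
each) are also resolved by the smallest `|D'|` among their supporting
calls, and a final lexical order on the allele pair guarantees
determinism even when depths are absent or equal.

# Evaluation

Matching against a truth set is per class (SNP, indel, and SVs by type),
1-to-1 — a call can credit at most one truth variant and vice versa,
which prevents double counting at multiallelic sites. The conventions
differ slightly from clustering because the benchmark rules are stated
with inclusive wording while the merge rules are strict; both are kept as
stated and both are configurable:

* SV: both start and end breakpoints within 200 bp (inclusive) of the
  truth, and size difference at most 25 % (inclusive) of the true size.
  An insertion has no reference span, so its end test degenerates to the
  start test plus the size test.
* indel: position difference strictly below 10 bp. No size or allele
  identity requirement by default; `match_rule(indel_size_rule = TRUE)`
  adds the 25 % size test for users who want the stricter reading.
* SNP: exact position *and* REF/ALT identity, so a mismatched
  substitution at the right position is not credited.

*Presence* means the match above; *genotype* additionally requires the
unordered allele pair to agree. At the genotype level a presence-matched
call with the wrong genotype counts as a false positive, which keeps
`tp + fp = |calls|` and `tp + fn = |truth|` at both levels.

Pairing is greedy nearest-first (by position difference, then length
difference, then genomic order). On sparse truth sets — variants spaced
further apart than twice the tolerance, which all SV benchmark sets in
practice are — greedy pairing attains the maximum matching; the test
suite checks it against an augmenting-path maximum-cardinality matcher.

Precision–recall curves re-evaluate the call set at every distinct score
threshold, keeping calls with score ≥ t; the score is GQ with DP
substituting where GQ is absent. Stratified evaluation assigns each truth
variant to exactly one stratum (signed-length bin, half-open `[a, b)`, or
first overlapping BED set with a `"non-repeat"` fallback) and attributes
unmatched calls to the stratum of their own length or position, so
per-stratum counts always sum to the overall counts.

# Genotyper selection

The plan module encodes the published decision rules: BayesTyper always;
Paragraph for SVs only in fast mode (its per-variant file I/O makes small
variants prohibitive) and for everything in precise mode; vg giraffe
above 1 Gb genome size (strict, 1 Gb = 1e9 bp) else vg map; GraphTyper2
when read length > 130 bp *and* depth > 5×; PanGenie when depth < 5× *or*
read length < 130 bp; long reads replace all of this with GraphAligner
plus vg. At exactly 130 bp and 5× neither conditional rule fires — the
source rules are stated as strict inequalities in both directions and we
read them literally, so the boundary plan holds only the unconditional
tools. The subsampling fraction is `min(1, target_depth × genome_size /
total_bases)` with a 15× target; data below target depth is never
up-sampled.

# The synthetic data generator

The generator replaces the read-simulation + alignment + genotyping stack
at desk scale. It emulates exactly the statistical structure the merge
and evaluation modules consume:

* a uniform random A/C/G/T reference (GC ≈ 0.5);
* a truth set with exact per-class counts, sizes uniform in the
  configured ranges (1–49 bp indels, 50–500 bp SVs by default), placed
  non-overlapping with at least `min_spacing` (default 300 bp) between
  events — sparse enough that clusters and matchings are unambiguous,
  which is also the regime real SV truth sets live in;
* heterozygosity controlled by a single `het_fraction` (default 0.5):
  each variant lands on one random haplotype (0/1) with that probability,
  else on both (1/1), and the two haplotype sequences are actually built
  by applying the variants, so length bookkeeping is testable;
* per-tool error profiles: false-negative rate, genotype-error rate,
  rounded-Gaussian breakpoint and length jitter on SVs (the VCF
  representation is rebuilt so POS, alleles and END stay consistent),
  truncated-normal DP, and GQ drawn around separate means for correct and
  erroneous calls so threshold sweeps are informative. One base seed fans
  out to per-tool seeds, so adding a tool never perturbs earlier streams.

What it does *not* emulate: repeat-derived insertion sequence and
repeat-context effects (inserted bases are uniform random), sequencing
error profiles, alignment artefacts, false-positive calls at sites absent
from the truth set, and polyploidy. Passing tests therefore demonstrate
the correctness of the clustering/consensus/evaluation logic under
controlled noise — not performance on real genomes, where repeat content
and breakpoint uncertainty are the dominant difficulties.

# Numerical and degenerate-input choices

* Half-missing genotypes (`./1`) count as missing; missing never equals
  missing.
* Balanced multi-base substitutions (MNPs) fit none of the three classes
  and are dropped with a warning at parse time.
* Symbolic ALTs (`<DEL>`, `<INV>`, `<DUP>`) resolve against the reference
  via INFO/END; a symbolic allele without END (or `<INS>`, which has no
  recoverable sequence) is rejected and logged, as is any allele with
  characters outside `{A,C,G,T,N}` after upper-casing.
* MAF is computed over alleles of non-missing genotypes only; an
  all-missing site has undefined MAF and fails any MAF threshold. Filter
  thresholds keep inclusively (`MAF >= min_maf`,
  `missing <= max_missing_rate`); filtering is off by default.
* Precision is undefined (NA) when no calls exist, recall when no truth
  exists; F is NA whenever either component is.

# Problem sizes

The test suite and the acceptance script run entirely on generated data:
clustering equivalence on 100 random instances of up to 200 anchors and
3 tools; consensus rules enumerated exhaustively for 2–4 genotypers over
`{0/0, 0/1, 1/1, missing}`; and the end-to-end benchmark on a
1000-variant truth set (500 SNP, 200 indel, 100 DEL, 100 INS, 50 INV,
50 DUP) on a 500-kb reference with three tools at 10 % miss rate, 5 %
genotype-error rate and 5-bp jitter. These sizes give stable metrics
(binomial SEs of a few per mille on the pooled F-score) while keeping a
full run in tens of seconds.

# Known limitations

* Clustering is anchored on the input variant set; unconstrained
  all-vs-all merging of de novo call sets is out of scope.
* Sequence-resolved SV comparison (aligning ALT alleles) is not
  implemented; matching is coordinate- and size-based.
* One sample per merge; multi-sample joint genotyping and ploidy > 2 are
  not supported.
* BCF input, phasing and liftover are not supported.
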