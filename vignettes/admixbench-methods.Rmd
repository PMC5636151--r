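---
title: "Simulating admixed heterogeneous tumors and scoring SNV callers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating admixed heterogeneous tumors and scoring SNV callers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixbench)
```

## Why simulate

Scoring a somatic SNV caller requires knowing, for every site, whether a
variant is truly there and at what allele frequency. Clinical tumor data
never provides this: biopsies carry 0–90% non-cancerous cells, tumors are
subclonal mixtures, and curated low-frequency truth sets are scarce.
`admixbench` therefore constructs the data: it implants known variants
into a reference, builds a heterogeneous tumor out of subclonal genomes,
dilutes it with control material, simulates targeted reads, and scores any
callset against the exact truth. Everything a caller is judged on —
position, allele, origin, expected allele frequency — is known by
construction.

## The generative model

### Personal genomes

The diploid control genome is two independently edited haplotypes.
Heterozygous germline variants are placed on one parental lineage,
homozygous ones on both. Somatic variants are then added on top of the
germline haplotypes to form `n` maternal and `n` paternal cancer genomes
(default `n = 5`); each somatic variant enters each cancer genome
independently with inclusion probability `q` (default 0.5) and is re-drawn
until it is carried by at least one genome, so no truth variant is
silently absent from the tumor.

Edits are applied by exact string surgery with a per-contig coordinate
map: a ledger of (reference breakpoint, cumulative offset) pairs plus the
matched/inserted/deleted alignment blocks. The map answers two questions
that indels make non-trivial — where does reference position `p` sit on
this haplotype (or is it deleted), and what haplotype interval corresponds
to a capture target? Overlapping edits are rejected outright rather than
resolved: any resolution rule would make the truth ambiguous. Insertions
anchor after their position; deletions consume `[pos, pos + len)`.
Variants may not sit on an ambiguous (N) base.

### Mixtures and expected allele frequencies

Subclone weights come from a flat Dirichlet (uniform on the simplex) per
lineage — the least-informative choice for "randomized proportions"; any
other simplex law can be substituted by constructing the `clone_mixture`
directly. A sequenced fragment originates from the control genome with
probability `a` (the admixture), else picks a lineage with probability 1/2
and a subclone by its weight. This yields the closed form

$$\mathrm{AF}(a) = (1-a)\,\Big(\tfrac12\!\!\sum_{i \in M}\! w^M_i +
\tfrac12\!\!\sum_{j \in P}\! w^P_j\Big) + a\,\mathrm{AF}_{\mathrm{control}},$$

where $M, P$ are the carrier subclones. Germline variants are carried by
every cancer genome of their lineage(s), so their AF is admixture-
invariant (0.5 het, 1.0 hom); somatic AFs shrink linearly toward zero.
Admixture is capped at 0.95 so somatic alleles stay observable at
realistic depths. The default admixture series is 0, 0.1, ..., 0.9 — ten
tumor samples sharing one mixture, plus one control that serves them all.

A note on linear dilution: it treats admixture as a fraction of sequenced
*alleles*. It ignores copy-number differences between tumor and normal
cells, which in real data make the mapping from cell fraction to allele
fraction nonlinear; copy-number-aware AFs are out of scope.

### Read simulation

Fragments are drawn per sample: a capture target is chosen with
probability proportional to its (lifted) length, fragment length is
Normal(`insert_mean`, `insert_sd`) truncated at the read length, and the
fragment is placed uniformly among positions overlapping the lifted
target by at least one base — which produces the coverage shoulders that
flank real capture targets. Both ends are read inward `read_length` bases;
reverse-strand reads are reverse-complemented in FASTQ. Presets: exome —
100 bp reads, 300 ± 100 insert, 70× median target coverage; panel —
200 ± 50 insert, 520×. The fragment count is
`coverage * target_bases / (2 * read_length)`, so the realized median
on-target coverage approximates the request when intervals are long
relative to the insert; for intervals shorter than a few inserts the
flanks dominate and realized coverage falls below nominal, exactly as it
does for short capture targets.

Sequencing errors are injected per base at independent substitution,
insertion and deletion rates (defaults 1e-3, 1e-4, 1e-4 — placeholders in
a realistic range; the error-class structure, not the exact rates, is what
the analyses depend on). Base qualities follow a deterministic linear
decay (Q37 → Q30 across the read) and are cosmetic: the bundled caller
uses counts only. Every read also carries its truth alignment — reference
position and CIGAR obtained by composing the haplotype's alignment blocks
with the read's error walk — replacing an external aligner so the loop is
self-contained. Probe hybridization, GC bias, duplicates and
machine-specific quality profiles are deliberately not modeled; they
change *which* sites are covered in real data, not the allele-frequency
arithmetic the package exists to test.

### Baseline caller

The bundled caller is the simplest member of the count-test family: from
a nucleotide pileup (via Rsamtools) it reports a site when depth,
alt count and alt fraction clear thresholds and the one-sided binomial
tail $P(X \ge k \mid n, e)$ under the assumed error rate `e` falls below
`p_cutoff`. Ties between alt alleles break lexicographically. It is
intentionally not a re-implementation of any published tool; it exists so
that admixture experiments run end to end with zero external dependencies,
and as a reference point that any serious caller should beat.

### Evaluation

True positives are truth SNVs matched by at least one call; matching is
by position and allele by default (stricter than position-only, which is
also provided since published benchmarks often match on position alone).
Multi-allelic records are split before matching; calls outside target
regions are dropped; evaluation is restricted to SNV truth records —
indels exist in the data as confounders and are written (flagged) to the
truth VCF, but are not scored. Precision with zero calls is `NA`, not
zero, to avoid rewarding silent callers. Printed percentages use
round-half-up at one decimal, the convention that reproduces
benchmark-style reporting (e.g. 56,869/59,664 → 95.3%). Parameter sweeps
are reduced to one row per tool and admixture level by maximizing the
harmonic mean of sensitivity and precision, ties broken by sensitivity
then parameter id.

## Seeds and reproducibility

Every stochastic stage takes an explicit seed; `run_all()` derives one
seed per stage (and per sample) from a single master seed and a stage
label via a polynomial hash, so stages can be replayed independently and
the whole run — FASTQ bytes included — is a pure function of the master
seed. RNG state is saved and restored around every seeded computation, so
package calls do not perturb a user's session RNG.

## What the tests do and do not show

The test suite validates the machinery against independent oracles at
desk scale, not the performance of real callers at genome scale:

* implantation and coordinate lifting are checked against a marker-based
  string-surgery oracle on 1,000 random 10 kb edit sets;
* the evaluator is checked against a brute-force all-pairs matcher on
  1,000 random truth/callset pairs;
* expected allele frequencies are checked against Monte-Carlo
  haplotype-draw sampling, and simulated alt fractions against their
  binomial expectation (within 3 s.e. at ≥100× for ≥99% of sites,
  error-free reads);
* realized median coverage is checked within ±10% of the 70×/520×
  presets on a 50 kb fixture;
* the end-to-end admixture experiment uses a 20 kb genome, 8 capture
  intervals, 40 germline plus 120 somatic variants (an elevated somatic
  count, for the same reason small-panel studies simulate hypermutated
  tumors: stable false-negative statistics), 50× coverage, a 3-point
  caller grid and five seeded replicates of the ten-level series.

For the last experiment, "sensitivity declines with admixture" is asserted
statistically: the mean curve over replicates must decline strictly
between well-separated levels (0 → 0.3 → 0.6 → 0.9), must not rise at any
adjacent step by more than two standard errors of that step (the mean of
finitely many replicates of a strictly decreasing true curve is itself
monotone only up to sampling noise), and must lose more than half its
starting value by 90% admixture. Passing these tests shows the simulator's
allele-frequency and coverage structure is right and that caller scoring
is exact; it does not show that any particular real-data caller ranking
would be reproduced, since real data adds mapping artifacts, error
correlation and capture bias that the generator intentionally omits.

## Degenerate inputs and edge rules

Empty variant lists, empty truth sets and empty callsets are valid
(identity haplotype, header-only VCF, zero-count evaluation with `NA`
precision). An interval entirely inside a deletion lifts to an empty
interval; a fragment that cannot be placed inside its contig after ten
attempts is skipped with a warning; a read that aligns entirely inside an
inserted sequence is emitted as unmapped. AF histogram bins are left-open
right-closed on (0, 1] so AF = 1 lands in the last bin and bin edges fall
to the lower bin. Duplicate admixture levels, overlapping edits,
reference-allele mismatches and unknown contigs are fatal errors, not
warnings.

## Known limitations

No structural variants, copy-number events, or multi-nucleotide
substitutions; no phasing inference; no tumor-in-normal contamination of
the control; no probe-capture or GC bias; indels are simulated but not
scored. The two-sample mixing helper (`mix_two_genomes()`) covers the
reference-material validation design (e.g. 1:7 mixtures of two reference
genomes with discrete AFs) but the package does not ship wrappers that
execute external callers — it scores whatever VCFs they produce.
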