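---
title: "Microhaplotype markers, frequencies, and variation statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microhaplotype methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microhapr)
```

## Background

A microhaplotype (microhap) is a forensic DNA marker composed of two or
more SNPs within a short genomic span -- a few hundred bp at most -- whose
state is reported as the phased allelic combination (the haplotype) across
its component SNPs. Because the span fits inside a single sequencing read,
one read simultaneously genotypes each component SNP and phases them,
giving a multiallelic marker with substantially more discriminatory power
than the independent biallelic SNPs it is built from. Microhaps can be
ranked for individual identification (within-population diversity) or for
biogeographic ancestry inference (among-population differentiation), and
the same marker collection can serve both purposes if per-population
haplotype frequencies are available on a common set of populations.

`microhapr` implements the full small-data stack this work needs: a
portable plain-text database of marker definitions, population samples and
haplotype frequencies; estimation of those frequencies from phased
genotype panels; the three ranking statistics in standard use; marker
geometry; and query/amplicon tooling. A built-in simulator generates
phased panels from *known* haplotype distributions so that every operation
is testable against an exact oracle.

## The database model

A database directory holds three core tab-delimited tables --
`marker.tsv` (name, source, chromosome, comma-joined 1-based SNP
positions, the three summary statistics, comma-joined rsIDs),
`population.tsv` (ID, name, source), and `frequency.tsv` (marker,
population, haplotype, frequency, count) -- plus optional ancillary tables:
`idmap.tsv` (third-party identifiers), `variantmap.tsv` (rsID to marker),
and `sequence.tsv` (flanking sequence per marker, for amplicon design).
Everything is UTF-8, LF-terminated, header-rowed text: the database is
diffable, versionable, and importable into any analysis environment with
no server component.

Conventions worth making explicit:

* **Coordinates** are stored and displayed 1-based inclusive (the
  dbSNP/VCF convention); all internal interval arithmetic is 0-based
  half-open at the boundaries where it matters, and converted at the edge.
* **Haplotype strings** join one allele token per component SNP with
  commas (`"A,T,C"`). Deletion alleles use the token `del`; insertions use
  the full inserted string. Tokens are taken verbatim from VCF REF/ALT
  fields -- haplotypes are allele-combination strings, never 0/1 vectors,
  so multiallelic SNPs need no special handling.
* **Frequency sums.** Published tables are rounded (typically to 3
  decimals), so per-(marker, population) groups are required to sum to 1
  only within ±0.005 on load. Renormalization is never silent: it must be
  requested with `renormalize = TRUE`, preserving source fidelity by
  default.
* **Chromosome labels.** `"1"` and `"chr1"` are both accepted on input;
  `"chr"`-prefixed labels are emitted.
* **Merging sources** (`merge_sources()`) takes the union of records,
  collapses byte-identical definitions (joining their source labels), and
  -- when two sources use one name for *different* SNP sets, a situation
  that genuinely occurs when labs adjust published markers -- retains both
  definitions under suffixed names and reports the collision rather than
  guessing which is canonical. Output order is total and deterministic
  (chromosome, start, name), which makes the merge idempotent.

## Frequency estimation from phased panels

Given a phased VCF and a sample-to-population map
(`read_phased_panel()`), the estimator for one marker is deliberately
plain:

1. locate the marker's component variants in the panel, by rsID first and
   by (chromosome, position) as a fallback (warning when the two keys
   disagree);
2. for each individual, read the allele off each phase strand at each
   component SNP, in position order, and concatenate per strand -- two
   haplotypes for diploid calls, one for haploid male X calls;
3. tally haplotypes within each population;
4. divide each tally by the population's allele total (2 x diploid
   individuals + haploid individuals).

Per-population frequencies therefore sum to exactly 1 before any
rounding, and allele totals are conserved: their sum equals the summed
ploidies of the included individuals.

Two policy decisions deserve a note. First, an individual with *any*
missing or unphased component call is excluded from that marker entirely
and the denominator reduced -- a partial haplotype is not a haplotype, and
silently imputing a strand would bias low-frequency haplotypes. Exclusion
counts are reported per population. Second, male X ploidy is taken from
the genotype field itself (a haploid call), not from sex metadata; when
metadata is present it is cross-checked and disagreements produce a
warning, but the genotype wins, since the call is the datum. Markers with
any component variant absent from the panel are not estimated at all and
are listed in an exclusion report (`estimate_all()`), mirroring how rare
variants absent from a survey panel force whole markers out of an
analysis.

## The three ranking statistics

**Effective number of alleles** (`effective_number_of_alleles()`,
`mean_ae()`). For a frequency vector \(p\), \(A_e = 1 / \sum_i p_i^2\) --
the reciprocal of homozygosity. It is 1 exactly when a single haplotype is
observed and reaches the number of observed haplotypes exactly at the
uniform distribution. \(A_e\) is computed independently per population on
that population's own conditional distribution (haplotypes unseen in the
population contribute nothing, and the row is renormalized over its
nonzero entries), then summarized as the unweighted arithmetic mean over
populations; a query-time option reports a single population instead.

**Informativeness for assignment** (`informativeness()`). Rosenberg's
statistic over \(K\) populations and \(N\) haplotype alleles:

\[
I_n \;=\; \sum_{j=1}^{N}\Bigl(-\bar p_j \log \bar p_j
  \;+\; \sum_{i=1}^{K} \frac{p_{ij}}{K}\,\log p_{ij}\Bigr)
\]

with three numerical conventions fixed here: the logarithm is natural, so
the upper bound \(\log K\) is attained exactly in the disjoint-fixation
case (this matches the INFOCALC reference implementation); \(0 \log 0
\equiv 0\), the standard information-theoretic limit, required whenever an
allele is absent from a population; and \(\bar p_j\) is the *unweighted*
mean of \(p_{ij}\) across populations -- the display equation divides by
\(K\), not by sample sizes. \(I_n = 0\) iff all populations share one
frequency vector.

**Weir-Cockerham FST** (`fst_weir_cockerham()`). Each individual's two
marker haplotypes are treated as one diploid genotype at a multiallelic
locus. For each haplotype allele \(j\) (allele \(j\) versus all others)
the 1984 variance components \(a\) (among populations), \(b\) (among
individuals within populations) and \(c\) (within individuals) are
computed from per-population sample sizes, allele frequencies and observed
heterozygosities, giving \(\hat\theta_j = a/(a+b+c)\). The marker value
is, by default, the unweighted mean of \(\hat\theta_j\) over alleles with
a nonzero denominator ("averaged across all alleles"); because the
estimator's averaging convention is genuinely ambiguous in parts of the
literature, the ratio-of-sums alternative \(\sum_j a_j / \sum_j
(a+b+c)_j\) is available behind `method = "ratio"`. Negative per-allele
estimates are retained (they are part of the estimator's sampling
behavior, and truncation would bias means); nothing is clamped to
\([0,1]\). A marker monomorphic everywhere has no defined component and
yields `NA`. Haploid male X calls carry no genotypic heterozygosity and
are omitted from FST input.

**Geometry.** `marker_length()` is the inclusive span of the most distal
component variants (`max - min + 1` for SNVs; an indel's reference span
extends its end by `nchar(ref) - 1`).
`closest_nonoverlapping_distance()` reports, per marker, the bases
strictly between its span and the nearest same-chromosome marker whose
span does not intersect it (0 when abutting, `NA` when no such marker
exists). Physical distance is the package's only proxy for linkage;
no LD estimation is attempted. `marker_stats()` exposes the conventional
exclusion flags (X-chromosome markers; ultra-SNP-dense markers) used when
correlating the three statistics across a collection, since a few extreme
markers otherwise dominate such comparisons.

## The amplicon arithmetic

`amplicon_bounds()` starts from the marker span extended by `delta` bases
on each side; if still shorter than `min_length`, both sides are extended
as evenly as possible with the odd surplus base going right (a fixed
tie-break, so output is deterministic); the interval is then clipped to
`[1, chrom_length]` with the clipped deficit shifted to the opposite side.
The final length is exactly `max(span + 2*delta, min_length)` whenever the
chromosome can accommodate it. Defaults (`delta = 10`, `min_length = 80`
in the detail view) reflect typical short-amplicon design floors for
degraded-sample assays; both are user-set per call. When the amplicon is
cut from a stored flanking-sequence window rather than a whole
chromosome, the window bounds play the role of the chromosome bounds.

## The synthetic panel generator

`simulate_markers()` places non-overlapping markers on synthetic
chromosomes (SNP count and core span drawn from configurable ranges, span
endpoints always component SNPs), generates a uniform-random reference
with at least 500 bp of flank around every marker, and plants one
alternate base per SNP. `simulate_model()` draws, per marker, a set of
2-4 haplotypes consistent with the planted ref/alt alleles and a true
distribution per population: a marker-wide base distribution from a flat
Dirichlet, then each population from `Dirichlet(concentration * base)`.
The default `concentration = 10` produces moderate among-population
differentiation -- visibly population-specific frequencies without routine
fixation, the regime in which all three statistics are informative.
`simulate_panel()` draws each individual's two haplotypes (one for males
at X markers; default sex ratio 0.5) i.i.d. from the population's
distribution and emits a phased VCF v4.2 (GT-only, `|`-separated),
population map, marker table, reference FASTA, and the generating truth
table.

Randomness is organized as per-key substreams derived from the base seed
by hashing stream names ("marker:mh01SY-001", "panel:...", ...), so a
fixed seed gives byte-identical output files and adding markers to a
simulation never perturbs the draws of existing ones.

What the generator emulates: the *observation model* of a phased
population survey -- phased diploid autosomal records, haploid male X
records, population structure in haplotype frequencies, rare haplotypes.
What it deliberately does not emulate: linkage disequilibrium decay
within and between markers, mutation/coalescent history, genotyping and
phasing error, and relatedness. Consequently, passing tests demonstrate
correctness of the estimation and statistics machinery conditional on
correct phasing, not robustness to the error modes of real pipelines.

## Problem sizes and numerical tolerances in the test suite

The suite exercises the estimator at a survey-like scale chosen to keep a
full run in the low tens of seconds: the largest fixture uses 26
populations x 500 individuals x 20 markers (13,000 samples, ~60 variants)
and checks every estimated frequency against the generating truth on the
binomial-sampling scale, alongside exact X-chromosome allele-total
accounting (2 x females + males). Note that an "every cell within 3
standard errors" check across ~1,600 truth cells is expected to see a few
~3-sigma exceedances under the generating model itself (the per-cell
breach rate is ~0.27%); the strict form is retained deliberately and its
outcome should be read with that in mind. Estimator correctness is
separately pinned by exact-identity checks (inversion of the simulator,
conservation laws) and by oracle equivalence: the FST implementation is
required to match an independent scalar transcription of the 1984
formulas to 1e-10 across 200 random configurations, and the amplicon and
neighbor-distance operations must match brute-force oracles over
thousands of random inputs. Floating-point equalities on analytic
boundary values (Ae = 1 and 4, In = 0 and log K, FST = 1) are asserted at
1e-12.

## Known limitations

* Input panels must already be phased; no statistical phasing is
  performed or checked beyond the phase separator.
* FST is undefined (NA) for monomorphic markers and is computed from
  diploid individuals only.
* The database carries alternate-assembly coordinates as data when
  present but performs no liftover.
* Query selector resolution is deterministic but precedence-based
  (marker name, then third-party ID, then rsID, then source); a token
  that is simultaneously a marker name and an rsID resolves as a name.
* The detail-view layout is this package's own fixed format; it is
  stable for golden-file testing but not a rendering of any external
  tool's output.
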