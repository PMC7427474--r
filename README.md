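# microhapr

Tools for microhaplotype (microhap) forensic markers: a portable
plain-text marker/frequency database, estimation of per-population
haplotype frequencies from phased genotype panels, the standard
marker-ranking statistics, and amplicon/query utilities — plus a phased
panel simulator with known generating distributions for testing.

## The problem

A microhaplotype is a marker of two or more SNPs within a short genomic
span (≲ 300 bp) whose state is the phased allelic combination — the
haplotype — across its component SNPs. One sequencing read both genotypes
and phases the marker, yielding a compact multiallelic locus useful for
human identification, mixture deconvolution, and ancestry inference.
Working with collections of published microhaps requires consistent
frequency data across a common population set and consistent statistics
to rank markers by purpose. `microhapr` provides that stack for R users:
panel designers get a file-backed queryable database with amplicon
export, and population-survey analysts get the estimator and statistics.

## The statistics

For haplotype frequencies `p` within one population, the **effective
number of alleles** is the reciprocal of homozygosity,

    Ae = 1 / Σᵢ pᵢ²

(1 when a single haplotype is observed; per-marker summary is the
unweighted mean of per-population values). Among K populations with
allele frequencies `p_ij`, **Rosenberg's informativeness for assignment**
is

    In = Σⱼ ( −p̄ⱼ·log p̄ⱼ + Σᵢ (p_ij / K)·log p_ij )

with natural log, 0·log 0 ≡ 0, and p̄ⱼ the unweighted mean over
populations (0 when populations are identical, log K at disjoint
fixation). **FST** uses the Weir–Cockerham (1984) variance components
a, b, c computed per haplotype allele from diploid marker genotypes, with
per-allele estimates a/(a+b+c) averaged across alleles.

## Worked example

Simulate a 6-marker, 3-population phased panel, estimate frequencies from
its VCF, and annotate the database with statistics:

```r
library(microhapr)

sim   <- simulate_markers(6, seed = 7)
model <- simulate_model(sim, n_populations = 3, pop_size = 40, seed = 7)
out   <- simulate_panel(model)

panel <- read_phased_panel(out$paths["vcf"], out$paths["populations"])
res   <- estimate_all(panel, sim$markers)
db    <- mhdb(sim$markers, model$populations[, c("ID", "Name", "Source")],
              res$frequencies, sequences = sim_sequence_table(sim))
db    <- annotate_stats(db, panel = panel)

query_frequencies(db, marker = "mh01SY-001")
#>       Marker Population Allele Frequency Count
#> 1 mh01SY-001      POP01    A,A     0.075     6
#> 2 mh01SY-001      POP01    C,A     0.925    74
#> 3 mh01SY-001      POP02    A,A     0.050     4
#> 4 mh01SY-001      POP02    C,A     0.750    60
#> 5 mh01SY-001      POP02    C,G     0.200    16
#> 6 mh01SY-001      POP03    C,A     0.750    60
#> 7 mh01SY-001      POP03    C,G     0.250    20
```

Each row is one haplotype's relative frequency in one population sample;
counts are raw haplotype tallies and divide by the population's allele
total (80 here: 2 × 40 diploid individuals; X markers get 2·females +
males). The annotated marker table ranks markers:

```r
marker_stats(db)
#>         Name Chrom NSnps Length       Ae         In          Fst
#> 1 mh01SY-001  chr1     2     52 1.471332 0.08359957 0.0658025168
#> 2 mh01SY-004  chr1     4     21 2.161972 0.10257007 0.1130251522
#> 3 mh02SY-002  chr2     4    146 2.694217 0.01122239 0.0003158815
#> 4 mh02SY-005  chr2     3     46 3.333618 0.06166594 0.0337179236
#> 5 mh0XSY-003  chrX     2    127 1.495049 0.08761240 0.1117531378
#> 6 mh0XSY-006  chrX     4     96 2.445491 0.08416513 0.0553610810
```

`Ae` near 1 (mh01SY-001) means one haplotype dominates within
populations — weak for identification; higher `In`/`Fst` (mh01SY-004)
means more population-specific frequencies — better for ancestry
inference. `write_database(db, dir)` persists everything as tab-delimited
text, and `load_database(dir)` round-trips it.

A command-line wrapper over the same functions ships in
`inst/cli/microhapr`:

```sh
Rscript inst/cli/microhapr marker mh01SY-001 --db demodb --format detail
```

prints the fixed-layout detail block (SNP coordinates, core span,
amplicon sequence with SNP positions starred, observed haplotypes), and
`--format fasta` exports amplicons for third-party design tools.

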