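# Marker-ranking statistics and marker geometry.
#
# Three statistics are computed per marker from population haplotype
# frequencies:
#   * Ae, the effective number of alleles: the reciprocal of homozygosity,
#     1 / sum(p_i^2). Within-population diversity; proxy for identification
#     power. Computed per population and summarized as the unweighted mean.
#   * In, Rosenberg's informativeness for assignment over K populations:
#     In = sum_j( -pbar_j * log(pbar_j) + sum_i (p_ij / K) * log(p_ij) ),
#     natural logarithm, 0*log(0) == 0, pbar_j the unweighted mean of p_ij
#     over populations. Among-population differentiation; proxy for
#     ancestry-inference power. Bounded by [0, log K].
#   * FST, the Weir-Cockerham (1984) estimator computed per haplotype allele
#     (allele j vs. all others) from diploid marker genotypes, then averaged
#     over alleles with defined values.

#' Effective number of alleles
#'
#' The reciprocal of homozygosity, `1 / sum(p^2)`. Equals 1 iff a single
#' haplotype is observed, and equals `length(p)` iff all haplotypes are
#' equally frequent.
#'
#' @param p frequency vector (non-negative, summing to 1).
#' @param tol tolerance on `|sum(p) - 1|`.
#' @return A single number in `[1, length(p)]`.
#' @examples
#' effective_number_of_alleles(1)                        # 1
#' effective_number_of_alleles(rep(0.25, 4))             # 4
#' effective_number_of_alleles(c(0.5, 0.3, 0.2))         # 1/0.38
#' @export
effective_number_of_alleles <- function(p, tol = 1e-6) {
  p <- as.numeric(p)
  if (!length(p) || sum(p) == 0) stop("empty or zero-sum frequency vector")
  if (any(p < 0)) stop("negative frequency")
  if (abs(sum(p) - 1) > tol) {
    stop("frequencies sum to ", format(sum(p), digits = 8), ", not 1")
  }
  1 / sum(p^2)
}

#' Build a population-by-haplotype frequency matrix for one marker
#'
#' @param freqs frequency table in the `frequency.tsv` dialect (or an
#'   `mhdb`, whose frequency table is used).
#' @param marker marker name.
#' @param populations optional population ordering; defaults to the sorted
#'   populations present for the marker.
#' @return An object of class `mh_freqmat`: list with `marker`,
#'   `populations` (K), `haplotypes` (N), `p` (K x N matrix; rows sum to 1)
#'   and `counts` (K x N integer matrix, or `NULL` if counts are absent).
#' @export
frequency_matrix <- function(freqs, marker, populations = NULL) {
  if (inherits(freqs, "mhdb")) freqs <- freqs$frequencies
  fq <- freqs[freqs$Marker == marker, , drop = FALSE]
  if (!nrow(fq)) stop("no frequency records for marker '", marker, "'")
  pops <- populations %||% sort(unique(fq$Population))
  haps <- sort(unique(fq$Allele))
  p <- matrix(0, length(pops), length(haps), dimnames = list(pops, haps))
  p[cbind(match(fq$Population, pops), match(fq$Allele, haps))] <- fq$Frequency
  counts <- NULL
  if (!anyNA(fq$Count)) {
    counts <- matrix(0L, length(pops), length(haps), dimnames = list(pops, haps))
    counts[cbind(match(fq$Population, pops), match(fq$Allele, haps))] <- fq$Count
  }
  structure(list(marker = marker, populations = pops, haplotypes = haps,
                 p = p, counts = counts),
            class = "mh_freqmat")
}

#' Per-population and mean effective number of alleles
#'
#' Ae is computed independently for each population on that population's own
#' conditional frequency distribution (haplotypes unobserved in the
#' population contribute nothing; the row is renormalized over its nonzero
#' entries). The summary value is the unweighted arithmetic mean over
#' populations.
#'
#' @param m an `mh_freqmat` from [frequency_matrix()].
#' @return List with `by_population` (named numeric) and `mean`.
#' @export
mean_ae <- function(m) {
  stopifnot(inherits(m, "mh_freqmat"))
  by_pop <- apply(m$p, 1, function(row) {
    row <- row[row > 0]
    if (!length(row)) return(NA_real_)
    effective_number_of_alleles(row / sum(row))
  })
  list(by_population = by_pop, mean = mean(by_pop, na.rm = TRUE))
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Informativeness for assignment
#'
#' Rosenberg's In statistic for a marker with N haplotype alleles across K
#' populations, using the natural logarithm, the `0*log(0) == 0` convention,
#' and the unweighted mean allele frequency across populations. In is 0 when
#' all populations share identical frequencies and attains its maximum
#' `log(K)` when `N >= K` and no allele is shared between populations.
#'
#' @param m an `mh_freqmat` with `K >= 2` populations.
#' @return In, in nats.
#' @export
informativeness <- function(m) {
  stopifnot(inherits(m, "mh_freqmat"))
  p <- m$p
  K <- nrow(p)
  if (K < 2) stop("informativeness requires K >= 2 populations")
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 1e-6)) stop("frequency matrix rows must sum to 1")
  p <- p / rs  # remove harmless rounding drift
  pbar <- colMeans(p)
  sum(-xlogx(pbar)) + sum(xlogx(p)) / K
}

#' Per-individual marker diplotypes
#'
#' Collapses each included diploid individual's two marker haplotypes into
#' one genotype row, the input required by the Weir-Cockerham FST estimator.
#' Haploid (male X) calls have no genotypic heterozygosity and are omitted.
#'
#' @inheritParams tally_marker
#' @return Data frame with columns `Sample`, `Population`, `Hap1`, `Hap2`.
#' @export
marker_diplotypes <- function(panel, marker) {
  stopifnot(inherits(panel, "mh_panel"))
  mh <- marker_haplotypes(panel, marker)
  keep <- which(!mh$excluded & mh$ploidy == 2L)
  data.frame(
    Sample = panel$samples$Sample[keep],
    Population = panel$samples$Population[keep],
    Hap1 = vapply(mh$haps[keep], `[`, character(1), 1),
    Hap2 = vapply(mh$haps[keep], `[`, character(1), 2),
    stringsAsFactors = FALSE
  )
}

# Weir & Cockerham (1984) variance components for one allele.
# n: per-population counts of diploid individuals; p: per-population allele
# frequencies; h: per-population observed heterozygote proportions.
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Weir-Cockerham FST for a multiallelic marker
#'
#' Treats each individual's two marker haplotypes as one diploid genotype at
#' a multiallelic locus. For each haplotype allele j, the 1984 variance
#' components a, b, c are computed for allele j versus all others, giving a
#' per-allele estimate `a / (a + b + c)`. The marker value is the unweighted
#' mean of the per-allele estimates over alleles with a nonzero denominator
#' (`method = "mean"`, the default), or the ratio of summed components
#' `sum(a) / sum(a + b + c)` (`method = "ratio"`). Negative per-allele
#' estimates are retained; no clamping to `[0, 1]` is applied. A marker
#' monomorphic in all populations has no defined component and yields `NA`.
#'
#' @param diplotypes data frame with columns `Population`, `Hap1`, `Hap2`,
#'   one row per diploid individual (see [marker_diplotypes()]).
#' @param method `"mean"` (mean of per-allele ratios) or `"ratio"` (ratio of
#'   summed variance components).
#' @return FST estimate (scalar); per-allele estimates in attribute
#'   `"per_allele"`.
#' @export
fst_weir_cockerham <- function(diplotypes, method = c("mean", "ratio")) {
  method <- match.arg(method)
  d <- as.data.frame(diplotypes, stringsAsFactors = FALSE)
  stopifnot(all(c("Population", "Hap1", "Hap2") %in% names(d)))
  pops <- sort(unique(d$Population))
  r <- length(pops)
  if (r < 2) stop("FST requires K >= 2 populations")
  n <- as.numeric(table(factor(d$Population, pops)))
  if (mean(n) <= 1) {
    warning("fewer than 2 individuals per population on average; FST undefined")
    return(NA_real_)
  }
  alleles <- sort(unique(c(d$Hap1, d$Hap2)))
  popf <- factor(d$Population, pops)
  per_allele <- vapply(alleles, function(al) {
    dose <- (d$Hap1 == al) + (d$Hap2 == al)
    p <- tapply(dose, popf, sum) / (2 * n)
    h <- tapply(dose == 1L, popf, mean)
    comp <- wc_components(n, as.numeric(p), as.numeric(h))
    denom <- sum(comp)
    if (denom == 0) c(NA_real_, NA_real_) else c(comp[["a"]], denom)
  }, numeric(2))
  a <- per_allele[1, ]
  denom <- per_allele[2, ]
  defined <- !is.na(denom)
  if (!any(defined)) return(structure(NA_real_, per_allele = stats::setNames(a / denom, alleles)))
  theta <- stats::setNames(a / denom, alleles)
  est <- if (method == "mean") mean(theta[defined]) else sum(a[defined]) / sum(denom[defined])
  structure(est, per_allele = theta)
}

#' Core marker length
#'
#' The number of nucleotides spanning a marker's most distal component
#' variants, inclusive. For single-nucleotide variants this is
#' `max(pos) - min(pos) + 1`; indel variants extend the span by their
#' reference-allele length (`end = pos + nchar(ref) - 1`).
#'
#' @param marker marker definition (see [as_marker()]).
#' @param ref_lengths optional integer vector of reference-allele lengths,
#'   parallel to the marker's positions (default: all 1, i.e. SNVs).
#' @return Span in bp.
#' @export
marker_length <- function(marker, ref_lengths = NULL) {
  marker <- as_marker(marker)
  rl <- ref_lengths %||% rep(1L, length(marker$positions))
  stopifnot(length(rl) == length(marker$positions))
  max(marker$positions + rl - 1L) - min(marker$positions) + 1L
}

marker_spans <- function(markers) {
  if (inherits(markers, "mhdb")) markers <- markers$markers
  if (is.data.frame(markers)) {
    pos <- int_csv(markers$Offsets)
    data.frame(Name = markers$Name, Chrom = norm_chrom(markers$Chrom),
               Start = vapply(pos, min, integer(1)),
               End = vapply(pos, max, integer(1)),
               stringsAsFactors = FALSE)
  } else {
    defs <- lapply(markers, as_marker)
    data.frame(Name = vapply(defs, `[[`, character(1), "name"),
               Chrom = vapply(defs, `[[`, character(1), "chrom"),
               Start = vapply(defs, function(d) min(d$positions), integer(1)),
               End = vapply(defs, function(d) max(d$positions), integer(1)),
               stringsAsFactors = FALSE)
  }
}

#' Distance to the closest non-overlapping marker
#'
#' For each marker, the number of bases strictly between its span and the
#' span of the nearest same-chromosome marker that does not overlap it
#' (0 when the two spans abut). Overlap means the two spans share at least
#' one position. Markers alone on their chromosome, or overlapping every
#' other marker there, get `NA`.
#'
#' @param markers an `mhdb`, marker table, or list of marker definitions.
#' @return Named numeric vector of distances (bp), `NA` where undefined.
#' @export
closest_nonoverlapping_distance <- function(markers) {
  sp <- marker_spans(markers)
  out <- stats::setNames(rep(NA_real_, nrow(sp)), sp$Name)
  for (ch in unique(sp$Chrom)) {
    idx <- which(sp$Chrom == ch)
    if (length(idx) < 2) next
    s <- sp$Start[idx]
    e <- sp$End[idx]
    for (k in seq_along(idx)) {
      gap_left <- s[k] - e - 1   # others entirely to the left
      gap_right <- s - e[k] - 1  # others entirely to the right
      gaps <- pmax(gap_left, gap_right)
      gaps[k] <- NA              # self
      gaps[gaps < 0] <- NA       # overlapping spans (share >= 1 position)
      if (any(!is.na(gaps))) out[idx[k]] <- min(gaps, na.rm = TRUE)
    }
  }
  out
}

#' Annotate a database with variation statistics
#'
#' Fills the `Ae` (mean over populations), `In` and `Fst` columns of the
#' marker table from the database's frequency table (and, for FST, from
#' per-individual diplotypes read out of a phased panel). Markers without
#' frequency data keep missing values; In needs at least two populations
#' with data; FST is computed only when `panel` is supplied and the marker's
#' variants are all present in it.
#'
#' @param db an `mhdb` whose frequency table is populated.
#' @param panel optional `mh_panel` supplying diplotypes for FST.
#' @param fst_method passed to [fst_weir_cockerham()].
#' @return `db` with updated marker statistic columns.
#' @export
annotate_stats <- function(db, panel = NULL, fst_method = "mean") {
  stopifnot(inherits(db, "mhdb"))
  mk <- db$markers
  for (i in seq_len(nrow(mk))) {
    name <- mk$Name[i]
    if (!any(db$frequencies$Marker == name)) next
    m <- frequency_matrix(db$frequencies, name)
    mk$Ae[i] <- mean_ae(m)$mean
    mk$In[i] <- if (length(m$populations) >= 2) informativeness(m) else NA_real_
    if (!is.null(panel)) {
      def <- marker_def(db, name)
      idx <- suppressWarnings(match_variants(panel, def))
      if (!anyNA(idx)) {
        d <- marker_diplotypes(panel, def)
        if (nrow(d) && length(unique(d$Population)) >= 2) {
          mk$Fst[i] <- as.numeric(fst_weir_cockerham(d, method = fst_method))
        }
      }
    }
  }
  db$markers <- mk
  db
}

#' Marker statistics table for correlation-style analyses
#'
#' Returns the annotated marker table with optional exclusion of
#' X-chromosome markers and of ultra-long / SNP-dense markers, the filters
#' conventionally applied before comparing Ae, In and FST across a marker
#' collection (a handful of unusually long, highly polymorphic markers
#' otherwise dominate).
#'
#' @param db annotated `mhdb`.
#' @param exclude_x drop chrX markers.
#' @param max_snps drop markers with more component SNPs than this.
#' @return Data frame with `Name`, `Chrom`, `NSnps`, `Length`, `Ae`, `In`,
#'   `Fst`.
#' @export
marker_stats <- function(db, exclude_x = FALSE, max_snps = Inf) {
  stopifnot(inherits(db, "mhdb"))
  mk <- db$markers
  pos <- int_csv(mk$Offsets)
  out <- data.frame(
    Name = mk$Name, Chrom = mk$Chrom,
    NSnps = lengths(pos),
    Length = vapply(pos, function(p) max(p) - min(p) + 1L, integer(1)),
    Ae = mk$Ae, In = mk$In, Fst = mk$Fst,
    stringsAsFactors = FALSE
  )
  if (exclude_x) out <- out[out$Chrom != "chrX", , drop = FALSE]
  out[out$NSnps <= max_snps, , drop = FALSE]
}
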