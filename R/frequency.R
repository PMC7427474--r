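# Estimation of per-population microhaplotype frequencies from phased
# genotype panels. The procedure mirrors the standard population-survey
# workflow: retrieve the phased genotype records for a marker's component
# variants, read each individual's haplotype(s) off the phase strands,
# tally haplotypes by population, and normalize each tally by the
# population's allele total. Autosomal (and female X) samples contribute two
# haplotypes; haploid male X calls contribute one.

#' Read a phased genotype panel
#'
#' Loads a phased VCF (GT fields with `|` separators; haploid calls allowed
#' on chrX for males) together with a sample-to-population mapping, into the
#' panel object consumed by the frequency-estimation operations.
#'
#' @param vcf path to a VCF file (plain or bgzipped), parsed with
#'   [vcfR::read.vcfR()].
#' @param popmap either a 2-column data frame (sample, population) or a path
#'   to a headerless (or `Sample`/`Population`-headed) 2-column TSV.
#' @param sex optional named character vector (`"M"`/`"F"` per sample) used
#'   only to cross-check ploidy of X-chromosome calls; ploidy itself is
#'   always taken from the genotype field.
#' @return An object of class `mh_panel`: list with `samples` (data frame
#'   `Sample`, `Population`, `Sex`), `variants` (data frame `RSID`, `Chrom`,
#'   `Pos`, `Ref`, `Alt`) and `gt` (character matrix, variants x samples).
#' @export
read_phased_panel <- function(vcf, popmap, sex = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  variants <- data.frame(
    RSID = fix[, "ID"],
    Chrom = norm_chrom(fix[, "CHROM"]),
    Pos = as.integer(fix[, "POS"]),
    Ref = fix[, "REF"],
    Alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  rownames(gt) <- NULL
  if (is.character(popmap) && length(popmap) == 1) {
    pm <- utils::read.delim(popmap, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
    if (nrow(pm) && tolower(pm[1, 1]) %in% c("sample", "sampleid")) pm <- pm[-1, , drop = FALSE]
    popmap <- data.frame(Sample = pm[[1]], Population = pm[[2]], stringsAsFactors = FALSE)
  } else {
    popmap <- as.data.frame(popmap, stringsAsFactors = FALSE)
    names(popmap)[1:2] <- c("Sample", "Population")
  }
  samples <- colnames(gt)
  idx <- match(samples, popmap$Sample)
  if (anyNA(idx)) {
    stop("sample(s) in VCF without population assignment: ",
         paste(utils::head(samples[is.na(idx)], 5), collapse = ", "))
  }
  sx <- rep(NA_character_, length(samples))
  if (!is.null(sex)) sx <- unname(sex[samples])
  structure(
    list(
      samples = data.frame(Sample = samples, Population = popmap$Population[idx],
                           Sex = sx, stringsAsFactors = FALSE),
      variants = variants,
      gt = gt
    ),
    class = "mh_panel"
  )
}

#' @export
print.mh_panel <- function(x, ...) {
  cat("phased panel:", ncol(x$gt), "samples,", nrow(x$variants), "variants,",
      length(unique(x$samples$Population)), "populations\n")
  invisible(x)
}

# Locate a marker's component variants in the panel registry: by rsID first,
# then by (chromosome, position); warn when both keys are present but point
# at different records.
match_variants <- function(panel, marker) {
  marker <- as_marker(marker)
  vr <- panel$variants
  idx <- match(marker$rsids, vr$RSID)
  poskey <- paste(vr$Chrom, vr$Pos)
  pidx <- match(paste(marker$chrom, marker$positions), poskey)
  mismatch <- !is.na(idx) & !is.na(pidx) & idx != pidx
  if (any(mismatch)) {
    warning("marker '", marker$name, "': rsID and (chrom, pos) disagree for ",
            paste(marker$rsids[mismatch], collapse = ", "), "; using rsID match")
  }
  idx[is.na(idx)] <- pidx[is.na(idx)]
  idx
}

# Vectorized haplotype readout for every sample at one marker.
# Returns list(haps = per-sample list of haplotype strings (length 2, 1, or
# 0 when excluded), ploidy, excluded, reasons).
marker_haplotypes <- function(panel, marker) {
  marker <- as_marker(marker)
  idx <- match_variants(panel, marker)
  if (anyNA(idx)) {
    stop("marker '", marker$name, "': component variant(s) absent from panel: ",
         paste(marker$rsids[is.na(idx)], collapse = ", "))
  }
  ord <- order(marker$positions)
  idx <- idx[ord]
  G <- panel$gt[idx, , drop = FALSE]
  v <- nrow(G)
  s <- ncol(G)

  miss <- is.na(G) | G == "." | grepl(".", G, fixed = TRUE)
  unph <- !miss & grepl("/", G, fixed = TRUE)
  dipl <- !miss & !unph & grepl("|", G, fixed = TRUE)
  hapl <- !miss & !unph & !dipl

  n_dip <- colSums(dipl)
  n_hap <- colSums(hapl)
  ploidy <- ifelse(n_dip == v, 2L, ifelse(n_hap == v, 1L, NA_integer_))
  any_miss <- colSums(miss) > 0
  any_unph <- colSums(unph) > 0
  excluded <- any_miss | any_unph | is.na(ploidy)
  reasons <- ifelse(any_miss, "missing call",
             ifelse(any_unph, "unphased genotype",
             ifelse(is.na(ploidy), "inconsistent ploidy", NA_character_)))

  if (any(any_unph)) {
    warning("marker '", marker$name, "': ", sum(any_unph),
            " sample(s) excluded for unphased genotypes")
  }
  # haploid calls only make sense for X-chromosome males
  if (any(ploidy == 1L, na.rm = TRUE) && !marker$chrom %in% c("chrX", "chrY")) {
    warning("marker '", marker$name, "': haploid call(s) on autosome; sample(s) excluded")
    excluded <- excluded | (!is.na(ploidy) & ploidy == 1L)
  }
  sx <- panel$samples$Sex
  if (marker$chrom == "chrX" && !all(is.na(sx))) {
    clash <- !is.na(sx) & !is.na(ploidy) &
      ((sx == "F" & ploidy == 1L) | (sx == "M" & ploidy == 2L))
    if (any(clash)) {
      warning("marker '", marker$name, "': X ploidy disagrees with sex metadata for ",
              paste(panel$samples$Sample[clash], collapse = ", "),
              "; genotype ploidy used")
    }
  }

  a1 <- matrix(sub("[|/].*$", "", G), v, s)
  a2 <- matrix(ifelse(dipl, sub("^[^|/]*[|/]", "", G), NA_character_), v, s)
  tokens <- mapply(function(r, a) c(r, strsplit(a, ",", fixed = TRUE)[[1]]),
                   panel$variants$Ref[idx], panel$variants$Alt[idx],
                   SIMPLIFY = FALSE, USE.NAMES = FALSE)
  tok_at <- function(A) {
    out <- matrix(NA_character_, v, s)
    for (i in seq_len(v)) {
      ai <- suppressWarnings(as.integer(A[i, ])) + 1L
      out[i, ] <- tokens[[i]][ai]
    }
    out
  }
  T1 <- tok_at(a1)
  T2 <- tok_at(a2)
  hap1 <- do.call(paste, c(lapply(seq_len(v), function(i) T1[i, ]), list(sep = ",")))
  hap2 <- do.call(paste, c(lapply(seq_len(v), function(i) T2[i, ]), list(sep = ",")))

  haps <- vector("list", s)
  for (j in seq_len(s)) {
    haps[[j]] <- if (excluded[j]) character(0)
      else if (ploidy[j] == 2L) c(hap1[j], hap2[j])
      else hap1[j]
  }
  names(haps) <- colnames(G)
  list(haps = haps, ploidy = ploidy, excluded = excluded, reasons = reasons)
}

#' Read one individual's haplotypes at a marker
#'
#' Aggregates the sample's phased genotypes across the marker's component
#' variants, in position order, pairing alleles by phase strand. A diploid
#' sample (autosome, or female X) yields two haplotype strings; a haploid
#' male X call yields one. A sample with any missing or unphased component
#' call is excluded entirely (a partial haplotype is not a haplotype) and
#' yields `character(0)`.
#'
#' @param panel an `mh_panel`.
#' @param marker marker definition (see [as_marker()]).
#' @param sample sample identifier.
#' @return Character vector of comma-joined haplotype strings.
#' @examples
#' # a sample phased 0|1 then 1|0 at a 2-SNP marker (ref A/C, alt G/T)
#' # yields haplotypes "A,T" and "G,C"
#' @export
extract_individual_haplotypes <- function(panel, marker, sample) {
  stopifnot(inherits(panel, "mh_panel"))
  if (!sample %in% colnames(panel$gt)) stop("unknown sample: ", sample)
  mh <- marker_haplotypes(panel, marker)
  mh$haps[[sample]]
}

#' Tally marker haplotypes by population
#'
#' Reads every individual's haplotypes at `marker` and counts them within
#' the individual's population. The per-population allele total (the
#' frequency denominator) is the number of haplotypes contributed:
#' 2 x (included diploid samples) + (included haploid male X samples).
#' Populations with no samples are omitted.
#'
#' @inheritParams extract_individual_haplotypes
#' @return An object of class `mh_tally`: list with `marker`, `counts`
#'   (data frame `Population`, `Allele`, `Count`), `totals` (named integer
#'   vector of allele totals) and `excluded` (named integer vector of
#'   excluded-individual counts per population).
#' @export
tally_marker <- function(panel, marker) {
  stopifnot(inherits(panel, "mh_panel"))
  marker <- as_marker(marker)
  mh <- marker_haplotypes(panel, marker)
  pops <- panel$samples$Population
  nh <- lengths(mh$haps)
  df <- data.frame(
    Population = rep(pops, nh),
    Allele = unlist(mh$haps, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    counts <- as.data.frame(table(df$Population, df$Allele), stringsAsFactors = FALSE)
    names(counts) <- c("Population", "Allele", "Count")
    counts <- counts[counts$Count > 0, , drop = FALSE]
    counts <- counts[order(counts$Population, counts$Allele, method = "radix"), , drop = FALSE]
    rownames(counts) <- NULL
    totals <- tapply(counts$Count, counts$Population, sum)
    totals <- stats::setNames(as.integer(totals), names(totals))
  } else {
    counts <- data.frame(Population = character(0), Allele = character(0),
                         Count = integer(0), stringsAsFactors = FALSE)
    totals <- stats::setNames(integer(0), character(0))
  }
  excl <- tapply(mh$excluded, pops, sum)
  excl <- stats::setNames(as.integer(excl), names(excl))
  structure(list(marker = marker$name, counts = counts, totals = totals,
                 excluded = excl),
            class = "mh_tally")
}

#' @export
print.mh_tally <- function(x, ...) {
  cat("haplotype tally for", x$marker, "-", length(x$totals), "population(s),",
      sum(x$counts$Count), "haplotypes\n")
  invisible(x)
}

#' Estimate haplotype frequencies from a tally
#'
#' Normalizes each population's haplotype tally by that population's allele
#' total. Frequencies within a population sum to exactly 1 before any
#' rounding. Populations with a zero allele total are skipped with a
#' warning.
#'
#' @param tally an `mh_tally` from [tally_marker()].
#' @return Data frame in the `frequency.tsv` dialect (`Marker`,
#'   `Population`, `Allele`, `Frequency`, `Count`).
#' @export
estimate_frequencies <- function(tally) {
  stopifnot(inherits(tally, "mh_tally"))
  counts <- tally$counts
  tot <- tally$totals[counts$Population]
  zero <- names(tally$totals)[tally$totals == 0]
  if (length(zero)) {
    warning("marker '", tally$marker, "': zero allele total for population(s) ",
            paste(zero, collapse = ", "), "; skipped")
    keep <- !counts$Population %in% zero
    counts <- counts[keep, , drop = FALSE]
    tot <- tot[keep]
  }
  out <- data.frame(
    Marker = rep(tally$marker, nrow(counts)),
    Population = counts$Population,
    Allele = counts$Allele,
    Frequency = counts$Count / as.numeric(tot),
    Count = counts$Count,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Estimate frequencies for a set of markers
#'
#' Runs the tally-and-normalize procedure for every marker whose component
#' variants are all present in the panel. Markers with at least one
#' component variant absent from the panel (e.g. rare variants not genotyped
#' in the survey) are excluded from estimation and listed in the report.
#'
#' @param panel an `mh_panel`.
#' @param markers an `mhdb`, a marker table, or a list of marker
#'   definitions.
#' @return List with `frequencies` (combined frequency table) and
#'   `excluded` (data frame `Marker`, `MissingRSIDs`).
#' @export
estimate_all <- function(panel, markers) {
  if (inherits(markers, "mhdb")) markers <- markers$markers
  defs <- if (is.data.frame(markers)) {
    lapply(seq_len(nrow(markers)), function(i) as_marker(markers[i, , drop = FALSE]))
  } else {
    lapply(markers, as_marker)
  }
  freq <- list()
  excl <- list()
  for (m in defs) {
    idx <- suppressWarnings(match_variants(panel, m))
    if (anyNA(idx)) {
      excl[[length(excl) + 1L]] <- data.frame(
        Marker = m$name,
        MissingRSIDs = paste(m$rsids[is.na(idx)], collapse = ","),
        stringsAsFactors = FALSE
      )
      next
    }
    freq[[length(freq) + 1L]] <- estimate_frequencies(tally_marker(panel, m))
  }
  frequencies <- if (length(freq)) do.call(rbind, freq) else empty_frequency_table()
  excluded <- if (length(excl)) {
    do.call(rbind, excl)
  } else {
    data.frame(Marker = character(0), MissingRSIDs = character(0),
               stringsAsFactors = FALSE)
  }
  list(frequencies = sort_frequencies(frequencies), excluded = excluded)
}
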