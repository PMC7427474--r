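# Synthetic fixtures: marker panels, reference sequences, and phased
# multi-population genotype panels drawn from known haplotype
# distributions. The generator emulates the shape of a phased population
# survey (diploid autosomal records, haploid male X records, a
# sample-to-population mapping) without any coalescent or LD realism:
# per-population haplotype distributions are specified directly and each
# individual's haplotypes are drawn i.i.d. from them, so the generating
# distribution is an exact oracle for everything downstream.
#
# All randomness flows through per-key substreams derived from the base
# seed (see substream_seed), so adding markers to a simulation never
# perturbs the draws of existing ones, and a fixed seed gives byte-identical
# output files.

BASES <- c("A", "C", "G", "T")

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, size, ...) x[sample.int(length(x), size, ...)]

#' Simulate microhaplotype marker definitions and a reference
#'
#' Places non-overlapping markers on synthetic chromosomes, assigns each
#' marker a SNP count and core span drawn from the given ranges (the span's
#' first and last positions are always component SNPs, so the core length
#' is exactly the drawn span), generates a random reference sequence
#' covering every marker plus at least `flank` bases on each side, and
#' plants one alternate base per SNP.
#'
#' @param n_markers number of markers.
#' @param snp_range integer range (min, max) of component SNPs per marker.
#' @param length_range integer range of core marker lengths, bp.
#' @param chromosomes chromosome labels to cycle through; `"chrX"` markers
#'   exercise haploid male handling downstream.
#' @param flank reference bases guaranteed on each side of every marker.
#' @param gap_range range of gaps between consecutive markers on a
#'   chromosome, bp.
#' @param seed base seed.
#' @return An object of class `mh_sim`: list with `markers` (marker table),
#'   `variants` (data frame `RSID`, `Chrom`, `Pos`, `Ref`, `Alt`),
#'   `reference` (named character vector of chromosome sequences) and
#'   `seed`.
#' @export
simulate_markers <- function(n_markers, snp_range = c(2, 4),
                             length_range = c(10, 150),
                             chromosomes = c("chr1", "chr2", "chrX"),
                             flank = 500, gap_range = c(300, 2000),
                             seed = 42) {
  stopifnot(n_markers >= 1, snp_range[1] >= 2, length_range[1] >= 2,
            snp_range[1] <= snp_range[2], length_range[1] <= length_range[2])
  if (length_range[2] < snp_range[2]) {
    stop("infeasible ranges: maximum core length ", length_range[2],
         " cannot hold ", snp_range[2], " SNPs")
  }
  chromosomes <- norm_chrom(chromosomes)
  chrom_of <- chromosomes[(seq_len(n_markers) - 1L) %% length(chromosomes) + 1L]
  cursor <- stats::setNames(rep(as.integer(flank), length(chromosomes)), chromosomes)

  rows <- vector("list", n_markers)
  vars <- vector("list", n_markers)
  rs_counter <- 0L
  for (i in seq_len(n_markers)) {
    ch <- chrom_of[i]
    code <- sub("^chr", "", ch)
    if (code %in% as.character(1:9)) code <- paste0("0", code)
    if (code %in% c("X", "Y")) code <- paste0("0", code)
    name <- sprintf("mh%sSY-%03d", code, i)
    set.seed(substream_seed(seed, paste0("marker:", name)))
    nsnp <- resample(snp_range[1]:snp_range[2], 1)
    lmin <- max(length_range[1], nsnp)
    len <- resample(lmin:length_range[2], 1)
    gap <- resample(gap_range[1]:gap_range[2], 1)
    start <- cursor[ch] + gap
    # first and last SNP anchor the span; interior SNPs are distinct
    inner <- if (nsnp > 2 && len > 2) sort(sample(seq_len(len - 2), nsnp - 2)) else integer(0)
    pos <- as.integer(start + c(0L, inner, len - 1L))
    cursor[ch] <- pos[length(pos)]
    rsids <- sprintf("rs9%08d", rs_counter + seq_along(pos))
    rs_counter <- rs_counter + length(pos)
    rows[[i]] <- data.frame(
      Name = name, Source = "synthetic", Chrom = ch,
      Offsets = paste(pos, collapse = ","),
      Ae = NA_real_, In = NA_real_, Fst = NA_real_,
      RSIDs = paste(rsids, collapse = ","),
      stringsAsFactors = FALSE
    )
    vars[[i]] <- data.frame(RSID = rsids, Chrom = ch, Pos = pos,
                            Ref = NA_character_, Alt = NA_character_,
                            stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, rows)
  variants <- do.call(rbind, vars)

  chrom_len <- cursor + as.integer(flank)
  reference <- vapply(chromosomes, function(ch) {
    set.seed(substream_seed(seed, paste0("ref:", ch)))
    paste(sample(BASES, chrom_len[ch], replace = TRUE), collapse = "")
  }, character(1))

  variants$Ref <- substring(reference[variants$Chrom], variants$Pos, variants$Pos)
  for (i in seq_len(n_markers)) {
    set.seed(substream_seed(seed, paste0("alt:", markers$Name[i])))
    idx <- which(variants$RSID %in% split_csv(markers$RSIDs[i])[[1]])
    variants$Alt[idx] <- vapply(variants$Ref[idx],
                                function(r) sample(setdiff(BASES, r), 1),
                                character(1))
  }
  structure(list(markers = sort_markers(markers), variants = variants,
                 reference = reference, seed = seed),
            class = "mh_sim")
}

# Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Build a generating model over simulated markers
#'
#' Chooses, per marker, a set of haplotypes consistent with the planted
#' ref/alt alleles, and a true haplotype distribution for each population.
#' Distributions are drawn hierarchically: a marker-wide base distribution
#' from a flat Dirichlet, then each population's distribution from
#' `Dirichlet(concentration * base)`, so `concentration` tunes how strongly
#' populations differentiate (small = strong differentiation, large =
#' nearly identical populations).
#'
#' @param sim an `mh_sim` from [simulate_markers()].
#' @param n_populations number of populations.
#' @param pop_size diploid individuals per population (scalar or vector).
#' @param hap_range range of distinct haplotypes per marker.
#' @param concentration Dirichlet concentration tying populations to the
#'   marker-wide base distribution.
#' @param sex_ratio probability that an individual is male (haploid on
#'   chrX).
#' @param seed base seed (defaults to the simulation's seed).
#' @return An object of class `mh_model`: list with `sim`, `populations`
#'   (data frame `ID`, `Name`, `Source`, `Size`), `distributions` (named
#'   list: marker -> K x H matrix of true haplotype frequencies, rows =
#'   populations), `sex_ratio`, `seed`.
#' @export
simulate_model <- function(sim, n_populations = 4, pop_size = 50,
                           hap_range = c(2, 4), concentration = 10,
                           sex_ratio = 0.5, seed = NULL) {
  stopifnot(inherits(sim, "mh_sim"), n_populations >= 1, hap_range[1] >= 2)
  seed <- seed %||% sim$seed
  pops <- data.frame(
    ID = sprintf("POP%02d", seq_len(n_populations)),
    Name = sprintf("Simulated population %02d", seq_len(n_populations)),
    Source = "synthetic",
    Size = rep_len(as.integer(pop_size), n_populations),
    stringsAsFactors = FALSE
  )
  dists <- list()
  for (i in seq_len(nrow(sim$markers))) {
    name <- sim$markers$Name[i]
    rsids <- split_csv(sim$markers$RSIDs[i])[[1]]
    vi <- match(rsids, sim$variants$RSID)
    set.seed(substream_seed(seed, paste0("model:", name)))
    nsnp <- length(vi)
    H <- resample(hap_range[1]:min(hap_range[2], 2^nsnp), 1)
    # haplotypes are ref/alt combinations across the component SNPs
    if (nsnp <= 20) {
      combos <- resample(0:(2^nsnp - 1), H)
      bits <- vapply(combos, function(cid) {
        bitwAnd(bitwShiftR(cid, seq_len(nsnp) - 1L), 1L)
      }, integer(nsnp))
    } else {
      # too many combinations to enumerate; rejection-sample distinct ones
      bits <- matrix(integer(0), nsnp, 0)
      while (ncol(bits) < H) {
        cand <- matrix(sample(0:1, nsnp * H, replace = TRUE), nsnp)
        bits <- cbind(bits, cand)
        bits <- bits[, !duplicated(apply(bits, 2, paste, collapse = "")), drop = FALSE]
      }
      bits <- bits[, seq_len(H), drop = FALSE]
    }
    haps <- apply(bits, 2, function(b) {
      paste(ifelse(b == 1L, sim$variants$Alt[vi], sim$variants$Ref[vi]),
            collapse = ",")
    })
    base <- rdirichlet1(rep(1, H))
    p <- t(vapply(seq_len(n_populations),
                  function(k) rdirichlet1(concentration * base),
                  numeric(H)))
    dimnames(p) <- list(pops$ID, haps)
    dists[[name]] <- p
  }
  structure(list(sim = sim, populations = pops, distributions = dists,
                 sex_ratio = sex_ratio, seed = seed),
            class = "mh_model")
}

#' True generating frequencies as a frequency table
#'
#' @param model an `mh_model`.
#' @return Data frame `Marker`, `Population`, `Allele`, `Frequency` (the
#'   generating distributions, for use as a test oracle).
#' @export
model_truth <- function(model) {
  stopifnot(inherits(model, "mh_model"))
  out <- lapply(names(model$distributions), function(nm) {
    p <- model$distributions[[nm]]
    data.frame(
      Marker = nm,
      Population = rep(rownames(p), times = ncol(p)),
      Allele = rep(colnames(p), each = nrow(p)),
      Frequency = as.vector(p),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$Marker, out$Population, out$Allele, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a phased multi-population genotype panel
#'
#' Draws each individual's two marker haplotypes (one for males at chrX
#' markers) i.i.d. from the individual's population distribution, with
#' consistent strand assignment across a marker's component SNPs, and
#' writes the panel as a set of plain-text files:
#' `panel.vcf` (VCF v4.2, GT-only, `|`-phased), `populations.tsv`
#' (sample-to-population map), `markers.tsv`, `reference.fasta`, and
#' `truth.tsv` (the generating distributions). Reading the files back with
#' [read_phased_panel()] and [extract_individual_haplotypes()] inverts the
#' simulation exactly.
#'
#' @param model an `mh_model` from [simulate_model()].
#' @param dir output directory (created; defaults to a fresh tempdir).
#' @return Invisibly, a list with `dir`, `paths` (named file paths),
#'   `samples` (data frame `Sample`, `Population`, `Sex`), `draws` (named
#'   list: marker -> 2 x n_samples character matrix of drawn haplotypes,
#'   second row `NA` for haploid calls) and `truth`.
#' @export
simulate_panel <- function(model, dir = tempfile("mhpanel")) {
  stopifnot(inherits(model, "mh_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- model$sim
  pops <- model$populations

  set.seed(substream_seed(model$seed, "samples"))
  samples <- do.call(rbind, lapply(seq_len(nrow(pops)), function(k) {
    n <- pops$Size[k]
    data.frame(
      Sample = sprintf("%s_S%04d", pops$ID[k], seq_len(n)),
      Population = pops$ID[k],
      Sex = sample(c("M", "F"), n, replace = TRUE,
                   prob = c(model$sex_ratio, 1 - model$sex_ratio)),
      stringsAsFactors = FALSE
    )
  }))
  ns <- nrow(samples)
  popf <- factor(samples$Population, pops$ID)

  draws <- list()
  gt <- matrix(NA_character_, nrow(sim$variants), ns,
               dimnames = list(sim$variants$RSID, samples$Sample))
  for (i in seq_len(nrow(sim$markers))) {
    name <- sim$markers$Name[i]
    chrom <- sim$markers$Chrom[i]
    p <- model$distributions[[name]]
    haps <- colnames(p)
    set.seed(substream_seed(model$seed, paste0("panel:", name)))
    h1 <- character(ns)
    h2 <- character(ns)
    for (k in seq_len(nrow(pops))) {
      j <- which(popf == pops$ID[k])
      pick <- sample(haps, 2 * length(j), replace = TRUE, prob = p[k, ])
      h1[j] <- pick[seq_along(j)]
      h2[j] <- pick[length(j) + seq_along(j)]
    }
    haploid <- chrom == "chrX" & samples$Sex == "M"
    h2[haploid] <- NA_character_
    draws[[name]] <- rbind(h1, h2)
    colnames(draws[[name]]) <- samples$Sample

    rsids <- split_csv(sim$markers$RSIDs[i])[[1]]
    vi <- match(rsids, sim$variants$RSID)
    tok1 <- matrix(unlist(strsplit(h1, ",", fixed = TRUE)), nrow = length(vi))
    a1 <- matrix(ifelse(tok1 == sim$variants$Ref[vi], "0", "1"), nrow = length(vi))
    a2 <- matrix("", length(vi), ns)
    dip <- !haploid
    if (any(dip)) {
      tok2 <- matrix(unlist(strsplit(h2[dip], ",", fixed = TRUE)), nrow = length(vi))
      a2[, dip] <- ifelse(tok2 == sim$variants$Ref[vi], "0", "1")
    }
    g <- matrix(paste0(a1, ifelse(rep(dip, each = length(vi)), "|", ""), a2),
                nrow = length(vi))
    gt[vi, ] <- g
  }

  ord <- order(chrom_rank(sim$variants$Chrom), sim$variants$Pos, method = "radix")
  vr <- sim$variants[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]

  paths <- c(
    vcf = file.path(dir, "panel.vcf"),
    populations = file.path(dir, "populations.tsv"),
    markers = file.path(dir, "markers.tsv"),
    reference = file.path(dir, "reference.fasta"),
    truth = file.path(dir, "truth.tsv")
  )

  con <- file(paths["vcf"], open = "wb")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=microhapr_simulate_panel",
    sprintf("##contig=<ID=%s,length=%d>", names(sim$reference),
            nchar(sim$reference)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples$Sample), collapse = "\t")
  ), con, sep = "\n")
  body <- paste(vr$Chrom, vr$Pos, vr$RSID, vr$Ref, vr$Alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con, sep = "\n")
  close(con)

  write_tsv(samples[, c("Sample", "Population")], paths["populations"])
  mk <- sim$markers
  for (cl in c("Ae", "In", "Fst")) mk[[cl]] <- fmt_stat(mk[[cl]])
  write_tsv(mk, paths["markers"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$reference),
                              paths["reference"])
  truth <- model_truth(model)
  tt <- truth
  tt$Frequency <- fmt_freq(tt$Frequency)
  write_tsv(tt, paths["truth"])

  invisible(list(dir = dir, paths = paths, samples = samples, draws = draws,
                 truth = truth))
}

#' Sequence table for simulated markers
#'
#' Extracts, from a simulation's reference, the flanking sequence window
#' around each marker (span plus `flank` bases each side, clipped to the
#' chromosome), in the `sequence.tsv` dialect consumed by the amplicon and
#' detail-view operations.
#'
#' @param sim an `mh_sim`.
#' @param flank flanking bases each side of the core span.
#' @return Data frame `Marker`, `Start`, `Sequence`.
#' @export
sim_sequence_table <- function(sim, flank = 500) {
  stopifnot(inherits(sim, "mh_sim"))
  sp <- marker_spans(sim$markers)
  start <- pmax(1L, sp$Start - as.integer(flank))
  end <- pmin(nchar(sim$reference[sp$Chrom]), sp$End + as.integer(flank))
  data.frame(
    Marker = sp$Name,
    Start = start,
    Sequence = substring(sim$reference[sp$Chrom], start, end),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mh_sim <- function(x, ...) {
  cat("simulated marker set:", nrow(x$markers), "markers on",
      length(x$reference), "chromosome(s)\n")
  invisible(x)
}

#' @export
print.mh_model <- function(x, ...) {
  cat("generating model:", nrow(x$sim$markers), "markers,",
      nrow(x$populations), "populations,",
      sum(x$populations$Size), "individuals\n")
  invisible(x)
}
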