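# Shared fixtures (built in code) and independent oracles.

fixture_sequence <- function(len, seed, at = integer(0), bases = character(0)) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  for (i in seq_along(at)) substr(s, at[i], at[i]) <- bases[i]
  s
}

# Three markers (two overlapping on chr1, sharing rs1003), two populated
# populations plus one without frequency data, a deletion-token haplotype,
# ancillary idmap/variantmap/sequence tables.
make_fixture_db <- function() {
  markers <- data.frame(
    Name = c("mh01SY-001", "mh01SY-002", "mh02SY-003"),
    Source = c("StudyA", "StudyA", "StudyB"),
    Chrom = c("chr1", "chr1", "chr2"),
    Offsets = c("101,110,120", "115,130", "5000,5349"),
    Ae = NA_real_, In = NA_real_, Fst = NA_real_,
    RSIDs = c("rs1001,rs1002,rs1003", "rs1003,rs1004", "rs1005,rs1006"),
    stringsAsFactors = FALSE
  )
  populations <- data.frame(
    ID = c("P1", "P2", "P3"),
    Name = c("Pop One", "Pop Two", "Pop Three"),
    Source = c("StudyA", "StudyB", "StudyB"),
    stringsAsFactors = FALSE
  )
  frequencies <- data.frame(
    Marker = c(rep("mh01SY-001", 3), rep("mh01SY-002", 2), rep("mh01SY-001", 2)),
    Population = c(rep("P1", 5), rep("P2", 2)),
    Allele = c("A,C,G", "A,C,T", "G,C,T", "C,G", "C,del", "A,C,G", "G,C,T"),
    Frequency = c(0.5, 0.3, 0.2, 0.6, 0.4, 0.45, 0.55),
    Count = c(50L, 30L, 20L, 60L, 40L, 45L, 55L),
    stringsAsFactors = FALSE
  )
  idmap <- data.frame(ID = c("SA-1", "SB-3"),
                      Name = c("mh01SY-001", "mh02SY-003"),
                      stringsAsFactors = FALSE)
  variantmap <- data.frame(
    RSID = c("rs1001", "rs1002", "rs1003", "rs1003", "rs1004", "rs1005", "rs1006"),
    Marker = c("mh01SY-001", "mh01SY-001", "mh01SY-001", "mh01SY-002",
               "mh01SY-002", "mh02SY-003", "mh02SY-003"),
    stringsAsFactors = FALSE
  )
  sequences <- data.frame(
    Marker = c("mh01SY-001", "mh02SY-003"),
    Start = c(1L, 4900L),
    Sequence = c(
      fixture_sequence(240, seed = 11, at = c(101, 110, 120), bases = c("A", "C", "G")),
      fixture_sequence(550, seed = 12)
    ),
    stringsAsFactors = FALSE
  )
  mhdb(markers, populations, frequencies, idmap = idmap,
       variantmap = variantmap, sequences = sequences)
}

# Hand-written 4-variant phased VCF: an autosomal 2-SNP marker and an
# X-chromosome 2-SNP marker; one male (haploid X), one female, and one
# sample with an unphased autosomal call and a missing X call.
make_tiny_panel <- function(dir = tempfile("tinypanel")) {
  dir.create(dir, showWarnings = FALSE)
  vcf <- file.path(dir, "panel.vcf")
  row <- function(...) paste(c(...), collapse = "\t")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    row("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
        "S1", "S2", "S3"),
    row("chr1", "100", "rsA", "A", "G", ".", "PASS", ".", "GT", "0|1", "0|0", "0|0"),
    row("chr1", "150", "rsB", "C", "T", ".", "PASS", ".", "GT", "1|0", "0|0", "0/1"),
    row("chrX", "200", "rsC", "A", "G", ".", "PASS", ".", "GT", "1", "0|1", "."),
    row("chrX", "250", "rsD", "C", "T", ".", "PASS", ".", "GT", "0", "1|1", "0|0")
  ), vcf)
  popmap <- file.path(dir, "pops.tsv")
  writeLines(c("S1\tP1", "S2\tP1", "S3\tP2"), popmap)
  panel <- read_phased_panel(vcf, popmap, sex = c(S1 = "M", S2 = "F", S3 = "F"))
  list(
    panel = panel,
    M1 = as_marker(list(name = "mh01TT-001", chrom = "chr1",
                        positions = c(100, 150), rsids = c("rsA", "rsB"))),
    MX = as_marker(list(name = "mh0XTT-002", chrom = "chrX",
                        positions = c(200, 250), rsids = c("rsC", "rsD"))),
    vcf = vcf, popmap = popmap
  )
}

freqmat <- function(p, marker = "m") {
  K <- nrow(p)
  structure(list(marker = marker,
                 populations = sprintf("P%02d", seq_len(K)),
                 haplotypes = sprintf("H%02d", seq_len(ncol(p))),
                 p = `dimnames<-`(p, list(sprintf("P%02d", seq_len(K)),
                                          sprintf("H%02d", seq_len(ncol(p))))),
                 counts = NULL),
            class = "mh_freqmat")
}

# Independent line-by-line transcription of the Weir & Cockerham (1984)
# variance-component formulas (r*nbar algebraic arrangement, scalar loops),
# used as the oracle for fst_weir_cockerham.
wc_fst_oracle <- function(d, method = "mean") {
  pops <- sort(unique(d$Population))
  r <- length(pops)
  alleles <- sort(unique(c(d$Hap1, d$Hap2)))
  thetas <- numeric(0)
  num <- den <- numeric(0)
  for (al in alleles) {
    n <- p <- h <- numeric(r)
    for (i in seq_len(r)) {
      rows <- d[d$Population == pops[i], , drop = FALSE]
      n[i] <- nrow(rows)
      dose <- (rows$Hap1 == al) + (rows$Hap2 == al)
      p[i] <- sum(dose) / (2 * n[i])
      h[i] <- mean(dose == 1)
    }
    nbar <- sum(n) / r
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (a + b + cc != 0) {
      thetas <- c(thetas, a / (a + b + cc))
      num <- c(num, a)
      den <- c(den, a + b + cc)
    }
  }
  if (!length(thetas)) return(NA_real_)
  if (method == "mean") mean(thetas) else sum(num) / sum(den)
}

# Random diplotype configurations for FST oracle-equivalence checks.
random_diplotypes <- function(K, N, n_range = c(5, 20)) {
  alleles <- LETTERS[seq_len(N)]
  rows <- lapply(seq_len(K), function(k) {
    n <- sample(n_range[1]:n_range[2], 1)
    w <- stats::rgamma(N, shape = 1)
    data.frame(
      Population = sprintf("P%02d", k),
      Hap1 = sample(alleles, n, replace = TRUE, prob = w),
      Hap2 = sample(alleles, n, replace = TRUE, prob = w),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# One-base-at-a-time amplicon oracle: extend right then left until
# min_length is reached, then clip and shift.
amplicon_oracle <- function(first, last, delta, min_length, chrom_length) {
  s <- first - delta
  e <- last + delta
  while (e - s + 1 < min_length) {
    e <- e + 1
    if (e - s + 1 < min_length) s <- s - 1
  }
  if (s < 1) {
    e <- min(e + (1 - s), chrom_length)
    s <- 1
  }
  if (e > chrom_length) {
    s <- max(1, s - (e - chrom_length))
    e <- chrom_length
  }
  c(s, e)
}

# All-pairs closest non-overlapping neighbor oracle.
neighbor_oracle <- function(spans) {
  out <- rep(NA_real_, nrow(spans))
  for (i in seq_len(nrow(spans))) {
    best <- Inf
    for (j in seq_len(nrow(spans))) {
      if (i == j || spans$Chrom[i] != spans$Chrom[j]) next
      overlap <- spans$Start[j] <= spans$End[i] && spans$End[j] >= spans$Start[i]
      if (overlap) next
      gap <- if (spans$Start[j] > spans$End[i]) {
        spans$Start[j] - spans$End[i] - 1
      } else {
        spans$Start[i] - spans$End[j] - 1
      }
      best <- min(best, gap)
    }
    if (is.finite(best)) out[i] <- best
  }
  out
}
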