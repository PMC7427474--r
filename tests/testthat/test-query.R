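# Query surface: selectors, regions, amplicon arithmetic, FASTA, detail.

test_that("selectors resolve by name, third-party id, rsID, and source", {
  db <- make_fixture_db()
  expect_identical(query_markers(db, "mh01SY-001")$Name, "mh01SY-001")
  expect_identical(query_markers(db, "SA-1")$Name, "mh01SY-001")
  # an rsID shared by two overlapping markers returns both
  expect_setequal(query_markers(db, "rs1003")$Name, c("mh01SY-001", "mh01SY-002"))
  expect_identical(query_markers(db, "StudyB")$Name, "mh02SY-003")
  expect_message(res <- query_markers(db, "rs404"), "no markers found")
  expect_identical(nrow(res), 0L)
})

test_that("region queries return exactly the intersecting markers", {
  db <- make_fixture_db()
  expect_setequal(query_markers(db, region = "chr1")$Name,
                  c("mh01SY-001", "mh01SY-002"))
  expect_identical(query_markers(db, region = "chr1:118-125")$Name,
                   c("mh01SY-001", "mh01SY-002"))
  expect_identical(query_markers(db, region = "chr1:121-300")$Name, "mh01SY-002")
  expect_message(res <- query_markers(db, region = "chr1:1-10"), "no markers")
  expect_identical(nrow(res), 0L)
  # exhaustive brute-force check on a larger simulated marker set
  sim <- simulate_markers(30, chromosomes = c("chr1", "chr2"), seed = 3)
  db2 <- mhdb(sim$markers, data.frame(ID = "P1", Name = "p", Source = "s"),
              empty_frequency_table())
  set.seed(99)
  for (rep in 1:40) {
    ch <- sample(c("chr1", "chr2"), 1)
    s <- sample(1:30000, 1)
    e <- s + sample(0:5000, 1)
    got <- suppressMessages(query_markers(db2, region = sprintf("%s:%d-%d", ch, s, e)))$Name
    pos <- lapply(strsplit(sim$markers$Offsets, ","), as.integer)
    want <- sim$markers$Name[sim$markers$Chrom == ch &
                               vapply(pos, min, 1L) <= e &
                               vapply(pos, max, 1L) >= s]
    expect_setequal(got, want)
  }
})

test_that("query results are stable under permutation of table rows", {
  db <- make_fixture_db()
  db2 <- db
  db2$markers <- db$markers[c(3, 1, 2), ]
  db2$frequencies <- db$frequencies[sample(nrow(db$frequencies)), ]
  expect_identical(query_markers(db, region = "chr1"),
                   query_markers(db2, region = "chr1"))
  expect_identical(query_frequencies(db, marker = "mh01SY-001"),
                   query_frequencies(db2, marker = "mh01SY-001"))
  expect_identical(population_detail(db, "P1"), population_detail(db2, "P1"))
})

test_that("region strings parse in the genome-browser dialect", {
  expect_identical(parse_region("chr5:100-200"),
                   list(chrom = "chr5", start = 100L, end = 200L))
  expect_identical(parse_region("5")$chrom, "chr5")
  expect_identical(parse_region("chrX:1000")$end, NA_integer_)
  expect_error(parse_region("chr5:200-100"), "exceeds")
  expect_error(parse_region("banana"), "malformed")
})

test_that("amplicon bounds extend, pad to min_length, and clip with deficit shift", {
  mk <- function(s, e) as_marker(list(name = "mh01XX-1", chrom = "chr1",
                                      positions = c(s, e), rsids = c("r1", "r2")))
  expect_identical(amplicon_bounds(mk(1000, 1050), 25, 0, 1e6), c(975L, 1075L))
  expect_identical(amplicon_bounds(mk(1000, 1050), 0, 61, 1e6), c(995L, 1055L))
  # left clip pushes the deficit right, preserving span + 2*delta
  expect_identical(amplicon_bounds(mk(10, 20), 25, 0, 10000), c(1L, 61L))
  # odd surplus base goes right
  expect_identical(amplicon_bounds(mk(1000, 1050), 0, 62, 1e6), c(995L, 1056L))
  # brute-force contract check over random tuples
  set.seed(17)
  for (rep in 1:150) {
    first <- sample(1:5000, 1)
    last <- first + sample(0:300, 1) + 1L
    delta <- sample(0:200, 1)
    minlen <- sample(0:600, 1)
    clen <- max(last, sample(1:6000, 1))
    got <- amplicon_bounds(mk(first, last), delta, minlen, clen)
    expect_identical(got, as.integer(amplicon_oracle(first, last, delta, minlen, clen)))
    expect_gte(got[1], 1L)
    expect_lte(got[2], clen)
    if (clen >= max(last - first + 1 + 2 * delta, minlen)) {
      expect_identical(got[2] - got[1] + 1L,
                       as.integer(max(last - first + 1 + 2 * delta, minlen)))
    }
  }
})

test_that("FASTA export parses and honors the amplicon length contract", {
  db <- make_fixture_db()
  fa <- markers_to_fasta(db, delta = 10, min_length = 60)
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(fa, tf, sep = "")
  recs <- Biostrings::readDNAStringSet(tf)
  expect_length(recs, 2)
  expect_true(all(Biostrings::width(recs) >= 60))
  # sequence lengths equal the amplicon intervals re-derived from headers
  for (i in seq_along(recs)) {
    hdr <- names(recs)[i]
    rng <- regmatches(hdr, regexec("(chr[0-9X]+):([0-9]+)-([0-9]+)", hdr))[[1]]
    expect_identical(Biostrings::width(recs)[i],
                     as.integer(rng[4]) - as.integer(rng[3]) + 1L)
  }
  # the base under each SNP offset matches an allele seen in the haplotypes
  av <- amplicon_view(db, "mh01SY-001", delta = 10, min_length = 60)
  toks <- strsplit(av$haplotypes, ",")
  for (k in seq_along(av$offsets)) {
    base <- substr(av$sequence, av$offsets[k] + 1, av$offsets[k] + 1)
    expect_true(base %in% unique(vapply(toks, `[`, "", k)))
  }
  expect_identical(markers_to_fasta(db, names = character(0)), "")
})

test_that("marker detail view renders a deterministic block", {
  db <- make_fixture_db()
  txt <- render_marker_detail(db, "mh01SY-001", delta = 5, min_length = 0)
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[2], "mh01SY-001    3-SNP microhaplotype marker (source: StudyA)")
  expect_true("Chromosome:  chr1" %in% lines)
  expect_true("Core span:   chr1:101-120 (20 bp)" %in% lines)
  expect_true(any(grepl("rs1002  chr1:110", lines)))
  expect_true(any(grepl("Amplicon \\(chr1:96-125, 30 bp", lines)))
  expect_true("  A,C,G" %in% lines)
  # the amplicon sequence is the stored window's bases 96..125
  seqrow <- db$sequences$Sequence[db$sequences$Marker == "mh01SY-001"]
  expect_true(substr(seqrow, 96, 125) %in% lines)
  # rendering is reproducible
  expect_identical(render_marker_detail(db, "mh01SY-001", delta = 5, min_length = 0), txt)
  # marker without frequency data reports no observed haplotypes
  txt3 <- render_marker_detail(db, "mh02SY-003", delta = 5, min_length = 0)
  expect_true(grepl("none observed", txt3))
  # a marker without a stored sequence still renders, with a warning
  db2 <- db
  db2$sequences <- db$sequences[0, ]
  expect_warning(txt4 <- render_marker_detail(db2, "mh01SY-001"), "without sequence")
  expect_true(grepl("Core span", txt4))
  expect_false(grepl("Amplicon", txt4))
})

test_that("increasing delta changes only the amplicon section of the detail", {
  db <- make_fixture_db()
  strip_seq <- function(txt) {
    lines <- strsplit(txt, "\n")[[1]]
    amp <- grep("^Amplicon", lines)
    hap <- grep("^Observed haplotypes", lines)
    c(lines[seq_len(amp - 1)], lines[hap:length(lines)])
  }
  a <- render_marker_detail(db, "mh01SY-001", delta = 5, min_length = 0)
  b <- render_marker_detail(db, "mh01SY-001", delta = 20, min_length = 0)
  expect_false(identical(a, b))
  expect_identical(
    sub("Amplicon.*", "", strip_seq(a)), sub("Amplicon.*", "", strip_seq(b)))
})

test_that("population detail counts markers and observed haplotypes", {
  db <- make_fixture_db()
  d <- population_detail(db, "P1")
  expect_identical(d$n_markers, 2L)
  expect_identical(d$n_haplotypes, 5L)
  empty <- population_detail(db, "P3")
  expect_identical(empty$n_markers, 0L)
  expect_identical(empty$n_haplotypes, 0L)
  expect_message(expect_null(population_detail(db, "P99")), "no population")
})
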