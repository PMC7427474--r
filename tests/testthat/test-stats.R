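# Variation statistics: Ae, In, Weir-Cockerham FST, and marker geometry.

test_that("effective number of alleles has the analytic boundary values", {
  expect_identical(effective_number_of_alleles(1.0), 1)
  expect_identical(effective_number_of_alleles(rep(0.25, 4)), 4)
  expect_equal(effective_number_of_alleles(c(0.5, 0.3, 0.2)), 1 / 0.38,
               tolerance = 1e-12)
  expect_error(effective_number_of_alleles(numeric(0)), "empty")
  expect_error(effective_number_of_alleles(c(0, 0)), "zero-sum")
  expect_error(effective_number_of_alleles(c(0.5, 0.4)), "not 1")
})

test_that("Ae is bounded by [1, N] and invariant to haplotype relabeling", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    p <- as.numeric(stats::rgamma(n, 1))
    p <- p / sum(p)
    ae <- effective_number_of_alleles(p)
    expect_gte(ae, 1)
    expect_lte(ae, n + 1e-12)
    expect_equal(effective_number_of_alleles(sample(p)), ae, tolerance = 1e-12)
  }
})

test_that("mean Ae averages per-population values computed on own distributions", {
  m <- freqmat(rbind(c(1, 0), c(0.5, 0.5)))
  res <- mean_ae(m)
  expect_equal(unname(res$by_population), c(1, 2))
  expect_equal(res$mean, 1.5)
  # identical rows: mean equals the row value; K = 1 degenerate mean
  m2 <- freqmat(rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)))
  expect_equal(mean_ae(m2)$mean, 1 / 0.38, tolerance = 1e-12)
  m3 <- freqmat(matrix(c(0.7, 0.3), 1))
  expect_equal(mean_ae(m3)$mean, 1 / 0.58, tolerance = 1e-12)
})

test_that("informativeness matches its analytic boundary and hand values", {
  # identical frequency vectors in all populations -> 0
  m0 <- freqmat(rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)))
  expect_equal(informativeness(m0), 0, tolerance = 1e-12)
  # K populations fixed for disjoint alleles -> log K
  expect_equal(informativeness(freqmat(rbind(c(1, 0), c(0, 1)))), log(2),
               tolerance = 1e-12)
  expect_equal(informativeness(freqmat(diag(3))), log(3), tolerance = 1e-12)
  # frozen hand evaluation of the display equation, term by term
  m <- freqmat(rbind(c(0.8, 0.2), c(0.2, 0.8)))
  expect_equal(informativeness(m), 0.192744757021757, tolerance = 1e-9)
  expect_error(informativeness(freqmat(matrix(c(0.5, 0.5), 1))), "K >= 2")
})

test_that("In lies in [0, log K] and is invariant under joint permutation", {
  set.seed(7)
  for (rep in 1:25) {
    K <- sample(2:5, 1)
    N <- sample(2:6, 1)
    p <- matrix(stats::rgamma(K * N, 1), K)
    p <- p / rowSums(p)
    v <- informativeness(freqmat(p))
    expect_gte(v, -1e-12)
    expect_lte(v, log(K) + 1e-12)
    v2 <- informativeness(freqmat(p[sample(K), sample(N), drop = FALSE]))
    expect_equal(v2, v, tolerance = 1e-12)
  }
})

test_that("FST is 1 for populations fixed on different haplotypes and NA when monomorphic", {
  d <- data.frame(Population = rep(c("P1", "P2"), each = 20),
                  Hap1 = rep(c("A,A", "C,C"), each = 20),
                  Hap2 = rep(c("A,A", "C,C"), each = 20))
  expect_equal(as.numeric(fst_weir_cockerham(d)), 1, tolerance = 1e-12)
  mono <- data.frame(Population = rep(c("P1", "P2"), each = 10),
                     Hap1 = "A,A", Hap2 = "A,A")
  expect_true(is.na(fst_weir_cockerham(mono)))
})

test_that("FST matches an independent transcription of the 1984 formulas", {
  # the spec-style two-population count configuration: 30/10 vs 10/30
  d <- data.frame(
    Population = rep(c("P1", "P2"), each = 20),
    Hap1 = c(rep("A", 15), rep("B", 5), rep("A", 5), rep("B", 15)),
    Hap2 = c(rep("A", 15), rep("B", 5), rep("A", 5), rep("B", 15))
  )
  expect_equal(as.numeric(fst_weir_cockerham(d)), wc_fst_oracle(d),
               tolerance = 1e-12)
  het <- data.frame(
    Population = rep(c("P1", "P2"), each = 20),
    Hap1 = rep("A", 40),
    Hap2 = c(rep("A", 10), rep("B", 10), rep("B", 20))
  )
  expect_equal(as.numeric(fst_weir_cockerham(het)), wc_fst_oracle(het),
               tolerance = 1e-12)
  expect_equal(as.numeric(fst_weir_cockerham(het, method = "ratio")),
               wc_fst_oracle(het, method = "ratio"), tolerance = 1e-12)
  # negative per-allele estimates are retained, not clamped
  set.seed(31)
  for (rep in 1:20) {
    d <- random_diplotypes(K = sample(2:4, 1), N = sample(2:5, 1))
    expect_equal(as.numeric(fst_weir_cockerham(d)), wc_fst_oracle(d),
                 tolerance = 1e-10)
  }
})

test_that("marker length spans the most distal variants inclusive", {
  mk <- function(pos) as_marker(list(name = "mh01XX-1", chrom = "chr1",
                                     positions = pos,
                                     rsids = paste0("rs", seq_along(pos))))
  expect_identical(marker_length(mk(c(100, 103))), 4L)
  expect_identical(marker_length(mk(c(100, 120, 449))), 350L)
  expect_identical(marker_length(mk(c(7, 8))), 2L)
  # an indel's reference span extends the marker end
  expect_identical(marker_length(mk(c(100, 110)), ref_lengths = c(1L, 4L)), 14L)
})

test_that("closest non-overlapping neighbor distances follow the gap arithmetic", {
  mk <- function(name, chrom, s, e) {
    as_marker(list(name = name, chrom = chrom, positions = c(s, e),
                   rsids = c("rsa", "rsb")))
  }
  d <- closest_nonoverlapping_distance(list(mk("a", "chr1", 100, 200),
                                            mk("b", "chr1", 350, 400)))
  expect_equal(unname(d), c(149, 149))
  # an overlapping marker is skipped in favor of the nearest disjoint one
  d <- closest_nonoverlapping_distance(list(mk("a", "chr1", 100, 200),
                                            mk("b", "chr1", 150, 250),
                                            mk("c", "chr1", 400, 500)))
  expect_equal(unname(d["a"]), 400 - 200 - 1)
  expect_equal(unname(d["b"]), 400 - 250 - 1)
  # abutting spans are 0 apart; a marker alone on its chromosome has none
  d <- closest_nonoverlapping_distance(list(mk("a", "chr1", 100, 200),
                                            mk("b", "chr1", 201, 300),
                                            mk("c", "chr2", 10, 20)))
  expect_equal(unname(d), c(0, 0, NA))
})

test_that("annotate_stats fills marker statistic columns from frequencies", {
  db <- make_fixture_db()
  db2 <- annotate_stats(db)
  i <- match("mh01SY-001", db2$markers$Name)
  m <- frequency_matrix(db2$frequencies, "mh01SY-001")
  expect_equal(db2$markers$Ae[i], mean_ae(m)$mean)
  expect_equal(db2$markers$In[i], informativeness(m))
  # per-population Ae is the Ae of that population's own frequency row
  expect_equal(unname(mean_ae(m)$by_population["P1"]),
               effective_number_of_alleles(c(0.5, 0.3, 0.2)))
  # a single-population marker gets Ae but no In; no frequencies, no stats
  j <- match("mh01SY-002", db2$markers$Name)
  expect_false(is.na(db2$markers$Ae[j]))
  expect_true(is.na(db2$markers$In[j]))
  k <- match("mh02SY-003", db2$markers$Name)
  expect_true(is.na(db2$markers$Ae[k]))
  expect_true("mh02SY-003" %in% db2$markers$Name)  # row retained
})

test_that("marker_stats applies the X-chromosome and SNP-count exclusion flags", {
  sim <- simulate_markers(6, snp_range = c(2, 5), seed = 9)
  db <- mhdb(sim$markers,
             data.frame(ID = "P1", Name = "p", Source = "s"),
             empty_frequency_table())
  st <- marker_stats(db, exclude_x = TRUE)
  expect_false(any(st$Chrom == "chrX"))
  st2 <- marker_stats(db, max_snps = 3)
  expect_true(all(st2$NSnps <= 3))
})

test_that("In and FST correlate positively across simulated markers", {
  sim <- simulate_markers(40, chromosomes = c("chr1", "chr2"), seed = 2024)
  model <- simulate_model(sim, n_populations = 4, pop_size = 60,
                          concentration = 3, seed = 2024)
  out <- simulate_panel(model)
  panel <- read_phased_panel(out$paths["vcf"], out$paths["populations"])
  res <- estimate_all(panel, sim$markers)
  stats <- vapply(sim$markers$Name, function(nm) {
    m <- frequency_matrix(res$frequencies, nm)
    d <- marker_diplotypes(panel, as_marker(
      sim$markers[sim$markers$Name == nm, , drop = FALSE]))
    c(In = informativeness(m), Fst = as.numeric(fst_weir_cockerham(d)))
  }, numeric(2))
  rho <- stats::cor(stats["In", ], stats["Fst", ], method = "spearman")
  expect_gt(rho, 0)
})
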