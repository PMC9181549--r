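test_that("mutate_k2p honours the zero-rate and determinism contracts", {
  s <- random_seq(500, seed = 1)
  expect_identical(mutate_k2p(s, 0), s)
  expect_error(mutate_k2p(s, -0.1), ">= 0")
  expect_error(mutate_k2p(s, 0.1, ts_tv_ratio = 0), "> 0")
  m1 <- mutate_k2p(s, 0.04, seed = 7)
  m2 <- mutate_k2p(s, 0.04, seed = 7)
  expect_identical(m1, m2)
  expect_false(identical(m1, mutate_k2p(s, 0.04, seed = 8)))
  expect_identical(nchar(m1), nchar(s))
})

test_that("K2P-estimated distance of mutated copies converges to target", {
  s <- random_seq(5000, seed = 2)
  ks <- vapply(1:100, function(i)
    k2p(s, mutate_k2p(s, 0.04, seed = i))$K, numeric(1))
  se <- stats::sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.04), 3 * se + 1e-4)
  # transitions dominate 2:1 at the default ratio
  ps <- vapply(1:50, function(i) {
    d <- k2p(s, mutate_k2p(s, 0.1, seed = 1000 + i)); d$P / d$Q
  }, numeric(1))
  expect_gt(mean(ps), 1.5)
})

test_that("simulated elements have the promised LTR divergence structure", {
  tp <- fix_templates()
  el0 <- simulate_element(tp$Angela, 0, seed = 3)
  tr <- el0$truth
  l5 <- substr(el0$sequence, tr$ltr5_start, tr$ltr5_end)
  l3 <- substr(el0$sequence, tr$ltr3_start, tr$ltr3_end)
  expect_identical(l5, l3)           # identical at the moment of insertion
  expect_identical(tr$true_age, 0)
  expect_error(simulate_element(tp$Angela, -1), ">= 0")

  # expected inter-LTR K2P distance is 2 r T: check 1 MYA over a cohort
  ks <- vapply(1:50, function(i) {
    el <- simulate_element(tp$Angela, 1, seed = 100 + i)
    t <- el$truth
    k2p(substr(el$sequence, t$ltr5_start, t$ltr5_end),
        substr(el$sequence, t$ltr3_start, t$ltr3_end))$K
  }, numeric(1))
  se <- stats::sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.04), 4 * se)
})

test_that("inter-LTR divergence converges to 2*r*T across ages", {
  tp <- fix_templates()
  for (age in c(0.5, 1, 2, 5)) {
    ks <- vapply(1:40, function(i) {
      el <- simulate_element(tp$Angela, age, seed = 7000 + 100 * age + i)
      t <- el$truth
      k2p(substr(el$sequence, t$ltr5_start, t$ltr5_end),
          substr(el$sequence, t$ltr3_start, t$ltr3_end))$K
    }, numeric(1))
    target <- 2 * 2e-8 * age * 1e6
    se <- stats::sd(ks) / sqrt(length(ks))
    expect_lt(abs(mean(ks) - target), 4 * se + 1e-3)
  }
})

test_that("build_genome conserves counts, truth coordinates and TSDs", {
  sim <- build_genome(data.frame(lineage = "Angela", age_mya = 1,
                                 count = 0),
                      background_length = 20000, solo_ltr_count = 0,
                      fragment_count = 0, seed = 5)
  expect_identical(nchar(sim$genome[[1]]), 20000L)
  expect_identical(nrow(sim$truth), 0L)

  sim2 <- fix_sim()
  truth <- sim2$truth[sim2$truth$type == "element", ]
  expect_identical(nrow(truth), 15L)
  # non-overlapping spans
  o <- order(truth$start)
  expect_true(all(truth$start[o][-1] > truth$end[o][-nrow(truth)]))
  # TSD flanks are exact duplicates
  g <- sim2$genome[[1]]
  for (i in seq_len(nrow(truth))) {
    len <- nchar(truth$tsd[i])
    expect_identical(substr(g, truth$start[i] - len, truth$start[i] - 1),
                     truth$tsd[i])
    expect_identical(substr(g, truth$end[i] + 1, truth$end[i] + len),
                     truth$tsd[i])
  }
  # genes sit in inter-element background
  for (i in seq_len(nrow(sim2$genes)))
    expect_false(any(sim2$genes$start[i] <= truth$end &
                       sim2$genes$end[i] >= truth$start))
})

test_that("truth LTR pairs stay above the detection identity threshold", {
  tp <- fix_templates()
  for (age in c(0.5, 1, 2, 3)) {
    for (i in 1:5) {
      el <- simulate_element(tp$SIRE, age, seed = 5000 + 100 * age + i)
      t <- el$truth
      l5 <- substr(el$sequence, t$ltr5_start, t$ltr5_end)
      l3 <- substr(el$sequence, t$ltr3_start, t$ltr3_end)
      ident <- 100 * mean(strsplit(l5, "")[[1]] == strsplit(l3, "")[[1]])
      expect_gte(ident, 85)
    }
  }
})

test_that("build_genome is byte-deterministic and respects capacity", {
  spec <- data.frame(lineage = "Ale", age_mya = 0.5, count = 3)
  a <- build_genome(spec, background_length = 50000, seed = 11)
  b <- build_genome(spec, background_length = 50000, seed = 11)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_error(build_genome(data.frame(lineage = "Angela", age_mya = 0.5,
                                       count = 40),
                            background_length = 30000, seed = 1),
               "capacity")
})

test_that("planted primer sites are written at exact coordinates", {
  primer <- "TTCAAGAATCACACCCTCTA"
  sim <- build_genome(data.frame(lineage = "Angela", age_mya = 1,
                                 count = 2),
                      background_length = 60000,
                      primer_sites_spec = list(primer = primer, count = 20),
                      solo_ltr_count = 0, fragment_count = 0, seed = 21)
  expect_identical(nrow(sim$primer_sites), 20L)
  found <- find_primer_sites(sim, primer, max_mismatches = 0)
  expect_identical(nrow(found), 20L)
  expect_setequal(found$start, sim$primer_sites$start)
})

test_that("simulate_reads has exact count arithmetic and clean substrings", {
  g <- c(chr1 = random_seq(85000, seed = 6))
  reads <- simulate_reads(g, read_length = 85, coverage = 1,
                          error_rate = 0, seed = 7)
  expect_identical(nrow(reads), 1000L)
  for (i in seq_len(25)) {
    r <- reads[i, ]
    sub <- substr(g[[r$chrom]], r$pos, r$pos + 84)
    expect_identical(r$seq, if (r$strand == "+") sub else revcomp(sub))
  }
  expect_error(simulate_reads(c(chr1 = "ACGT"), coverage = 1), "exceeds")
  expect_error(simulate_reads(g, coverage = 0), "> 0")
  expect_identical(simulate_reads(g, coverage = 0.1, seed = 8),
                   simulate_reads(g, coverage = 0.1, seed = 8))
})

test_that("dominant-marker simulation obeys the band-presence model", {
  tr1 <- make_population_truth(6, 1, 10, seed = 1)
  tr1$allele_freqs[] <- 1
  expect_true(all(simulate_marker_population(tr1, seed = 2) == 1))
  tr1$allele_freqs[] <- 0
  expect_true(all(simulate_marker_population(tr1, seed = 2) == 0))
  bad <- tr1; bad$Q_true[1, 1] <- 0.5
  expect_error(simulate_marker_population(bad), "sum to 1")
  # P(band) = 1 - a^2 empirically at a fixed locus
  tr <- make_population_truth(4, 2, 1, seed = 3)
  tr$allele_freqs[, 1] <- c(0.9, 0.2)
  tr$Q_true[] <- rep(c(0.5, 0.5), each = 4)
  p_expect <- 1 - (0.5 * 0.1 + 0.5 * 0.8)^2
  hits <- vapply(1:400, function(i)
    mean(simulate_marker_population(tr, seed = i)), numeric(1))
  expect_lt(abs(mean(hits) - p_expect), 0.02)
})
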