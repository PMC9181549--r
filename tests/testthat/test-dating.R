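test_that("distance-to-age conversion follows T = K/(2r)", {
  expect_identical(age_from_k(0), 0)
  expect_equal(age_from_k(0.04), 1)          # rate 2e-8 -> 1 MYA
  expect_equal(age_from_k(0.08), 2)
  # age scales inversely with rate: doubling the rate halves T exactly
  ks <- c(0.01, 0.04, 0.2)
  expect_identical(age_from_k(ks, rate = 4e-8), age_from_k(ks) / 2)
  expect_error(age_from_k(0.1, rate = 0), "> 0")
})

test_that("identical LTRs date to zero; saturated pairs are flagged", {
  ltr <- random_seq(400, seed = 60)
  g <- c(chr1 = paste0(random_seq(200, seed = 61), ltr,
                       random_seq(2000, seed = 62), ltr,
                       strrep("A", 300), strrep("C", 300)))
  els <- data.frame(element_id = c("a", "b"), chrom = "chr1",
                    ltr5_start = c(201L, 3001L), ltr5_end = c(600L, 3300L),
                    ltr3_start = c(2601L, 3301L), ltr3_end = c(3000L, 3600L),
                    stringsAsFactors = FALSE)
  ages <- ltr_insertion_age(els, g)
  expect_identical(ages$T_mya[1], 0)
  expect_true(ages$datable[1])
  expect_false(ages$datable[2])      # A-block vs C-block: all transversions
  expect_identical(attr(ages, "n_saturated"), 1L)
})

test_that("a simulated cohort recovers its true age within 10%", {
  tp <- fix_templates()
  ages <- vapply(1:40, function(i) {
    el <- simulate_element(tp$Angela, 2, seed = 6000 + i)
    t <- el$truth
    d <- k2p(substr(el$sequence, t$ltr5_start, t$ltr5_end),
             substr(el$sequence, t$ltr3_start, t$ltr3_end))
    age_from_k(d$K)
  }, numeric(1))
  expect_lt(abs(mean(ages) - 2), 0.2)
})

test_that("detected elements date close to the simulator truth", {
  sim <- fix_sim()
  els <- fix_elements()
  ages <- ltr_insertion_age(els, sim)
  truth <- sim$truth
  idx <- vapply(seq_len(nrow(els)), function(i)
    which.max(pmin(truth$end, els$end[i]) -
                pmax(truth$start, els$start[i])), integer(1))
  ok <- ages$datable
  expect_gte(mean(abs(ages$T_mya[ok] - truth$true_age[idx][ok]) < 0.5), 0.9)
})

test_that("error-free reads from one invariant RT all date to zero", {
  rt <- random_seq(400, seed = 63)
  reads <- simulate_reads(c(chrA = rt), coverage = 8, error_rate = 0,
                          seed = 64)
  est <- rt_read_dating(c(anchor = rt), reads, lineages = "L1", seed = 65)
  expect_gt(nrow(est), 10)
  expect_true(all(est$K == 0))
  expect_true(all(est$T_mya == 0))
})

test_that("two diverged RT haplotypes produce an old dating peak", {
  set.seed(66)
  rt0 <- random_seq(800)
  rt1 <- mutate_k2p(rt0, 0.08, seed = 67)
  true_k <- k2p(rt0, rt1)$K          # realised divergence of this draw
  reads <- simulate_reads(c(chrA = rt0, chrB = rt1), coverage = 12,
                          error_rate = 0, seed = 68)
  est <- rt_read_dating(c(anchor = rt0), reads, lineages = "L1", seed = 69)
  prof <- age_profile(est, bin_width = 0.5)
  # one burst at ~0 (within-haplotype pairs), one at the realised K2P age
  expect_gte(length(prof$peak_ages), 2)
  expect_lt(min(abs(prof$peak_ages - age_from_k(true_k))), 0.5)
  expect_lt(min(prof$peak_ages), 0.5)
})

test_that("short references are dropped and sparse ones skipped", {
  rt <- random_seq(300, seed = 70)
  reads <- simulate_reads(c(chrA = rt), coverage = 5, error_rate = 0,
                          seed = 71)
  expect_message(
    est <- rt_read_dating(c(ok = rt, tiny = random_seq(100)), reads,
                          lineages = c("L1", "L2"), seed = 72),
    "shorter than 150")
  expect_true(all(est$ref_id == "ok"))
  # a reference nothing maps to contributes nothing but is logged
  est2 <- rt_read_dating(c(ok = rt, lonely = random_seq(300, seed = 73)),
                         reads, lineages = c("L1", "L2"), seed = 74)
  expect_identical(attr(est2, "n_refs_skipped"), 1L)
})

test_that("age profiles report means, bins and burst peaks", {
  expect_error(age_profile(numeric(0)), "no age estimates")
  p1 <- age_profile(rep(1, 50))
  expect_equal(p1$mean_age, 1)
  expect_identical(length(p1$peak_ages), 1L)
  expect_lt(abs(p1$peak_ages - 1), 0.3)
  pn <- age_profile(3.2)
  expect_equal(pn$mean_age, 3.2)
  expect_identical(pn$peak_ages, 3.2)
  set.seed(75)
  x <- c(rnorm(1000, 1, 0.1), rnorm(1000, 10, 1))
  pm <- age_profile(x, bin_width = 0.5)
  expect_identical(length(pm$peak_ages), 2L)
  expect_lt(abs(pm$peak_ages[1] - 1), 0.5)
  expect_lt(abs(pm$peak_ages[2] - 10), 1)
  # per-lineage split
  df <- data.frame(T_mya = c(rep(1, 30), rep(4, 30)),
                   lineage = rep(c("A", "B"), each = 30))
  ps <- age_profile(df)
  expect_s3_class(ps, "age_profile_set")
  expect_equal(ps$A$mean_age, 1)
  expect_equal(ps$B$mean_age, 4)
})
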