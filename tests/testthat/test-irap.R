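ANG5 <- "TTCAAGAATCACACCCTCTA"

test_that("primer scanning finds exact and degenerate sites, both strands", {
  set.seed(90)
  g <- c(chr1 = paste0(random_seq(300), ANG5, random_seq(300)))
  s <- find_primer_sites(g, ANG5)
  expect_identical(nrow(s), 1L)
  expect_identical(s$strand, "+")
  expect_identical(s$start, 301L)
  expect_identical(s$three_prime, 320L)
  # the reverse-complemented genome carries the site on the minus strand
  s2 <- find_primer_sites(c(chr1 = revcomp(g[[1]])), ANG5)
  expect_identical(s2$strand, "-")
  expect_identical(s2$three_prime, nchar(g[[1]]) - 320L + 1L)
  # degenerate base: W matches A and T
  wprimer <- "ATGGGACTTCGWTATTCTAGTG"
  for (b in c("A", "T")) {
    gi <- c(chr1 = paste0(random_seq(100), sub("W", b, wprimer),
                          random_seq(100)))
    expect_identical(nrow(find_primer_sites(gi, wprimer,
                                            max_mismatches = 0)), 1L)
  }
  expect_error(find_primer_sites(g, "TTCAAGAATCACACCCTCTZ"), "non-IUPAC")
  expect_error(find_primer_sites(g, "ACGT"), "18-25")
})

test_that("a 3'-terminal mismatch kills a site; internal ones do not", {
  set.seed(91)
  internal_mm <- paste0("ATCAAGAATCACACCCTCTA")  # pos 2 T->A vs ANG5
  terminal_mm <- paste0("TTCAAGAATCACACCCTCTT")  # last base A->T
  g <- c(chr1 = paste0(random_seq(200), internal_mm, random_seq(50),
                       terminal_mm, random_seq(200)))
  s <- find_primer_sites(g, ANG5, max_mismatches = 1)
  expect_identical(nrow(s), 1L)
  expect_identical(s$start, 201L)
})

test_that("amplicon arithmetic uses the 5'-end inclusive span", {
  set.seed(92)
  # + site then a facing - site, product exactly 500 bp
  block <- paste0(ANG5, random_seq(500 - 2 * nchar(ANG5)), revcomp(ANG5))
  g <- c(chr1 = paste0(random_seq(150), block, random_seq(150)))
  s <- find_primer_sites(g, ANG5)
  a <- predict_amplicons(s)
  expect_identical(nrow(a), 1L)
  expect_identical(a$length, 500L)
  # beyond the scorable window: nothing
  g2 <- c(chr1 = paste0(random_seq(100), ANG5, random_seq(5000),
                        revcomp(ANG5), random_seq(100)))
  expect_identical(nrow(predict_amplicons(find_primer_sites(g2, ANG5))), 0L)
  # diverging orientations (- before +) never amplify
  g3 <- c(chr1 = paste0(random_seq(100), revcomp(ANG5), random_seq(500),
                        ANG5, random_seq(100)))
  expect_identical(nrow(predict_amplicons(find_primer_sites(g3, ANG5))), 0L)
})

test_that("adjacent elements with outward primer sites give one amplicon", {
  tp <- fix_templates()
  # embed the primer near the 3' end of the LTR consensus
  ltr <- tp$Angela$ltr_consensus
  ltr_p <- paste0(substr(ltr, 1, nchar(ltr) - 60), ANG5,
                  substr(ltr, nchar(ltr) - 39, nchar(ltr)))
  elem <- paste0(ltr_p, random_seq(2500, seed = 93), ltr_p)
  # element A forward, element B inverted downstream: the two inner LTRs
  # carry convergent (outward-facing) sites
  set.seed(94)
  g <- c(chr1 = paste0(random_seq(400), elem, random_seq(700),
                       revcomp(elem), random_seq(400)))
  s <- find_primer_sites(g, ANG5)
  expect_identical(sort(table(s$strand), decreasing = TRUE),
                   sort(table(c("+", "+", "-", "-")), decreasing = TRUE))
  a <- predict_amplicons(s)
  expect_identical(nrow(a), 1L)   # only the inter-element product is scorable
  expect_lt(a$length, 3000L)
})

test_that("amplicon length multisets are reverse-complement invariant", {
  set.seed(95)
  pieces <- character(0)
  for (i in 1:6)
    pieces <- c(pieces, random_seq(sample(200:900, 1)),
                if (i %% 2) ANG5 else revcomp(ANG5))
  g <- c(chr1 = paste(c(pieces, random_seq(300)), collapse = ""))
  a_fwd <- predict_amplicons(find_primer_sites(g, ANG5))
  a_rev <- predict_amplicons(find_primer_sites(c(chr1 = revcomp(g[[1]])),
                                               ANG5))
  expect_identical(sort(a_fwd$length), sort(a_rev$length))
})

test_that("band matrices score presence/absence with gel tolerance", {
  sets <- list(acc1 = c(150, 400, 1000), acc2 = c(150, 400, 1000),
               acc3 = c(152, 700))
  m <- band_matrix(sets)
  expect_identical(m["acc1", ], m["acc2", ])
  # 150 vs 152 co-migrate at 2%; 400/700/1000 are distinct bands
  expect_identical(ncol(m), 4L)
  expect_identical(sum(m[, 1]), 3L)
  u <- colSums(m)
  expect_identical(sum(u == 1L), 1L)   # the 700-bp band is acc3-private
  expect_error(band_matrix(sets[1]), ">= 2")
  # 39 well-separated segregating loci are recovered as 39 columns
  set.seed(96)
  loci <- round(100 * 1.07^(0:38))
  sets2 <- lapply(1:10, function(i) loci[runif(39) < 0.6])
  m2 <- band_matrix(sets2)
  expect_identical(ncol(m2), 39L)
})

test_that("PCA separates simulated subpopulations", {
  expect_error(irap_pca(matrix(1L, 4, 5)), "no variance")
  m <- rbind(a = c(1L, 0L, 1L, 0L), b = c(1L, 0L, 1L, 0L),
             c = c(0L, 1L, 0L, 1L))
  p <- irap_pca(m)
  expect_equal(p$scores["a", ], p$scores["b", ])
  expect_equal(p$explained[1], 1)    # rank-1 contrast
  tr <- make_population_truth(24, 2, 40, admix_alpha = 5, seed = 97)
  tr$Q_true[] <- 0; tr$Q_true[1:12, 1] <- 1; tr$Q_true[13:24, 2] <- 1
  mm <- simulate_marker_population(tr, seed = 98)
  pp <- irap_pca(mm)
  g1 <- pp$scores[1:12, 1]; g2 <- pp$scores[13:24, 1]
  expect_true(max(min(g1) - max(g2), min(g2) - max(g1)) > 0)
})

test_that("admixture EM matches the K = 1 closed form", {
  tr <- make_population_truth(20, 1, 30, seed = 99)
  m <- simulate_marker_population(tr, seed = 100)
  fit <- admixture_em(m, 1, n_replicates = 2, seed = 101)
  expect_true(all(fit$Q == 1))
  closed <- 1 - sqrt(pmax(0, 1 - colMeans(m)))
  expect_equal(as.numeric(fit$allele_freqs), as.numeric(closed),
               tolerance = 0.01)
  expect_error(admixture_em(m, 0), ">= 1")
  expect_error(admixture_em(m, 21), "exceeds")
})

test_that("identical accessions leave no structure for K = 2 to find", {
  row <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L)
  m <- matrix(rep(row, each = 8), nrow = 8,
              dimnames = list(paste0("a", 1:8), NULL))
  f1 <- admixture_em(m, 1, n_replicates = 2, seed = 102)
  f2 <- admixture_em(m, 2, n_replicates = 2, seed = 103)
  expect_lt(abs(f1$log_likelihood - f2$log_likelihood), 1e-3)
})

test_that("EM recovers strongly differentiated K = 2 structure", {
  tr <- make_population_truth(25, 2, 40, seed = 104)
  m <- simulate_marker_population(tr, seed = 105)
  fit <- admixture_em(m, 2, n_replicates = 7, seed = 106)
  expect_lt(q_mae(fit$Q, tr$Q_true), 0.1)
  # permuting accessions permutes Q rows and preserves the likelihood
  perm <- c(5:25, 1:4)
  fitp <- admixture_em(m[perm, ], 2, n_replicates = 7, seed = 106)
  expect_lt(abs(fitp$log_likelihood - fit$log_likelihood), 0.01)
  aligned <- align_q_columns(list(fit$Q[perm, ], fitp$Q))[[2]]
  expect_lt(mean(abs(aligned - fit$Q[perm, ])), 0.05)
})

test_that("replicate Q matrices align across label switching", {
  q1 <- cbind(c(0.9, 0.8, 0.1), c(0.1, 0.2, 0.9))
  q2 <- q1[, 2:1]                     # switched labels
  out <- align_q_columns(list(q1, q2))
  expect_equal(out[[2]], q1, ignore_attr = TRUE)
})

test_that("Evanno delta-K picks the knee of the likelihood curve", {
  # piecewise-linear mean L with a single slope change at K = 4
  Ks <- 1:7
  meanL <- ifelse(Ks <= 4, -1000 + 100 * Ks, -600 + 10 * (Ks - 4))
  L <- rbind(meanL + 1, meanL - 1, meanL + 0.5)  # replicate offsets
  colnames(L) <- Ks
  ev <- evanno_delta_k(L)
  expect_identical(ev$selected_K, 4L)
  expect_true(all(ev$delta_k[names(ev$delta_k) != "4"] < 1e-9))
  # exactly linear L: selection undefined
  L2 <- rbind(meanL2 <- -1000 + 50 * Ks + 1, meanL2 - 2)
  colnames(L2) <- Ks
  expect_true(is.na(evanno_delta_k(L2)$selected_K))
  # degenerate replicates
  L3 <- rbind(meanL, meanL)
  colnames(L3) <- Ks
  expect_error(evanno_delta_k(L3), "sd = 0")
  expect_error(evanno_delta_k(L[, 1:2]), ">= 3")
  expect_error(evanno_delta_k(L[1, , drop = FALSE]), ">= 2")
})

test_that("Qi > 0.8 assignment is strict at the boundary", {
  q <- rbind(a = c(0.9, 0.1), b = c(0.5, 0.5), c = c(0.8, 0.2))
  colnames(q) <- c("pop1", "pop2")
  cls <- classify_admixed(q)
  expect_identical(unname(cls), c("pop1", "admixed", "admixed"))
  expect_error(classify_admixed(rbind(c(0.5, 0.2))), "sum to 1")
})

test_that("replicate seeds derived from large master seeds stay valid", {
  tr <- make_population_truth(8, 2, 10, seed = 1)
  m <- simulate_marker_population(tr, seed = 2)
  # a master seed near 2^31 must not overflow integer arithmetic
  fit <- admixture_em(m, 2, n_replicates = 2, seed = 2147483000)
  expect_s3_class(fit, "admixture_fit")
  expect_true(is.finite(fit$log_likelihood))
})

test_that("non-reproducible bands are dropped across replicate gels", {
  reps <- list(c(150, 400, 1000), c(151, 400, 700), c(150, 402, 1000))
  keep <- filter_reproducible_bands(reps, min_support = 2)
  # 700 appears once only; 150/400/1000 are reproducible
  expect_identical(length(keep), 3L)
  expect_false(any(abs(keep - 700) < 20))
  expect_error(filter_reproducible_bands(reps[1], min_support = 2),
               "fewer replicates")
})

test_that("the bundled primer panel is intact", {
  p <- irap_primers()
  expect_identical(nrow(p), 11L)
  expect_identical(p$sequence[p$code == "ANG 5+"], ANG5)
  expect_true(grepl("W", p$sequence[p$code == "ANG RNase+"]))
  expect_true(all(nchar(p$sequence) >= 18 & nchar(p$sequence) <= 25))
})
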