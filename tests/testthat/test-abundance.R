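test_that("verbatim element reads map back; background reads do not", {
  set.seed(80)
  lib <- c(el1 = random_seq(3000), el2 = random_seq(3000))
  read_el <- substr(lib[["el1"]], 101, 185)
  read_rc <- revcomp(substr(lib[["el2"]], 501, 585))
  read_bg <- random_seq(85)
  asg <- map_reads(c(read_el, read_rc, read_bg), lib)
  expect_identical(asg$element_id[1], "el1")
  expect_identical(asg$element_id[2], "el2")
  expect_identical(asg$status[3], "unmapped")
  expect_equal(asg$identity[1], 1)
  expect_error(map_reads("ACGT", character(0)), "empty")
})

test_that("mapping honours the length-fraction and similarity filters", {
  set.seed(81)
  lib <- c(el1 = random_seq(2000))
  # read hanging off the end of the reference: aligned fraction too small
  hang <- paste0(substr(lib[["el1"]], 1951, 2000), random_seq(35))
  # read at ~75% identity (mismatches clustered in its first half, so
  # seeds still place it): below the similarity filter
  noisy <- strsplit(substr(lib[["el1"]], 301, 385), "")[[1]]
  idx <- seq(1, 42, by = 2)
  noisy[idx] <- vapply(noisy[idx], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  asg <- map_reads(c(hang, paste(noisy, collapse = "")), lib)
  expect_identical(asg$status, c("unmapped", "unmapped"))
  # the same noisy read passes at a permissive similarity
  asg2 <- map_reads(paste(noisy, collapse = ""), lib, similarity = 0.7)
  expect_identical(asg2$status, "mapped")
})

test_that("ties are reported as ambiguous or resolved at random", {
  set.seed(82)
  s <- random_seq(2000)
  lib <- c(a = s, b = s)           # two identical elements
  rd <- substr(s, 901, 985)
  amb <- map_reads(rd, lib, tie_policy = "ambiguous")
  expect_identical(amb$n_best, 2L)
  expect_identical(amb$best_elements, "a,b")
  rnd <- map_reads(rd, lib, tie_policy = "random", seed = 1)
  expect_identical(rnd$n_best, 1L)
  expect_true(rnd$element_id %in% c("a", "b"))
  expect_identical(map_reads(rd, lib, tie_policy = "random", seed = 1),
                   rnd)
})

test_that("proportions are additive, unit-sum, and split ambiguity", {
  ann <- data.frame(element_id = c("a", "b", "c"),
                    lineage = c("Angela", "SIRE", "Angela"),
                    superfamily = "Copia", stringsAsFactors = FALSE)
  asg <- data.frame(
    read_id = sprintf("r%d", 1:6),
    element_id = c("a", "b", "a", NA, "a", "c"),
    identity = 1, n_best = c(1L, 1L, 2L, 0L, 1L, 2L),
    best_elements = c("a", "b", "a,b", NA, "a", "a,c"),
    status = c("mapped", "mapped", "mapped", "unmapped", "mapped",
               "mapped"), stringsAsFactors = FALSE)
  tab <- proportions(asg, ann)
  expect_equal(sum(tab$proportion), 1)
  expect_identical(sum(tab$reads), 6L)
  # the a,b tie spans two lineages -> ambiguous; a,c does not
  expect_identical(tab$reads[tab$lineage == "ambiguous"], 1L)
  expect_identical(tab$reads[tab$lineage == "Angela"], 3L)
  sup <- attr(tab, "superfamily_totals")
  expect_equal(sup$proportion[sup$superfamily == "Copia"],
               sum(tab$proportion[tab$superfamily == "Copia"]))
})

test_that("all-unmapped input yields zero proportions everywhere", {
  ann <- data.frame(element_id = "a", lineage = "Angela",
                    superfamily = "Copia", stringsAsFactors = FALSE)
  asg <- data.frame(read_id = c("r1", "r2"), element_id = NA_character_,
                    identity = NA_real_, n_best = 0L,
                    best_elements = NA_character_, status = "unmapped",
                    stringsAsFactors = FALSE)
  tab <- proportions(asg, ann)
  expect_identical(tab$lineage, "unmapped")
  expect_equal(tab$proportion, 1)
})

test_that("two lineages with equal truth share estimate equally", {
  sim <- build_genome(data.frame(lineage = c("Angela", "SIRE"),
                                 age_mya = 0.5, count = c(4, 4)),
                      background_length = 8e4, solo_ltr_count = 0,
                      fragment_count = 0, seed = 83)
  truth <- sim$truth
  bp <- tapply(truth$end - truth$start + 1, truth$lineage, sum)
  reads <- simulate_reads(sim, coverage = 6, seed = 84)
  asg <- map_reads(reads, element_sequences(truth, sim), seed = 85)
  tab <- proportions(asg, truth)
  est <- stats::setNames(tab$proportion, tab$lineage)
  glen <- sum(nchar(sim$genome))
  for (lin in c("Angela", "SIRE"))
    expect_lt(abs(est[[lin]] - bp[[lin]] / glen), 0.03)
})
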