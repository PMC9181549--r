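# Helper: minimal hit tables with the attributes classify_hits() uses.
fake_hits <- function(domains, starts, lineages, scores = 500,
                      frames = "+1") {
  h <- data.frame(domain = domains, frame = rep_len(frames, length(domains)),
                  start = starts, end = starts + 300L,
                  score = rep_len(scores, length(domains)),
                  best_lineage = rep_len(lineages, length(domains)),
                  stringsAsFactors = FALSE)
  ls <- tapply(h$score, h$best_lineage, max)
  attr(h, "lineage_scores") <- ls[order(-ls)]
  attr(h, "lineage_superfamily") <-
    stats::setNames(domain_exemplars(fix_templates())$superfamily,
                    domain_exemplars(fix_templates())$lineage)
  h
}

test_that("domain order defines the superfamily", {
  co <- fake_hits(c("PROT", "INT", "RT", "RH"), c(100L, 500L, 900L, 1400L),
                  "Angela")
  expect_identical(classify_hits(co)$superfamily, "Copia")
  gy <- fake_hits(c("PROT", "RT", "RH", "INT"), c(100L, 500L, 900L, 1400L),
                  "Tekay")
  expect_identical(classify_hits(gy)$superfamily, "Gypsy")
  # on the minus strand the coordinate order is reversed
  gy_m <- fake_hits(c("PROT", "RT", "RH", "INT"), c(1400L, 900L, 500L, 100L),
                    "Tekay", frames = "-2")
  expect_identical(classify_hits(gy_m)$superfamily, "Gypsy")
  expect_identical(classify_hits(gy_m)$strand, "-")
})

test_that("a single RT hit maps lineage to its superfamily", {
  h <- fake_hits("RT", 500L, "SIRE")
  cl <- classify_hits(h)
  expect_identical(cl$superfamily, "Copia")
  expect_identical(cl$lineage, "SIRE")
  expect_identical(cl$evidence, "domain")
  expect_false(cl$autonomous)
})

test_that("classification is invariant to hit order and ties stay open", {
  h <- fake_hits(c("GAG", "PROT", "INT", "RT", "RH"),
                 c(10L, 400L, 800L, 1200L, 1700L), "Angela")
  a <- classify_hits(h)
  b <- classify_hits(h[sample.int(nrow(h)), ])
  expect_identical(a$superfamily, b$superfamily)
  expect_identical(a$lineage, b$lineage)
  expect_true(a$autonomous)
  # two lineages at exactly equal score: lineage undetermined,
  # superfamily kept when unambiguous
  tie <- fake_hits(c("RT", "RH"), c(100L, 500L), c("Angela", "SIRE"),
                   scores = c(400, 400))
  cl <- classify_hits(tie)
  expect_identical(cl$lineage, "undetermined")
  expect_identical(cl$superfamily, "Copia")
  expect_identical(classify_hits(NULL)$superfamily, "undetermined")
})

test_that("scanning a pristine element recovers all its own domains", {
  tp <- fix_templates()
  for (lin in c("Angela", "Tekay")) {
    el <- simulate_element(tp[[lin]], 0, seed = 50)
    t <- el$truth
    internal <- substr(el$sequence, t$internal_start, t$internal_end)
    hits <- scan_domains(internal)
    expect_setequal(hits$domain, c("GAG", "PROT", "INT", "RT", "RH"))
    expect_true(all(hits$best_lineage == lin))
    cl <- classify_hits(hits)
    expect_identical(cl$lineage, lin)
    expect_identical(cl$superfamily, tp[[lin]]$superfamily)
    expect_true(cl$autonomous)
  }
  expect_error(scan_domains("ACGT", exemplars = NULL), "empty exemplar")
})

test_that("an RT deletion removes the RT hit and autonomy", {
  tp <- fix_templates()
  el <- simulate_element(tp$Angela, 0.5, seed = 51)
  t <- el$truth
  internal <- substr(el$sequence, t$internal_start, t$internal_end)
  dc <- tp$Angela$domain_coords
  rt <- dc[dc$domain == "RT", ]
  cut <- paste0(substr(internal, 1, rt$start - 1),
                substr(internal, rt$end + 1, nchar(internal)))
  hits <- scan_domains(cut)
  expect_false("RT" %in% hits$domain)
  expect_false(classify_hits(hits)$autonomous)
})

test_that("raising min_score never rescues an undetermined element", {
  tp <- fix_templates()
  el <- simulate_element(tp$SIRE, 1, seed = 52)
  t <- el$truth
  internal <- substr(el$sequence, t$internal_start, t$internal_end)
  low <- classify_hits(scan_domains(internal, min_score = 100))
  high <- classify_hits(scan_domains(internal, min_score = 1e7))
  expect_identical(high$superfamily, "undetermined")
  expect_false(low$superfamily == "undetermined" &&
                 high$superfamily != "undetermined")
})

test_that("homology rescue adopts the top hit's annotation", {
  tp <- fix_templates()
  el <- simulate_element(tp$Angela, 0.5, seed = 53)
  # a 95%-identical copy with no recognisable domains: strip the coding
  # part, keep LTRs + untranslated margins
  t <- el$truth
  dc <- tp$Angela$domain_coords
  stripped <- paste0(
    substr(el$sequence, 1, t$ltr5_end + min(dc$start) - 1),
    substr(el$sequence, t$ltr5_end + max(dc$end) + 1, nchar(el$sequence)))
  stripped <- mutate_k2p(stripped, 0.05, seed = 54)
  seqs <- c(A = el$sequence, B = stripped, C = random_seq(3000, seed = 55))
  ann <- data.frame(element_id = c("A", "B", "C"),
                    superfamily = c("Copia", "undetermined", "undetermined"),
                    lineage = c("Angela", "undetermined", "undetermined"),
                    autonomous = c(TRUE, FALSE, FALSE),
                    evidence = "domain", strand = "+", n_domains = c(5, 0, 0),
                    stringsAsFactors = FALSE)
  out <- homology_rescue(ann, seqs)
  expect_identical(out$lineage[2], "Angela")
  expect_identical(out$evidence[2], "homology")
  # the unrelated sequence stays undetermined
  expect_identical(out$lineage[3], "undetermined")
  expect_error(homology_rescue(ann[2:3, ], seqs[2:3]), "no classified")
})

test_that("detected elements are annotated to their true lineage", {
  sim <- fix_sim()
  els <- fix_elements()
  ann <- annotate_elements(els, sim)
  truth <- sim$truth
  idx <- vapply(seq_len(nrow(els)), function(i)
    which.max(pmin(truth$end, els$end[i]) -
                pmax(truth$start, els$start[i])), integer(1))
  agree <- mean(ann$lineage == truth$lineage[idx])
  expect_gte(agree, 0.95)
  expect_true(all(ann$strand == truth$strand[idx]))
  # autonomous + non-autonomous partition the set
  expect_identical(sum(ann$autonomous) + sum(!ann$autonomous), nrow(ann))
})
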