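# Shared fixtures and independent oracle helpers. Everything is built in
# code at test time; heavy objects are memoised across test files.

.fixture_env <- new.env()

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

fix_templates <- function() fixture("templates", lineage_templates())

# A mid-sized simulated genome reused by detect/annotate/dating tests.
fix_sim <- function() fixture("sim", build_genome(
  data.frame(lineage = c("Angela", "SIRE", "Tekay"),
             age_mya = c(0.5, 1, 1), count = c(5, 5, 5)),
  templates = fix_templates(), background_length = 3e5,
  solo_ltr_count = 0, fragment_count = 0, seed = 909))

fix_elements <- function() fixture("elements", detect_ltr(fix_sim()))

# --- independent K2P oracle: explicit transition/transversion counting
# over all positions, then the closed form.
oracle_k2p <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  ts_pairs <- c("AG", "GA", "CT", "TC")
  pair <- paste0(a, b)
  P <- sum(pair %in% ts_pairs) / n
  Q <- sum(a != b & !pair %in% ts_pairs) / n
  list(P = P, Q = Q, K = -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)),
       n = n)
}

# reciprocal-overlap matching of detected elements against truth
overlap_stats <- function(found, truth, frac = 0.8) {
  rec_hit <- function(s1, e1, s2, e2) {
    o <- pmin(e1, e2) - pmax(s1, s2) + 1
    any(o > 0 & o >= frac * (e1 - s1 + 1) & o >= frac * (e2 - s2 + 1))
  }
  recall <- if (nrow(truth) == 0) NA else mean(vapply(seq_len(nrow(truth)),
    function(i) rec_hit(truth$start[i], truth$end[i],
                        found$start, found$end), logical(1)))
  precision <- if (nrow(found) == 0) NA else mean(vapply(seq_len(nrow(found)),
    function(i) rec_hit(found$start[i], found$end[i],
                        truth$start, truth$end), logical(1)))
  list(precision = precision, recall = recall)
}

# mean absolute error of an estimated Q against truth, minimised over
# column permutations (label switching)
q_mae <- function(Q_hat, Q_true) {
  K <- ncol(Q_true)
  perms <- if (K <= 4) {
    m <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
    m[apply(m, 1, function(r) length(unique(r)) == K), , drop = FALSE]
  } else stop("q_mae: K too large")
  min(apply(perms, 1, function(p) mean(abs(Q_hat[, p] - Q_true))))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
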