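# In-silico IRAP: primer-site scanning, amplicon prediction, band-matrix
# construction, PCA ordination, dominant-marker admixture inference (EM)
# and Evanno delta-K model selection.

#' Bundled IRAP primer panel
#'
#' The eleven oligonucleotides designed on the LTRs of a highly redundant
#' Copia/Angela element family, shipped as plain TSV. `ANG 5+` is the
#' primer whose genome-wide redundancy makes it the workhorse of the
#' fingerprinting protocol; `ANG RNase+` contains the IUPAC degenerate
#' base W.
#'
#' @return data.frame with columns `code`, `direction`, `sequence`.
#' @export
irap_primers <- function() {
  utils::read.delim(system.file("extdata", "irap_primers.tsv",
                                package = "retroscape"),
                    stringsAsFactors = FALSE)
}

#' Find primer annealing sites in a genome
#'
#' Scans both strands for matches of a (possibly IUPAC-degenerate) primer
#' with at most `max_mismatches` mismatches, none of which may fall in
#' the 3 terminal bases of the primer's 3' end (a mismatch there kills
#' extension by the polymerase).
#'
#' @param genome named character vector of chromosome sequences, or an
#'   `ltr_genome_sim` object.
#' @param primer primer sequence, 5'->3', 18-25 nt, IUPAC codes allowed.
#' @param max_mismatches maximum mismatches outside the 3' terminus
#'   (default 1).
#' @return data.frame of class `primer_sites`: `chrom`, `start`, `end`
#'   (footprint, 1-based inclusive, forward-strand coordinates),
#'   `strand`, `three_prime` (genome position of the primer's 3' end),
#'   `mismatches`.
#' @export
#' @examples
#' g <- c(chr1 = paste0(strrep("A", 30), "TTCAAGAATCACACCCTCTA",
#'                      strrep("A", 30)))
#' find_primer_sites(g, "TTCAAGAATCACACCCTCTA")
find_primer_sites <- function(genome, primer, max_mismatches = 1L) {
  if (inherits(genome, "ltr_genome_sim")) genome <- genome$genome
  primer <- toupper(primer)
  if (!all(s2c(primer) %in% names(IUPAC_SETS)))
    stop("primer contains non-IUPAC characters")
  plen <- nchar(primer)
  if (plen < 18L || plen > 25L)
    stop("primer length must be 18-25 nt")
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    three_prime = integer(0), mismatches = integer(0),
                    stringsAsFactors = FALSE)
  pat <- Biostrings::DNAString(primer)
  for (ch in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ch]])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatches,
                                    fixed = FALSE)
      if (length(m) == 0L) next
      st <- Biostrings::start(m); en <- Biostrings::end(m)
      mm <- vapply(seq_along(m), function(i) {
        .count_iupac_mismatches(as.character(m[[i]]),
                                if (strand == "+") primer else
                                  revcomp(primer))
      }, integer(1L))
      # no mismatch allowed in the 3 terminal 3' bases
      tail_mm <- vapply(seq_along(m), function(i) {
        s <- as.character(m[[i]])
        if (strand == "+")
          .count_iupac_mismatches(substr(s, plen - 2L, plen),
                                  substr(primer, plen - 2L, plen))
        else
          .count_iupac_mismatches(substr(s, 1L, 3L),
                                  substr(revcomp(primer), 1L, 3L))
      }, integer(1L))
      keep <- mm <= max_mismatches & tail_mm == 0L
      if (!any(keep)) next
      out <- rbind(out, data.frame(
        chrom = ch, start = st[keep], end = en[keep], strand = strand,
        three_prime = ifelse(strand == "+", en[keep], st[keep]),
        mismatches = mm[keep], stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("primer_sites", "data.frame")
  out
}

# mismatches of a concrete genome word against an IUPAC pattern
.count_iupac_mismatches <- function(word, pattern) {
  w <- s2c(word); p <- s2c(pattern)
  sum(!mapply(function(a, b) a %in% IUPAC_SETS[[b]], w, p))
}

#' Predict IRAP amplicons from primer sites
#'
#' Every pair of a plus-strand site upstream of a minus-strand site on
#' the same chromosome yields one amplicon when the product length falls
#' within the gel-scorable window. The length convention is the
#' inclusive span between the two primer 5' ends (i.e. the full product
#' a polymerase would synthesise).
#'
#' @param sites `primer_sites` data.frame from [find_primer_sites()].
#' @param min_len,max_len scorable product size window in bp
#'   (default 100-3000).
#' @return data.frame of class `amplicons`: `chrom`, `start`, `end`,
#'   `length`.
#' @export
predict_amplicons <- function(sites, min_len = 100L, max_len = 3000L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("amplicons", "data.frame")
  if (is.null(sites) || nrow(sites) == 0L) return(empty)
  out <- empty
  for (ch in unique(sites$chrom)) {
    fw <- sites[sites$chrom == ch & sites$strand == "+", , drop = FALSE]
    rv <- sites[sites$chrom == ch & sites$strand == "-", , drop = FALSE]
    if (nrow(fw) == 0L || nrow(rv) == 0L) next
    for (i in seq_len(nrow(fw))) {
      # 5' end of a + site is its start; of a - site its end
      len <- rv$end - fw$start[i] + 1L
      ok <- which(rv$start > fw$end[i] & len >= min_len & len <= max_len)
      if (length(ok) == 0L) next
      out <- rbind(out, data.frame(
        chrom = ch, start = fw$start[i], end = rv$end[ok],
        length = len[ok], stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("amplicons", "data.frame")
  out
}

#' Score per-accession amplicon sets into a binary band matrix
#'
#' Pools amplicon lengths across accessions and bins them single-linkage:
#' two lengths co-migrate (same band) when they differ by at most
#' `size_tolerance` (relative, a gel-resolution proxy). Each band becomes
#' one presence/absence column.
#'
#' @param amplicon_sets named list of `amplicons` data.frames (or bare
#'   numeric vectors of lengths), one per accession.
#' @param size_tolerance relative co-migration tolerance (default 0.02).
#' @return binary matrix of class `irap_matrix` (accessions x bands) with
#'   band-size metadata in the `band_sizes` attribute.
#' @export
band_matrix <- function(amplicon_sets, size_tolerance = 0.02) {
  if (length(amplicon_sets) < 2L) stop("need >= 2 accessions")
  if (is.null(names(amplicon_sets)))
    names(amplicon_sets) <- sprintf("acc%02d", seq_along(amplicon_sets))
  lens <- lapply(amplicon_sets, function(a)
    if (is.data.frame(a)) a$length else as.numeric(a))
  all_len <- sort(unique(unlist(lens)))
  if (length(all_len) == 0L)
    return(structure(matrix(0L, length(amplicon_sets), 0L,
                            dimnames = list(names(amplicon_sets), NULL)),
                     class = c("irap_matrix", "matrix", "array")))
  # single-linkage chaining on sorted lengths
  brk <- c(TRUE, diff(all_len) / all_len[-length(all_len)] > size_tolerance)
  bin <- cumsum(brk)
  band_size <- round(tapply(all_len, bin, stats::median))
  m <- matrix(0L, nrow = length(lens), ncol = max(bin),
              dimnames = list(names(amplicon_sets),
                              sprintf("band_%d", band_size)))
  for (i in seq_along(lens)) {
    b <- unique(bin[match(lens[[i]], all_len)])
    m[i, b] <- 1L
  }
  attr(m, "band_sizes") <- as.integer(band_size)
  class(m) <- c("irap_matrix", class(m))
  m
}

#' Filter non-reproducible bands across replicate amplifications
#'
#' Wet-lab fingerprints are scored from several replicate gels, and
#' bands seen only sporadically are excluded. Given one amplicon set
#' (or length vector) per replicate amplification of the *same*
#' accession, this keeps only bands supported by at least `min_support`
#' replicates. In-silico amplification is deterministic, so the filter
#' is off the default path and exists for imported wet-lab data.
#'
#' @param replicate_sets list of `amplicons` data.frames or numeric
#'   length vectors, one per replicate amplification.
#' @param min_support minimum number of replicates a band must appear in
#'   (default 2).
#' @param size_tolerance relative co-migration tolerance (default 0.02).
#' @return numeric vector of reproducible band lengths (bin medians).
#' @export
filter_reproducible_bands <- function(replicate_sets, min_support = 2L,
                                      size_tolerance = 0.02) {
  if (length(replicate_sets) < min_support)
    stop("fewer replicates than 'min_support'")
  names(replicate_sets) <- sprintf("rep%02d", seq_along(replicate_sets))
  m <- band_matrix(replicate_sets, size_tolerance = size_tolerance)
  sizes <- attr(m, "band_sizes")
  sizes[colSums(unclass(m)) >= min_support]
}

#' Principal component analysis of an IRAP matrix
#'
#' Column-centers the binary matrix and eigendecomposes its covariance;
#' accession scores on the leading components and the explained-variance
#' fractions are returned.
#'
#' @param m binary matrix (accessions x bands).
#' @param n_components number of components to keep (default 5, capped by
#'   the matrix rank).
#' @return list of class `irap_pca`: `scores`, `explained` (variance
#'   fractions), `sdev`.
#' @export
irap_pca <- function(m, n_components = 5L) {
  m <- unclass(m)
  v <- apply(m, 2L, stats::var)
  if (all(v == 0)) stop("matrix has no variance (all bands monomorphic)")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
                 sdev = p$sdev),
            class = "irap_pca")
}

#' @export
print.irap_pca <- function(x, ...) {
  cat(sprintf("<irap_pca> %d accessions; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$explained[1L],
              if (length(x$explained) > 1L) 100 * x$explained[2L] else 0))
  invisible(x)
}

#' @export
plot.irap_pca <- function(x, ...) {
  graphics::plot(x$scores[, 1L], x$scores[, 2L],
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2L]),
                 ...)
  graphics::text(x$scores[, 1L], x$scores[, 2L],
                 labels = rownames(x$scores), pos = 3, cex = 0.7)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Dominant-marker admixture model
#
# Band presence y_il for diploid accession i at locus l:
#   a_il = sum_k Q_ik (1 - f_kl)      (one haplotype lacks the band allele)
#   P(y_il = 1) = 1 - a_il^2
#   logL = sum_il log[ y (1 - a^2) + (1 - y) a^2 ]
# fitted by EM over the latent haplotype origins and alleles.
# ---------------------------------------------------------------------------

.admix_loglik <- function(y, Q, f) {
  a <- Q %*% (1 - f)
  p1 <- 1 - a * a
  eps <- 1e-12
  sum(log(ifelse(y == 1L, pmax(p1, eps), pmax(1 - p1, eps))))
}

#' Fit the dominant-marker admixture model by EM
#'
#' Maximum-likelihood estimation of per-accession admixture proportions
#' `Q` (n x K) and per-subpopulation band-allele frequencies `f` (K x L)
#' from a binary band matrix, under the diploid dominant-marker model
#' (band absent only when both haplotypes carry the absence allele; each
#' haplotype's subpopulation of origin is drawn from the accession's `Q`
#' row). Replicate fits differ only by their random initialisation seed;
#' the log-likelihood is asserted non-decreasing across EM iterations.
#'
#' @param m binary matrix (accessions x loci).
#' @param K_pop number of subpopulations (>= 1, <= accessions).
#' @param n_replicates number of independently initialised fits
#'   (default 7).
#' @param seed integer; replicate r uses a seed derived from it.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   gain drops below `tol` (default 1e-6) or after `max_iter` (2000)
#'   iterations.
#' @return object of class `admixture_fit`: list with `Q`, `allele_freqs`,
#'   `log_likelihood`, `K_pop`, `replicates` (all replicate fits),
#'   `log_likelihoods` (per replicate), `n_iter`, `seed`. `Q` and
#'   `allele_freqs` come from the best replicate.
#' @export
admixture_em <- function(m, K_pop, n_replicates = 7L, seed = NULL,
                         max_iter = 2000L, tol = 1e-6) {
  y <- unclass(m)
  storage.mode(y) <- "integer"
  if (!all(y %in% c(0L, 1L))) stop("matrix must be binary")
  n <- nrow(y); L <- ncol(y)
  if (K_pop < 1L) stop("'K_pop' must be >= 1")
  if (K_pop > n) stop("'K_pop' exceeds the number of accessions")

  fit_one <- function(rep_seed) with_seed(rep_seed, {
    K <- K_pop
    Q <- matrix(stats::rgamma(n * K, 1, 1), n, K)
    Q <- Q / rowSums(Q)
    f <- matrix(stats::runif(K * L, 0.2, 0.8), K, L)
    ll_old <- -Inf
    it <- 0L
    repeat {
      it <- it + 1L
      a_k <- 1 - f                    # K x L: P(absence allele | k)
      a <- Q %*% a_k                  # n x L
      # E-step: per-haplotype posterior origin/allele expectations.
      # For y = 0 both haplotypes carry the absence allele:
      #   P(z = k | y=0) prop. to Q_ik (1 - f_kl)
      # For y = 1 (not both absent):
      #   P(z = k, x = 1 | y=1) = Q_ik f_kl / (1 - a^2)
      #   P(z = k, x = 0 | y=1) = Q_ik (1 - f_kl)(1 - a) / (1 - a^2)
      eps <- 1e-12
      denom1 <- pmax(1 - a * a, eps)  # n x L
      a0 <- pmax(a, eps)
      zk <- matrix(0, n, K)           # E[# haplotypes from k] / 2, by acc.
      num <- matrix(0, K, L)          # E[# band alleles from k] / 2
      den <- matrix(0, K, L)          # E[# haplotypes from k] / 2, by locus
      for (k in seq_len(K)) {
        qa <- outer(Q[, k], a_k[k, ])          # Q_ik (1 - f_kl)
        qf <- outer(Q[, k], f[k, ])            # Q_ik f_kl
        post0 <- qa / a0                       # y = 0 case
        post1 <- (qf + qa * (1 - a)) / denom1  # y = 1, origin k
        Ez_k <- post0 + y * (post1 - post0)    # y is 0/1
        Ex_k <- y * (qf / denom1)              # y = 1, origin k & band
        zk[, k] <- rowSums(Ez_k)
        den[k, ] <- colSums(Ez_k)
        num[k, ] <- colSums(Ex_k)
      }
      # M-step
      Q <- zk / rowSums(zk)
      f <- pmin(pmax(num / pmax(den, eps), 0), 1)
      ll <- .admix_loglik(y, Q, f)
      if (ll < ll_old - 1e-6)
        stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
      if (ll - ll_old < tol || it >= max_iter) break
      ll_old <- ll
    }
    rownames(Q) <- rownames(y)
    colnames(Q) <- paste0("pop", seq_len(K))
    dimnames(f) <- list(paste0("pop", seq_len(K)), colnames(y))
    list(Q = Q, allele_freqs = f, log_likelihood = ll, n_iter = it,
         seed = rep_seed)
  })

  reps <- lapply(seq_len(n_replicates), function(r)
    fit_one(derive_seed(seed %||% 0L, r)))
  lls <- vapply(reps, `[[`, numeric(1L), "log_likelihood")
  best <- reps[[which.max(lls)]]
  structure(list(Q = best$Q, allele_freqs = best$allele_freqs,
                 log_likelihood = best$log_likelihood, K_pop = K_pop,
                 replicates = reps, log_likelihoods = lls,
                 n_iter = best$n_iter, seed = seed),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf(
    "<admixture_fit> K = %d, %d accessions, logL = %.2f (best of %d replicates)\n",
    x$K_pop, nrow(x$Q), x$log_likelihood, length(x$replicates)))
  invisible(x)
}

#' @export
coef.admixture_fit <- function(object, ...) object$Q

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$Q) - nrow(object$Q) +
              length(object$allele_freqs),
            class = "logLik")
}

#' @export
summary.admixture_fit <- function(object, threshold = 0.8, ...) {
  cls <- classify_admixed(object$Q, threshold = threshold)
  out <- list(fit = object, assignment = cls,
              n_admixed = sum(cls == "admixed"))
  class(out) <- "summary.admixture_fit"
  out
}

#' @export
print.summary.admixture_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d/%d accessions admixed (Qi <= threshold)\n",
              x$n_admixed, nrow(x$fit$Q)))
  invisible(x)
}

#' @export
plot.admixture_fit <- function(x, ...) {
  graphics::barplot(t(x$Q), col = seq_len(x$K_pop) + 1L, border = NA,
                    las = 2, ylab = "ancestry proportion", ...)
  invisible(x)
}

#' Align Q-matrix columns across replicate fits
#'
#' Subpopulation labels are arbitrary per replicate (label switching);
#' columns of each replicate's Q are greedily matched to the reference
#' replicate's columns by correlation before any averaging or comparison.
#'
#' @param Q_list list of Q matrices with identical dimensions.
#' @param reference index of the reference replicate (default 1).
#' @return list of Q matrices with columns permuted to match the
#'   reference.
#' @export
align_q_columns <- function(Q_list, reference = 1L) {
  ref <- Q_list[[reference]]
  K <- ncol(ref)
  lapply(Q_list, function(q) {
    if (K == 1L) return(q)
    cc <- suppressWarnings(stats::cor(ref, q))
    cc[!is.finite(cc)] <- 0
    perm <- integer(K)  # perm[ref column] = matching replicate column
    for (step in seq_len(K)) {
      idx <- which(cc == max(cc), arr.ind = TRUE)[1L, , drop = TRUE]
      perm[idx[1L]] <- idx[2L]
      cc[idx[1L], ] <- -Inf
      cc[, idx[2L]] <- -Inf
    }
    q[, perm, drop = FALSE]
  })
}

#' Evanno delta-K statistic and model selection
#'
#' For consecutive K values with replicated log-likelihoods L(K),
#' \deqn{\Delta K = \mathrm{mean}_{reps}\,|L(K+1) - 2L(K) + L(K-1)| \;/\;
#'   \mathrm{sd}_{reps}\,L(K)} and the selected K maximises it. The
#' statistic is defined only for interior K; it needs at least three
#' consecutive K values and two replicates each.
#'
#' @param L matrix of log-likelihoods with rows = replicates and columns
#'   named by K (consecutive integers), e.g. built from
#'   `admixture_em(...)$log_likelihoods` across K.
#' @return list of class `evanno_result`: `delta_k` (named vector over
#'   interior K), `selected_K`, `mean_L`, `sd_L`. When every second
#'   difference is (numerically) zero the selection is flagged undefined
#'   (`selected_K = NA`).
#' @export
evanno_delta_k <- function(L) {
  L <- as.matrix(L)
  Ks <- as.integer(colnames(L) %||% seq_len(ncol(L)))
  if (is.null(colnames(L))) colnames(L) <- Ks
  if (ncol(L) < 3L) stop("need >= 3 consecutive K values")
  if (nrow(L) < 2L) stop("need >= 2 replicates per K")
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  sd_L <- apply(L, 2L, stats::sd)
  interior <- 2L:(ncol(L) - 1L)
  if (any(sd_L[interior] == 0))
    stop("replicate log-likelihoods are degenerate (sd = 0)")
  second <- abs(L[, interior + 1L, drop = FALSE] -
                  2 * L[, interior, drop = FALSE] +
                  L[, interior - 1L, drop = FALSE])
  dk <- colMeans(second) / sd_L[interior]
  names(dk) <- Ks[interior]
  selected <- if (all(colMeans(second) < 1e-9)) NA_integer_ else
    Ks[interior][which.max(dk)]
  structure(list(delta_k = dk, selected_K = selected,
                 mean_L = colMeans(L), sd_L = sd_L),
            class = "evanno_result")
}

#' @export
print.evanno_result <- function(x, ...) {
  cat("<evanno_result> delta-K by K:\n")
  print(round(x$delta_k, 3))
  if (is.na(x$selected_K))
    cat("  selection undefined (log-likelihood linear in K)\n")
  else cat(sprintf("  selected K = %d\n", x$selected_K))
  invisible(x)
}

#' @export
plot.evanno_result <- function(x, ...) {
  graphics::plot(as.integer(names(x$delta_k)), x$delta_k, type = "b",
                 xlab = "K", ylab = expression(Delta * K), ...)
  invisible(x)
}

#' Assign accessions to subpopulations from admixture coefficients
#'
#' An accession is unequivocally assigned to subpopulation k only when
#' its admixture coefficient exceeds the threshold strictly
#' (Qi > 0.8 by default); otherwise it is labelled admixed. A coefficient
#' exactly at the threshold therefore stays admixed.
#'
#' @param Q admixture matrix (rows sum to 1) or an `admixture_fit`.
#' @param threshold assignment threshold (default 0.8).
#' @return character vector: column name of the assigned subpopulation or
#'   `"admixed"`, named by accession.
#' @export
classify_admixed <- function(Q, threshold = 0.8) {
  if (inherits(Q, "admixture_fit")) Q <- Q$Q
  if (any(abs(rowSums(Q) - 1) > 1e-6)) stop("Q rows must sum to 1")
  cn <- colnames(Q) %||% paste0("pop", seq_len(ncol(Q)))
  out <- vapply(seq_len(nrow(Q)), function(i) {
    j <- which.max(Q[i, ])
    if (Q[i, j] > threshold) cn[j] else "admixed"
  }, character(1L))
  names(out) <- rownames(Q)
  out
}
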