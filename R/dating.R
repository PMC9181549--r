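# Insertion-time estimation: (A) divergence between the two LTRs of each
# full-length element; (B) pairwise divergence of reads mapped to
# RT-encoding reference sequences. Both convert K2P distances to ages via
# T = K / (2 r).

#' Convert a K2P distance to an insertion age
#'
#' The two LTRs are identical at insertion and each accumulates
#' substitutions at rate `r`, so a pair diverges at `2r` and
#' \eqn{T = K / (2r)}.
#'
#' @param K K2P distance in substitutions/site.
#' @param rate substitution rate per site per year (default `2e-8`).
#' @return age in million years (MYA).
#' @export
#' @examples
#' age_from_k(0.04)   # 1 MYA at the default rate
age_from_k <- function(K, rate = 2e-8) {
  if (any(rate <= 0)) stop("'rate' must be > 0")
  K / (2 * rate) / 1e6
}

#' Insertion ages from LTR-pair divergence
#'
#' For every element, the 5' and 3' LTR sequences are extracted from the
#' genome, globally aligned end-to-end, and their K2P distance converted
#' to an age. Saturated pairs (distance undefined) are flagged undatable
#' rather than clamped; their count is recorded in the `n_saturated`
#' attribute.
#'
#' @param elements an `ltr_elements` data.frame (or any data.frame with
#'   `element_id`, `chrom` and the four LTR interval columns).
#' @param genome the genome the elements live on.
#' @param rate substitution rate per site per year.
#' @return data.frame `element_id`, `K`, `P`, `Q`, `sites`, `T_mya`,
#'   `datable`; attribute `n_saturated`.
#' @export
ltr_insertion_age <- function(elements, genome, rate = 2e-8) {
  if (inherits(genome, "ltr_genome_sim")) genome <- genome$genome
  n <- nrow(elements)
  out <- data.frame(element_id = elements$element_id,
                    K = NA_real_, P = NA_real_, Q = NA_real_,
                    sites = NA_integer_, T_mya = NA_real_,
                    datable = rep(TRUE, n), stringsAsFactors = FALSE)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  for (i in seq_len(n)) {
    chseq <- genome[[elements$chrom[i]]]
    l5 <- substr(chseq, elements$ltr5_start[i], elements$ltr5_end[i])
    l3 <- substr(chseq, elements$ltr3_start[i], elements$ltr3_end[i])
    d <- tryCatch(k2p_aligned_pair(l5, l3, submat),
                  retroscape_saturation = function(e) NULL)
    if (is.null(d)) { out$datable[i] <- FALSE; next }
    out$K[i] <- d$K; out$P[i] <- d$P; out$Q[i] <- d$Q
    out$sites[i] <- d$sites_compared
    out$T_mya[i] <- age_from_k(d$K, rate)
  }
  attr(out, "n_saturated") <- sum(!out$datable)
  out
}

# Global end-to-end alignment of two sequences followed by K2P.
k2p_aligned_pair <- function(a, b, submat = NULL) {
  if (nchar(a) == nchar(b) && a == b) return(k2p(a, b))
  if (is.null(submat))
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                       mismatch = -3)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = submat, gapOpening = 8, gapExtension = 2)
  k2p(as.character(Biostrings::alignedPattern(aln)),
      as.character(Biostrings::alignedSubject(aln)))
}

#' Insertion-age estimates from reads mapped to RT-encoding references
#'
#' Reads are aligned to each reference (ungapped, seeded semi-global
#' placement) and kept when at least `length_fraction` of the read aligns
#' at `similarity` identity or better. For each reference, mapped read
#' pairs overlapping by at least `min_overlap` nt are compared with
#' [k2p()] on their overlap (pairwise deletion), and each pairwise
#' distance is converted to MYA. References attracting fewer than two
#' reads contribute nothing (counted in attribute `n_refs_skipped`);
#' saturated pairs are excluded (attribute `n_saturated`).
#'
#' @param rt_refs named character vector of RT-encoding nucleotide
#'   sequences (>= 150 nt each; shorter ones are dropped with a message).
#' @param reads character vector of read sequences, or a `read_sim`
#'   data.frame.
#' @param lineages lineage label per reference (defaults to the names of
#'   `rt_refs`).
#' @param rate substitution rate per site per year.
#' @param length_fraction minimum aligned fraction of the read length.
#' @param similarity minimum identity of the aligned part.
#' @param min_overlap minimum read-read overlap for a pairwise comparison.
#' @param max_pairs cap on compared pairs per reference; beyond it a
#'   seeded random subsample of pairs is used.
#' @param seed integer or NULL (used for subsampling only).
#' @return data.frame `lineage`, `ref_id`, `K`, `T_mya`.
#' @export
rt_read_dating <- function(rt_refs, reads, lineages = names(rt_refs),
                           rate = 2e-8, length_fraction = 0.9,
                           similarity = 0.8, min_overlap = 40L,
                           max_pairs = 20000L, seed = NULL) {
  if (is.data.frame(reads)) reads <- reads$seq
  if (is.null(names(rt_refs)))
    names(rt_refs) <- sprintf("rt%03d", seq_along(rt_refs))
  if (is.null(lineages)) lineages <- names(rt_refs)
  short <- nchar(rt_refs) < 150L
  if (any(short)) {
    message(sum(short), " reference(s) shorter than 150 nt dropped")
    rt_refs <- rt_refs[!short]; lineages <- lineages[!short]
  }
  if (length(rt_refs) == 0L) stop("no usable RT references")
  hits <- map_reads_ungapped(reads, rt_refs,
                             length_fraction = length_fraction,
                             similarity = similarity)
  out <- data.frame(lineage = character(0), ref_id = character(0),
                    K = numeric(0), T_mya = numeric(0),
                    stringsAsFactors = FALSE)
  n_sat <- 0L; n_skip <- 0L
  with_seed(seed, {
    for (r in seq_along(rt_refs)) {
      h <- hits[hits$ref == r, , drop = FALSE]
      if (nrow(h) < 2L) { n_skip <- n_skip + 1L; next }
      idx <- utils::combn(nrow(h), 2L)
      # overlap on reference coordinates
      s <- pmax(h$ref_start[idx[1L, ]], h$ref_start[idx[2L, ]])
      e <- pmin(h$ref_end[idx[1L, ]], h$ref_end[idx[2L, ]])
      ok <- which(e - s + 1L >= min_overlap)
      if (length(ok) > max_pairs) ok <- sample(ok, max_pairs)
      Ks <- rep(NA_real_, length(ok))
      for (m in seq_along(ok)) {
        p <- ok[m]
        i1 <- idx[1L, p]; i2 <- idx[2L, p]
        a <- substr(h$oriented_seq[i1], s[p] - h$ref_start[i1] + 1L,
                    e[p] - h$ref_start[i1] + 1L)
        b <- substr(h$oriented_seq[i2], s[p] - h$ref_start[i2] + 1L,
                    e[p] - h$ref_start[i2] + 1L)
        d <- tryCatch(k2p(a, b), retroscape_saturation = function(x) NULL)
        if (is.null(d)) { n_sat <- n_sat + 1L; next }
        Ks[m] <- d$K
      }
      Ks <- Ks[!is.na(Ks)]
      if (length(Ks) > 0L)
        out <- rbind(out, data.frame(
          lineage = lineages[r], ref_id = names(rt_refs)[r], K = Ks,
          T_mya = age_from_k(Ks, rate), stringsAsFactors = FALSE))
    }
  })
  attr(out, "n_saturated") <- n_sat
  attr(out, "n_refs_skipped") <- n_skip
  out
}

#' Binned age profile with transposition-burst peaks
#'
#' Builds a histogram of insertion-age estimates per lineage and finds
#' peaks — local maxima of a Gaussian kernel density (bandwidth =
#' `smoothing_bandwidth`) whose height exceeds `peak_frac` of the highest
#' peak. Peaks in the age distribution are read as transposition bursts.
#'
#' @param estimates numeric vector of ages (MYA), or a data.frame with a
#'   `T_mya` column and optionally `lineage`.
#' @param bin_width histogram bin width in MYA (default 0.5).
#' @param smoothing_bandwidth kernel bandwidth; defaults to `bin_width`.
#' @param peak_frac minimum height of a reported peak relative to the
#'   density maximum (default 0.05).
#' @return for a single lineage an object of class `age_profile` (list
#'   with `lineage`, `bin_edges`, `counts`, `mean_age`, `peak_ages`,
#'   `n`); for several lineages a named list of them (class
#'   `age_profile_set`).
#' @export
age_profile <- function(estimates, bin_width = 0.5,
                        smoothing_bandwidth = bin_width, peak_frac = 0.05) {
  if (is.data.frame(estimates)) {
    ages <- estimates$T_mya
    lin <- if ("lineage" %in% names(estimates)) estimates$lineage else
      rep("all", length(ages))
  } else { ages <- as.numeric(estimates); lin <- rep("all", length(ages)) }
  keep <- !is.na(ages)
  ages <- ages[keep]; lin <- lin[keep]
  if (length(ages) == 0L) stop("no age estimates supplied")
  one <- function(x, name) {
    edges <- seq(0, max(x, bin_width) + bin_width, by = bin_width)
    counts <- as.integer(table(cut(x, edges, include.lowest = TRUE,
                                   right = FALSE)))
    peaks <- if (length(x) == 1L) x else {
      d <- stats::density(x, bw = smoothing_bandwidth, n = 1024)
      y <- d$y
      i <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1L], -Inf))
      i <- i[y[i] >= peak_frac * max(y)]
      d$x[i]
    }
    structure(list(lineage = name, bin_edges = edges, counts = counts,
                   mean_age = mean(x), peak_ages = peaks, n = length(x),
                   ages = x),
              class = "age_profile")
  }
  lins <- unique(lin)
  if (length(lins) == 1L) return(one(ages, lins))
  out <- lapply(lins, function(l) one(ages[lin == l], l))
  names(out) <- lins
  class(out) <- "age_profile_set"
  out
}

#' @export
print.age_profile <- function(x, ...) {
  cat(sprintf("<age_profile> %s: n = %d, mean %.2f MYA, peak(s) at %s\n",
              x$lineage, x$n, x$mean_age,
              paste(sprintf("%.2f", x$peak_ages), collapse = ", ")))
  invisible(x)
}

#' @export
print.age_profile_set <- function(x, ...) {
  for (p in x) print(p)
  invisible(x)
}

#' @export
plot.age_profile <- function(x, ...) {
  graphics::hist(x$ages, breaks = x$bin_edges,
                 main = sprintf("%s insertion ages", x$lineage),
                 xlab = "insertion time (MYA)", ...)
  graphics::abline(v = x$peak_ages, lty = 2)
  invisible(x)
}
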