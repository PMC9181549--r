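# De novo structural detection of full-length LTR retrotransposons:
# exact k-mer seed pairs on a shared diagonal -> diagonal clusters ->
# ungapped X-drop extension -> identity/motif/TSD refinement.

#' Find candidate LTR pairs in a genome
#'
#' Scans each chromosome for pairs of exact k-mer matches lying on a
#' shared diagonal with a separation compatible with a full-length LTR
#' retrotransposon, clusters them, and extends each cluster into a
#' putative LTR pair by ungapped alignment extension (match +1,
#' mismatch -2, running-maximum cut-off). Because a direct repeat remains
#' a direct repeat on the reverse complement, the forward scan recovers
#' elements inserted on either strand.
#'
#' @param genome named character vector of chromosome sequences, or an
#'   `ltr_genome_sim` object.
#' @param k seed length (default 20).
#' @param min_ltr,max_ltr LTR length bounds in bp (default 100, 3000).
#' @param min_elem,max_elem element length bounds in bp (default 1000,
#'   16000).
#' @param seed_gap maximum gap between seeds of one diagonal cluster (bp).
#' @return data.frame of candidates: `chrom`, `ltr5_start`, `ltr5_end`,
#'   `ltr3_start`, `ltr3_end`, `n_seeds`. LTR spans of a candidate always
#'   have equal length (ungapped model).
#' @seealso [refine_and_filter()], [detect_ltr()]
#' @export
find_candidates <- function(genome, k = 20L, min_ltr = 100L, max_ltr = 3000L,
                            min_elem = 1000L, max_elem = 16000L,
                            seed_gap = 500L) {
  if (inherits(genome, "ltr_genome_sim")) genome <- genome$genome
  stopifnot(min_ltr >= k, min_elem > 2L * min_ltr)
  empty <- data.frame(chrom = character(0), ltr5_start = integer(0),
                      ltr5_end = integer(0), ltr3_start = integer(0),
                      ltr3_end = integer(0), n_seeds = integer(0),
                      stringsAsFactors = FALSE)
  if (length(genome) == 0L || all(nchar(genome) == 0L)) return(empty)
  d_lo <- max(min_elem - 2L * max_ltr, min_ltr)
  d_hi <- max_elem

  out <- lapply(names(genome) %||% seq_along(genome), function(ch) {
    seqc <- s2c(genome[[ch]])
    n <- length(seqc)
    if (n < 2L * k) return(empty)
    code <- base_codes(seqc)
    codes <- kmer_codes(code, k)
    valid <- which(!is.na(codes))
    if (length(valid) < 2L) return(empty)
    ord <- valid[order(codes[valid], valid)]
    cds <- codes[ord]
    m <- length(ord)

    p1 <- integer(0); p2 <- integer(0)
    for (lag in 1:10) {
      if (m <= lag) break
      i1 <- seq_len(m - lag)
      same <- cds[i1] == cds[i1 + lag]
      if (!any(same)) next
      a <- ord[i1][same]; b <- ord[i1 + lag][same]
      d <- b - a
      keep <- d >= d_lo & d <= d_hi
      p1 <- c(p1, a[keep]); p2 <- c(p2, b[keep])
    }
    if (length(p1) == 0L) return(empty)
    d <- p2 - p1
    oo <- order(d, p1)
    d <- d[oo]; p1 <- p1[oo]
    grp <- cumsum(c(TRUE, diff(d) != 0L | diff(p1) > seed_gap))
    s1 <- tapply(p1, grp, min)
    e1 <- tapply(p1, grp, max) + k - 1L
    dg <- tapply(d, grp, function(x) x[1L])
    ns <- tapply(p1, grp, length)

    res <- lapply(seq_along(s1), function(i) {
      ext <- .extend_ltr_pair(code, s1[[i]], e1[[i]], dg[[i]], n, max_ltr)
      ltr_len <- ext[2L] - ext[1L] + 1L
      elem_len <- dg[[i]] + ltr_len
      if (ltr_len < min_ltr || ltr_len > max_ltr ||
          elem_len < min_elem || elem_len > max_elem) return(NULL)
      data.frame(chrom = as.character(ch),
                 ltr5_start = ext[1L], ltr5_end = ext[2L],
                 ltr3_start = ext[1L] + dg[[i]], ltr3_end = ext[2L] + dg[[i]],
                 n_seeds = ns[[i]], stringsAsFactors = FALSE)
    })
    do.call(rbind, c(list(empty), res))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Extend a seed-supported diagonal match outward in both directions with a
# +1/-2 running score, capped so the two LTR spans never overlap, then snap
# boundaries to the canonical TG...CA termini when found within +-2 bp.
.extend_ltr_pair <- function(code, s1, e1, d, n, max_ltr) {
  span <- e1 - s1 + 1L
  cap <- min(max_ltr, d - 1L) - span   # extension budget (both sides share)
  # left
  wl <- min(cap, s1 - 1L)
  if (wl > 0L) {
    a <- code[(s1 - 1L):(s1 - wl)]
    b <- code[(s1 + d - 1L):(s1 + d - wl)]
    eq <- !is.na(a) & !is.na(b) & a == b
    sc <- cumsum(ifelse(eq, 1L, -2L))
    best <- which.max(sc)
    if (sc[best] > 0L) s1 <- s1 - best
  }
  cap <- min(max_ltr, d - 1L) - (e1 - s1 + 1L)
  wr <- min(cap, n - (e1 + d))
  if (wr > 0L) {
    a <- code[(e1 + 1L):(e1 + wr)]
    b <- code[(e1 + d + 1L):(e1 + d + wr)]
    eq <- !is.na(a) & !is.na(b) & a == b
    sc <- cumsum(ifelse(eq, 1L, -2L))
    best <- which.max(sc)
    if (sc[best] > 0L) e1 <- e1 + best
  }
  # snap to TG / CA termini (2 = G code, etc.) within +-2 bp
  tg_at <- function(s) {
    for (sh in c(0L, -1L, 1L, -2L, 2L)) {
      p <- s + sh
      if (p >= 1L && p + 1L <= n &&
          ((identical(code[p], 3L) && identical(code[p + 1L], 2L)) ||
           (identical(code[p + d], 3L) && identical(code[p + d + 1L], 2L))))
        return(p)
    }
    s
  }
  ca_at <- function(e) {
    for (sh in c(0L, 1L, -1L, 2L, -2L)) {
      p <- e + sh
      if (p + d <= n && p - 1L >= 1L &&
          ((identical(code[p - 1L], 1L) && identical(code[p], 0L)) ||
           (identical(code[p + d - 1L], 1L) && identical(code[p + d], 0L))))
        return(p)
    }
    e
  }
  s1n <- tg_at(s1); e1n <- ca_at(e1)
  if (e1n > s1n) { s1 <- s1n; e1 <- e1n }
  c(s1, e1)
}

#' Refine LTR-pair candidates into full-length elements
#'
#' Scores each candidate's LTR-LTR global alignment identity, annotates
#' TG...CA terminal dinucleotides and 4-6 bp target-site-duplication (TSD)
#' flanks, drops candidates below the identity threshold, and resolves
#' overlapping candidates. Motif and TSD are evidence annotations, not
#' hard filters, unless `require_tg_ca` is set; they do, however, take
#' first priority in overlap resolution, because tandem same-family
#' elements create "bridge" candidates (3'-LTR of one paired with 5'-LTR
#' of the next) whose LTR identity is indistinguishable from real
#' elements' — only the TSD flanks separate them.
#'
#' @param candidates data.frame from [find_candidates()].
#' @param genome the same genome the candidates came from.
#' @param min_identity minimum LTR-LTR percent identity (default 85).
#' @param require_tg_ca drop candidates without TG...CA on either LTR.
#' @param tsd_search look for 4-6 bp TSD flanks (default TRUE).
#' @return data.frame of class `ltr_elements`: `element_id`, `chrom`,
#'   `start`, `end`, `strand`, LTR intervals, `ltr_identity`, `tg_ca5`,
#'   `tg_ca3`, `tsd`, `n_seeds`.
#' @export
refine_and_filter <- function(candidates, genome, min_identity = 85,
                              require_tg_ca = FALSE, tsd_search = TRUE) {
  if (inherits(genome, "ltr_genome_sim")) genome <- genome$genome
  empty <- data.frame(element_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0),
                      ltr5_start = integer(0), ltr5_end = integer(0),
                      ltr3_start = integer(0), ltr3_end = integer(0),
                      ltr_identity = numeric(0), tg_ca5 = logical(0),
                      tg_ca3 = logical(0), tsd = character(0),
                      n_seeds = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("ltr_elements", "data.frame")
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)

  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  res <- candidates
  res$start <- res$ltr5_start
  res$end <- res$ltr3_end
  nc <- nrow(res)
  res$ltr_identity <- NA_real_
  res$tg_ca5 <- res$tg_ca3 <- FALSE
  res$tsd <- NA_character_
  for (i in seq_len(nc)) {
    chseq <- genome[[res$chrom[i]]]
    l5 <- substr(chseq, res$ltr5_start[i], res$ltr5_end[i])
    l3 <- substr(chseq, res$ltr3_start[i], res$ltr3_end[i])
    res$ltr_identity[i] <- ltr_alignment_identity(l5, l3, submat)
    res$tg_ca5[i] <- startsWith(l5, "TG") && endsWith(l5, "CA")
    res$tg_ca3[i] <- startsWith(l3, "TG") && endsWith(l3, "CA")
    if (tsd_search)
      res$tsd[i] <- .find_tsd(chseq, res$start[i], res$end[i])
  }
  keep <- res$ltr_identity >= min_identity
  if (require_tg_ca) keep <- keep & (res$tg_ca5 | res$tg_ca3)
  res <- res[keep, , drop = FALSE]
  if (nrow(res) == 0L) return(empty)

  # overlap resolution: TSD evidence first, then identity, length, position
  ord <- order(!is.na(res$tsd), res$ltr_identity,
               res$end - res$start, -res$start,
               decreasing = TRUE)
  res <- res[ord, , drop = FALSE]
  # Does any LTR span of candidate i coincide with an LTR span of an
  # accepted element? True host/guest nesting never shares LTRs, but a
  # "bridge" candidate (5'-LTR of one element + 3'-LTR of its tandem
  # neighbour) always does — and it contains both true elements, so the
  # containment exemption alone would admit it.
  shares_ltr <- function(i, j) {
    for (a in c("ltr5", "ltr3")) for (b in c("ltr5", "ltr3")) {
      s1 <- res[[paste0(a, "_start")]][i]; e1 <- res[[paste0(a, "_end")]][i]
      s2 <- res[[paste0(b, "_start")]][j]; e2 <- res[[paste0(b, "_end")]][j]
      ov <- min(e1, e2) - max(s1, s2) + 1L
      if (ov >= 0.5 * min(e1 - s1 + 1L, e2 - s2 + 1L)) return(TRUE)
    }
    FALSE
  }
  kept <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    ok <- TRUE
    for (j in which(kept)) {
      if (res$chrom[i] != res$chrom[j]) next
      ov <- min(res$end[i], res$end[j]) - max(res$start[i], res$start[j])
      if (ov < 0L) next
      nested <- (res$start[i] >= res$start[j] && res$end[i] <= res$end[j]) ||
        (res$start[j] >= res$start[i] && res$end[j] <= res$end[i])
      if (!nested || shares_ltr(i, j)) { ok <- FALSE; break }
    }
    kept[i] <- ok
  }
  res <- res[kept, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$element_id <- sprintf("RS%04d", seq_len(nrow(res)))
  res$strand <- "*"
  res <- res[, c("element_id", "chrom", "start", "end", "strand",
                 "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end",
                 "ltr_identity", "tg_ca5", "tg_ca3", "tsd", "n_seeds")]
  rownames(res) <- NULL
  class(res) <- c("ltr_elements", "data.frame")
  res
}

# Global LTR-LTR alignment percent identity (matches / alignment length).
ltr_alignment_identity <- function(l5, l3, submat = NULL) {
  if (identical(l5, l3)) return(100)
  if (is.null(submat))
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                       mismatch = -3)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(l5), Biostrings::DNAString(l3), type = "global",
    substitutionMatrix = submat, gapOpening = 8, gapExtension = 2)
  Biostrings::pid(aln, type = "PID1")
}

# TSD search: identical 4-6 bp flanks, allowing the detected boundaries to
# be off by up to 2 bp on each side. Homopolymer flanks are ignored.
.find_tsd <- function(chseq, start, end, max_shift = 2L) {
  n <- nchar(chseq)
  shifts <- order(abs(-max_shift:max_shift))  # 0 first, then +-1, +-2
  svals <- (-max_shift:max_shift)[shifts]
  for (a in svals) for (b in svals) {
    s <- start + a; e <- end + b
    for (len in c(5L, 6L, 4L)) {
      if (s - len < 1L || e + len > n) next
      left <- substr(chseq, s - len, s - 1L)
      right <- substr(chseq, e + 1L, e + len)
      if (left == right && !grepl("N", left, fixed = TRUE) &&
          length(unique(s2c(left))) > 1L)
        return(left)
    }
  }
  NA_character_
}

#' Detect full-length LTR retrotransposons
#'
#' Convenience wrapper running [find_candidates()] then
#' [refine_and_filter()] with shared parameters.
#'
#' @inheritParams find_candidates
#' @inheritParams refine_and_filter
#' @return an `ltr_elements` data.frame (see [refine_and_filter()]).
#' @export
#' @examples
#' tp <- lineage_templates()
#' sim <- build_genome(data.frame(lineage = "Angela", age_mya = 1, count = 3),
#'                     templates = tp, background_length = 6e4,
#'                     solo_ltr_count = 0, fragment_count = 0, seed = 7)
#' detect_ltr(sim)
detect_ltr <- function(genome, k = 20L, min_ltr = 100L, max_ltr = 3000L,
                       min_elem = 1000L, max_elem = 16000L,
                       min_identity = 85, require_tg_ca = FALSE,
                       tsd_search = TRUE) {
  cand <- find_candidates(genome, k = k, min_ltr = min_ltr,
                          max_ltr = max_ltr, min_elem = min_elem,
                          max_elem = max_elem)
  refine_and_filter(cand, genome, min_identity = min_identity,
                    require_tg_ca = require_tg_ca, tsd_search = tsd_search)
}

#' @export
print.ltr_elements <- function(x, ...) {
  cat(sprintf("<ltr_elements> %d full-length element(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf("  median LTR identity %.1f%%, %d with TSD, %d with TG...CA\n",
                stats::median(x$ltr_identity), sum(!is.na(x$tsd)),
                sum(x$tg_ca5 & x$tg_ca3)))
    print.data.frame(utils::head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat("  ...\n")
  }
  invisible(x)
}
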