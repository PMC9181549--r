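# Read mapping against an element library and genome-proportion
# estimation. The mapper is seeded + ungapped: k-mer probes propose
# (reference, offset) placements, each verified by direct base comparison
# against the acceptance filters (aligned length fraction, identity).

CODE256 <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v[utf8ToInt("a")] <- 0L; v[utf8ToInt("c")] <- 1L
  v[utf8ToInt("g")] <- 2L; v[utf8ToInt("t")] <- 3L
  v
})

# Internal engine shared by map_reads() and rt_read_dating().
# Returns one row per *mapped* read with its best placement.
map_reads_ungapped <- function(reads, refs, k = 13L, probe_step = 10L,
                               length_fraction = 0.9, similarity = 0.8,
                               max_candidates = 10L) {
  nref <- length(refs)
  ref_int <- lapply(refs, utf8ToInt)
  ref_len <- nchar(refs)
  # library k-mer index
  lib_code <- vector("list", nref); lib_ref <- vector("list", nref)
  lib_pos <- vector("list", nref)
  for (r in seq_len(nref)) {
    cd <- kmer_codes(CODE256[ref_int[[r]]], k)
    ok <- which(!is.na(cd))
    lib_code[[r]] <- cd[ok]; lib_pos[[r]] <- ok
    lib_ref[[r]] <- rep.int(r, length(ok))
  }
  lib_code <- unlist(lib_code); lib_ref <- unlist(lib_ref)
  lib_pos <- unlist(lib_pos)
  o <- order(lib_code)
  lib_code <- lib_code[o]; lib_ref <- lib_ref[o]; lib_pos <- lib_pos[o]

  n <- length(reads)
  res_read <- integer(n); res_ref <- integer(n)
  res_s <- integer(n); res_e <- integer(n); res_strand <- character(n)
  res_id <- numeric(n); res_aln <- integer(n); res_nbest <- integer(n)
  res_best <- character(n); res_seq <- character(n)
  n_out <- 0L
  comp256 <- local({
    v <- integer(256L)
    v[utf8ToInt("A")] <- utf8ToInt("T"); v[utf8ToInt("T")] <- utf8ToInt("A")
    v[utf8ToInt("C")] <- utf8ToInt("G"); v[utf8ToInt("G")] <- utf8ToInt("C")
    v[utf8ToInt("N")] <- utf8ToInt("N")
    v
  })

  for (i in seq_len(n)) {
    rd <- reads[[i]]
    len <- nchar(rd)
    if (len < k) next
    min_aln <- as.integer(ceiling(length_fraction * len))
    best_score <- -1L; best <- NULL; best_ties <- integer(0)
    ints_f <- utf8ToInt(rd)
    for (strand in c("+", "-")) {
      ints <- if (strand == "+") ints_f else rev(comp256[ints_f])
      sq <- if (strand == "+") rd else intToUtf8(ints)
      cd <- kmer_codes(CODE256[ints], k)
      probes <- seq(1L, len - k + 1L, by = probe_step)
      his <- findInterval(cd[probes], lib_code)
      cand_ref <- integer(0); cand_off <- integer(0)
      for (pi in seq_along(probes)) {
        p <- probes[pi]
        x <- cd[p]
        if (is.na(x)) next
        j <- his[pi]
        if (is.na(j)) next
        cnt <- 0L
        while (j >= 1L && cnt < 60L && lib_code[j] == x) {
          cand_ref <- c(cand_ref, lib_ref[j])
          cand_off <- c(cand_off, lib_pos[j] - p + 1L)
          j <- j - 1L; cnt <- cnt + 1L
        }
        if (length(cand_ref) >= 4L * max_candidates) break
      }
      if (length(cand_ref) == 0L) next
      keyed <- !duplicated(cand_ref * 1e9 + cand_off)
      cand_ref <- cand_ref[keyed]; cand_off <- cand_off[keyed]
      if (length(cand_ref) > max_candidates) {
        cand_ref <- cand_ref[seq_len(max_candidates)]
        cand_off <- cand_off[seq_len(max_candidates)]
      }
      for (ci in seq_along(cand_ref)) {
        r <- cand_ref[ci]; off <- cand_off[ci]
        s_ref <- max(1L, off); e_ref <- min(ref_len[r], off + len - 1L)
        aligned <- e_ref - s_ref + 1L
        if (aligned < min_aln) next
        seg <- (s_ref - off + 1L):(e_ref - off + 1L)
        matches <- sum(ints[seg] == ref_int[[r]][s_ref:e_ref])
        if (matches / aligned < similarity) next
        if (matches > best_score) {
          best_score <- matches
          best <- list(ref = r, s = s_ref, e = e_ref, strand = strand,
                       identity = matches / aligned, aligned = aligned,
                       seq = substr(sq, seg[1L], seg[length(seg)]))
          best_ties <- r
        } else if (matches == best_score && !(r %in% best_ties)) {
          best_ties <- c(best_ties, r)
        }
      }
    }
    if (!is.null(best)) {
      n_out <- n_out + 1L
      res_read[n_out] <- i; res_ref[n_out] <- best$ref
      res_s[n_out] <- best$s; res_e[n_out] <- best$e
      res_strand[n_out] <- best$strand
      res_id[n_out] <- best$identity; res_aln[n_out] <- best$aligned
      res_nbest[n_out] <- length(best_ties)
      res_best[n_out] <- paste(sort(best_ties), collapse = ",")
      res_seq[n_out] <- best$seq
    }
  }
  keep <- seq_len(n_out)
  data.frame(read = res_read[keep], ref = res_ref[keep],
             ref_start = res_s[keep], ref_end = res_e[keep],
             strand = res_strand[keep], identity = res_id[keep],
             aligned = res_aln[keep], n_best = res_nbest[keep],
             best_refs = res_best[keep], oriented_seq = res_seq[keep],
             stringsAsFactors = FALSE)
}

#' Map reads to a full-length element library
#'
#' Assigns every read to its best-scoring element (both strands tried),
#' keeping hits where at least `length_fraction` of the read aligns at
#' `similarity` identity or better. Reads tied between several elements
#' are either reported with all tied element ids (`tie_policy =
#' "ambiguous"`, the default) or resolved uniformly at random under the
#' given seed (`tie_policy = "random"`, mimicking single-assignment
#' mappers).
#'
#' @param reads character vector of read sequences or a `read_sim`
#'   data.frame.
#' @param library named character vector of element sequences (see
#'   [element_sequences()]).
#' @param length_fraction,similarity mapping acceptance filters
#'   (defaults 0.9 and 0.8).
#' @param tie_policy `"ambiguous"` or `"random"`.
#' @param seed integer; used only to break ties under `"random"`.
#' @return data.frame with one row per read: `read_id`, `element_id`
#'   (NA when unmapped), `identity`, `n_best`, `best_elements`
#'   (comma-separated ids of all tied best elements), `status`
#'   (mapped/unmapped).
#' @export
map_reads <- function(reads, library, length_fraction = 0.9,
                      similarity = 0.8,
                      tie_policy = c("ambiguous", "random"), seed = NULL) {
  tie_policy <- match.arg(tie_policy)
  if (length(library) == 0L) stop("empty element library")
  ids <- if (is.data.frame(reads)) reads$read_id else
    sprintf("read%07d", seq_along(reads))
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  hits <- map_reads_ungapped(seqs, library,
                             length_fraction = length_fraction,
                             similarity = similarity)
  n <- length(seqs)
  out <- data.frame(read_id = ids, element_id = NA_character_,
                    identity = NA_real_, n_best = 0L,
                    best_elements = NA_character_, status = "unmapped",
                    stringsAsFactors = FALSE)
  if (nrow(hits) > 0L) {
    lib_ids <- names(library)
    best_ids <- vapply(strsplit(hits$best_refs, ",", fixed = TRUE),
                       function(x) paste(lib_ids[as.integer(x)],
                                         collapse = ","), character(1L))
    chosen <- lib_ids[hits$ref]
    if (tie_policy == "random") {
      multi <- which(hits$n_best > 1L)
      if (length(multi) > 0L) with_seed(seed, {
        for (m in multi) {
          opts <- strsplit(hits$best_refs[m], ",", fixed = TRUE)[[1L]]
          chosen[m] <- lib_ids[as.integer(sample(opts, 1L))]
        }
      })
      hits$n_best <- 1L
      best_ids <- chosen
    }
    out$element_id[hits$read] <- chosen
    out$identity[hits$read] <- hits$identity
    out$n_best[hits$read] <- hits$n_best
    out$best_elements[hits$read] <- best_ids
    out$status[hits$read] <- "mapped"
  }
  out
}

#' Extract element sequences from a genome
#'
#' @param elements `ltr_elements` data.frame (or the simulator's truth
#'   table).
#' @param genome named character vector or `ltr_genome_sim`.
#' @return named character vector (names = element ids).
#' @export
element_sequences <- function(elements, genome) {
  if (inherits(genome, "ltr_genome_sim")) genome <- genome$genome
  out <- vapply(seq_len(nrow(elements)), function(i)
    substr(genome[[elements$chrom[i]]], elements$start[i], elements$end[i]),
    character(1L))
  names(out) <- elements$element_id
  out
}

#' Genome proportions per lineage and superfamily
#'
#' Aggregates read assignments by lineage; the genome proportion of a
#' lineage is its mapped-read count divided by the *total* read count
#' (the read fraction is the standard proxy for the genomic fraction).
#' Reads whose tied best elements belong to a single lineage count for
#' that lineage; ties across lineages go to an `ambiguous` row.
#' Unassigned reads form the `unmapped` row, so proportions always sum
#' to 1 exactly.
#'
#' @param assignments data.frame from [map_reads()].
#' @param annotations data.frame with `element_id`, `lineage`,
#'   `superfamily` (from [annotate_elements()] or simulator truth).
#' @return data.frame of class `abundance_table`: `superfamily`,
#'   `lineage`, `reads`, `proportion`; attribute `superfamily_totals`.
#' @export
proportions <- function(assignments, annotations) {
  n_total <- nrow(assignments)
  lin_of <- stats::setNames(annotations$lineage, annotations$element_id)
  sup_of <- stats::setNames(annotations$superfamily, annotations$element_id)
  lab_lin <- rep("unmapped", n_total)
  lab_sup <- rep("unmapped", n_total)
  mapped <- which(assignments$status == "mapped")
  if (length(mapped) > 0L) {
    bl <- strsplit(assignments$best_elements[mapped], ",", fixed = TRUE)
    for (j in seq_along(mapped)) {
      lins <- unique(lin_of[bl[[j]]])
      sups <- unique(sup_of[bl[[j]]])
      lab_lin[mapped[j]] <- if (length(lins) == 1L) lins else "ambiguous"
      lab_sup[mapped[j]] <- if (length(sups) == 1L) sups else "ambiguous"
    }
  }
  tab <- table(lab_sup, lab_lin)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("superfamily", "lineage", "reads")
  df <- df[df$reads > 0L | df$lineage == df$superfamily, , drop = FALSE]
  df <- df[df$reads > 0L, , drop = FALSE]
  df$proportion <- df$reads / n_total
  ord <- order(match(df$superfamily,
                     c("Copia", "Gypsy", "undetermined", "ambiguous",
                       "unmapped")), -df$proportion)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  sup <- stats::aggregate(cbind(reads = df$reads,
                                proportion = df$proportion),
                          by = list(superfamily = df$superfamily), FUN = sum)
  attr(df, "superfamily_totals") <- sup
  attr(df, "n_total_reads") <- n_total
  class(df) <- c("abundance_table", "data.frame")
  df
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d reads\n", attr(x, "n_total_reads")))
  print.data.frame(as.data.frame(x), digits = 4)
  cat("superfamily totals:\n")
  print.data.frame(attr(x, "superfamily_totals"), digits = 4)
  invisible(x)
}
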