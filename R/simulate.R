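# Synthetic data generation: K2P sequence mutation, single elements, whole
# repeat-rich genomes with known truth, short reads, and dominant-marker
# populations.

#' Mutate a sequence under the Kimura two-parameter process
#'
#' Applies site-wise substitutions so that the expected K2P *distance* to
#' the input equals `expected_divergence` (substitutions/site). Each site
#' is resolved from the exact K2P transition-probability matrix at that
#' distance, so multiple hits are modelled and the [k2p()] estimator is
#' consistent for the requested divergence. Indels are not introduced.
#'
#' @param seq nucleotide string (A/C/G/T; other characters left untouched).
#' @param expected_divergence target distance in substitutions/site (>= 0).
#' @param ts_tv_ratio transition:transversion ratio (> 0); default 2.
#' @param seed integer or NULL; the result is deterministic given the seed.
#' @return mutated nucleotide string of the same length.
#' @export
#' @examples
#' mutate_k2p("ACGTACGT", 0)                 # unchanged
#' mutate_k2p("ACGTACGT", 0.5, seed = 1)
mutate_k2p <- function(seq, expected_divergence, ts_tv_ratio = 2,
                       seed = NULL) {
  if (expected_divergence < 0) stop("'expected_divergence' must be >= 0")
  if (ts_tv_ratio <= 0) stop("'ts_tv_ratio' must be > 0")
  if (expected_divergence == 0) return(seq)
  with_seed(seed, {
    chars <- s2c(seq)
    code <- base_codes(chars)
    ok <- !is.na(code)
    pq <- k2p_expected_pq(expected_divergence, ts_tv_ratio)
    u <- stats::runif(sum(ok))
    cc <- code[ok]
    # transition flips parity partner: A<->G (0<->2), C<->T (1<->3)
    new <- cc
    is_ts <- u < pq["P"]
    is_tv <- !is_ts & u < pq["P"] + pq["Q"]
    new[is_ts] <- (cc[is_ts] + 2L) %% 4L
    if (any(is_tv)) {
      # each of the two transversion targets equally likely
      pick <- sample(c(1L, 3L), sum(is_tv), replace = TRUE)
      new[is_tv] <- (cc[is_tv] + pick) %% 4L
    }
    chars[ok] <- code_to_base(new)
    c2s(chars)
  })
}

#' Simulate one full-length LTR retrotransposon of known age
#'
#' Both LTR copies start identical (as at the moment of insertion) and are
#' then mutated independently with expected divergence `rate * age_mya *
#' 1e6` each, so the expected *inter-LTR* K2P distance is `2 * rate * age`.
#' The internal region is mutated at the same per-site expectation.
#'
#' @param template a `lineage_template` (see [lineage_templates()]).
#' @param age_mya true insertion age in million years (>= 0).
#' @param rate substitution rate per site per year (> 0); default `2e-8`.
#' @param seed integer or NULL.
#' @return list with `sequence` (nucleotide string) and `truth`, a one-row
#'   data.frame with lineage, superfamily, LTR/internal intervals (element-
#'   relative, 1-based inclusive) and `true_age`.
#' @export
simulate_element <- function(template, age_mya, rate = 2e-8, seed = NULL) {
  if (age_mya < 0) stop("'age_mya' must be >= 0")
  if (rate <= 0) stop("'rate' must be > 0")
  d <- rate * age_mya * 1e6
  with_seed(seed, {
    ltr5 <- mutate_k2p(template$ltr_consensus, d)
    ltr3 <- mutate_k2p(template$ltr_consensus, d)
    internal <- mutate_k2p(template$internal_consensus, d)
    L1 <- nchar(ltr5); Li <- nchar(internal)
    list(sequence = paste0(ltr5, internal, ltr3),
         truth = data.frame(
           lineage = template$lineage_name,
           superfamily = template$superfamily,
           ltr5_start = 1L, ltr5_end = L1,
           internal_start = L1 + 1L, internal_end = L1 + Li,
           ltr3_start = L1 + Li + 1L, ltr3_end = 2L * L1 + Li,
           true_age = age_mya, stringsAsFactors = FALSE))
  })
}

# One decoy block: a solo LTR (the recombination remnant of an element) or
# a one-LTR truncated fragment. Both retain a real LTR so they stress the
# detector the way real remnants do.
.simulate_decoy <- function(template, age_mya, type, rate) {
  d <- rate * age_mya * 1e6
  if (type == "solo_ltr") {
    list(seq = mutate_k2p(template$ltr_consensus, d), type = type)
  } else {
    el <- simulate_element(template, age_mya, rate)
    tr <- el$truth
    keep <- if (stats::runif(1) < 0.5) {
      # 3'-truncated: 5' LTR plus 30-70% of the internal region
      c(1L, tr$internal_start +
          as.integer((tr$internal_end - tr$internal_start) *
                       stats::runif(1, 0.3, 0.7)))
    } else {
      c(tr$internal_end -
          as.integer((tr$internal_end - tr$internal_start) *
                       stats::runif(1, 0.3, 0.7)),
        tr$ltr3_end)
    }
    list(seq = substr(el$sequence, keep[1], keep[2]), type = type)
  }
}

#' Build a synthetic repeat-rich genome with known truth
#'
#' Inserts simulated full-length elements (plus optional solo-LTR and
#' truncated-fragment decoys) into an i.i.d. random background at
#' non-overlapping — or deliberately nested — positions, each flanked by a
#' target-site duplication (TSD). Gene intervals and primer-site placements
#' are recorded with exact coordinates.
#'
#' @param element_specs data.frame with columns `lineage`, `age_mya`,
#'   `count`: how many elements of each lineage/age to insert.
#' @param templates named list of `lineage_template`s.
#' @param background_length background size in bp.
#' @param gene_count number of gene intervals to place in inter-element
#'   background (coordinates only).
#' @param gene_length gene interval length in bp.
#' @param primer_sites_spec either `NULL`, or
#'   `list(primer =, count =)` to plant `count` copies of a primer sequence
#'   at random background positions, or `list(primer =, positions =)` with
#'   a data.frame of explicit `pos` (1-based start) and `strand` values.
#'   Planting overwrites background bases, keeping coordinates stable.
#' @param nesting_fraction fraction of elements inserted inside a
#'   previously placed element rather than into background, in `[0, 1]`.
#' @param solo_ltr_count,fragment_count decoy counts (default 5 each).
#' @param tsd_len TSD length in bp (4-6; default 5).
#' @param rate substitution rate per site per year.
#' @param gc background GC content.
#' @param chrom chromosome name for all output coordinates.
#' @param seed integer; identical seeds give byte-identical output.
#' @return an object of class `ltr_genome_sim`: a list with `genome`
#'   (named character vector of chromosome sequences), `truth` (data.frame
#'   of all inserted repeats, 1-based inclusive coordinates), `genes`,
#'   `primer_sites`, and the generation parameters.
#' @export
build_genome <- function(element_specs,
                         templates = lineage_templates(),
                         background_length = 2e6,
                         gene_count = 0, gene_length = 2000L,
                         primer_sites_spec = NULL,
                         nesting_fraction = 0,
                         solo_ltr_count = 5L, fragment_count = 5L,
                         tsd_len = 5L, rate = 2e-8, gc = 0.5,
                         chrom = "chr1", seed = NULL) {
  stopifnot(is.data.frame(element_specs),
            all(c("lineage", "age_mya", "count") %in% names(element_specs)))
  if (any(element_specs$count < 0)) stop("element counts must be >= 0")
  if (nesting_fraction < 0 || nesting_fraction > 1)
    stop("'nesting_fraction' must be in [0, 1]")
  if (tsd_len < 4L || tsd_len > 6L) stop("'tsd_len' must be 4-6")
  background_length <- as.integer(background_length)

  with_seed(seed, {
    bg <- random_dna(background_length, gc = gc)
    specs <- element_specs[rep(seq_len(nrow(element_specs)),
                               element_specs$count), c("lineage", "age_mya")]
    n_elem <- nrow(specs)
    ages_pool <- if (n_elem > 0) specs$age_mya else 1

    # --- simulate blocks (a block = one top-level insert and its records)
    blocks <- list()
    rec_template <- function() data.frame(
      element_id = character(0), type = character(0), lineage = character(0),
      superfamily = character(0), start = integer(0), end = integer(0),
      ltr5_start = integer(0), ltr5_end = integer(0),
      ltr3_start = integer(0), ltr3_end = integer(0),
      true_age = numeric(0), strand = character(0), tsd = character(0),
      nested_in = character(0), stringsAsFactors = FALSE)

    elem_idx <- 0L
    add_element_record <- function(el, strand, id, nested_in = NA_character_) {
      tr <- el$truth
      L <- nchar(el$sequence)
      if (strand == "+") {
        c5 <- c(tr$ltr5_start, tr$ltr5_end); c3 <- c(tr$ltr3_start, tr$ltr3_end)
      } else {
        # coordinates reported on the forward strand of the inserted copy
        c5 <- c(L - tr$ltr3_end + 1L, L - tr$ltr3_start + 1L)
        c3 <- c(L - tr$ltr5_end + 1L, L - tr$ltr5_start + 1L)
      }
      data.frame(element_id = id, type = "element", lineage = tr$lineage,
                 superfamily = tr$superfamily, start = 1L, end = L,
                 ltr5_start = c5[1], ltr5_end = c5[2],
                 ltr3_start = c3[1], ltr3_end = c3[2],
                 true_age = tr$true_age, strand = strand,
                 tsd = NA_character_, nested_in = nested_in,
                 stringsAsFactors = FALSE)
    }

    if (n_elem > 0) {
      total_len_guess <- 0
      for (i in seq_len(n_elem)) {
        tp <- templates[[specs$lineage[i]]]
        if (is.null(tp)) stop("unknown lineage: ", specs$lineage[i])
        el <- simulate_element(tp, specs$age_mya[i], rate)
        strand <- sample(c("+", "-"), 1L)
        seq_i <- if (strand == "+") el$sequence else revcomp(el$sequence)
        elem_idx <- elem_idx + 1L
        id <- sprintf("TE%04d", elem_idx)
        total_len_guess <- total_len_guess + nchar(seq_i)

        nest <- length(blocks) > 0 && stats::runif(1) < nesting_fraction
        if (!nest) {
          rec <- add_element_record(el, strand, id)
          blocks[[length(blocks) + 1L]] <- list(seq = seq_i, records = rec)
        } else {
          bi <- sample.int(length(blocks), 1L)
          blk <- blocks[[bi]]
          host <- blk$records[blk$records$type == "element" &
                                is.na(blk$records$nested_in), , drop = FALSE]
          host <- host[1L, ]
          # insertion point inside the host internal region
          lo <- host$ltr5_end + 50L; hi <- host$ltr3_start - 50L - tsd_len
          if (hi <= lo) {
            rec <- add_element_record(el, strand, id)
            blocks[[length(blocks) + 1L]] <- list(seq = seq_i, records = rec)
          } else {
            t0 <- sample(lo:hi, 1L)  # insert after local position t0
            tsd <- substr(blk$seq, t0 + 1L, t0 + tsd_len)
            ins_len <- nchar(seq_i) + tsd_len
            blk$seq <- paste0(substr(blk$seq, 1L, t0 + tsd_len), seq_i,
                              substr(blk$seq, t0 + 1L, nchar(blk$seq)))
            r <- blk$records
            for (cl in c("start", "end", "ltr5_start", "ltr5_end",
                         "ltr3_start", "ltr3_end")) {
              shift <- r[[cl]] > t0
              r[[cl]][shift] <- r[[cl]][shift] + ins_len
            }
            rec <- add_element_record(el, strand, id,
                                      nested_in = host$element_id)
            rec$start <- t0 + tsd_len + 1L
            rec$end <- rec$start + nchar(seq_i) - 1L
            for (cl in c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end"))
              rec[[cl]] <- rec[[cl]] + rec$start - 1L
            rec$tsd <- tsd
            blk$records <- rbind(r, rec)
            blocks[[bi]] <- blk
          }
        }
      }
      if (total_len_guess > background_length)
        stop("total inserted length exceeds background capacity")
    }

    # --- decoys
    n_dec <- solo_ltr_count + fragment_count
    if (n_dec > 0) {
      types <- rep(c("solo_ltr", "fragment"),
                   c(solo_ltr_count, fragment_count))
      for (ty in types) {
        tp <- templates[[sample(names(templates), 1L)]]
        if (n_elem > 0) tp <- templates[[sample(specs$lineage, 1L)]]
        dec <- .simulate_decoy(tp, sample(ages_pool, 1L), ty, rate)
        strand <- sample(c("+", "-"), 1L)
        seq_i <- if (strand == "+") dec$seq else revcomp(dec$seq)
        elem_idx <- elem_idx + 1L
        rec <- data.frame(element_id = sprintf("TE%04d", elem_idx),
                          type = ty, lineage = tp$lineage_name,
                          superfamily = tp$superfamily,
                          start = 1L, end = nchar(seq_i),
                          ltr5_start = NA_integer_, ltr5_end = NA_integer_,
                          ltr3_start = NA_integer_, ltr3_end = NA_integer_,
                          true_age = NA_real_, strand = strand,
                          tsd = NA_character_, nested_in = NA_character_,
                          stringsAsFactors = FALSE)
        blocks[[length(blocks) + 1L]] <- list(seq = seq_i, records = rec)
      }
    }

    # --- place blocks into the background with TSDs
    nb <- length(blocks)
    truth <- rec_template()
    free_segments <- data.frame(start = 1L, end = background_length)
    genome <- bg
    if (nb > 0) {
      pts <- NULL
      for (try in 1:200) {
        cand <- sort(sample.int(background_length - tsd_len - 1L, nb))
        if (nb == 1L || all(diff(cand) > tsd_len)) { pts <- cand; break }
      }
      if (is.null(pts)) stop("could not place inserts; background too small")
      pieces <- character(2L * nb + 1L)
      offsets <- integer(nb)
      prev <- 1L
      added <- 0L
      for (i in seq_len(nb)) {
        t0 <- pts[i]
        pieces[2L * i - 1L] <- substr(bg, prev, t0 + tsd_len)
        pieces[2L * i] <- blocks[[i]]$seq
        offsets[i] <- t0 + tsd_len + added
        added <- added + nchar(blocks[[i]]$seq) + tsd_len
        prev <- t0 + 1L
      }
      pieces[2L * nb + 1L] <- substr(bg, prev, background_length)
      genome <- paste(pieces, collapse = "")
      for (i in seq_len(nb)) {
        r <- blocks[[i]]$records
        for (cl in c("start", "end", "ltr5_start", "ltr5_end",
                     "ltr3_start", "ltr3_end"))
          r[[cl]] <- r[[cl]] + offsets[i]
        top <- is.na(r$nested_in)
        r$tsd[top] <- substr(bg, pts[i] + 1L, pts[i] + tsd_len)
        truth <- rbind(truth, r)
      }
      # background coordinates (final genome) still free for genes/primers
      fin_pts <- offsets  # block i occupies offsets[i]+1 .. +len
      fin_len <- vapply(blocks, function(b) nchar(b$seq), integer(1L))
      free_segments <- data.frame(
        start = c(1L, fin_pts + fin_len + 1L),
        end = c(fin_pts, nchar(genome)))
      free_segments <- free_segments[free_segments$end - free_segments$start
                                     >= 200L, , drop = FALSE]
    }
    truth$chrom <- rep(chrom, nrow(truth))
    truth <- truth[, c("element_id", "type", "chrom", "start", "end",
                       "strand", "lineage", "superfamily",
                       "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end",
                       "true_age", "tsd", "nested_in")]

    # --- genes in free background
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    if (gene_count > 0) {
      placed <- integer(0)
      guard <- 0L
      while (length(placed) < gene_count && guard < 50000L) {
        guard <- guard + 1L
        seg <- free_segments[sample.int(nrow(free_segments), 1L), ]
        if (seg$end - seg$start + 1L < gene_length + 2L) next
        s <- sample(seg$start:(seg$end - gene_length), 1L)
        if (any(abs(placed - s) < gene_length + 10L)) next
        placed <- c(placed, s)
      }
      if (length(placed) < gene_count)
        stop("could not place ", gene_count, " non-overlapping genes")
      placed <- sort(placed)
      genes <- data.frame(gene_id = sprintf("gene%03d", seq_along(placed)),
                          chrom = chrom, start = placed,
                          end = placed + gene_length - 1L,
                          strand = "+", stringsAsFactors = FALSE)
    }

    # --- primer-site planting (overwrites background bases in place)
    primer_sites <- data.frame(chrom = character(0), start = integer(0),
                               strand = character(0), stringsAsFactors = FALSE)
    if (!is.null(primer_sites_spec)) {
      primer <- toupper(primer_sites_spec$primer)
      plen <- nchar(primer)
      if (!is.null(primer_sites_spec$positions)) {
        pos_df <- primer_sites_spec$positions
      } else {
        cnt <- primer_sites_spec$count
        seg <- free_segments[free_segments$end - free_segments$start > plen + 2L, ]
        pos <- integer(0)
        guard <- 0L
        while (length(pos) < cnt && guard < 100000L) {
          guard <- guard + 1L
          sg <- seg[sample.int(nrow(seg), 1L), ]
          s <- sample(sg$start:(sg$end - plen), 1L)
          if (any(abs(pos - s) <= plen)) next
          pos <- c(pos, s)
        }
        if (length(pos) < cnt) stop("could not plant ", cnt, " primer sites")
        pos_df <- data.frame(pos = sort(pos),
                             strand = sample(c("+", "-"), cnt, replace = TRUE))
      }
      for (i in seq_len(nrow(pos_df))) {
        ins <- if (pos_df$strand[i] == "+") primer else revcomp(primer)
        substr(genome, pos_df$pos[i], pos_df$pos[i] + plen - 1L) <- ins
      }
      primer_sites <- data.frame(chrom = chrom, start = pos_df$pos,
                                 strand = pos_df$strand,
                                 stringsAsFactors = FALSE)
    }

    g <- stats::setNames(genome, chrom)
    structure(list(genome = g, truth = truth, genes = genes,
                   primer_sites = primer_sites,
                   params = list(background_length = background_length,
                                 tsd_len = tsd_len, rate = rate,
                                 nesting_fraction = nesting_fraction,
                                 seed = seed)),
              class = "ltr_genome_sim")
  })
}

#' @export
print.ltr_genome_sim <- function(x, ...) {
  tt <- table(factor(x$truth$type,
                     levels = c("element", "solo_ltr", "fragment")))
  cat(sprintf(paste0(
    "<ltr_genome_sim> %d chromosome(s), %s bp\n",
    "  full-length elements: %d   solo LTRs: %d   fragments: %d\n",
    "  genes: %d   planted primer sites: %d\n"),
    length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
    tt[["element"]], tt[["solo_ltr"]], tt[["fragment"]],
    nrow(x$genes), nrow(x$primer_sites)))
  invisible(x)
}

#' Simulate single-end short reads from a genome
#'
#' Reads are sampled uniformly along the genome on a uniformly random
#' strand, with a uniform per-base substitution error rate. The read count
#' is `ceiling(coverage * genome_length / read_length)`.
#'
#' @param genome named character vector of chromosome sequences, or an
#'   `ltr_genome_sim` object.
#' @param read_length read length in nt (default 85).
#' @param coverage target fold-coverage (> 0).
#' @param error_rate per-base substitution error probability (default 0.005).
#' @param seed integer or NULL.
#' @return data.frame of class `read_sim` with columns `read_id`, `seq`,
#'   `qual`, and truth columns `chrom`, `pos`, `strand`.
#' @export
simulate_reads <- function(genome, read_length = 85L, coverage,
                           error_rate = 0.005, seed = NULL) {
  if (inherits(genome, "ltr_genome_sim")) genome <- genome$genome
  if (coverage <= 0) stop("'coverage' must be > 0")
  lens <- nchar(genome)
  if (any(read_length > lens)) stop("'read_length' exceeds genome length")
  n_reads <- as.integer(ceiling(coverage * sum(lens) / read_length))
  with_seed(seed, {
    ci <- if (length(genome) == 1L) rep(1L, n_reads) else
      sample(seq_along(genome), n_reads, replace = TRUE, prob = lens)
    pos <- floor(stats::runif(n_reads) * (lens[ci] - read_length + 1L)) + 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(genome[ci], pos, pos + read_length - 1L)
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    if (error_rate > 0) {
      n_err <- stats::rbinom(n_reads, read_length, error_rate)
      for (i in which(n_err > 0L)) {
        p <- sample.int(read_length, n_err[i])
        ch <- s2c(seqs[i])
        ch[p] <- vapply(ch[p], function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1L))
        seqs[i] <- c2s(ch)
      }
    }
    out <- data.frame(read_id = sprintf("read%07d", seq_len(n_reads)),
                      seq = seqs,
                      qual = strrep("I", read_length),
                      chrom = names(genome)[ci], pos = pos, strand = strand,
                      stringsAsFactors = FALSE)
    class(out) <- c("read_sim", "data.frame")
    out
  })
}

#' Generative truth for a dominant-marker population
#'
#' Draws per-subpopulation band-allele frequencies and per-accession
#' admixture proportions. Frequencies follow Beta(0.5, 0.5) — most loci
#' end up strongly differentiated between subpopulations — and admixture
#' rows follow a symmetric Dirichlet. So that the truth really contains
#' `K_true` subpopulations, each accession's *largest* ancestry
#' component is assigned to a home subpopulation in round-robin order:
#' the Dirichlet shape of every row is untouched, but every
#' subpopulation anchors an equal share of accessions instead of
#' occasionally ending up with next to no ancestry mass (which would
#' make the labelled K_true fictitious in a small panel).
#'
#' @param n_accessions number of accessions.
#' @param K_true number of ancestral subpopulations (>= 1).
#' @param n_loci number of band loci.
#' @param freq_shape Beta shape parameter for allele frequencies.
#' @param admix_alpha Dirichlet concentration for admixture rows; small
#'   values give mostly-assigned accessions, large values heavy admixture.
#' @param seed integer or NULL.
#' @return object of class `population_truth`: list with `allele_freqs`
#'   (K x L), `Q_true` (n x K), `K_true`, `n_accessions`.
#' @export
make_population_truth <- function(n_accessions, K_true, n_loci,
                                  freq_shape = 0.5, admix_alpha = 0.3,
                                  seed = NULL) {
  if (K_true < 1L) stop("'K_true' must be >= 1")
  with_seed(seed, {
    f <- matrix(stats::rbeta(K_true * n_loci, freq_shape, freq_shape),
                nrow = K_true, ncol = n_loci,
                dimnames = list(paste0("pop", seq_len(K_true)),
                                sprintf("L%03d", seq_len(n_loci))))
    q <- matrix(stats::rgamma(n_accessions * K_true, admix_alpha, 1),
                nrow = n_accessions)
    q <- q / rowSums(q)
    if (K_true > 1L) {
      home <- rep(seq_len(K_true), length.out = n_accessions)
      for (i in seq_len(n_accessions)) {
        vals <- sort(q[i, ], decreasing = TRUE)
        others <- setdiff(seq_len(K_true), home[i])
        if (length(others) > 1L) others <- sample(others)
        q[i, c(home[i], others)] <- vals
      }
    }
    dimnames(q) <- list(sprintf("acc%02d", seq_len(n_accessions)),
                        paste0("pop", seq_len(K_true)))
    structure(list(allele_freqs = f, Q_true = q, K_true = K_true,
                   n_accessions = n_accessions),
              class = "population_truth")
  })
}

#' Simulate a dominant-marker presence/absence matrix
#'
#' For diploid accession *i* at locus *l*, each haplotype draws its
#' subpopulation of origin from the accession's admixture row `Q[i, ]` and
#' then its band allele from that subpopulation's frequency, so the band is
#' absent only when both haplotypes carry the absence allele:
#' `P(band) = 1 - a^2` with `a = sum_k Q[i,k] * (1 - f[k,l])`.
#'
#' @param truth a `population_truth` object (see [make_population_truth()]),
#'   or any list with `allele_freqs` and `Q_true`.
#' @param seed integer or NULL.
#' @return binary matrix (accessions x loci) of class `irap_matrix`.
#' @export
simulate_marker_population <- function(truth, seed = NULL) {
  f <- truth$allele_freqs
  q <- truth$Q_true
  if (any(abs(rowSums(q) - 1) > 1e-8))
    stop("admixture rows of Q must sum to 1")
  if (any(f < 0 | f > 1)) stop("allele frequencies must be in [0, 1]")
  with_seed(seed, {
    a <- q %*% (1 - f)            # P(one haplotype lacks the band allele)
    p <- 1 - a * a
    m <- matrix(stats::rbinom(length(p), 1L, p), nrow = nrow(p),
                dimnames = dimnames(p))
    class(m) <- c("irap_matrix", class(m))
    m
  })
}
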