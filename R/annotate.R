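# Lineage annotation: protein-domain scanning of element internal regions,
# superfamily calls from domain order, and homology rescue of
# unclassified elements.

utils::globalVariables("BLOSUM80")

.blosum80 <- function() {
  e <- new.env()
  utils::data("BLOSUM80", package = "Biostrings", envir = e)
  get("BLOSUM80", envir = e)
}

# Six-frame translation; returns list of peptides named +1..+3, -1..-3.
six_frame_translate <- function(dna) {
  rc <- revcomp(dna)
  peps <- c(
    lapply(1:3, function(f) translate_dna(substr(dna, f, nchar(dna)))),
    lapply(1:3, function(f) translate_dna(substr(rc, f, nchar(rc)))))
  names(peps) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  peps
}

#' Scan an element's internal region for retrotransposon protein domains
#'
#' Translates the sequence in all six frames and locally aligns each frame
#' against every exemplar peptide (BLOSUM80 scoring). The best
#' above-threshold hit per domain type (GAG, PROT, INT, RT, RH) is
#' reported with its frame, element-relative nucleotide interval, score
#' and best-matching lineage.
#'
#' @param sequence nucleotide string (typically the internal region of a
#'   detected element).
#' @param exemplars data.frame with columns `domain`, `lineage`,
#'   `superfamily`, `peptide` (see [domain_exemplars()],
#'   [read_exemplar_fasta()]).
#' @param min_score minimum local alignment score (raw BLOSUM80 units)
#'   for a hit to be reported; default 100.
#' @return data.frame of domain hits (`domain`, `frame`, `start`, `end`,
#'   `score`, `best_lineage`), with an attribute `lineage_scores` (summed
#'   best scores per lineage) and `lineage_superfamily` (named map) used
#'   by [classify_hits()].
#' @export
scan_domains <- function(sequence, exemplars = domain_exemplars(),
                         min_score = 100) {
  if (is.null(exemplars) || nrow(exemplars) == 0L)
    stop("empty exemplar reference set")
  bl <- .blosum80()
  peps <- six_frame_translate(sequence)
  pat <- Biostrings::AAStringSet(exemplars$peptide)
  hits <- data.frame(domain = character(0), frame = character(0),
                     start = integer(0), end = integer(0),
                     score = numeric(0), best_lineage = character(0),
                     stringsAsFactors = FALSE)
  best <- list()
  lin_scores <- stats::setNames(numeric(0), character(0))
  for (fr in names(peps)) {
    subj <- peps[[fr]]
    if (nchar(subj) < 10L) next
    aln <- Biostrings::pairwiseAlignment(
      pat, Biostrings::AAString(subj), type = "local",
      substitutionMatrix = bl, gapOpening = 10, gapExtension = 1)
    sc <- Biostrings::score(aln)
    st <- Biostrings::start(Biostrings::subject(aln))
    en <- Biostrings::end(Biostrings::subject(aln))
    for (i in seq_along(sc)) {
      if (sc[i] < min_score) next
      d <- exemplars$domain[i]
      # aa position on frame -> element-relative nucleotide interval
      f_off <- as.integer(substr(fr, 2L, 2L))
      if (startsWith(fr, "+")) {
        nt_s <- f_off + (st[i] - 1L) * 3L
        nt_e <- f_off + en[i] * 3L - 1L
      } else {
        L <- nchar(sequence)
        nt_e <- L - (f_off + (st[i] - 1L) * 3L) + 1L
        nt_s <- L - (f_off + en[i] * 3L - 1L) + 1L
      }
      lin_scores[exemplars$lineage[i]] <-
        max(lin_scores[exemplars$lineage[i]], sc[i], 0, na.rm = TRUE)
      if (is.null(best[[d]]) || sc[i] > best[[d]]$score)
        best[[d]] <- data.frame(domain = d, frame = fr, start = nt_s,
                                end = nt_e, score = sc[i],
                                best_lineage = exemplars$lineage[i],
                                stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, c(list(hits), unname(best)))
  rownames(hits) <- NULL
  sup_map <- stats::setNames(exemplars$superfamily, exemplars$lineage)
  sup_map <- sup_map[!duplicated(names(sup_map))]
  attr(hits, "lineage_scores") <- sort(lin_scores, decreasing = TRUE)
  attr(hits, "lineage_superfamily") <- sup_map
  hits
}

#' Classify an element from its domain hits
#'
#' The superfamily is read from the linear order of the enzyme domains
#' when both INT and RT are present — integrase upstream of reverse
#' transcriptase means Copia, the reverse means Gypsy — taking the
#' element's reading strand (majority hit frame sign) into account.
#' Otherwise it falls back to a score-weighted vote over the hits' best
#' lineages. The lineage is the highest-scoring one; an exact score tie
#' leaves the lineage undetermined (the superfamily is kept if
#' unambiguous). An element with all five domain types present is flagged
#' autonomous.
#'
#' @param hits data.frame from [scan_domains()] (possibly empty).
#' @return list of class `lineage_annotation`: `superfamily`, `lineage`,
#'   `autonomous`, `evidence`, `strand`, `n_domains`.
#' @export
classify_hits <- function(hits) {
  und <- structure(list(superfamily = "undetermined",
                        lineage = "undetermined", autonomous = FALSE,
                        evidence = "domain", strand = "*", n_domains = 0L),
                   class = "lineage_annotation")
  if (is.null(hits) || nrow(hits) == 0L) return(und)
  sup_map <- attr(hits, "lineage_superfamily")
  lin_scores <- attr(hits, "lineage_scores")
  neg <- startsWith(hits$frame, "-")
  strand <- if (sum(hits$score[neg]) > sum(hits$score[!neg])) "-" else "+"

  superfamily <- NA_character_
  if (all(c("INT", "RT") %in% hits$domain)) {
    pos_int <- hits$start[hits$domain == "INT"][1L]
    pos_rt <- hits$start[hits$domain == "RT"][1L]
    if (strand == "-") { pos_int <- -pos_int; pos_rt <- -pos_rt }
    superfamily <- if (pos_int < pos_rt) "Copia" else "Gypsy"
  } else {
    # score-weighted vote over hit lineages' superfamilies
    v <- tapply(hits$score, sup_map[hits$best_lineage], sum)
    if (length(v) > 0L) {
      top <- names(v)[v == max(v)]
      superfamily <- if (length(top) == 1L) top else "undetermined"
    }
  }
  lineage <- "undetermined"
  if (length(lin_scores) > 0L) {
    if (!is.null(sup_map) && !is.na(superfamily) &&
        superfamily %in% c("Copia", "Gypsy")) {
      consistent <- lin_scores[sup_map[names(lin_scores)] == superfamily]
    } else consistent <- lin_scores
    if (length(consistent) > 0L) {
      top <- names(consistent)[consistent == max(consistent)]
      if (length(top) == 1L) lineage <- top
    }
  }
  if (is.na(superfamily)) superfamily <- "undetermined"
  structure(list(superfamily = superfamily, lineage = lineage,
                 autonomous = all(DOMAIN_TYPES %in% hits$domain),
                 evidence = "domain", strand = strand,
                 n_domains = length(unique(hits$domain))),
            class = "lineage_annotation")
}

#' @export
print.lineage_annotation <- function(x, ...) {
  cat(sprintf("<lineage_annotation> %s/%s (%s evidence, strand %s, %d domains%s)\n",
              x$superfamily, x$lineage, x$evidence, x$strand, x$n_domains,
              if (x$autonomous) ", autonomous" else ""))
  invisible(x)
}

#' Annotate detected elements at superfamily and lineage level
#'
#' Runs [scan_domains()] + [classify_hits()] on the internal region of
#' every element, then (optionally) rescues undetermined elements by
#' nucleotide homology to the classified ones ([homology_rescue()]).
#'
#' @param elements an `ltr_elements` data.frame from [detect_ltr()].
#' @param genome the genome the elements were detected in.
#' @param exemplars exemplar peptide set (see [scan_domains()]).
#' @param min_score minimum domain alignment score.
#' @param rescue run homology rescue on undetermined elements.
#' @param min_identity,min_coverage rescue thresholds (percent identity of
#'   the locally aligned region; fraction of the shorter sequence aligned).
#' @return data.frame with one row per element: `element_id`,
#'   `superfamily`, `lineage`, `autonomous`, `evidence`, `strand`,
#'   `n_domains`.
#' @export
annotate_elements <- function(elements, genome,
                              exemplars = domain_exemplars(),
                              min_score = 100, rescue = TRUE,
                              min_identity = 80, min_coverage = 0.5) {
  if (inherits(genome, "ltr_genome_sim")) genome <- genome$genome
  n <- nrow(elements)
  ann <- data.frame(element_id = elements$element_id,
                    superfamily = rep("undetermined", n),
                    lineage = rep("undetermined", n),
                    autonomous = rep(FALSE, n),
                    evidence = rep("domain", n),
                    strand = rep("*", n),
                    n_domains = rep(0L, n), stringsAsFactors = FALSE)
  if (n == 0L) return(ann)
  seqs <- character(n)
  for (i in seq_len(n)) {
    chseq <- genome[[elements$chrom[i]]]
    internal <- substr(chseq, elements$ltr5_end[i] + 1L,
                       elements$ltr3_start[i] - 1L)
    seqs[i] <- substr(chseq, elements$start[i], elements$end[i])
    cl <- classify_hits(scan_domains(internal, exemplars, min_score))
    ann$superfamily[i] <- cl$superfamily
    ann$lineage[i] <- cl$lineage
    ann$autonomous[i] <- cl$autonomous
    ann$strand[i] <- cl$strand
    ann$n_domains[i] <- cl$n_domains
  }
  names(seqs) <- elements$element_id
  if (rescue && any(ann$lineage == "undetermined") &&
      any(ann$lineage != "undetermined"))
    ann <- homology_rescue(ann, seqs, min_identity = min_identity,
                           min_coverage = min_coverage)
  ann
}

#' Rescue unclassified elements by homology to classified ones
#'
#' Each element with an undetermined lineage is screened against all
#' classified elements by shared k-mer content (both strands), and the
#' best subject is verified by local nucleotide alignment. When the
#' aligned region passes the identity and coverage thresholds the subject
#' element's annotation is adopted with `evidence = "homology"`.
#'
#' @param annotations annotation data.frame as from [annotate_elements()].
#' @param sequences named character vector of element sequences (names =
#'   `element_id`).
#' @param min_identity minimum percent identity of the aligned region
#'   (gap-excluded), default 80.
#' @param min_coverage minimum aligned fraction of the shorter sequence,
#'   default 0.5.
#' @param k k-mer size of the screening stage.
#' @return the updated annotation data.frame.
#' @export
homology_rescue <- function(annotations, sequences, min_identity = 80,
                            min_coverage = 0.5, k = 16L) {
  und <- which(annotations$lineage == "undetermined")
  cls <- which(annotations$lineage != "undetermined")
  if (length(cls) == 0L) stop("no classified elements to rescue against")
  if (length(und) == 0L) return(annotations)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  km <- function(s) {
    cd <- kmer_codes(base_codes(s2c(s)), k)
    unique(cd[!is.na(cd)])
  }
  cls_km <- lapply(annotations$element_id[cls],
                   function(id) km(sequences[[id]]))
  for (i in und) {
    q <- sequences[[annotations$element_id[i]]]
    qk <- c(km(q), km(revcomp(q)))
    shared <- vapply(cls_km, function(s) sum(qk %in% s), numeric(1L))
    if (max(shared) == 0) next
    j <- cls[which.max(shared)]
    s <- sequences[[annotations$element_id[j]]]
    # verify against the subject on the strand with more shared k-mers
    qf <- if (sum(km(q) %in% cls_km[[which.max(shared)]]) >=
              sum(km(revcomp(q)) %in% cls_km[[which.max(shared)]])) q else
                revcomp(q)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qf), Biostrings::DNAString(s), type = "local",
      substitutionMatrix = submat, gapOpening = 10, gapExtension = 0.5)
    ident <- Biostrings::pid(aln, type = "PID2")
    aligned <- Biostrings::nchar(aln)
    cov <- aligned / min(nchar(qf), nchar(s))
    if (ident >= min_identity && cov >= min_coverage) {
      annotations$superfamily[i] <- annotations$superfamily[j]
      annotations$lineage[i] <- annotations$lineage[j]
      annotations$evidence[i] <- "homology"
    }
  }
  annotations
}
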