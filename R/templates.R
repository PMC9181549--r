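# Lineage templates: synthetic consensus models of LTR retrotransposon
# families, used by the simulator and as the bundled exemplar set for
# protein-domain annotation.

DOMAIN_TYPES <- c("GAG", "PROT", "INT", "RT", "RH")

# Domain order along the internal region (the Pol polyprotein) is the
# structural signature separating the superfamilies: Copia carries the
# integrase upstream of the reverse transcriptase, Gypsy the reverse.
DOMAIN_ORDER <- list(
  Copia = c("GAG", "PROT", "INT", "RT", "RH"),
  Gypsy = c("GAG", "PROT", "RT", "RH", "INT"))

AA20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")

# codons per amino acid, for reverse translation
.codons_by_aa <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)

random_peptide <- function(n) c2s(sample(AA20, n, replace = TRUE))

reverse_translate <- function(pep) {
  aa <- s2c(pep)
  c2s(vapply(aa, function(x) {
    cs <- .codons_by_aa[[x]]
    cs[sample.int(length(cs), 1L)]
  }, character(1L), USE.NAMES = FALSE))
}

# Translate a nucleotide string in frame 1; codons containing non-ACGT
# become "X", stop codons "*".
translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  c2s(aa)
}

# Default domain lengths in amino acids. RT is kept long enough that its
# nucleotide span always exceeds the 150-nt minimum used for read dating.
DOMAIN_AA_LEN <- c(GAG = 150L, PROT = 100L, INT = 130L, RT = 180L, RH = 100L)

new_lineage_template <- function(lineage_name, superfamily, ltr_len,
                                 spacer_len = 60L, leader_len = 200L,
                                 trailer_len = 200L) {
  stopifnot(superfamily %in% c("Copia", "Gypsy"))
  if (ltr_len < 100L || ltr_len > 3000L)
    stop("LTR length must be within [100, 3000]")
  ltr <- paste0("TG", random_dna(ltr_len - 4L), "CA")
  ord <- DOMAIN_ORDER[[superfamily]]
  parts <- character(0)
  coords <- data.frame(domain = character(0), start = integer(0),
                       end = integer(0), peptide = character(0),
                       stringsAsFactors = FALSE)
  pos <- leader_len
  internal <- random_dna(leader_len)
  for (d in ord) {
    pep <- random_peptide(DOMAIN_AA_LEN[[d]])
    dna <- reverse_translate(pep)
    coords <- rbind(coords, data.frame(
      domain = d, start = pos + 1L, end = pos + nchar(dna),
      peptide = pep, stringsAsFactors = FALSE))
    internal <- paste0(internal, dna, random_dna(spacer_len))
    pos <- pos + nchar(dna) + spacer_len
  }
  internal <- paste0(internal, random_dna(trailer_len))
  structure(list(lineage_name = lineage_name, superfamily = superfamily,
                 ltr_consensus = ltr, internal_consensus = internal,
                 domain_coords = coords),
            class = "lineage_template")
}

#' Built-in synthetic lineage templates
#'
#' Constructs a fixed, reproducible set of consensus models covering both
#' superfamilies and the common plant lineages: Copia (Angela, SIRE, Ale,
#' Bianca) and Gypsy (Tekay of the Chromovirus clade, Retand of the Tat
#' clade). Each template holds an LTR consensus (starting `TG`, ending
#' `CA`), an internal region with GAG/PROT/INT/RT/RH protein-domain
#' segments in the superfamily-specific order, and the domain coordinates.
#'
#' The sequences are synthetic: they carry the *structure* of real
#' families (domain order, LTR bounds, sizes), not their sequences, and
#' serve both as simulator input and as annotation exemplars in tests.
#'
#' @param seed integer; the template set is deterministic given the seed.
#' @return a named list of `lineage_template` objects.
#' @export
lineage_templates <- function(seed = 101L) {
  with_seed(seed, {
    list(
      Angela = new_lineage_template("Angela", "Copia", ltr_len = 1000L),
      SIRE   = new_lineage_template("SIRE",   "Copia", ltr_len = 800L),
      Ale    = new_lineage_template("Ale",    "Copia", ltr_len = 600L),
      Bianca = new_lineage_template("Bianca", "Copia", ltr_len = 700L),
      Tekay  = new_lineage_template("Tekay",  "Gypsy", ltr_len = 1200L),
      Retand = new_lineage_template("Retand", "Gypsy", ltr_len = 1500L))
  })
}

#' @export
print.lineage_template <- function(x, ...) {
  cat(sprintf("<lineage_template> %s (%s): LTR %d nt, internal %d nt, domains %s\n",
              x$lineage_name, x$superfamily, nchar(x$ltr_consensus),
              nchar(x$internal_consensus),
              paste(x$domain_coords$domain, collapse = "-")))
  invisible(x)
}

#' Protein-domain exemplar set from lineage templates
#'
#' Extracts one exemplar peptide per (domain, lineage) from a template set,
#' in the form consumed by [scan_domains()]. Any user-supplied exemplar
#' FASTA with headers `domain|lineage|superfamily` can replace this via
#' [read_exemplar_fasta()].
#'
#' @param templates a list of `lineage_template` objects.
#' @return data.frame with columns `domain`, `lineage`, `superfamily`,
#'   `peptide`.
#' @export
domain_exemplars <- function(templates = lineage_templates()) {
  do.call(rbind, lapply(templates, function(tp) {
    data.frame(domain = tp$domain_coords$domain,
               lineage = tp$lineage_name,
               superfamily = tp$superfamily,
               peptide = tp$domain_coords$peptide,
               stringsAsFactors = FALSE)
  }))
}
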