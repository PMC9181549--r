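# Readers/writers for the formats the pipeline consumes and emits.
# Conventions: internal coordinates are 1-based inclusive (GFF3-native);
# BED is converted at the boundary (0-based half-open).

#' Read a FASTA file
#'
#' Sequences are uppercased and line wrapping removed.
#'
#' @param path file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param x named character vector, or an `ltr_genome_sim` (its genome is
#'   written).
#' @param path file path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "ltr_genome_sim")) x <- x$genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path,
                              width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path file path.
#' @return data.frame with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # readQualityScaledDNAStringSet warns about dropped metadata columns
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads `read_sim` data.frame (or any with `read_id`, `seq`,
#'   `qual`).
#' @param path file path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                             "+", reads$qual)), con)
  invisible(path)
}

GFF3_COLS <- c("seqid", "source", "type", "start", "end", "score",
               "strand", "phase", "attributes")

#' Read a GFF3 file
#'
#' @param path file path.
#' @return data.frame with the nine GFF3 columns (`start`/`end` 1-based
#'   inclusive). Malformed records raise an error naming the line.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(stats::setNames(
      data.frame(character(0), character(0), character(0), integer(0),
                 integer(0), character(0), character(0), character(0),
                 character(0), stringsAsFactors = FALSE), GFF3_COLS))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad) > 0L)
    stop("malformed GFF3 record at line ", idx[bad[1L]], " of ", path)
  m <- do.call(rbind, parts)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- GFF3_COLS
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (any(is.na(out$start) | is.na(out$end) | out$start > out$end))
    stop("invalid coordinates in GFF3 record at line ",
         idx[which(is.na(out$start) | is.na(out$end) |
                     out$start > out$end)[1L]], " of ", path)
  out
}

#' Write a GFF3 file
#'
#' @param df data.frame with the nine GFF3 columns (see [read_gff3()]).
#' @param path file path.
#' @export
write_gff3 <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(do.call(paste, c(df[GFF3_COLS], sep = "\t")), con)
  invisible(path)
}

# Elements (detected or simulator truth) -> GFF3 feature rows:
# LTR_retrotransposon parents with long_terminal_repeat children (and
# target_site_duplication children when a TSD is recorded).
elements_to_gff3 <- function(elements, source = "retroscape") {
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    id <- e$element_id
    attrs <- sprintf("ID=%s", id)
    for (f in intersect(c("lineage", "superfamily", "true_age",
                          "ltr_identity", "type", "nested_in"),
                        names(elements))) {
      v <- e[[f]]
      if (!is.na(v)) attrs <- paste0(attrs, ";", f, "=", v)
    }
    strand <- if ("strand" %in% names(elements) &&
                  e$strand %in% c("+", "-")) e$strand else "."
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = e$chrom, source = source,
      type = if (!is.null(e$type) && !is.na(e$type) && e$type != "element")
        switch(e$type, solo_ltr = "solo_LTR", fragment = "LTR_fragment",
               "LTR_retrotransposon") else "LTR_retrotransposon",
      start = e$start, end = e$end, score = ".", strand = strand,
      phase = ".", attributes = attrs, stringsAsFactors = FALSE)
    if (!is.null(e$ltr5_start) && !is.na(e$ltr5_start)) {
      for (w in c("5", "3")) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = e$chrom, source = source, type = "long_terminal_repeat",
          start = e[[paste0("ltr", w, "_start")]],
          end = e[[paste0("ltr", w, "_end")]],
          score = ".", strand = strand, phase = ".",
          attributes = sprintf("ID=%s_LTR%s;Parent=%s", id, w, id),
          stringsAsFactors = FALSE)
      }
    }
    if ("tsd" %in% names(elements) && !is.na(e$tsd)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = e$chrom, source = source, type = "target_site_duplication",
        start = max(1L, e$start - nchar(e$tsd)), end = e$start - 1L,
        score = ".", strand = strand, phase = ".",
        attributes = sprintf("ID=%s_TSD;Parent=%s;seq=%s", id, id, e$tsd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write detected elements or simulator truth as GFF3
#'
#' Emits `LTR_retrotransposon` features with `long_terminal_repeat`
#' children (plus `target_site_duplication` where recorded); solo-LTR and
#' fragment decoys in a truth table become `solo_LTR` / `LTR_fragment`
#' features.
#'
#' @param elements `ltr_elements` data.frame or an `ltr_genome_sim` truth
#'   table (pass `sim$truth`).
#' @param path file path.
#' @export
write_elements_gff3 <- function(elements, path) {
  write_gff3(elements_to_gff3(elements), path)
}

#' Read a BED file of gene intervals
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path file path.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    stop("malformed BED record at line ", bad[1L], " of ", path)
  m <- lapply(parts, function(p) {
    data.frame(gene_id = if (length(p) >= 4L) p[4L] else NA_character_,
               chrom = p[1L], start = as.integer(p[2L]) + 1L,
               end = as.integer(p[3L]),
               strand = if (length(p) >= 6L) p[6L] else "+",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, m)
  if (anyNA(out$gene_id))
    out$gene_id <- sprintf("gene%03d", seq_len(nrow(out)))
  out
}

#' Write gene intervals to BED (0-based half-open)
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), optional `strand`.
#' @param path file path.
#' @export
write_bed <- function(genes, path) {
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  writeLines(paste(genes$chrom, genes$start - 1L, genes$end,
                   genes$gene_id, 0L, strand, sep = "\t"), path)
  invisible(path)
}

#' Read / write a binary marker matrix TSV
#'
#' First column is the accession id; remaining columns are 0/1 band
#' presence calls.
#'
#' @param path file path.
#' @return binary matrix of class `irap_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("matrix entries must be 0/1: ", path)
  rownames(m) <- df[[1L]]
  class(m) <- c("irap_matrix", class(m))
  m
}

#' @rdname read_matrix_tsv
#' @param m binary matrix (accessions x loci).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(accession = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write protein-domain exemplars as FASTA
#'
#' Headers follow the `domain|lineage|superfamily` convention, so any
#' external exemplar collection can be plugged into [scan_domains()].
#'
#' @param path file path.
#' @return data.frame `domain`, `lineage`, `superfamily`, `peptide`.
#' @export
read_exemplar_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L)
    stop("exemplar header not in domain|lineage|superfamily form: ",
         names(x)[bad[1L]])
  m <- do.call(rbind, parts)
  data.frame(domain = m[, 1L], lineage = m[, 2L], superfamily = m[, 3L],
             peptide = as.character(x), stringsAsFactors = FALSE)
}

#' @rdname read_exemplar_fasta
#' @param exemplars data.frame as returned by [domain_exemplars()].
#' @export
write_exemplar_fasta <- function(exemplars, path) {
  x <- Biostrings::AAStringSet(exemplars$peptide)
  names(x) <- paste(exemplars$domain, exemplars$lineage,
                    exemplars$superfamily, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
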