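# Primer-gene proximity enrichment: flank-window intersection counts and
# a 2x2 chi-square contrast against a random control gene set.

#' Count genes with a primer site within their flanks
#'
#' For each gene, the window is `[start - flank_bp, end + flank_bp]`
#' (inclusive on both ends, clipped at the chromosome edges); the gene
#' counts as proximal when at least one primer site starts inside the
#' window.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param sites `primer_sites` data.frame (or any data.frame with
#'   `chrom` and `start`).
#' @param flank_bp flank size on each side (default 100000).
#' @param chrom_lengths optional named vector for clipping; windows are
#'   clipped at 1 regardless.
#' @param label gene-set label carried into the result.
#' @return list of class `proximity_count`: `label`, `n_genes`,
#'   `n_with_hit`, `flank_bp`, `per_gene` (logical vector).
#' @export
count_proximal <- function(genes, sites, flank_bp = 100000L,
                           chrom_lengths = NULL, label = "genes") {
  if (nrow(genes) > 0L && !all(genes$chrom %in%
                               unique(c(sites$chrom, names(chrom_lengths)))))
    stop("gene on a chromosome absent from the site set / genome: ",
         paste(setdiff(genes$chrom,
                       unique(c(sites$chrom, names(chrom_lengths)))),
               collapse = ", "))
  hit <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    lo <- max(1L, genes$start[i] - flank_bp)
    hi <- genes$end[i] + flank_bp
    if (!is.null(chrom_lengths) && genes$chrom[i] %in% names(chrom_lengths))
      hi <- min(hi, chrom_lengths[[genes$chrom[i]]])
    s <- sites$start[sites$chrom == genes$chrom[i]]
    hit[i] <- any(s >= lo & s <= hi)
  }
  names(hit) <- genes$gene_id
  structure(list(label = label, n_genes = nrow(genes),
                 n_with_hit = sum(hit), flank_bp = flank_bp,
                 per_gene = hit),
            class = "proximity_count")
}

#' @export
print.proximity_count <- function(x, ...) {
  cat(sprintf("<proximity_count> %s: %d/%d genes with a site within %s bp\n",
              x$label, x$n_with_hit, x$n_genes,
              format(x$flank_bp, big.mark = ",")))
  invisible(x)
}

#' Sample a control gene set
#'
#' Uniform sample without replacement from the gene pool after removing
#' the focal set; deterministic given the seed.
#'
#' @param all_genes data.frame of candidate genes (`gene_id` column).
#' @param exclude gene ids (or a genes data.frame) to remove from the
#'   pool first.
#' @param n sample size.
#' @param seed integer or NULL.
#' @return data.frame subset of `all_genes`.
#' @export
sample_control_genes <- function(all_genes, exclude = character(0), n,
                                 seed = NULL) {
  if (is.data.frame(exclude)) exclude <- exclude$gene_id
  pool <- all_genes[!all_genes$gene_id %in% exclude, , drop = FALSE]
  if (nrow(pool) < n)
    stop("only ", nrow(pool), " genes available after exclusion, need ", n)
  with_seed(seed, {
    out <- pool[sort(sample.int(nrow(pool), n)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' 2x2 chi-square test of proximity enrichment
#'
#' Pearson chi-square on the 2x2 table of genes with/without a proximal
#' primer site in the focal versus control set. The Yates continuity
#' correction is applied by default; both variants are reported.
#'
#' @param a_with,a_without counts for the focal gene set.
#' @param b_with,b_without counts for the control gene set.
#' @param continuity_correction apply the Yates correction
#'   (default TRUE).
#' @return list of class `chi_square_result`: `table`, `statistic`, `df`,
#'   `p_value`, `continuity_correction`, and the other variant as
#'   `statistic_other` / `p_value_other`.
#' @export
#' @examples
#' chi_square_2x2(35, 68, 16, 87)   # p about 0.0037
chi_square_2x2 <- function(a_with, a_without, b_with, b_without,
                           continuity_correction = TRUE) {
  counts <- c(a_with, a_without, b_with, b_without)
  if (any(counts < 0)) stop("counts must be >= 0")
  tab <- matrix(counts, nrow = 2L, byrow = TRUE,
                dimnames = list(set = c("focal", "control"),
                                proximal = c("with", "without")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: a table margin is zero")
  corr <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  plain <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  use <- if (continuity_correction) corr else plain
  other <- if (continuity_correction) plain else corr
  structure(list(table = tab,
                 statistic = unname(use$statistic), df = 1L,
                 p_value = use$p.value,
                 continuity_correction = continuity_correction,
                 statistic_other = unname(other$statistic),
                 p_value_other = other$p.value),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square = %.4f (df = 1, %s), p = %.4g\n",
              x$statistic,
              if (x$continuity_correction) "Yates-corrected" else
                "uncorrected",
              x$p_value))
  cat(sprintf("  [%s variant: statistic %.4f, p = %.4g]\n",
              if (x$continuity_correction) "uncorrected" else "corrected",
              x$statistic_other, x$p_value_other))
  invisible(x)
}

#' Proximity enrichment analysis of a focal gene set
#'
#' Convenience wrapper: counts proximal genes in the focal set and in a
#' seeded random control set of equal size, then contrasts them with
#' [chi_square_2x2()].
#'
#' @param focal_genes,all_genes gene data.frames (see
#'   [count_proximal()]).
#' @param sites `primer_sites` data.frame.
#' @param flank_bp flank size (default 100000).
#' @param seed integer; controls the control-set draw.
#' @param chrom_lengths optional named vector for window clipping.
#' @return list of class `proximity_result`: `focal`, `control`
#'   (`proximity_count`s), `test` (`chi_square_result`).
#' @export
proximity_enrichment <- function(focal_genes, all_genes, sites,
                                 flank_bp = 100000L, seed = NULL,
                                 chrom_lengths = NULL) {
  ctrl_genes <- sample_control_genes(all_genes, exclude = focal_genes,
                                     n = nrow(focal_genes), seed = seed)
  fc <- count_proximal(focal_genes, sites, flank_bp, chrom_lengths,
                       label = "focal")
  cc <- count_proximal(ctrl_genes, sites, flank_bp, chrom_lengths,
                       label = "control")
  structure(list(focal = fc, control = cc,
                 test = chi_square_2x2(fc$n_with_hit,
                                       fc$n_genes - fc$n_with_hit,
                                       cc$n_with_hit,
                                       cc$n_genes - cc$n_with_hit)),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  print(x$focal); print(x$control); print(x$test)
  invisible(x)
}
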