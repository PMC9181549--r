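# Bundled reference tables from the published stevia LTR-retrotransposon
# survey, shipped as plain TSV under inst/extdata. These are *inputs*
# (printed counts and proportions), not results of this package.

#' Published stevia reference counts and proportions
#'
#' Headline numbers of the published genome-wide survey of
#' *Stevia rebaudiana* full-length LTR retrotransposons: the
#' steviol-glycoside (SVgly) proximity gene counts (35/103 focal vs
#' 16/103 control genes with a primer site within 100 kb) and the
#' superfamily genome proportions (Gypsy 36.7%, Copia 18.7%,
#' undetermined 0.4%, total 55.8%). Used by the worked examples and the
#' reproduction script as fixed inputs.
#'
#' @return named numeric vector.
#' @export
stevia_reference_counts <- function() {
  df <- utils::read.delim(system.file("extdata",
                                      "stevia_reference_counts.tsv",
                                      package = "retroscape"),
                          stringsAsFactors = FALSE)
  stats::setNames(df$value, df$quantity)
}

#' Published SVgly gene-family breakdown
#'
#' The families of the 35 steviol-glycoside-pathway genes found with a
#' primer site within their 100-kb flanks in the published survey.
#'
#' @return data.frame with `gene_family` and `n_genes`.
#' @export
svgly_gene_families <- function() {
  utils::read.delim(system.file("extdata", "svgly_gene_families.tsv",
                                package = "retroscape"),
                    stringsAsFactors = FALSE)
}
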