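# Umbrella configuration and end-to-end pipeline runner.

#' Pipeline run configuration
#'
#' Collects every tunable of the simulate -> detect -> annotate -> date ->
#' abundance -> irap -> proximity pipeline, with validated defaults. All
#' randomness flows from the single `seed` through per-stage derived
#' seeds.
#'
#' @param seed master seed (integer).
#' @param rate substitution rate per site per year.
#' @param element_specs element spec data.frame for [build_genome()].
#' @param background_length,gene_count,nesting_fraction,solo_ltr_count,fragment_count
#'   simulator settings.
#' @param primer primer sequence used for IRAP and proximity stages.
#' @param primer_count planted primer-site copies.
#' @param coverage,read_length,error_rate read-simulation settings.
#' @param min_ltr,max_ltr,min_elem,max_elem,min_identity detection
#'   settings.
#' @param length_fraction,similarity mapping filters.
#' @param flank_bp proximity flank size.
#' @param n_accessions,K_true,n_loci,K_range,n_replicates
#'   population-structure settings.
#' @param output_dir optional directory; when set, stage outputs are
#'   written there (FASTA/GFF3/BED/TSV).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, rate = 2e-8,
                       element_specs = data.frame(
                         lineage = c("Angela", "SIRE", "Tekay"),
                         age_mya = c(0.5, 1, 1.5),
                         count = c(4L, 4L, 4L)),
                       background_length = 150000L, gene_count = 30L,
                       nesting_fraction = 0, solo_ltr_count = 2L,
                       fragment_count = 2L,
                       primer = "TTCAAGAATCACACCCTCTA", primer_count = 25L,
                       coverage = 3, read_length = 85L, error_rate = 0.005,
                       min_ltr = 100L, max_ltr = 3000L, min_elem = 1000L,
                       max_elem = 16000L, min_identity = 85,
                       length_fraction = 0.9, similarity = 0.8,
                       flank_bp = 5000L,
                       n_accessions = 25L, K_true = 3L, n_loci = 40L,
                       K_range = 1:4, n_replicates = 4L,
                       output_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(rate > 0, background_length > 0,
            nesting_fraction >= 0, nesting_fraction <= 1,
            min_ltr >= 20, max_ltr >= min_ltr, min_elem > 2 * min_ltr,
            max_elem >= min_elem, min_identity > 0, min_identity <= 100,
            length_fraction > 0, length_fraction <= 1,
            similarity > 0, similarity <= 1, flank_bp >= 0,
            coverage > 0, K_true >= 1, n_accessions >= 2,
            length(K_range) >= 3, n_replicates >= 2)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' Round-trip stable: reading back a written configuration reproduces
#' the validated `run_config` object (data.frame fields included).
#'
#' @param config a `run_config` object.
#' @param path file path.
#' @return `read_config()` returns a `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$element_specs <- as.list(x$element_specs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$element_specs <- as.data.frame(x$element_specs,
                                   stringsAsFactors = FALSE)
  x$K_range <- as.integer(x$K_range)
  do.call(run_config, x)
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes all seven stages as configured and returns every intermediate
#' result plus a manifest (per-stage record counts, derived seeds,
#' package version, timestamp). Re-running with the same configuration
#' reproduces all outputs identically; only the manifest timestamp
#' differs. A stage failure aborts with the stage name and cause.
#'
#' @param config a `run_config` object.
#' @return list of class `pipeline_result` with `sim`, `reads`,
#'   `elements`, `annotations`, `ages`, `profile`, `abundance`, `irap`
#'   (sites/amplicons/population results), `proximity`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage_seed <- function(i) derive_seed(config$seed, i)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("retroscape")),
                   seed = config$seed, timestamp = format(Sys.time()),
                   stages = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  note <- function(name, count) {
    manifest$stages[[name]] <<- list(records = count)
  }

  sim <- run_stage("simulate", build_genome(
    config$element_specs, background_length = config$background_length,
    gene_count = config$gene_count,
    primer_sites_spec = list(primer = config$primer,
                             count = config$primer_count),
    nesting_fraction = config$nesting_fraction,
    solo_ltr_count = config$solo_ltr_count,
    fragment_count = config$fragment_count,
    rate = config$rate, seed = stage_seed(1L)))
  note("simulate", nrow(sim$truth))

  reads <- run_stage("reads", simulate_reads(
    sim, read_length = config$read_length, coverage = config$coverage,
    error_rate = config$error_rate, seed = stage_seed(2L)))
  note("reads", nrow(reads))

  elements <- run_stage("detect", detect_ltr(
    sim, min_ltr = config$min_ltr, max_ltr = config$max_ltr,
    min_elem = config$min_elem, max_elem = config$max_elem,
    min_identity = config$min_identity))
  note("detect", nrow(elements))

  annotations <- run_stage("annotate",
                           annotate_elements(elements, sim))
  note("annotate", sum(annotations$lineage != "undetermined"))

  ages <- run_stage("dating", ltr_insertion_age(elements, sim,
                                                rate = config$rate))
  profile <- if (any(ages$datable))
    age_profile(merge(ages, annotations[, c("element_id", "lineage")],
                      by = "element_id")) else NULL
  note("dating", sum(ages$datable))

  abun <- run_stage("abundance", {
    lib <- element_sequences(elements, sim)
    asg <- map_reads(reads, lib, length_fraction = config$length_fraction,
                     similarity = config$similarity, seed = stage_seed(3L))
    proportions(asg, annotations)
  })
  note("abundance", sum(abun$reads))

  irap <- run_stage("irap", {
    sites <- find_primer_sites(sim, config$primer)
    amps <- predict_amplicons(sites)
    truth <- make_population_truth(config$n_accessions, config$K_true,
                                   config$n_loci, seed = stage_seed(4L))
    mat <- simulate_marker_population(truth, seed = stage_seed(5L))
    fits <- lapply(config$K_range, function(K)
      admixture_em(mat, K, n_replicates = config$n_replicates,
                   seed = derive_seed(config$seed, 100L + K)))
    L <- vapply(fits, `[[`, numeric(config$n_replicates),
                "log_likelihoods")
    colnames(L) <- config$K_range
    ev <- evanno_delta_k(L)
    list(sites = sites, amplicons = amps, truth = truth, matrix = mat,
         fits = fits, evanno = ev,
         pca = if (ncol(mat) > 1) irap_pca(mat) else NULL)
  })
  note("irap", nrow(irap$sites))

  prox <- run_stage("proximity", {
    if (nrow(sim$genes) >= 4L) {
      focal <- sim$genes[seq_len(nrow(sim$genes) %/% 2L), , drop = FALSE]
      proximity_enrichment(focal, sim$genes, irap$sites,
                           flank_bp = config$flank_bp,
                           seed = stage_seed(6L),
                           chrom_lengths = nchar(sim$genome))
    } else NULL
  })
  note("proximity", if (is.null(prox)) 0L else prox$focal$n_with_hit)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$output_dir
    write_fasta(sim, file.path(od, "genome.fasta"))
    write_fastq(reads, file.path(od, "reads.fastq"))
    write_elements_gff3(sim$truth, file.path(od, "truth.gff3"))
    write_elements_gff3(elements, file.path(od, "elements.gff3"))
    if (nrow(sim$genes) > 0) write_bed(sim$genes, file.path(od, "genes.bed"))
    write_matrix_tsv(irap$matrix, file.path(od, "irap_matrix.tsv"))
  }

  structure(list(sim = sim, reads = reads, elements = elements,
                 annotations = annotations, ages = ages,
                 profile = profile, abundance = abun, irap = irap,
                 proximity = prox, manifest = manifest,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (s in names(x$manifest$stages))
    cat(sprintf("  %-10s records: %s\n", s,
                x$manifest$stages[[s]]$records))
  invisible(x)
}
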