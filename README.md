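# retroscape

Structural annotation, insertion dating and marker-based population
analysis of LTR retrotransposons, for people studying the repetitive
fraction of plant genomes — with a truth-tracking simulator so every
stage can be verified without downloading an assembly.

Long-terminal-repeat retrotransposons (LTR-REs) make up more than half
of many plant genomes. A full-length element carries two LTRs that are
identical at the moment of insertion and then diverge at the neutral
substitution rate, which turns every element into its own molecular
clock: with the Kimura two-parameter distance

&nbsp;&nbsp;&nbsp;&nbsp;*K* = −½ ln((1 − 2*P* − *Q*)·√(1 − 2*Q*))

between the two LTRs (*P* transitions, *Q* transversions per site) and
a rate *r*, the insertion age is *T* = *K*/(2*r*). The package
implements the standard analysis chain around this clock:

| stage | functions |
|---|---|
| simulate genomes/reads/populations with known truth | `build_genome()`, `simulate_reads()`, `make_population_truth()`, `simulate_marker_population()` |
| detect full-length elements (both LTRs, TSD/TG...CA evidence) | `detect_ltr()`, `find_candidates()`, `refine_and_filter()` |
| classify to superfamily/lineage from protein-domain order | `scan_domains()`, `classify_hits()`, `annotate_elements()`, `homology_rescue()` |
| date insertions (LTR pairs and RT-mapped read pairs) | `k2p()`, `ltr_insertion_age()`, `rt_read_dating()`, `age_profile()` |
| estimate genome proportions from reads | `map_reads()`, `proportions()` |
| in-silico IRAP fingerprinting & population structure | `find_primer_sites()`, `predict_amplicons()`, `band_matrix()`, `irap_pca()`, `admixture_em()`, `evanno_delta_k()`, `classify_admixed()` |
| primer–gene proximity enrichment | `count_proximal()`, `sample_control_genes()`, `chi_square_2x2()`, `proximity_enrichment()` |
| whole pipeline + I/O (FASTA/FASTQ/GFF3/BED/TSV) | `run_pipeline()`, `read_fasta()`, `read_gff3()`, `read_bed()`, ... |

The eleven IRAP primers designed on the Angela-lineage LTRs of
*Stevia rebaudiana* ship as plain TSV (`irap_primers()`), as do the
published survey's headline counts (`stevia_reference_counts()`),
which are used as fixed inputs by the reproduction script.

## Worked example

Simulate a 129-kb genome with six full-length elements of known lineage
and age, then detect, annotate and date them:

```r
library(retroscape)

sim <- build_genome(
  data.frame(lineage = c("Angela", "Tekay"), age_mya = c(0.5, 1.5),
             count = c(3, 3)),
  background_length = 1e5, solo_ltr_count = 0, fragment_count = 0,
  seed = 11)
sim
#> <ltr_genome_sim> 1 chromosome(s), 129,310 bp
#>   full-length elements: 6   solo LTRs: 0   fragments: 0
#>   genes: 0   planted primer sites: 0

els  <- detect_ltr(sim)
ann  <- annotate_elements(els, sim)
ages <- ltr_insertion_age(els, sim)
merge(merge(els[, c("element_id", "start", "end", "ltr_identity", "tsd")],
            ann[, c("element_id", "superfamily", "lineage", "autonomous")]),
      ages[, c("element_id", "K", "T_mya")])
#>  element_id  start    end ltr_identity   tsd superfamily lineage autonomous      K T_mya
#>      RS0001   4122   8801         98.4 TTATT       Copia  Angela       TRUE 0.0162  0.41
#>      RS0002   8904  13583         97.9 ACTTG       Copia  Angela       TRUE 0.0214  0.53
#>      RS0003  28296  32975         97.9 GAGCG       Copia  Angela       TRUE 0.0214  0.53
#>      RS0004  84632  89711         93.9 CGTCC       Gypsy   Tekay       TRUE 0.0638  1.60
#>      RS0005  94205  99284         93.8 GTCAA       Gypsy   Tekay       TRUE 0.0657  1.64
#>      RS0006 108744 113823         95.0 AAACA       Gypsy   Tekay       TRUE 0.0520  1.30
```

All six planted elements are recovered with their target-site
duplications; the Angela cohort (planted at 0.5 Myr ago) dates to
0.41–0.53 MYA and the Tekay cohort (planted at 1.5) to 1.30–1.64 MYA —
the scatter is the per-element noise of a ~5-kb molecular clock. LTR
identity falls with age exactly as the clock predicts (≈98% at 0.5 MYA,
≈94% at 1.5 MYA).

The proximity test on the published steviol-glycoside gene counts
(35 of 103 focal genes vs 16 of 103 random genes with a primer site
within 100 kb):

```r
chi_square_2x2(35, 68, 16, 87)
#>          proximal
#> set       with without
#>   focal     35      68
#>   control   16      87
#> chi-square = 8.4433 (df = 1, Yates-corrected), p = 0.003664
#>   [uncorrected variant: statistic 9.4075, p = 0.002161]
```

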