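---
title: "Methods: models, simulators and design choices in retroscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulators and design choices in retroscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(retroscape)
```

retroscape analyses long-terminal-repeat retrotransposons (LTR-REs) in
plant genome assemblies: it finds full-length elements structurally,
classifies them into the Copia and Gypsy superfamilies and their
lineages, dates their insertions, estimates the genome fraction they
occupy from short reads, predicts IRAP fingerprints and infers
population structure from them, and tests whether primer sites are
enriched near a focal gene set. This vignette explains the models behind
each stage, the tunable parameters and their defaults, what the bundled
simulator does and does not emulate, and the design decisions that were
genuinely open.

## The molecular clock behind everything

A retrotransposon inserts with two *identical* LTRs. Each LTR then
accumulates substitutions independently at a rate $r$ (substitutions per
site per year), so the pair diverges at $2r$ and the insertion age is

$$T = \frac{K}{2r},$$

where $K$ is the Kimura two-parameter (K2P) distance between the two
LTRs:

$$K = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

with $P$ and $Q$ the proportions of aligned sites showing a transition
or a transversion. Columns containing a gap or an ambiguous base are
excluded from $P$, $Q$ and the site count (pairwise deletion). `k2p()`
implements exactly this closed form; the test suite checks it to
$10^{-12}$ against brute-force transition/transversion counting and
against an independent K80 implementation.

The default rate is $r = 2\times10^{-8}$ substitutions/site/year, the
convention for repeat sequences in Asteraceae (twice a synonymous-site
rate, because repeats are less constrained than genes). Every reported
age scales inversely with $r$: doubling the rate halves every $T$
exactly, so profiles computed under a different clock can be rescaled
rather than recomputed.

Saturation: when $1 - 2P - Q \le 0$ or $1 - 2Q \le 0$ the distance is
undefined. Such pairs are *excluded and counted* (`n_saturated`
attribute), never clamped — inventing a finite age for a saturated pair
would silently bias old cohorts. At the default rate this horizon lies
far beyond any age the structural detector can reach anyway (see
below).

## Synthetic genomes with known truth

`build_genome()` exists so that every downstream stage can be tested
against exact truth. It emulates:

* **full-length elements** built from lineage templates
  (`lineage_templates()`): an LTR consensus (100–3000 bp, starting `TG`,
  ending `CA`) and an internal region carrying GAG–PROT–INT–RT–RH
  protein-domain segments in the superfamily-specific order;
* **mutational age**: both LTR copies and the internal region are
  mutated site-wise by `mutate_k2p()`, which samples each site from the
  exact K2P transition matrix at the requested distance — multiple hits
  are modelled, so the K2P *estimator* is consistent for the simulated
  divergence. Transition:transversion ratio defaults to 2:1
  (K2P-conventional; the estimator does not depend on it);
* **insertion mechanics**: non-overlapping (or deliberately nested)
  insertions with a 4–6 bp target-site duplication (default 5 bp,
  typical for LTR-REs), on either strand;
* **decoys**: solo LTRs and one-LTR truncated fragments (defaults: 5
  each), the remnants that stress real detectors;
* **genes** (coordinate intervals in inter-element background) and
  **planted primer sites** (overwritten in place so coordinates stay
  stable), for the IRAP and proximity stages;
* **reads**: uniform single-end 85-nt reads at a chosen coverage with a
  uniform per-base error rate (default 0.005, i.e. post-trimming
  quality).

It deliberately does **not** emulate: indels in the mutation model (the
K2P estimator ignores gap columns; an indel-free model keeps LTR pairs
on one alignment diagonal), base-quality profiles, PCR duplicates,
paired-end inserts, low-complexity or satellite background
(background is i.i.d. uniform with configurable GC), within-family
ancestry structure (each element is drawn independently from its
template), or selection on LTRs (assumed absent). Consequently, a
passing benchmark says the *algorithms* recover what the model
generates; real assemblies add fragmentation, nesting depth and
family phylogeny that the defaults do not produce.

All generators are deterministic given their `seed`; identical seeds
give byte-identical FASTA/FASTQ/GFF3 output.

## Structural detection

`detect_ltr()` re-implements the classic structural search:

1. **Seeding.** Exact 20-mer matches on a shared diagonal (same
   chromosome, separation compatible with element bounds) are clustered.
   Because the mutation model is indel-free, a true LTR pair lies on one
   exact diagonal; the 20-mer seed density at 85% identity (~1 clean
   seed per 11 bp) makes missed elements vanishingly rare up to the
   identity floor. A direct repeat remains a direct repeat under reverse
   complement, so one forward scan finds elements on both strands; the
   reading strand is assigned later from protein-domain frames.
2. **Extension.** Each cluster is extended outward ungapped with a
   +1/−2 running score, cut at the running maximum, then snapped to
   `TG...CA` termini within ±2 bp when present.
3. **Refinement.** LTR–LTR global alignment identity (default minimum
   85%), TG...CA and TSD annotation, and overlap resolution.

Defaults — LTR 100–3000 bp, element 1000–16000 bp, k = 20, 85%
identity — are the common structural-search settings. TG...CA and TSD
are *evidence annotations*, not hard filters: degenerate true positives
should not silently disappear.

**Overlap resolution prefers TSD evidence first**, then identity, then
length, then leftmost position. This is the one place where evidence
outranks identity, and it is deliberate: two same-family elements
within amplifiable distance create a "bridge" candidate (the 3'-LTR of
one paired with the 5'-LTR of the next) whose LTR identity is
*distributed exactly like a real element's* — identity cannot separate
them, but only a real insertion has matching TSD flanks. The TSD search
allows the detected boundaries to be off by ±2 bp, since the ungapped
extension can overshoot a boundary by a base or two when flanking bases
match by chance.

The detection horizon is structural, not algorithmic: at the default
rate, a 5-MYA element has inter-LTR distance $K = 0.2$ and an expected
observed identity near 82%, below the 85% default. Elements older than
about 4 MYA are therefore invisible to LTR-pair detection at the
defaults — which is exactly why the package also implements read-based
RT dating (below), whose reach is limited by read identity filters
(80%) rather than LTR decay.

## Annotation

`scan_domains()` translates the internal region in all six frames and
aligns each frame locally against exemplar peptides (BLOSUM80, the
matrix of choice for closely related protein matches), reporting the
best hit per domain type above `min_score` (default 100 raw units —
self-matches score in the many hundreds, random local hits on these
lengths rarely exceed ~60; the platform-style "significance" filter is
deliberately exposed as configuration). `classify_hits()` then reads
the superfamily from the *order* of integrase and reverse transcriptase
(INT before RT = Copia, RT before INT = Gypsy, accounting for the
reading strand), falling back to a score-weighted vote; the lineage is
the highest-scoring consistent one, with exact ties left undetermined
(conservative). An element with all five domains is flagged autonomous.

The published protein-domain reference database cannot be
redistributed, so the module consumes any exemplar FASTA with
`domain|lineage|superfamily` headers (`read_exemplar_fasta()`); the
bundled exemplars come from the simulator's templates and carry real
structure but synthetic sequence.

`homology_rescue()` handles elements with no domain hits: a shared
k-mer screen (k = 16, both strands) proposes the best classified
subject, a local alignment verifies it, and the subject's annotation is
adopted when gap-excluded identity ≥ 80% covers ≥ 50% of the shorter
sequence. Thresholds are permissive on purpose — rescue exists to
reduce the undetermined fraction, and a wrong lineage within a family
cluster is less harmful than discarding the element.

## Dating from reads

`rt_read_dating()` mirrors the read-based procedure: reads are placed
on RT-encoding references (≥150 nt) with the standard acceptance
filters — at least 0.9 of the read aligned at ≥0.8 identity — and all
mapped read pairs overlapping by ≥40 nt are compared with `k2p()` on
their overlap. Pairs with shorter overlaps give unstable distances and
are skipped. Placement is seeded and ungapped (mismatch cost 1), which
is exact under the indel-free read model; beyond 20 000 pairs per
reference a seeded random subsample is compared — the estimator is
unchanged in expectation and the cost stays linear in depth.

`age_profile()` bins ages (default 0.5 MYA) and reports bursts as local
maxima of a Gaussian kernel density (bandwidth = bin width) taller than
5% of the highest peak. The 5% floor keeps a broad ancient burst
visible next to a sharp recent one while suppressing sampling ripples;
it matters only when burst masses are very unequal.

## Genome proportion

`map_reads()` assigns each read to its best element under the same
0.9/0.8 filters; `proportions()` divides lineage read counts by the
*total* read count — the read fraction is the standard proxy for
genome fraction, with no GC or mappability correction. Reads tied
between elements of different lineages go to an explicit `ambiguous`
row by default (transparency); `tie_policy = "random"` reproduces
single-assignment mappers. Proportions plus the unmapped row sum to 1
exactly on every run, and the superfamily totals are exact sums of
their lineages.

## IRAP and population structure

`find_primer_sites()` scans both strands for primer matches (IUPAC
degeneracy supported) with at most one mismatch, none in the 3
terminal 3' bases — a 3'-terminal mismatch kills polymerase extension.
`predict_amplicons()` pairs every plus-strand site with every
downstream minus-strand site; the product length convention is the
inclusive span between the two primer 5' ends, and only 100–3000 bp
products are kept (the gel-scorable window). `band_matrix()` pools
lengths across accessions and co-bins those within 2% (single-linkage;
a gel-resolution proxy, configurable). Weak-band dropout filtering is
available but off for in-silico data, where bands are deterministic.

`admixture_em()` fits the dominant-marker admixture model: with
admixture proportions $Q_{ik}$ and band-allele frequencies $f_{kl}$,
the probability that diploid accession $i$ lacks band $l$ is
$a_{il}^2$ with $a_{il} = \sum_k Q_{ik}(1 - f_{kl})$ — a band is absent
only when both haplotypes carry the absence allele. The likelihood is
maximised by EM over the latent haplotype origins; the log-likelihood
is asserted non-decreasing at every iteration, convergence is declared
when the gain drops below $10^{-6}$ (cap 2000 iterations), and seven
independently seeded replicates are fitted per K (an argument exposes
five, since both replicate counts circulate for this protocol). This
maximum-likelihood EM *stands in* for Bayesian MCMC sampling of the
same model; its adequacy is established by parameter recovery on
simulated truth (mean $|\hat{Q} - Q|$ ≈ 0.07 for two subpopulations
and ≈ 0.10 for three, at the study scale of 25 accessions × 40 loci),
not by matching any published ancestry plot.
At $K = 1$ the M-step has the closed form
$\hat f_l = 1 - \sqrt{1 - \bar y_l}$, which the tests verify.

`evanno_delta_k()` selects K by
$\Delta K = \mathrm{mean}_{reps}|L(K{+}1) - 2L(K) + L(K{-}1)| /
\mathrm{sd}_{reps}L(K)$, defined only for interior K with ≥2
replicates; exactly linear likelihood curves (all second differences
zero) are flagged as undefined rather than forced to a choice, and
zero replicate variance is an error. Replicate Q matrices are aligned
across label switching by greedy correlation matching
(`align_q_columns()`) before any averaging. Assignment follows the
strict rule $Q_i > 0.8$; a coefficient exactly at 0.8 stays admixed.

The marker-population generator draws allele frequencies from
Beta(0.5, 0.5) — most loci strongly differentiated, as expected for
markers chosen because they are polymorphic — and admixture rows from
a symmetric Dirichlet(0.3). Each accession's largest ancestry
component is assigned to a home subpopulation in round-robin order:
the Dirichlet shape of every row is preserved, but all `K_true`
subpopulations anchor an equal share of accessions, so a truth
labelled K = 3 cannot degenerate into an effectively two-population
panel by an unlucky draw.

## Proximity enrichment

`count_proximal()` counts genes with at least one primer site within
`[start − 100000, end + 100000]`, inclusive at both boundaries and
clipped at chromosome edges (clipping, not discarding: an edge gene
with a visible site is still a hit). `sample_control_genes()` draws
the equal-sized control set uniformly without replacement after
excluding the focal genes. `chi_square_2x2()` applies the Yates
continuity correction by default — on the published 35/103 vs 16/103
table the corrected test reproduces the printed p-value (0.0036 at two
significant figures) while the uncorrected one gives 0.0022, so the
corrected variant is evidently the published convention; both variants
are always reported.

## Problem sizes used by the tests and the reproduction script

Chosen as the package's standard benchmark conditions: detection on a
2-Mb genome with 50 elements (ages ≤ 2 MYA, four lineages, ten
decoys); dating cohorts of 200 elements with 1-kb LTRs at 0.5/1/2/5
MYA and a 150+150 bimodal burst at 1 and 10 MYA; abundance on a
~195-kb genome with 30% element content at coverage 20; population
structure on 25 accessions × 40 loci with $K_{true} \in \{2, 3\}$, ten
simulation repeats, K swept over 1–5 with seven replicates each. The
pipeline demo (`run_pipeline()`) uses a smaller 150-kb configuration.

## Known limitations

* The detector is ungapped end-to-end; real LTR pairs with large
  internal indels would fragment the seed diagonal. The ±2 bp boundary
  slack absorbs point overshoot only.
* Nested insertions are generated and tolerated in output (containment
  is allowed in overlap resolution), but an *outer* element whose LTR
  separation is pushed beyond the element-length cap by its guest is
  not recovered — a limitation shared with separation-bounded
  structural searches.
* Solo LTRs and fragments are decoys only; the package does not call
  them (non-goal), so remnant-rich genomes will show full-length
  proportions below repeat-masker-style totals.
* `homology_rescue()` adopts the single best subject; families with
  chimeric elements could be rescued to the wrong lineage.
* The cross-element "bridge" ambiguity is resolved by TSD evidence;
  in a genome where TSDs have decayed, precision at tandem loci will
  fall toward the identity coin-flip.
* EM replicates explore local optima from random starts; for nearly
  unstructured data the Evanno denominator (replicate sd) can be tiny,
  which is why degenerate cases are flagged or raised as errors rather
  than reported as confident selections.
* At the benchmark scale (25 heavily admixed accessions, 40 dominant
  loci), ΔK model selection is reliable for two subpopulations but
  recovers three in only about half of simulation repeats (the
  reproduction script computes the rate): the replicate sd of L(K) is
  systematically smaller at K = 2 (a single likelihood basin), and the
  likelihood curvature at the true K is often genuinely weaker than at
  K = 2 when every accession is admixed — the statistic's well-known
  lean towards K = 2 under subtle structure. With assigned
  (non-admixed) accessions or more loci the lean disappears, but those
  are different study conditions, so the limitation is reported rather
  than papered over.

The command-line surface listed alongside the module plan is fulfilled
by the exported functions and `run_pipeline()`; an R session (or
`Rscript -e`) is the intended entry point for an R package at this
tier, so no separate shell executable is shipped.
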