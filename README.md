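# wgsmut

Downstream mutation-landscape analysis for paired tumor/normal
whole-genome sequencing cohorts, written for analysts who already have
variant calls and annotations in hand and need the cohort-level results:

* per-sample **mutation tallies** by region and functional class (the
  per-sample count tables of a WGS landscape study);
* six-class and 96-trinucleotide-context **mutation spectra** with
  **KL-NMF signature extraction** and per-sample signature contributions;
* a **significantly-mutated-gene screen** (one-sided Fisher exact test of
  per-gene mutation counts against a footprint-proportional background
  mutation rate, Bonferroni-corrected);
* genome-binned **copy-number recurrence** (frequency x amplitude
  scores, a simplified G-score analogue) with a cyclic-shift
  **permutation null**;
* the five-step **germline susceptibility cascade** (depth >= 10; MAF <=
  0.0014 in 1000 Genomes/ExAC/ESP6500 and dbSNP-unless-COSMIC; coding
  regions only; non-synonymous, non-segdup; at least one damaging call
  among SIFT / PolyPhen2 HVAR / PolyPhen2 HDIV / MutationTaster), ending
  in a samples x genes genotype matrix and per-gene carrier frequencies;
* a fully seeded **synthetic-cohort generator** (reference, gene models,
  signature-mixture somatic variants with designated hypermutators,
  HWE germline genotypes with population-database annotations, CNV
  segments with planted recurrent regions) so the entire pipeline runs
  and is validated with known ground truth and no patient data.

At its core: each SNV is collapsed to its pyrimidine-strand
representation and, with one flanking base each side, binned into the 96
channels `f5[C>X]f3` / `f5[T>X]f3`; the 96 x S count matrix V is
factorized as V ≈ W·H (W >= 0 column-stochastic signatures, H >= 0
exposures) by multiplicative updates minimizing the generalized
Kullback-Leibler divergence. The SMG screen tests the 2x2 table
[[m_g, L_g − m_g], [M − m_g, (L − L_g) − (M − m_g)]] (gene mutations
m_g, gene footprint L_g, cohort totals M, L) with a one-sided Fisher
exact test. CNV recurrence per bin and direction is
freq x mean|log2 ratio| among affected samples, thresholded at the 95th
percentile of per-permutation maxima. Carrier frequency per gene is
(het + hom_alt)/n x 100.

## Worked example

The package ships the published 26-sample susceptibility genotype grid
(`inst/extdata/crc26_genotypes.tsv`). Reproducing the carrier
frequencies and the ranking:

```r
library(wgsmut)
m <- read_genotype_tsv(example_cohort_file("genotypes"))
carrier_frequency(m, "SH3BP1")
#> [1] 76.92
rank_susceptibility(m)
#> # A tibble: 6 × 3
#>   gene    carrier_freq tie
#>   <chr>          <dbl> <lgl>
#> 1 C4orf54        80.8  FALSE
#> 2 SH3BP1         76.9  FALSE
#> 3 ZNF888         46.2  FALSE
#> 4 ANKRD16        30.8  FALSE
#> 5 ATN1           11.5  FALSE
#> 6 CPA6            3.85 FALSE
```

76.92% means 20 of the 26 patients carry at least one qualifying variant
(het or hom_alt) in *SH3BP1*; the two top-ranked genes are the cohort's
candidate susceptibility genes.

The same machinery runs end-to-end on a synthetic cohort with known
ground truth:

```r
cfg <- sim_config(seed = 1)          # 26 samples, 2 hypermutators, ...
sim <- simulate_cohort(cfg)
ann <- annotate_variants(sim$somatic$variants, sim$genes, sim$reference)

ctx <- context_matrix(ann, sim$reference, sample_order = cfg$sample_ids)
fit <- nmf_extract(ctx, k = 2, seed = 1)
fit
#> KL-NMF signature fit: rank 2 | 26 samples | divergence 1218.84 | 60 iterations
match_signatures(fit$signatures, sim$somatic$ground_truth$signatures)
#> (maps the arbitrary extracted labels onto the true signatures;
#>  cosines ~0.999 at the default problem size)

casc <- apply_cascade(sim$germline$records)
casc$trace
#> # A tibble: 5 × 4
#>   step             n_in n_removed n_out
#>   <chr>           <int>     <int> <int>
#> 1 depth           11740       532 11208
#> 2 population      11208     11184    24
#> 3 region             24         3    21
#> 4 func               21         0    21
#> 5 deleteriousness    21         0    21
gm <- genotype_matrix(casc$surviving, cfg$sample_ids)
rank_susceptibility(gm)
#> # A tibble: 2 × 3
#>   gene  carrier_freq tie
#>   <chr>        <dbl> <lgl>
#> 1 G002         76.9  FALSE
#> 2 G040          3.85 FALSE
```

The cascade's attrition trace shows the population-frequency step doing
almost all the work (as it does on real cohorts), and the planted
susceptibility gene `G002` is recovered at exactly its configured 20/26
carrier fraction. `run_cohort_analysis(cfg, outdir = "out")` runs every
stage and writes the TSVs plus a JSON manifest.

See `vignettes/wgsmut-methods.Rmd` for the models, parameter rationale,
numerical choices, and the generator's scope and limits.

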