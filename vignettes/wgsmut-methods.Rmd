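---
title: "Methods and design notes for wgsmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for wgsmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgsmut)
```

# Scope

`wgsmut` implements the downstream analysis stages of a paired
tumor/normal whole-genome sequencing study of a 26-patient colorectal
cancer cohort: everything after variant calling and annotation. Read
alignment, variant calling, and annotation engines are out of scope; the
package consumes VCFs and annotation tables and produces count tables,
spectra, signatures, gene screens, copy-number recurrence profiles, and a
germline susceptibility screen. Because the patient-level data cannot be
shipped, a fully seeded synthetic-cohort generator reproduces the
cohort's statistical structure with known ground truth, and the test
suite validates every stage against that ground truth or against
independent oracles.

# Variant model and classification

A variant is one called allele in one sample: chromosome, 1-based
inclusive start/end, ref/alt strings, class (SNV, insertion, deletion),
genotype (`hom_ref`, `het`, `hom_alt`, `missing`), read depth, and origin
(somatic or germline). Multi-allelic VCF records are split into
bi-allelic records before any counting; each split record carries the
sample genotype restricted to that allele (two copies = `hom_alt`, one =
`het`, zero = `hom_ref`, any `.` = `missing`). Gene models read from BED6
are converted from 0-based half-open to 1-based inclusive at the reader
boundary; everything downstream is 1-based.

Region classification uses the fixed precedence exonic > splicing >
intronic > upstream/downstream > intergenic. Two windows matter:

* `splice_window` (default 2 bp): intronic bases within this distance of
  an exon boundary are `splicing`. 2 bp is the conventional annotation
  default; the choice is exposed as a parameter because no single value
  is canonical.
* `near_gene_window` (default 1000 bp): strand-aware flanks labelled
  `upstream`/`downstream`, again the conventional default.

The package's gene models are purely protein-coding (exons + strand +
frame offset), so the classifier never emits UTR or ncRNA labels; those
labels exist in the annotation vocabulary because externally produced
annotation tables may carry them, and the tally and cascade stages honor
them when present.

Coding consequences: SNVs are classified by translating the affected
codon before and after the substitution with the standard genetic code
(`synonymous_SNV`, `nonsynonymous_SNV`, `stopgain`, `stoploss`); a codon
spanning an exon junction is assembled from the spliced coding sequence,
and minus-strand genes complement the alleles first. Indels are
classified purely by length: an inserted/deleted length that is not a
multiple of 3 is a frameshift. Variants landing in an incomplete trailing
codon return `"unknown"` rather than guessing.

# Count tables

`tally_sample()` counts one sample's records into the standard
coding-region categories, restricted to a scope (SNV, indel, or both).
Two semantics deserve a note because the published tables force them:

* `total` counts every record in scope regardless of region. In the
  published per-sample tables the Total column exceeds the sum of the
  printed columns; the unprinted categories (UTRs, upstream/downstream,
  ncRNA) absorb the difference. This is the only reading consistent with
  those tables.
* Functional categories are counted *inside* exonic, not in addition to
  it, so `synonymous + nonsynonymous + stopgain <= exonic` for SNVs.

`cohort_table()` appends a column-sum row. Column sums are treated as the
authoritative cohort totals: one printed cohort total in the source
tables (the somatic synonymous total) disagrees with its own table's
column sum by 30, and the package trusts the per-sample rows.

# Mutation spectra and signatures

Every SNV is collapsed to its pyrimidine-strand representation: if the
reference base is a purine, ref and alt are complemented and the flanks
reverse-complemented. This folds 12 substitution types into the 6 classes
C>A, C>G, C>T, T>A, T>C, T>G, and with one flanking base on each side
gives the standard 96 trinucleotide channels. Channel order is fixed
(substitution-major, then 5' and 3' flanks each in A, C, G, T order) so
written matrices are interoperable with the field's conventional layout.
SNVs at a contig edge have no defined context; they are excluded from the
96-channel matrix (and logged) but still contribute to the 6-class
spectrum, which needs no flanks.

Signature extraction is non-negative matrix factorization of the
96 x S count matrix, minimizing the generalized Kullback-Leibler
divergence by multiplicative updates. KL rather than a least-squares
objective because the entries are Poisson-like counts spanning orders of
magnitude between ordinary and hypermutated samples. Numerical choices:

* initialization: seeded uniform(0,1] entries; `n_restarts = 10`, best
  final divergence wins; a machine-epsilon floor guards divisions;
* stopping: relative divergence change below `tol = 1e-6` or
  `max_iter = 2000`; the per-iteration divergence trace is retained and
  asserted non-increasing in the tests (the classical monotonicity
  guarantee of the updates);
* normalization: signature columns are scaled to sum to 1 with the scale
  absorbed into the exposures, and normalized exposures sum to 1 per
  sample;
* rank: fixed at `k = 2` by default, mirroring the two-signature
  description of the cohort. The source study does not name its
  extraction algorithm or rank rule, so KL-NMF at rank 2 is this
  package's own reconstruction, not a claim about the original software.
* degenerate input: an all-zero matrix is an error, not a silent
  factorization.

`dominant_signature()` takes the per-sample argmax of normalized
exposures; exact ties go to the lower signature index and are flagged.

## Identifiability and the simulated exposure design

NMF recovers the true signatures only if the observed mixtures span them.
If every simulated sample mixed the two signatures in the same (or only
two distinct) proportions, the count matrix would occupy a cone whose
extreme rays are those mixtures — any factorization algorithm would
recover the mixtures, not the underlying signatures, and per-sample
exposures would be systematically stretched. The generator therefore
assigns a deterministic spread of signature-A weights: the A-dominated
samples range over 0.55-1.0 (including near-pure samples) and the two
B-dominated samples over 0.0-0.1. This heterogeneity is a designed
property of the synthetic cohort, required for the recovery validation to
be mathematically attainable; real cohorts show comparable spread.

# Significantly mutated genes

Qualifying records are protein-altering exonic changes (nonsynonymous,
stopgain/stoploss, frameshift) and splice-site variants. Per gene the
screen counts distinct qualifying sites and affected samples;
`sample_percent` is affected/26 at full precision (rounded only for
display, so the affected count is always recoverable).

The test is a one-sided Fisher exact test on the 2x2 table contrasting
mutated vs unmutated base pairs inside the gene against the rest of the
analyzed footprint — a uniform, footprint-proportional background
mutation rate. One-sided because the screen asks only about enrichment.
Bonferroni correction is applied over the genes actually tested (those
with at least one qualifying mutation). Covariate-aware background models
(expression, replication timing) are deliberately out of scope.

The published screen's p-values depend on gene-length inputs and an
"effectively analyzed sites" definition that the source does not state,
so they are not reproduction targets; counts and percentages are. The
package's own p-value path is validated two ways: exact agreement
(to 1e-12) with a brute-force hypergeometric enumeration oracle, and a
null calibration in which background-only cohorts yield a raw-p < 0.05
fraction near the nominal 0.05. The calibration regime uses 25 genes of
3 kb in a 1 Mb footprint with 10,000 total mutations (about 30 expected
per gene) so that the discreteness of the exact test is negligible; at
much smaller expected counts the test is conservative, which is a
property of exact tests, not a defect of the screen.

# Copy-number recurrence

Per-sample segments (log2 ratios) are reduced to per-bin states on a
fixed-width genome binning (1 Mb by default for real-scale genomes; the
synthetic genome uses 100 kb bins). A bin's value is the length-weighted
mean log2 ratio of the segments overlapping it; values above +0.2 /
below -0.2 are gain/loss calls — conventional thresholds for WGS ratio
data, exposed as parameters. Sex chromosomes are excluded by name.

For each bin and direction the recurrence score is
`frequency x mean |log2 ratio| among affected samples` — a
frequency-and-amplitude statistic in the spirit of a G-score. Scores are
linear in amplitude at fixed calls and invariant to sample and segment
order.

Significance uses a cyclic-shift permutation null: each permutation
shifts every sample's entire segment set by an independent uniform offset
along the concatenated autosomal genome (wrapping and re-splitting at
chromosome boundaries), preserving each sample's segment-length structure
while destroying cross-sample alignment. The threshold is the 95th
percentile of the per-permutation maximum bin score, per direction, with
at least 100 permutations enforced. This is a defined simplification of
the established recurrence tools: no q-values, no peak deconvolution, no
arm-level statistics, and no claim of reproducing any specific tool's
output. One degenerate case is worth knowing: under the default noise
level (sd 0.05, well inside the +-0.2 call window) a pure-noise cohort
typically produces *no* calls at all, so observed maxima and thresholds
are both exactly zero; the null calibration therefore counts "within
threshold" as `<=`.

# Germline susceptibility cascade

Five steps, in the published order, over annotated germline records:

1. **depth**: keep records with depth >= 10;
2. **population**: remove records whose frequency exceeds 0.0014 in any
   of 1000 Genomes, ExAC, or ESP6500; then remove dbSNP members unless
   they are also in COSMIC. The 0.0014 ceiling is the original screen's
   stated value but is kept configurable because its exact intent
   (strictly greater vs at-least, per-database vs any-database) is
   ambiguous; this package removes a record if *any* database frequency
   exceeds the ceiling. COSMIC membership overrides only the dbSNP
   removal, not the frequency filter — the more conservative reading of
   an ambiguous rule.
3. **region**: remove intergenic, intronic, ncRNA, upstream/downstream,
   and UTR records;
4. **function**: remove synonymous variants and (by default) records
   flagged as segmental-duplication regions — the standard
   annotation-track reading of the original screen's duplication-gene
   rule;
5. **deleteriousness**: keep records with at least one damaging call
   among SIFT, PolyPhen2-HVAR, PolyPhen2-HDIV, MutationTaster. Missing
   predictions never rescue a variant; an all-of rule is available as an
   option.

Predictor letter codes are normalized upstream: SIFT "D" is damaging;
PolyPhen2 "D"/"P" damaging; MutationTaster "A"/"D" damaging; everything
else tolerated.

The cascade emits a per-step attrition trace with the conservation
invariant `out = in - removed` at every step, is idempotent, and is
monotone in the frequency ceiling. The surviving records are folded into
a samples x genes genotype matrix with severity precedence (`hom_alt`
beats `het` beats `hom_ref`); samples with no surviving record in a gene
are explicit `hom_ref`, which is how the published genotype grid is laid
out. Carrier frequency is (het + hom_alt)/n x 100 to 2 decimals, and the
susceptibility ranking is by descending carrier frequency with
alphabetical, flagged tie-breaks.

# The synthetic cohort

What it emulates: 26 samples; somatic SNV burdens Poisson around 800 per
ordinary sample with two hypermutated samples at 20x (mirroring the two
extreme cases in the real cohort); SNV channels drawn from a two-signature
mixture (signature A concentrated on C>T, signature B on T>A/C>G, cosine
~0.1 apart); indels at 10% of the SNV count with lengths uniform on 1-6 so
4/6 shift the frame; somatic placement over exonic/intronic/intergenic
in proportions 0.02/0.34/0.64; germline sites with true MAFs from
Beta(0.3, 3) truncated to [1e-4, 0.5] (rare-skewed, populating both sides
of the 0.0014 cascade ceiling), Hardy-Weinberg genotypes, noisy
per-database frequencies, MAF-dependent dbSNP rates, and independent
predictor calls; one planted significantly-mutated gene (per-sample
mutation probability 0.5); one planted susceptibility variant (rare,
COSMIC-flagged, damaging, exonic nonsynonymous, carried by 20/26 samples,
30% of carriers homozygous); and CNV segments with Normal(0, 0.05)
background and planted recurrent gain/loss regions (penetrance 0.8/0.6,
amplitude 0.9/0.7).

What it does not emulate: GC structure or any sequence composition bias
(the reference is i.i.d. uniform so that every trinucleotide context is
abundantly available), linkage disequilibrium, sequencing error, read
depth structure beyond a Poisson(60) with a 5% low-depth admixture, UTR
and ncRNA gene structure, and subclonality. Consequently, passing tests
demonstrate correctness of the computations and recoverability of planted
structure — not that the generator's outputs are indistinguishable from
real tumor genomes.

Determinism: one master seed; each generator derives a fixed child seed
(master + fixed offset), so regenerating one output never perturbs the
others, and two runs at one seed are byte-identical down to the written
files.

Problem sizes: the default synthetic genome is 6 chromosomes x 800 kb
with 60 genes; signature-recovery validation uses 26 samples x 10^4 SNVs;
the Fisher oracle sweeps all enrichment tables at N = 30 plus 500 random
tables up to N = 500; the SMG null calibration uses 200 replicates x 25
genes; the CNV null calibration uses 50 noise cohorts with 100
permutations each. These sizes were chosen so the full validation runs
comfortably on a laptop while keeping every statistical check
well-powered.

# Known limitations

* The region classifier understands only protein-coding gene models;
  ncRNA/UTR structure must come from upstream annotation.
* The SMG background is uniform per base pair; genes with atypical
  mutability will mis-rank, as with any uniform-BMR screen.
* The CNV module scores recurrence only; it does not segment, call
  purity/ploidy, or separate focal from arm-level events.
* The NMF rank survey is advisory; rank selection for real cohorts
  deserves dedicated stability analysis.
* Carrier-frequency denominators assume every sample is assayed at every
  surviving site; whole-sample missingness is not modelled.
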