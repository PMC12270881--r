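test_that("simulation is fully deterministic given config and seed", {
  cfg <- small_sim_config(seed = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(a$genes, b$genes)
  expect_identical(a$somatic$variants, b$somatic$variants)
  expect_identical(a$germline$records, b$germline$records)
  expect_identical(a$cnv$segments, b$cnv$segments)

  # written outputs are byte-identical too
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("reference simulation places disjoint genes that fit", {
  cfg <- small_sim_config()
  r <- simulate_reference(cfg)
  expect_equal(sum(nchar(as.character(r$reference))),
               sum(cfg$chrom_lengths))
  expect_equal(length(unique(r$genes$gene)), cfg$n_genes)
  spans <- do.call(rbind, lapply(split(r$genes, r$genes$gene), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start),
               end = max(g$end))
  }))
  for (ch in unique(spans$chrom)) {
    s <- spans[spans$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1L) expect_true(all(s$start[-1L] > s$end[-nrow(s)]))
  }
  # an impossible request errors
  expect_error(simulate_reference(
    sim_config(chrom_lengths = c(chr1 = 20000L), n_genes = 50L,
               planted_cnv = NULL)),
    "could not place")
})

test_that("somatic variants carry the reference allele they claim", {
  cfg <- small_sim_config()
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  set.seed(1)
  v <- som$variants[sample.int(nrow(som$variants), 200), ]
  actual <- vapply(seq_len(nrow(v)), function(i) {
    as.character(Biostrings::subseq(r$reference[[v$chrom[i]]],
                                    v$pos[i], v$end[i]))
  }, character(1))
  expect_equal(actual, v$ref)
})

test_that("pure-exposure samples converge to their signature", {
  cfg <- sim_config(seed = 5, n_samples = 2L,
                    chrom_lengths = c(chr1 = 400000L), n_genes = 5L,
                    somatic_burden = 10000, hypermutator_samples = 1L,
                    hypermutator_factor = 1, indel_fraction = 0,
                    region_mix = c(exonic = 0, intronic = 0,
                                   intergenic = 1),
                    exposures = matrix(c(1, 1, 0, 0), 2L),
                    planted_smg = list(gene = "G001", prob = 0),
                    planted_cnv = NULL,
                    planted_susceptibility = NULL)
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  ctx <- context_matrix(som$variants, r$reference)
  emp <- rowSums(ctx) / sum(ctx)
  expect_gt(cosine_similarity(emp, cfg$true_signatures[, 1]), 0.99)
})

test_that("indel lengths give roughly the designed 2/3 frameshift rate", {
  cfg <- small_sim_config(seed = 21)
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  ind <- som$variants[som$variants$variant_class != "SNV", ]
  len <- abs(nchar(ind$ref) - nchar(ind$alt))
  expect_true(all(len %in% 1:6))
  fs_rate <- mean(len %% 3 != 0)
  n <- length(len)
  expect_lt(abs(fs_rate - 4 / 6), 3 * sqrt((4 / 6) * (2 / 6) / n))
})

test_that("generated region mix matches the configured proportions", {
  cfg <- small_sim_config(seed = 8)
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  lab <- classify_region(som$variants, r$genes)
  coarse <- c(exonic = "exonic", splicing = "intronic",
              intronic = "intronic", upstream = "intergenic",
              downstream = "intergenic", intergenic = "intergenic")
  obs <- table(coarse[lab]) / length(lab)
  n <- length(lab)
  for (k in names(cfg$region_mix)) {
    p <- cfg$region_mix[[k]]
    expect_lt(abs(obs[[k]] - p), 4 * sqrt(p * (1 - p) / n) + 0.01,
              label = k)
  }
})

test_that("planted SMG appears in exactly the recorded carriers", {
  cfg <- small_sim_config(seed = 13,
                          planted_smg = list(gene = "G001", prob = 1.0))
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  expect_setequal(som$ground_truth$smg_carriers, cfg$sample_ids)
  ann <- annotate_variants(som$variants, r$genes, r$reference)
  in_gene <- ann[!is.na(ann$gene) & ann$gene == "G001" &
                   ann$region == "exonic" &
                   ann$func %in% c("nonsynonymous_SNV", "stopgain"), ]
  expect_true(all(cfg$sample_ids %in% in_gene$sample_id))
})

test_that("germline genotypes follow Hardy-Weinberg proportions", {
  set.seed(99)
  for (maf in c(0.1, 0.3, 0.5)) {
    g <- wgsmut:::.hwe_genotypes(maf, 10000L)
    het <- mean(g == "het")
    expected <- 2 * maf * (1 - maf)
    expect_lt(abs(het - expected),
              4 * sqrt(expected * (1 - expected) / 10000))
  }
})

test_that("germline ground truth is recoverable from emitted files", {
  cfg <- small_sim_config(seed = 17)
  sim <- simulate_cohort(cfg)
  d <- file.path(tempdir(), "audit")
  write_cohort(sim, d)
  # re-parse the annotation table independently and find the planted gene
  back <- read_annotation_tsv(file.path(d, "germline_annotated.tsv"))
  planted <- back[!is.na(back$gene) &
                    back$gene ==
                    sim$germline$ground_truth$susceptibility_gene &
                    back$in_cosmic, ]
  expect_setequal(unique(planted$sample_id),
                  sim$germline$ground_truth$carriers)
  # and the germline VCF genotypes match the annotation records
  vcf <- read_vcf(file.path(d, "germline.vcf"), origin = "germline",
                  drop_hom_ref = TRUE)
  key <- function(x) paste(x$sample_id, x$chrom, x$pos, x$alt, x$genotype)
  expect_setequal(key(vcf), key(back))
})

test_that("germline population frequencies straddle the cascade cutoff", {
  cfg <- small_sim_config(seed = 23)
  r <- simulate_reference(cfg)
  germ <- simulate_germline(cfg, r$reference, r$genes)
  maf <- germ$sites$true_maf
  expect_true(all(maf >= 1e-4 & maf <= 0.5))
  expect_gt(sum(maf > 0.0014), 0)
  expect_gt(sum(maf <= 0.0014), 0)
})

test_that("planted CNV regions appear at the recorded penetrance", {
  cfg <- small_sim_config(seed = 29,
                          planted_cnv = data.frame(
                            chrom = "chr2", start = 50001L, end = 150000L,
                            direction = 1L, penetrance = 0.5,
                            amplitude = 0.9))
  cnv <- simulate_cnv(cfg)
  carriers <- cnv$ground_truth$planted$carriers[[1]]
  seg <- cnv$segments
  hit <- seg[seg$chrom == "chr2" & seg$start == 50001L &
               seg$end == 150000L & seg$log2_ratio == 0.9, ]
  expect_setequal(hit$sample_id, carriers)
  # binomial 99% CI check on observed penetrance
  n <- cfg$n_samples
  p_hat <- length(carriers) / n
  expect_lt(abs(p_hat - 0.5), 2.58 * sqrt(0.25 / n) + 1e-9)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(region_mix = c(exonic = 0.5, intronic = 0.5,
                                         intergenic = 0.5)), "sum to 1")
  expect_error(sim_config(exposures = matrix(1, 3, 2)), "exposures")
  expect_error(
    sim_config(planted_susceptibility = list(gene = "G002",
                                             carrier_fraction = 1.5,
                                             hom_fraction = 0)),
    "carrier fraction")
  expect_error(sim_config(planted_cnv = data.frame(
    chrom = c("chr1", "chr1"), start = c(1L, 50000L),
    end = c(100000L, 150000L), direction = c(1L, -1L),
    penetrance = 0.5, amplitude = 0.5)), "opposite direction")
  expect_error(sim_config(planted_cnv = data.frame(
    chrom = "chr9", start = 1L, end = 10L, direction = 1L,
    penetrance = 1, amplitude = 1)), "outside")
})
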