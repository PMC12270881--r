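test_that("read_vcf maps fields and splits multi-allelic sites", {
  p <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:30",
    "chr1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT:DP\t1/2:44",
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT:DP\t1/1:12",
    "chr1\t400\t.\tC\tCGG\t.\tPASS\t.\tGT:DP\t./.:7"))
  v <- read_vcf(p, origin = "somatic")
  expect_equal(nrow(v), 5L)  # 200 A>G,T splits into two records

  snv <- v[v$pos == 100, ]
  expect_equal(snv$variant_class, "SNV")
  expect_equal(snv$genotype, "het")
  expect_equal(snv$depth, 30L)
  expect_equal(snv$origin, "somatic")

  split <- v[v$pos == 200, ]
  expect_equal(nrow(split), 2L)
  expect_setequal(split$alt, c("G", "T"))
  # GT 1/2: one copy of each alt allele
  expect_equal(split$genotype, c("het", "het"))

  del <- v[v$pos == 300, ]
  expect_equal(del$variant_class, "deletion")
  expect_equal(del$genotype, "hom_alt")
  expect_equal(del$end, 301L)

  ins <- v[v$pos == 400, ]
  expect_equal(ins$variant_class, "insertion")
  expect_equal(ins$genotype, "missing")
})

test_that("read_vcf handles empty bodies and flags malformed lines", {
  p <- write_test_vcf(character(0))
  v <- read_vcf(p, origin = "germline")
  expect_equal(nrow(v), 0L)

  bad <- write_test_vcf("chr1\t100\tonly-three-fields")
  expect_error(read_vcf(bad, "somatic"), "line 5")

  badpos <- write_test_vcf(
    "chr1\txyz\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:30")
  expect_error(read_vcf(badpos, "somatic"), "POS")
})

test_that("vcf writer and reader round-trip variant fields", {
  g <- make_tiny_genome()
  v <- tibble::tibble(
    sample_id = c("S1", "S1", "S2"), chrom = "chrT",
    pos = c(14L, 30L, 14L), end = c(14L, 30L, 14L),
    ref = c("G", "G", "G"), alt = c("A", "GTT", "A"),
    variant_class = c("SNV", "insertion", "SNV"),
    genotype = c("het", "hom_alt", "hom_alt"),
    depth = c(30L, 11L, 60L), origin = "somatic")
  p <- tempfile(fileext = ".vcf")
  write_vcf(v, p, contig_lengths = c(chrT = 80L))
  back <- read_vcf(p, origin = "somatic")
  # absent sample/site pairs come back as explicit hom_ref records
  carried <- back[back$genotype != "hom_ref", names(v)]
  expect_equal(
    as.data.frame(carried[order(carried$sample_id, carried$pos), ]),
    as.data.frame(v[order(v$sample_id, v$pos), ]),
    ignore_attr = TRUE)
})

test_that("region classification follows the documented precedence", {
  g <- make_tiny_genome()
  vars <- tibble::tibble(
    sample_id = "S1", chrom = "chrT",
    pos = c(15L, 23L, 30L, 26L, 5L, 75L, 50L),
    end = pos, ref = "A", alt = "C", variant_class = "SNV")
  labels <- classify_region(vars, g$genes, splice_window = 2L,
                            near_gene_window = 1000L)
  expect_equal(labels, c("exonic",     # inside FWD exon 1
                         "splicing",   # 1 bp into the intron
                         "splicing",   # last intron base (window 2)
                         "intronic",   # intron interior
                         "upstream",   # 5' of FWD (+ strand)
                         "upstream",   # 3' end of chrT is 5' of REV (-)
                         "downstream"))
  # no genes at all -> everything intergenic
  expect_equal(unique(classify_region(vars, g$genes[0, ])), "intergenic")
  # shrinking the splice window reclassifies the boundary base
  expect_equal(classify_region(vars[2, ], g$genes, splice_window = 0L),
               "intronic")
})

test_that("region labels partition the cohort", {
  cfg <- small_sim_config()
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  labels <- classify_region(som$variants, r$genes)
  expect_length(labels, nrow(som$variants))
  expect_true(all(labels %in% c("exonic", "splicing", "intronic",
                                "upstream", "downstream", "intergenic")))
  expect_equal(sum(table(labels)), nrow(som$variants))
})

test_that("coding consequences: codon translation on both strands", {
  g <- make_tiny_genome()
  mk <- function(pos, ref, alt) {
    tibble::tibble(sample_id = "S1", chrom = "chrT", pos = pos, end = pos,
                   ref = ref, alt = alt,
                   variant_class = variant_class(ref, alt))
  }
  # + strand gene: GCT -> GCC is Ala -> Ala
  expect_equal(classify_function(mk(16L, "T", "C"), "FWD", g$genes,
                                 g$reference), "synonymous_SNV")
  # GCT -> ACT is Ala -> Thr
  expect_equal(classify_function(mk(14L, "G", "A"), "FWD", g$genes,
                                 g$reference), "nonsynonymous_SNV")
  # AAA -> TAA creates a stop
  expect_equal(classify_function(mk(20L, "A", "T"), "FWD", g$genes,
                                 g$reference), "stopgain")
  # TAG -> TCG loses the stop (codon spans into exon 2)
  expect_equal(classify_function(mk(41L, "A", "C"), "FWD", g$genes,
                                 g$reference), "stoploss")
  # - strand gene: genomic T>C at the last exon base is ATG -> GTG
  expect_equal(classify_function(mk(72L, "T", "C"), "REV", g$genes,
                                 g$reference), "nonsynonymous_SNV")
  # indel length rule: 4 mod 3 = 1 shifts the frame, 3 does not
  expect_equal(classify_function(mk(14L, "GCTGC", "G"), "FWD", g$genes,
                                 g$reference), "frameshift_deletion")
  expect_equal(classify_function(mk(14L, "G", "GAAA"), "FWD", g$genes,
                                 g$reference), "nonframeshift_insertion")
  expect_equal(classify_function(mk(14L, "G", "GA"), "FWD", g$genes,
                                 g$reference), "frameshift_insertion")
  # outside the gene's coding exons -> contract violation
  expect_error(classify_function(mk(26L, "G", "A"), "FWD", g$genes,
                                 g$reference), "not inside")
})

test_that("SNV consequence is invariant to strand representation", {
  # For a - strand gene, representing the same genomic change is the only
  # representation; instead check that complementing a + strand gene's
  # variant together with flipping the gene strand (and reversing the
  # sequence) preserves the consequence class.
  g <- make_tiny_genome()
  fwd_seq <- as.character(g$reference[["chrT"]])
  flipped <- Biostrings::DNAStringSet(c(chrT = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd_seq)))))
  n <- nchar(fwd_seq)
  genes_flipped <- gene_models(
    gene = c("FWD", "FWD"), chrom = "chrT",
    start = n - c(22L, 42L) + 1L, end = n - c(11L, 31L) + 1L,
    strand = "-")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cases <- list(c(16L, "T", "C"), c(14L, "G", "A"), c(20L, "A", "T"))
  for (cs in cases) {
    pos <- as.integer(cs[1])
    v1 <- tibble::tibble(sample_id = "S1", chrom = "chrT", pos = pos,
                         end = pos, ref = cs[2], alt = cs[3],
                         variant_class = "SNV")
    v2 <- tibble::tibble(sample_id = "S1", chrom = "chrT",
                         pos = n - pos + 1L, end = n - pos + 1L,
                         ref = comp[[cs[2]]], alt = comp[[cs[3]]],
                         variant_class = "SNV")
    expect_equal(classify_function(v1, "FWD", g$genes, g$reference),
                 classify_function(v2, "FWD", genes_flipped, flipped))
  }
})

test_that("gene model validation and BED round-trip", {
  expect_error(gene_models("G", "chr1", c(10L, 15L), c(20L, 30L), "+"),
               "overlapping")
  g <- make_tiny_genome()
  p <- tempfile(fileext = ".bed")
  write_gene_bed(g$genes, p)
  back <- read_gene_bed(p)
  expect_equal(as.data.frame(back[order(back$gene, back$start), ]),
               as.data.frame(g$genes[order(g$genes$gene,
                                           g$genes$start), ]),
               ignore_attr = TRUE)
  expect_equal(gene_footprints(g$genes),
               c(FWD = 24L, REV = 12L))
})

test_that("annotation TSV writer/reader round-trips all fields", {
  recs <- make_cascade_records(50)
  p <- tempfile(fileext = ".tsv")
  write_annotation_tsv(recs, p)
  back <- read_annotation_tsv(p)
  cols <- intersect(names(recs), names(back))
  expect_equal(as.data.frame(back[cols]), as.data.frame(recs[cols]),
               ignore_attr = TRUE)
  expect_error(read_annotation_tsv(
    write_test_vcf(character(0))), "version header")
})
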