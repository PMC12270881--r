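# Shared fixtures built in code at test time.

# Minimal VCF writer for hand-built records (header + raw body lines).
write_test_vcf <- function(body_lines, samples = "S1",
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body_lines), path)
  path
}

# A small deterministic reference + one gene on each strand.
# chrT sequence is built so codon arithmetic can be done by hand.
make_tiny_genome <- function() {
  # gene "FWD": + strand, exons 11-22 and 31-42 (two exons, 24 coding bp)
  # gene "REV": - strand, exon 61-72 (12 coding bp)
  seq <- paste0(
    "AAAAAAAAAA",            # 1-10
    "ATGGCTGCTAAA",          # 11-22  exon1 FWD: M A A K
    "GGGGGGGG",              # 23-30  intron
    "TGTTGGTTATAG",          # 31-42  exon2 FWD: C W L *
    "AAAAAAAAAAAAAAAAAA",    # 43-60
    "TTACAGAGCCAT",          # 61-72  exon REV (- strand: ATG GCT CTG TAA)
    "AAAAAAAA")              # 73-80
  reference <- Biostrings::DNAStringSet(c(chrT = seq))
  genes <- gene_models(
    gene = c("FWD", "FWD", "REV"),
    chrom = "chrT",
    start = c(11L, 31L, 61L),
    end = c(22L, 42L, 72L),
    strand = c("+", "+", "-"))
  list(reference = reference, genes = genes)
}

# Annotated germline records with every cascade-relevant field populated.
make_cascade_records <- function(n, seed = 42) {
  set.seed(seed)
  regions <- c("exonic", "splicing", "intronic", "intergenic", "UTR5",
               "upstream", "downstream", "ncRNA_exonic")
  funcs <- c("synonymous_SNV", "nonsynonymous_SNV", "stopgain",
             "frameshift_deletion", "unknown")
  pred <- function() sample(c("damaging", "tolerated", "missing"), n,
                            replace = TRUE, prob = c(0.3, 0.6, 0.1))
  freq <- function() ifelse(runif(n) < 0.2, NA_real_,
                            rbeta(n, 0.3, 3) / 2)
  reg <- sample(regions, n, replace = TRUE)
  tibble::tibble(
    sample_id = sample(sprintf("S%02d", 1:26), n, replace = TRUE),
    chrom = "chr1", pos = sample.int(1e6, n), end = pos,
    ref = "A", alt = "G", variant_class = "SNV",
    genotype = sample(c("het", "hom_alt"), n, replace = TRUE,
                      prob = c(0.8, 0.2)),
    depth = rpois(n, 20), origin = "germline",
    region = reg,
    gene = ifelse(reg %in% c("exonic", "splicing", "intronic"),
                  sample(sprintf("G%03d", 1:20), n, replace = TRUE),
                  NA_character_),
    func = ifelse(reg == "exonic", sample(funcs, n, replace = TRUE),
                  "unknown"),
    pop_freq_1000g = freq(), pop_freq_exac = freq(),
    pop_freq_esp6500 = freq(),
    in_dbsnp = runif(n) < 0.5, in_cosmic = runif(n) < 0.15,
    in_segdup = runif(n) < 0.1,
    sift = pred(), pp2_hvar = pred(), pp2_hdiv = pred(),
    mutation_taster = pred())
}

# Cohort simulation at reduced scale for unit tests (fast, seeded).
small_sim_config <- function(seed = 11,
                             planted_cnv = data.frame(
                               chrom = "chr2", start = 50001L,
                               end = 150000L, direction = 1L,
                               penetrance = 1.0, amplitude = 0.8),
                             ...) {
  sim_config(seed = seed, n_samples = 6L,
             chrom_lengths = setNames(rep(200000L, 3L),
                                      paste0("chr", 1:3)),
             n_genes = 12L, somatic_burden = 300,
             hypermutator_samples = 2L, hypermutator_factor = 5,
             germline_site_count = 400L,
             exposures = matrix(c(rep(0.9, 5), 0.1,
                                  rep(0.1, 5), 0.9), ncol = 2L),
             planted_cnv = planted_cnv,
             ...)
}

# Independent brute-force re-count of a context matrix via an environment
# hash map (used as the oracle for context_matrix).
brute_force_context_counts <- function(snvs, reference) {
  env <- new.env(hash = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(snvs))) {
    v <- snvs[i, ]
    if (v$variant_class != "SNV") next
    chr <- as.character(reference[[v$chrom]])
    if (v$pos <= 1 || v$pos >= nchar(chr)) next
    f5 <- substr(chr, v$pos - 1, v$pos - 1)
    f3 <- substr(chr, v$pos + 1, v$pos + 1)
    ref <- v$ref; alt <- v$alt
    if (ref %in% c("A", "G")) {
      tmp <- comp[[f5]]; f5 <- comp[[f3]]; f3 <- tmp
      ref <- comp[[ref]]; alt <- comp[[alt]]
    }
    key <- paste0(v$sample_id, "|", f5, "[", ref, ">", alt, "]", f3)
    env[[key]] <- (env[[key]] %||% 0L) + 1L
  }
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent enumeration oracle for the one-sided (enrichment) Fisher
# test: hypergeometric tail summed from binomial coefficients on the log
# scale.
hypergeom_tail <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- a:min(r1, c1)
  sum(exp(lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)))
}

# Independent single-pass predicate filter: one boolean expression per
# record, coded separately from the cascade's step machinery.
oracle_filter <- function(x, cfg = cascade_config()) {
  keep <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    freqs <- c(r$pop_freq_1000g, r$pop_freq_exac, r$pop_freq_esp6500)
    damaging <- c(r$sift, r$pp2_hvar, r$pp2_hdiv,
                  r$mutation_taster) == "damaging"
    keep[i] <-
      !is.na(r$depth) && r$depth >= cfg$min_depth &&
      !any(freqs > cfg$max_pop_freq, na.rm = TRUE) &&
      (!r$in_dbsnp || r$in_cosmic) &&
      !(r$region %in% cfg$excluded_regions) &&
      r$func != "synonymous_SNV" &&
      !(cfg$exclude_segdup && r$in_segdup) &&
      any(damaging)
  }
  x[keep, , drop = FALSE]
}
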