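#' Default pair of well-separated mutational signatures
#'
#' Signature A concentrates 75% of its mass uniformly on the 16 C>T
#' channels (the transition-dominant pattern typical of these tumors);
#' signature B concentrates on T>A (55%) and C>G (25%). The remaining mass
#' is spread uniformly over the other channels. Cosine similarity between
#' the two is ~0.1, so a rank-2 factorization is well identified.
#'
#' @return A 96 x 2 matrix with columns `A` and `B`, each summing to 1.
#' @export
default_signatures <- function() {
  ch <- context_channels()
  cls <- sub(".*\\[(.*)\\].*", "\\1", ch)
  sigA <- numeric(96)
  sigA[cls == "C>T"] <- 0.75 / 16
  sigA[cls != "C>T"] <- 0.25 / 80
  sigB <- numeric(96)
  sigB[cls == "T>A"] <- 0.55 / 16
  sigB[cls == "C>G"] <- 0.25 / 16
  rest <- !(cls %in% c("T>A", "C>G"))
  sigB[rest] <- 0.20 / sum(rest)
  m <- cbind(A = sigA, B = sigB)
  rownames(m) <- ch
  m
}

#' Synthetic-cohort simulation configuration
#'
#' Defaults emulate the statistical structure of a 26-patient tumor/normal
#' WGS cohort: 26 samples with two designated somatic hypermutators at 20x
#' burden, a two-signature mixture with most samples dominated by
#' signature A and two by signature B, rare-skewed germline allele
#' frequencies, one planted significantly-mutated gene, one planted
#' susceptibility gene carried by 20/26 samples, and planted recurrent
#' copy-number gain and loss regions.
#'
#' @param seed Master integer seed. Each generator derives its own child
#'   seed by a fixed offset so regenerating one output leaves the others
#'   untouched.
#' @param n_samples Cohort size (default 26).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_genes Number of non-overlapping multi-exon genes to place.
#' @param somatic_burden Expected somatic SNV count per ordinary sample.
#' @param hypermutator_samples Indices of hypermutated samples.
#' @param hypermutator_factor Burden multiplier for hypermutators
#'   (default 20, within the 10-30x range seen in hypermutated cases).
#' @param indel_fraction Somatic indels as a fraction of the SNV count.
#' @param region_mix Target proportions of somatic variants over
#'   exonic/intronic/intergenic placement.
#' @param true_signatures 96 x 2 column-stochastic signature matrix.
#' @param exposures n_samples x 2 matrix, rows summing to 1.
#' @param germline_site_count Number of germline variant sites.
#' @param maf_shape1,maf_shape2 Beta parameters of the true minor-allele
#'   frequency distribution, truncated to `[1e-4, 0.5]` (rare-skewed).
#' @param dbsnp_rate_common,dbsnp_rate_rare dbSNP membership probability
#'   for sites with MAF >= 1% / < 1%.
#' @param cosmic_rate Background COSMIC membership probability.
#' @param predictor_damaging_rate Per-predictor probability of a damaging
#'   call at a background site.
#' @param predictor_missing_rate Per-predictor missing-call probability.
#' @param segdup_rate Probability a site is flagged as segmental
#'   duplication.
#' @param mean_depth Mean sequencing depth (Poisson).
#' @param low_depth_fraction,low_depth_mean A fraction of records drawn at
#'   low depth to exercise the depth filter.
#' @param planted_smg List `(gene, prob)`: per-sample probability of a
#'   qualifying somatic mutation in the planted SMG.
#' @param planted_susceptibility List `(gene, carrier_fraction,
#'   hom_fraction)` for the planted germline susceptibility gene.
#' @param planted_cnv Data frame of planted recurrent regions: `chrom`,
#'   `start`, `end`, `direction` (+1 gain / -1 loss), `penetrance`,
#'   `amplitude` (absolute log2 ratio).
#' @param cnv_noise_sd SD of background segment log2 ratios.
#' @return A validated list of class `wgsmut_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 26L,
                       chrom_lengths = setNames(rep(800000L, 6L),
                                                paste0("chr", 1:6)),
                       n_genes = 60L,
                       somatic_burden = 800,
                       hypermutator_samples = c(9L, 15L),
                       hypermutator_factor = 20,
                       indel_fraction = 0.10,
                       region_mix = c(exonic = 0.02, intronic = 0.34,
                                      intergenic = 0.64),
                       true_signatures = default_signatures(),
                       exposures = NULL,
                       germline_site_count = 3000L,
                       maf_shape1 = 0.3, maf_shape2 = 3,
                       dbsnp_rate_common = 0.95, dbsnp_rate_rare = 0.30,
                       cosmic_rate = 0.02,
                       predictor_damaging_rate = 0.15,
                       predictor_missing_rate = 0.05,
                       segdup_rate = 0.05,
                       mean_depth = 60,
                       low_depth_fraction = 0.05, low_depth_mean = 6,
                       planted_smg = list(gene = "G001", prob = 0.5),
                       planted_susceptibility =
                         list(gene = "G002", carrier_fraction = 20 / 26,
                              hom_fraction = 0.3),
                       planted_cnv = data.frame(
                         chrom = c("chr2", "chr4"),
                         start = c(300001L, 100001L),
                         end = c(500000L, 300000L),
                         direction = c(1L, -1L),
                         penetrance = c(0.8, 0.6),
                         amplitude = c(0.9, 0.7)),
                       cnv_noise_sd = 0.05) {
  if (is.null(exposures)) {
    # Deterministic spread of signature-A weights: most samples
    # A-dominated at varying strength (including near-pure), two samples
    # B-dominated. The spread matters: a cohort in which every sample had
    # identical mixing proportions would carry no information to separate
    # the signatures (the count matrix would be effectively rank 1), so
    # exposure heterogeneity is part of the designed cohort structure.
    b_dom <- intersect(unique(c(15L, n_samples)), seq_len(n_samples))
    a_idx <- setdiff(seq_len(n_samples), b_dom)
    a_w <- numeric(n_samples)
    a_w[a_idx] <- seq(0.55, 1.0, length.out = max(length(a_idx), 1L))
    a_w[b_dom] <- seq(0.0, 0.1, length.out = length(b_dom))
    exposures <- cbind(a_w, 1 - a_w)
  }
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              sample_ids = sprintf("S%02d", seq_len(n_samples)),
              chrom_lengths = chrom_lengths, n_genes = as.integer(n_genes),
              somatic_burden = somatic_burden,
              hypermutator_samples = hypermutator_samples,
              hypermutator_factor = hypermutator_factor,
              indel_fraction = indel_fraction, region_mix = region_mix,
              true_signatures = true_signatures, exposures = exposures,
              germline_site_count = as.integer(germline_site_count),
              maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
              dbsnp_rate_common = dbsnp_rate_common,
              dbsnp_rate_rare = dbsnp_rate_rare,
              cosmic_rate = cosmic_rate,
              predictor_damaging_rate = predictor_damaging_rate,
              predictor_missing_rate = predictor_missing_rate,
              segdup_rate = segdup_rate, mean_depth = mean_depth,
              low_depth_fraction = low_depth_fraction,
              low_depth_mean = low_depth_mean,
              planted_smg = planted_smg,
              planted_susceptibility = planted_susceptibility,
              planted_cnv = planted_cnv, cnv_noise_sd = cnv_noise_sd)
  class(cfg) <- "wgsmut_sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `wgsmut_sim_config` list.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 1L)
  if (any(cfg$chrom_lengths <= 0)) stop("chrom_lengths must be positive")
  probs <- c(cfg$region_mix, cfg$indel_fraction, cfg$cosmic_rate,
             cfg$dbsnp_rate_common, cfg$dbsnp_rate_rare,
             cfg$predictor_damaging_rate, cfg$predictor_missing_rate,
             cfg$segdup_rate, cfg$low_depth_fraction,
             cfg$planted_smg$prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0,1]")
  if (!is.null(cfg$planted_susceptibility)) {
    cf <- cfg$planted_susceptibility$carrier_fraction
    if (cf < 0 || cf > 1) stop("carrier fraction outside [0,1]")
  }
  if (abs(sum(cfg$region_mix) - 1) > 1e-8) {
    stop("region_mix must sum to 1")
  }
  ex <- cfg$exposures
  if (nrow(ex) != cfg$n_samples || any(abs(rowSums(ex) - 1) > 1e-8) ||
      any(ex < 0)) {
    stop("exposures must be n_samples x K, nonnegative, rows summing to 1")
  }
  sig <- cfg$true_signatures
  if (nrow(sig) != 96L || any(sig < 0) ||
      any(abs(colSums(sig) - 1) > 1e-8)) {
    stop("true_signatures must be 96 x K column-stochastic")
  }
  pc <- cfg$planted_cnv
  if (!is.null(pc) && nrow(pc) > 1L) {
    gr <- GenomicRanges::GRanges(pc$chrom, IRanges::IRanges(pc$start,
                                                            pc$end))
    ov <- GenomicRanges::findOverlaps(gr, gr)
    ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
    if (any(pc$direction[S4Vectors::queryHits(ov)] !=
            pc$direction[S4Vectors::subjectHits(ov)])) {
      stop("planted CNV regions of opposite direction overlap")
    }
  }
  if (!is.null(pc)) {
    bad <- !(pc$chrom %in% names(cfg$chrom_lengths)) |
      pc$end > cfg$chrom_lengths[pc$chrom]
    if (any(bad)) stop("planted CNV region outside chrom_lengths")
  }
  cfg
}

#' Simulate a reference genome and gene models
#'
#' Each chromosome is i.i.d. uniform A/C/G/T (uniform base composition:
#' the spectrum machinery needs every trinucleotide context available, not
#' compositional realism). Genes are multi-exon, non-overlapping, placed
#' uniformly with a 2 kb buffer, random strand, total exonic length padded
#' to a multiple of 3 so each gene is a clean open reading frame.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()] object.
#' @return List with `reference` (named [Biostrings::DNAStringSet]) and
#'   `genes` (gene-model tibble).
#' @export
simulate_reference <- function(cfg) {
  set.seed(cfg$seed + 11L)
  seqs <- vapply(cfg$chrom_lengths, function(len) {
    paste(sample(.BASES, len, replace = TRUE), collapse = "")
  }, character(1))
  reference <- Biostrings::DNAStringSet(seqs)
  names(reference) <- names(cfg$chrom_lengths)

  placed <- list()
  occ <- data.frame(chrom = character(), start = integer(),
                    end = integer())
  buffer <- 2000L
  chrom_prob <- cfg$chrom_lengths / sum(cfg$chrom_lengths)
  for (i in seq_len(cfg$n_genes)) {
    ok <- FALSE
    for (try in 1:200) {
      chrom <- sample(names(cfg$chrom_lengths), 1L, prob = chrom_prob)
      n_exon <- sample(3:5, 1L)
      exon_len <- sample(120:240, n_exon, replace = TRUE)
      pad <- (3L - sum(exon_len) %% 3L) %% 3L
      exon_len[n_exon] <- exon_len[n_exon] + pad
      intron_len <- sample(200:600, n_exon - 1L, replace = TRUE)
      span <- sum(exon_len) + sum(intron_len)
      max_start <- cfg$chrom_lengths[[chrom]] - span - buffer
      if (max_start <= buffer) next
      start <- sample(seq.int(buffer, max_start), 1L)
      c_start <- start - buffer
      c_end <- start + span + buffer
      clash <- occ$chrom == chrom & occ$start <= c_end & occ$end >= c_start
      if (any(clash)) next
      occ <- rbind(occ, data.frame(chrom = chrom, start = c_start,
                                   end = c_end))
      starts <- start + cumsum(c(0L, head(exon_len, -1L) +
                                   intron_len))
      placed[[i]] <- tibble::tibble(
        gene = sprintf("G%03d", i), chrom = chrom,
        start = as.integer(starts),
        end = as.integer(starts + exon_len - 1L),
        strand = sample(c("+", "-"), 1L), coding_frame_offset = 0L)
      ok <- TRUE
      break
    }
    if (!ok) stop("configuration error: could not place ", cfg$n_genes,
                  " genes in the configured genome")
  }
  genes <- do.call(rbind, placed)
  validate_gene_models(genes)
  list(reference = reference, genes = genes)
}

# ---- context/region site index -----------------------------------------

# Encode each position of the genome by coarse region (0 intergenic,
# 1 intronic, 2 exonic) and trinucleotide context code (16*c5 + 4*ref + c3,
# bases coded A=0 C=1 G=2 T=3). Returns position pools (global coordinates)
# per region*64 + ctx key, plus chromosome offsets for decoding.
.site_index <- function(reference, genes) {
  chroms <- names(reference)
  lens <- vapply(chroms, function(ch) length(reference[[ch]]), integer(1))
  offsets <- cumsum(c(0, as.numeric(lens)))[seq_along(chroms)]
  names(offsets) <- chroms
  keys <- vector("list", length(chroms))
  globs <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    code <- match(strsplit(as.character(reference[[ch]]), "",
                           fixed = TRUE)[[1]], .BASES) - 1L
    n <- length(code)
    region <- integer(n)
    if (!is.null(genes) && nrow(genes) > 0L) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      for (gene in unique(g$gene)) {
        gg <- g[g$gene == gene, ]
        region[min(gg$start):max(gg$end)] <- 1L
      }
      for (j in seq_len(nrow(g))) region[g$start[j]:g$end[j]] <- 2L
    }
    p <- 2:(n - 1L)
    ctx <- 16L * code[p - 1L] + 4L * code[p] + code[p + 1L]
    keys[[i]] <- region[p] * 64L + ctx
    globs[[i]] <- offsets[i] + p
  }
  key_all <- unlist(keys, use.names = FALSE)
  glob_all <- unlist(globs, use.names = FALSE)
  pools <- split(glob_all, key_all)
  list(pools = pools, offsets = offsets, chroms = chroms, lens = lens)
}

.decode_global <- function(glob, index) {
  i <- findInterval(glob, c(index$offsets, sum(index$lens) + 1))
  list(chrom = index$chroms[i], pos = as.integer(glob - index$offsets[i]))
}

# Channel k (1..96) -> ctx key codes on pyrimidine and purine strands,
# plus ref/alt characters for each strand.
.channel_codes <- function() {
  classes <- substitution_classes()
  out <- vector("list", 96L)
  k <- 0L
  for (cl in classes) {
    pyr_ref <- substr(cl, 1L, 1L)
    pyr_alt <- substr(cl, 3L, 3L)
    for (f5 in .BASES) {
      for (f3 in .BASES) {
        k <- k + 1L
        c5 <- match(f5, .BASES) - 1L
        c3 <- match(f3, .BASES) - 1L
        cr <- match(pyr_ref, .BASES) - 1L
        pyr_code <- 16L * c5 + 4L * cr + c3
        pur_code <- 16L * (3L - c3) + 4L * (3L - cr) + (3L - c5)
        out[[k]] <- list(pyr = pyr_code, pur = pur_code,
                         pyr_ref = pyr_ref, pyr_alt = pyr_alt,
                         pur_ref = .COMPLEMENT[[pyr_ref]],
                         pur_alt = .COMPLEMENT[[pyr_alt]])
      }
    }
  }
  out
}

#' Simulate somatic variants under a signature mixture
#'
#' Per sample, the SNV count is Poisson with the configured burden
#' (hypermutators multiplied up); each SNV's 96-channel is drawn from the
#' sample's signature mixture, its coarse region (exonic / intronic /
#' intergenic) from `region_mix`, and its genomic site uniformly among
#' positions of that region whose trinucleotide context matches the
#' channel. Half the SNVs are emitted in purine-strand representation to
#' exercise pyrimidine collapsing downstream. Indels (lengths 1-6 uniform,
#' so 4/6 shift the frame) are added at `indel_fraction` of the SNV count,
#' and the planted SMG receives one qualifying exonic mutation per carrier
#' sample. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()] object.
#' @param reference,genes Output of [simulate_reference()].
#' @return List with `variants` (cohort tibble) and `ground_truth` (true
#'   signatures, exposures, per-sample SNV counts, SMG carrier samples).
#' @export
simulate_somatic <- function(cfg, reference, genes) {
  set.seed(cfg$seed + 22L)
  index <- .site_index(reference, genes)
  chr_cache <- as.list(as.character(reference))
  codes <- .channel_codes()
  region_code <- c(exonic = 2L, intronic = 1L, intergenic = 0L)
  burdens <- rep(cfg$somatic_burden, cfg$n_samples)
  burdens[cfg$hypermutator_samples] <-
    burdens[cfg$hypermutator_samples] * cfg$hypermutator_factor
  mix <- cfg$true_signatures %*% t(cfg$exposures)  # 96 x S

  all_rows <- vector("list", cfg$n_samples)
  smg_carriers <- character(0)
  for (s in seq_len(cfg$n_samples)) {
    sid <- cfg$sample_ids[s]
    n <- rpois(1L, burdens[s])
    rows <- NULL
    if (n > 0L) {
      ch <- sample.int(96L, n, replace = TRUE, prob = mix[, s])
      reg <- sample(region_code, n, replace = TRUE,
                    prob = cfg$region_mix[names(region_code)])
      pyr_strand <- runif(n) < 0.5
      ctx <- integer(n)
      refc <- altc <- character(n)
      for (u in unique(ch)) {
        cc <- codes[[u]]
        i <- which(ch == u)
        ip <- i[pyr_strand[i]]; iq <- i[!pyr_strand[i]]
        ctx[ip] <- cc$pyr; refc[ip] <- cc$pyr_ref; altc[ip] <- cc$pyr_alt
        ctx[iq] <- cc$pur; refc[iq] <- cc$pur_ref; altc[iq] <- cc$pur_alt
      }
      key <- as.character(reg * 64L + ctx)
      glob <- numeric(n)
      for (kk in unique(key)) {
        i <- which(key == kk)
        pool <- index$pools[[kk]]
        if (is.null(pool) || length(pool) < length(i)) {
          stop("generation error: required trinucleotide context ",
               "unavailable in reference (key ", kk, ")")
        }
        glob[i] <- sample(pool, length(i))
      }
      dec <- .decode_global(glob, index)
      rows <- tibble::tibble(sample_id = sid, chrom = dec$chrom,
                             pos = dec$pos, end = dec$pos, ref = refc,
                             alt = altc, variant_class = "SNV")
    }
    # indels
    n_ind <- if (is.null(rows)) 0L else round(cfg$indel_fraction * n)
    if (n_ind > 0L) {
      reg <- sample(region_code, n_ind, replace = TRUE,
                    prob = cfg$region_mix[names(region_code)])
      lens <- sample(1:6, n_ind, replace = TRUE)
      is_ins <- runif(n_ind) < 0.5
      glob <- numeric(n_ind)
      for (rg in unique(reg)) {
        i <- which(reg == rg)
        pool_keys <- as.character(rg * 64L + 0:63)
        pool <- unlist(index$pools[intersect(pool_keys,
                                             names(index$pools))],
                       use.names = FALSE)
        glob[i] <- sample(pool, length(i))
      }
      dec <- .decode_global(glob, index)
      chrom_len <- index$lens[dec$chrom]
      keep <- which(dec$pos + lens < chrom_len)  # room for deleted bases
      ch <- dec$chrom[keep]; p <- dec$pos[keep]; L <- lens[keep]
      ins <- is_ins[keep]
      anchor <- del_seq <- character(length(keep))
      for (cc in unique(ch)) {
        i <- which(ch == cc)
        seq_str <- chr_cache[[cc]]
        anchor[i] <- substring(seq_str, p[i], p[i])
        anchor_del <- i[!ins[i]]
        if (length(anchor_del) > 0L) {
          del_seq[anchor_del] <- substring(seq_str, p[anchor_del],
                                           p[anchor_del] + L[anchor_del])
        }
      }
      ins_seq <- vapply(L, function(l) {
        paste(sample(.BASES, l, replace = TRUE), collapse = "")
      }, character(1))
      irows <- tibble::tibble(
        sample_id = sid, chrom = ch, pos = p,
        end = ifelse(ins, p, p + L),
        ref = ifelse(ins, anchor, del_seq),
        alt = ifelse(ins, paste0(anchor, ins_seq), anchor),
        variant_class = ifelse(ins, "insertion", "deletion"))
      rows <- rbind(rows, irows)
    }
    # planted SMG mutation
    if (!is.null(cfg$planted_smg) &&
        runif(1) < cfg$planted_smg$prob) {
      smg_carriers <- c(smg_carriers, sid)
      rows <- rbind(rows, .plant_coding_snv(cfg$planted_smg$gene, sid,
                                            reference, genes))
    }
    all_rows[[s]] <- rows
  }
  variants <- do.call(rbind, all_rows)
  variants$genotype <- "het"
  variants$depth <- rpois(nrow(variants), cfg$mean_depth)
  variants$origin <- "somatic"
  variants <- variants[order(variants$sample_id, variants$chrom,
                             variants$pos), ]
  list(variants = variants,
       ground_truth = list(signatures = cfg$true_signatures,
                           exposures = cfg$exposures,
                           burdens = burdens,
                           smg_gene = cfg$planted_smg$gene,
                           smg_carriers = smg_carriers))
}

# One nonsynonymous (or otherwise qualifying) SNV at a random coding
# position of `gene`.
.plant_coding_snv <- function(gene, sid, reference, genes) {
  g <- genes[genes$gene == gene, , drop = FALSE]
  if (nrow(g) == 0L) stop("planted gene absent from models: ", gene)
  for (try in 1:50) {
    ex <- g[sample.int(nrow(g), 1L), ]
    pos <- sample(seq.int(ex$start, ex$end), 1L)
    ref <- as.character(Biostrings::subseq(reference[[ex$chrom]], pos,
                                           pos))
    for (alt in sample(setdiff(.BASES, ref))) {
      v <- tibble::tibble(sample_id = sid, chrom = ex$chrom, pos = pos,
                          end = pos, ref = ref, alt = alt,
                          variant_class = "SNV")
      f <- classify_function(v, gene, genes, reference)
      if (f %in% c("nonsynonymous_SNV", "stopgain")) return(v)
    }
  }
  stop("could not place a qualifying coding SNV in ", gene)
}

# Hardy-Weinberg genotype draw: copies ~ Binomial(2, maf).
.hwe_genotypes <- function(maf, n) {
  copies <- rbinom(n, 2L, maf)
  c("hom_ref", "het", "hom_alt")[copies + 1L]
}

#' Simulate annotated germline variants
#'
#' Sites are placed uniformly over the genome with true minor-allele
#' frequencies from a truncated Beta distribution; per-sample genotypes
#' are drawn under Hardy-Weinberg equilibrium. Each site receives noisy
#' per-database population frequencies (1000 Genomes / ExAC / ESP6500),
#' dbSNP and COSMIC membership flags, segmental-duplication flags, and
#' four deleteriousness-predictor calls. The planted susceptibility gene
#' receives a rare (MAF below the filtering-cascade threshold),
#' COSMIC-flagged, damaging-predicted exonic nonsynonymous variant carried
#' by the configured fraction of samples. Only carrier records (het or
#' hom_alt) are emitted; non-carrier samples are implicitly `hom_ref`.
#'
#' @inheritParams simulate_somatic
#' @return List with `records` (annotated per-sample variant tibble),
#'   `sites` (site-level annotation tibble), and `ground_truth` (true MAF
#'   per site, susceptibility gene and carrier set).
#' @export
simulate_germline <- function(cfg, reference, genes) {
  set.seed(cfg$seed + 33L)
  n_sites <- cfg$germline_site_count
  lens <- cfg$chrom_lengths
  glob <- sort(sample.int(sum(lens) - 2L, n_sites)) + 1L
  offsets <- cumsum(c(0, as.numeric(lens)))[seq_along(lens)]
  ci <- findInterval(glob, c(offsets, sum(lens) + 1))
  chrom <- names(lens)[ci]
  pos <- as.integer(glob - offsets[ci])
  ref <- vapply(seq_len(n_sites), function(i) {
    as.character(Biostrings::subseq(reference[[chrom[i]]], pos[i], pos[i]))
  }, character(1))
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L),
                character(1))
  maf <- pmin(pmax(rbeta(n_sites, cfg$maf_shape1, cfg$maf_shape2), 1e-4),
              0.5)

  sites <- tibble::tibble(site_id = seq_len(n_sites), chrom = chrom,
                          pos = pos, end = pos, ref = ref, alt = alt,
                          variant_class = "SNV", true_maf = maf)
  ann <- annotate_variants(
    tibble::tibble(sample_id = "site", chrom = chrom, pos = pos,
                   end = pos, ref = ref, alt = alt,
                   variant_class = "SNV"),
    genes, reference)
  sites$region <- ann$region
  sites$gene <- ann$gene
  sites$func <- ann$func

  noisy <- function() pmin(pmax(maf * exp(rnorm(n_sites, 0, 0.2)), 0), 1)
  sites$pop_freq_1000g <- noisy()
  sites$pop_freq_exac <- noisy()
  sites$pop_freq_esp6500 <- noisy()
  dbsnp_rate <- ifelse(maf >= 0.01, cfg$dbsnp_rate_common,
                       cfg$dbsnp_rate_rare)
  sites$in_dbsnp <- runif(n_sites) < dbsnp_rate
  sites$in_cosmic <- runif(n_sites) < cfg$cosmic_rate
  sites$in_segdup <- runif(n_sites) < cfg$segdup_rate
  draw_pred <- function() {
    x <- ifelse(runif(n_sites) < cfg$predictor_damaging_rate, "damaging",
                "tolerated")
    x[runif(n_sites) < cfg$predictor_missing_rate] <- "missing"
    x
  }
  sites$sift <- draw_pred()
  sites$pp2_hvar <- draw_pred()
  sites$pp2_hdiv <- draw_pred()
  sites$mutation_taster <- draw_pred()

  # planted susceptibility site
  ps <- cfg$planted_susceptibility
  planted_site <- NULL
  carriers <- character(0)
  if (!is.null(ps)) {
    pv <- .plant_coding_snv(ps$gene, "site", reference, genes)
    planted_site <- tibble::tibble(
      site_id = n_sites + 1L, chrom = pv$chrom, pos = pv$pos,
      end = pv$pos, ref = pv$ref, alt = pv$alt, variant_class = "SNV",
      true_maf = 5e-4, region = "exonic", gene = ps$gene,
      func = classify_function(pv, ps$gene, genes, reference),
      pop_freq_1000g = 5e-4, pop_freq_exac = 5e-4,
      pop_freq_esp6500 = 5e-4, in_dbsnp = TRUE, in_cosmic = TRUE,
      in_segdup = FALSE, sift = "damaging", pp2_hvar = "damaging",
      pp2_hdiv = "tolerated", mutation_taster = "damaging")
    sites <- rbind(sites, planted_site)
    n_carrier <- round(ps$carrier_fraction * cfg$n_samples)
    carriers <- sort(sample(cfg$sample_ids, n_carrier))
  }

  # per-sample genotypes under HWE; carrier records only
  recs <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!is.null(planted_site) && sites$site_id[i] == planted_site$site_id) {
      if (length(carriers) == 0L) next
      n_hom <- round(ps$hom_fraction * length(carriers))
      gt <- rep("het", length(carriers))
      if (n_hom > 0L) gt[sample.int(length(carriers), n_hom)] <- "hom_alt"
      who <- carriers
    } else {
      gt_all <- .hwe_genotypes(sites$true_maf[i], cfg$n_samples)
      carry <- gt_all != "hom_ref"
      if (!any(carry)) next
      who <- cfg$sample_ids[carry]
      gt <- gt_all[carry]
    }
    recs[[i]] <- tibble::tibble(sample_id = who, site_id = sites$site_id[i],
                                genotype = gt)
  }
  recs <- do.call(rbind, recs)
  records <- cbind(recs[c("sample_id", "site_id")],
                   sites[match(recs$site_id, sites$site_id),
                         setdiff(names(sites), "site_id")],
                   recs["genotype"])
  records <- tibble::as_tibble(records)
  n_rec <- nrow(records)
  low <- runif(n_rec) < cfg$low_depth_fraction
  if (!is.null(planted_site)) {
    # the planted susceptibility variant is a designed pass-through;
    # it is always well covered
    low[records$site_id == planted_site$site_id] <- FALSE
  }
  records$depth <- ifelse(low, rpois(n_rec, cfg$low_depth_mean),
                          rpois(n_rec, cfg$mean_depth))
  records$origin <- "germline"
  records <- records[order(records$sample_id, records$chrom,
                           records$pos), ]
  list(records = records, sites = sites,
       ground_truth = list(true_maf = sites$true_maf,
                           susceptibility_gene = ps$gene %||% NA_character_,
                           carriers = carriers))
}

#' Simulate per-sample copy-number segment tables
#'
#' Background segments partition each chromosome at random breakpoints
#' with log2 ratios ~ Normal(0, `cnv_noise_sd`). Each planted recurrent
#' region is present in a `penetrance` fraction of samples at its
#' configured signed amplitude (background noise added on top elsewhere,
#' the planted segment itself carries the exact amplitude).
#'
#' @param cfg A [sim_config()] object.
#' @return List with `segments` (tibble: `sample_id`, `chrom`, `start`,
#'   `end`, `log2_ratio`) and `ground_truth` (planted regions and their
#'   carrier samples).
#' @export
simulate_cnv <- function(cfg) {
  set.seed(cfg$seed + 44L)
  pc <- cfg$planted_cnv
  carriers <- list()
  if (!is.null(pc) && nrow(pc) > 0L) {
    for (r in seq_len(nrow(pc))) {
      carriers[[r]] <- cfg$sample_ids[runif(cfg$n_samples) <=
                                        pc$penetrance[r]]
    }
  }
  all_segs <- vector("list", cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    sid <- cfg$sample_ids[s]
    segs <- list()
    for (ch in names(cfg$chrom_lengths)) {
      len <- cfg$chrom_lengths[[ch]]
      k <- 1L + rpois(1L, 3L)
      bp <- sort(sample.int(len - 1L, k))
      starts <- c(1L, bp + 1L)
      ends <- c(bp, len)
      segs[[ch]] <- tibble::tibble(
        sample_id = sid, chrom = ch, start = starts, end = ends,
        log2_ratio = rnorm(length(starts), 0, cfg$cnv_noise_sd))
    }
    segs <- do.call(rbind, segs)
    if (!is.null(pc) && nrow(pc) > 0L) {
      for (r in seq_len(nrow(pc))) {
        if (!sid %in% carriers[[r]]) next
        segs <- .overlay_segment(segs, pc$chrom[r], pc$start[r], pc$end[r],
                                 pc$direction[r] * pc$amplitude[r])
      }
    }
    all_segs[[s]] <- segs
  }
  segments <- do.call(rbind, all_segs)
  gt <- if (is.null(pc)) NULL else {
    pc$carriers <- carriers
    pc
  }
  list(segments = segments, ground_truth = list(planted = gt))
}

# Replace [start, end] on `chrom` of one sample's segment set with a
# single segment at log2 = value, clipping/splitting background segments.
.overlay_segment <- function(segs, chrom, start, end, value) {
  on_chr <- segs$chrom == chrom
  keep <- segs[!on_chr, , drop = FALSE]
  cs <- segs[on_chr, , drop = FALSE]
  pieces <- list()
  for (i in seq_len(nrow(cs))) {
    s0 <- cs$start[i]; e0 <- cs$end[i]
    if (e0 < start || s0 > end) {
      pieces[[length(pieces) + 1L]] <- cs[i, ]
      next
    }
    if (s0 < start) {
      left <- cs[i, ]; left$end <- start - 1L
      pieces[[length(pieces) + 1L]] <- left
    }
    if (e0 > end) {
      right <- cs[i, ]; right$start <- end + 1L
      pieces[[length(pieces) + 1L]] <- right
    }
  }
  planted <- cs[1L, ]
  planted$start <- as.integer(start); planted$end <- as.integer(end)
  planted$log2_ratio <- value
  out <- rbind(keep, do.call(rbind, pieces), planted)
  out[order(out$chrom, out$start), ]
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_reference()], [simulate_somatic()],
#' [simulate_germline()], and [simulate_cnv()] under one master seed and
#' returns all outputs plus ground truth. Because each generator derives
#' its own child seed, the pieces can also be regenerated independently.
#'
#' @param cfg A [sim_config()] object.
#' @return List with `reference`, `genes`, `somatic`, `germline`, `cnv`,
#'   and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  refgen <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, refgen$reference, refgen$genes)
  germ <- simulate_germline(cfg, refgen$reference, refgen$genes)
  cnv <- simulate_cnv(cfg)
  list(reference = refgen$reference, genes = refgen$genes, somatic = som,
       germline = germ, cnv = cnv, config = cfg)
}

#' Write a simulated cohort to disk
#'
#' Emits FASTA (reference), BED6 (gene models), per-sample somatic VCFs, a
#' multi-sample germline VCF, the annotated germline TSV, a CNV segment
#' TSV, and a JSON ground-truth manifest. All text, UTF-8, LF endings.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$reference,
                              file.path(dir, "reference.fasta"))
  write_gene_bed(sim$genes, file.path(dir, "genes.bed"))
  cl <- sim$config$chrom_lengths
  som_dir <- file.path(dir, "somatic")
  dir.create(som_dir, showWarnings = FALSE)
  for (sid in unique(sim$somatic$variants$sample_id)) {
    v <- sim$somatic$variants[sim$somatic$variants$sample_id == sid, ]
    write_vcf(v, file.path(som_dir, paste0(sid, ".vcf")),
              contig_lengths = cl)
  }
  write_vcf(sim$germline$records, file.path(dir, "germline.vcf"),
            contig_lengths = cl, sample_order = sim$config$sample_ids)
  write_annotation_tsv(sim$germline$records,
                       file.path(dir, "germline_annotated.tsv"))
  write_segments_tsv(sim$cnv$segments, file.path(dir, "cnv_segments.tsv"))
  gt <- list(
    exposures = unname(sim$config$exposures),
    smg_gene = sim$somatic$ground_truth$smg_gene,
    smg_carriers = sim$somatic$ground_truth$smg_carriers,
    susceptibility_gene = sim$germline$ground_truth$susceptibility_gene,
    susceptibility_carriers = sim$germline$ground_truth$carriers,
    cnv_planted = if (!is.null(sim$cnv$ground_truth$planted)) {
      p <- sim$cnv$ground_truth$planted
      lapply(seq_len(nrow(p)), function(r) {
        list(chrom = p$chrom[r], start = p$start[r], end = p$end[r],
             direction = p$direction[r], penetrance = p$penetrance[r],
             amplitude = p$amplitude[r], carriers = p$carriers[[r]])
      })
    })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
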