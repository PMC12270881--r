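#' Read variant calls from a VCF file
#'
#' Parses a VCF 4.x file into a flat variant table, one row per
#' sample-allele. Multi-allelic sites are split into bi-allelic records;
#' each split record carries the sample genotype restricted to that allele
#' (two copies of the allele give `hom_alt`, one gives `het`, none gives
#' `hom_ref`; any missing allele call gives `missing`). Records are sorted
#' by (chrom, pos).
#'
#' Coordinates are 1-based inclusive (`end = pos + nchar(ref) - 1`),
#' following VCF convention.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param origin `"somatic"` or `"germline"`; stamped on every record.
#' @param drop_hom_ref Drop sample-allele records whose restricted genotype
#'   is `hom_ref` (default `FALSE`; per-sample somatic VCFs rarely contain
#'   any, multi-sample germline VCFs contain many).
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `end`, `ref`,
#'   `alt`, `variant_class` (`SNV`/`insertion`/`deletion`), `genotype`
#'   (`hom_ref`/`het`/`hom_alt`/`missing`), `depth`, `origin`.
#' @export
read_vcf <- function(path, origin = c("somatic", "germline"),
                     drop_hom_ref = FALSE) {
  origin <- match.arg(origin)
  .validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0L) {
    return(.empty_variants())
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  dp_mat <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  samples <- colnames(gt_mat)

  out <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    recs <- .split_sample_records(fix, gt_mat[, j], dp_mat[, j], samples[j])
    out[[j]] <- recs
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) return(.empty_variants())
  res$origin <- origin
  if (drop_hom_ref) res <- res[res$genotype != "hom_ref", , drop = FALSE]
  res <- res[order(res$chrom, res$pos, res$alt, res$sample_id), ,
             drop = FALSE]
  tibble::as_tibble(res)
}

.empty_variants <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 pos = integer(), end = integer(), ref = character(),
                 alt = character(), variant_class = character(),
                 genotype = character(), depth = integer(),
                 origin = character())
}

# Light structural validation so malformed lines fail with a line number
# (vcfR is permissive and would silently mangle them).
.validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 10L) {
      stop("malformed VCF line ", i, ": expected >= 10 tab-separated fields ",
           "(FORMAT plus at least one sample), got ", length(fields))
    }
    if (is.na(suppressWarnings(as.integer(fields[2])))) {
      stop("malformed VCF line ", i, ": POS is not an integer")
    }
  }
  invisible(TRUE)
}

.split_sample_records <- function(fix, gt, dp, sample_id) {
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_idx <- rep.int(seq_len(nrow(fix)), n_alt)
  allele_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  ref <- fix$REF[row_idx]
  alt <- unlist(alts, use.names = FALSE)
  gt_rep <- gt[row_idx]
  geno <- .genotype_for_allele(gt_rep, allele_idx)
  pos <- as.integer(fix$POS[row_idx])
  vc <- variant_class(ref, alt)
  keep <- !is.na(vc)
  if (any(!keep)) {
    warning("dropping ", sum(!keep),
            " record(s) that are neither SNV, insertion, nor deletion")
  }
  data.frame(sample_id = sample_id, chrom = fix$CHROM[row_idx],
             pos = pos, end = pos + nchar(ref) - 1L, ref = ref, alt = alt,
             variant_class = vc, genotype = geno,
             depth = as.integer(dp[row_idx]),
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

.genotype_for_allele <- function(gt, allele_idx) {
  vapply(seq_along(gt), function(i) {
    g <- gt[i]
    if (is.na(g)) return("missing")
    codes <- strsplit(g, "[/|]")[[1]]
    if (any(codes == ".")) return("missing")
    n <- sum(codes == as.character(allele_idx[i]))
    c("hom_ref", "het", "hom_alt")[n + 1L]
  }, character(1))
}

#' Classify variants as SNV, insertion, or deletion
#'
#' An SNV has one-base ref and alt; an insertion has a longer alt; a
#' deletion a longer ref. Equal-length multi-base substitutions are
#' unsupported and return `NA`.
#'
#' @param ref,alt Allele strings over A/C/G/T.
#' @return Character vector of `"SNV"`, `"insertion"`, `"deletion"`, or `NA`.
#' @export
variant_class <- function(ref, alt) {
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV",
         ifelse(na > nr, "insertion", ifelse(nr > na, "deletion",
                                             NA_character_)))
}

#' Construct a gene-model table
#'
#' One row per exon. Exons of a gene must be non-overlapping; they are
#' sorted by start. `coding_frame_offset` (0-2) is the number of bases to
#' skip at the coding start before the first complete codon.
#'
#' @param gene Gene symbol (one per exon row).
#' @param chrom,start,end Exon coordinates, 1-based inclusive.
#' @param strand `"+"` or `"-"`.
#' @param coding_frame_offset Integer 0-2 per exon row (constant per gene).
#' @return A tibble of exons with class checks applied.
#' @export
gene_models <- function(gene, chrom, start, end, strand,
                        coding_frame_offset = 0L) {
  g <- tibble::tibble(gene = gene, chrom = chrom, start = as.integer(start),
                      end = as.integer(end), strand = strand,
                      coding_frame_offset = as.integer(coding_frame_offset))
  validate_gene_models(g)
  g[order(g$gene, g$chrom, g$start), ]
}

#' @rdname gene_models
#' @param genes A gene-model tibble to validate.
#' @export
validate_gene_models <- function(genes) {
  stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  if (any(genes$end < genes$start)) stop("exon end < start")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  by_gene <- split(genes, genes$gene)
  for (g in by_gene) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)])) {
      stop("overlapping exons in gene ", g$gene[1])
    }
  }
  invisible(genes)
}

#' Read gene models from a BED6 file
#'
#' BED is 0-based half-open; coordinates are converted to 1-based inclusive
#' here at the reader boundary. Column 4 (name) is the gene symbol, column
#' 5 (score) carries the coding frame offset (0-2), column 6 the strand.
#'
#' @param path BED6 file, one exon per row.
#' @return A gene-model tibble (see [gene_models()]).
#' @export
read_gene_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop("expected BED6 (6 columns), got ", ncol(bed))
  gene_models(gene = bed[[4]], chrom = bed[[1]],
              start = as.integer(bed[[2]]) + 1L, end = as.integer(bed[[3]]),
              strand = bed[[6]], coding_frame_offset = as.integer(bed[[5]]))
}

#' Write gene models to BED6
#'
#' @param genes Gene-model tibble.
#' @param path Output file.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene,
                    genes$coding_frame_offset, genes$strand)
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  writeLines(apply(bed, 1L, paste, collapse = "\t"), con, sep = "\n")
  invisible(path)
}

#' Total exonic footprint per gene
#'
#' @param genes Gene-model tibble.
#' @return Named integer vector of summed exon lengths (bp).
#' @export
gene_footprints <- function(genes) {
  w <- genes$end - genes$start + 1L
  vapply(split(w, genes$gene), sum, integer(1))
}

.genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         strand = genes$strand, gene = genes$gene)
}

#' Classify the genomic region of variants
#'
#' Assigns each variant (by its start position) one region label with the
#' deterministic precedence exonic > splicing > intronic >
#' upstream/downstream > intergenic. "Splicing" is an intronic position
#' within `splice_window` bp of an exon boundary. Upstream/downstream are
#' strand-aware windows of `near_gene_window` bp flanking the gene span.
#' Gene models here are protein-coding, so the ncRNA and UTR labels of the
#' annotation vocabulary are never produced by this classifier.
#'
#' @param variants Variant tibble (needs `chrom`, `pos`).
#' @param genes Gene-model tibble.
#' @param splice_window Intronic bases next to an exon boundary called
#'   splicing (default 2, the conventional annotation window).
#' @param near_gene_window Flanking window for upstream/downstream
#'   (default 1000 bp).
#' @return Character vector of region labels, one per variant.
#' @export
classify_region <- function(variants, genes, splice_window = 2L,
                            near_gene_window = 1000L) {
  n <- nrow(variants)
  if (n == 0L) return(character(0))
  out <- rep("intergenic", n)
  if (is.null(genes) || nrow(genes) == 0L) return(out)

  pos_gr <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos,
                                                    variants$pos))
  exon_gr <- .genes_to_granges(genes)

  span_df <- do.call(rbind, lapply(split(genes, genes$gene), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               strand = g$strand[1], stringsAsFactors = FALSE)
  }))
  span_gr <- GenomicRanges::GRanges(span_df$chrom,
                                    IRanges::IRanges(span_df$start,
                                                     span_df$end),
                                    strand = span_df$strand)

  intron_gr <- GenomicRanges::setdiff(
    GenomicRanges::reduce(.unstranded(span_gr)),
    GenomicRanges::reduce(.unstranded(exon_gr)))

  # splice region: intron bases within splice_window of an exon edge
  edge_gr <- c(
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$start - splice_window,
                                            genes$start - 1L)),
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$end + 1L,
                                            genes$end + splice_window)))
  splice_gr <- GenomicRanges::intersect(GenomicRanges::reduce(edge_gr),
                                        intron_gr)

  up_gr <- GenomicRanges::flank(span_gr, near_gene_window, start = TRUE)
  down_gr <- GenomicRanges::flank(span_gr, near_gene_window, start = FALSE)

  hit <- function(subject) {
    IRanges::overlapsAny(pos_gr, .unstranded(subject), ignore.strand = TRUE)
  }
  is_down <- hit(down_gr)
  out[is_down] <- "downstream"
  is_up <- hit(up_gr)
  out[is_up] <- "upstream"          # upstream wins ties with downstream
  is_intron <- hit(intron_gr)
  out[is_intron] <- "intronic"
  is_splice <- hit(splice_gr)
  out[is_splice] <- "splicing"
  is_exon <- hit(exon_gr)
  out[is_exon] <- "exonic"
  out
}

.unstranded <- function(gr) {
  BiocGenerics::strand(gr) <- "*"
  gr
}

# Spliced coding sequence of one gene plus a map from genomic position to
# CDS coordinate (1-based, before frame offset).
.gene_cds <- function(gene_df, reference) {
  gene_df <- gene_df[order(gene_df$start), ]
  chrom <- gene_df$chrom[1]
  seqs <- vapply(seq_len(nrow(gene_df)), function(i) {
    as.character(Biostrings::subseq(reference[[chrom]], gene_df$start[i],
                                    gene_df$end[i]))
  }, character(1))
  cds_plus <- paste(seqs, collapse = "")
  widths <- gene_df$end - gene_df$start + 1L
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  strand <- gene_df$strand[1]
  cds <- if (strand == "+") cds_plus else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_plus)))
  }
  list(cds = cds, strand = strand, exon_starts = gene_df$start,
       exon_ends = gene_df$end, exon_offsets = offsets,
       total = sum(widths),
       frame_offset = gene_df$coding_frame_offset[1] %||% 0L)
}

.cds_position <- function(cds_info, pos) {
  i <- which(pos >= cds_info$exon_starts & pos <= cds_info$exon_ends)
  if (length(i) != 1L) return(NA_integer_)
  plus_pos <- cds_info$exon_offsets[i] + (pos - cds_info$exon_starts[i]) + 1L
  if (cds_info$strand == "+") plus_pos else cds_info$total - plus_pos + 1L
}

#' Classify the coding consequence of exonic variants
#'
#' SNVs are classified by translating the affected codon before and after
#' the change (`synonymous_SNV`, `nonsynonymous_SNV`, `stopgain`,
#' `stoploss`); indels by the length rule: an inserted/deleted length that
#' is not a multiple of 3 shifts the reading frame
#' (`frameshift_insertion`/`frameshift_deletion`), otherwise
#' `nonframeshift_insertion`/`nonframeshift_deletion`. Variants falling in
#' an incomplete trailing codon return `"unknown"`.
#'
#' @param variants Variant tibble rows, all exonic within `gene`.
#' @param gene Single gene symbol present in `genes`.
#' @param genes Gene-model tibble.
#' @param reference A named [Biostrings::DNAStringSet] keyed by chromosome.
#' @return Character vector of function labels.
#' @export
classify_function <- function(variants, gene, genes, reference) {
  gene_df <- genes[genes$gene == gene, , drop = FALSE]
  if (nrow(gene_df) == 0L) stop("gene not found in models: ", gene)
  info <- .gene_cds(gene_df, reference)
  vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    vc <- v$variant_class
    if (vc == "insertion") {
      len <- nchar(v$alt) - nchar(v$ref)
      return(if (len %% 3L != 0L) "frameshift_insertion"
             else "nonframeshift_insertion")
    }
    if (vc == "deletion") {
      len <- nchar(v$ref) - nchar(v$alt)
      return(if (len %% 3L != 0L) "frameshift_deletion"
             else "nonframeshift_deletion")
    }
    cds_pos <- .cds_position(info, v$pos)
    if (is.na(cds_pos)) {
      stop("variant at ", v$chrom, ":", v$pos,
           " is not inside a coding exon of ", gene)
    }
    k <- cds_pos - info$frame_offset
    if (k < 1L) return("unknown")
    codon_idx <- (k - 1L) %/% 3L
    within <- (k - 1L) %% 3L
    codon_start <- info$frame_offset + codon_idx * 3L + 1L
    if (codon_start + 2L > info$total) return("unknown")
    codon <- substr(info$cds, codon_start, codon_start + 2L)
    alt_base <- if (info$strand == "+") v$alt else .COMPLEMENT[[v$alt]]
    new_codon <- codon
    substr(new_codon, within + 1L, within + 1L) <- alt_base
    aa_old <- Biostrings::GENETIC_CODE[[codon]]
    aa_new <- Biostrings::GENETIC_CODE[[new_codon]]
    if (aa_old == aa_new) "synonymous_SNV"
    else if (aa_new == "*") "stopgain"
    else if (aa_old == "*") "stoploss"
    else "nonsynonymous_SNV"
  }, character(1))
}

#' Annotate variants with region, gene, and coding consequence
#'
#' Runs [classify_region()] over the cohort, assigns the containing gene to
#' exonic/splicing/intronic variants, and computes [classify_function()]
#' labels for exonic variants. Non-exonic variants get function
#' `"unknown"`, consistent with the rule that functional classes are
#' defined only inside coding sequence.
#'
#' @inheritParams classify_region
#' @param reference Named [Biostrings::DNAStringSet].
#' @return The input tibble with columns `region`, `gene`, `func` added.
#' @export
annotate_variants <- function(variants, genes, reference,
                              splice_window = 2L, near_gene_window = 1000L) {
  variants$region <- classify_region(variants, genes, splice_window,
                                     near_gene_window)
  variants$gene <- NA_character_
  variants$func <- "unknown"
  if (is.null(genes) || nrow(genes) == 0L || nrow(variants) == 0L) {
    return(variants)
  }
  pos_gr <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos,
                                                    variants$pos))
  span_list <- lapply(split(genes, genes$gene), function(g) {
    data.frame(gene = g$gene[1], chrom = g$chrom[1], start = min(g$start),
               end = max(g$end), stringsAsFactors = FALSE)
  })
  span_df <- do.call(rbind, span_list)
  span_gr <- GenomicRanges::GRanges(span_df$chrom,
                                    IRanges::IRanges(span_df$start,
                                                     span_df$end))
  ov <- GenomicRanges::findOverlaps(pos_gr, span_gr, select = "first")
  in_gene <- !is.na(ov) &
    variants$region %in% c("exonic", "splicing", "intronic")
  variants$gene[in_gene] <- span_df$gene[ov[in_gene]]

  exonic <- which(variants$region == "exonic" & !is.na(variants$gene))
  for (g in unique(variants$gene[exonic])) {
    idx <- exonic[variants$gene[exonic] == g]
    variants$func[idx] <- classify_function(variants[idx, ], g, genes,
                                            reference)
  }
  variants
}

# ---- annotation table dialect ------------------------------------------

.ANNOTATION_COLS <- c("sample_id", "chrom", "pos", "end", "ref", "alt",
                      "variant_class", "genotype", "depth", "origin",
                      "region", "gene", "func",
                      "pop_freq_1000g", "pop_freq_exac", "pop_freq_esp6500",
                      "in_dbsnp", "in_cosmic", "in_segdup",
                      "sift", "pp2_hvar", "pp2_hdiv", "mutation_taster")

#' Read/write the annotated-variant TSV dialect
#'
#' A tab-separated table with a versioned header line
#' (`#wgsmut_annotation_v1`) and a fixed column set covering variant
#' identity, genotype, region/function classes, population frequencies,
#' database flags, and deleteriousness-predictor calls. Missing values are
#' written as `NA`; files are UTF-8 with LF line endings. The writer/reader
#' pair round-trips all fields exactly.
#'
#' @param x Annotated-variant tibble.
#' @param path File path.
#' @return `read_annotation_tsv` returns the tibble; `write_annotation_tsv`
#'   returns `path` invisibly.
#' @export
write_annotation_tsv <- function(x, path) {
  missing_cols <- setdiff(.ANNOTATION_COLS, names(x))
  for (m in missing_cols) x[[m]] <- NA
  x <- x[, .ANNOTATION_COLS]
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#wgsmut_annotation_v1", con, sep = "\n")
  writeLines(paste(.ANNOTATION_COLS, collapse = "\t"), con, sep = "\n")
  if (nrow(x) > 0L) {
    body <- do.call(paste, c(lapply(x, .format_field), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

.format_field <- function(col) {
  if (is.logical(col)) return(ifelse(is.na(col), "NA", ifelse(col, "TRUE",
                                                              "FALSE")))
  if (is.double(col)) {
    return(ifelse(is.na(col), "NA", format(col, digits = 17,
                                           scientific = FALSE, trim = TRUE)))
  }
  out <- as.character(col)
  out[is.na(out)] <- "NA"
  out
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, "#wgsmut_annotation_v1")) {
    stop("not a wgsmut annotation table (missing version header): ", path)
  }
  x <- read.delim(path, skip = 1L, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("pos", "end", "depth")) x[[col]] <- as.integer(x[[col]])
  for (col in c("pop_freq_1000g", "pop_freq_exac", "pop_freq_esp6500")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  for (col in c("in_dbsnp", "in_cosmic", "in_segdup")) {
    x[[col]] <- as.logical(x[[col]])
  }
  tibble::as_tibble(x)
}

#' Write variants to a VCF 4.2 file
#'
#' Emits one bi-allelic record per distinct site/allele with per-sample
#' `GT:DP` fields. Samples absent at a site are written as `0/0` with
#' missing depth. Output is plain text, LF line endings.
#'
#' @param variants Variant tibble (`sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `genotype`, `depth`).
#' @param path Output path.
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @param sample_order Optional character vector fixing sample columns.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL,
                      sample_order = NULL) {
  samples <- sample_order %||% sort(unique(variants$sample_id))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = "\r")
  sites <- !duplicated(key)
  site_df <- variants[sites, c("chrom", "pos", "ref", "alt")]
  ord <- order(site_df$chrom, site_df$pos, site_df$alt)
  site_df <- site_df[ord, ]
  site_key <- paste(site_df$chrom, site_df$pos, site_df$ref, site_df$alt,
                    sep = "\r")
  cell <- matrix("0/0:.", nrow = nrow(site_df), ncol = length(samples),
                 dimnames = list(NULL, samples))
  ri <- match(key, site_key)
  ci <- match(variants$sample_id, samples)
  dp <- ifelse(is.na(variants$depth), ".", as.character(variants$depth))
  cell[cbind(ri, ci)] <- paste0(gt_code[variants$genotype], ":", dp)

  hdr <- c("##fileformat=VCFv4.2",
           "##source=wgsmut",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  body <- if (nrow(site_df) == 0L) character(0) else {
    paste(site_df$chrom, site_df$pos, ".", site_df$ref, site_df$alt,
          ".", "PASS", ".", "GT:DP",
          apply(cell, 1L, paste, collapse = "\t"), sep = "\t")
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}
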