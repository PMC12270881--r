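.SMG_QUALIFYING_FUNCS <- c("nonsynonymous_SNV", "stopgain", "stoploss",
                           "frameshift_insertion", "frameshift_deletion")

# Records that count toward the SMG screen: protein-altering exonic
# changes and splice-site variants.
.smg_qualifying <- function(annotated) {
  (annotated$region == "exonic" &
     annotated$func %in% .SMG_QUALIFYING_FUNCS) |
    annotated$region == "splicing"
}

#' Per-gene qualifying mutation counts
#'
#' Counts, for each gene, the distinct qualifying mutation sites
#' (protein-altering exonic or splicing) and the number of cohort samples
#' carrying at least one. `sample_percent` is `sample_affected /
#' n_samples * 100`, reported at full precision (round for display).
#' Records without a gene assignment are excluded.
#'
#' @param annotated Annotated somatic variant tibble.
#' @param n_samples Cohort size (denominator for `sample_percent`).
#' @return Tibble with `gene`, `muts`, `sample_affected`,
#'   `sample_percent`, plus the cohort-wide `total_muts` (distinct
#'   qualifying sites) as an attribute.
#' @export
gene_counts <- function(annotated, n_samples) {
  q <- annotated[.smg_qualifying(annotated) & !is.na(annotated$gene), ,
                 drop = FALSE]
  site_key <- paste(q$chrom, q$pos, q$ref, q$alt, sep = "\r")
  total_muts <- length(unique(site_key))
  if (nrow(q) == 0L) {
    out <- tibble::tibble(gene = character(), muts = integer(),
                          sample_affected = integer(),
                          sample_percent = numeric())
    attr(out, "total_muts") <- 0L
    return(out)
  }
  by_gene <- split(seq_len(nrow(q)), q$gene)
  out <- tibble::tibble(
    gene = names(by_gene),
    muts = unname(vapply(by_gene, function(i) {
      length(unique(site_key[i]))
    }, integer(1))),
    sample_affected = unname(vapply(by_gene, function(i) {
      length(unique(q$sample_id[i]))
    }, integer(1))))
  out$sample_percent <- out$sample_affected / n_samples * 100
  attr(out, "total_muts") <- total_muts
  out
}

#' One-sided Fisher exact test for gene-level mutation enrichment
#'
#' Tests whether a gene's mutation count exceeds expectation under a
#' footprint-proportional background: the 2x2 table contrasts mutated vs
#' unmutated base pairs inside the gene against the rest of the analyzed
#' footprint, with a one-sided (enrichment) alternative.
#'
#' @param muts_in_gene Qualifying mutation sites in the gene.
#' @param gene_footprint_bp Exonic footprint of the gene (bp).
#' @param total_muts Cohort-wide qualifying mutation sites.
#' @param total_footprint_bp Total analyzed footprint (bp).
#' @return One-sided p-value.
#' @export
fisher_smg <- function(muts_in_gene, gene_footprint_bp, total_muts,
                       total_footprint_bp) {
  tab <- matrix(c(muts_in_gene, gene_footprint_bp - muts_in_gene,
                  total_muts - muts_in_gene,
                  (total_footprint_bp - gene_footprint_bp) -
                    (total_muts - muts_in_gene)),
                nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) {
    stop("negative cell in Fisher table; check counts vs footprints")
  }
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Significantly-mutated-gene screen
#'
#' Combines [gene_counts()] with per-gene [fisher_smg()] p-values under a
#' uniform footprint-proportional background mutation rate, applies a
#' Bonferroni correction over the genes actually tested (those with at
#' least one qualifying mutation), and ranks by ascending p.
#'
#' @param annotated Annotated somatic variant tibble.
#' @param genes Gene-model tibble (for exonic footprints).
#' @param n_samples Cohort size.
#' @param alpha Significance level for the flags (default 0.05).
#' @return Tibble sorted by `p_value`: `gene`, `muts`, `total_muts`,
#'   `sample_affected`, `sample_percent`, `p_value`, `p_bonferroni`,
#'   `significant_raw`, `significant_bonferroni`.
#' @export
smg_screen <- function(annotated, genes, n_samples, alpha = 0.05) {
  counts <- gene_counts(annotated, n_samples)
  total_muts <- attr(counts, "total_muts")
  fp <- gene_footprints(genes)
  total_fp <- sum(fp)
  missing <- setdiff(counts$gene, names(fp))
  if (length(missing) > 0L) {
    warning("records in genes absent from models, excluded: ",
            paste(missing, collapse = ", "))
    counts <- counts[counts$gene %in% names(fp), , drop = FALSE]
  }
  counts$total_muts <- total_muts
  counts$p_value <- vapply(seq_len(nrow(counts)), function(i) {
    fisher_smg(counts$muts[i], fp[[counts$gene[i]]], total_muts, total_fp)
  }, numeric(1))
  n_tested <- nrow(counts)
  counts$p_bonferroni <- pmin(1, counts$p_value * n_tested)
  counts$significant_raw <- counts$p_value < alpha
  counts$significant_bonferroni <- counts$p_bonferroni < alpha
  counts <- counts[order(counts$p_value, counts$gene), ]
  counts[, c("gene", "muts", "total_muts", "sample_affected",
             "sample_percent", "p_value", "p_bonferroni",
             "significant_raw", "significant_bonferroni")]
}

#' Write an SMG screen table as TSV
#'
#' Columns follow the conventional screen layout (Gene, Muts, Total_Muts,
#' Sample_affected, Sample_percent, Pvalue, Pbonferroni); percentages are
#' printed to 2 decimals.
#'
#' @param tab Output of [smg_screen()].
#' @param path Output file.
#' @export
write_smg_tsv <- function(tab, path) {
  out <- data.frame(Gene = tab$gene, Muts = tab$muts,
                    Total_Muts = tab$total_muts,
                    Sample_affected = tab$sample_affected,
                    Sample_percent = sprintf("%.2f%%", tab$sample_percent),
                    Pvalue = format(tab$p_value, digits = 5),
                    Pbonferroni = format(tab$p_bonferroni, digits = 5))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(out, sep = "\t")), con, sep = "\n")
  invisible(path)
}
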