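#' Configuration of the germline susceptibility filtering cascade
#'
#' Five steps, applied in order:
#' 1. depth: keep records with sequencing depth >= `min_depth`;
#' 2. population: remove records whose frequency in any of the three
#'    population databases (1000 Genomes, ExAC, ESP6500) exceeds
#'    `max_pop_freq`; then remove dbSNP members unless they are also in
#'    COSMIC (the COSMIC flag does not override the frequency filter);
#' 3. region: remove records in the excluded region classes (intergenic,
#'    intronic, ncRNA, upstream/downstream, UTR);
#' 4. function: remove synonymous variants and, optionally, records in
#'    segmental-duplication regions;
#' 5. deleteriousness: keep records with at least one damaging call among
#'    SIFT, PolyPhen2 (HVAR/HDIV), and MutationTaster (`any`), or require
#'    all non-missing calls damaging (`all`); missing predictions never
#'    rescue a variant.
#'
#' @param min_depth Minimum read depth (default 10).
#' @param max_pop_freq Population-frequency ceiling (default 0.0014).
#' @param excluded_regions Region labels removed at step 3.
#' @param exclude_segdup Remove segmental-duplication-flagged records at
#'   step 4 (default TRUE).
#' @param deleteriousness_rule `"any"` (default) or `"all"`.
#' @return A list of class `wgsmut_cascade_config`.
#' @export
cascade_config <- function(min_depth = 10L, max_pop_freq = 0.0014,
                           excluded_regions = c("intergenic", "intronic",
                                                "ncRNA_exonic",
                                                "ncRNA_intronic",
                                                "upstream", "downstream",
                                                "UTR5", "UTR3"),
                           exclude_segdup = TRUE,
                           deleteriousness_rule = c("any", "all")) {
  deleteriousness_rule <- match.arg(deleteriousness_rule)
  if (min_depth < 0L) stop("min_depth must be >= 0")
  if (max_pop_freq < 0 || max_pop_freq > 1) {
    stop("max_pop_freq must be in [0,1]")
  }
  structure(list(min_depth = as.integer(min_depth),
                 max_pop_freq = max_pop_freq,
                 excluded_regions = excluded_regions,
                 exclude_segdup = exclude_segdup,
                 deleteriousness_rule = deleteriousness_rule),
            class = "wgsmut_cascade_config")
}

.CASCADE_REQUIRED <- c("depth", "pop_freq_1000g", "pop_freq_exac",
                       "pop_freq_esp6500", "in_dbsnp", "in_cosmic",
                       "in_segdup", "region", "func", "sift", "pp2_hvar",
                       "pp2_hdiv", "mutation_taster")

#' Apply the five-step susceptibility filtering cascade
#'
#' Runs the steps of [cascade_config()] in order on annotated germline
#' records and records the attrition at each step. Missing population
#' frequencies are treated as not exceeding the ceiling; missing predictor
#' calls count as non-damaging.
#'
#' @param records Annotated germline variant tibble (the annotation-TSV
#'   dialect of [read_annotation_tsv()]).
#' @param cfg A [cascade_config()].
#' @return List with `surviving` (tibble) and `trace` (tibble: `step`,
#'   `n_in`, `n_removed`, `n_out`).
#' @export
apply_cascade <- function(records, cfg = cascade_config()) {
  missing_cols <- setdiff(.CASCADE_REQUIRED, names(records))
  if (length(missing_cols) > 0L) {
    stop("records missing required annotation fields: ",
         paste(missing_cols, collapse = ", "))
  }
  steps <- list(
    depth = function(x) {
      !is.na(x$depth) & x$depth >= cfg$min_depth
    },
    population = function(x) {
      freq_hi <- (!is.na(x$pop_freq_1000g) &
                    x$pop_freq_1000g > cfg$max_pop_freq) |
        (!is.na(x$pop_freq_exac) & x$pop_freq_exac > cfg$max_pop_freq) |
        (!is.na(x$pop_freq_esp6500) &
           x$pop_freq_esp6500 > cfg$max_pop_freq)
      dbsnp_drop <- x$in_dbsnp & !x$in_cosmic
      !(freq_hi | dbsnp_drop)
    },
    region = function(x) {
      !(x$region %in% cfg$excluded_regions)
    },
    func = function(x) {
      drop <- x$func == "synonymous_SNV"
      if (cfg$exclude_segdup) drop <- drop | x$in_segdup
      !drop
    },
    deleteriousness = function(x) {
      calls <- cbind(x$sift, x$pp2_hvar, x$pp2_hdiv, x$mutation_taster)
      dmg <- calls == "damaging"
      if (cfg$deleteriousness_rule == "any") {
        rowSums(dmg, na.rm = TRUE) >= 1L
      } else {
        known <- calls != "missing" & !is.na(calls)
        rowSums(known) >= 1L & rowSums(dmg & known) == rowSums(known)
      }
    })
  trace <- tibble::tibble(step = character(), n_in = integer(),
                          n_removed = integer(), n_out = integer())
  x <- records
  for (nm in names(steps)) {
    keep <- steps[[nm]](x)
    trace <- rbind(trace, tibble::tibble(
      step = nm, n_in = nrow(x), n_removed = sum(!keep),
      n_out = sum(keep)))
    x <- x[keep, , drop = FALSE]
  }
  list(surviving = x, trace = trace)
}

#' Samples x genes genotype matrix
#'
#' For every (sample, gene) cell: `hom_alt` if the sample has any
#' surviving homozygous-alternate variant in the gene, else `het` if any
#' heterozygous, else `hom_ref` (severity precedence). Genes are those
#' with at least one surviving variant; all samples in `sample_ids`
#' appear, so non-carriers are explicit `hom_ref` rows.
#'
#' @param surviving Surviving annotated records (need `sample_id`, `gene`,
#'   `genotype`).
#' @param sample_ids Character vector of all cohort samples.
#' @return A character matrix (samples x genes) of class
#'   `wgsmut_genotype_matrix`.
#' @export
genotype_matrix <- function(surviving, sample_ids) {
  x <- surviving[!is.na(surviving$gene) &
                   surviving$genotype %in% c("het", "hom_alt"), ,
                 drop = FALSE]
  genes <- sort(unique(x$gene))
  m <- matrix("hom_ref", length(sample_ids), length(genes),
              dimnames = list(sample_ids, genes))
  if (nrow(x) > 0L) {
    sev <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
    best <- tapply(sev[x$genotype],
                   list(factor(x$sample_id, levels = sample_ids),
                        factor(x$gene, levels = genes)),
                   max)
    best[is.na(best)] <- 0L
    m[] <- names(sev)[best + 1L]
  }
  class(m) <- c("wgsmut_genotype_matrix", class(m))
  m
}

#' Carrier frequency of a gene
#'
#' Percentage of cohort samples typed `het` or `hom_alt` for the gene,
#' reported to 2 decimals.
#'
#' @param m Genotype matrix from [genotype_matrix()] (samples x genes).
#' @param gene Gene symbol (column of `m`).
#' @return Carrier frequency in percent.
#' @export
carrier_frequency <- function(m, gene) {
  if (!gene %in% colnames(m)) stop("gene not in genotype matrix: ", gene)
  carriers <- sum(m[, gene] %in% c("het", "hom_alt"))
  round(carriers / nrow(m) * 100, 2)
}

#' Rank genes by carrier frequency
#'
#' Descending carrier frequency; exact ties are broken alphabetically and
#' flagged.
#'
#' @param m Genotype matrix from [genotype_matrix()].
#' @return Tibble with `gene`, `carrier_freq`, `tie`.
#' @export
rank_susceptibility <- function(m) {
  if (ncol(m) == 0L) stop("empty genotype matrix")
  freq <- vapply(colnames(m), function(g) carrier_frequency(m, g),
                 numeric(1))
  ord <- order(-freq, colnames(m))
  freq <- freq[ord]
  tie <- duplicated(freq) | duplicated(freq, fromLast = TRUE)
  tibble::tibble(gene = names(freq), carrier_freq = unname(freq),
                 tie = unname(tie))
}

#' Read/write a genotype matrix TSV
#'
#' Samples as rows (first column `sample_id`), genes as columns — the
#' layout of published susceptibility-gene genotype grids.
#'
#' @param m Genotype matrix.
#' @param path File path.
#' @export
write_genotype_tsv <- function(m, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con,
             sep = "\n")
  writeLines(paste(rownames(m),
                   apply(unclass(m), 1L, paste, collapse = "\t"),
                   sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  x <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x[[1L]]
  bad <- !m %in% c("hom_ref", "het", "hom_alt")
  if (any(bad)) stop("invalid genotype codes in ", path)
  class(m) <- c("wgsmut_genotype_matrix", class(m))
  m
}

#' Write a cascade attrition trace as TSV
#'
#' @param trace Trace tibble from [apply_cascade()].
#' @param path Output file.
#' @export
write_trace_tsv <- function(trace, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(trace), collapse = "\t"), con, sep = "\n")
  writeLines(paste(trace$step, trace$n_in, trace$n_removed, trace$n_out,
                   sep = "\t"), con, sep = "\n")
  invisible(path)
}
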