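.TALLY_CATEGORIES <- c("exonic", "synonymous_SNV", "nonsynonymous_SNV",
                       "stopgain", "frameshift_insertion",
                       "frameshift_deletion", "intronic", "intergenic",
                       "splicing", "ncRNA_exonic", "ncRNA_intronic")

#' Tally one sample's annotated variants by region and function
#'
#' Counts annotated records of one sample into the standard coding-region
#' summary categories. `total` counts every record in scope regardless of
#' region, so it can exceed the sum of the printed categories (regions
#' such as UTR or upstream/downstream contribute to the total but have no
#' column of their own). Functional categories (synonymous, nonsynonymous,
#' stopgain, frameshift) are counted inside exonic, not in addition to it.
#'
#' @param annotated Annotation tibble rows of a single sample and origin
#'   (columns `sample_id`, `region`, `func`, `variant_class`).
#' @param scope `"SNV"`, `"indel"`, or `"both"`: which variant classes to
#'   count.
#' @return A list of class `wgsmut_tally`: `sample_id`, `counts` (named
#'   integer vector over the categories), `total`, `scope`.
#' @export
tally_sample <- function(annotated, scope = c("SNV", "indel", "both")) {
  scope <- match.arg(scope)
  sid <- unique(annotated$sample_id)
  if (length(sid) > 1L) {
    stop("tally_sample expects records of a single sample, got: ",
         paste(sid, collapse = ", "))
  }
  if (length(sid) == 0L) sid <- NA_character_
  keep <- switch(scope,
                 SNV = annotated$variant_class == "SNV",
                 indel = annotated$variant_class %in% c("insertion",
                                                        "deletion"),
                 both = rep(TRUE, nrow(annotated)))
  x <- annotated[keep, , drop = FALSE]
  counts <- setNames(integer(length(.TALLY_CATEGORIES)),
                     .TALLY_CATEGORIES)
  region_cats <- c("exonic", "intronic", "intergenic", "splicing",
                   "ncRNA_exonic", "ncRNA_intronic")
  for (rc in region_cats) counts[rc] <- sum(x$region == rc)
  func_cats <- c("synonymous_SNV", "nonsynonymous_SNV", "stopgain",
                 "frameshift_insertion", "frameshift_deletion")
  for (fc in func_cats) {
    counts[fc] <- sum(x$region == "exonic" & x$func == fc)
  }
  structure(list(sample_id = sid, counts = counts, total = nrow(x),
                 scope = scope),
            class = "wgsmut_tally")
}

#' Cohort count table with column sums
#'
#' Binds per-sample tallies into a matrix-like tibble (one row per sample,
#' one column per category plus `total`) and appends a `Total` column-sum
#' row, matching the layout of per-sample mutation count tables.
#'
#' @param tallies A list of `wgsmut_tally` objects, one per sample.
#' @return Tibble with `sample_id`, the category columns, and `total`; the
#'   last row holds column sums.
#' @export
cohort_table <- function(tallies) {
  ids <- vapply(tallies, function(t) t$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample in cohort table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(tallies, function(t) {
    tibble::as_tibble(c(list(sample_id = t$sample_id), as.list(t$counts),
                        list(total = t$total)))
  })
  tab <- do.call(rbind, rows)
  sums <- tibble::as_tibble(c(list(sample_id = "Total"),
                              lapply(tab[, -1L], sum)))
  rbind(tab, sums)
}

#' Write a cohort count table as TSV
#'
#' @param tab Output of [cohort_table()] (or any tibble).
#' @param path Output file.
#' @export
write_cohort_table <- function(tab, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(lapply(tab, as.character), sep = "\t")),
             con, sep = "\n")
  invisible(path)
}
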