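#' Run the full downstream analysis on a (synthetic) cohort
#'
#' Orchestrates every stage on one configuration: simulate the cohort,
#' tally somatic SNVs/indels and germline variants, compute the six-class
#' spectrum and 96-context matrix, extract signatures by KL-NMF, screen
#' for significantly mutated genes, score copy-number recurrence with its
#' permutation null, and run the germline susceptibility cascade. All
#' randomness flows from `cfg$seed`. If `outdir` is given, every stage
#' writes its TSV outputs plus a JSON manifest listing stages, parameters,
#' and files; stages listed in `skip` are omitted and recorded as skipped
#' in the manifest.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional output directory.
#' @param nmf_rank Signature count for [nmf_extract()] (default 2).
#' @param n_perm Permutations for the CNV null (default 100).
#' @param skip Character vector of stage names to skip (subset of
#'   `c("cnv", "smg", "signatures", "germline")`).
#' @return List with elements `sim`, `tallies`, `spectrum`, `contexts`,
#'   `nmf`, `dominant`, `smg`, `cnv_profile`, `cnv_null`, `cascade`,
#'   `genotypes`, `ranking`, `manifest`.
#' @export
run_cohort_analysis <- function(cfg = sim_config(), outdir = NULL,
                                nmf_rank = 2L, n_perm = 100L,
                                skip = character(0)) {
  manifest <- list(tool = "wgsmut",
                   version = as.character(utils::packageVersion("wgsmut")),
                   seed = cfg$seed, n_samples = cfg$n_samples,
                   stages = list())
  note <- function(stage, status, files = NULL) {
    manifest$stages[[stage]] <<- list(status = status,
                                      files = files %||% character(0))
  }
  sim <- simulate_cohort(cfg)
  note("simulate", "done")

  ann_somatic <- annotate_variants(sim$somatic$variants, sim$genes,
                                   sim$reference)
  by_sample <- split(ann_somatic, ann_somatic$sample_id)
  snv_tab <- cohort_table(lapply(by_sample, tally_sample, scope = "SNV"))
  indel_tab <- cohort_table(lapply(by_sample, tally_sample,
                                   scope = "indel"))
  note("tally", "done")

  spec <- spectrum_table(ann_somatic)
  ctx <- context_matrix(ann_somatic, sim$reference,
                        sample_order = cfg$sample_ids)
  note("spectrum", "done")

  nmf <- dom <- NULL
  if (!"signatures" %in% skip) {
    nmf <- nmf_extract(ctx, k = nmf_rank, seed = cfg$seed)
    dom <- dominant_signature(nmf)
    note("signatures", "done")
  } else note("signatures", "skipped")

  smg <- NULL
  if (!"smg" %in% skip) {
    smg <- smg_screen(ann_somatic, sim$genes, cfg$n_samples)
    note("smg", "done")
  } else note("smg", "skipped")

  profile <- null <- NULL
  if (!"cnv" %in% skip) {
    bins <- cnv_bins(cfg$chrom_lengths, bin_size = 1e5)
    profile <- cnv_recurrence(sim$cnv$segments, bins)
    null <- cnv_permutation_null(sim$cnv$segments, bins, n_perm = n_perm,
                                 seed = cfg$seed)
    note("cnv", "done")
  } else note("cnv", "skipped")

  casc <- gm <- ranking <- NULL
  if (!"germline" %in% skip) {
    casc <- apply_cascade(sim$germline$records, cascade_config())
    gm <- genotype_matrix(casc$surviving, cfg$sample_ids)
    ranking <- if (ncol(gm) > 0L) rank_susceptibility(gm)
    note("germline-screen", "done")
  } else note("germline-screen", "skipped")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      snv_tally = write_cohort_table(snv_tab,
                                     file.path(outdir, "snv_tally.tsv")),
      indel_tally = write_cohort_table(indel_tab,
                                       file.path(outdir,
                                                 "indel_tally.tsv")),
      annotation = write_annotation_tsv(ann_somatic,
                                        file.path(outdir,
                                                  "somatic_annotated.tsv")))
    if (!is.null(smg)) {
      files <- c(files, smg = write_smg_tsv(smg,
                                            file.path(outdir, "smg.tsv")))
    }
    if (!is.null(profile)) {
      files <- c(files,
                 cnv = write_recurrence_tsv(profile,
                                            file.path(outdir,
                                                      "cnv_recurrence.tsv")))
    }
    if (!is.null(gm)) {
      files <- c(files,
                 genotypes = write_genotype_tsv(gm,
                                                file.path(outdir,
                                                          "genotypes.tsv")),
                 trace = write_trace_tsv(casc$trace,
                                         file.path(outdir,
                                                   "cascade_trace.tsv")))
    }
    manifest$files <- as.list(files)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(sim = sim, annotated_somatic = ann_somatic,
       snv_tally = snv_tab, indel_tally = indel_tab, spectrum = spec,
       contexts = ctx, nmf = nmf, dominant = dom, smg = smg,
       cnv_profile = profile, cnv_null = null, cascade = casc,
       genotypes = gm, ranking = ranking, manifest = manifest)
}

#' Bundled example data from a published 26-patient colorectal cohort
#'
#' Plain-text copies of per-sample summary tables from a 26-patient
#' colorectal tumor/normal WGS cohort, shipped under `inst/extdata` for
#' worked examples: coding-region somatic SNV and indel tallies, germline
#' SNV and indel tallies, a significantly-mutated-gene screen, and the
#' 26 x 6 susceptibility-gene genotype grid.
#'
#' @param name One of `"somatic_snv_tally"`, `"somatic_indel_tally"`,
#'   `"germline_snv_tally"`, `"germline_indel_tally"`, `"smg_screen"`,
#'   `"genotypes"`.
#' @return Path to the TSV file.
#' @export
example_cohort_file <- function(name = c("somatic_snv_tally",
                                         "somatic_indel_tally",
                                         "germline_snv_tally",
                                         "germline_indel_tally",
                                         "smg_screen", "genotypes")) {
  name <- match.arg(name)
  system.file("extdata", paste0("crc26_", name, ".tsv"),
              package = "wgsmut", mustWork = TRUE)
}
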