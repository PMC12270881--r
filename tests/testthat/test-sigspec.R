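test_that("pyrimidine collapse complements purine-reference changes", {
  # G>A with flanks (T, C) is C>T with flanks (G, A) on the other strand
  x <- collapse_to_pyrimidine("G", "A", "T", "C")
  expect_equal(x$class, "C>T")
  expect_equal(x$flank5, "G")
  expect_equal(x$flank3, "A")
  # pyrimidine input is untouched
  y <- collapse_to_pyrimidine("C", "T", "A", "G")
  expect_equal(y$channel, "A[C>T]G")
  # applying the collapse to its own output changes nothing
  x2 <- collapse_to_pyrimidine(substr(x$class, 1, 1),
                               substr(x$class, 3, 3),
                               x$flank5, x$flank3)
  expect_equal(x2, x)
  expect_error(collapse_to_pyrimidine("N", "A"), "non-ACGT")
  expect_error(collapse_to_pyrimidine("A", "A"), "differ")
})

test_that("the 96 channels cover all classes in fixed order", {
  ch <- context_channels()
  expect_length(ch, 96L)
  expect_equal(anyDuplicated(ch), 0L)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[96], "T[T>G]T")
  cls <- sub(".*\\[(.*)\\].*", "\\1", ch)
  expect_equal(unique(cls), substitution_classes())
  expect_equal(as.vector(table(cls)[substitution_classes()]),
               rep(16L, 6L))
})

test_that("spectrum proportions are computed over collapsed classes", {
  snv <- function(ref, alt, n) {
    tibble::tibble(sample_id = "S1", chrom = "chr1",
                   pos = seq_len(n), end = seq_len(n), ref = ref,
                   alt = alt, variant_class = "SNV")
  }
  # 10 G>A plus 10 C>T all collapse to C>T
  sp <- mutation_spectrum(rbind(snv("G", "A", 10), snv("C", "T", 10)))
  expect_equal(sp$proportions[["C>T"]], 1.0)
  expect_equal(sp$n_snv, 20L)
  # one of each class is uniform 1/6
  six <- rbind(snv("C", "A", 1), snv("C", "G", 1), snv("C", "T", 1),
               snv("T", "A", 1), snv("T", "C", 1), snv("T", "G", 1))
  expect_equal(unname(mutation_spectrum(six)$proportions),
               rep(1 / 6, 6))
  # empty input flags undefined proportions
  e <- mutation_spectrum(six[0, ])
  expect_equal(e$n_snv, 0L)
  expect_true(all(is.na(e$proportions)))
})

test_that("simulated C>T-dominant exposure yields C>T argmax", {
  cfg <- small_sim_config(seed = 41)
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  s1 <- som$variants[som$variants$sample_id == "S01", ]  # A-dominated
  sp <- mutation_spectrum(s1)
  expect_equal(names(which.max(sp$proportions)), "C>T")
})

test_that("context matrix counts, conserves, and skips edges", {
  ref <- Biostrings::DNAStringSet(c(chrZ = "ACTGA"))
  one <- tibble::tibble(sample_id = "S1", chrom = "chrZ", pos = 2L,
                        end = 2L, ref = "C", alt = "T",
                        variant_class = "SNV")
  m <- context_matrix(one, ref)
  expect_equal(sum(m), 1L)
  expect_equal(m["A[C>T]T", "S1"], 1L)

  # an SNV at position 1 has no 5' flank: skipped and logged
  edge <- tibble::tibble(sample_id = "S1", chrom = "chrZ", pos = 1L,
                         end = 1L, ref = "A", alt = "G",
                         variant_class = "SNV")
  m2 <- context_matrix(rbind(one, edge), ref)
  expect_equal(sum(m2), 1L)
  expect_equal(nrow(attr(m2, "skipped")), 1L)

  expect_error(context_matrix(
    tibble::tibble(sample_id = "S1", chrom = "chrZ", pos = 9L, end = 9L,
                   ref = "A", alt = "G", variant_class = "SNV"), ref),
    "outside")
})

test_that("context matrix equals a hash-map brute-force recount", {
  cfg <- small_sim_config(seed = 43)
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  snvs <- som$variants[som$variants$variant_class == "SNV", ]
  set.seed(3)
  snvs <- snvs[sample.int(nrow(snvs), 1000), ]
  m <- context_matrix(snvs, r$reference)
  env <- brute_force_context_counts(snvs, r$reference)
  expect_equal(sum(m), sum(unlist(as.list(env))))
  for (key in ls(env)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    expect_equal(m[parts[2], parts[1]], env[[key]], label = key)
  }
  # column sums conserve per-sample SNV counts (no edges possible here)
  cs <- colSums(m)
  tab <- table(snvs$sample_id)
  expect_equal(as.vector(cs[names(tab)]), as.vector(tab))
})

test_that("spectrum and contexts are strand-invariant", {
  cfg <- small_sim_config(seed = 47)
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  snvs <- som$variants[som$variants$variant_class == "SNV", ][1:500, ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped_ref <- Biostrings::DNAStringSet(vapply(
    as.character(r$reference), function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, character(1)))
  names(flipped_ref) <- names(r$reference)
  lens <- setNames(nchar(as.character(r$reference)), names(r$reference))
  flipped <- snvs
  flipped$pos <- lens[snvs$chrom] - snvs$pos + 1L
  flipped$end <- flipped$pos
  flipped$ref <- unname(comp[snvs$ref])
  flipped$alt <- unname(comp[snvs$alt])
  expect_equal(mutation_spectrum(flipped)$proportions,
               mutation_spectrum(snvs)$proportions)
  expect_equal(context_matrix(flipped, flipped_ref),
               context_matrix(snvs, r$reference), ignore_attr = TRUE)
})

test_that("NMF recovers an exact rank-1 factorization", {
  set.seed(7)
  s <- runif(96); s <- s / sum(s)
  e <- c(40, 80, 120, 160)
  V <- outer(s, e)
  rownames(V) <- context_channels()
  colnames(V) <- paste0("S", 1:4)
  fit <- nmf_extract(V, k = 1L, seed = 2, n_restarts = 3)
  expect_gt(cosine_similarity(fit$signatures[, 1], s), 1 - 1e-6)
  expect_lt(fit$divergence, 1e-4)
  expect_equal(unname(colSums(fit$signatures)), 1, tolerance = 1e-12)
  expect_equal(unname(colSums(fit$exposures_norm)), rep(1, 4),
               tolerance = 1e-12)
})

test_that("NMF divergence is monotone non-increasing and seeded", {
  cfg <- small_sim_config(seed = 53)
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  m <- context_matrix(som$variants, r$reference)
  fit1 <- nmf_extract(m, k = 2, seed = 9, n_restarts = 2)
  fit2 <- nmf_extract(m, k = 2, seed = 9, n_restarts = 2)
  expect_identical(fit1, fit2)
  d <- fit1$divergence_trace
  expect_true(all(diff(d) <= 1e-8 * pmax(abs(d[-length(d)]), 1)))
})

test_that("rank-2 fit beats rank-1 on rank-2 data", {
  cfg <- small_sim_config(seed = 59)
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  m <- context_matrix(som$variants, r$reference)
  f1 <- nmf_extract(m, k = 1, seed = 4, n_restarts = 3)
  f2 <- nmf_extract(m, k = 2, seed = 4, n_restarts = 3)
  expect_lt(f2$divergence, f1$divergence)
})

test_that("rank survey reports non-increasing divergence in k", {
  cfg <- small_sim_config(seed = 63)
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  m <- context_matrix(som$variants, r$reference)
  sv <- nmf_rank_survey(m, ks = 1:3, seed = 2, n_restarts = 2)
  expect_equal(sv$k, 1:3)
  expect_true(all(diff(sv$divergence) <= 1e-6 * sv$divergence[-3]))
})

test_that("NMF input validation", {
  expect_error(nmf_extract(matrix(0, 96, 4)), "all-zero")
  expect_error(nmf_extract(matrix(-1, 96, 4)), "nonnegative")
  expect_error(nmf_extract(matrix(1, 96, 4), k = 5), "rank")
})

test_that("dominant signature uses argmax with flagged ties", {
  e <- matrix(c(0.8, 0.2, 0.5, 0.5, 0.1, 0.9), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  d <- dominant_signature(e)
  expect_equal(d$signature, c("A", "A", "B"))
  expect_equal(d$tie, c(FALSE, TRUE, FALSE))
})

test_that("dominant signatures match designed exposures cohort-wide", {
  cfg <- small_sim_config(seed = 61)
  r <- simulate_reference(cfg)
  som <- simulate_somatic(cfg, r$reference, r$genes)
  m <- context_matrix(som$variants, r$reference,
                      sample_order = cfg$sample_ids)
  fit <- nmf_extract(m, k = 2, seed = 3, n_restarts = 5)
  dom <- dominant_signature(fit)
  # map extracted labels onto the true ones before comparing
  mt <- match_signatures(fit$signatures, som$ground_truth$signatures)
  map <- setNames(mt$reference, mt$extracted)
  truth <- ifelse(cfg$exposures[, 1] > 0.5, "A", "B")
  expect_equal(unname(map[dom$signature]), truth)
})
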