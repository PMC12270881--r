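#' Substitution classes and 96-channel context order
#'
#' The six pyrimidine-referenced substitution classes (C>A, C>G, C>T, T>A,
#' T>C, T>G) and the fixed 96-channel order used for all context matrices:
#' substitution-major, then 5' flank, then 3' flank, each lexicographic
#' A, C, G, T. Channel labels follow the `A[C>T]G` convention.
#'
#' @return `substitution_classes()` the 6 class labels;
#'   `context_channels()` the 96 channel labels in fixed order.
#' @export
substitution_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' @rdname substitution_classes
#' @export
context_channels <- function() {
  unlist(lapply(substitution_classes(), function(cl) {
    unlist(lapply(.BASES, function(f5) paste0(f5, "[", cl, "]", .BASES)))
  }), use.names = FALSE)
}

#' Collapse a substitution to its pyrimidine-strand representation
#'
#' Every SNV is reported with a pyrimidine (C or T) reference base. If the
#' reference base is a purine, ref and alt are complemented and the two
#' flanking bases are reverse-complemented (5' and 3' swap). The operation
#' is the identity on pyrimidine-reference input, hence idempotent.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @param flank5,flank3 Optional single flanking bases (vectorized).
#' @return A tibble with `class` (one of the six substitution classes) and,
#'   when flanks are given, oriented `flank5`, `flank3`, and the 96-channel
#'   `channel` label.
#' @export
collapse_to_pyrimidine <- function(ref, alt, flank5 = NULL, flank3 = NULL) {
  ok <- ref %in% .BASES & alt %in% .BASES
  if (!all(ok)) stop("non-ACGT base in ref/alt")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- ref %in% c("A", "G")
  cref <- ifelse(purine, .COMPLEMENT[ref], ref)
  calt <- ifelse(purine, .COMPLEMENT[alt], alt)
  out <- tibble::tibble(class = paste0(cref, ">", calt))
  if (!is.null(flank5)) {
    if (!all(flank5 %in% .BASES & flank3 %in% .BASES)) {
      stop("non-ACGT base in flanks")
    }
    f5 <- ifelse(purine, .COMPLEMENT[flank3], flank5)
    f3 <- ifelse(purine, .COMPLEMENT[flank5], flank3)
    out$flank5 <- unname(f5)
    out$flank3 <- unname(f3)
    out$channel <- paste0(out$flank5, "[", out$class, "]", out$flank3)
  }
  out
}

#' Six-class mutation spectrum of a sample
#'
#' Proportion of SNVs in each collapsed substitution class. Classes need
#' only ref/alt, so every SNV contributes (contig-edge SNVs included).
#'
#' @param snvs Variant tibble rows with `variant_class == "SNV"`.
#' @return A list with `proportions` (named 6-vector) and `n_snv`. With no
#'   SNVs, `proportions` is all-`NA` and `n_snv` 0.
#' @export
mutation_spectrum <- function(snvs) {
  snvs <- snvs[snvs$variant_class == "SNV", , drop = FALSE]
  classes <- substitution_classes()
  if (nrow(snvs) == 0L) {
    return(list(proportions = setNames(rep(NA_real_, 6L), classes),
                n_snv = 0L))
  }
  cl <- collapse_to_pyrimidine(snvs$ref, snvs$alt)$class
  counts <- table(factor(cl, levels = classes))
  list(proportions = setNames(as.vector(counts) / nrow(snvs), classes),
       n_snv = nrow(snvs))
}

#' Cohort spectrum table
#'
#' Runs [mutation_spectrum()] per sample and stacks the results.
#'
#' @param variants Cohort variant tibble.
#' @return Tibble with `sample_id`, one column per class, and `n_snv`.
#' @export
spectrum_table <- function(variants) {
  by_sample <- split(variants, variants$sample_id)
  rows <- lapply(names(by_sample), function(s) {
    sp <- mutation_spectrum(by_sample[[s]])
    c(list(sample_id = s), as.list(sp$proportions),
      list(n_snv = sp$n_snv))
  })
  tibble::as_tibble(do.call(rbind, lapply(rows, as.data.frame)))
}

# Fetch 5'/3' flanking bases for SNV positions; NA at contig edges.
.fetch_flanks <- function(snvs, reference) {
  f5 <- rep(NA_character_, nrow(snvs))
  f3 <- rep(NA_character_, nrow(snvs))
  for (chrom in unique(snvs$chrom)) {
    if (!chrom %in% names(reference)) {
      stop("SNV position on chromosome absent from reference: ", chrom)
    }
    idx <- which(snvs$chrom == chrom)
    seq_str <- as.character(reference[[chrom]])
    len <- nchar(seq_str)
    pos <- snvs$pos[idx]
    if (any(pos < 1L | pos > len)) {
      stop("SNV position outside reference bounds on ", chrom)
    }
    inner5 <- pos > 1L
    inner3 <- pos < len
    f5[idx[inner5]] <- substring(seq_str, pos[inner5] - 1L, pos[inner5] - 1L)
    f3[idx[inner3]] <- substring(seq_str, pos[inner3] + 1L, pos[inner3] + 1L)
  }
  list(flank5 = f5, flank3 = f3)
}

#' 96-channel trinucleotide context matrix
#'
#' Counts each sample's SNVs into the 96 pyrimidine-collapsed trinucleotide
#' channels (fixed order of [context_channels()]). SNVs at contig edges
#' have no defined context; they are excluded from the matrix and reported
#' in the `skipped` attribute (a tibble of the skipped records).
#'
#' @param snvs Cohort SNV tibble (`sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `variant_class`).
#' @param reference Named [Biostrings::DNAStringSet].
#' @param sample_order Optional character vector fixing column order.
#' @return 96 x S integer matrix (channels x samples) with a `skipped`
#'   attribute.
#' @export
context_matrix <- function(snvs, reference, sample_order = NULL) {
  snvs <- snvs[snvs$variant_class == "SNV", , drop = FALSE]
  samples <- sample_order %||% sort(unique(snvs$sample_id))
  channels <- context_channels()
  m <- matrix(0L, nrow = 96L, ncol = length(samples),
              dimnames = list(channels, samples))
  if (nrow(snvs) == 0L) {
    attr(m, "skipped") <- snvs
    return(m)
  }
  fl <- .fetch_flanks(snvs, reference)
  edge <- is.na(fl$flank5) | is.na(fl$flank3)
  skipped <- snvs[edge, , drop = FALSE]
  keep <- which(!edge)
  if (length(keep)) {
    coll <- collapse_to_pyrimidine(snvs$ref[keep], snvs$alt[keep],
                                   fl$flank5[keep], fl$flank3[keep])
    tab <- table(factor(coll$channel, levels = channels),
                 factor(snvs$sample_id[keep], levels = samples))
    m[] <- as.integer(tab)
  }
  attr(m, "skipped") <- skipped
  m
}

# Generalized KL divergence D(V || WH); 0*log0 taken as 0.
.kl_div <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' Extract mutational signatures by KL-NMF
#'
#' Factorizes a nonnegative 96 x S count matrix as `V ~ W %*% H` with
#' multiplicative updates minimizing the generalized Kullback-Leibler
#' divergence (the natural objective for Poisson-like counts). The best of
#' `n_restarts` seeded uniform initializations (by final divergence) is
#' kept. Signature columns are normalized to sum 1 with the scale absorbed
#' into the exposures; `exposures_norm` columns sum to 1 per sample.
#'
#' @param m 96 x S nonnegative matrix (e.g. from [context_matrix()]).
#' @param k Factorization rank (number of signatures), default 2.
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iter Maximum multiplicative updates per restart (default 2000).
#' @param tol Relative divergence-change stopping tolerance (default 1e-6).
#' @return An object of class `wgsmut_nmf`: list with `signatures` (96 x k,
#'   labeled A, B, ...), `exposures` (k x S), `exposures_norm`,
#'   `divergence`, `divergence_trace` (of the winning restart), `n_iter`,
#'   `k`.
#' @export
nmf_extract <- function(m, k = 2L, seed = 1L, n_restarts = 10L,
                        max_iter = 2000L, tol = 1e-6) {
  V <- as.matrix(m)
  if (any(V < 0)) stop("count matrix must be nonnegative")
  if (all(V == 0)) stop("degenerate input: all-zero count matrix")
  if (k < 1L || k > min(nrow(V), ncol(V))) {
    stop("rank k must be between 1 and min(dim(V))")
  }
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    W <- matrix(runif(nrow(V) * k, min = eps, max = 1), nrow(V), k)
    H <- matrix(runif(k * ncol(V), min = eps, max = 1), k, ncol(V))
    trace <- numeric(0)
    d_prev <- Inf
    for (it in seq_len(max_iter)) {
      WH <- W %*% H + eps
      H <- H * (crossprod(W, V / WH)) / (colSums(W) + eps)
      WH <- W %*% H + eps
      W <- W * ((V / WH) %*% t(H)) / rep(rowSums(H) + eps,
                                         each = nrow(V))
      d <- .kl_div(V, W %*% H + eps)
      trace <- c(trace, d)
      if (is.finite(d_prev) &&
          abs(d_prev - d) <= tol * max(abs(d_prev), eps)) {
        d_prev <- d
        break
      }
      d_prev <- d
    }
    if (is.null(best) || d_prev < best$divergence) {
      best <- list(W = W, H = H, divergence = d_prev, trace = trace,
                   n_iter = length(trace))
    }
  }
  scale <- colSums(best$W)
  W <- sweep(best$W, 2L, scale, "/")
  H <- best$H * scale
  csum <- colSums(H)
  Hn <- sweep(H, 2L, ifelse(csum > 0, csum, 1), "/")
  labels <- LETTERS[seq_len(k)]
  dimnames(W) <- list(rownames(V) %||% as.character(seq_len(nrow(V))),
                      labels)
  dimnames(H) <- list(labels, colnames(V))
  dimnames(Hn) <- dimnames(H)
  structure(list(signatures = W, exposures = H, exposures_norm = Hn,
                 divergence = best$divergence,
                 divergence_trace = best$trace, n_iter = best$n_iter,
                 k = k),
            class = "wgsmut_nmf")
}

#' @export
print.wgsmut_nmf <- function(x, ...) {
  cat("KL-NMF signature fit: rank", x$k, "|", ncol(x$exposures),
      "samples | divergence", format(x$divergence, digits = 6),
      "|", x$n_iter, "iterations\n")
  invisible(x)
}

#' Survey factorization ranks by reconstruction error
#'
#' Fits [nmf_extract()] at each rank in `ks` and reports the final KL
#' divergence and iteration count, as an aid for choosing the number of
#' signatures (look for the elbow). Advisory only; the package default is
#' rank 2.
#'
#' @inheritParams nmf_extract
#' @param ks Ranks to survey (default 1:5).
#' @return Tibble with `k`, `divergence`, `n_iter`.
#' @export
nmf_rank_survey <- function(m, ks = 1:5, seed = 1L, n_restarts = 5L,
                            max_iter = 2000L, tol = 1e-6) {
  ks <- ks[ks >= 1L & ks <= min(dim(as.matrix(m)))]
  rows <- lapply(ks, function(k) {
    fit <- nmf_extract(m, k = k, seed = seed, n_restarts = n_restarts,
                       max_iter = max_iter, tol = tol)
    tibble::tibble(k = k, divergence = fit$divergence,
                   n_iter = fit$n_iter)
  })
  do.call(rbind, rows)
}

#' Dominant signature per sample
#'
#' The signature with the largest normalized exposure in each sample. Exact
#' ties are broken toward the lower signature index and flagged.
#'
#' @param fit A `wgsmut_nmf` object, or a normalized exposure matrix
#'   (signatures x samples).
#' @return Tibble with `sample_id`, `signature`, `tie`.
#' @export
dominant_signature <- function(fit) {
  e <- if (inherits(fit, "wgsmut_nmf")) fit$exposures_norm else as.matrix(fit)
  labels <- rownames(e) %||% LETTERS[seq_len(nrow(e))]
  idx <- apply(e, 2L, which.max)
  tie <- apply(e, 2L, function(col) sum(col == max(col)) > 1L)
  tibble::tibble(sample_id = colnames(e) %||%
                   as.character(seq_len(ncol(e))),
                 signature = labels[idx], tie = unname(tie))
}

#' Cosine similarity between two nonnegative vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in `[0, 1]` for nonnegative input.
#' @export
cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match extracted signatures to reference signatures by best cosine
#'
#' Greedy assignment: each extracted signature is paired with its
#' best-cosine reference column, highest similarity first, without reuse.
#'
#' @param extracted,reference 96 x k matrices with columns as signatures.
#' @return Tibble with `extracted`, `reference` (column names), `cosine`.
#' @export
match_signatures <- function(extracted, reference) {
  sim <- matrix(NA_real_, ncol(extracted), ncol(reference),
                dimnames = list(colnames(extracted), colnames(reference)))
  for (i in seq_len(ncol(extracted))) {
    for (j in seq_len(ncol(reference))) {
      sim[i, j] <- cosine_similarity(extracted[, i], reference[, j])
    }
  }
  pairs <- list()
  while (any(is.finite(sim))) {
    ij <- which(sim == max(sim, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    pairs[[length(pairs) + 1L]] <-
      tibble::tibble(extracted = rownames(sim)[ij[1]],
                     reference = colnames(sim)[ij[2]],
                     cosine = sim[ij[1], ij[2]])
    sim[ij[1], ] <- NA_real_
    sim[, ij[2]] <- NA_real_
  }
  do.call(rbind, pairs)
}
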