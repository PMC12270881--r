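#' Fixed-width genome bins
#'
#' Tiles each autosome into fixed-width bins (last bin truncated at the
#' chromosome end). Sex chromosomes are excluded by name.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (default 1e6, conventional for WGS
#'   copy-number recurrence).
#' @param exclude Chromosome names to drop (default sex chromosomes).
#' @return Tibble with `bin`, `chrom`, `start`, `end`.
#' @export
cnv_bins <- function(chrom_lengths, bin_size = 1e6,
                     exclude = c("chrX", "chrY", "X", "Y")) {
  chrom_lengths <- chrom_lengths[!names(chrom_lengths) %in% exclude]
  rows <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(1L, len, by = bin_size)
    tibble::tibble(chrom = ch, start = as.integer(starts),
                   end = as.integer(pmin(starts + bin_size - 1, len)))
  })
  out <- do.call(rbind, rows)
  out$bin <- seq_len(nrow(out))
  out[, c("bin", "chrom", "start", "end")]
}

# bins x samples matrix of length-weighted mean log2 ratios; NA where no
# segment overlaps a bin.
.bin_log2_matrix <- function(segments, bins, samples = NULL) {
  samples <- samples %||% sort(unique(segments$sample_id))
  if (!all(segments$chrom %in% unique(bins$chrom))) {
    stop("segment on a chromosome outside the binned genome")
  }
  seg_gr <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start,
                                                    segments$end))
  bin_gr <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(bins$start, bins$end))
  ov <- GenomicRanges::findOverlaps(seg_gr, bin_gr)
  qi <- S4Vectors::queryHits(ov)
  bi <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(seg_gr)[qi], IRanges::ranges(bin_gr)[bi]))
  si <- match(segments$sample_id[qi], samples)
  key <- (si - 1L) * nrow(bins) + bi
  wsum <- rowsum(w, key)
  lsum <- rowsum(w * segments$log2_ratio[qi], key)
  m <- matrix(NA_real_, nrow(bins), length(samples),
              dimnames = list(bins$bin, samples))
  k <- as.integer(rownames(wsum))
  m[k] <- lsum[, 1L] / wsum[, 1L]
  m
}

#' Per-sample per-bin copy-number state calls
#'
#' Each bin's value is the length-weighted mean log2 ratio of the
#' segments overlapping it; bins above `gain_thr` are `gain`, below
#' `loss_thr` are `loss`, otherwise `neutral` (including bins with no
#' overlapping segment).
#'
#' @param segments Segment tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `log2_ratio`).
#' @param bins Output of [cnv_bins()].
#' @param gain_thr,loss_thr Log2-ratio call thresholds (defaults +0.2 /
#'   -0.2); `gain_thr` must be positive and `loss_thr` negative.
#' @param samples Optional sample order.
#' @return List with `state` (bins x samples character matrix) and `log2`
#'   (the weighted-mean matrix).
#' @export
cnv_call_states <- function(segments, bins, gain_thr = 0.2,
                            loss_thr = -0.2, samples = NULL) {
  if (!(gain_thr > 0 && loss_thr < 0)) {
    stop("need gain_thr > 0 > loss_thr")
  }
  m <- .bin_log2_matrix(segments, bins, samples)
  state <- matrix("neutral", nrow(m), ncol(m), dimnames = dimnames(m))
  state[!is.na(m) & m > gain_thr] <- "gain"
  state[!is.na(m) & m < loss_thr] <- "loss"
  list(state = state, log2 = m)
}

#' Copy-number recurrence profile
#'
#' For each bin and direction: `freq` = affected samples / total samples,
#' and `score` = freq x mean |log2 ratio| among affected samples — a
#' frequency-and-amplitude recurrence statistic in the spirit of a
#' G-score. Scores are zero where no sample is affected.
#'
#' @inheritParams cnv_call_states
#' @return A tibble of class `wgsmut_recurrence`: bins with `gain_freq`,
#'   `loss_freq`, `gain_score`, `loss_score`.
#' @export
cnv_recurrence <- function(segments, bins, gain_thr = 0.2,
                           loss_thr = -0.2, samples = NULL) {
  cs <- cnv_call_states(segments, bins, gain_thr, loss_thr, samples)
  n <- ncol(cs$state)
  gain <- cs$state == "gain"
  loss <- cs$state == "loss"
  gain_n <- unname(rowSums(gain))
  loss_n <- unname(rowSums(loss))
  amp <- abs(cs$log2)
  mean_if <- function(mask, k) {
    s <- unname(rowSums(amp * mask, na.rm = TRUE))
    ifelse(k > 0, s / k, 0)
  }
  out <- bins
  out$gain_freq <- gain_n / n
  out$loss_freq <- loss_n / n
  out$gain_score <- out$gain_freq * mean_if(gain, gain_n)
  out$loss_score <- out$loss_freq * mean_if(loss, loss_n)
  class(out) <- c("wgsmut_recurrence", class(out))
  out
}

#' Permutation null for recurrence scores
#'
#' Each permutation cyclically shifts every sample's segment set by an
#' independent uniform offset along the concatenated (binned) genome,
#' preserving each sample's segment-length structure while destroying
#' cross-sample alignment. The returned thresholds are the stated
#' quantile (default 95th percentile) of the per-permutation maximum bin
#' score in each direction. Deterministic given `seed`.
#'
#' @inheritParams cnv_call_states
#' @param n_perm Number of permutations (must be >= 100).
#' @param seed Integer seed.
#' @param probs Quantile for the threshold (default 0.95).
#' @return List with `gain_threshold`, `loss_threshold`, and the
#'   per-permutation `max_gain` / `max_loss` vectors.
#' @export
cnv_permutation_null <- function(segments, bins, n_perm = 100L, seed = 1L,
                                 gain_thr = 0.2, loss_thr = -0.2,
                                 probs = 0.95) {
  if (n_perm < 100L) {
    stop("configuration error: n_perm must be at least 100")
  }
  set.seed(seed)
  chroms <- unique(bins$chrom)
  chrom_len <- vapply(chroms, function(ch) {
    max(bins$end[bins$chrom == ch])
  }, numeric(1))
  G <- sum(chrom_len)
  offsets <- setNames(cumsum(c(0, chrom_len[-length(chrom_len)])), chroms)
  samples <- sort(unique(segments$sample_id))

  g_start <- offsets[segments$chrom] + segments$start
  g_end <- offsets[segments$chrom] + segments$end
  bounds <- c(unname(offsets), G)

  max_gain <- max_loss <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    shift <- setNames(floor(runif(length(samples), 0, G)), samples)
    sh <- shift[segments$sample_id]
    ns <- (g_start - 1 + sh) %% G + 1
    ne <- ns + (g_end - g_start)
    # split segments that wrap past the genome end or cross a chromosome
    # boundary back into per-chromosome pieces
    pieces <- .split_global_segments(ns, ne, segments$sample_id,
                                     segments$log2_ratio, bounds, chroms,
                                     G)
    mx <- .max_scores_fast(pieces, bins, samples, gain_thr, loss_thr)
    max_gain[p] <- mx[1L]
    max_loss[p] <- mx[2L]
  }
  list(gain_threshold = unname(quantile(max_gain, probs)),
       loss_threshold = unname(quantile(max_loss, probs)),
       max_gain = max_gain, max_loss = max_loss)
}

# Map shifted global-coordinate segments back to chromosome coordinates,
# splitting pieces that wrap the circular genome or span chromosomes.
.split_global_segments <- function(ns, ne, sample_id, log2_ratio, bounds,
                                   chroms, G) {
  wrap <- ne > G
  idx <- c(seq_along(ns), which(wrap))
  s <- c(ns, rep(1, sum(wrap)))
  e <- c(pmin(ne, G), ne[wrap] - G)
  sid <- sample_id[idx]
  l2 <- log2_ratio[idx]
  # position p belongs to chromosome k iff bounds[k] < p <= bounds[k+1]
  cuts <- findInterval(s - 1, bounds)
  cute <- findInterval(e - 1, bounds)
  simple <- cuts == cute
  res_sid <- sid[simple]
  res_chr <- chroms[cuts[simple]]
  res_s <- s[simple] - bounds[cuts[simple]]
  res_e <- e[simple] - bounds[cuts[simple]]
  res_l2 <- l2[simple]
  for (i in which(!simple)) {
    ks <- cuts[i]:cute[i]
    ss <- pmax(s[i], bounds[ks] + 1)
    ee <- pmin(e[i], bounds[ks + 1L])
    res_sid <- c(res_sid, rep(sid[i], length(ks)))
    res_chr <- c(res_chr, chroms[ks])
    res_s <- c(res_s, ss - bounds[ks])
    res_e <- c(res_e, ee - bounds[ks])
    res_l2 <- c(res_l2, rep(l2[i], length(ks)))
  }
  tibble::tibble(sample_id = res_sid, chrom = res_chr,
                 start = as.integer(res_s), end = as.integer(res_e),
                 log2_ratio = res_l2)
}

# Arithmetic recurrence scorer for the fixed-width bins produced by
# cnv_bins(): same weighted-mean/state/score definitions as
# cnv_recurrence() (asserted against it in the tests), but without
# GRanges overhead, for the permutation inner loop. Returns
# c(max_gain_score, max_loss_score).
.max_scores_fast <- function(pieces, bins, samples, gain_thr, loss_thr) {
  chroms <- unique(bins$chrom)
  first <- match(chroms, bins$chrom)
  bin_w <- (bins$end - bins$start + 1L)[first]
  names(bin_w) <- chroms
  bin_off <- setNames(first - 1L, chroms)

  w <- bin_w[pieces$chrom]
  b1 <- bin_off[pieces$chrom] + (pieces$start - 1L) %/% w + 1L
  b2 <- bin_off[pieces$chrom] + (pieces$end - 1L) %/% w + 1L
  nk <- b2 - b1 + 1L
  bin_id <- sequence(nk, from = b1, by = 1L)
  seg_id <- rep.int(seq_len(nrow(pieces)), nk)
  ov <- pmin(pieces$end[seg_id], bins$end[bin_id]) -
    pmax(pieces$start[seg_id], bins$start[bin_id]) + 1L
  si <- match(pieces$sample_id, samples)[seg_id]
  key <- (si - 1L) * nrow(bins) + bin_id
  wsum <- rowsum(as.numeric(ov), key)
  lsum <- rowsum(ov * pieces$log2_ratio[seg_id], key)
  m <- matrix(NA_real_, nrow(bins), length(samples))
  m[as.integer(rownames(wsum))] <- lsum[, 1L] / wsum[, 1L]

  gain <- !is.na(m) & m > gain_thr
  loss <- !is.na(m) & m < loss_thr
  amp <- abs(m)
  n <- length(samples)
  gn <- rowSums(gain)
  ln <- rowSums(loss)
  gscore <- ifelse(gn > 0, (gn / n) *
                     rowSums(amp * gain, na.rm = TRUE) / gn, 0)
  lscore <- ifelse(ln > 0, (ln / n) *
                     rowSums(amp * loss, na.rm = TRUE) / ln, 0)
  c(max(gscore), max(lscore))
}

#' Read/write copy-number segment tables
#'
#' Plain TSV with columns `sample_id`, `chrom`, `start`, `end`,
#' `log2_ratio`.
#'
#' @param segments Segment tibble.
#' @param path File path.
#' @export
write_segments_tsv <- function(segments, path) {
  cols <- c("sample_id", "chrom", "start", "end", "log2_ratio")
  x <- segments[, cols]
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  writeLines(paste(x$sample_id, x$chrom, x$start, x$end,
                   format(x$log2_ratio, digits = 17, scientific = FALSE,
                          trim = TRUE), sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
read_segments_tsv <- function(path) {
  x <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$log2_ratio <- as.numeric(x$log2_ratio)
  tibble::as_tibble(x)
}

#' Write a recurrence profile as BED-like TSV
#'
#' @param profile Output of [cnv_recurrence()].
#' @param path Output file.
#' @export
write_recurrence_tsv <- function(profile, path) {
  x <- as.data.frame(profile)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(x), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(lapply(x, function(col) {
    if (is.double(col)) format(col, digits = 17, scientific = FALSE,
                               trim = TRUE) else as.character(col)
  }), sep = "\t")), con, sep = "\n")
  invisible(path)
}
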