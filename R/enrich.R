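#' Tile chromosomes into fixed-width windows
#'
#' Non-overlapping windows of `width` bp per chromosome, starting at
#' position 1 and aligned to multiples of the width (`start` to
#' `start + width - 1`, 1-based inclusive); the last window is a stub ending at
#' the chromosome's span. Chromosome spans default to the last SNP position.
#'
#' @param panel a [haplotype_panel()] (supplies chromosomes and spans).
#' @param width window width in bp (default 10000, within which linkage
#'   disequilibrium typically decays in selfing panels).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return tibble with `chrom`, `start`, `end`, `window` (genome-wide
#'   0-based index over the concatenated window sequence).
#' @export
build_windows <- function(panel, width = 10000, chrom_lengths = NULL) {
  if (width < 1) abort("width must be at least 1")
  chroms <- unique(panel$snps$chrom)
  out <- lapply(chroms, function(ch) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]]
           else max(panel$snps$pos[panel$snps$chrom == ch])
    starts <- seq(1, len, by = width)
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(pmin(starts + width - 1, len)))
  })
  out <- dplyr::bind_rows(out)
  out$window <- seq_len(nrow(out)) - 1L
  out
}

#' Window-max iHS statistic
#'
#' Assigns each valid iHS SNP to its window and takes the maximum absolute
#' standardized score per window as the window's test statistic; windows
#' without a valid SNP stay undefined. Empirical P values (rank-based, most
#' extreme = rank 1, ties share the mean rank) are attached for windows with
#' a defined statistic.
#'
#' @param windows window tibble from [build_windows()].
#' @param ihs_table iHS tibble from [ihs_scan()].
#' @param signed `"abs"` (default: max of |iHS|) or `"max"` (max signed
#'   score) or `"min"` (most negative, reported as its absolute value).
#' @return the window tibble with `max_abs_ihs` and `emp_p` columns.
#' @export
window_max_stat <- function(windows, ihs_table, signed = c("abs", "max",
                                                           "min")) {
  signed <- match.arg(signed)
  valid <- ihs_table[ihs_table$valid, ]
  stat <- switch(signed,
                 abs = abs(valid$ihs),
                 max = valid$ihs,
                 min = -valid$ihs)
  idx <- assign_windows(valid$chrom, valid$pos, windows)
  mx <- tapply(stat, factor(idx, levels = windows$window), max)
  windows$max_abs_ihs <- as.numeric(mx)
  windows$emp_p <- empirical_p(windows$max_abs_ihs)
  windows
}

# map (chrom, pos) to the genome-wide window index
assign_windows <- function(chrom, pos, windows) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    w <- windows[windows$chrom == ch, ]
    sel <- chrom == ch
    j <- findInterval(pos[sel], w$start)
    ok <- j >= 1 & pos[sel] <= w$end[pmax(j, 1)]
    out[sel][ok] <- w$window[j[ok]]
  }
  out
}

#' Rank-based empirical P values
#'
#' `P_i = rank_i / N` over the `N` defined values, where rank 1 is the most
#' extreme (largest) value and ties share the mean rank; undefined inputs
#' get `NA`.
#'
#' @param values numeric vector (larger = more extreme).
#' @return numeric vector of empirical P values in `(0, 1]`.
#' @export
empirical_p <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  out <- rep(NA_real_, length(values))
  if (n == 0) return(out)
  out[ok] <- rank(-values[ok], ties.method = "average") / n
  out
}

#' Flag GWAS-peak windows
#'
#' A window is a peak when it contains at least one SNP with association
#' `pvalue < p_thresh` and `maf > maf_min` (both strict).
#'
#' @param windows window tibble.
#' @param assoc association tibble from [association_scan()].
#' @param p_thresh association P threshold (default 1e-4).
#' @param maf_min MAF threshold (default 0.1).
#' @return the window tibble with an `is_gwas_peak` column.
#' @export
call_gwas_peak_windows <- function(windows, assoc, p_thresh = 1e-4,
                                   maf_min = 0.1) {
  hits <- assoc[assoc$pvalue < p_thresh & assoc$maf > maf_min, ]
  idx <- assign_windows(hits$chrom, hits$pos, windows)
  windows$is_gwas_peak <- windows$window %in% idx[!is.na(idx)]
  windows
}

#' Tail overlap and fold enrichment
#'
#' Counts GWAS-peak windows falling in the extreme tail of the window-max
#' iHS empirical distribution (`emp_p <= tail_t`), against the expectation
#' `tail_t` times the number of peak windows with a defined statistic.
#'
#' @param windows window tibble with `emp_p` and `is_gwas_peak`.
#' @param tail_t tail threshold in (0, 1).
#' @return one-row tibble with `tail`, `observed`, `expected`, `fold`,
#'   `n_peaks`.
#' @export
tail_enrichment <- function(windows, tail_t) {
  if (!(tail_t > 0 && tail_t < 1)) abort("tail_t must be in (0,1)")
  peaks <- windows[windows$is_gwas_peak, ]
  if (nrow(peaks) == 0) abort("nothing to test: no GWAS-peak windows")
  defined <- peaks[!is.na(peaks$emp_p), ]
  observed <- sum(defined$emp_p <= tail_t)
  expected <- tail_t * nrow(defined)
  tibble(tail = tail_t, observed = observed, expected = expected,
         fold = if (expected > 0) observed / expected else NA_real_,
         n_peaks = nrow(defined))
}

#' Circular shift of window indices
#'
#' Shifts a set of genome-wide window indices by `k` modulo the total
#' number of windows, preserving the multiset of pairwise index gaps (mod
#' `W`) and hence the spatial autocorrelation of the set.
#'
#' @param indices integer window indices in `[0, W)`.
#' @param k shift in `[0, W)`.
#' @param W total number of windows.
#' @return shifted indices.
#' @export
circular_shift <- function(indices, k, W) {
  stopifnot(k >= 0, k < W, all(indices >= 0), all(indices < W))
  (indices + k) %% W
}

#' Circular-shift permutation test for tail enrichment
#'
#' The null preserves the peak windows' relative positions: each permutation
#' shifts the whole peak set by a uniformly drawn offset over the genome-wide
#' concatenated window sequence and recounts the tail overlap. The
#' permutation P value uses the add-one convention
#' `(1 + #{permuted >= observed}) / (1 + n_perm)`, so it is never zero.
#'
#' @param windows window tibble with `emp_p` and `is_gwas_peak`.
#' @param tails tail thresholds (default `c(0.10, 0.05, 0.025, 0.01)`).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param exclude_zero_shift drop `k = 0` from the uniform draw (default
#'   `FALSE`; its probability `1/W` is negligible).
#' @return tibble with one row per tail: `tail`, `observed`, `expected`,
#'   `fold`, `perm_p`, `n_perm`.
#' @export
permutation_test <- function(windows, tails = c(0.10, 0.05, 0.025, 0.01),
                             n_perm = 1000, seed = 1L,
                             exclude_zero_shift = FALSE) {
  W <- nrow(windows)
  peak_idx <- windows$window[windows$is_gwas_peak]
  if (length(peak_idx) == 0) abort("nothing to test: no GWAS-peak windows")
  emp_p <- windows$emp_p[order(windows$window)]

  obs <- lapply(tails, function(t) tail_enrichment(windows, t))
  obs <- dplyr::bind_rows(obs)

  set.seed(seed)
  ks <- if (exclude_zero_shift) {
    sample(seq_len(W - 1), n_perm, replace = TRUE)
  } else {
    sample(seq_len(W), n_perm, replace = TRUE) - 1L
  }
  exceed <- integer(length(tails))
  for (b in seq_len(n_perm)) {
    shifted <- (peak_idx + ks[b]) %% W
    p_sh <- emp_p[shifted + 1L]
    for (ti in seq_along(tails)) {
      ov <- sum(p_sh <= tails[ti], na.rm = TRUE)
      if (ov >= obs$observed[ti]) exceed[ti] <- exceed[ti] + 1L
    }
  }
  obs$perm_p <- (1 + exceed) / (1 + n_perm)
  obs$n_perm <- n_perm
  obs
}

#' Per-SNP variant of the enrichment chain
#'
#' Same logic as the window chain but on SNPs directly: empirical P values
#' over valid |iHS| scores, peak SNPs from the association thresholds, and a
#' circular shift over the genome-wide SNP sequence.
#'
#' @param ihs_table iHS tibble from [ihs_scan()].
#' @param assoc association tibble.
#' @param tails tail thresholds.
#' @param p_thresh,maf_min GWAS peak thresholds (strict, as in
#'   [call_gwas_peak_windows()]).
#' @param n_perm,seed permutation settings.
#' @return tibble as in [permutation_test()].
#' @export
snp_enrichment <- function(ihs_table, assoc,
                           tails = c(0.10, 0.05, 0.025, 0.01),
                           p_thresh = 1e-4, maf_min = 0.1,
                           n_perm = 1000, seed = 1L) {
  stat <- ifelse(ihs_table$valid, abs(ihs_table$ihs), NA_real_)
  snp_windows <- tibble(
    chrom = ihs_table$chrom, start = ihs_table$pos, end = ihs_table$pos,
    window = seq_len(nrow(ihs_table)) - 1L,
    max_abs_ihs = stat, emp_p = empirical_p(stat)
  )
  hit_ids <- assoc$id[assoc$pvalue < p_thresh & assoc$maf > maf_min]
  snp_windows$is_gwas_peak <- ihs_table$id %in% hit_ids
  permutation_test(snp_windows, tails = tails, n_perm = n_perm, seed = seed)
}

#' End-to-end enrichment report for one phenotype
#'
#' Runs the window chain — tiling, window-max statistic, empirical P, peak
#' calls, permutation test — and returns both the annotated window table and
#' the per-tail report.
#'
#' @param panel a [haplotype_panel()].
#' @param ihs_table iHS tibble from [ihs_scan()].
#' @param assoc association tibble from [association_scan()].
#' @param width window width in bp.
#' @param tails tail thresholds.
#' @param p_thresh,maf_min peak thresholds.
#' @param n_perm,seed permutation settings.
#' @param chrom_lengths optional chromosome lengths for the tiling.
#' @return list with `windows` (annotated tibble) and `report` (per-tail
#'   tibble).
#' @export
enrichment_report <- function(panel, ihs_table, assoc, width = 10000,
                              tails = c(0.10, 0.05, 0.025, 0.01),
                              p_thresh = 1e-4, maf_min = 0.1,
                              n_perm = 1000, seed = 1L,
                              chrom_lengths = NULL) {
  windows <- build_windows(panel, width = width,
                           chrom_lengths = chrom_lengths) |>
    window_max_stat(ihs_table) |>
    call_gwas_peak_windows(assoc, p_thresh = p_thresh, maf_min = maf_min)
  report <- permutation_test(windows, tails = tails, n_perm = n_perm,
                             seed = seed)
  list(windows = windows, report = report)
}

#' Rank a focal phenotype's enrichment against a comparison panel
#'
#' Stacks per-tail enrichment reports for the focal phenotype and a set of
#' comparison phenotypes analyzed on the same window grid, and ranks
#' phenotypes per tail by fold enrichment (descending, minimum rank on
#' ties); the permutation P accompanies each row.
#'
#' @param reports named list of per-tail report tibbles (from
#'   [permutation_test()] or [enrichment_report()]`$report`); the first is
#'   the focal phenotype.
#' @return tibble with `phenotype`, `tail`, `fold`, `perm_p`, `rank`, and
#'   `is_focal`.
#' @export
phenotype_panel_comparison <- function(reports) {
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    names(reports) <- c("focal", paste0("null_",
                                        seq_len(length(reports) - 1)))[
                                          seq_along(reports)]
  }
  tabs <- purrr::imap(reports, function(r, nm) {
    dplyr::mutate(r[, c("tail", "fold", "perm_p")], phenotype = nm)
  })
  out <- dplyr::bind_rows(tabs)
  focal <- names(reports)[1]
  out <- out |>
    dplyr::group_by(.data$tail) |>
    dplyr::mutate(rank = rank(-.data$fold, ties.method = "min")) |>
    dplyr::ungroup() |>
    dplyr::mutate(is_focal = .data$phenotype == focal) |>
    dplyr::select("phenotype", "tail", "fold", "perm_p", "rank", "is_focal")
  out
}

#' Read / write the window TSV and enrichment report
#'
#' @param path file path.
#' @return [read_windows()]: the window tibble.
#' @export
read_windows <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_windows
#' @param windows window tibble to write.
#' @export
write_windows <- function(windows, path) {
  readr::write_tsv(windows, path)
  invisible(path)
}

#' @rdname read_windows
#' @param report per-tail report tibble to write.
#' @export
write_enrichment <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
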