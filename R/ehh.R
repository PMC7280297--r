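#' Extended haplotype homozygosity around a core SNP
#'
#' EHH at distance `d` is the probability that two randomly chosen
#' haplotypes carrying the specified core allele are identical over the
#' whole interval from the core out to `d`. Walking outward SNP by SNP,
#' carriers are partitioned into groups with identical haplotypes over the
#' interval, and `EHH = sum_h C(n_h, 2) / C(n_a, 2)`. The walk stops on each
#' side when EHH drops below `ehh_cutoff` (the first sub-cutoff point is
#' kept) or the chromosome ends, which sets the truncation flag for that
#' side.
#'
#' @param panel a [haplotype_panel()] (single chromosome at the core's
#'   chromosome is assumed; other chromosomes are ignored).
#' @param core_index SNP column index of the core.
#' @param allele which core allele to follow: 1 = derived, 0 = ancestral.
#' @param ehh_cutoff decay cutoff (default 0.05).
#' @return object of class `ehh_profile`: tibble `profile` with columns
#'   `pos`, `ehh`, `side` (ordered left to right, one row at the core with
#'   `ehh = 1`), plus `core_index`, `allele`, `n_carriers`,
#'   `truncated_left`, `truncated_right`.
#' @export
compute_ehh <- function(panel, core_index, allele = 1L, ehh_cutoff = 0.05) {
  on_chrom <- panel$snps$chrom == panel$snps$chrom[core_index]
  carriers <- which(panel$alleles[, core_index] == allele & TRUE)
  n_a <- length(carriers)
  if (n_a < 2) abort("EHH undefined: fewer than 2 carriers of the core allele")
  H <- panel$alleles[carriers, on_chrom, drop = FALSE]
  pos <- panel$snps$pos[on_chrom]
  core <- sum(on_chrom[seq_len(core_index)])
  m <- ncol(H)

  walk <- function(step_idx) {
    # step_idx: SNP indices in walking order away from the core
    grp <- rep(1L, n_a)
    out_pos <- numeric(0)
    out_ehh <- numeric(0)
    truncated <- TRUE
    for (j in step_idx) {
      key <- grp * 2L + H[, j]
      grp <- match(key, unique(key))
      sizes <- tabulate(grp)
      ehh <- sum(sizes * (sizes - 1) / 2) / (n_a * (n_a - 1) / 2)
      out_pos <- c(out_pos, pos[j])
      out_ehh <- c(out_ehh, ehh)
      if (ehh < ehh_cutoff) {
        truncated <- FALSE
        break
      }
    }
    if (length(step_idx) == 0) truncated <- TRUE
    list(pos = out_pos, ehh = out_ehh, truncated = truncated)
  }

  right <- walk(if (core < m) seq(core + 1L, m) else integer(0))
  left <- walk(if (core > 1) seq(core - 1L, 1L) else integer(0))

  profile <- tibble(
    pos = c(rev(left$pos), pos[core], right$pos),
    ehh = c(rev(left$ehh), 1, right$ehh),
    side = c(rep("left", length(left$pos)), "core",
             rep("right", length(right$pos)))
  )
  structure(
    list(profile = profile, core_index = core_index,
         core_pos = pos[core], allele = allele, n_carriers = n_a,
         truncated_left = left$truncated, truncated_right = right$truncated),
    class = "ehh_profile"
  )
}

#' @export
print.ehh_profile <- function(x, ...) {
  cat("<ehh_profile> core at", x$core_pos, "bp, allele", x$allele,
      "(", x$n_carriers, "carriers )\n")
  cat("  span:", min(x$profile$pos), "-", max(x$profile$pos), "bp;",
      "truncated:", x$truncated_left, "(L)", x$truncated_right, "(R)\n")
  invisible(x)
}

#' Integrate an EHH profile to iHH
#'
#' Trapezoid rule over the (position, EHH) pairs on each side of the core,
#' summed, in base pairs. Where the walk ended by crossing the cutoff the
#' final segment is included down to its last computed point; no
#' extrapolation below the last SNP. A profile truncated at a chromosome
#' border is invalid under the default policy (`NA` returned) or integrated
#' to the border under `truncation = "integrate"`.
#'
#' @param profile an `ehh_profile` from [compute_ehh()].
#' @param truncation `"discard"` (default) or `"integrate"`.
#' @return iHH in bp, or `NA_real_` for a discarded truncated profile.
#' @export
integrate_ihh <- function(profile, truncation = c("discard", "integrate")) {
  truncation <- match.arg(truncation)
  if ((profile$truncated_left || profile$truncated_right) &&
      truncation == "discard") {
    return(NA_real_)
  }
  pr <- profile$profile
  trapz <- function(pos, ehh) {
    if (length(pos) < 2) return(0)
    sum(diff(pos) * (utils::head(ehh, -1) + utils::tail(ehh, -1)) / 2)
  }
  core_row <- which(pr$side == "core")
  left <- pr[seq_len(core_row), ]
  right <- pr[seq(core_row, nrow(pr)), ]
  trapz(left$pos, left$ehh) + trapz(right$pos, right$ehh)
}

#' Raw (unstandardized) iHS
#'
#' `ln(iHH_ancestral / iHH_derived)`: negative when the derived allele sits
#' on the longer haplotype.
#'
#' @param ihh_a,ihh_d integrated EHH for the ancestral / derived allele (bp).
#' @return the log ratio, or `NA_real_` when either argument is not a
#'   positive finite number.
#' @export
raw_ihs <- function(ihh_a, ihh_d) {
  out <- log(ihh_a / ihh_d)
  out[!is.finite(out) | ihh_a <= 0 | ihh_d <= 0] <- NA_real_
  out
}

#' Standardize iHS within derived-frequency bins
#'
#' Raw scores are binned on derived-allele frequency (`[k w, (k+1) w)`,
#' default width 0.025) and, within each bin, centered on the bin mean and
#' scaled by the bin population SD (denominator `n`), so every occupied bin
#' has exactly mean 0 and SD 1. Bins with fewer than 2 valid scores, or zero
#' SD, leave their members invalid.
#'
#' @param uni_hs raw scores (may contain `NA`).
#' @param p_derived derived-allele frequencies, same length.
#' @param bin_width frequency bin width (default 0.025).
#' @return tibble with `uni_hs`, `p_derived`, `freq_bin`, `ihs`, `valid`.
#' @export
standardize_ihs <- function(uni_hs, p_derived, bin_width = 0.025) {
  # tiny epsilon guards against p/w landing just below an integer in
  # floating point (e.g. 0.3/0.025); boundary frequencies stay in bin k
  bin <- pmin(floor(p_derived / bin_width + 1e-9),
              ceiling(1 / bin_width) - 1L)
  ihs <- rep(NA_real_, length(uni_hs))
  valid <- !is.na(uni_hs)
  for (b in unique(bin[valid])) {
    sel <- valid & bin == b
    x <- uni_hs[sel]
    if (length(x) < 2) {
      valid[sel] <- FALSE
      hs_log("standardize_ihs: bin ", b, " has <2 scores, flagged invalid")
      next
    }
    mu <- mean(x)
    sdp <- sqrt(mean((x - mu)^2))
    if (sdp == 0) {
      valid[sel] <- FALSE
      hs_log("standardize_ihs: bin ", b, " has zero SD, flagged invalid")
      next
    }
    ihs[sel] <- (x - mu) / sdp
  }
  valid <- valid & !is.na(ihs)
  tibble(uni_hs = uni_hs, p_derived = p_derived, freq_bin = bin,
         ihs = ihs, valid = valid)
}

#' Genome-wide iHS scan
#'
#' For every SNP with derived-allele frequency in
#' `[min_freq, 1 - min_freq]` (and at least two carriers of each allele),
#' computes integrated EHH for both alleles with the compiled walker, the
#' raw log-ratio score, and the frequency-bin standardized iHS. SNPs whose
#' EHH walk hits a chromosome border before decaying below the cutoff are
#' flagged invalid under the default truncation policy.
#'
#' @param panel a polarized [haplotype_panel()].
#' @param ehh_cutoff EHH decay cutoff (default 0.05).
#' @param min_freq minimum derived-allele frequency for scoring
#'   (default 0.05).
#' @param bin_width standardization bin width (default 0.025).
#' @param truncation `"discard"` (default) or `"integrate"` to the border.
#' @return tibble with one row per SNP: `chrom`, `pos`, `id`, `p_derived`,
#'   `ihh_a`, `ihh_d`, `uni_hs`, `freq_bin`, `ihs`, `valid`.
#' @export
ihs_scan <- function(panel, ehh_cutoff = 0.05, min_freq = 0.05,
                     bin_width = 0.025, truncation = c("discard",
                                                       "integrate")) {
  truncation <- match.arg(truncation)
  if (!panel$polarized) {
    warn("ihs_scan: panel is not polarized; treating alt as derived")
  }
  chroms <- unique(panel$snps$chrom)
  res <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    sel <- panel$snps$chrom == chroms[ci]
    H <- panel$alleles[, sel, drop = FALSE]
    sc <- ihh_scan_cpp(H, as.numeric(panel$snps$pos[sel]), ehh_cutoff,
                       min_freq, truncation == "integrate")
    res[[ci]] <- tibble(
      chrom = chroms[ci],
      pos = panel$snps$pos[sel],
      id = panel$snps$id[sel],
      p_derived = sc$freq,
      ihh_a = sc$ihh_a,
      ihh_d = sc$ihh_d,
      scored = sc$scored
    )
  }
  out <- dplyr::bind_rows(res)
  out$ihh_a[!out$scored] <- NA_real_
  out$ihh_d[!out$scored] <- NA_real_
  uni <- raw_ihs(out$ihh_a, out$ihh_d)
  std <- standardize_ihs(uni, out$p_derived, bin_width = bin_width)
  out$uni_hs <- std$uni_hs
  out$freq_bin <- std$freq_bin
  out$ihs <- std$ihs
  out$valid <- std$valid
  out$scored <- NULL
  out
}

#' Read / write the iHS TSV
#'
#' Dialect: TSV with header `chrom`, `pos`, `id`, `p_derived`, `ihh_a`,
#' `ihh_d`, `uni_hs`, `freq_bin`, `ihs`, `valid`.
#'
#' @param path file path.
#' @return [read_ihs()]: the iHS tibble.
#' @export
read_ihs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    pos = readr::col_integer(),
                    id = readr::col_character(),
                    p_derived = readr::col_double(),
                    ihh_a = readr::col_double(),
                    ihh_d = readr::col_double(),
                    uni_hs = readr::col_double(),
                    freq_bin = readr::col_integer(),
                    ihs = readr::col_double(),
                    valid = readr::col_logical()
                  ))
}

#' @rdname read_ihs
#' @param ihs_table iHS tibble to write.
#' @export
write_ihs <- function(ihs_table, path) {
  readr::write_tsv(ihs_table, path)
  invisible(path)
}
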