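#' Manhattan plot of an association scan
#'
#' @param assoc association tibble from [association_scan()].
#' @param p_thresh horizontal reference line (default the nominal Bonferroni
#'   threshold `0.05 / nrow(assoc)`).
#' @return a ggplot object.
#' @export
plot_manhattan <- function(assoc, p_thresh = 0.05 / nrow(assoc)) {
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$pos / 1e6,
                                      y = -log10(.data$pvalue),
                                      colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_thresh), linetype = "dashed") +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
}

#' Q-Q plot of association P values
#'
#' @param results association tibble or numeric P values (see
#'   [qq_and_lambda()]).
#' @return a ggplot object annotated with the genomic inflation factor.
#' @export
plot_qq <- function(results) {
  ql <- qq_and_lambda(results)
  ggplot2::ggplot(ql$qq, ggplot2::aes(x = .data$expected,
                                      y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(expected ~ -log[10](italic(P))),
      y = expression(observed ~ -log[10](italic(P))),
      subtitle = sprintf("lambda[GC] = %.3f", ql$lambda_gc)
    ) +
    ggplot2::theme_minimal()
}

#' EHH decay curves for both core alleles
#'
#' Plots the EHH profile of the derived (long-haplotype candidate) and
#' ancestral allele around a core SNP.
#'
#' @param panel a [haplotype_panel()].
#' @param core_index core SNP column index.
#' @param ehh_cutoff decay cutoff passed to [compute_ehh()].
#' @return a ggplot object.
#' @export
plot_ehh <- function(panel, core_index, ehh_cutoff = 0.05) {
  prof_d <- compute_ehh(panel, core_index, allele = 1L,
                        ehh_cutoff = ehh_cutoff)
  prof_a <- compute_ehh(panel, core_index, allele = 0L,
                        ehh_cutoff = ehh_cutoff)
  df <- dplyr::bind_rows(
    dplyr::mutate(prof_d$profile, allele = "derived"),
    dplyr::mutate(prof_a$profile, allele = "ancestral")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$ehh,
                                   colour = .data$allele)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = prof_d$core_pos / 1e6,
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(derived = "#c0392b",
                                            ancestral = "#2980b9")) +
    ggplot2::labs(x = "position (Mb)", y = "EHH") +
    ggplot2::theme_minimal()
}

#' Fold-enrichment curves across iHS tails
#'
#' One line per phenotype, fold enrichment against the tail threshold —
#' the multi-phenotype comparison view.
#'
#' @param comparison tibble from [phenotype_panel_comparison()].
#' @return a ggplot object.
#' @export
plot_enrichment <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$tail, y = .data$fold,
                               group = .data$phenotype,
                               colour = .data$is_focal)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_reverse(breaks = c(0.10, 0.05, 0.025, 0.01)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey50"),
                                 guide = "none") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "iHS empirical-P tail threshold",
                  y = "fold enrichment of GWAS-peak windows") +
    ggplot2::theme_minimal()
}

#' @method autoplot ehh_profile
#' @export
autoplot.ehh_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$pos / 1e6, y = .data$ehh)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$core_pos / 1e6,
                        linetype = "dotted") +
    ggplot2::labs(x = "position (Mb)", y = "EHH") +
    ggplot2::theme_minimal()
}
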