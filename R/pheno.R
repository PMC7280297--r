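#' Drop flowers with implausibly low counts
#'
#' Flowers with very few counted grains usually reflect unopened anthers
#' rather than genetics; rows with `count < min_count` are removed (strict
#' inequality: a count equal to the threshold survives). Removals are logged
#' per accession.
#'
#' @param flowers tibble with columns `accession`, `plant`, `flower`,
#'   `batch`, `count`.
#' @param min_count threshold (default 10).
#' @return the filtered tibble.
#' @export
filter_low_counts <- function(flowers, min_count = 10) {
  drop <- flowers$count < min_count
  if (any(drop)) {
    per_acc <- table(flowers$accession[drop])
    hs_log("filter_low_counts: removed ", sum(drop), " flower(s) across ",
           length(per_acc), " accession(s)")
    gone <- setdiff(unique(flowers$accession),
                    unique(flowers$accession[!drop]))
    if (length(gone) > 0) {
      warn(paste0("filter_low_counts: accession(s) lost entirely: ",
                  paste(gone, collapse = ", ")))
    }
  }
  flowers[!drop, , drop = FALSE]
}

#' Harmonize batches to a common median and SD
#'
#' Removes an affine location/scale batch artifact by mapping each batch onto
#' pooled statistics: `x' = (x - median_b) / sd_b * sd_pooled +
#' median_pooled`. The pooled median is the median of the combined raw data;
#' the pooled SD is the pooled within-batch sample SD (the usual pooled
#' variance estimator, `sqrt(sum((n_b - 1) sd_b^2) / sum(n_b - 1))`), which
#' makes the transform exactly idempotent. Afterwards every batch has the
#' same median and the same sample SD (n-1 denominator) to within 1e-9.
#' With a single batch the transform is the identity.
#'
#' @param flowers flower tibble (see [filter_low_counts()]).
#' @param reference `"pooled"` (default) targets the combined data's
#'   statistics; `"batch1"` targets the first batch's.
#' @return tibble with harmonized `count`.
#' @export
harmonize_batches <- function(flowers, reference = c("pooled", "batch1")) {
  reference <- match.arg(reference)
  batches <- sort(unique(flowers$batch))
  if (length(batches) == 1) return(flowers)
  if (reference == "pooled") {
    m_ref <- median(flowers$count)
    per_batch <- vapply(batches, function(b) {
      x <- flowers$count[flowers$batch == b]
      c(var = var(x), df = length(x) - 1)
    }, numeric(2))
    s_ref <- sqrt(sum(per_batch["var", ] * per_batch["df", ]) /
                    sum(per_batch["df", ]))
  } else {
    b1 <- flowers$count[flowers$batch == batches[1]]
    m_ref <- median(b1)
    s_ref <- sd(b1)
  }
  out <- flowers
  for (b in batches) {
    sel <- flowers$batch == b
    s_b <- sd(flowers$count[sel])
    if (!is.finite(s_b) || s_b == 0) {
      abort(paste0("harmonize_batches: batch ", b, " has zero SD"))
    }
    m_b <- median(flowers$count[sel])
    out$count[sel] <- (flowers$count[sel] - m_b) / s_b * s_ref + m_ref
  }
  out
}

#' Summarize flowers to one value per accession
#'
#' The per-accession phenotype is the median of its surviving flower counts,
#' optionally natural-log transformed (the default for GWAS input; the log
#' base only shifts and scales the phenotype, so inference is unchanged, but
#' it is logged for the record).
#'
#' @param flowers flower tibble.
#' @param transform `"log"` (natural log of the median) or `"none"`.
#' @return tibble with columns `accession`, `value`, `n_flowers`.
#' @export
summarize_accessions <- function(flowers, transform = c("log", "none")) {
  transform <- match.arg(transform)
  if (nrow(flowers) == 0) abort("empty flower table")
  out <- flowers |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(value = median(.data$count),
                     n_flowers = dplyr::n(), .groups = "drop")
  if (transform == "log") {
    bad <- out$accession[out$value <= 0]
    if (length(bad) > 0) {
      abort(paste0("non-positive median under log transform for: ",
                   paste(bad, collapse = ", ")))
    }
    out$value <- log(out$value)
    hs_log("summarize_accessions: natural log of per-accession medians")
  }
  out
}

#' Flower counts to GWAS-ready accession phenotypes
#'
#' Fixed preprocessing order: low-count filter, batch harmonization, then
#' per-accession median and log transform. The order matters (harmonizing
#' before filtering would let artefactual near-zero flowers distort the batch
#' statistics) and is logged.
#'
#' @param flowers flower tibble.
#' @param min_count low-count threshold (default 10).
#' @param transform passed to [summarize_accessions()].
#' @param reference passed to [harmonize_batches()].
#' @return accession-level tibble (`accession`, `value`, `n_flowers`).
#' @export
prep_phenotypes <- function(flowers, min_count = 10,
                            transform = c("log", "none"),
                            reference = c("pooled", "batch1")) {
  hs_log("prep_phenotypes: filter -> harmonize -> summarize")
  flowers |>
    filter_low_counts(min_count = min_count) |>
    harmonize_batches(reference = reference) |>
    summarize_accessions(transform = transform)
}

#' Read / write the flower-level phenotype TSV
#'
#' Dialect: TSV with header `accession`, `plant`, `flower`, `batch`,
#' `count`.
#'
#' @param path file path.
#' @return [read_phenotypes()]: the flower tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    accession = readr::col_character(),
                    plant = readr::col_integer(),
                    flower = readr::col_integer(),
                    batch = readr::col_integer(),
                    count = readr::col_double()
                  ))
}

#' @rdname read_phenotypes
#' @param flowers flower tibble to write.
#' @export
write_phenotypes <- function(flowers, path) {
  readr::write_tsv(flowers, path)
  invisible(path)
}
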