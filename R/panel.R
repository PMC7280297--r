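#' Haplotype panel container
#'
#' A `haplotype_panel` holds one 0/1 haplotype per inbred accession together
#' with per-SNP metadata. Allele coding is 0 = ancestral, 1 = derived when the
#' panel has been polarized against an outgroup table (see
#' [polarize_alleles()]); otherwise 0 = reference, 1 = alternate and the
#' `polarized` flag is `FALSE`.
#'
#' @param alleles integer matrix, accessions x SNPs, entries in `{0, 1}`,
#'   no missing values.
#' @param snps tibble with one row per SNP and columns `chrom`, `pos`
#'   (1-based bp), `id`, `ref`, `alt`, `ancestral` (one of `ref`/`alt`
#'   nucleotide or `NA` for unknown). Positions must be strictly increasing
#'   within each chromosome.
#' @param samples character vector of unique accession identifiers, one per
#'   matrix row.
#' @param polarized logical flag: `TRUE` when column coding is
#'   ancestral/derived.
#'
#' @return An object of class `haplotype_panel`.
#' @examples
#' p <- haplotype_panel(
#'   alleles = rbind(c(0L, 1L, 1L), c(1L, 0L, 1L)),
#'   snps = snp_meta("1", c(100L, 200L, 300L), "A", "T"),
#'   samples = c("acc1", "acc2")
#' )
#' p
#' @export
haplotype_panel <- function(alleles, snps, samples, polarized = FALSE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (anyNA(alleles)) abort("haplotype panel may not contain missing alleles")
  if (!all(alleles %in% c(0L, 1L))) {
    abort("haplotype alleles must all be 0 or 1")
  }
  snps <- as_tibble(snps)
  if (nrow(snps) != ncol(alleles)) {
    abort("number of SNP metadata rows must match allele matrix columns")
  }
  samples <- as.character(samples)
  if (length(samples) != nrow(alleles)) {
    abort("number of samples must match allele matrix rows")
  }
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample id: ",
                 samples[duplicated(samples)][1]))
  }
  check_sorted_positions(snps)
  dimnames(alleles) <- list(samples, snps$id)
  structure(
    list(alleles = alleles, snps = snps, samples = samples,
         polarized = isTRUE(polarized)),
    class = "haplotype_panel"
  )
}

check_sorted_positions <- function(snps) {
  for (ch in unique(snps$chrom)) {
    pos <- snps$pos[snps$chrom == ch]
    bad <- which(diff(pos) <= 0)
    if (length(bad) > 0) {
      abort(paste0("SNP positions not strictly increasing on chromosome ",
                   ch, " at index ", bad[1] + 1L))
    }
  }
  invisible(TRUE)
}

#' Build a SNP metadata tibble
#'
#' Convenience constructor for the per-SNP metadata used by
#' [haplotype_panel()]. SNP ids follow the `"chrom-pos"` dialect
#' (e.g. `"1-8852112"`).
#'
#' @param chrom chromosome labels (recycled).
#' @param pos 1-based physical positions in bp.
#' @param ref,alt reference/alternate nucleotides (recycled).
#' @param ancestral ancestral nucleotide, `NA` when unknown (recycled).
#' @return tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`, `ancestral`.
#' @export
snp_meta <- function(chrom, pos, ref = "A", alt = "T", ancestral = NA) {
  n <- length(pos)
  tibble(
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    id = paste0(rep_len(as.character(chrom), n), "-", as.integer(pos)),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    ancestral = rep_len(as.character(ancestral), n)
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", length(x$samples), " accessions x ",
      nrow(x$snps), " SNPs\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$snps$chrom), collapse = ", "), "\n",
      sep = "")
  cat("  coding: ", if (x$polarized) "ancestral(0)/derived(1)"
      else "ref(0)/alt(1), unpolarized", "\n", sep = "")
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

#' Derived-allele frequency per SNP
#'
#' @param panel a [haplotype_panel()].
#' @return numeric vector, one frequency per SNP (frequency of allele 1,
#'   i.e. the derived allele on polarized panels).
#' @export
derived_freq <- function(panel) {
  colMeans(panel$alleles)
}

#' Subset a haplotype panel by SNP index
#'
#' @param panel a [haplotype_panel()].
#' @param snp_idx integer vector of SNP column indices to keep (in order).
#' @return a [haplotype_panel()] restricted to the selected SNPs.
#' @export
subset_snps <- function(panel, snp_idx) {
  haplotype_panel(panel$alleles[, snp_idx, drop = FALSE],
                  panel$snps[snp_idx, ], panel$samples,
                  polarized = panel$polarized)
}

# ---------------------------------------------------------------------------
# readers / writers

#' Read a haplotype panel from VCF or hap/legend TSV
#'
#' Two dialects are supported. A diploid VCF of an inbred panel collapses to
#' one haplotype per accession: sites with any heterozygous or missing call
#' are dropped (the count is logged). A hap/legend pair stores the matrix
#' directly: `legend` is a TSV with columns `chrom`, `pos`, `ref`, `alt`,
#' `ancestral`, and `hap` holds whitespace-separated 0/1 rows, one row per
#' accession.
#'
#' When `ancestral_table` is supplied the panel is polarized with
#' [polarize_alleles()]; otherwise coding stays ref = 0 / alt = 1 and the
#' returned panel carries `polarized = FALSE`.
#'
#' @param path path to a `.vcf` file, or to the hap file of a hap/legend pair.
#' @param legend path to the legend TSV (hap/legend dialect only). Defaults to
#'   `path` with a `.legend.tsv` suffix.
#' @param samples accession ids for the hap dialect (defaults to `hap_1..n`).
#' @param ancestral_table optional tibble or TSV path with columns `chrom`,
#'   `pos`, `ancestral` used to polarize alleles.
#' @param unknown_policy how to treat SNPs with unknown ancestral state when
#'   polarizing: `"drop"` (default) or `"keep_ref"`.
#' @return a [haplotype_panel()].
#' @export
read_haplotypes <- function(path, legend = NULL, samples = NULL,
                            ancestral_table = NULL,
                            unknown_policy = c("drop", "keep_ref")) {
  unknown_policy <- match.arg(unknown_policy)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)
  panel <- if (is_vcf) {
    read_panel_vcf(path)
  } else {
    read_panel_haplegend(path, legend, samples)
  }
  if (!is.null(ancestral_table)) {
    if (is.character(ancestral_table)) {
      ancestral_table <- readr::read_tsv(ancestral_table,
                                         show_col_types = FALSE)
    }
    panel <- polarize_alleles(panel, ancestral_table,
                              unknown_policy = unknown_policy)
  }
  panel
}

read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  # normalise separators; inbred panels must be homozygous at retained sites
  gt_clean <- gsub("\\|", "/", gt)
  gt_clean[is.na(gt_clean)] <- "."
  hom_ref <- gt_clean == "0/0" | gt_clean == "0"
  hom_alt <- gt_clean == "1/1" | gt_clean == "1"
  ok_site <- apply(hom_ref | hom_alt, 1, all) & !is.na(fix$POS)
  n_drop <- sum(!ok_site)
  if (n_drop > 0) {
    hs_log("read_haplotypes: dropped ", n_drop,
           " site(s) with heterozygous or missing genotypes")
  }
  if (!any(ok_site)) abort("no sites remain after filtering genotypes")
  alleles <- t(ifelse(hom_alt[ok_site, , drop = FALSE], 1L, 0L))
  snps <- tibble(
    chrom = fix$CHROM[ok_site],
    pos = as.integer(fix$POS[ok_site]),
    id = paste0(fix$CHROM[ok_site], "-", as.integer(fix$POS[ok_site])),
    ref = fix$REF[ok_site],
    alt = fix$ALT[ok_site],
    ancestral = NA_character_
  )
  haplotype_panel(alleles, snps, colnames(gt), polarized = FALSE)
}

default_legend_path <- function(path) {
  paste0(sub("\\.hap(\\.tsv)?$", "", path), ".legend.tsv")
}

read_panel_haplegend <- function(path, legend = NULL, samples = NULL) {
  if (is.null(legend)) legend <- default_legend_path(path)
  leg <- readr::read_tsv(legend, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           pos = readr::col_integer(),
                           ref = readr::col_character(),
                           alt = readr::col_character(),
                           ancestral = readr::col_character()
                         ))
  rows <- readLines(path)
  rows <- rows[nzchar(rows)]
  alleles <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"),
                                   as.integer))
  if (is.null(samples)) samples <- paste0("hap_", seq_len(nrow(alleles)))
  snps <- tibble(
    chrom = leg$chrom, pos = leg$pos,
    id = paste0(leg$chrom, "-", leg$pos),
    ref = leg$ref, alt = leg$alt, ancestral = leg$ancestral
  )
  # hap/legend written by write_haplotypes is already ancestral/derived coded
  polarized <- all(!is.na(leg$ancestral)) &&
    all(leg$ancestral == leg$ref)
  haplotype_panel(alleles, snps, samples, polarized = polarized)
}

#' Write a haplotype panel
#'
#' Emits either the hap/legend TSV pair (exact 0/1 round trip) or a minimal
#' VCF v4.2 in which each haplotype is written as a homozygous diploid
#' genotype, the inbred-panel convention consumed by [read_haplotypes()].
#'
#' @param panel a [haplotype_panel()].
#' @param path output path; dialect chosen by extension (`.vcf` for VCF,
#'   anything else is treated as the hap file of a hap/legend pair).
#' @param legend legend path for the hap/legend dialect (default: `path`
#'   with any `.hap`/`.hap.tsv` suffix replaced by `.legend.tsv`).
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(panel, path, legend = NULL) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    write_panel_vcf(panel, path)
  } else {
    if (is.null(legend)) legend <- default_legend_path(path)
    leg <- panel$snps
    if (panel$polarized) leg$ancestral <- leg$ref
    readr::write_tsv(leg[, c("chrom", "pos", "ref", "alt", "ancestral")],
                     legend)
    writeLines(apply(panel$alleles, 1, paste, collapse = " "), path)
  }
  invisible(path)
}

write_panel_vcf <- function(panel, path) {
  gt <- t(panel$alleles)
  body <- matrix(ifelse(gt == 1L, "1|1", "0|0"), nrow = nrow(gt))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=hapsweep",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  rows <- paste(panel$snps$chrom, panel$snps$pos, panel$snps$id,
                panel$snps$ref, panel$snps$alt, ".", "PASS", ".", "GT",
                apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# polarization & validation

#' Polarize alleles to ancestral/derived coding
#'
#' Recodes a ref/alt panel so that 0 means ancestral and 1 means derived,
#' using an outgroup-inferred ancestral-state table. Columns whose ancestral
#' allele equals the alternate allele are bit-flipped; columns with unknown
#' ancestral state (or absent from the table) are dropped by default.
#'
#' @param panel a ref/alt-coded [haplotype_panel()].
#' @param ancestral_table tibble with columns `chrom`, `pos`, `ancestral`
#'   (nucleotide, or `NA` for unknown).
#' @param unknown_policy `"drop"` (default) removes SNPs with unknown
#'   ancestral state; `"keep_ref"` keeps them coded ref = 0.
#' @return a polarized [haplotype_panel()].
#' @export
polarize_alleles <- function(panel, ancestral_table,
                             unknown_policy = c("drop", "keep_ref")) {
  unknown_policy <- match.arg(unknown_policy)
  ancestral_table <- as_tibble(ancestral_table)
  key <- paste(panel$snps$chrom, panel$snps$pos)
  tkey <- paste(ancestral_table$chrom, ancestral_table$pos)
  anc <- ancestral_table$ancestral[match(key, tkey)]
  n_missing <- sum(is.na(match(key, tkey)))
  if (n_missing > 0) {
    hs_log("polarize_alleles: ", n_missing,
           " SNP(s) absent from ancestral table, treated as unknown")
  }
  is_ref <- !is.na(anc) & anc == panel$snps$ref
  is_alt <- !is.na(anc) & anc == panel$snps$alt
  unknown <- !is_ref & !is_alt

  alleles <- panel$alleles
  alleles[, is_alt] <- 1L - alleles[, is_alt, drop = FALSE]
  snps <- panel$snps
  snps$ancestral <- ifelse(is_ref, snps$ref, ifelse(is_alt, snps$alt,
                                                    NA_character_))
  # after flipping, allele 0 is ancestral: swap ref/alt labels on flips
  tmp_ref <- snps$ref
  snps$ref[is_alt] <- snps$alt[is_alt]
  snps$alt[is_alt] <- tmp_ref[is_alt]

  if (unknown_policy == "drop" && any(unknown)) {
    hs_log("polarize_alleles: dropped ", sum(unknown),
           " SNP(s) with unknown ancestral state")
    alleles <- alleles[, !unknown, drop = FALSE]
    snps <- snps[!unknown, ]
  }
  haplotype_panel(alleles, snps, panel$samples, polarized = TRUE)
}

#' Validate a panel / phenotype pair
#'
#' Reports dataset summaries and invariant violations without mutating
#' anything: shared accession count, per-chromosome SNP counts, a
#' derived-frequency histogram, and a character vector of violated
#' invariants (empty when the dataset is clean).
#'
#' @param panel a [haplotype_panel()].
#' @param phenotypes a flower-level phenotype tibble with columns
#'   `accession`, `plant`, `flower`, `batch`, `count`.
#' @return a list with elements `n_shared`, `snps_per_chrom`,
#'   `freq_histogram`, `errors`, `warnings`.
#' @export
validate_dataset <- function(panel, phenotypes) {
  errors <- character()
  warnings <- character()
  raw <- panel$alleles
  if (!all(raw %in% c(0L, 1L))) {
    errors <- c(errors, "allele matrix contains entries outside {0,1}")
  }
  pos_ok <- tryCatch({check_sorted_positions(panel$snps); TRUE},
                     error = function(e) FALSE)
  if (!pos_ok) errors <- c(errors, "SNP positions not strictly increasing")
  if (anyDuplicated(panel$samples)) {
    errors <- c(errors, "duplicate sample ids")
  }
  if (nrow(phenotypes) > 0) {
    if (any(phenotypes$count < 0)) {
      errors <- c(errors, "negative phenotype counts")
    }
    if (any(is.na(phenotypes$batch))) {
      errors <- c(errors, "phenotype rows without batch label")
    }
  } else {
    warnings <- c(warnings, "phenotype table is empty")
  }
  shared <- intersect(panel$samples, unique(phenotypes$accession))
  freqs <- colMeans(raw)
  list(
    n_shared = length(shared),
    snps_per_chrom = table(panel$snps$chrom),
    freq_histogram = table(cut(freqs, breaks = seq(0, 1, by = 0.05),
                               include.lowest = TRUE)),
    errors = errors,
    warnings = warnings
  )
}
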