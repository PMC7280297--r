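test_that("generators are bit-reproducible given (config, seed)", {
  cfg <- sim_config(n_accessions = 20, n_snps = 60, chrom_length = 1e5,
                    seed = 42L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$panel$alleles, b$panel$alleles)
  expect_identical(a$flowers, b$flowers)
  expect_identical(a$truth$carriers, b$truth$carriers)
})

test_that("without switching or mutation every haplotype equals a founder", {
  cfg <- sim_config(n_accessions = 30, n_founders = 4, n_snps = 40,
                    chrom_length = 1e5, switch_rate = 0, mutation_rate = 0,
                    sweep = NULL, seed = 7L)
  panel <- simulate_founder_mosaic(cfg)
  expect_lte(nrow(unique(panel$alleles)), 4L)
})

test_that("a single founder yields identical, monomorphic haplotypes", {
  cfg <- sim_config(n_accessions = 10, n_founders = 1, n_snps = 30,
                    chrom_length = 1e5, mutation_rate = 0, sweep = NULL,
                    seed = 8L)
  panel <- simulate_founder_mosaic(cfg)
  expect_equal(nrow(unique(panel$alleles)), 1L)
  expect_true(all(derived_freq(panel) %in% c(0, 1)))
})

test_that("adjacent-SNP allele correlation decays with the switch rate", {
  adj_cor <- function(switch_rate, seed) {
    cfg <- sim_config(n_accessions = 10000, n_founders = 2, n_snps = 40,
                      chrom_length = 4e5, switch_rate = switch_rate,
                      mutation_rate = 0, sweep = NULL, seed = seed)
    panel <- simulate_founder_mosaic(cfg)
    X <- panel$alleles
    keep <- apply(X, 2, sd) > 0
    X <- X[, keep]
    cors <- vapply(seq_len(ncol(X) - 1),
                   function(j) cor(X[, j], X[, j + 1]), numeric(1))
    mean(abs(cors))
  }
  # at >= 1 expected switch per gap the founder choice decorrelates and the
  # large-sample correlation approaches the unlinked expectation (zero);
  # with no switching, samples stay on one founder and correlation is high
  expect_lt(adj_cor(switch_rate = 1e-3, seed = 21L), 0.08)
  expect_gt(adj_cor(switch_rate = 0, seed = 22L), 0.4)
})

test_that("an uneroded sweep makes all carriers share the donor haplotype", {
  cfg <- sim_config(n_accessions = 20, n_snps = 100, chrom_length = 2e5,
                    sweep = NULL, seed = 10L)
  panel <- simulate_founder_mosaic(cfg)
  sw <- inject_sweep(panel, core_pos = 1e5, f = 0.5, erosion_mean = 1e12,
                     seed = 3L)
  carriers <- match(sw$truth$carriers, sw$panel$samples)
  donor <- match(sw$truth$donor, sw$panel$samples)
  hap <- sw$panel$alleles[donor, ]
  for (i in carriers) {
    expect_identical(unname(sw$panel$alleles[i, ]), unname(hap))
  }
  # derived-allele EHH stays 1 across the whole chromosome
  prof <- compute_ehh(sw$panel, sw$truth$core_index, allele = 1L)
  expect_true(all(prof$profile$ehh == 1))
  expect_true(prof$truncated_left && prof$truncated_right)
})

test_that("carrier count follows the rounding rule and the 2-carrier floor", {
  cfg <- sim_config(n_accessions = 4, n_snps = 50, chrom_length = 1e5,
                    sweep = NULL, seed = 12L)
  panel <- simulate_founder_mosaic(cfg)
  sw <- inject_sweep(panel, 5e4, f = 0.7, erosion_mean = 1e4, seed = 1L)
  expect_length(sw$truth$carriers, 3L)  # round(0.7 * 4) = 3
  expect_equal(unname(derived_freq(sw$panel)[sw$truth$core_index]), 3 / 4)
  expect_error(inject_sweep(panel, 5e4, f = 0.2, erosion_mean = 1e4),
               "EHH undefined")
})

test_that("sweep injection leaves alleles outside the eroded intervals alone", {
  cfg <- sim_config(n_accessions = 30, n_snps = 200, chrom_length = 4e5,
                    sweep = NULL, seed = 14L)
  panel <- simulate_founder_mosaic(cfg)
  sw <- inject_sweep(panel, 2e5, f = 0.3, erosion_mean = 2e4, seed = 5L)
  pos <- panel$snps$pos
  core <- sw$truth$core_index
  changed <- which(panel$alleles != sw$panel$alleles, arr.ind = TRUE)
  carriers <- match(sw$truth$carriers, panel$samples)
  for (r in seq_len(nrow(changed))) {
    i <- changed[r, 1]; j <- changed[r, 2]
    if (j == core) next  # core column is reset for everyone by design
    k <- match(i, carriers)
    expect_false(is.na(k))
    expect_true(pos[j] >= sw$truth$seg_lo[k] && pos[j] <= sw$truth$seg_hi[k])
  }
})

test_that("mean eroded half-length tracks the exponential mean", {
  cfg <- sim_config(n_accessions = 50, n_founders = 20, n_snps = 2000,
                    chrom_length = 1e6, mutation_rate = 0, sweep = NULL,
                    seed = 16L)
  panel <- simulate_founder_mosaic(cfg)
  pos <- panel$snps$pos
  lens <- c()
  for (r in 1:200) {
    sw <- inject_sweep(panel, 5e5, f = 0.3, erosion_mean = 2e4,
                       seed = 100L + r)
    core <- sw$truth$core_index
    carriers <- match(sw$truth$carriers, panel$samples)
    donor_row <- sw$panel$alleles[match(sw$truth$donor, panel$samples), ]
    for (i in carriers) {
      hap <- sw$panel$alleles[i, ]
      mism_r <- which(hap != donor_row & seq_along(hap) > core)
      mism_l <- which(hap != donor_row & seq_along(hap) < core)
      if (length(mism_r) > 0) {
        lens <- c(lens, pos[min(mism_r) - 1L] - pos[core])
      }
      if (length(mism_l) > 0) {
        lens <- c(lens, pos[core] - pos[max(mism_l) + 1L])
      }
    }
  }
  expect_lt(abs(mean(lens) - 2e4) / 2e4, 0.1)
})

test_that("with all noise off, counts are exp(baseline) exactly", {
  cfg <- sim_config(n_accessions = 10, n_snps = 50, chrom_length = 1e5,
                    sweep = NULL,
                    phenotype = list(h2_polygenic = 0, sigma_e = 0,
                                     flower_cv = 0, batch_shift = 0,
                                     batch_scale = 1),
                    seed = 18L)
  panel <- simulate_founder_mosaic(cfg)
  ph <- simulate_phenotypes(panel, NULL, cfg, seed = 2L)
  expect_true(all(ph$flowers$count == exp(log(4000))))
  expect_equal(nrow(ph$flowers), 10 * 4 * 3)
})

test_that("a negative core effect with noise off separates carriers cleanly", {
  cfg <- sim_config(n_accessions = 12, n_snps = 80, chrom_length = 2e5,
                    sweep = NULL,
                    phenotype = list(beta_core = -0.5, h2_polygenic = 0,
                                     sigma_e = 0, flower_cv = 0,
                                     batch_shift = 0, batch_scale = 1),
                    seed = 19L)
  panel <- simulate_founder_mosaic(cfg)
  sw <- inject_sweep(panel, 1e5, f = 0.5, erosion_mean = 1e4, seed = 4L)
  ph <- simulate_phenotypes(sw$panel, sw$truth, cfg, seed = 5L)
  carrier_counts <- ph$flowers$count[ph$flowers$accession %in%
                                       sw$truth$carriers]
  other_counts <- ph$flowers$count[!ph$flowers$accession %in%
                                     sw$truth$carriers]
  expect_lt(max(carrier_counts), min(other_counts))
})

test_that("null phenotype panels share accessions but differ in values", {
  cfg <- sim_config(n_accessions = 15, n_snps = 60, chrom_length = 1e5,
                    sweep = NULL, seed = 20L)
  panel <- simulate_founder_mosaic(cfg)
  nulls <- simulate_null_phenotype_panel(panel, k = 3, cfg, seed = 50L)
  expect_length(nulls, 3L)
  for (tb in nulls) {
    expect_setequal(unique(tb$accession), panel$samples)
  }
  expect_false(identical(nulls[[1]]$count, nulls[[2]]$count))

  quiet <- sim_config(n_accessions = 15, n_snps = 60, chrom_length = 1e5,
                      sweep = NULL,
                      phenotype = list(h2_polygenic = 0, sigma_e = 0,
                                       flower_cv = 0, batch_shift = 0,
                                       batch_scale = 1),
                      seed = 20L)
  one <- simulate_null_phenotype_panel(panel, k = 1, quiet, seed = 51L)
  expect_equal(length(unique(one[[1]]$count)), 1L)
})
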