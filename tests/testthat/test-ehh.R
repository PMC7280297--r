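test_that("EHH equals the grouped-count values on hand-built haplotypes", {
  # 4 carriers split into extended-haplotype groups {2,2} one SNP to the
  # right: EHH = (1 + 1) / C(4,2) = 1/3
  alleles <- rbind(c(1, 0, 0),
                   c(1, 0, 0),
                   c(1, 1, 0),
                   c(1, 1, 1))
  p <- make_panel(alleles, pos = c(1000L, 2000L, 3000L))
  prof <- compute_ehh(p, core_index = 1, allele = 1L, ehh_cutoff = 0)
  expect_equal(prof$profile$ehh[prof$profile$side == "core"], 1)
  expect_equal(prof$profile$ehh[prof$profile$pos == 2000], 1 / 3)
  # groups {2,1,1} two SNPs out -> 1/6
  expect_equal(prof$profile$ehh[prof$profile$pos == 3000], 1 / 6)

  # all carriers pairwise distinct -> EHH 0
  distinct <- rbind(c(1, 0, 0),
                    c(1, 0, 1),
                    c(1, 1, 0),
                    c(1, 1, 1))
  p2 <- make_panel(distinct, pos = c(1000L, 2000L, 3000L))
  prof2 <- compute_ehh(p2, 1, allele = 1L)
  expect_equal(prof2$profile$ehh[prof2$profile$pos == 3000], 0)

  expect_error(compute_ehh(make_panel(rbind(c(1, 0), c(0, 0))), 1, 1L),
               "EHH undefined")
})

test_that("grouped-count EHH matches the exhaustive pairwise oracle", {
  for (seed in 1:40) {
    n <- sample(4:12, 1)
    m <- sample(5:30, 1)
    panel <- random_panel(n, m, seed = 4000 + seed)
    freqs <- derived_freq(panel)
    cores <- which(freqs * n >= 2 & (1 - freqs) * n >= 2)
    if (length(cores) == 0) next
    core <- cores[sample.int(length(cores), 1)]
    for (allele in c(0L, 1L)) {
      got <- compute_ehh(panel, core, allele)
      want <- oracle_ehh(panel, core, allele)
      expect_identical(got$profile$pos, want$pos)
      expect_equal(got$profile$ehh, want$ehh, tolerance = 1e-12)
      expect_identical(got$truncated_left, want$truncated_left)
      expect_identical(got$truncated_right, want$truncated_right)
    }
  }
})

test_that("EHH never increases moving away from the core", {
  for (seed in 1:10) {
    panel <- random_panel(10, 25, seed = 6000 + seed)
    core <- 12
    if (sum(panel$alleles[, core]) < 2) next
    prof <- compute_ehh(panel, core, 1L, ehh_cutoff = 0)$profile
    left <- prof$ehh[prof$pos <= prof$pos[prof$side == "core"]]
    right <- prof$ehh[prof$pos >= prof$pos[prof$side == "core"]]
    expect_true(all(diff(rev(left)) <= 1e-12))
    expect_true(all(diff(right) <= 1e-12))
  }
})

test_that("trapezoid integration reproduces hand arithmetic", {
  flat <- structure(list(
    profile = tibble::tibble(pos = c(0, 1500), ehh = c(1, 1),
                             side = c("core", "right")),
    truncated_left = FALSE, truncated_right = FALSE
  ), class = "ehh_profile")
  expect_equal(integrate_ihh(flat), 1500)

  decay <- structure(list(
    profile = tibble::tibble(pos = c(0, 1000, 2000),
                             ehh = c(1, 0.5, 0.05),
                             side = c("core", "right", "right")),
    truncated_left = FALSE, truncated_right = FALSE
  ), class = "ehh_profile")
  expect_equal(integrate_ihh(decay), 0.75 * 1000 + 0.275 * 1000)

  # trapezoid on piecewise-linear data is exact: refining each segment with
  # interpolated points changes nothing
  fine_pos <- seq(0, 2000, by = 10)
  fine_ehh <- approx(c(0, 1000, 2000), c(1, 0.5, 0.05), xout = fine_pos)$y
  fine <- structure(list(
    profile = tibble::tibble(pos = fine_pos, ehh = fine_ehh,
                             side = c("core", rep("right",
                                                  length(fine_pos) - 1))),
    truncated_left = FALSE, truncated_right = FALSE
  ), class = "ehh_profile")
  expect_equal(integrate_ihh(fine), integrate_ihh(decay),
               tolerance = 1e-9)

  # truncated profiles are discarded by default, integrable on request
  trunc <- decay
  trunc$truncated_right <- TRUE
  expect_true(is.na(integrate_ihh(trunc)))
  expect_equal(integrate_ihh(trunc, truncation = "integrate"), 1025)
})

test_that("the raw score is the log iHH ratio with exact antisymmetry", {
  expect_equal(raw_ihs(1025, 1025), 0)
  expect_equal(raw_ihs(1025, 2050), log(0.5))
  expect_equal(raw_ihs(2050, 1025), -raw_ihs(1025, 2050))
  expect_true(is.na(raw_ihs(0, 100)))
  expect_true(is.na(raw_ihs(100, NA)))
})

test_that("standardization leaves every occupied bin at mean 0, SD 1", {
  set.seed(123)
  uni <- rnorm(400, mean = 2)
  freq <- runif(400, 0.05, 0.95)
  std <- standardize_ihs(uni, freq)
  for (b in unique(std$freq_bin[std$valid])) {
    x <- std$ihs[std$valid & std$freq_bin == b]
    expect_equal(mean(x), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-9)
  }
  # a bin already at mean 0 / population SD 1 is returned unchanged
  two <- standardize_ihs(c(-1, 1), c(0.3, 0.31), bin_width = 0.025)
  expect_equal(two$ihs, c(-1, 1))
  # scores outside a bin cannot influence it
  more <- standardize_ihs(c(-1, 1, 50, 60), c(0.3, 0.31, 0.9, 0.91))
  expect_equal(more$ihs[1:2], c(-1, 1))
  # singleton bins are flagged invalid
  lone <- standardize_ihs(c(-1, 1, 3), c(0.3, 0.31, 0.9))
  expect_false(lone$valid[3])
})

test_that("the compiled scan agrees with the R walker and integrator", {
  for (seed in 1:6) {
    cfg <- sim_config(n_accessions = 12, n_snps = 60, chrom_length = 2e5,
                      switch_rate = 2e-4, sweep = NULL, seed = 7000 + seed)
    panel <- simulate_founder_mosaic(cfg)
    tab <- ihs_scan(panel, truncation = "integrate")
    scored <- which(!is.na(tab$ihh_a))
    expect_gt(length(scored), 0)
    for (j in scored) {
      ihh_d_r <- integrate_ihh(compute_ehh(panel, j, 1L),
                               truncation = "integrate")
      ihh_a_r <- integrate_ihh(compute_ehh(panel, j, 0L),
                               truncation = "integrate")
      expect_equal(tab$ihh_d[j], ihh_d_r, tolerance = 1e-9)
      expect_equal(tab$ihh_a[j], ihh_a_r, tolerance = 1e-9)
    }
  }
})

test_that("flipping ancestral/derived labels at a SNP negates its raw score", {
  cfg <- sim_config(n_accessions = 30, n_snps = 80, chrom_length = 4e5,
                    sweep = NULL, seed = 77L)
  panel <- simulate_founder_mosaic(cfg)
  tab <- ihs_scan(panel, truncation = "integrate")
  j <- which(!is.na(tab$uni_hs))[1]
  flipped <- panel
  flipped$alleles[, j] <- 1L - flipped$alleles[, j]
  tab2 <- ihs_scan(flipped, truncation = "integrate")
  expect_equal(tab2$uni_hs[j], -tab$uni_hs[j], tolerance = 1e-12)
  expect_equal(tab2$p_derived[j], 1 - tab$p_derived[j])
})

test_that("a swept core stands out from its frequency bin", {
  cfg <- sim_config(seed = 99L)
  st <- simulate_study(cfg)
  tab <- ihs_scan(st$panel)
  ci <- which(tab$id == st$truth$core_id)
  expect_true(tab$valid[ci])
  expect_lt(tab$ihs[ci], 0)  # derived allele on the long haplotype
  mates <- tab$valid & tab$freq_bin == tab$freq_bin[ci] &
    tab$id != st$truth$core_id
  expect_gt(abs(tab$ihs[ci]),
            quantile(abs(tab$ihs[mates]), 0.95, na.rm = TRUE))
})

test_that("the iHS TSV dialect round-trips", {
  cfg <- sim_config(n_accessions = 15, n_snps = 40, chrom_length = 1e5,
                    sweep = NULL, seed = 88L)
  panel <- simulate_founder_mosaic(cfg)
  tab <- ihs_scan(panel, truncation = "integrate")
  tsv <- tempfile(fileext = ".tsv")
  write_ihs(tab, tsv)
  expect_equal(as.data.frame(read_ihs(tsv)), as.data.frame(tab),
               tolerance = 1e-12)
})
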