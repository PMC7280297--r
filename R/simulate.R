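#' Simulation configuration
#'
#' Bundles every tunable of the synthetic study generator. Defaults describe
#' the package's reference study conditions: an inbred panel of 200
#' accessions over a 5 Mb chromosome with 5000 SNPs (about one per kb, so LD
#' decays within roughly 10 kb), a partial sweep at intermediate frequency,
#' and a pollen-count-like phenotype with a causal effect at the sweep core,
#' kinship-structured polygenic background, flower-level replicate noise and
#' a two-batch affine artifact.
#'
#' @param n_accessions number of inbred accessions (one haplotype each).
#' @param n_founders number of founder haplotypes in the mosaic process.
#' @param chrom_length chromosome length in bp.
#' @param n_snps number of SNP positions drawn (before deduplication).
#' @param switch_rate founder-switch rate per bp; between adjacent SNPs a
#'   sample switches to a uniformly chosen founder with probability
#'   `1 - exp(-switch_rate * gap_bp)`.
#' @param mutation_rate per-site allele flip probability after copying.
#' @param sweep list with `core_pos` (bp), `carrier_fraction` and
#'   `erosion_mean` (bp, exponential mean of each eroded flank), or `NULL`
#'   for no sweep.
#' @param phenotype list of phenotype tunables: `beta_core` (log-scale effect
#'   per derived core allele; default -0.4243, about one accession-level
#'   phenotypic SD at the default variance settings), `h2_polygenic`
#'   (polygenic fraction of the accession-level latent variance),
#'   `sigma_e` (log-scale residual SD), `baseline` (log mean count; default
#'   `log(4000)`), `flowers_per_plant`, `plants_per_accession`, `flower_cv`
#'   (per-flower coefficient of variation), `batch_shift` and `batch_scale`
#'   (affine artifact applied to batch 2 counts).
#' @param seed integer seed; every generator consumes it deterministically.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 200,
                       n_founders = 12,
                       chrom_length = 5e6,
                       n_snps = 5000,
                       switch_rate = 5e-5,
                       mutation_rate = 1e-3,
                       sweep = list(core_pos = 2.5e6,
                                    carrier_fraction = 0.3,
                                    erosion_mean = 2e4),
                       phenotype = list(),
                       seed = 1L) {
  ph_default <- list(
    beta_core = -0.4243, h2_polygenic = 0.5, sigma_e = 0.3,
    baseline = log(4000), flowers_per_plant = 3, plants_per_accession = 4,
    flower_cv = 0.2, batch_shift = 200, batch_scale = 1.2
  )
  ph <- utils::modifyList(ph_default, phenotype)
  if (!is.null(sweep)) {
    f <- sweep$carrier_fraction
    if (!(f > 0 && f < 1)) abort("carrier_fraction must be in (0,1)")
    if (!(sweep$erosion_mean > 0)) abort("erosion_mean must be positive")
  }
  if (switch_rate < 0 || mutation_rate < 0 || ph$sigma_e < 0 ||
      ph$flower_cv < 0) {
    abort("rates and noise SDs must be non-negative")
  }
  if (!(ph$h2_polygenic >= 0 && ph$h2_polygenic < 1)) {
    abort("h2_polygenic must be in [0,1)")
  }
  if (ph$h2_polygenic > 0 && ph$sigma_e <= 0) {
    abort("h2_polygenic > 0 requires sigma_e > 0 (polygenic variance is scaled off the residual variance)")
  }
  structure(
    list(n_accessions = n_accessions, n_founders = n_founders,
         chrom_length = chrom_length, n_snps = n_snps,
         switch_rate = switch_rate, mutation_rate = mutation_rate,
         sweep = sweep, phenotype = ph, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a founder-mosaic haplotype panel
#'
#' A Li-Stephens-like copying process: SNP positions are drawn uniformly on
#' `[1, chrom_length]`, sorted and deduplicated; `n_founders` founder
#' haplotypes carry iid Bernoulli(0.5) derived alleles; each accession copies
#' a founder, switching to a uniformly chosen founder between adjacent SNPs
#' with probability `1 - exp(-switch_rate * gap)`, and each copied allele
#' flips with probability `mutation_rate`. Ancestral/derived labels are set
#' by construction, so the returned panel is polarized.
#'
#' @param config a [sim_config()].
#' @return a [haplotype_panel()] with accessions `acc_001`, ...
#' @export
simulate_founder_mosaic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_snps < 2) abort("need at least 2 SNPs")
  if (config$n_founders < 1) abort("need at least 1 founder")
  set.seed(config$seed)
  pos <- sort(unique(as.integer(ceiling(
    runif(config$n_snps, 0, config$chrom_length)))))
  m <- length(pos)
  if (m < 2) abort("fewer than 2 distinct SNP positions after deduplication")
  n <- config$n_accessions
  F <- config$n_founders

  founders <- matrix(rbinom(F * m, 1L, 0.5), nrow = F, ncol = m)
  gaps <- diff(pos)
  p_switch <- 1 - exp(-config$switch_rate * gaps)

  fid <- matrix(0L, nrow = n, ncol = m)
  fid[, 1] <- sample.int(F, n, replace = TRUE)
  for (j in 2:m) {
    sw <- runif(n) < p_switch[j - 1]
    fid[, j] <- ifelse(sw, sample.int(F, n, replace = TRUE), fid[, j - 1])
  }
  alleles <- matrix(founders[cbind(as.vector(fid),
                                   rep(seq_len(m), each = n))],
                    nrow = n, ncol = m)
  if (config$mutation_rate > 0) {
    flips <- matrix(runif(n * m) < config$mutation_rate, n, m)
    alleles[flips] <- 1L - alleles[flips]
  }
  samples <- sprintf("acc_%03d", seq_len(n))
  haplotype_panel(alleles, snp_meta("1", pos, ref = "A", alt = "T",
                                    ancestral = "A"),
                  samples, polarized = TRUE)
}

#' Inject a partial sweep into a panel
#'
#' Emulates an incomplete selective sweep: the SNP nearest `core_pos` becomes
#' the core, a donor haplotype is chosen, and a random set of
#' `round(f * n)` carriers have their alleles replaced by the donor's over
#' the interval `[core - e_L, core + e_R]`, with `e_L, e_R` drawn
#' independently per carrier from an exponential with mean `erosion_mean`
#' (erosion of the swept segment by recombination). The derived core allele
#' is set to 1 for carriers and 0 for everyone else, so its frequency equals
#' the carrier fraction exactly (after rounding).
#'
#' @param panel a [haplotype_panel()].
#' @param core_pos target position in bp.
#' @param f carrier fraction in (0,1).
#' @param erosion_mean exponential mean flank length in bp.
#' @param seed integer seed.
#' @return list with elements `panel` (modified panel) and `truth`, a list
#'   holding `core_index`, `core_id`, `carriers` (accession ids), `donor`
#'   and the per-carrier segment bounds.
#' @export
inject_sweep <- function(panel, core_pos, f, erosion_mean, seed = 1L) {
  n <- length(panel$samples)
  n_car <- round(f * n)
  if (n_car < 2) abort("carrier count below 2: EHH undefined")
  set.seed(seed)
  core <- which.min(abs(panel$snps$pos - core_pos))
  carriers <- sort(sample.int(n, n_car))
  donor <- carriers[1]
  e_l <- rexp(n_car, rate = 1 / erosion_mean)
  e_r <- rexp(n_car, rate = 1 / erosion_mean)
  pos <- panel$snps$pos
  alleles <- panel$alleles
  donor_hap <- alleles[donor, ]
  lo <- pos[core] - e_l
  hi <- pos[core] + e_r
  for (k in seq_len(n_car)) {
    span <- pos >= lo[k] & pos <= hi[k]
    alleles[carriers[k], span] <- donor_hap[span]
  }
  alleles[, core] <- 0L
  alleles[carriers, core] <- 1L
  truth <- list(core_index = core, core_id = panel$snps$id[core],
                carriers = panel$samples[carriers], donor = panel$samples[donor],
                seg_lo = lo, seg_hi = hi)
  list(panel = haplotype_panel(alleles, panel$snps, panel$samples,
                               polarized = panel$polarized),
       truth = truth)
}

#' Simulate flower-level phenotypes linked to a panel
#'
#' Accession-level latent value on the log scale:
#' `z_i = beta_core * x_i + u_i + e_i`, with `x_i` the derived allele at the
#' sweep core, `u ~ MVN(0, sigma_g^2 K)` a kinship-structured polygenic
#' background (`sigma_g^2` chosen so the polygenic fraction of
#' `sigma_g^2 + sigma_e^2` equals `h2_polygenic`), and
#' `e_i ~ N(0, sigma_e^2)`. Per-flower counts are
#' `max(0, Normal(mean = exp(z_i + baseline), sd = flower_cv * mean))`.
#' Plants are split evenly into two batches and batch 2 counts receive the
#' affine artifact `x -> batch_scale * x + batch_shift`.
#'
#' @param panel a [haplotype_panel()].
#' @param truth sweep truth from [inject_sweep()], or `NULL` for a phenotype
#'   with no causal core (`beta_core` ignored).
#' @param config a [sim_config()]; the `phenotype` block supplies all
#'   tunables.
#' @param seed integer seed.
#' @return list with `flowers`, a tibble of (`accession`, `plant`, `flower`,
#'   `batch`, `count`), and `truth` carrying the per-accession latent values
#'   and batch assignments.
#' @export
simulate_phenotypes <- function(panel, truth, config, seed = 1L) {
  ph <- config$phenotype
  n <- length(panel$samples)
  set.seed(seed)
  sigma_e2 <- ph$sigma_e^2
  h2 <- ph$h2_polygenic
  sigma_g2 <- if (h2 > 0) sigma_e2 * h2 / (1 - h2) else 0

  u <- rep(0, n)
  if (sigma_g2 > 0) {
    K <- compute_kinship(panel)$K
    ek <- eigen(K, symmetric = TRUE)
    lam <- pmax(ek$values, 0)
    u <- as.vector(ek$vectors %*% (sqrt(lam * sigma_g2) * rnorm(n)))
  }
  x_core <- if (!is.null(truth)) {
    panel$alleles[, truth$core_index]
  } else rep(0L, n)
  beta <- if (!is.null(truth)) ph$beta_core else 0
  z <- beta * x_core + u + rnorm(n, 0, ph$sigma_e)

  n_plants <- ph$plants_per_accession
  n_flowers <- ph$flowers_per_plant
  flowers <- tidyr::expand_grid(
    accession = panel$samples,
    plant = seq_len(n_plants),
    flower = seq_len(n_flowers)
  )
  mu <- exp(z[match(flowers$accession, panel$samples)] + ph$baseline)
  counts <- pmax(0, rnorm(nrow(flowers), mean = mu, sd = ph$flower_cv * mu))
  batch <- rep(c(1L, 2L), length.out = n_plants)[flowers$plant]
  counts[batch == 2L] <- ph$batch_scale * counts[batch == 2L] + ph$batch_shift
  flowers$batch <- batch
  flowers$count <- counts
  truth_out <- c(truth, list(
    genetic_value = setNames(beta * x_core + u, panel$samples),
    latent_value = setNames(z, panel$samples),
    polygenic = setNames(u, panel$samples),
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
    batch_of_plant = rep(c(1L, 2L), length.out = n_plants)
  ))
  list(flowers = flowers, truth = truth_out)
}

#' Simulate a panel of null phenotypes
#'
#' Generates `k` independent phenotypes with no causal core effect
#' (polygenic background and noise only), sharing the accession set of
#' `panel`. Used as the comparison panel against which the focal phenotype's
#' enrichment is ranked.
#'
#' @param panel a [haplotype_panel()].
#' @param k number of phenotypes.
#' @param config a [sim_config()].
#' @param seed integer seed; phenotype `j` uses `seed + j`.
#' @return list of `k` flower tibbles.
#' @export
simulate_null_phenotype_panel <- function(panel, k, config, seed = 1L) {
  if (k < 1) abort("k must be at least 1")
  lapply(seq_len(k), function(j) {
    simulate_phenotypes(panel, truth = NULL, config, seed = seed + j)$flowers
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper: founder-mosaic panel, sweep injection (when the
#' config has one) and the linked focal phenotype.
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `truth`, `flowers`.
#' @export
simulate_study <- function(config) {
  panel <- simulate_founder_mosaic(config)
  truth <- NULL
  if (!is.null(config$sweep)) {
    sw <- inject_sweep(panel, config$sweep$core_pos,
                       config$sweep$carrier_fraction,
                       config$sweep$erosion_mean,
                       seed = config$seed + 1L)
    panel <- sw$panel
    truth <- sw$truth
  }
  ph <- simulate_phenotypes(panel, truth, config, seed = config$seed + 2L)
  list(panel = panel, truth = ph$truth, flowers = ph$flowers)
}
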