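#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the fraction of SNPs at which haplotypes `i` and `j` carry
#' the same allele. On 0/1 haplotypes this is
#' `(X X' + (1 - X)(1 - X)') / m`, symmetric with unit diagonal and positive
#' semi-definite (a sum of two Gram matrices).
#'
#' @param panel a [haplotype_panel()].
#' @param method `"ibs"` (default) or `"centered"` (the centered-genotype
#'   cross-product `Z Z' / m` with `Z = X - colMeans(X)`, rescaled to unit
#'   mean diagonal).
#' @return list of class `kinship_matrix` with elements `K` (n x n) and
#'   `samples`.
#' @export
compute_kinship <- function(panel, method = c("ibs", "centered")) {
  method <- match.arg(method)
  X <- panel$alleles
  m <- ncol(X)
  if (m < 1) abort("panel has no SNPs")
  if (method == "ibs") {
    K <- (tcrossprod(X) + tcrossprod(1L - X)) / m
  } else {
    Z <- sweep(X, 2, colMeans(X))
    K <- tcrossprod(Z) / m
    K <- K / mean(diag(K))
  }
  structure(list(K = K, samples = panel$samples, method = method),
            class = "kinship_matrix")
}

#' Fit the null mixed model by REML
#'
#' Variance-component fit of `y = X b + u + e`, `u ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_e^2 I)`, with `delta = sigma_e^2 / sigma_g^2` profiled
#' out of the restricted likelihood. The spectrum of the projected kinship
#' is computed once; `log(delta)` is optimized on a 100-point grid spanning
#' `[-10, 10]` followed by local refinement (tolerance 1e-6).
#'
#' @param y named numeric vector of accession phenotypes, or an accession
#'   tibble from [summarize_accessions()].
#' @param kinship a `kinship_matrix` from [compute_kinship()].
#' @param covariates optional numeric matrix of fixed-effect covariates (an
#'   intercept is always included).
#' @param n_grid grid size over `log(delta)` (minimum 100).
#' @return object of class `null_model_fit` with variance components
#'   `sigma_g2`, `sigma_e2`, `delta`, `reml_loglik`, `pseudo_heritability`,
#'   and the spectral pieces reused by [association_scan()].
#' @export
fit_null_reml <- function(y, kinship, covariates = NULL, n_grid = 100) {
  if (is.data.frame(y)) {
    y <- setNames(y$value, y$accession)
  }
  if (!is.null(names(y))) {
    keep <- intersect(kinship$samples, names(y))
    if (length(keep) < length(kinship$samples)) {
      hs_log("fit_null_reml: restricting to ", length(keep),
             " accessions present in both phenotype and kinship")
    }
    idx <- match(keep, kinship$samples)
    K <- kinship$K[idx, idx, drop = FALSE]
    y <- y[keep]
  } else {
    K <- kinship$K
    keep <- kinship$samples
  }
  n <- length(y)
  if (n < 3) abort("need at least 3 accessions")
  if (sd(y) == 0) abort("phenotype is constant: variance components undefined")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  q <- ncol(X)

  # restricted likelihood via the spectrum of the projected kinship:
  # with S = I - X (X'X)^-1 X', the n - q nonzero eigenpairs of S K S carry
  # the whole REML surface in delta.
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- es$values[seq_len(n - q)]
  xi <- pmax(xi, 0)
  eta <- as.vector(crossprod(es$vectors[, seq_len(n - q), drop = FALSE], y))

  reml_ll <- function(log_delta) {
    d <- exp(log_delta)
    denom <- xi + d
    ss <- sum(eta^2 / denom)
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 - log(ss)) -
             sum(log(denom)))
  }
  grid <- seq(-10, 10, length.out = max(100, n_grid))
  vals <- vapply(grid, reml_ll, numeric(1))
  if (!any(is.finite(vals))) abort("REML likelihood non-finite on the grid")
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = 1e-6)
  # keep boundary optima honest: grid edge may beat the interior refinement
  if (vals[i] > opt$objective) {
    opt <- list(maximum = grid[i], objective = vals[i])
  }
  delta <- exp(opt$maximum)
  sigma_g2 <- sum(eta^2 / (xi + delta)) / (n - q)
  sigma_e2 <- delta * sigma_g2
  # spectrum of K itself, reused for the per-SNP rotation in the scan
  ek <- eigen(K, symmetric = TRUE)
  structure(
    list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
         reml_loglik = opt$objective,
         pseudo_heritability = sigma_g2 / (sigma_g2 + sigma_e2),
         y = y, X = X, samples = keep,
         eigen_values = pmax(ek$values, 0), eigen_vectors = ek$vectors),
    class = "null_model_fit"
  )
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat("<null_model_fit> n =", length(x$y), "\n")
  cat(sprintf("  sigma_g2 = %.4g  sigma_e2 = %.4g  delta = %.4g\n",
              x$sigma_g2, x$sigma_e2, x$delta))
  cat(sprintf("  pseudo-heritability = %.3f  REML loglik = %.3f\n",
              x$pseudo_heritability, x$reml_loglik))
  invisible(x)
}

#' @method tidy null_model_fit
#' @export
tidy.null_model_fit <- function(x, ...) {
  tibble(term = c("sigma_g2", "sigma_e2", "delta", "pseudo_heritability"),
         estimate = c(x$sigma_g2, x$sigma_e2, x$delta,
                      x$pseudo_heritability))
}

#' @method glance null_model_fit
#' @export
glance.null_model_fit <- function(x, ...) {
  tibble(nobs = length(x$y), reml_loglik = x$reml_loglik,
         pseudo_heritability = x$pseudo_heritability, delta = x$delta)
}

#' Mixed-model association scan
#'
#' Per-SNP generalized least squares with variance components fixed from the
#' null fit (the EMMAX approximation): phenotype and design are rotated by
#' the kinship eigenvectors, weighted by `(lambda + delta)^(-1/2)`, and each
#' SNP is tested with a two-sided t test on its coefficient with `n - q`
#' degrees of freedom. SNPs with minor allele frequency below `maf_min` are
#' excluded; monomorphic SNPs are skipped with a log entry.
#'
#' @param panel a [haplotype_panel()].
#' @param nullfit a `null_model_fit` from [fit_null_reml()].
#' @param maf_min minor-allele-frequency threshold (default 0.15; SNPs with
#'   `maf < maf_min` are dropped).
#' @return tibble with one row per tested SNP: `chrom`, `pos`, `id`, `maf`,
#'   `beta`, `se`, `pvalue`.
#' @export
association_scan <- function(panel, nullfit, maf_min = 0.15) {
  idx <- match(nullfit$samples, panel$samples)
  if (anyNA(idx)) abort("null fit samples missing from panel")
  X <- panel$alleles[idx, , drop = FALSE]
  n <- length(idx)
  freq <- colMeans(X)
  maf <- pmin(freq, 1 - freq)
  mono <- maf == 0
  if (any(mono)) {
    hs_log("association_scan: skipped ", sum(mono), " monomorphic SNP(s)")
  }
  keep <- which(!mono & maf >= maf_min)
  if (length(keep) == 0) abort("no SNPs pass the MAF filter")

  w <- 1 / sqrt(nullfit$eigen_values + nullfit$delta)
  Ut <- t(nullfit$eigen_vectors)
  ys <- w * as.vector(Ut %*% nullfit$y)
  X0s <- w * (Ut %*% nullfit$X)
  Gs <- w * (Ut %*% X[, keep, drop = FALSE])
  q <- ncol(X0s) + 1L

  # project out the rotated fixed effects, then per-SNP simple regression
  P0 <- diag(n) - X0s %*% solve(crossprod(X0s), t(X0s))
  ry <- as.vector(P0 %*% ys)
  RG <- P0 %*% Gs
  sxx <- unname(colSums(RG^2))
  sxy <- as.vector(crossprod(RG, ry))
  beta <- sxy / sxx
  df <- n - q
  rss <- sum(ry^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)

  tibble(
    chrom = panel$snps$chrom[keep],
    pos = panel$snps$pos[keep],
    id = panel$snps$id[keep],
    maf = maf[keep],
    beta = beta,
    se = se,
    pvalue = pval
  )
}

#' Q-Q coordinates and the genomic inflation factor
#'
#' Sorted observed `-log10(P)` against the expected `-log10` of uniform
#' order statistics `(i - 0.5) / n`, plus `lambda_GC`: the median 1-df
#' chi-square quantile of the P values divided by 0.4549364 (the null
#' median).
#'
#' @param results association tibble from [association_scan()] (only the
#'   `pvalue` column is used), or a numeric vector of P values.
#' @return list with `qq` (tibble of `expected`, `observed`) and
#'   `lambda_gc`.
#' @export
qq_and_lambda <- function(results) {
  p <- if (is.data.frame(results)) results$pvalue else results
  p <- p[is.finite(p)]
  if (length(p) < 1) abort("no P values")
  n <- length(p)
  qq <- tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(p))
  )
  lambda <- median(qchisq(p, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1)
  list(qq = qq, lambda_gc = lambda)
}

#' Read / write the association TSV
#'
#' Dialect: TSV with header `chrom`, `pos`, `id`, `maf`, `beta`, `se`,
#' `pvalue`; consumed verbatim by the enrichment stage.
#'
#' @param path file path.
#' @return [read_assoc()]: the association tibble.
#' @export
read_assoc <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    pos = readr::col_integer(),
                    id = readr::col_character(),
                    maf = readr::col_double(),
                    beta = readr::col_double(),
                    se = readr::col_double(),
                    pvalue = readr::col_double()
                  ))
}

#' @rdname read_assoc
#' @param results association tibble to write.
#' @export
write_assoc <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}
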