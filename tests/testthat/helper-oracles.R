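# test helpers: tiny builders and independent oracles

options(hapsweep.verbose = FALSE)

# panel from an explicit allele matrix; positions default to 1 kb spacing
make_panel <- function(alleles, pos = NULL, chrom = "1", polarized = TRUE) {
  alleles <- as.matrix(alleles)
  if (is.null(pos)) pos <- seq_len(ncol(alleles)) * 1000L
  haplotype_panel(alleles,
                  snp_meta(chrom, pos, ref = "A", alt = "T",
                           ancestral = if (polarized) "A" else NA),
                  paste0("s", seq_len(nrow(alleles))),
                  polarized = polarized)
}

random_panel <- function(n, m, seed) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  alleles <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
  pos <- sort(sample.int(m * 2000L, m))
  make_panel(alleles, pos)
}

# exhaustive pairwise-identity EHH: for every carrier pair, direct comparison
# of the haplotype interval from the core through the current SNP; same
# stopping rule as compute_ehh (first sub-cutoff point kept, then stop)
oracle_ehh <- function(panel, core_index, allele, ehh_cutoff = 0.05) {
  H <- panel$alleles
  carriers <- which(H[, core_index] == allele)
  n_a <- length(carriers)
  pairs <- utils::combn(carriers, 2)
  n_pairs <- ncol(pairs)
  pos <- panel$snps$pos
  m <- ncol(H)

  walk <- function(idx) {
    out_pos <- numeric(0); out_ehh <- numeric(0); truncated <- TRUE
    for (j in idx) {
      span <- if (j > core_index) seq(core_index + 1L, j)
              else seq(j, core_index - 1L)
      same <- vapply(seq_len(n_pairs), function(k) {
        all(H[pairs[1, k], span] == H[pairs[2, k], span])
      }, logical(1))
      ehh <- sum(same) / n_pairs
      out_pos <- c(out_pos, pos[j]); out_ehh <- c(out_ehh, ehh)
      if (ehh < ehh_cutoff) { truncated <- FALSE; break }
    }
    list(pos = out_pos, ehh = out_ehh, truncated = truncated)
  }
  right <- walk(if (core_index < m) seq(core_index + 1L, m) else integer(0))
  left <- walk(if (core_index > 1) seq(core_index - 1L, 1L) else integer(0))
  list(
    pos = c(rev(left$pos), pos[core_index], right$pos),
    ehh = c(rev(left$ehh), 1, right$ehh),
    truncated_left = left$truncated, truncated_right = right$truncated
  )
}

# dense REML log-likelihood (no eigen shortcut), sigma_g2 profiled out
dense_reml_loglik <- function(y, K, delta, X = matrix(1, length(y), 1)) {
  n <- length(y)
  q <- ncol(X)
  H <- K + delta * diag(n)
  Hi <- solve(H)
  XtHiX <- crossprod(X, Hi %*% X)
  P <- Hi - Hi %*% X %*% solve(XtHiX, crossprod(X, Hi))
  s2 <- as.numeric(crossprod(y, P %*% y)) / (n - q)
  as.numeric(-0.5 * ((n - q) * log(2 * pi * s2) +
                     determinant(H)$modulus +
                     determinant(XtHiX)$modulus -
                     determinant(crossprod(X))$modulus + (n - q)))
}

# per-accession OLS scan used as the identity-kinship reference
ols_scan <- function(panel, y) {
  vapply(seq_len(ncol(panel$alleles)), function(j) {
    x <- panel$alleles[, j]
    if (sd(x) == 0) return(NA_real_)
    summary(lm(y ~ x))$coefficients[2, 4]
  }, numeric(1))
}

identity_kinship <- function(panel) {
  structure(list(K = diag(length(panel$samples)), samples = panel$samples,
                 method = "identity"),
            class = "kinship_matrix")
}
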