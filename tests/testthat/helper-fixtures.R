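# Shared fixtures and independent oracles used across test files.

# small pool over 3 variants with one-allele haplotypes
tiny_pool <- function(freqs = c(0.7, 0.15, 0.1, 0.05)) {
  haplotype_pool(variant_labels = c("v1", "v2", "v3"),
                 haplotype_alleles = c("000", "100", "010", "001"),
                 frequencies = freqs)
}

# genotype matrix from a plain dosage matrix
gm_from_dosage <- function(D, chrom = "1", pos0 = 1000L) {
  m <- ncol(D)
  ids <- colnames(D) %||% sprintf("v%d", seq_len(m))
  if (is.null(rownames(D))) rownames(D) <- sprintf("S%04d", seq_len(nrow(D)))
  genotype_matrix(D, data.frame(chrom = chrom, pos = pos0 + 10L * seq_len(m),
                                id = ids, ref = "A", alt = "G",
                                stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force maximiser of the HWE diplotype likelihood over the
# haplotype frequency simplex (softmax parameterisation, multi-start BFGS);
# shares no code with the EM implementation
bruteforce_hap_freqs <- function(D) {
  m <- ncol(D)
  haps <- as.matrix(expand.grid(rep(list(0:1), m)))[, m:1, drop = FALSE]
  H <- nrow(haps)
  # all unordered pairs and the genotype each implies
  pair_i <- rep(seq_len(H), times = H)
  pair_j <- rep(seq_len(H), each = H)
  keep <- pair_i <= pair_j
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
  geno <- haps[pair_i, , drop = FALSE] + haps[pair_j, , drop = FALSE]
  gkey <- apply(geno, 1, paste, collapse = "")
  okey <- apply(D, 1, paste, collapse = "")
  mult <- ifelse(pair_i == pair_j, 1, 2)
  negll <- function(theta) {
    f <- exp(theta - max(theta)); f <- f / sum(f)
    pg <- mult * f[pair_i] * f[pair_j]
    lik <- vapply(okey, function(k) sum(pg[gkey == k]), 0)
    -sum(log(pmax(lik, 1e-300)))
  }
  best <- NULL
  for (s in 1:4) {
    set.seed(1000 + s)
    fit <- optim(rnorm(H, 0, 0.5), negll, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  f <- exp(best$par - max(best$par)); f <- f / sum(f)
  names(f) <- apply(haps, 1, paste, collapse = "")
  f
}

# explicit GLS estimator under the block covariance sigma_b^2 J + sigma_e^2 I
gls_oracle <- function(y, D, fam, sigma2_b, sigma2_e) {
  n <- length(y)
  Sigma <- diag(sigma2_e, n)
  for (f in unique(fam)) {
    i <- which(fam == f)
    Sigma[i, i] <- Sigma[i, i] + sigma2_b
  }
  Si <- solve(Sigma)
  A <- solve(t(D) %*% Si %*% D)
  list(beta = drop(A %*% t(D) %*% Si %*% y), cov = A)
}

# per-variant score z-statistic by direct regression (independent of the
# package's whitening/residualisation path)
regression_score_oracle <- function(y, X, g) {
  qx <- qr(X)
  r <- qr.resid(qx, y)
  gt <- qr.resid(qx, g)
  sigma2 <- sum(r^2) / (length(y) - ncol(X))
  list(slope = sum(gt * y) / sum(gt^2),
       z = sum(gt * r) / sqrt(sigma2 * sum(gt^2)))
}
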