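#' Combine cohort score sets by score summation
#'
#' Element-wise sums of U and V over the union variant list, matching
#' variants by identifier and alleles. A cohort whose ref/alt pair is the
#' reverse of the first-seen orientation is harmonised by flipping the sign
#' of its U entry and the corresponding V row/column (equivalent to recoding
#' dosage d to 2 - d) and restating its MAF as 1 - MAF. Variants absent from
#' a cohort contribute zeros. Pooled MAF is the allele-count-weighted mean
#' over contributing cohorts.
#'
#' @param sets list of [score_stats()] results for the same gene/trait
#' @return an object of class `meta_score_set`
#' @export
combine_scores <- function(sets) {
  if (length(sets) == 0)
    glyrare_stop("glyrare_bad_meta", "no score sets supplied")
  kinds <- unique(vapply(sets, `[[`, "", "trait_kind"))
  genes <- unique(vapply(sets, `[[`, "", "gene"))
  if (length(kinds) != 1 || length(genes) != 1)
    glyrare_stop("glyrare_bad_meta", "score sets must share gene and trait kind")

  vmeta <- NULL
  for (s in sets) {
    add <- s$variants[, c("id", "chrom", "pos", "ref", "alt")]
    vmeta <- if (is.null(vmeta)) add else rbind(vmeta, add[!(add$id %in% vmeta$id), ])
  }
  vmeta <- vmeta[order(vmeta$pos), , drop = FALSE]
  ids <- vmeta$id
  m <- length(ids)

  U <- stats::setNames(rep(0, m), ids)
  V <- matrix(0, m, m, dimnames = list(ids, ids))
  ac <- an <- rep(0, m)   # pooled allele counts / called allele totals
  contrib <- stats::setNames(vector("list", m), ids)
  n_total <- 0

  for (s in sets) {
    j <- match(s$variants$id, ids)
    flip <- rep(FALSE, length(j))
    same <- s$variants$ref == vmeta$ref[j] & s$variants$alt == vmeta$alt[j]
    swapped <- s$variants$ref == vmeta$alt[j] & s$variants$alt == vmeta$ref[j]
    if (any(!same & !swapped))
      glyrare_stop("glyrare_allele_mismatch",
                   sprintf("irreconcilable alleles for variant(s): %s",
                           paste(s$variants$id[!same & !swapped], collapse = ", ")))
    flip[swapped] <- TRUE
    sgn <- ifelse(flip, -1, 1)
    U[j] <- U[j] + sgn * s$U
    V[j, j] <- V[j, j] + (sgn %o% sgn) * s$V
    maf_c <- ifelse(flip, 1 - s$variants$maf, s$variants$maf)
    ac[j] <- ac[j] + maf_c * 2 * s$variants$n_called
    an[j] <- an[j] + 2 * s$variants$n_called
    for (k in seq_along(j)) contrib[[j[k]]] <- c(contrib[[j[k]]], s$cohort)
    n_total <- n_total + s$n
  }

  pooled_maf <- ifelse(an > 0, ac / an, NA_real_)
  variants <- data.frame(vmeta,
                         maf = pooled_maf,
                         mac = round(ac),
                         n_called = an / 2,
                         stringsAsFactors = FALSE)
  structure(list(gene = genes, variants = variants, U = U, V = V,
                 n = n_total, trait_kind = kinds,
                 cohorts = vapply(sets, `[[`, "", "cohort"),
                 contributing = contrib,
                 conditioned_on = character(0)),
            class = "meta_score_set")
}

#' @export
print.meta_score_set <- function(x, ...) {
  cat(sprintf("meta_score_set %s (%s): %d variants, %d cohorts, n=%d\n",
              x$gene, x$trait_kind, length(x$U), length(x$cohorts), x$n))
  if (length(x$conditioned_on))
    cat("  conditioned on:", paste(x$conditioned_on, collapse = ", "), "\n")
  invisible(x)
}

#' Single-variant meta-analysis result
#'
#' beta = U_j / V_jj, se = 1 / sqrt(V_jj), and a two-sided normal p-value
#' for the score z-statistic U_j / sqrt(V_jj). Variants whose pooled minor
#' allele count falls below `mac_min` (20 by default, the exome-chip
#' single-variant filter) are marked filtered.
#'
#' @param ms a [combine_scores()] result
#' @param variant variant identifier (default: all variants)
#' @param mac_min pooled-MAC filter threshold
#' @return data.frame with id, maf, mac, beta, se, z, p, filtered
#' @export
single_variant_meta <- function(ms, variant = names(ms$U), mac_min = 20) {
  j <- match(variant, names(ms$U))
  if (anyNA(j))
    glyrare_stop("glyrare_bad_meta", "unknown variant identifier")
  vjj <- diag(ms$V)[j]
  uj <- ms$U[j]
  beta <- ifelse(vjj > 0, uj / vjj, NA_real_)
  se <- ifelse(vjj > 0, 1 / sqrt(vjj), NA_real_)
  z <- ifelse(vjj > 0, uj / sqrt(vjj), NA_real_)
  p <- ifelse(vjj > 0, 2 * stats::pnorm(-abs(z)), NA_real_)
  p[!is.na(uj) & uj == 0 & vjj > 0] <- 1
  data.frame(id = variant,
             maf = ms$variants$maf[j], mac = ms$variants$mac[j],
             beta = unname(beta), se = unname(se), z = unname(z),
             p = unname(p),
             filtered = unname(ms$variants$mac[j] < mac_min | vjj <= 0),
             stringsAsFactors = FALSE)
}

#' Beta(1, 25)-density SKAT weights ("Wu weights")
#' @param maf per-variant minor allele frequency
#' @return numeric weights
#' @export
wu_weights <- function(maf) stats::dbeta(maf, 1, 25)

#' Madsen-Browning inverse binomial-SD weights
#' @param maf pooled minor allele frequency
#' @param n total sample size
#' @return numeric weights
#' @export
mb_weights <- function(maf, n) 1 / sqrt(n * maf * (1 - maf))

# Tail probability P(sum lambda_i chi2_1 > q).
# Exact chi-square when all eigenvalues coincide; otherwise Imhof's
# characteristic-function inversion at rel.tol 1e-9, switching to the
# Kuonen saddlepoint approximation in the far tail (below quadrature
# resolution) and to Liu 4-moment matching if all else fails.
quadform_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12 * max(lambda)]
  m <- length(lambda)
  if (m == 0) glyrare_stop("glyrare_undefined_test", "no positive eigenvalues")
  if (max(lambda) / min(lambda) < 1 + 1e-12) {
    p <- stats::pchisq(q / lambda[1], df = m, lower.tail = FALSE)
    return(list(p = p, method = "exact-chisq"))
  }
  imhof <- function() {
    integrand <- function(u) {
      theta <- 0.5 * colSums(atan(lambda %o% u)) - 0.5 * q * u
      rho <- exp(0.25 * colSums(log1p((lambda %o% u)^2)))
      sin(theta) / (u * rho)
    }
    int <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                            subdivisions = 2000L, stop.on.error = FALSE)
    if (int$message != "OK" && int$abs.error > 1e-7) return(NULL)
    0.5 + int$value / pi
  }
  saddlepoint <- function() {
    if (q <= sum(lambda)) return(NULL)   # below the mean: not a far tail
    upper <- 1 / (2 * max(lambda))
    kp <- function(z) sum(lambda / (1 - 2 * z * lambda))
    root <- tryCatch(
      stats::uniroot(function(z) kp(z) - q, c(0, upper * (1 - 1e-12)),
                     tol = .Machine$double.eps^0.75)$root,
      error = function(e) NULL)
    if (is.null(root)) return(NULL)
    K <- -0.5 * sum(log1p(-2 * root * lambda))
    K2 <- 2 * sum(lambda^2 / (1 - 2 * root * lambda)^2)
    w <- sqrt(2 * (root * q - K))
    v <- root * sqrt(K2)
    if (abs(w) < 1e-8) return(NULL)
    stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
  }
  liu <- function() {
    c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
    s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
    if (s1^2 > s2) {
      a <- 1 / (s1 - sqrt(s1^2 - s2)); d <- s1 * a^3 - a^2; l <- a^2 - 2 * d
    } else {
      a <- 1 / s1; d <- 0; l <- c2^3 / c3^2
    }
    tstar <- (q - c1) / sqrt(2 * c2)
    stats::pchisq(tstar * sqrt(2) * sqrt(l + 2 * d) + l + d, df = l, ncp = d,
                  lower.tail = FALSE)
  }
  # Liu serves as a cheap plausibility check: adaptive quadrature cannot
  # resolve the wildly oscillatory integrand in the far tail and can return
  # a central-looking value there, so Imhof is only trusted in the central
  # region and when it agrees with the moment approximation.
  p_liu <- liu()
  if (is.finite(p_liu) && p_liu >= 1e-4) {
    p <- imhof()
    if (!is.null(p) && p > 0 && abs(p - p_liu) < 0.1)
      return(list(p = min(p, 1), method = "imhof"))
  }
  ps <- saddlepoint()
  if (!is.null(ps) && ps > 0 && ps <= 1) return(list(p = ps, method = "saddlepoint"))
  list(p = p_liu, method = "liu")
}

#' Gene-based SKAT from meta-analysed scores
#'
#' Variance-component score test Q = sum_j w_j^2 U_j^2 with the null
#' distribution sum_i lambda_i chi2_1, lambda the eigenvalues of W V W.
#' Weights default to the Beta(1, 25) density of the pooled MAF.
#'
#' @param ms a [combine_scores()] result
#' @param variants variant subset to test (default: all)
#' @param weights per-variant weights; default [wu_weights()] of pooled MAF
#' @return an object of class `gene_test_result` (gene, test, statistic,
#'   p-value, p-value method, cmaf, n_variants, conditioning set)
#' @export
skat <- function(ms, variants = names(ms$U), weights = NULL) {
  j <- match(variants, names(ms$U))
  if (anyNA(j)) glyrare_stop("glyrare_bad_meta", "unknown variant identifier")
  U <- ms$U[j]
  V <- ms$V[j, j, drop = FALSE]
  if (all(abs(V) < 1e-14))
    glyrare_stop("glyrare_undefined_test",
                 "all score variances are zero; SKAT is undefined")
  w <- weights %||% wu_weights(ms$variants$maf[j])
  Q <- sum((w * U)^2)
  WVW <- V * (w %o% w)
  lam <- eigen(WVW, symmetric = TRUE, only.values = TRUE)$values
  pv <- quadform_pvalue(Q, lam)
  structure(list(gene = ms$gene, test = "SKAT", statistic = Q,
                 p = pv$p, p_method = pv$method,
                 cmaf = sum(ms$variants$maf[j]),
                 n_variants = length(j),
                 conditioned_on = ms$conditioned_on),
            class = "gene_test_result")
}

#' Madsen-Browning weighted-sum burden test from meta-analysed scores
#'
#' Collapses the gene into the weighted burden score S = sum_j w_j U_j with
#' weights w_j = 1 / sqrt(n p_j (1 - p_j)) at the pooled MAF, tested against
#' a two-sided normal with variance w' V w. The sign of S gives the
#' direction of the aggregate effect.
#'
#' @inheritParams skat
#' @return a `gene_test_result` with an extra `direction` field
#' @export
wst_burden <- function(ms, variants = names(ms$U), weights = NULL) {
  j <- match(variants, names(ms$U))
  if (anyNA(j)) glyrare_stop("glyrare_bad_meta", "unknown variant identifier")
  U <- ms$U[j]
  V <- ms$V[j, j, drop = FALSE]
  if (all(abs(V) < 1e-14))
    glyrare_stop("glyrare_undefined_test",
                 "all score variances are zero; the burden test is undefined")
  w <- weights %||% mb_weights(ms$variants$maf[j], ms$n)
  S <- sum(w * U)
  vS <- drop(w %*% V %*% w)
  z <- if (vS > 0) S / sqrt(vS) else NA_real_
  p <- if (is.na(z)) NA_real_ else if (S == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(gene = ms$gene, test = "WST", statistic = S,
                 variance = vS, z = z, p = p, p_method = "normal",
                 direction = sign(S),
                 cmaf = sum(ms$variants$maf[j]),
                 n_variants = length(j),
                 conditioned_on = ms$conditioned_on),
            class = "gene_test_result")
}

#' @export
print.gene_test_result <- function(x, ...) {
  cat(sprintf("%s %s: statistic=%.4g, p=%.3g (%s), %d variants, cMAF=%.4g\n",
              x$gene, x$test, x$statistic, x$p, x$p_method,
              x$n_variants, x$cmaf))
  if (length(x$conditioned_on))
    cat("  conditioned on:", paste(x$conditioned_on, collapse = ", "), "\n")
  invisible(x)
}

#' Conditional adjustment of meta-analysed scores
#'
#' Projects the signal of the conditioning variants out of the score vector
#' via the score covariance: U* = U - V_gc V_cc^{-1} U_c and
#' V* = V - V_gc V_cc^{-1} V_cg. Conditioning variants remain in the output
#' with exactly zero adjusted score and variance. A near-singular V_cc is
#' regularised by adding 1e-8 x trace to its diagonal (recorded in the
#' result).
#'
#' @param ms a [combine_scores()] result
#' @param condition identifiers of the conditioning variants
#' @return a `meta_score_set` with adjusted U and V and the conditioning set
#'   recorded
#' @export
conditional_adjust <- function(ms, condition) {
  if (length(condition) == 0) return(ms)
  cidx <- match(condition, names(ms$U))
  if (anyNA(cidx))
    glyrare_stop("glyrare_missing_conditioning",
                 sprintf("conditioning variant(s) absent: %s",
                         paste(condition[is.na(cidx)], collapse = ", ")))
  Vcc <- ms$V[cidx, cidx, drop = FALSE]
  ridge_used <- FALSE
  if (rcond(Vcc) < 1e-12) {
    Vcc <- Vcc + diag(1e-8 * sum(diag(Vcc)), nrow(Vcc))
    ridge_used <- TRUE
  }
  Vic <- ms$V[, cidx, drop = FALSE]
  A <- Vic %*% solve(Vcc)
  ms$U <- ms$U - drop(A %*% ms$U[cidx])
  ms$V <- ms$V - A %*% t(Vic)
  ms$V <- (ms$V + t(ms$V)) / 2
  # the conditioning rows are an exact projection to zero
  ms$U[cidx] <- 0
  ms$V[cidx, ] <- 0
  ms$V[, cidx] <- 0
  ms$conditioned_on <- unique(c(ms$conditioned_on, condition))
  ms$ridge_used <- ridge_used
  ms
}

#' Variants within a window of an index position
#'
#' Candidate selector for conditional analysis: variants whose position lies
#' in the half-open interval [pos - width, pos + width).
#'
#' @param ms a `meta_score_set`
#' @param index_variant identifier of the index variant
#' @param width window half-width in base pairs (default 500 kb)
#' @return character vector of variant identifiers in the window
#' @export
variants_within <- function(ms, index_variant, width = 5e5) {
  j <- match(index_variant, ms$variants$id)
  if (is.na(j)) glyrare_stop("glyrare_bad_meta", "unknown index variant")
  pos <- ms$variants$pos[j]
  keep <- ms$variants$pos >= pos - width & ms$variants$pos < pos + width &
    ms$variants$chrom == ms$variants$chrom[j]
  ms$variants$id[keep]
}

#' Leave-one-variant-out SKAT scan
#'
#' Removes one variant at a time from the gene set and recomputes SKAT on
#' the remaining variants (weights recomputed from the remaining pooled
#' MAFs), quantifying each variant's contribution to the gene-based signal.
#'
#' @param ms a [combine_scores()] result
#' @param variants gene variant set (default: all; at least 2)
#' @return data.frame ordered by variant position: removed, pos, Q, p,
#'   p_method
#' @export
loo_skat_scan <- function(ms, variants = names(ms$U)) {
  if (length(variants) < 2)
    glyrare_stop("glyrare_bad_meta", "leave-one-out scan needs at least 2 variants")
  pos <- ms$variants$pos[match(variants, ms$variants$id)]
  ord <- order(pos)
  variants <- variants[ord]; pos <- pos[ord]
  rows <- lapply(seq_along(variants), function(k) {
    res <- skat(ms, variants = variants[-k])
    data.frame(removed = variants[k], pos = pos[k],
               Q = res$statistic, p = res$p, p_method = res$p_method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact binomial direction-consistency test
#'
#' One-sided probability that at least k of n independent effects share the
#' previously reported direction under a fair-coin null:
#' p = sum_{i=k}^{n} C(n, i) / 2^n, computed in log space.
#'
#' @param observed_signs,reference_signs vectors of +1/-1 effect directions
#' @return list with k (agreements), n, and the exact p-value
#' @export
direction_consistency <- function(observed_signs, reference_signs) {
  if (length(observed_signs) != length(reference_signs))
    glyrare_stop("glyrare_bad_signs", "sign vectors must have equal length")
  if (any(observed_signs == 0) || any(reference_signs == 0))
    glyrare_stop("glyrare_bad_signs", "zero signs are not allowed")
  n <- length(observed_signs)
  k <- sum(sign(observed_signs) == sign(reference_signs))
  p <- exp(log_sum_exp(lchoose(n, k:n) - n * log(2)))
  list(k = k, n = n, p = min(p, 1))
}

#' Bonferroni significance threshold
#' @param n_tests number of tests performed (>= 1)
#' @param alpha family-wise error level
#' @return alpha / n_tests
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) glyrare_stop("glyrare_bad_meta", "n_tests must be >= 1")
  alpha / n_tests
}
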