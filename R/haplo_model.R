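#' Cohort-level haplotype association model
#'
#' Fits Y = X beta + sum_{m != ref} h_m gamma_m + b + e, where h_m is the
#' expected haplotype dosage, b is a family random intercept (dropped for
#' unrelated cohorts) and the most frequent haplotype is the reference with
#' effect fixed at 0. Family cohorts are fitted by profiled REML over the
#' single variance ratio; the returned gamma covariance is conditional on
#' the fitted variance components. Collinear dosage columns are resolved by
#' dropping the rarest offending haplotype (with a warning) until the design
#' has full rank.
#'
#' @param pheno data.frame with `sample_id`, the trait column, covariates
#'   and optionally a family column
#' @param hd a [em_dosages()] result (or any object with `dosage`,
#'   `frequencies`, `labels`) whose dosage rownames are sample ids
#' @param trait name of the trait column
#' @param covariates covariate column names (may be empty)
#' @param family_col family-identifier column, or NULL for unrelated
#' @param reference reference haplotype label; defaults to the most frequent
#' @param cohort cohort label
#' @return an object of class `haplotype_fit`: gamma (named, length K-1),
#'   vcov, reference, frequencies, n, sigma2, sigma2_b, dropped haplotypes
#' @export
fit_hap_model <- function(pheno, hd, trait = "trait", covariates = character(0),
                          family_col = NULL, reference = NULL,
                          cohort = "cohort1") {
  K <- length(hd$labels)
  if (K < 2)
    glyrare_stop("glyrare_no_variation", "only one haplotype: no association model")
  reference <- reference %||% hd$labels[which.max(hd$frequencies)]
  if (!reference %in% hd$labels)
    glyrare_stop("glyrare_bad_reference", "reference haplotype not in the dosage set")

  keep <- stats::complete.cases(pheno[, c(trait, covariates), drop = FALSE])
  pheno <- pheno[keep, , drop = FALSE]
  i <- match(pheno$sample_id, rownames(hd$dosage))
  if (anyNA(i))
    glyrare_stop("glyrare_bad_spec", "phenotype sample ids missing from dosage matrix")
  H <- hd$dosage[i, setdiff(hd$labels, reference), drop = FALSE]

  y <- pheno[[trait]]
  X <- if (length(covariates) > 0) {
    stats::model.matrix(stats::reformulate(covariates), data = pheno)
  } else {
    matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  }
  fam <- if (is.null(family_col)) pheno$sample_id else as.character(pheno[[family_col]])

  dropped <- character(0)
  repeat {
    D <- cbind(X, H)
    if (qr(D)$rank == ncol(D)) break
    if (ncol(H) == 0)
      glyrare_stop("glyrare_singular_design", "covariate design itself is singular")
    rarest <- colnames(H)[which.min(hd$frequencies[colnames(H)])]
    dropped <- c(dropped, rarest)
    glyrare_warn("glyrare_collinear_haplotype",
                 sprintf("dropping collinear haplotype dosage column %s", rarest))
    H <- H[, setdiff(colnames(H), rarest), drop = FALSE]
  }

  fit <- fit_lmm_blocks(y, D, fam)
  hap_cols <- colnames(H)
  structure(list(cohort = cohort, reference = reference,
                 gamma = fit$beta[hap_cols],
                 vcov = fit$cov_beta[hap_cols, hap_cols, drop = FALSE],
                 beta_covar = fit$beta[colnames(X)],
                 sigma2 = fit$sigma2, sigma2_b = fit$sigma2_b,
                 frequencies = hd$frequencies,
                 dropped = dropped, n = fit$n),
            class = "haplotype_fit")
}

#' @export
print.haplotype_fit <- function(x, ...) {
  cat(sprintf("haplotype_fit (%s): %d non-reference haplotypes, n=%d, reference=%s\n",
              x$cohort, length(x$gamma), x$n, x$reference))
  invisible(x)
}

#' Multivariate fixed-effects meta-analysis of haplotype fits
#'
#' Combines cohort-level haplotype effect vectors by generalized
#' least-squares stacking with selection maps, so cohorts may contribute
#' different (partially overlapping) haplotype sets: with S_c mapping the
#' union set to cohort c's set, the pooled estimate is
#' (sum S_c' V_c^{-1} S_c)^{-1} sum S_c' V_c^{-1} gamma_c with covariance
#' the inverted pooled information. The global association test is the Wald
#' statistic against chi-square with df = |union| - 1 (reference excluded).
#' A per-coordinate scalar inverse-variance mode is available for
#' sensitivity checks.
#'
#' @param fits list of [fit_hap_model()] results sharing one reference
#' @param mode "gls" (multivariate, default) or "scalar" (per-coordinate
#'   inverse-variance, ignoring cross-haplotype covariance)
#' @return an object of class `haplotype_meta_result`
#' @export
meta_hap <- function(fits, mode = c("gls", "scalar")) {
  mode <- match.arg(mode)
  if (length(fits) < 1)
    glyrare_stop("glyrare_bad_meta", "at least one cohort fit is required")
  refs <- unique(vapply(fits, `[[`, "", "reference"))
  if (length(refs) != 1)
    glyrare_stop("glyrare_mismatched_reference",
                 "all cohort fits must share the same reference haplotype")

  union_labels <- unique(unlist(lapply(fits, function(f) names(f$gamma))))
  Ku <- length(union_labels)

  # pooled haplotype frequencies (sample-size weighted; absent = 0)
  all_freq_labels <- unique(unlist(lapply(fits, function(f) names(f$frequencies))))
  wsum <- stats::setNames(numeric(length(all_freq_labels)), all_freq_labels)
  ntot <- 0
  for (f in fits) {
    wsum[names(f$frequencies)] <- wsum[names(f$frequencies)] + f$n * f$frequencies
    ntot <- ntot + f$n
  }
  pooled_freq <- sort(wsum / ntot, decreasing = TRUE)

  A <- matrix(0, Ku, Ku, dimnames = list(union_labels, union_labels))
  bvec <- stats::setNames(numeric(Ku), union_labels)
  contrib <- stats::setNames(vector("list", Ku), union_labels)
  for (f in fits) {
    pos <- match(names(f$gamma), union_labels)
    Vinv <- solve(f$vcov)
    A[pos, pos] <- A[pos, pos] + Vinv
    bvec[pos] <- bvec[pos] + drop(Vinv %*% f$gamma)
    for (k in pos) contrib[[k]] <- c(contrib[[k]], f$cohort)
  }
  if (mode == "scalar") {
    info <- stats::setNames(numeric(Ku), union_labels)
    bvec <- stats::setNames(numeric(Ku), union_labels)
    for (f in fits) {
      pos <- match(names(f$gamma), union_labels)
      vi <- 1 / diag(f$vcov)
      info[pos] <- info[pos] + vi
      bvec[pos] <- bvec[pos] + vi * f$gamma
    }
    A <- diag(info, Ku)
    dimnames(A) <- list(union_labels, union_labels)
  }

  ridge_used <- FALSE
  if (rcond(A) < 1e-12) {
    A <- A + diag(1e-10 * sum(diag(A)), Ku)
    ridge_used <- TRUE
  }
  cov_meta <- solve(A)
  gamma_meta <- drop(cov_meta %*% bvec)
  names(gamma_meta) <- union_labels
  global_stat <- drop(bvec %*% cov_meta %*% bvec)   # gamma' A gamma
  df <- Ku
  global_p <- stats::pchisq(global_stat, df = df, lower.tail = FALSE)

  se <- sqrt(diag(cov_meta))
  z <- gamma_meta / se
  per_hap <- data.frame(haplotype = union_labels,
                        estimate = unname(gamma_meta), se = unname(se),
                        z = unname(z),
                        p = unname(2 * stats::pnorm(-abs(z))),
                        n_cohorts = vapply(contrib, length, 0L),
                        stringsAsFactors = FALSE)

  structure(list(reference = refs, labels = union_labels,
                 gamma = gamma_meta, vcov = cov_meta,
                 global_stat = global_stat, df = df, global_p = global_p,
                 per_hap = per_hap, contributing = contrib,
                 pooled_freq = pooled_freq, mode = mode,
                 ridge_used = ridge_used, n = ntot),
            class = "haplotype_meta_result")
}

#' @export
print.haplotype_meta_result <- function(x, ...) {
  cat(sprintf("haplotype meta-analysis (%s): global chi2=%.4g, df=%d, p=%.3g\n",
              x$mode, x$global_stat, x$df, x$global_p))
  print(x$per_hap, row.names = FALSE)
  invisible(x)
}

#' Report table of a haplotype meta-analysis
#'
#' One row per haplotype (reference included), ordered by decreasing pooled
#' frequency: allele string, pooled frequency, effect estimate, SE and
#' p-value versus the reference; the reference row shows effect 0 and a
#' blank p-value. The global test p-value is attached as the `global_p`
#' attribute.
#'
#' @param res a [meta_hap()] result
#' @return data.frame with attribute `global_p`
#' @export
format_hap_table <- function(res) {
  labs <- names(res$pooled_freq)
  j <- match(labs, res$per_hap$haplotype)
  out <- data.frame(haplotype = labs,
                    frequency = unname(res$pooled_freq),
                    estimate = ifelse(labs == res$reference, 0,
                                      res$per_hap$estimate[j]),
                    se = res$per_hap$se[j],
                    p = res$per_hap$p[j],
                    stringsAsFactors = FALSE)
  out$se[labs == res$reference] <- NA_real_
  out$p[labs == res$reference] <- NA_real_
  # haplotypes never fitted (e.g. pruned everywhere) keep NA effect rows
  attr(out, "global_p") <- res$global_p
  attr(out, "reference") <- res$reference
  out
}
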