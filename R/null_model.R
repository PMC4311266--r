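# Family-block linear mixed model machinery.
#
# The only random effect the analysis needs is a single intercept shared
# within family, so Sigma = sigma_e^2 I + sigma_b^2 J per family block.
# Writing Sigma0 = I + lambda J with lambda = sigma_b^2 / sigma_e^2, the
# block square-root inverse is closed form:
#   Sigma0^{-1/2} x = x - (1 - 1/sqrt(1 + k lambda)) * xbar   (per block)
# so GLS reduces to whitened OLS and REML profiles down to a bracketed
# one-dimensional search in lambda.

block_whitener <- function(fam) {
  fidx <- as.integer(factor(fam, levels = unique(fam)))
  ksize <- tabulate(fidx)
  list(
    fidx = fidx, ksize = ksize,
    apply = function(M, lambda) {
      M <- as.matrix(M)
      if (lambda <= 0) return(M)
      means <- rowsum(M, fidx) / ksize
      shrink <- 1 - 1 / sqrt(1 + ksize * lambda)
      M - (means * shrink)[fidx, , drop = FALSE]
    },
    logdet = function(lambda) sum(log1p(ksize * lambda))
  )
}

# profiled REML fit of y = X beta + b_family + e; lambda >= 0 searched on
# [0, lambda_max] with stats::optimize at tol 1e-8, then endpoints checked.
fit_lmm_blocks <- function(y, X, fam, lambda_max = 1000, tol = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  wh <- block_whitener(fam)

  reml_parts <- function(lambda) {
    Xw <- wh$apply(X, lambda)
    yw <- drop(wh$apply(matrix(y, ncol = 1), lambda))
    qrx <- qr(Xw)
    if (qrx$rank < p)
      glyrare_stop("glyrare_singular_design", "the covariate design is singular")
    beta <- qr.coef(qrx, yw)
    res <- yw - drop(Xw %*% beta)
    rss <- sum(res^2)
    sigma2 <- rss / (n - p)
    R <- qr.R(qrx)
    crit <- -0.5 * (wh$logdet(lambda) + (n - p) * log(sigma2) +
                      2 * sum(log(abs(diag(R)))))
    list(crit = crit, beta = beta, res = res, sigma2 = sigma2,
         qrx = qrx, Xw = Xw, yw = yw, lambda = lambda)
  }

  if (all(wh$ksize == 1L)) {
    best <- reml_parts(0)
  } else {
    opt <- stats::optimize(function(l) -reml_parts(l)$crit,
                           interval = c(0, lambda_max), tol = tol)
    cand <- list(reml_parts(0), reml_parts(opt$minimum))
    best <- cand[[which.max(vapply(cand, `[[`, 0, "crit"))]]
  }

  R <- qr.R(best$qrx)
  cov_unit <- chol2inv(R)   # (Xw'Xw)^{-1}
  dimnames(cov_unit) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(best$beta, colnames(X)),
       cov_beta = best$sigma2 * cov_unit,
       sigma2 = best$sigma2,
       sigma2_b = best$lambda * best$sigma2,
       lambda = best$lambda,
       residuals_w = best$res,
       qr_Xw = best$qrx, Xw = best$Xw, yw = best$yw,
       whiten = function(M) wh$apply(M, best$lambda),
       n = n, p = p)
}

#' Fit the cohort null model for score-statistic extraction
#'
#' Quantitative traits in family cohorts are fitted with a linear mixed
#' model carrying one random intercept per family (profiled REML);
#' quantitative traits in unrelated cohorts reduce to ordinary least
#' squares. Binary traits are fitted by logistic regression after reducing
#' each family to a single member. Rows with missing trait or covariates are
#' dropped listwise.
#'
#' @param pheno data.frame with one row per sample; must contain `sample_id`,
#'   the trait column, the covariates, and the family column if used
#' @param trait name of the trait column
#' @param covariates character vector of covariate column names (may be empty;
#'   an intercept is always included)
#' @param family_col name of the family-identifier column, or NULL for an
#'   unrelated cohort
#' @param trait_kind "quantitative" or "binary"
#' @return an object of class `null_model`
#' @export
fit_null <- function(pheno, trait = "trait", covariates = character(0),
                     family_col = NULL, trait_kind = c("quantitative", "binary")) {
  trait_kind <- match.arg(trait_kind)
  need <- c("sample_id", trait, covariates, family_col)
  miss <- setdiff(need, names(pheno))
  if (length(miss) > 0)
    glyrare_stop("glyrare_missing_column",
                 sprintf("phenotype table lacks column(s): %s",
                         paste(miss, collapse = ", ")))
  keep <- stats::complete.cases(pheno[, c(trait, covariates), drop = FALSE])
  pheno <- pheno[keep, , drop = FALSE]
  y <- pheno[[trait]]
  X <- if (length(covariates) > 0) {
    stats::model.matrix(stats::reformulate(covariates), data = pheno)
  } else {
    matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  }
  fam <- if (is.null(family_col)) pheno$sample_id else as.character(pheno[[family_col]])

  if (trait_kind == "quantitative") {
    fit <- fit_lmm_blocks(y, X, fam)
    out <- list(trait_kind = trait_kind,
                beta = fit$beta, sigma2 = fit$sigma2, sigma2_b = fit$sigma2_b,
                lambda = fit$lambda, residuals_w = fit$residuals_w,
                qr_Xw = fit$qr_Xw, Xw = fit$Xw, whiten = fit$whiten,
                cov_beta = fit$cov_beta,
                sample_ids = pheno$sample_id, family = fam,
                n = fit$n, y = y, X = X)
  } else {
    if (!all(y %in% c(0, 1)))
      glyrare_stop("glyrare_bad_trait", "binary trait must be coded 0/1")
    first <- !duplicated(fam)
    y <- y[first]; X <- X[first, , drop = FALSE]
    ids <- pheno$sample_id[first]
    if (length(unique(y)) < 2)
      glyrare_stop("glyrare_bad_trait", "both classes must be present for a binary trait")
    if (qr(X)$rank < ncol(X))
      glyrare_stop("glyrare_singular_design", "the covariate design is singular")
    fit <- stats::glm.fit(X, y, family = stats::binomial())
    if (!fit$converged)
      glyrare_stop("glyrare_non_convergence",
                   sprintf("logistic null model failed to converge after %d iterations",
                           fit$iter),
                   iterations = fit$iter)
    mu <- fit$fitted.values
    out <- list(trait_kind = trait_kind,
                beta = stats::setNames(fit$coefficients, colnames(X)),
                mu = mu, w = mu * (1 - mu),
                sample_ids = ids, family = fam[first],
                n = length(y), y = y, X = X,
                sigma2 = NA_real_, sigma2_b = 0, lambda = 0)
  }
  class(out) <- "null_model"
  out
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("null_model (%s): n=%d", x$trait_kind, x$n))
  if (x$trait_kind == "quantitative")
    cat(sprintf(", sigma2=%.4g, sigma2_b=%.4g", x$sigma2, x$sigma2_b))
  cat("\n")
  invisible(x)
}
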