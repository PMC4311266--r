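#' Score statistics for a gene from a fitted null model
#'
#' Computes the per-gene score vector U and covariance matrix V that are the
#' interchange unit of meta-analysis, in the usual seqMeta-style scaling:
#' for quantitative traits U = G'~ Sigma^{-1} r and V = G'~ Sigma^{-1} G~
#' with G~ the genotype columns residualised on the null design after
#' whitening by the fitted family covariance, so that U_j / V_jj is the
#' per-allele effect estimate and U_j / sqrt(V_jj) the score z-statistic.
#' Binary traits use the logistic score U = G'(y - mu) with the expected
#' information V = G'WG - G'WX (X'WX)^{-1} X'WG.
#'
#' Missing dosages are imputed to the variant's mean dosage among analysed
#' samples before residualisation. Zero-variance variants contribute
#' U_j = 0, V_jj = 0 and are flagged.
#'
#' @param nm a [fit_null()] model
#' @param g a [genotype_matrix()] containing the null model's samples
#' @param gene variant identifiers forming the gene (default: all variants)
#' @param gene_id label for the gene
#' @param cohort cohort label recorded in the result
#' @return an object of class `score_set` with fields gene, variants
#'   (id, pos, alleles, maf, mac, flagged), U, V, n, trait_kind, cohort
#' @export
score_stats <- function(nm, g, gene = g$variants$id, gene_id = "gene",
                        cohort = "cohort1") {
  gs <- subset_genotypes(g, samples = nm$sample_ids, variants = gene)
  fs <- freq_stats(gs)
  G <- gs$dosage
  # mean imputation of missing dosages
  if (anyNA(G)) {
    mu_g <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu_g[idx[, 2]]
  }
  m <- ncol(G)

  if (nm$trait_kind == "quantitative") {
    Gw <- nm$whiten(G)
    Gt <- qr.resid(nm$qr_Xw, Gw)
    U <- drop(crossprod(Gt, nm$residuals_w)) / nm$sigma2
    V <- crossprod(Gt) / nm$sigma2
  } else {
    sw <- sqrt(nm$w)
    Xw <- nm$X * sw
    Gw <- G * sw
    Gt <- qr.resid(qr(Xw), Gw)
    U <- drop(crossprod(G, nm$y - nm$mu))
    V <- crossprod(Gt)
  }

  flagged <- diag(V) < 1e-12
  if (any(flagged)) {
    U[flagged] <- 0
    V[flagged, ] <- 0
    V[, flagged] <- 0
  }
  names(U) <- gs$variants$id
  dimnames(V) <- list(gs$variants$id, gs$variants$id)

  variants <- data.frame(gs$variants,
                         maf = fs$maf, mac = fs$mac, n_called = fs$n_called,
                         flagged = unname(flagged),
                         stringsAsFactors = FALSE)
  structure(list(gene = gene_id, variants = variants, U = U, V = V,
                 n = nm$n, trait_kind = nm$trait_kind, cohort = cohort),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("score_set %s (%s, cohort %s): %d variants, n=%d\n",
              x$gene, x$trait_kind, x$cohort, length(x$U), x$n))
  invisible(x)
}

# annotation classes considered protein-altering for gene-based tests
DAMAGING_CLASSES <- c("nonsynonymous", "splice-site", "stop-gain", "stop-loss")

#' Select variants for a gene-based test
#'
#' Keeps protein-altering variants (nonsynonymous, splice-site, stop
#' gain/loss) with MAF below `maf_max` and at least one observed minor
#' allele; the gene passes only if the cumulative MAC of the kept variants
#' reaches the trait-kind threshold (20 for quantitative traits, 40 for
#' binary traits by default).
#'
#' @param variant_ids candidate variant identifiers for the gene
#' @param ann data.frame with columns `id` and `class`
#' @param freq per-variant frequency table from [freq_stats()] (or the
#'   pooled analogue), with columns id, maf, mac
#' @param trait_kind "quantitative" or "binary"
#' @param maf_max MAF upper bound for inclusion (exclusive)
#' @param cmac_min cumulative-MAC threshold; defaults to 20/40 by trait kind
#' @return list with `variants` (kept ids), `pass` (logical), `cmaf`, `cmac`
#' @export
select_gene_variants <- function(variant_ids, ann, freq,
                                 trait_kind = c("quantitative", "binary"),
                                 maf_max = 0.01, cmac_min = NULL) {
  trait_kind <- match.arg(trait_kind)
  if (is.null(cmac_min)) cmac_min <- if (trait_kind == "binary") 40 else 20
  cls <- ann$class[match(variant_ids, ann$id)]
  if (anyNA(cls))
    glyrare_stop("glyrare_missing_annotation",
                 "every gene-test variant needs a functional class annotation")
  f <- freq[match(variant_ids, freq$id), ]
  keep <- cls %in% DAMAGING_CLASSES & !is.na(f$maf) &
    f$maf < maf_max & f$mac >= 1
  kept <- variant_ids[keep]
  cmac <- sum(f$mac[keep])
  cmaf <- sum(f$maf[keep])
  list(variants = kept,
       pass = length(kept) > 0 && cmac >= cmac_min,
       cmaf = cmaf, cmac = cmac)
}
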