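#' Genotype dosage matrix
#'
#' Sample x variant diploid dosages in {0, 1, 2} or missing, with per-variant
#' metadata (chromosome, 1-based position, ref/alt alleles, identifier) and a
#' flip log recording variants recoded to the minor allele.
#'
#' @param dosage integer/numeric matrix, samples in rows (rownames = sample
#'   ids), variants in columns
#' @param variants data.frame with columns chrom, pos, id, ref, alt
#' @param flipped logical vector marking variants whose coding has been
#'   flipped to the minor allele
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(dosage, variants,
                            flipped = rep(FALSE, ncol(dosage))) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
  if (anyDuplicated(variants$id))
    glyrare_stop("glyrare_bad_genotypes", "variant identifiers must be unique")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok))
    glyrare_stop("glyrare_bad_genotypes", "dosages must be 0, 1, 2 or missing")
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants, flipped = flipped),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d flipped to minor allele)\n",
              nrow(x$dosage), ncol(x$dosage), sum(x$flipped)))
  invisible(x)
}

#' Recode variants additively to the minor allele
#'
#' Variants whose coded-allele frequency exceeds 0.5 have dosages replaced by
#' 2 - dosage and their ref/alt alleles swapped; the flip is logged. A
#' frequency of exactly 0.5 is left unflipped, so the operation is
#' deterministic and idempotent.
#'
#' @param g a [genotype_matrix()]
#' @return a recoded [genotype_matrix()]
#' @export
recode_to_minor <- function(g) {
  freq <- colMeans(g$dosage, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    g$dosage[, flip] <- 2 - g$dosage[, flip]
    ref <- g$variants$ref[flip]
    g$variants$ref[flip] <- g$variants$alt[flip]
    g$variants$alt[flip] <- ref
    g$flipped[flip] <- !g$flipped[flip]
  }
  g
}

#' Per-variant allele frequency statistics
#'
#' For a matrix already recoded to the minor allele: MAC is the sum of
#' non-missing minor-allele dosages, MAF = MAC / (2 x called samples), and
#' the call rate is the fraction of non-missing genotypes.
#'
#' @param g a [genotype_matrix()]
#' @return data.frame with id, maf, mac, call_rate, n_called
#' @export
freq_stats <- function(g) {
  called <- colSums(!is.na(g$dosage))
  mac <- colSums(g$dosage, na.rm = TRUE)
  maf <- ifelse(called > 0, mac / (2 * called), NA_real_)
  data.frame(id = g$variants$id,
             maf = unname(maf), mac = unname(mac),
             call_rate = unname(called / nrow(g$dosage)),
             n_called = unname(called),
             stringsAsFactors = FALSE)
}

#' Subset a genotype matrix by sample and/or variant identifiers
#' @param g a [genotype_matrix()]
#' @param samples sample ids to keep (in this order); NULL keeps all
#' @param variants variant ids to keep (in this order); NULL keeps all
#' @return a [genotype_matrix()]
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  d <- g$dosage
  v <- g$variants
  fl <- g$flipped
  if (!is.null(variants)) {
    j <- match(variants, v$id)
    if (anyNA(j))
      glyrare_stop("glyrare_bad_genotypes", "unknown variant id in subset")
    d <- d[, j, drop = FALSE]; v <- v[j, , drop = FALSE]; fl <- fl[j]
  }
  if (!is.null(samples)) {
    i <- match(samples, rownames(d))
    if (anyNA(i))
      glyrare_stop("glyrare_bad_genotypes", "unknown sample id in subset")
    d <- d[i, , drop = FALSE]
  }
  genotype_matrix(d, v, fl)
}
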