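#' Haplotype pools
#'
#' A haplotype pool is the generative unit of the synthetic-cohort module: a
#' set of distinct haplotypes over m biallelic variants (allele strings of
#' 0/1 characters, 1 = minor allele) together with their population
#' frequencies. Individuals are later formed by drawing two haplotypes
#' independently from the pool (Hardy-Weinberg random mating).
#'
#' @param variant_labels character vector of variant identifiers (length m)
#' @param haplotype_alleles character vector of allele strings, one 0/1
#'   character per variant
#' @param frequencies numeric vector of haplotype frequencies; normalised to
#'   sum to one
#' @param haplotype_labels optional haplotype names; defaults to H01, H02, ...
#'   in decreasing-frequency order
#' @return an object of class `haplotype_pool`
#' @export
haplotype_pool <- function(variant_labels, haplotype_alleles, frequencies,
                           haplotype_labels = NULL) {
  stopifnot(length(haplotype_alleles) == length(frequencies),
            length(frequencies) >= 1, all(frequencies >= 0))
  m <- nchar(haplotype_alleles[1])
  if (any(nchar(haplotype_alleles) != m))
    glyrare_stop("glyrare_bad_pool", "all haplotype allele strings must have identical length")
  if (length(variant_labels) != m)
    glyrare_stop("glyrare_bad_pool", "variant_labels length must match allele string length")
  if (anyDuplicated(haplotype_alleles))
    glyrare_stop("glyrare_bad_pool", "haplotypes must be distinct")
  if (any(!strsplit(paste(haplotype_alleles, collapse = ""), "")[[1]] %in% c("0", "1")))
    glyrare_stop("glyrare_bad_pool", "allele strings must contain only 0/1")
  frequencies <- frequencies / sum(frequencies)
  ord <- order(frequencies, decreasing = TRUE)
  haplotype_alleles <- haplotype_alleles[ord]
  frequencies <- frequencies[ord]
  if (is.null(haplotype_labels)) {
    haplotype_labels <- sprintf("H%02d", seq_along(frequencies))
  } else {
    haplotype_labels <- haplotype_labels[ord]
  }
  structure(
    list(variant_labels = variant_labels,
         haplotype_alleles = haplotype_alleles,
         frequencies = frequencies,
         haplotype_labels = haplotype_labels),
    class = "haplotype_pool"
  )
}

# K x m 0/1 matrix of pool haplotype alleles
pool_allele_matrix <- function(pool) {
  mat <- do.call(rbind, lapply(strsplit(pool$haplotype_alleles, ""), as.integer))
  dimnames(mat) <- list(pool$haplotype_labels, pool$variant_labels)
  mat
}

#' Variant minor-allele frequencies implied by a haplotype pool
#'
#' @param pool a [haplotype_pool()]
#' @return named numeric vector of per-variant allele-1 frequencies
#' @export
implied_maf <- function(pool) {
  drop(pool$frequencies %*% pool_allele_matrix(pool))
}

#' Reference haplotype of a pool (the most frequent one)
#' @param pool a [haplotype_pool()]
#' @return the reference haplotype label
#' @export
reference_haplotype <- function(pool) {
  pool$haplotype_labels[which.max(pool$frequencies)]
}

#' Drop haplotypes from a pool, renormalising the remaining frequencies
#'
#' Used to emulate cohorts whose genotyping cannot observe some haplotypes.
#' The reference (most frequent) haplotype can never be dropped.
#'
#' @param pool a [haplotype_pool()]
#' @param drop character vector of haplotype labels to remove
#' @return a [haplotype_pool()] over the remaining haplotypes
#' @export
drop_haplotypes <- function(pool, drop) {
  if (length(drop) == 0) return(pool)
  ref <- reference_haplotype(pool)
  if (ref %in% drop)
    glyrare_stop("glyrare_drop_reference",
                 sprintf("cannot drop the reference haplotype %s", ref))
  if (!all(drop %in% pool$haplotype_labels))
    glyrare_stop("glyrare_bad_pool", "unknown haplotype label in drop set")
  keep <- !(pool$haplotype_labels %in% drop)
  haplotype_pool(pool$variant_labels,
                 pool$haplotype_alleles[keep],
                 pool$frequencies[keep],
                 haplotype_labels = pool$haplotype_labels[keep])
}

#' Build a G6PC2-like haplotype pool
#'
#' Constructs the rare-variant architecture the downstream tests exercise:
#' 16 variants, one common (implied MAF about 0.40) and 15 rare (each implied
#' MAF below 1%, cumulative about 1.6%), with each rare minor allele carried
#' on exactly one haplotype. Haplotypes are the all-reference background, one
#' haplotype carrying only the common allele, and one single-rare-allele
#' haplotype per rare variant.
#'
#' @param seed integer seed; the same seed reproduces the same pool
#' @return a [haplotype_pool()] over 17 haplotypes and 16 variants
#' @export
build_g6pc2_like_pool <- function(seed) {
  set.seed(mix_seed(seed, 905L))
  m_rare <- 15L
  f_common <- stats::runif(1, 0.38, 0.42)
  u <- stats::runif(m_rare, 0.5, 2)
  f_rare <- 0.016 * u / sum(u)            # each ~0.0005-0.002, cumulative 0.016
  labels <- c("snv_common", sprintf("snv_rare%02d", seq_len(m_rare)))
  zeros <- strrep("0", m_rare + 1L)
  hap_common <- paste0("1", strrep("0", m_rare))
  hap_rare <- vapply(seq_len(m_rare), function(j) {
    a <- rep("0", m_rare + 1L)
    a[j + 1L] <- "1"
    paste(a, collapse = "")
  }, character(1))
  freqs <- c(1 - f_common - sum(f_rare), f_common, f_rare)
  haplotype_pool(labels, c(zeros, hap_common, hap_rare), freqs)
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d haplotypes x %d variants\n",
              length(x$frequencies), length(x$variant_labels)))
  df <- data.frame(haplotype = x$haplotype_labels,
                   alleles = x$haplotype_alleles,
                   frequency = signif(x$frequencies, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
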