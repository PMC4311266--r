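# Haplotype frequency EM and expected dosages from unphased genotypes.
#
# Individuals are grouped by genotype pattern, so the E-step cost depends on
# the number of distinct patterns and their phase ambiguity, not the sample
# size. Per pattern all compatible ordered haplotype pairs are enumerated:
# homozygous sites fix both alleles, heterozygous sites contribute a 2-way
# phase choice, missing sites are marginalised over all 4 allele pairs.

enumerate_pairs <- function(pattern, max_combos = 65536L) {
  m <- length(pattern)
  het <- which(!is.na(pattern) & pattern == 1L)
  mis <- which(is.na(pattern))
  n_combo <- 2^length(het) * 4^length(mis)
  if (n_combo > max_combos)
    glyrare_stop("glyrare_intractable",
                 "genotype pattern is too ambiguous for diplotype enumeration")
  base <- ifelse(is.na(pattern), 0L, as.integer(pattern >= 1L))
  h1 <- matrix(rep(ifelse(is.na(pattern), 0L, as.integer(pattern == 2L)), n_combo),
               ncol = m, byrow = TRUE)
  h2 <- h1
  h1[, het] <- 1L   # het sites: allele split between the two haplotypes
  combo <- 0:(n_combo - 1)
  bit <- 0L
  for (s in het) {
    swap <- bitwAnd(combo %/% 2^bit, 1L) == 1L
    tmp <- h1[swap, s]; h1[swap, s] <- h2[swap, s]; h2[swap, s] <- tmp
    bit <- bit + 1L
  }
  for (s in mis) {
    a <- bitwAnd(combo %/% 2^bit, 1L); bit <- bit + 1L
    b <- bitwAnd(combo %/% 2^bit, 1L); bit <- bit + 1L
    h1[, s] <- a; h2[, s] <- b
  }
  list(h1 = apply(h1, 1, paste, collapse = ""),
       h2 = apply(h2, 1, paste, collapse = ""))
}

#' EM haplotype frequencies and expected dosages
#'
#' Estimates haplotype frequencies under random mating (Hardy-Weinberg
#' pairing) by EM over the compatible diplotypes of each unphased genotype,
#' and returns each individual's expected haplotype dosage
#' E[copies of haplotype | genotypes]: 0/1/2 exactly where phase is
#' unambiguous, posterior expectations otherwise. Missing genotypes are
#' marginalised over compatible haplotype pairs. Initialisation is the
#' deterministic product of observed allele frequencies; `seed` is accepted
#' for interface compatibility but unused in the default deterministic path.
#'
#' @param g a [genotype_matrix()] or plain dosage matrix over the variant
#'   set (at most ~25 variants; diplotype enumeration must stay tractable)
#' @param tol convergence tolerance on the log-likelihood gain
#' @param max_iter maximum EM iterations
#' @param prune_tol haplotypes with final frequency below this are pruned
#'   and dosages renormalised
#' @param seed unused in the default deterministic path
#' @return an object of class `haplotype_dosage`: labels (allele strings),
#'   frequencies (decreasing), dosage matrix (rows sum to 2), loglik and its
#'   per-iteration trace, iterations, converged flag
#' @export
em_dosages <- function(g, tol = 1e-8, max_iter = 1000L, prune_tol = 1e-6,
                       seed = NULL) {
  D <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  n <- nrow(D); m <- ncol(D)
  if (m > 25)
    glyrare_stop("glyrare_intractable", "more than 25 variants: enumeration intractable")

  key <- apply(D, 1, function(r) paste(ifelse(is.na(r), "N", r), collapse = ""))
  ukey <- unique(key)
  pat_of <- match(key, ukey)
  counts <- tabulate(pat_of, nbins = length(ukey))

  pairs <- lapply(ukey, function(k) {
    r <- suppressWarnings(as.integer(strsplit(chartr("N", "9", k), "")[[1]]))
    r[r == 9L] <- NA_integer_
    enumerate_pairs(r)
  })
  universe <- unique(unlist(lapply(pairs, function(p) c(p$h1, p$h2))))
  pairs <- lapply(pairs, function(p)
    list(i1 = match(p$h1, universe), i2 = match(p$h2, universe)))
  H <- length(universe)

  # deterministic init: product of observed allele frequencies
  pj <- colMeans(D, na.rm = TRUE) / 2
  pj[is.na(pj)] <- 0.5
  amat <- do.call(rbind, lapply(strsplit(universe, ""), as.integer))
  f <- exp(amat %*% log(pmax(pj, 1e-12)) + (1 - amat) %*% log(pmax(1 - pj, 1e-12)))
  f <- pmax(drop(f), 1e-12)
  f <- f / sum(f)

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  iters <- 0L
  converged <- FALSE
  post_list <- vector("list", length(pairs))
  repeat {
    iters <- iters + 1L
    nh <- numeric(H)
    ll <- 0
    for (u in seq_along(pairs)) {
      i1 <- pairs[[u]]$i1; i2 <- pairs[[u]]$i2
      pk <- f[i1] * f[i2]
      s <- sum(pk)
      ll <- ll + counts[u] * log(s)
      post <- pk / s
      post_list[[u]] <- post
      inc <- rowsum(c(post, post), c(i1, i2))
      nh[as.integer(rownames(inc))] <- nh[as.integer(rownames(inc))] +
        counts[u] * inc[, 1]
    }
    loglik_trace <- c(loglik_trace, ll)
    f <- nh / (2 * n)
    if (ll - ll_old < tol && iters > 1L) { converged <- TRUE; break }
    ll_old <- ll
    if (iters >= max_iter) break
  }
  if (!converged)
    glyrare_warn("glyrare_non_convergence",
                 sprintf("EM did not converge within %d iterations", max_iter))

  # expected dosages per pattern, mapped back to individuals
  dos_pat <- matrix(0, length(pairs), H)
  for (u in seq_along(pairs)) {
    i1 <- pairs[[u]]$i1; i2 <- pairs[[u]]$i2
    post <- post_list[[u]]
    inc <- rowsum(c(post, post), c(i1, i2))
    dos_pat[u, as.integer(rownames(inc))] <- inc[, 1]
  }
  dosage <- dos_pat[pat_of, , drop = FALSE]

  keep <- f >= prune_tol
  f <- f[keep] / sum(f[keep])
  dosage <- dosage[, keep, drop = FALSE]
  universe <- universe[keep]
  dosage <- dosage * (2 / rowSums(dosage))

  ord <- order(f, decreasing = TRUE)
  f <- f[ord]; universe <- universe[ord]
  dosage <- dosage[, ord, drop = FALSE]
  dimnames(dosage) <- list(rownames(D), universe)

  structure(list(labels = universe,
                 frequencies = stats::setNames(f, universe),
                 dosage = dosage,
                 loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace,
                 iterations = iters, converged = converged),
            class = "haplotype_dosage")
}

#' @export
print.haplotype_dosage <- function(x, ...) {
  cat(sprintf("haplotype_dosage: %d haplotypes, %d samples, EM %d iterations (loglik %.4f)\n",
              length(x$labels), nrow(x$dosage), x$iterations, x$loglik))
  print(data.frame(haplotype = x$labels, frequency = signif(x$frequencies, 5)),
        row.names = FALSE)
  invisible(x)
}
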