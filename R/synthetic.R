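#' Family structure specification
#'
#' Describes sibship structure: a distribution over sibship sizes. Families
#' are filled until the requested cohort size is reached, so the expected
#' total matches the requested n exactly (the last family is truncated if
#' needed).
#'
#' @param sibship_sizes named numeric vector: names are integer sibship sizes
#'   (>= 1), values are probabilities (normalised internally). The default is
#'   all singletons, i.e. an unrelated cohort.
#' @return an object of class `family_spec`
#' @export
family_spec <- function(sibship_sizes = c("1" = 1)) {
  sizes <- as.integer(names(sibship_sizes))
  if (any(is.na(sizes)) || any(sizes < 1L))
    glyrare_stop("glyrare_bad_spec", "sibship sizes must be named integers >= 1")
  p <- as.numeric(sibship_sizes)
  if (any(p < 0) || sum(p) <= 0)
    glyrare_stop("glyrare_bad_spec", "sibship size probabilities must be non-negative")
  structure(list(sizes = sizes, prob = p / sum(p)), class = "family_spec")
}

#' Trait-generation effect specification
#'
#' Holds the generative parameters of the trait model
#' Y = X beta + sum_m h_m gamma_m + b + e with b ~ N(0, family_sd^2) shared
#' within family and e ~ N(0, residual_sd^2). Binary traits apply a logistic
#' link to the same linear predictor, with an intercept solved numerically so
#' the population prevalence matches `prevalence`.
#'
#' @param haplotype_effects named numeric vector of per-copy haplotype
#'   effects (trait units); the reference haplotype must have effect 0 (or be
#'   omitted). Unnamed haplotypes default to 0.
#' @param covariate_effects named numeric vector of covariate effects; names
#'   `age` and `sex` get realistic marginals (N(50, 10^2), Bernoulli(0.5)),
#'   any other name a standard normal covariate
#' @param family_sd standard deviation of the family random intercept (>= 0)
#' @param residual_sd residual standard deviation (> 0)
#' @param trait_kind "quantitative" or "binary"
#' @param prevalence target case fraction for binary traits
#' @return an object of class `effect_spec`
#' @export
effect_spec <- function(haplotype_effects = numeric(0),
                        covariate_effects = numeric(0),
                        family_sd = 0, residual_sd = 1,
                        trait_kind = c("quantitative", "binary"),
                        prevalence = 0.15) {
  trait_kind <- match.arg(trait_kind)
  if (family_sd < 0) glyrare_stop("glyrare_bad_spec", "family_sd must be >= 0")
  if (residual_sd <= 0) glyrare_stop("glyrare_bad_spec", "residual_sd must be > 0")
  if (trait_kind == "binary" && (prevalence <= 0 || prevalence >= 1))
    glyrare_stop("glyrare_bad_spec", "binary prevalence must be strictly inside (0, 1)")
  structure(list(haplotype_effects = haplotype_effects,
                 covariate_effects = covariate_effects,
                 family_sd = family_sd, residual_sd = residual_sd,
                 trait_kind = trait_kind, prevalence = prevalence),
            class = "effect_spec")
}

# expand a family spec into per-individual family ids summing to exactly n
draw_families <- function(families, n) {
  sizes <- integer(0)
  while (sum(sizes) < n) {
    need <- n - sum(sizes)
    k <- max(16L, ceiling(need / sum(families$sizes * families$prob)))
    idx <- sample.int(length(families$sizes), k, replace = TRUE,
                      prob = families$prob)
    sizes <- c(sizes, families$sizes[idx])
  }
  cum <- cumsum(sizes)
  last <- which(cum >= n)[1]
  sizes <- sizes[seq_len(last)]
  sizes[last] <- sizes[last] - (cum[last] - n)
  sizes <- sizes[sizes > 0L]
  rep(sprintf("F%05d", seq_along(sizes)), times = sizes)
}

#' Draw one synthetic cohort from a haplotype pool
#'
#' Each individual receives two haplotypes drawn independently from the pool
#' frequencies; the unphased genotype is the allele-wise sum. The trait
#' follows the generative model of [effect_spec()]. The returned truth record
#' retains the phased haplotypes, the per-family random intercepts and all
#' parameters, so downstream estimators can be checked against the truth.
#'
#' @param pool a [haplotype_pool()]
#' @param families a [family_spec()]
#' @param effects an [effect_spec()]
#' @param n cohort size (>= 1)
#' @param seed integer seed
#' @param label cohort label
#' @param missing_rate fraction of genotype entries set missing at random
#' @return list with elements `genotypes` (a [genotype_matrix()]),
#'   `phenotypes` (data.frame with sample_id, family_id, trait, covariates),
#'   and `truth` (phased haplotype indices, haplotype dosages, random
#'   intercepts, parameters)
#' @export
draw_cohort <- function(pool, families = family_spec(), effects = effect_spec(),
                        n, seed, label = "cohort1", missing_rate = 0) {
  if (n < 1) glyrare_stop("glyrare_bad_spec", "cohort size n must be >= 1")
  set.seed(mix_seed(seed, 11L))
  K <- length(pool$frequencies)
  A <- pool_allele_matrix(pool)
  m <- ncol(A)

  fam <- draw_families(families, n)
  g1 <- sample.int(K, n, replace = TRUE, prob = pool$frequencies)
  g2 <- sample.int(K, n, replace = TRUE, prob = pool$frequencies)
  G <- A[g1, , drop = FALSE] + A[g2, , drop = FALSE]
  sample_ids <- sprintf("%s_S%05d", label, seq_len(n))
  rownames(G) <- sample_ids

  # expected-copy truth dosage (here exact counts, phase known)
  H <- matrix(0L, n, K, dimnames = list(sample_ids, pool$haplotype_labels))
  idx <- cbind(seq_len(n), g1)
  H[idx] <- H[idx] + 1L
  idx <- cbind(seq_len(n), g2)
  H[idx] <- H[idx] + 1L

  # covariates
  covars <- effects$covariate_effects
  Xc <- NULL
  if (length(covars) > 0) {
    Xc <- sapply(names(covars), function(nm) {
      switch(nm,
             age = stats::rnorm(n, 50, 10),
             sex = stats::rbinom(n, 1, 0.5),
             stats::rnorm(n))
    })
    Xc <- matrix(Xc, nrow = n, dimnames = list(sample_ids, names(covars)))
  }

  gam <- stats::setNames(rep(0, K), pool$haplotype_labels)
  if (length(effects$haplotype_effects) > 0) {
    nm <- names(effects$haplotype_effects)
    if (!all(nm %in% pool$haplotype_labels))
      glyrare_stop("glyrare_bad_spec", "haplotype_effects name not in pool")
    gam[nm] <- effects$haplotype_effects
  }
  ref <- reference_haplotype(pool)
  if (abs(gam[ref]) > 0)
    glyrare_stop("glyrare_bad_spec", "the reference haplotype effect must be 0")

  fam_levels <- unique(fam)
  b_fam <- stats::setNames(stats::rnorm(length(fam_levels), 0, effects$family_sd), fam_levels)
  b <- b_fam[fam]
  lp <- drop(H %*% gam) + b
  if (!is.null(Xc)) lp <- lp + drop(Xc %*% covars)

  if (effects$trait_kind == "quantitative") {
    y <- lp + stats::rnorm(n, 0, effects$residual_sd)
    status <- rep(NA_integer_, n)
  } else {
    f <- function(c0) mean(stats::plogis(c0 + lp)) - effects$prevalence
    sol <- tryCatch(stats::uniroot(f, c(-50, 50), tol = 1e-10),
                    error = function(e) NULL)
    if (is.null(sol))
      glyrare_stop("glyrare_degenerate_prevalence",
                   "implied prevalence is 0 or 1; cannot generate a binary trait")
    pr <- stats::plogis(sol$root + lp)
    y <- stats::rbinom(n, 1, pr)
    status <- y
  }

  if (missing_rate > 0) {
    miss <- stats::runif(n * m) < missing_rate
    G[matrix(miss, n, m)] <- NA_integer_
  }

  variants <- data.frame(
    chrom = "2",
    pos = 169757930L + 400L * (seq_len(m) - 1L),
    id = pool$variant_labels,
    ref = "A", alt = "G",
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(G, variants)
  pheno <- data.frame(sample_id = sample_ids, family_id = fam,
                      trait = y, status = status,
                      stringsAsFactors = FALSE)
  if (!is.null(Xc)) pheno <- cbind(pheno, as.data.frame(Xc))

  truth <- list(label = label, hap1 = g1, hap2 = g2,
                hap_labels = pool$haplotype_labels,
                hap_dosage = H, b = unname(b), family = fam,
                gamma = gam, effects = effects, pool = pool, seed = seed)
  list(genotypes = gm, phenotypes = pheno, truth = truth)
}

#' Draw a consortium of cohorts with possibly different haplotype sets
#'
#' Each cohort spec may drop haplotypes from the pool (frequencies are
#' renormalised), emulating cohorts that cannot observe some haplotypes; the
#' reference haplotype must be observable everywhere. A manifest records the
#' haplotype set each cohort can observe.
#'
#' @param pool a [haplotype_pool()]
#' @param cohort_specs list of specs; each a list with `n` (size) and
#'   optionally `label`, `drop` (haplotype labels), `families`
#'   (a [family_spec()]), `effects` (an [effect_spec()]), `missing_rate`
#' @param seed integer master seed; cohort index is mixed into the stream
#' @return list with `cohorts` (list of [draw_cohort()] results) and
#'   `manifest` (named list of observable haplotype labels per cohort)
#' @export
draw_consortium <- function(pool, cohort_specs, seed) {
  if (length(cohort_specs) < 1)
    glyrare_stop("glyrare_bad_spec", "at least one cohort spec is required")
  manifest <- list()
  cohorts <- vector("list", length(cohort_specs))
  for (i in seq_along(cohort_specs)) {
    spec <- cohort_specs[[i]]
    label <- spec$label %||% sprintf("cohort%d", i)
    pool_i <- drop_haplotypes(pool, spec$drop %||% character(0))
    cohorts[[i]] <- draw_cohort(
      pool_i,
      families = spec$families %||% family_spec(),
      effects = spec$effects %||% effect_spec(),
      n = spec$n, seed = mix_seed(seed, i), label = label,
      missing_rate = spec$missing_rate %||% 0
    )
    manifest[[label]] <- pool_i$haplotype_labels
  }
  names(cohorts) <- names(manifest)
  list(cohorts = cohorts, manifest = manifest)
}
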