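test_that("EM dosages are exact when phase is unambiguous", {
  # one variant: haplotype frequencies equal allele frequencies, dosages equal genotypes
  D <- matrix(c(0, 1, 2, 1, 0, 0), ncol = 1,
              dimnames = list(sprintf("S%d", 1:6), "v1"))
  hd <- em_dosages(D)
  expect_equal(sort(unname(hd$frequencies), decreasing = TRUE),
               c(8 / 12, 4 / 12))
  expect_equal(unname(hd$dosage[, "1"]), unname(D[, 1]))
  expect_equal(rowSums(hd$dosage), rep(2, 6), ignore_attr = TRUE)

  # individuals heterozygous at <= 1 site have integer dosages
  set.seed(81)
  D2 <- cbind(rbinom(40, 2, 0.3), rbinom(40, 2, 0.2), rbinom(40, 2, 0.1))
  rownames(D2) <- sprintf("S%d", 1:40)
  hd2 <- em_dosages(D2)
  nhet <- rowSums(D2 == 1)
  unamb <- nhet <= 1
  expect_true(all(abs(hd2$dosage[unamb, ] - round(hd2$dosage[unamb, ])) < 1e-9))
  # monomorphic input: a single haplotype with frequency 1
  hd0 <- em_dosages(matrix(0, 5, 2, dimnames = list(sprintf("S%d", 1:5), NULL)))
  expect_equal(unname(hd0$frequencies), 1)
  expect_equal(unname(hd0$dosage[, 1]), rep(2, 5))
})

test_that("EM frequencies maximise the diplotype likelihood (brute-force oracle) and the trace is monotone", {
  set.seed(83)
  pool <- tiny_pool(c(0.55, 0.2, 0.15, 0.1))
  co <- draw_cohort(pool, n = 50, seed = 85)
  D <- co$genotypes$dosage
  hd <- em_dosages(D, tol = 1e-12)
  oracle <- bruteforce_hap_freqs(D)
  for (h in names(hd$frequencies)) {
    expect_lt(abs(hd$frequencies[[h]] - oracle[[h]]), 1e-4)
  }
  expect_true(all(diff(hd$loglik_trace) > -1e-9))
  # total expected haplotype count is twice the sample size
  expect_equal(sum(hd$dosage), 2 * nrow(D))
  expect_equal(sum(hd$frequencies), 1, tolerance = 1e-10)
})

test_that("EM marginalises missing genotypes over compatible haplotype pairs", {
  set.seed(87)
  pool <- tiny_pool()
  co <- draw_cohort(pool, n = 300, seed = 89)
  D <- co$genotypes$dosage
  Dm <- D
  Dm[sample(length(Dm), 30)] <- NA
  hd <- em_dosages(Dm)
  expect_equal(rowSums(hd$dosage), rep(2, nrow(D)), ignore_attr = TRUE)
  hd_full <- em_dosages(D)
  common <- intersect(names(hd$frequencies), names(hd_full$frequencies))
  expect_gt(length(common), 2)
  expect_lt(max(abs(hd$frequencies[common] - hd_full$frequencies[common])), 0.05)
})

test_that("the haplotype model reduces to OLS with two haplotypes and matches the GLS oracle", {
  set.seed(91)
  pool <- haplotype_pool(c("v1"), c("0", "1"), c(0.7, 0.3))
  co <- draw_cohort(pool, effects = effect_spec(haplotype_effects = c(H02 = 0.4)),
                    n = 400, seed = 93)
  hd <- em_dosages(co$genotypes)
  hf <- fit_hap_model(co$phenotypes, hd)
  slope <- coef(lm(co$phenotypes$trait ~ hd$dosage[, 2]))[2]
  expect_equal(unname(hf$gamma), unname(slope), tolerance = 1e-10)

  # family cohort: equals explicit GLS at the fitted variance components
  co2 <- draw_cohort(tiny_pool(), family_spec(c("2" = 0.5, "3" = 0.5)),
                     effect_spec(haplotype_effects = c(H02 = 0.5, H03 = -0.3),
                                 family_sd = 1, residual_sd = 1),
                     n = 600, seed = 95)
  hd2 <- em_dosages(co2$genotypes)
  hf2 <- fit_hap_model(co2$phenotypes, hd2, family_col = "family_id")
  i <- match(co2$phenotypes$sample_id, rownames(hd2$dosage))
  H <- hd2$dosage[i, setdiff(hd2$labels, hf2$reference), drop = FALSE]
  Dmat <- cbind(1, H)
  gls <- gls_oracle(co2$phenotypes$trait, Dmat, co2$phenotypes$family_id,
                    hf2$sigma2_b, hf2$sigma2)
  expect_equal(unname(hf2$gamma), unname(gls$beta[-1]), tolerance = 1e-6)
  expect_equal(unname(hf2$vcov), unname(gls$cov[-1, -1]), tolerance = 1e-6)
  # degenerate input: a single haplotype has no association model
  expect_error(fit_hap_model(co2$phenotypes,
                             list(labels = "000", frequencies = c(`000` = 1),
                                  dosage = matrix(2, nrow(co2$phenotypes), 1,
                                                  dimnames = list(co2$phenotypes$sample_id, "000")))),
               class = "glyrare_no_variation")
})

test_that("haplotype effects are recovered without bias under family structure", {
  reps <- 200
  est <- matrix(NA_real_, reps, 3)
  truth <- c(0.5, -0.3, 0)
  pool <- tiny_pool()
  for (r in seq_len(reps)) {
    co <- draw_cohort(pool, family_spec(c("2" = 0.5, "3" = 0.5)),
                      effect_spec(haplotype_effects = c(H02 = 0.5, H03 = -0.3),
                                  family_sd = 1, residual_sd = 1),
                      n = 1000, seed = 20000 + r)
    # a handful of replicates see a vanishing haplotype whose frequency decays
    # slower than the iteration cap; the dosages are converged for our purpose
    hd <- suppressWarnings(em_dosages(co$genotypes))
    hf <- fit_hap_model(co$phenotypes, hd, family_col = "family_id")
    lab <- c("100", "010", "001")
    est[r, ] <- hf$gamma[lab]
  }
  for (j in 1:3) {
    se <- sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - truth[j]), 3 * se)
  }
})

test_that("EM-dosage and truth-phase fits agree when phase ambiguity is rare", {
  # rare-only architecture: haplotypes carry at most one minor allele, so a
  # phase-ambiguous individual needs two distinct rare haplotypes (< 0.1%)
  pool <- drop_haplotypes(build_g6pc2_like_pool(31), "H02")
  co <- draw_cohort(pool, effects = effect_spec(haplotype_effects = c(H03 = 0.5),
                                                residual_sd = 1),
                    n = 3000, seed = 97)
  hd <- em_dosages(co$genotypes)
  # the architecture keeps phase-ambiguous individuals rare (< 5%)
  amb <- rowSums(abs(hd$dosage - round(hd$dosage)) > 1e-9) > 0
  expect_lt(mean(amb), 0.05)
  hf_em <- suppressWarnings(fit_hap_model(co$phenotypes, hd))
  truth_hd <- list(labels = colnames(co$truth$hap_dosage),
                   frequencies = pool$frequencies,
                   dosage = co$truth$hap_dosage)
  names(truth_hd$frequencies) <- pool$haplotype_labels
  hf_tr <- suppressWarnings(fit_hap_model(co$phenotypes, truth_hd))
  # align by haplotype allele strings vs labels
  A <- glyrare:::pool_allele_matrix(pool)
  str_of <- apply(A, 1, paste, collapse = "")
  gamma_tr <- setNames(hf_tr$gamma, str_of[match(names(hf_tr$gamma),
                                                 pool$haplotype_labels)])
  common <- intersect(names(hf_em$gamma), names(gamma_tr))
  expect_gt(length(common), 10)
  expect_lt(mean(abs(hf_em$gamma[common] - gamma_tr[common])), 0.02)
})

test_that("haplotype meta-analysis satisfies identity, additivity and missing-haplotype laws", {
  set.seed(99)
  pool <- tiny_pool()
  co <- draw_cohort(pool, effects = effect_spec(haplotype_effects = c(H02 = 0.4)),
                    n = 500, seed = 101)
  hd <- em_dosages(co$genotypes)
  hf <- fit_hap_model(co$phenotypes, hd, cohort = "A")

  # one cohort: identity
  m1 <- meta_hap(list(hf))
  expect_equal(m1$gamma, hf$gamma)
  expect_equal(unname(m1$vcov), unname(hf$vcov), tolerance = 1e-12)
  # two identical cohorts: same estimate, covariance halved
  hfB <- hf; hfB$cohort <- "B"
  m2 <- meta_hap(list(hf, hfB))
  expect_equal(m2$gamma, hf$gamma)
  expect_equal(unname(m2$vcov), unname(hf$vcov) / 2, tolerance = 1e-12)

  # a cohort missing a haplotype: the union estimate for it comes from the
  # remaining cohorts alone (block-GLS law)
  co2 <- draw_cohort(drop_haplotypes(pool, "H04"),
                     effects = effect_spec(haplotype_effects = c(H02 = 0.4)),
                     n = 500, seed = 103, label = "B")
  hf2 <- fit_hap_model(co2$phenotypes, em_dosages(co2$genotypes), cohort = "B")
  expect_false("001" %in% names(hf2$gamma))
  m3 <- meta_hap(list(hf, hf2))
  # with "001" only observed in cohort A, its pooled information row couples
  # to shared haplotypes; verify against an explicit stacked-GLS computation
  union <- m3$labels
  A1 <- matrix(0, length(union), length(union), dimnames = list(union, union))
  b1 <- setNames(numeric(length(union)), union)
  for (f in list(hf, hf2)) {
    pos <- match(names(f$gamma), union)
    Vi <- solve(f$vcov)
    A1[pos, pos] <- A1[pos, pos] + Vi
    b1[pos] <- b1[pos] + drop(Vi %*% f$gamma)
  }
  expect_equal(m3$gamma, drop(solve(A1) %*% b1)[union], tolerance = 1e-10)
  expect_equal(m3$per_hap$n_cohorts[match("001", m3$per_hap$haplotype)], 1L)

  # diagonal covariances: multivariate GLS equals scalar inverse-variance
  hfD <- hf; hfD$vcov <- diag(diag(hf$vcov)); dimnames(hfD$vcov) <- dimnames(hf$vcov)
  hfD2 <- hfD; hfD2$cohort <- "B"
  hfD2$gamma <- hfD$gamma + 0.1
  mg <- meta_hap(list(hfD, hfD2), mode = "gls")
  msc <- meta_hap(list(hfD, hfD2), mode = "scalar")
  expect_equal(mg$gamma, msc$gamma, tolerance = 1e-12)
  expect_equal(mg$global_stat, msc$global_stat, tolerance = 1e-12)

  # mismatched references are rejected
  hfR <- hf2; hfR$reference <- "100"
  expect_error(meta_hap(list(hf, hfR)), class = "glyrare_mismatched_reference")
})

test_that("the report table is ordered by pooled frequency with a zero-effect reference row", {
  pool <- tiny_pool()
  co <- draw_cohort(pool, effects = effect_spec(haplotype_effects = c(H02 = 0.3)),
                    n = 400, seed = 105)
  hf <- fit_hap_model(co$phenotypes, em_dosages(co$genotypes))
  res <- meta_hap(list(hf))
  tab <- format_hap_table(res)
  expect_equal(nrow(tab), length(res$pooled_freq))
  expect_true(all(diff(tab$frequency) <= 0))
  expect_identical(tab$haplotype[1], res$reference)  # reference is most frequent
  expect_equal(tab$estimate[1], 0)
  expect_true(is.na(tab$p[1]))
  expect_equal(sum(tab$frequency), 1, tolerance = 1e-6)
  expect_equal(attr(tab, "global_p"), res$global_p)
})

test_that("the global haplotype test outranks the burden test under opposing rare effects", {
  reps <- 500
  pool <- build_g6pc2_like_pool(51)
  alpha <- 0.05
  rej_hap <- rej_wst <- 0L
  ann <- data.frame(id = pool$variant_labels,
                    class = ifelse(grepl("rare", pool$variant_labels),
                                   "nonsynonymous", "other"))
  eff <- effect_spec(haplotype_effects = c(H03 = 0.8, H04 = -0.8),
                     residual_sd = 1)
  for (r in seq_len(reps)) {
    cons <- draw_consortium(pool, list(list(n = 1000, effects = eff),
                                       list(n = 1000, effects = eff),
                                       list(n = 1000, effects = eff)),
                            seed = 30000 + r)
    fits <- list(); sets <- list()
    for (k in seq_along(cons$cohorts)) {
      co <- cons$cohorts[[k]]
      nm <- fit_null(co$phenotypes)
      g <- recode_to_minor(co$genotypes)
      sets[[k]] <- score_stats(nm, g, cohort = sprintf("c%d", k))
      truth_hd <- list(labels = colnames(co$truth$hap_dosage),
                       frequencies = setNames(pool$frequencies,
                                              pool$haplotype_labels),
                       dosage = co$truth$hap_dosage)
      fits[[k]] <- suppressWarnings(
        fit_hap_model(co$phenotypes, truth_hd, cohort = sprintf("c%d", k)))
    }
    mh <- meta_hap(fits)
    if (mh$global_p < alpha) rej_hap <- rej_hap + 1L
    ms <- combine_scores(sets)
    sel <- select_gene_variants(ms$variants$id, ann,
                                ms$variants[, c("id", "maf", "mac")],
                                "quantitative")
    if (sel$pass && wst_burden(ms, sel$variants)$p < alpha)
      rej_wst <- rej_wst + 1L
  }
  expect_gt(rej_hap / reps, rej_wst / reps)
})
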