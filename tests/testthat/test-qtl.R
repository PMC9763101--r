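# Cis-QTL mapping: nominal/permutation/conditional passes, interactions,
# RTC, sharing.

test_that("nominal pass: perfect association, window bounds, null p", {
  n <- 80
  gm <- tiny_genotypes(n = n, m = 3, seed = 1,
                       pos = c(5e5, 9e5, 2.6e6))   # third is 1.5 Mb away
  y <- gm$dosages[, 1]
  pm <- tiny_phenotypes(cbind(y), kind = "normalized",
                        start = 1.1e6, sample_ids = gm$sample_ids)
  res <- nominal_pass(pm, gm, window = 1e6)
  expect_equal(sort(res$variant_id), sort(gm$variant_ids[1:2]))  # cis only
  hit <- res[res$variant_id == gm$variant_ids[1], ]
  expect_equal(hit$slope, 1, tolerance = 1e-10)
  expect_lt(hit$p, 1e-30)
  expect_equal(hit$distance, 5e5 - 1.1e6)
})

test_that("nominal p-values are uniform under the null", {
  set.seed(2)
  n <- 100
  gm <- tiny_genotypes(n = n, m = 100, seed = 3)
  pm <- tiny_phenotypes(matrix(rnorm(n * 100), n), kind = "normalized",
                        start = rep(1e6, 100) + seq_len(100),
                        sample_ids = gm$sample_ids)
  res <- nominal_pass(pm, gm)
  expect_gt(nrow(res), 9000)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("single-variant permutation pass: adjusted ~ nominal (Beta ~ U)", {
  set.seed(4)
  n <- 150
  gm <- tiny_genotypes(n = n, m = 1, seed = 4, pos = 1e6)
  pm <- tiny_phenotypes(matrix(rnorm(n * 50), n), kind = "normalized",
                        start = rep(1e6, 50) + seq_len(50),
                        sample_ids = gm$sample_ids)
  res <- permutation_pass(pm, gm, n_perm = 1000, seed = 1)
  # with one variant the minimum is the only p: Beta(a~1, b~1)
  expect_equal(mean(res$beta_a), 1, tolerance = 0.15)
  expect_equal(cor(res$p_adjusted, res$p_nominal), 1, tolerance = 0.05)
  expect_lt(max(abs(res$p_adjusted - res$p_nominal)), 0.2)
})

test_that("a strong planted QTL is detected with a tiny adjusted p", {
  set.seed(5)
  n <- 200
  gm <- tiny_genotypes(n = n, m = 50, seed = 5, maf = 0.3)
  y <- 0.8 * gm$dosages[, 25] + rnorm(n)
  pm <- tiny_phenotypes(cbind(y), kind = "normalized",
                        start = gm$pos[25], sample_ids = gm$sample_ids)
  res <- permutation_pass(pm, gm, n_perm = 1000, seed = 2)
  expect_identical(res$variant_id, gm$variant_ids[25])
  expect_lt(res$p_adjusted, 0.001)
})

test_that("beta-adjusted p agrees with a deep direct-permutation oracle", {
  # moderate effects so the 20,000-permutation empirical p is estimable
  set.seed(6)
  n <- 200
  gm <- tiny_genotypes(n = n, m = 50, seed = 6, maf = 0.3)
  ratios <- replicate(5, {
    y <- 0.33 * gm$dosages[, sample(50, 1)] + rnorm(n)
    pm <- tiny_phenotypes(cbind(y), kind = "normalized", start = 1e6,
                          sample_ids = gm$sample_ids)
    res <- permutation_pass(pm, gm, n_perm = 1000,
                            seed = sample.int(1e6, 1))
    # direct oracle: 20,000 fresh permutations of y
    X <- scale(gm$dosages)
    best_obs <- max(abs(cor(y, gm$dosages)))
    perm_best <- replicate(20000, max(abs(crossprod(scale(y[sample(n)]), X) /
                                            (n - 1))))
    p_emp <- (1 + sum(perm_best >= best_obs)) / 20001
    res$p_adjusted / p_emp
  })
  expect_true(all(ratios > 0.5 & ratios < 2))
})

test_that("null permutation pass yields uniform adjusted p", {
  set.seed(7)
  n <- 120
  gm <- tiny_genotypes(n = n, m = 50, seed = 7)
  pm <- tiny_phenotypes(matrix(rnorm(n * 150), n), kind = "normalized",
                        start = rep(1e6, 150) + seq_len(150),
                        sample_ids = gm$sample_ids)
  res <- permutation_pass(pm, gm, n_perm = 300, seed = 3)
  expect_gt(ks.test(res$p_adjusted, "punif")$p.value, 0.01)
  # permuting variant order changes nothing
  ord <- sample(50)
  gm2 <- subset_variants(gm, ord)
  res2 <- permutation_pass(pm, gm2, n_perm = 300, seed = 3)
  expect_equal(res2$p_adjusted, res$p_adjusted)
  expect_identical(res2$variant_id, res$variant_id)
})

test_that("conditional scan separates independent signals", {
  set.seed(8)
  n <- 300
  found <- replicate(10, {
    gm <- tiny_genotypes(n = n, m = 60, seed = sample.int(1e6, 1), maf = 0.4)
    v1 <- 10; v2 <- 50
    y <- 0.8 * gm$dosages[, v1] + 0.8 * gm$dosages[, v2] + rnorm(n)
    pm <- tiny_phenotypes(cbind(y), kind = "normalized", start = 1e6,
                          sample_ids = gm$sample_ids)
    # only run when the two dosage vectors are essentially unlinked
    if (cor(gm$dosages[, v1], gm$dosages[, v2])^2 >= 0.01) return(NA)
    pr <- permutation_pass(pm, gm, n_perm = 300, seed = 4)
    cr <- conditional_pass(pm, gm, pr, fdr = 0.05)
    setequal(cr$variant_id, gm$variant_ids[c(v1, v2)])
  })
  found <- found[!is.na(found)]
  expect_gte(mean(found), 0.9)
})

test_that("conditional scan reports one signal for one planted QTL", {
  set.seed(9)
  n <- 250
  extra <- replicate(10, {
    gm <- tiny_genotypes(n = n, m = 40, seed = sample.int(1e6, 1), maf = 0.3)
    y <- 0.7 * gm$dosages[, 20] + rnorm(n)
    pm <- tiny_phenotypes(cbind(y), kind = "normalized", start = 1e6,
                          sample_ids = gm$sample_ids)
    pr <- permutation_pass(pm, gm, n_perm = 300, seed = 5)
    nrow(conditional_pass(pm, gm, pr, fdr = 0.05))
  })
  expect_gte(mean(extra == 1), 0.9)
  expect_true(all(extra <= 2))
})

test_that("perfectly linked variants yield exactly one conditional signal", {
  set.seed(10)
  n <- 200
  gm0 <- tiny_genotypes(n = n, m = 10, seed = 10, maf = 0.4)
  d <- gm0$dosages
  d[, 6] <- d[, 5]                      # perfect LD pair
  gm <- genotype_matrix(d, gm0$chrom, gm0$pos)
  y <- 0.9 * d[, 5] + rnorm(n)
  pm <- tiny_phenotypes(cbind(y), kind = "normalized", start = 1e6,
                        sample_ids = gm$sample_ids)
  pr <- permutation_pass(pm, gm, n_perm = 300, seed = 6)
  cr <- conditional_pass(pm, gm, pr, fdr = 0.05)
  expect_equal(nrow(cr), 1L)
  expect_true(cr$variant_id %in% gm$variant_ids[5:6])
})

test_that("interaction test is calibrated and sign-symmetric", {
  set.seed(11)
  n <- 250
  s <- rep(c(1, 0), c(100, 150))
  meta <- sample_metadata(sprintf("S%04d", 1:n),
                          ifelse(s == 1, "case", "control"))
  m <- 400
  gm <- tiny_genotypes(n = n, m = m, seed = 11, maf = 0.3,
                       pos = seq_len(m) * 1000L)
  vals <- 0.5 * gm$dosages + 0.3 * s + matrix(rnorm(n * m), n)  # no interaction
  pm <- tiny_phenotypes(vals, kind = "normalized",
                        start = seq_len(m) * 1000L,
                        sample_ids = gm$sample_ids)
  recs <- data.frame(phenotype_id = pm$feature_ids,
                     variant_id = gm$variant_ids)
  res <- interaction_qtl(pm, gm, meta, recs)
  expect_equal(mean(res$p_interaction < 0.05), 0.05, tolerance = 0.05)
  expect_gt(ks.test(res$p_interaction, "punif")$p.value, 0.01)
  # flipped status coding: slope sign flips, p unchanged
  meta_f <- sample_metadata(meta$sample_id,
                            ifelse(s == 1, "control", "case"))
  res_f <- interaction_qtl(pm, gm, meta_f, recs[1:50, ])
  expect_equal(res_f$slope_interaction, -res$slope_interaction[1:50],
               tolerance = 1e-9)
  expect_equal(res_f$p_interaction, res$p_interaction[1:50],
               tolerance = 1e-9)
  # single-group data refused
  meta_1 <- sample_metadata(meta$sample_id, rep("case", n))
  expect_error(interaction_qtl(pm, gm, meta_1, recs), "both")
})

test_that("interaction test has power for a case-only slope", {
  set.seed(12)
  n <- 250
  s <- rep(c(1, 0), c(100, 150))
  meta <- sample_metadata(sprintf("S%04d", 1:n),
                          ifelse(s == 1, "case", "control"))
  m <- 200
  gm <- tiny_genotypes(n = n, m = m, seed = 12, maf = 0.3,
                       pos = seq_len(m) * 1000L)
  vals <- 0.6 * gm$dosages * s + matrix(rnorm(n * m), n)
  pm <- tiny_phenotypes(vals, kind = "normalized",
                        start = seq_len(m) * 1000L,
                        sample_ids = gm$sample_ids)
  recs <- data.frame(phenotype_id = pm$feature_ids,
                     variant_id = gm$variant_ids)
  res <- interaction_qtl(pm, gm, meta, recs)
  expect_gte(mean(res$p_interaction < 0.05), 0.8)
  expect_gt(mean(res$slope_case - res$slope_control, na.rm = TRUE), 0.4)
})

test_that("RTC is high for shared signals and refuses split intervals", {
  set.seed(13)
  n <- 300
  hots <- interval_set(c("chr1", "chr1"), c(0L, 60000L), c(60000L, 120000L))
  rtcs <- replicate(15, {
    gm <- tiny_genotypes(n = n, m = 50, seed = sample.int(1e6, 1),
                         pos = sort(sample(59000L, 50)))
    qv <- sample(50, 1)
    # GWAS variant in perfect LD with (identical to a copy of) the QTL variant
    d <- cbind(gm$dosages, gwas_copy = gm$dosages[, qv])
    gm2 <- genotype_matrix(d, c(gm$chrom, "chr1"), c(gm$pos, 59500L))
    qid <- colnames(gm$dosages)[qv]
    gid <- "gwas_copy"
    y <- 0.8 * d[, qv] + rnorm(n)
    pm <- tiny_phenotypes(cbind(y), kind = "normalized", start = 1000L,
                          sample_ids = gm2$sample_ids)
    rec <- data.frame(phenotype_id = pm$feature_ids[1], variant_id = qid)
    rtc(rec, gid, pm, gm2, hots)$rtc
  })
  expect_gte(mean(rtcs >= 0.9), 0.9)
  # unrelated GWAS variant: RTC spread over [0, 1]
  null_rtcs <- replicate(15, {
    gm <- tiny_genotypes(n = n, m = 50, seed = sample.int(1e6, 1),
                         pos = sort(sample(59000L, 50)))
    y <- 0.8 * gm$dosages[, 10] + rnorm(n)
    pm <- tiny_phenotypes(cbind(y), kind = "normalized", start = 1000L,
                          sample_ids = gm$sample_ids)
    rec <- data.frame(phenotype_id = pm$feature_ids[1],
                      variant_id = gm$variant_ids[10])
    rtc(rec, gm$variant_ids[40], pm, gm, hots)$rtc
  })
  expect_gt(max(null_rtcs) - min(null_rtcs), 0.3)
  # different hotspot intervals -> refused
  gm <- tiny_genotypes(n = 50, m = 2, seed = 14, pos = c(1000L, 70000L))
  pm <- tiny_phenotypes(cbind(rnorm(50)), kind = "normalized", start = 1000L,
                        sample_ids = gm$sample_ids)
  rec <- data.frame(phenotype_id = pm$feature_ids[1],
                    variant_id = gm$variant_ids[1])
  expect_error(rtc(rec, gm$variant_ids[2], pm, gm, hots), "same hotspot")
})

test_that("sharing pi1 tracks the preserved fraction of effects", {
  set.seed(15)
  n <- 200
  m <- 60
  gm <- tiny_genotypes(n = n, m = m, seed = 15, maf = 0.3,
                       pos = seq_len(m) * 1000L)
  gm_rep <- tiny_genotypes(n = n, m = m, seed = 16, maf = 0.3,
                           pos = seq_len(m) * 1000L)
  recs <- data.frame(phenotype_id = sprintf("F%05d", seq_len(m)),
                     variant_id = gm$variant_ids)
  mk_pm <- function(g, frac_effect) {
    vals <- matrix(rnorm(n * m), n)
    k <- round(frac_effect * m)
    if (k > 0) vals[, seq_len(k)] <- vals[, seq_len(k)] +
        0.8 * g$dosages[, seq_len(k)]
    tiny_phenotypes(vals, kind = "normalized", start = seq_len(m) * 1000L,
                    sample_ids = g$sample_ids)
  }
  # replication = discovery signal everywhere -> pi1 ~ 1
  expect_gt(sharing_pi1(recs, mk_pm(gm_rep, 1), gm_rep)$pi1, 0.85)
  # no shared signal -> pi1 ~ 0
  expect_lt(abs(sharing_pi1(recs, mk_pm(gm_rep, 0), gm_rep)$pi1), 0.1)
  # half preserved
  half <- mean(replicate(10, sharing_pi1(recs, mk_pm(gm_rep, 0.5),
                                         gm_rep)$pi1))
  expect_lt(abs(half - 0.5), 0.1)
  expect_error(sharing_pi1(recs[1:5, ], mk_pm(gm_rep, 1), gm_rep), ">= 20")
})
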