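# Gene-CRD pairs, PC1 pseudo-phenotypes, Bayesian-network model selection,
# bootstrap confidence, mechanism comparison.

mk_pair_data <- function(n = 200, gamma = 0.6, n_crd = 15, n_gene = 15,
                         seed = 1) {
  set.seed(seed)
  crd_vals <- matrix(rnorm(n * n_crd), n)
  gene_vals <- matrix(rnorm(n * n_gene), n)
  # gene j wired to CRD j for the first 5 genes
  for (j in 1:5) gene_vals[, j] <- gamma * crd_vals[, j] + rnorm(n)
  act <- phenotype_matrix(apply(crd_vals, 2, inverse_normal_transform),
                          rep("chr1", n_crd), seq_len(n_crd) * 10000L,
                          seq_len(n_crd) * 10000L + 5000L,
                          kind = "normalized",
                          sample_ids = sprintf("S%04d", seq_len(n)),
                          feature_ids = sprintf("crd%02d", seq_len(n_crd)))
  expr <- phenotype_matrix(apply(gene_vals, 2, inverse_normal_transform),
                           rep("chr1", n_gene), seq_len(n_gene) * 10000L + 2000L,
                           seq_len(n_gene) * 10000L + 2500L,
                           kind = "normalized",
                           sample_ids = sprintf("S%04d", seq_len(n)),
                           feature_ids = sprintf("gene%02d", seq_len(n_gene)))
  list(act = act, expr = expr)
}

test_that("wired gene-CRD pairs are recovered and nulls controlled", {
  set.seed(41)
  recovered <- replicate(10, {
    d <- mk_pair_data(seed = sample.int(1e6, 1))
    pr <- map_gene_crd_pairs(d$expr, d$act, n_perm = 300, seed = 1)
    sig <- pr[pr$q <= 0.05, ]
    mean(vapply(1:5, function(j)
      any(sig$gene_id == sprintf("gene%02d", j) &
            sig$crd_id == sprintf("crd%02d", j)), TRUE))
  })
  expect_gte(mean(recovered), 0.9)
  # fully null genes: q <= 0.05 hit rate stays near the FDR level
  null_rate <- replicate(10, {
    d <- mk_pair_data(gamma = 0, seed = sample.int(1e6, 1))
    pr <- map_gene_crd_pairs(d$expr, d$act, n_perm = 300, seed = 1)
    mean(pr$q <= 0.05)
  })
  expect_lte(mean(null_rate), 0.075)
})

test_that("pair distances honour TSS-inside-CRD geometry", {
  d <- mk_pair_data(seed = 3)
  pr <- map_gene_crd_pairs(d$expr, d$act, n_perm = 100, seed = 1)
  # gene TSS at crd_start + 2000 within a 5000-bp CRD: inside
  row <- pr[pr$gene_id == "gene01" & pr$crd_id == "crd01", ]
  expect_equal(row$distance, 0L)
  expect_equal(row$rel_position, 0.4)        # 2000 / 5000
  far <- pr[pr$distance != 0, ]
  if (nrow(far)) expect_true(all(is.na(far$rel_position)))
})

test_that("PC1 variance explained equals (1 + |r|) / 2", {
  set.seed(4)
  n <- 500
  a <- rnorm(n)
  for (r_target in c(0.5, -0.5, 0.9)) {
    b <- r_target * a + sqrt(1 - r_target^2) * rnorm(n)
    Z <- cbind(scale(a), scale(b))
    pc <- prcomp(Z, center = FALSE)
    ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
    r <- cor(a, b)
    expect_equal(ve, (1 + abs(r)) / 2, tolerance = 1e-10)
  }
  # identical series -> variance explained 1
  Z <- cbind(scale(a), scale(a))
  pc <- prcomp(Z, center = FALSE)
  expect_equal(pc$sdev[1]^2 / sum(pc$sdev^2), 1, tolerance = 1e-12)
})

test_that("triplets are built around the planted pseudo-phenotype QTL", {
  found <- replicate(10, {
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    n <- 200
    gm <- tiny_genotypes(n = n, m = 30, seed = seed, maf = 0.3,
                         pos = sort(sample(100000L, 30)))
    v <- gm$dosages[, 15]
    crd <- 0.6 * v + rnorm(n)
    gene <- 0.7 * crd + rnorm(n)
    act <- tiny_phenotypes(cbind(inverse_normal_transform(crd)),
                           kind = "normalized", start = 50000L,
                           sample_ids = gm$sample_ids)
    act$feature_ids <- "crdA"; colnames(act$values) <- "crdA"
    expr <- tiny_phenotypes(cbind(inverse_normal_transform(gene)),
                            kind = "normalized", start = 52000L,
                            sample_ids = gm$sample_ids)
    expr$feature_ids <- "geneA"; colnames(expr$values) <- "geneA"
    pairs <- map_gene_crd_pairs(expr, act, n_perm = 200, seed = 2)
    tr <- build_triplets(pairs, expr, act, gm, n_perm = 200, seed = 3)
    nrow(tr) == 1 && tr$variant_id == gm$variant_ids[15]
  })
  expect_gte(mean(found), 0.9)
})

test_that("degenerate pairs (|r| < 0.05) are skipped", {
  set.seed(6)
  n <- 100
  a0 <- rnorm(n)
  g0 <- resid(lm(rnorm(n) ~ a0))            # exactly orthogonal: r = 0
  act <- tiny_phenotypes(cbind(a0), kind = "normalized", start = 50000L)
  act$feature_ids <- "crdA"; colnames(act$values) <- "crdA"
  expr <- tiny_phenotypes(cbind(g0), kind = "normalized", start = 52000L)
  expr$feature_ids <- "geneA"; colnames(expr$values) <- "geneA"
  gm <- tiny_genotypes(n = n, m = 5, seed = 6, pos = c(1e3, 2e3, 3e3, 4e3,
                                                       5e3))
  pairs <- data.frame(gene_id = "geneA", crd_id = "crdA", q = 0.01)
  expect_error(build_triplets(pairs, expr, act, gm, n_perm = 100, seed = 1),
               "degenerate")
})

test_that("BN posteriors are normalized and affine-invariant", {
  set.seed(7)
  d <- simulate_triplet("causal", 100, 0.5, 0.7, seed = 7)
  p1 <- bn_posteriors(d$dosage, d$crd, d$gene)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  expect_true(all(p1 >= 0))
  # affine rescaling of C and G leaves posteriors unchanged
  p2 <- bn_posteriors(d$dosage, 3 * d$crd - 5, -2 * d$gene + 1)
  expect_equal(unname(p2), unname(p1), tolerance = 1e-6)
  expect_error(bn_posteriors(rep(1, 100), d$crd, d$gene), "constant")
  expect_error(bn_posteriors(d$dosage[1:20], d$crd[1:20], d$gene[1:20]),
               ">= 30")
})

test_that("BN recovers the generative model", {
  models <- c("causal", "reactive", "independent")
  rec <- vapply(models, function(mod) {
    mean(vapply(1:100, function(s) {
      d <- simulate_triplet(mod, 150, 0.5, 0.7, seed = s)
      names(which.max(bn_posteriors(d$dosage, d$crd, d$gene))) == mod
    }, TRUE))
  }, 0)
  expect_gte(rec[["causal"]], 0.9)
  expect_gte(rec[["independent"]], 0.9)
  # reactive is harder when the two betas pull symmetrically; asymmetric
  # betas keep it identifiable
  rec_re <- mean(vapply(1:100, function(s) {
    d <- simulate_triplet("reactive", 150, 0.5, 0.9, seed = s)
    names(which.max(bn_posteriors(d$dosage, d$crd, d$gene))) == "reactive"
  }, TRUE))
  expect_gte(rec_re, 0.7)
})

test_that("bootstrap accuracy separates strong signals from noise", {
  d <- simulate_triplet("causal", 300, 2, 2, seed = 8)
  ba <- bootstrap_accuracy(d$dosage, d$crd, d$gene, B = 100, seed = 1)
  expect_gte(ba$accuracy, 0.95)
  expect_true(ba$pass)
  expect_identical(ba$top_model, "causal")
  # B = 1: accuracy is 0 or 1
  b1 <- bootstrap_accuracy(d$dosage, d$crd, d$gene, B = 1, seed = 2)
  expect_true(b1$accuracy %in% c(0, 1))
  # pure-noise triplets mostly fail the 0.55 threshold
  passes <- vapply(1:30, function(s) {
    set.seed(s)
    v <- rbinom(150, 2, 0.3)
    bootstrap_accuracy(v, rnorm(150), rnorm(150), B = 100, seed = s)$pass
  }, TRUE)
  expect_lt(mean(passes), 0.5)
})

test_that("mechanism comparison classifies direction changes", {
  t_case <- data.frame(variant_id = c("v1", "v2", "v3"),
                       crd_id = c("c1", "c2", "c3"),
                       gene_id = c("g1", "g2", "g3"),
                       top_model = c("causal", "causal", "reactive"),
                       pass = TRUE, stringsAsFactors = FALSE)
  t_ctrl <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                       crd_id = c("c1", "c2", "c3", "c4"),
                       gene_id = c("g1", "g2", "g3", "g4"),
                       top_model = c("causal", "reactive", "independent",
                                     "causal"),
                       pass = c(TRUE, TRUE, TRUE, TRUE),
                       stringsAsFactors = FALSE)
  mc <- compare_mechanisms(t_case, t_ctrl)
  expect_equal(nrow(mc), 3L)                 # v4 unmatched, excluded
  expect_equal(mc$change[mc$triplet_key == "v1|c1|g1"], "same")
  expect_equal(mc$change[mc$triplet_key == "v2|c2|g2"],
               "different_to_causal")
  expect_equal(mc$change[mc$triplet_key == "v3|c3|g3"],
               "non_causal_change")
  # identical inputs -> all same; empty intersection -> empty table
  expect_true(all(compare_mechanisms(t_case, t_case)$change == "same"))
  t_other <- t_ctrl[4, , drop = FALSE]
  expect_equal(nrow(compare_mechanisms(t_case, t_other)), 0L)
})

test_that("paired case/control triplets are classified different_to_causal", {
  hits <- vapply(1:20, function(s) {
    dc <- simulate_triplet("causal", 200, 1, 1, seed = s)
    dr <- simulate_triplet("reactive", 200, 1, 1, seed = s + 1000)
    ca <- bootstrap_accuracy(dc$dosage, dc$crd, dc$gene, B = 50, seed = s)
    co <- bootstrap_accuracy(dr$dosage, dr$crd, dr$gene, B = 50, seed = s)
    t_a <- data.frame(variant_id = "v", crd_id = "c", gene_id = "g",
                      top_model = ca$top_model, pass = ca$pass)
    t_b <- data.frame(variant_id = "v", crd_id = "c", gene_id = "g",
                      top_model = co$top_model, pass = co$pass)
    mc <- compare_mechanisms(t_a, t_b)
    nrow(mc) == 1 && mc$change == "different_to_causal"
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("cross-phenotype QTL effects share under a causal chain", {
  set.seed(9)
  n <- 300
  m <- 25
  gm <- tiny_genotypes(n = n, m = m, seed = 9, maf = 0.3,
                       pos = seq_len(m) * 2000L)
  crd_vals <- 0.8 * gm$dosages + matrix(rnorm(n * m), n)
  gene_vals <- 0.8 * crd_vals + matrix(rnorm(n * m), n)
  act <- tiny_phenotypes(crd_vals, kind = "normalized",
                         start = seq_len(m) * 2000L,
                         sample_ids = gm$sample_ids)
  expr <- tiny_phenotypes(gene_vals, kind = "normalized",
                          start = seq_len(m) * 2000L + 500L,
                          sample_ids = gm$sample_ids)
  recs <- data.frame(phenotype_id = act$feature_ids,
                     variant_id = gm$variant_ids,
                     stringsAsFactors = FALSE)
  pairs <- data.frame(gene_id = expr$feature_ids,
                      crd_id = act$feature_ids, stringsAsFactors = FALSE)
  out <- cross_qtl_effect(recs, expr, gm, pairs)
  expect_gte(out$fraction_shared, 0.8)
  expect_gt(out$pi1, 0.5)
  # severed chain: sharing collapses to the nominal rate
  gene_null <- tiny_phenotypes(matrix(rnorm(n * m), n), kind = "normalized",
                               start = seq_len(m) * 2000L + 500L,
                               sample_ids = gm$sample_ids)
  out0 <- cross_qtl_effect(recs, gene_null, gm, pairs)
  expect_lt(out0$fraction_shared, 0.15)
})
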