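# Correlation map, adjacency-constrained clustering, CRD criteria,
# quantification.

norm_peaks <- function(values, start = NULL, width = 1000L) {
  m <- ncol(values)
  if (is.null(start)) start <- (seq_len(m) - 1L) * 2000L
  phenotype_matrix(values, rep("chr1", m), start, start + width,
                   kind = "normalized",
                   sample_ids = sprintf("S%03d", seq_len(nrow(values))),
                   feature_ids = sprintf("p%04d", seq_len(m)))
}

test_that("correlation map stores exact correlations within the band", {
  set.seed(1)
  base <- rnorm(50)
  v <- cbind(base, base, -base, rnorm(50))
  maps <- build_correlation_map(norm_peaks(v), window = 250)
  r <- maps$chr1$r
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_equal(r[1, 4], cor(base, v[, 4]))
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(r, t(r))
})

test_that("the sliding window bounds which pairs are computed", {
  set.seed(2)
  v <- matrix(rnorm(20 * 300), 20)
  maps <- build_correlation_map(norm_peaks(v), window = 250)
  r <- maps$chr1$r
  expect_false(is.na(r[1, 251]))   # index distance 250: inside the band
  expect_true(is.na(r[1, 300]))    # index distance 299: beyond the band
  expect_true(is.na(r[1, 252]))
})

test_that("pairs with too few complete samples get NA and are logged", {
  set.seed(3)
  v <- matrix(rnorm(30 * 3), 30)
  v[1:25, 2] <- NA                       # only 5 complete with any partner
  maps <- build_correlation_map(norm_peaks(v), min_complete = 10)
  expect_true(is.na(maps$chr1$r[1, 2]))
  expect_false(is.na(maps$chr1$r[1, 3]))
})

test_that("two peaks give a single root with mean_corr = r", {
  set.seed(4)
  v <- matrix(rnorm(40 * 2), 40)
  maps <- build_correlation_map(norm_peaks(v))
  tree <- build_tree(maps$chr1)
  expect_equal(tree$nodes$mean_corr[3], cor(v[, 1], v[, 2]))
  expect_equal(tree$nodes$edge_corr[3], cor(v[, 1], v[, 2]))
  expect_equal(tree$nodes[3, c("lo", "hi")], data.frame(lo = 1L, hi = 2L),
               ignore_attr = TRUE)
})

test_that("merge order follows the maximal adjacent mean correlation", {
  # 4 peaks, r(1,2) = r(3,4) ~ 0.9, cross pairs ~ 0: the first two merges
  # must be {1,2} and {3,4}, the root joins them (enumeration oracle:
  # adjacency allows merge sequences only through these pairs)
  set.seed(5)
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  v <- cbind(f1 + 0.3 * rnorm(n), f1 + 0.3 * rnorm(n),
             f2 + 0.3 * rnorm(n), f2 + 0.3 * rnorm(n))
  maps <- build_correlation_map(norm_peaks(v))
  tree <- build_tree(maps$chr1)
  nd <- tree$nodes
  internal <- nd[5:7, ]
  expect_true(any(internal$lo == 1 & internal$hi == 2))
  expect_true(any(internal$lo == 3 & internal$hi == 4))
  expect_true(any(internal$lo == 1 & internal$hi == 4))
  # permuting sample order leaves the tree unchanged
  perm <- sample(n)
  tree2 <- build_tree(build_correlation_map(norm_peaks(v[perm, ]))$chr1)
  expect_equal(tree2$nodes, tree$nodes, tolerance = 1e-12)
})

test_that("a planted correlated block is called exactly", {
  set.seed(6)
  n <- 500
  m <- 40
  v <- matrix(rnorm(n * m), n)
  f <- rnorm(n)
  block <- 18:22
  v[, block] <- f + matrix(rnorm(n * 5), n)   # within-r ~ 0.5
  pm <- norm_peaks(v)
  cs <- crd_call(pm)
  expect_equal(nrow(cs$table), 1L)
  expect_identical(cs$members[[1]], pm$feature_ids[block])
  # stored criteria are internally consistent with the brute-force oracle
  maps <- build_correlation_map(pm)
  expect_true(oracle_criteria(v, pm$start, pm$end, 18L, 22L, 250L,
                              maps$chr1$background))
})

test_that("fully overlapping member intervals fail the non-overlap rule", {
  set.seed(7)
  n <- 300
  m <- 20
  f <- rnorm(n)
  v <- matrix(rnorm(n * m), n)
  v[, 10:11] <- f + 0.5 * matrix(rnorm(n * 2), n)
  start <- (seq_len(m) - 1L) * 2000L
  end <- start + 1000L
  # the correlated pair shares one interval -> only 1 non-overlapping member
  start[11] <- start[10]; end[11] <- end[10]
  pm <- phenotype_matrix(v, rep("chr1", m), start, end, kind = "normalized",
                         sample_ids = sprintf("S%03d", seq_len(n)),
                         feature_ids = sprintf("p%02d", seq_len(m)))
  expect_equal(nrow(crd_call(pm)$table), 0L)
  # same signal with disjoint intervals is called
  expect_equal(nrow(crd_call(norm_peaks(v))$table), 1L)
})

test_that("caller equals exhaustive maximal-node search on small chromosomes", {
  set.seed(8)
  for (rep in 1:25) {
    n_peaks <- sample(4:12, 1)
    n <- 80
    v <- matrix(rnorm(n * n_peaks), n)
    if (rep %% 2 == 0) {                  # plant a block half the time
      k <- sample(2:min(4, n_peaks), 1)
      at <- sample(seq_len(n_peaks - k + 1), 1)
      v[, at:(at + k - 1)] <- rnorm(n) + matrix(rnorm(n * k), n)
    }
    pm <- norm_peaks(v)
    maps <- build_correlation_map(pm)
    tree <- build_tree(maps$chr1)
    called <- call_crds(tree, maps$chr1)
    nd <- tree$nodes
    qualifies <- vapply(seq_len(nrow(nd)), function(i) {
      if (nd$lo[i] == nd$hi[i]) return(FALSE)
      oracle_criteria(v, pm$start, pm$end, nd$lo[i], nd$hi[i], 250L,
                      maps$chr1$background)
    }, TRUE)
    # maximal qualifying nodes: no qualifying strict ancestor
    is_anc <- function(a, d) nd$lo[a] <= nd$lo[d] && nd$hi[a] >= nd$hi[d] &&
      (nd$lo[a] != nd$lo[d] || nd$hi[a] != nd$hi[d])
    expected <- which(qualifies & !vapply(seq_len(nrow(nd)), function(i)
      any(qualifies & vapply(seq_len(nrow(nd)), is_anc, TRUE, d = i)), TRUE))
    got <- sort(paste(called$table$start, called$table$end))
    want <- sort(paste(pm$start[nd$lo[expected]], pm$end[nd$hi[expected]]))
    expect_identical(got, want)
  }
})

test_that("called CRDs are disjoint and satisfy their stored criteria", {
  co <- ref_cohort()
  pm <- normalize_phenotypes(co$peaks)
  cs <- crd_call(pm)
  all_members <- unlist(cs$members, use.names = FALSE)
  expect_false(anyDuplicated(all_members) > 0)
  expect_true(all(cs$table$n_members >= 2))
  expect_true(all(cs$table$mean_corr >= 2 * cs$table$background))
  expect_true(all(cs$table$edge_corr >= 2 * cs$table$background))
  # spot-recompute the criteria from scratch for the first 10 CRDs
  maps <- build_correlation_map(pm)
  for (i in seq_len(min(10, nrow(cs$table)))) {
    lo <- match(cs$members[[i]][1], pm$feature_ids)
    hi <- match(tail(cs$members[[i]], 1), pm$feature_ids)
    expect_true(oracle_criteria(pm$values, pm$start, pm$end, lo, hi, 250L,
                                maps$chr1$background))
  }
})

test_that("CRD activity is the NA-aware mean of member peaks", {
  v <- matrix(c(1, 3, NA, 2, NA, NA), 3, 2)   # samples x 2 member peaks
  pm <- norm_peaks(v)
  cs <- list(table = data.frame(crd_id = "c1", chrom = "chr1", start = 0L,
                                end = 3000L, n_members = 2L, mean_corr = 0.9,
                                edge_corr = 0.9, background = 0.1),
             members = list(c1 = pm$feature_ids),
             peak_universe = pm$feature_ids, factor = 2)
  class(cs) <- "CRDSet"
  act <- quantify_crds(pm, cs)
  expect_equal(unname(act$values[, 1]), c(1.5, 3, NA))
  expect_error(quantify_crds(subset_features(pm, 1), cs), "missing")
})

test_that("planted-CRD activity tracks the latent factor", {
  # r = sqrt(k l^2 / (k l^2 + noise^2)) with k = 5, l = 1, noise 1 -> 0.913
  set.seed(9)
  n <- 500
  f <- rnorm(n)
  v <- f + matrix(rnorm(n * 5), n)
  act <- rowMeans(v)
  expect_equal(cor(act, f), sqrt(5 / 6), tolerance = 0.03)
})

test_that("summed CRD counts are integer, additive and conserved", {
  cnt <- matrix(c(5L, 2L, 7L, 4L, 1L, 9L), 2, 3)
  pm <- phenotype_matrix(cnt, rep("chr1", 3), c(0L, 2000L, 4000L),
                         c(1000L, 3000L, 5000L), kind = "raw_count",
                         sample_ids = c("a", "b"),
                         feature_ids = c("p1", "p2", "p3"))
  cs <- list(table = data.frame(crd_id = c("c1", "c2"),
                                chrom = c("chr1", "chr1"),
                                start = c(0L, 4000L), end = c(3000L, 5000L),
                                n_members = c(2L, 1L), mean_corr = 1,
                                edge_corr = 1, background = 0.1),
             members = list(c1 = c("p1", "p2"), c2 = "p3"),
             peak_universe = c("p1", "p2", "p3"), factor = 2)
  class(cs) <- "CRDSet"
  out <- sum_crd_counts(pm, cs)
  expect_equal(unname(out$values[, "c1"]), c(12, 6))   # 5+7, 2+4
  expect_equal(unname(out$values[, "c2"]), c(1, 9))
  expect_true(all(rowSums(out$values) <= rowSums(pm$values)))
  qm <- pm; qm$kind <- "quantified"
  expect_error(sum_crd_counts(qm, cs), "raw_count")
})

test_that("CRD BED round-trips", {
  co <- ref_cohort()
  cs <- crd_call(normalize_phenotypes(co$peaks))
  path <- withr::local_tempfile(fileext = ".bed")
  write_crd_bed(cs, path)
  back <- read_crd_bed(path, peak_universe = cs$peak_universe)
  expect_identical(back$table$crd_id, cs$table$crd_id)
  expect_identical(back$members, cs$members)
  expect_equal(back$table$start, cs$table$start)
})
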