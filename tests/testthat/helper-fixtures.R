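# Shared fixture builders. Everything is generated in code at test time;
# the reference cohort is cached per session because several files use it.

options(crdscan.quiet = TRUE)

.fixture_env <- new.env(parent = emptyenv())

# The reference synthetic cohort (default study conditions, seed 1).
ref_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- simulate_cohort(simulation_config(seed = 1L))
  .fixture_env$cohort
}

# Downsized simulation config for unit tests (role counts fit small n_genes).
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_pair_genes = 5L, n_eqtl_genes = 5L, n_diff_genes = 5L,
                   triplet_models = c(causal = 3, reactive = 3,
                                      independent = 3),
                   n_null_variants = 50L)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(simulation_config, args)
}

# Small genotype matrix: n samples x m independent variants.
tiny_genotypes <- function(n = 100, m = 50, seed = 1, maf = NULL,
                           chrom = "chr1", pos = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
  maf <- rep_len(maf, m)
  if (is.null(pos)) pos <- sort(sample.int(2e6, m))
  d <- vapply(maf, function(p) rbinom(n, 2L, p), numeric(n))
  genotype_matrix(d, chrom = rep(chrom, m), pos = pos)
}

# Phenotype matrix from a values matrix, all features at one anchor region.
tiny_phenotypes <- function(values, kind = "normalized", chrom = "chr1",
                            start = NULL, width = 1000L,
                            sample_ids = NULL) {
  dimnames(values) <- NULL
  m <- ncol(values)
  if (is.null(start)) start <- 1e6 + seq_len(m) * 10L
  phenotype_matrix(values, chrom = rep(chrom, m), start = start,
                   end = start + width, kind = kind,
                   sample_ids = sample_ids %||% sprintf("S%04d",
                                                        seq_len(nrow(values))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force CRD criteria oracle: recompute the three criteria for a peak
# index range directly from the raw normalized values (independent of the
# caller's stored statistics).
oracle_criteria <- function(values, start, end, lo, hi, window, background,
                            factor = 2) {
  k <- hi - lo + 1L
  if (k < 2L) return(FALSE)
  r <- suppressWarnings(cor(values[, lo:hi, drop = FALSE],
                            use = "pairwise.complete.obs"))
  idx <- abs(row(r) - col(r)) > window
  r[idx] <- background
  r[is.na(r)] <- background
  pairs <- r[upper.tri(r)]
  mean_corr <- mean(pairs)
  edge <- mean(c(r[1L, -1L], r[k, -k]))
  novl <- {
    s <- start[lo:hi]; e <- end[lo:hi]
    o <- order(e); cnt <- 0L; cur <- -Inf
    for (i in o) if (s[i] >= cur) { cnt <- cnt + 1L; cur <- e[i] }
    cnt
  }
  mean_corr >= factor * background && edge >= factor * background &&
    novl >= 2L
}

# Best-match Jaccard of each truth CRD against a called CRDSet.
best_jaccard <- function(truth_members, crd_set) {
  vapply(truth_members, function(tm) {
    best <- 0
    for (m in crd_set$members)
      best <- max(best, length(intersect(tm, m)) / length(union(tm, m)))
    best
  }, 0)
}
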