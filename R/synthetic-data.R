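# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: latent per-CRD
# activity factors shared by member peaks, genotype effects on factors and
# genes, case/control shifts, genotype-by-status interactions, triplets wired
# under known causal models, and NB-distributed read counts linked to
# activity. Every draw is a deterministic function of the config seed.

#' Simulation configuration
#'
#' Defaults describe the reference synthetic cohort used throughout the test
#' suite: 200 individuals at the 98:174 case:control proportion of the study
#' cohort, 1,000 peaks on one synthetic chromosome at 2-kb spacing, 60% of
#' peaks grouped into CRDs of 2-10 members, peak loading 1 and residual sd 1
#' (within-CRD correlation loading^2/(loading^2+noise_sd^2) = 0.5).
#'
#' @param n_cases,n_controls Sample counts per group.
#' @param n_peaks Number of chromatin peaks.
#' @param crd_size_range Integer (min >= 2, max) range of planted CRD sizes.
#' @param within_crd_loading Peak loading on its CRD's latent factor.
#' @param noise_sd Residual sd of peak activity around the factor term.
#' @param fraction_peaks_in_crds Fraction of peaks grouped into planted CRDs.
#' @param n_genes Number of genes.
#' @param maf_range Uniform range for variant minor allele frequencies.
#' @param qtl_effect_sd SD of planted QTL effect sizes (effects ~ N(0, sd)).
#' @param interaction_effect Case-only genotype slope for interaction QTLs.
#' @param diff_effect Case shift of the latent factor mean (differentially
#'   active CRDs) and of gene expression (differentially expressed genes).
#' @param nb_dispersion NB dispersion of simulated counts.
#' @param triplet_models Named counts per generative model,
#'   `c(causal=, reactive=, independent=)`.
#' @param seed Integer seed fixing the cohort bit-for-bit.
#' @param n_null_variants Background variants with no planted effect.
#' @param frac_crds_with_qtl,frac_crds_diff Fractions of (non-triplet) planted
#'   CRDs receiving a QTL effect / a differential case shift.
#' @param frac_qtls_interaction Fraction of CRD-QTLs made case-only.
#' @param n_pair_genes,n_eqtl_genes,n_diff_genes Genes wired to a CRD factor,
#'   genes with their own eQTL, genes with a case shift.
#' @param gene_loading Loading of CRD-wired genes on the CRD factor.
#' @param triplet_beta_vc,triplet_beta_cg Variant->phenotype and
#'   phenotype->phenotype effects inside planted triplets.
#' @param peak_spacing,peak_width Peak layout (bp).
#' @param count_intercept,count_slope Log-linear link from activity to NB
#'   count mean: `mean = exp(count_intercept + count_slope * activity)`.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_cases = 72, n_controls = 128, n_peaks = 1000,
                              crd_size_range = c(2L, 10L),
                              within_crd_loading = 1, noise_sd = 1,
                              fraction_peaks_in_crds = 0.6, n_genes = 120,
                              maf_range = c(0.1, 0.5), qtl_effect_sd = 0.5,
                              interaction_effect = 0.6, diff_effect = 0.5,
                              nb_dispersion = 0.1,
                              triplet_models = c(causal = 10, reactive = 10,
                                                 independent = 10),
                              seed = 1L, n_null_variants = 300L,
                              frac_crds_with_qtl = 0.3, frac_crds_diff = 0.2,
                              frac_qtls_interaction = 0.25,
                              n_pair_genes = 25L, n_eqtl_genes = 25L,
                              n_diff_genes = 20L, gene_loading = 0.7,
                              triplet_beta_vc = 0.5, triplet_beta_cg = 0.7,
                              peak_spacing = 2000L, peak_width = 1000L,
                              count_intercept = log(100), count_slope = 0.4) {
  cfg <- as.list(environment())
  # YAML-loaded configs arrive as lists; coerce vector-valued fields
  for (nm in c("crd_size_range", "maf_range", "triplet_models"))
    cfg[[nm]] <- unlist(cfg[[nm]])
  if (is.null(names(cfg$triplet_models))) {
    if (length(cfg$triplet_models) != 3L)
      crd_stop("triplet_models must be named or of length 3")
    names(cfg$triplet_models) <- c("causal", "reactive", "independent")
  }
  with(cfg, {
    stopifnot(n_cases >= 0, n_controls >= 0, n_cases + n_controls >= 3,
              n_peaks > 0, n_genes > 0,
              length(crd_size_range) == 2L, crd_size_range[1] >= 2,
              crd_size_range[1] <= crd_size_range[2],
              fraction_peaks_in_crds > 0, fraction_peaks_in_crds <= 1,
              maf_range[1] <= maf_range[2], maf_range[1] > 0,
              maf_range[2] <= 0.5, noise_sd > 0, nb_dispersion > 0,
              all(triplet_models >= 0))
  })
  if (cfg$crd_size_range[2] > cfg$n_peaks)
    crd_stop("crd_size_range max exceeds n_peaks")
  n_trip <- sum(cfg$triplet_models)
  if (n_trip + cfg$n_pair_genes + cfg$n_eqtl_genes + cfg$n_diff_genes >
      cfg$n_genes)
    crd_stop("gene role counts exceed n_genes")
  class(cfg) <- "SimulationConfig"
  cfg
}

# Partition peaks into contiguous planted CRDs separated by >= 1 background
# peak (the caller assumes genomic ordering; gaps keep truth unambiguous).
plan_crd_layout <- function(cfg) {
  target <- round(cfg$fraction_peaks_in_crds * cfg$n_peaks)
  sizes <- integer(0)
  while (sum(sizes) < target) {
    s <- sample(seq(cfg$crd_size_range[1], cfg$crd_size_range[2]), 1L)
    if (sum(sizes) + s > target && length(sizes)) break
    sizes <- c(sizes, s)
  }
  k <- length(sizes)
  n_bg <- cfg$n_peaks - sum(sizes)
  if (n_bg < k - 1L)
    crd_stop("not enough background peaks to separate %d planted CRDs", k)
  gaps <- rep(0L, k + 1L)
  gaps[2:k] <- 1L                                  # interior separators
  extra <- n_bg - sum(gaps)
  if (extra > 0) {
    add <- as.vector(stats::rmultinom(1L, extra, rep(1, k + 1L)))
    gaps <- gaps + add
  }
  members <- vector("list", k)
  pos <- 0L
  for (i in seq_len(k)) {
    pos <- pos + gaps[i]
    members[[i]] <- seq(pos + 1L, pos + sizes[i])
    pos <- pos + sizes[i]
  }
  members
}

#' Simulate a synthetic cohort with ground truth
#'
#' @param config A [simulation_config()].
#' @return A list with elements `genotypes` (GenotypeMatrix), `peaks`, `genes`
#'   (quantified PhenotypeMatrix), `peak_counts`, `gene_counts` (raw-count
#'   PhenotypeMatrix), `metadata` (SampleMetadata) and `truth` (GroundTruth
#'   list: `crd_membership`, `diff_active_crds`, `diff_genes`, `qtl_map`,
#'   `interaction_qtls`, `triplet_labels`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_cases + cfg$n_controls
  sample_ids <- sprintf("S%04d", seq_len(n))
  status <- c(rep(1L, cfg$n_cases), rep(0L, cfg$n_controls))
  meta <- sample_metadata(sample_ids,
                          ifelse(status == 1L, "case", "control"),
                          covariates = cbind(cov1 = rnorm(n)))

  ## peak layout -------------------------------------------------------------
  peak_start <- (seq_len(cfg$n_peaks) - 1L) * cfg$peak_spacing
  peak_end <- peak_start + cfg$peak_width
  peak_ids <- sprintf("peak%05d", seq_len(cfg$n_peaks))
  chrom_len <- cfg$n_peaks * cfg$peak_spacing + 200000L

  members <- plan_crd_layout(cfg)
  k_crd <- length(members)
  crd_ids <- sprintf("TCRD%04d", seq_len(k_crd))

  ## role assignment ---------------------------------------------------------
  n_trip <- sum(cfg$triplet_models)
  if (n_trip > k_crd) crd_stop("more triplets requested than planted CRDs")
  pool <- sample(k_crd)
  trip_crd <- pool[seq_len(n_trip)]
  rest <- setdiff(pool, trip_crd)
  n_qtl <- min(length(rest), round(cfg$frac_crds_with_qtl * k_crd))
  qtl_crd <- rest[seq_len(n_qtl)]
  rest2 <- setdiff(rest, qtl_crd)
  n_diff <- min(length(rest2), round(cfg$frac_crds_diff * k_crd))
  diff_crd <- rest2[seq_len(n_diff)]
  n_int <- round(cfg$frac_qtls_interaction * n_qtl)
  int_crd <- if (n_int > 0) qtl_crd[seq_len(n_int)] else integer(0)

  trip_model <- rep(names(cfg$triplet_models), cfg$triplet_models)

  ## variants ----------------------------------------------------------------
  crd_anchor <- vapply(members, function(m) peak_start[m[1L]], 0)
  gene_roles <- c(rep("triplet", n_trip), rep("pair", cfg$n_pair_genes),
                  rep("eqtl", cfg$n_eqtl_genes), rep("diff", cfg$n_diff_genes))
  gene_roles <- c(gene_roles,
                  rep("null", cfg$n_genes - length(gene_roles)))
  # pair genes are wired to QTL-bearing CRDs when available (cycled)
  pair_src <- if (n_qtl > 0) rep_len(qtl_crd, cfg$n_pair_genes)
              else rep_len(seq_len(k_crd), cfg$n_pair_genes)

  near <- function(anchor) {
    pmax(1L, pmin(chrom_len,
                  as.integer(anchor + round(runif(length(anchor), -5e5, 5e5)))))
  }
  v_pos <- integer(0); v_target <- character(0); v_class <- character(0)
  add_v <- function(pos, target, class) {
    v_pos <<- c(v_pos, pos)
    v_target <<- c(v_target, rep_len(target, length(pos)))
    v_class <<- c(v_class, rep_len(class, length(pos)))
  }
  if (n_qtl > 0) add_v(near(crd_anchor[qtl_crd]), crd_ids[qtl_crd],
                       ifelse(qtl_crd %in% int_crd, "crd_qtl_interaction",
                              "crd_qtl"))
  if (n_trip > 0) add_v(near(crd_anchor[trip_crd]), crd_ids[trip_crd],
                        "triplet")
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  # gene TSS: wired genes near their CRD, others uniform
  gene_tss <- integer(cfg$n_genes)
  gi_trip <- which(gene_roles == "triplet")
  gi_pair <- which(gene_roles == "pair")
  gene_src_crd <- rep(NA_integer_, cfg$n_genes)
  gene_src_crd[gi_trip] <- trip_crd
  gene_src_crd[gi_pair] <- pair_src
  for (i in seq_len(cfg$n_genes)) {
    gene_tss[i] <- if (!is.na(gene_src_crd[i]))
      pmax(1L, pmin(chrom_len, as.integer(crd_anchor[gene_src_crd[i]] +
                                            round(runif(1, -1e5, 1e5)))))
    else as.integer(runif(1, 1, chrom_len))
  }
  gi_eqtl <- which(gene_roles == "eqtl")
  if (length(gi_eqtl)) add_v(near(gene_tss[gi_eqtl]), gene_ids[gi_eqtl],
                             "gene_qtl")
  if (cfg$n_null_variants > 0)
    add_v(as.integer(runif(cfg$n_null_variants, 1, chrom_len)),
          rep(NA_character_, cfg$n_null_variants), "null")

  m_var <- length(v_pos)
  v_maf <- runif(m_var, cfg$maf_range[1], cfg$maf_range[2])
  dosages <- vapply(v_maf, function(p) rbinom(n, 2L, p), numeric(n))
  v_ids <- sprintf("var%05d", seq_len(m_var))
  genotypes <- genotype_matrix(dosages, chrom = rep("chr1", m_var),
                               pos = v_pos, sample_ids = sample_ids,
                               variant_ids = v_ids)
  v_of <- function(target, class) v_ids[v_target == target & v_class %in% class]
  dose_of <- function(id) dosages[, match(id, v_ids)]

  ## latent factors ----------------------------------------------------------
  factors <- matrix(rnorm(n * k_crd), n, k_crd)
  qtl_map <- data.frame(variant_id = character(0), phenotype_id = character(0),
                        class = character(0), effect = numeric(0),
                        stringsAsFactors = FALSE)
  int_map <- qtl_map
  for (ci in diff_crd)
    factors[, ci] <- factors[, ci] + cfg$diff_effect * status
  for (ci in qtl_crd) {
    vid <- v_of(crd_ids[ci], c("crd_qtl", "crd_qtl_interaction"))[1L]
    beta <- rnorm(1, 0, cfg$qtl_effect_sd)
    d <- dose_of(vid)
    factors[, ci] <- factors[, ci] + beta * (d - mean(d))
    qtl_map <- rbind(qtl_map, data.frame(variant_id = vid,
                                         phenotype_id = crd_ids[ci],
                                         class = "crd", effect = beta,
                                         stringsAsFactors = FALSE))
    if (ci %in% int_crd) {
      factors[, ci] <- factors[, ci] +
        cfg$interaction_effect * (d - mean(d)) * status
      int_map <- rbind(int_map, data.frame(variant_id = vid,
                                           phenotype_id = crd_ids[ci],
                                           class = "crd",
                                           effect = cfg$interaction_effect,
                                           stringsAsFactors = FALSE))
    }
  }

  ## genes and triplets ------------------------------------------------------
  expr <- matrix(rnorm(n * cfg$n_genes), n, cfg$n_genes)
  diff_genes <- character(0)
  triplet_labels <- data.frame(triplet_id = character(0),
                               variant_id = character(0),
                               crd_id = character(0), gene_id = character(0),
                               model = character(0), stringsAsFactors = FALSE)
  for (t in seq_len(n_trip)) {
    ci <- trip_crd[t]; gi <- gi_trip[t]
    vid <- v_of(crd_ids[ci], "triplet")[1L]
    d <- dose_of(vid); dc <- d - mean(d)
    bvc <- cfg$triplet_beta_vc; bcg <- cfg$triplet_beta_cg
    if (trip_model[t] == "causal") {
      factors[, ci] <- bvc * dc + rnorm(n)
      expr[, gi] <- bcg * factors[, ci] + rnorm(n)
    } else if (trip_model[t] == "reactive") {
      expr[, gi] <- bvc * dc + rnorm(n)
      factors[, ci] <- bcg * expr[, gi] + rnorm(n)
    } else {
      factors[, ci] <- bvc * dc + rnorm(n)
      expr[, gi] <- bcg * dc + rnorm(n)
    }
    qtl_map <- rbind(qtl_map,
                     data.frame(variant_id = vid,
                                phenotype_id = c(crd_ids[ci], gene_ids[gi]),
                                class = c("crd", "gene"),
                                effect = c(bvc, bvc * bcg),
                                stringsAsFactors = FALSE))
    triplet_labels <- rbind(triplet_labels,
                            data.frame(triplet_id = sprintf("trip%03d", t),
                                       variant_id = vid, crd_id = crd_ids[ci],
                                       gene_id = gene_ids[gi],
                                       model = trip_model[t],
                                       stringsAsFactors = FALSE))
  }
  for (j in seq_along(gi_pair)) {
    gi <- gi_pair[j]
    expr[, gi] <- cfg$gene_loading * factors[, gene_src_crd[gi]] + rnorm(n)
  }
  for (gi in gi_eqtl) {
    vid <- v_of(gene_ids[gi], "gene_qtl")[1L]
    beta <- rnorm(1, 0, cfg$qtl_effect_sd)
    d <- dose_of(vid)
    expr[, gi] <- expr[, gi] + beta * (d - mean(d))
    qtl_map <- rbind(qtl_map, data.frame(variant_id = vid,
                                         phenotype_id = gene_ids[gi],
                                         class = "gene", effect = beta,
                                         stringsAsFactors = FALSE))
  }
  gi_diff <- which(gene_roles == "diff")
  for (gi in gi_diff) {
    expr[, gi] <- expr[, gi] + cfg$diff_effect * status
    diff_genes <- c(diff_genes, gene_ids[gi])
  }

  ## peak activity -----------------------------------------------------------
  peaks_val <- matrix(rnorm(n * cfg$n_peaks, sd = cfg$noise_sd), n,
                      cfg$n_peaks)
  for (ci in seq_len(k_crd))
    peaks_val[, members[[ci]]] <- cfg$within_crd_loading * factors[, ci] +
      peaks_val[, members[[ci]]]

  ## NB counts linked to activity -------------------------------------------
  nb_counts <- function(act) {
    mu <- exp(cfg$count_intercept + cfg$count_slope * act)
    matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
           nrow(act), ncol(act))
  }
  peak_counts <- nb_counts(peaks_val)
  gene_counts <- nb_counts(expr)

  peaks <- phenotype_matrix(peaks_val, rep("chr1", cfg$n_peaks), peak_start,
                            peak_end, kind = "quantified",
                            sample_ids = sample_ids, feature_ids = peak_ids)
  genes <- phenotype_matrix(expr, rep("chr1", cfg$n_genes), gene_tss,
                            gene_tss + 500L, kind = "quantified",
                            sample_ids = sample_ids, feature_ids = gene_ids)
  pc <- phenotype_matrix(peak_counts, rep("chr1", cfg$n_peaks), peak_start,
                         peak_end, kind = "raw_count",
                         sample_ids = sample_ids, feature_ids = peak_ids)
  gc <- phenotype_matrix(gene_counts, rep("chr1", cfg$n_genes), gene_tss,
                         gene_tss + 500L, kind = "raw_count",
                         sample_ids = sample_ids, feature_ids = gene_ids)

  truth <- list(
    crd_membership = setNames(lapply(members, function(m) peak_ids[m]),
                              crd_ids),
    diff_active_crds = crd_ids[diff_crd],
    diff_genes = diff_genes,
    qtl_map = qtl_map,
    interaction_qtls = int_map,
    triplet_labels = triplet_labels)
  list(genotypes = genotypes, peaks = peaks, genes = genes, peak_counts = pc,
       gene_counts = gc, metadata = meta, truth = truth, config = cfg)
}

#' Simulate a single (variant, CRD, gene) triplet under a known causal model
#'
#' Generative models: causal `C = b_vc V + e1, G = b_cg C + e2`; reactive
#' `G = b_vc V + e1, C = b_cg G + e2`; independent `C = b_vc V + e1,
#' G = b_cg V + e2`, with `e ~ N(0,1)` and `V` a dosage drawn from
#' Binomial(2, maf).
#'
#' @param model One of "causal", "reactive", "independent".
#' @param n Sample size (>= 10).
#' @param beta_vc,beta_cg Structural effects.
#' @param seed Integer seed.
#' @param maf Variant minor allele frequency.
#' @return List with numeric vectors `dosage`, `crd`, `gene`.
#' @export
simulate_triplet <- function(model, n, beta_vc, beta_cg, seed, maf = 0.3) {
  if (!model %in% c("causal", "reactive", "independent"))
    crd_stop("unknown triplet model '%s'", model)
  stopifnot(n >= 10)
  set.seed(seed)
  v <- rbinom(n, 2L, maf)
  tries <- 0L
  while (sd(v) == 0 && tries < 50L) { v <- rbinom(n, 2L, maf); tries <- tries + 1L }
  if (model == "causal") {
    crd <- beta_vc * v + rnorm(n)
    gene <- beta_cg * crd + rnorm(n)
  } else if (model == "reactive") {
    gene <- beta_vc * v + rnorm(n)
    crd <- beta_cg * gene + rnorm(n)
  } else {
    crd <- beta_vc * v + rnorm(n)
    gene <- beta_cg * v + rnorm(n)
  }
  list(dosage = v, crd = crd, gene = gene)
}

#' Write a simulated cohort to disk
#'
#' Emits `genotypes.vcf`, `peaks.bed`, `genes.bed`, `peak_counts.bed`,
#' `gene_counts.bed`, `metadata.tsv` and `truth_*.tsv` files loadable by the
#' io readers. No triplet truth file is written when no triplets were planted.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genotypes_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_phenotype_bed(cohort$peaks, file.path(dir, "peaks.bed"))
  write_phenotype_bed(cohort$genes, file.path(dir, "genes.bed"))
  write_phenotype_bed(cohort$peak_counts, file.path(dir, "peak_counts.bed"))
  write_phenotype_bed(cohort$gene_counts, file.path(dir, "gene_counts.bed"))
  write_sample_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  tr <- cohort$truth
  crd_df <- data.frame(crd_id = names(tr$crd_membership),
                       peak_ids = vapply(tr$crd_membership, paste,
                                         collapse = ",", ""),
                       stringsAsFactors = FALSE)
  class(crd_df) <- c("truth_crds", "data.frame")
  write_results_table(crd_df, file.path(dir, "truth_crds.tsv"))
  qm <- tr$qtl_map; class(qm) <- c("truth_qtls", "data.frame")
  write_results_table(qm, file.path(dir, "truth_qtls.tsv"))
  dd <- data.frame(feature_id = c(tr$diff_active_crds, tr$diff_genes),
                   class = c(rep("crd", length(tr$diff_active_crds)),
                             rep("gene", length(tr$diff_genes))),
                   stringsAsFactors = FALSE)
  class(dd) <- c("truth_differential", "data.frame")
  write_results_table(dd, file.path(dir, "truth_differential.tsv"))
  if (nrow(tr$interaction_qtls)) {
    im <- tr$interaction_qtls
    class(im) <- c("truth_interaction_qtls", "data.frame")
    write_results_table(im, file.path(dir, "truth_interaction_qtls.tsv"))
  }
  if (nrow(tr$triplet_labels)) {
    tl <- tr$triplet_labels
    class(tl) <- c("truth_triplets", "data.frame")
    write_results_table(tl, file.path(dir, "truth_triplets.tsv"))
  }
  invisible(dir)
}

#' Load a cohort previously written by [write_cohort()]
#' @param dir Directory written by [write_cohort()].
#' @return A list with the same matrix elements as [simulate_cohort()] (ground
#'   truth is returned as the written tables).
#' @export
read_cohort <- function(dir) {
  out <- list(
    genotypes = read_genotypes(file.path(dir, "genotypes.vcf")),
    peaks = read_phenotype_bed(file.path(dir, "peaks.bed"), "quantified"),
    genes = read_phenotype_bed(file.path(dir, "genes.bed"), "quantified"),
    peak_counts = read_phenotype_bed(file.path(dir, "peak_counts.bed"),
                                     "raw_count"),
    gene_counts = read_phenotype_bed(file.path(dir, "gene_counts.bed"),
                                     "raw_count"),
    metadata = read_sample_metadata(file.path(dir, "metadata.tsv")))
  for (f in c("truth_crds", "truth_qtls", "truth_differential",
              "truth_interaction_qtls", "truth_triplets")) {
    p <- file.path(dir, paste0(f, ".tsv"))
    if (file.exists(p)) out[[f]] <- read_results_table(p)
  }
  out
}
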