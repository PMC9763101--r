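# End-to-end orchestration on a config: simulate-or-load -> preprocess ->
# CRD calls (cases, controls, combined) -> structure analysis ->
# differential -> QTL passes -> gene-CRD pairs -> triplets -> mechanism
# comparison, with a deterministic run manifest.
#
# Group-specific CRD calls feed the structure analysis; CRDs from the
# combined set feed everything downstream.

#' Default pipeline configuration
#'
#' Permutation counts are reduced relative to the per-module defaults so the
#' reference synthetic run stays interactive; every parameter can be
#' overridden.
#'
#' @param seed Master seed; per-stage seeds are derived by stage name.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(),                       # simulation_config() overrides
    preprocess = list(n_genotype_pcs = 2L, n_phenotype_pcs = 2L),
    crd = list(window = 250L, factor = 2),
    qtl = list(window = 1e6, n_perm = 200L, fdr = 0.05, min_maf = 0.05),
    pairs = list(window = 1e6, n_perm = 200L, fdr = 0.05),
    triplets = list(n_perm = 200L, bootstrap = 100L, threshold = 0.55,
                    fdr = 0.05))
}

# Deep-merge override list into defaults.
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' @param config A configuration list (see [default_run_config()]) or a path
#'   to a YAML file with the same structure.
#' @param out_dir Output directory.
#' @return The run manifest (also written as `manifest.json`), listing the
#'   config hash, seed, per-stage parameters and status, output-file
#'   checksums and result counts.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_run_config(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  stages <- list()
  counts <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    stages[[name]] <<- list(
      status = if (ok) "ok" else paste("refused:", conditionMessage(res)))
    crd_log("[stage %s] %s (%.1fs)", name, stages[[name]]$status,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    if (ok) res else NULL
  }

  ## simulate ----------------------------------------------------------------
  sim_args <- config$simulate
  sim_args$seed <- derive_seed(seed, "simulate")
  cohort <- stage("simulate", {
    co <- simulate_cohort(do.call(simulation_config, sim_args))
    write_cohort(co, file.path(out_dir, "cohort"))
    co
  })
  if (is.null(cohort)) crd_stop("simulation stage failed; aborting")
  meta <- cohort$metadata
  groups <- unique(meta$disease_status)
  two_groups <- length(groups) == 2L

  ## preprocess --------------------------------------------------------------
  norm <- stage("preprocess", {
    gpc <- compute_pcs(cohort$genotypes$dosages,
                       config$preprocess$n_genotype_pcs)
    ppc <- compute_pcs(cohort$peaks$values, config$preprocess$n_phenotype_pcs)
    epc <- compute_pcs(cohort$genes$values, config$preprocess$n_phenotype_pcs)
    peaks_norm <- normalize_phenotypes(cohort$peaks, cbind(gpc, ppc))
    genes_norm <- normalize_phenotypes(cohort$genes, cbind(gpc, epc))
    peaks_corr <- regress_out(cohort$peaks, cbind(gpc, ppc))
    write_phenotype_bed(peaks_norm, file.path(out_dir, "peaks.norm.bed"))
    write_phenotype_bed(genes_norm, file.path(out_dir, "genes.norm.bed"))
    list(peaks = peaks_norm, genes = genes_norm, peaks_corr = peaks_corr,
         gpc = gpc)
  })
  if (is.null(norm)) crd_stop("preprocess stage failed; aborting")

  ## CRD calls ---------------------------------------------------------------
  crds <- stage("crd_call", {
    case_idx <- meta$status_code == 1L
    w <- config$crd$window; f <- config$crd$factor
    combined <- crd_call(norm$peaks, window = w, factor = f)
    cases <- if (two_groups)
      crd_call(subset_samples(norm$peaks, case_idx), window = w, factor = f)
      else NULL
    controls <- if (two_groups)
      crd_call(subset_samples(norm$peaks, !case_idx), window = w, factor = f)
      else NULL
    write_crd_bed(combined, file.path(out_dir, "crds_combined.bed"))
    if (two_groups) {
      write_crd_bed(cases, file.path(out_dir, "crds_cases.bed"))
      write_crd_bed(controls, file.path(out_dir, "crds_controls.bed"))
    }
    if (nrow(combined$table) == 0L) crd_stop("no CRDs called in combined set")
    activity <- quantify_crds(norm$peaks, combined)
    activity_norm <- activity
    activity_norm$values <- apply(activity$values, 2,
                                  inverse_normal_transform)
    activity_norm$kind <- "normalized"
    write_phenotype_bed(activity_norm, file.path(out_dir, "activity.bed"))
    list(combined = combined, cases = cases, controls = controls,
         activity = activity_norm)
  })
  if (is.null(crds)) crd_stop("CRD stage failed; aborting")
  counts$crds_combined <- nrow(crds$combined$table)
  counts$crds_cases <- if (two_groups) nrow(crds$cases$table) else NA
  counts$crds_controls <- if (two_groups) nrow(crds$controls$table) else NA

  ## structure analysis ------------------------------------------------------
  struct <- stage("structure", {
    if (!two_groups) crd_stop("two groups required")
    specific <- find_specific_crds(crds$cases, crds$controls)
    spec_peaks <- unique(unlist(specific$members, use.names = FALSE))
    pd <- NULL; shift <- NULL
    if (length(spec_peaks) >= 1L) {
      sub <- subset_features(cohort$peaks,
                             cohort$peaks$feature_ids %in% spec_peaks)
      pd <- per_peak_differential(sub, meta)
      write_results_table(pd, file.path(out_dir, "specific_peak_diff.tsv"))
    }
    if (nrow(specific$table) >= 2L) {
      shift <- per_crd_correlation_shift(norm$peaks_corr, specific, meta)
      sh <- shift$per_crd
      class(sh) <- c("crd_correlation_shift", "data.frame")
      write_results_table(sh, file.path(out_dir, "specific_crd_shift.tsv"))
    }
    list(specific = specific, peak_diff = pd, shift = shift)
  })
  counts$specific_crds <- if (!is.null(struct)) nrow(struct$specific$table)
                          else NA

  ## differential ------------------------------------------------------------
  diff <- stage("differential", {
    if (!two_groups) crd_stop("two groups required")
    dg <- nb_wald_test(cohort$gene_counts, meta)
    crd_counts <- sum_crd_counts(cohort$peak_counts, crds$combined)
    dc <- nb_wald_test(crd_counts, meta)
    write_results_table(dg, file.path(out_dir, "diff_genes.tsv"))
    write_results_table(dc, file.path(out_dir, "diff_crds.tsv"))
    list(genes = dg, crds = dc)
  })
  if (!is.null(diff)) {
    counts$diff_genes <- sum(diff$genes$q <= 0.05, na.rm = TRUE)
    counts$diff_crds <- sum(diff$crds$q <= 0.05, na.rm = TRUE)
  }

  ## QTL mapping -------------------------------------------------------------
  qtl <- stage("qtl", {
    qc <- config$qtl
    eqtl <- permutation_pass(norm$genes, cohort$genotypes, window = qc$window,
                             n_perm = qc$n_perm,
                             seed = derive_seed(seed, "eqtl"),
                             min_maf = qc$min_maf)
    acrd <- permutation_pass(crds$activity, cohort$genotypes,
                             window = qc$window, n_perm = qc$n_perm,
                             seed = derive_seed(seed, "acrdqtl"),
                             min_maf = qc$min_maf)
    cqtl <- permutation_pass(norm$peaks, cohort$genotypes,
                             window = qc$window, n_perm = qc$n_perm,
                             seed = derive_seed(seed, "cqtl"),
                             min_maf = qc$min_maf)
    econd <- conditional_pass(norm$genes, cohort$genotypes, eqtl,
                              fdr = qc$fdr, window = qc$window,
                              min_maf = qc$min_maf)
    acond <- conditional_pass(crds$activity, cohort$genotypes, acrd,
                              fdr = qc$fdr, window = qc$window,
                              min_maf = qc$min_maf)
    write_results_table(eqtl, file.path(out_dir, "qtl_e.tsv"))
    write_results_table(acrd, file.path(out_dir, "qtl_acrd.tsv"))
    write_results_table(cqtl, file.path(out_dir, "qtl_c.tsv"))
    write_results_table(econd, file.path(out_dir, "qtl_e_conditional.tsv"))
    write_results_table(acond, file.path(out_dir, "qtl_acrd_conditional.tsv"))
    list(eqtl = eqtl, acrd = acrd, cqtl = cqtl, econd = econd, acond = acond)
  })
  if (!is.null(qtl)) {
    counts$eqtl <- sum(qtl$eqtl$q <= config$qtl$fdr, na.rm = TRUE)
    counts$acrd_qtl <- sum(qtl$acrd$q <= config$qtl$fdr, na.rm = TRUE)
    counts$cqtl <- sum(qtl$cqtl$q <= config$qtl$fdr, na.rm = TRUE)
  }

  ## interaction QTLs (case-discovered effects, tested on all samples) ------
  inter <- stage("interaction", {
    if (!two_groups) crd_stop("two groups required")
    if (is.null(qtl)) crd_stop("qtl stage did not run")
    qc <- config$qtl
    case_idx <- which(meta$status_code == 1L)
    geno_cases <- subset_samples(cohort$genotypes, case_idx)
    eqtl_cases <- permutation_pass(subset_samples(norm$genes, case_idx),
                                   geno_cases, window = qc$window,
                                   n_perm = qc$n_perm,
                                   seed = derive_seed(seed, "eqtl_cases"),
                                   min_maf = qc$min_maf)
    acrd_cases <- permutation_pass(subset_samples(crds$activity, case_idx),
                                   geno_cases, window = qc$window,
                                   n_perm = qc$n_perm,
                                   seed = derive_seed(seed, "acrd_cases"),
                                   min_maf = qc$min_maf)
    hits <- rbind(eqtl_cases[eqtl_cases$q <= qc$fdr, ],
                  acrd_cases[acrd_cases$q <= qc$fdr, ])
    if (!nrow(hits)) crd_stop("no case-set QTLs to test")
    pheno_all <- norm$genes
    # one matrix holding both phenotype classes for the interaction test
    both <- phenotype_matrix(cbind(norm$genes$values, crds$activity$values),
                             c(norm$genes$chrom, crds$activity$chrom),
                             c(norm$genes$start, crds$activity$start),
                             c(norm$genes$end, crds$activity$end),
                             c(norm$genes$strand, crds$activity$strand),
                             kind = "normalized",
                             sample_ids = norm$genes$sample_ids,
                             feature_ids = c(norm$genes$feature_ids,
                                             crds$activity$feature_ids))
    ir <- interaction_qtl(both, cohort$genotypes, meta, hits,
                          covariates = norm$gpc)
    write_results_table(ir, file.path(out_dir, "interaction.tsv"))
    ir
  })
  if (!is.null(inter))
    counts$interaction_qtls <- sum(inter$q <= config$qtl$fdr, na.rm = TRUE)

  ## gene-CRD pairs ----------------------------------------------------------
  pairs <- stage("pairs", {
    pc <- config$pairs
    pr <- map_gene_crd_pairs(norm$genes, crds$activity, window = pc$window,
                             n_perm = pc$n_perm,
                             seed = derive_seed(seed, "pairs"))
    write_results_table(pr, file.path(out_dir, "pairs.tsv"))
    pr
  })
  if (!is.null(pairs))
    counts$gene_crd_pairs <- sum(pairs$q <= config$pairs$fdr, na.rm = TRUE)

  ## triplets + mechanisms ---------------------------------------------------
  trip <- stage("triplets", {
    if (is.null(pairs)) crd_stop("pairs stage did not run")
    tc <- config$triplets
    tr <- build_triplets(pairs, norm$genes, crds$activity, cohort$genotypes,
                         window = config$pairs$window, n_perm = tc$n_perm,
                         seed = derive_seed(seed, "triplets"), fdr = tc$fdr)
    if (!nrow(tr)) crd_stop("no triplets")
    out <- list(all = tr)
    if (two_groups) {
      for (grp in c("cases", "controls")) {
        idx <- which(meta$status_code == (grp == "cases"))
        cl <- classify_triplets(tr, subset_samples(norm$genes, idx),
                                subset_samples(crds$activity, idx),
                                subset_samples(cohort$genotypes, idx),
                                B = tc$bootstrap, threshold = tc$threshold,
                                seed = derive_seed(seed, paste0("boot_",
                                                                grp)))
        write_results_table(cl, file.path(out_dir,
                                          sprintf("triplets_%s.tsv", grp)))
        out[[grp]] <- cl
      }
      mc <- compare_mechanisms(out$cases, out$controls)
      write_results_table(mc, file.path(out_dir, "mechanism_changes.tsv"))
      out$mechanisms <- mc
    }
    out
  })
  if (!is.null(trip)) {
    counts$triplets <- nrow(trip$all)
    if (!is.null(trip$mechanisms))
      counts$mechanism_comparisons <- nrow(trip$mechanisms)
  }

  ## manifest ----------------------------------------------------------------
  cfg_yaml <- yaml::as.yaml(config)
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(sums) <- files
  manifest <- list(
    config_hash = unname(tools::md5sum(local({
      tf <- tempfile(); writeLines(cfg_yaml, tf); tf
    }))),
    seed = seed,
    parameters = config[setdiff(names(config), "seed")],
    stages = stages,
    counts = counts,
    files = sums,
    complete = all(vapply(stages, function(s) s$status == "ok", TRUE)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(manifest)
}
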