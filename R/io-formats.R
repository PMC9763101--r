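# Domain containers and on-disk formats.
#
# All genomic features use the BED convention internally (0-based, half-open);
# variant positions are kept 1-based as in VCF. Phenotype matrices are stored
# samples x features throughout the package.

## ---- GenotypeMatrix ---------------------------------------------------------

#' Construct a genotype matrix
#'
#' Samples-by-variants dosage matrix (0-2 scale) with variant coordinates and
#' minor allele frequencies. Variants are sorted by (chromosome, position);
#' MAF is always recomputed from the dosages.
#'
#' @param dosages Numeric matrix, samples x variants, entries in \[0, 2\].
#' @param chrom,pos,ref,alt Per-variant chromosome, 1-based position (as in
#'   VCF), reference and alternate allele.
#' @param sample_ids,variant_ids Identifiers; taken from `dimnames(dosages)`
#'   when omitted.
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, ref = NULL, alt = NULL,
                            sample_ids = rownames(dosages),
                            variant_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  nv <- ncol(dosages)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(dosages)))
  if (is.null(variant_ids)) variant_ids <- sprintf("V%05d", seq_len(nv))
  stopifnot(length(chrom) == nv, length(pos) == nv)
  if (anyDuplicated(sample_ids)) crd_stop("duplicate sample ids in genotype matrix")
  if (anyDuplicated(variant_ids)) crd_stop("duplicate variant ids in genotype matrix")
  if (any(dosages < -1e-9 | dosages > 2 + 1e-9, na.rm = TRUE))
    crd_stop("dosages outside [0, 2]")
  sample_ids <- unname(sample_ids); variant_ids <- unname(variant_ids)
  chrom <- unname(chrom); pos <- unname(pos)
  ord <- order(chrom, pos)
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- list(sample_ids, variant_ids[ord])
  p <- colMeans(dosages, na.rm = TRUE) / 2
  obj <- list(sample_ids = sample_ids, variant_ids = variant_ids[ord],
              chrom = chrom[ord], pos = as.integer(pos[ord]),
              ref = (ref %||% rep("A", nv))[ord],
              alt = (alt %||% rep("G", nv))[ord],
              dosages = dosages, maf = pmin(p, 1 - p))
  class(obj) <- "GenotypeMatrix"
  obj
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants on %d chromosome(s)\n",
              length(x$sample_ids), length(x$variant_ids),
              length(unique(x$chrom))))
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' Biallelic SNVs only; records with more than one ALT allele are skipped and
#' counted. Dosages are taken from the DS FORMAT field when present, otherwise
#' from the GT allele count. Missing genotypes become NA.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param min_maf Variants below this MAF are dropped (default 0: keep all;
#'   QTL passes apply their own filter).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, min_maf = 0) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) crd_stop("malformed VCF '%s': %s", path,
                                               conditionMessage(e)))
  if (nrow(vcf@fix) == 0L) crd_stop("no usable variants in '%s'", path)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    crd_log("read_genotypes: skipped %d non-biallelic record(s)", sum(!bi))
    vcf <- vcf[bi, ]
  }
  if (nrow(vcf@fix) == 0L) crd_stop("no usable biallelic variants in '%s'", path)
  fix <- vcf@fix
  fmt <- vcf@gt[, 1L]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, 2, function(g) {
      a1 <- substr(g, 1, 1); a2 <- substr(g, 3, 3)
      out <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
      out
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(fix))
  }
  ids <- fix[, "ID"]
  miss <- is.na(ids) | ids == "."
  ids[miss] <- sprintf("%s_%s_%s_%s", fix[miss, "CHROM"], fix[miss, "POS"],
                       fix[miss, "REF"], fix[miss, "ALT"])
  gm <- genotype_matrix(t(ds), chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        sample_ids = colnames(vcf@gt)[-1L], variant_ids = ids)
  if (min_maf > 0) {
    keep <- gm$maf >= min_maf
    gm <- subset_variants(gm, keep)
  }
  gm
}

#' Subset a genotype matrix by variant
#' @param gm A `GenotypeMatrix`.
#' @param idx Logical or integer index over variants.
#' @export
subset_variants <- function(gm, idx) {
  genotype_matrix(gm$dosages[, idx, drop = FALSE], gm$chrom[idx], gm$pos[idx],
                  gm$ref[idx], gm$alt[idx], gm$sample_ids,
                  gm$variant_ids[idx])
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF v4.2 with GT and DS FORMAT fields. Integer dosages are
#' written as hard genotypes; fractional dosages keep full precision in DS.
#'
#' @param gm A `GenotypeMatrix`.
#' @param path Output path (plain text).
#' @export
write_genotypes_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")), con)
  gt_of <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & abs(d - round(d)) < 1e-9 & round(d) == 0] <- "0/0"
    out[!is.na(d) & abs(d - round(d)) < 1e-9 & round(d) == 1] <- "0/1"
    out[!is.na(d) & abs(d - round(d)) < 1e-9 & round(d) == 2] <- "1/1"
    out
  }
  for (j in seq_along(gm$variant_ids)) {
    d <- gm$dosages[, j]
    ds <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 10))
    cells <- paste(gt_of(d), ds, sep = ":")
    writeLines(paste(c(gm$chrom[j], gm$pos[j], gm$variant_ids[j], gm$ref[j],
                       gm$alt[j], ".", "PASS", ".", "GT:DS", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

## ---- PhenotypeMatrix --------------------------------------------------------

#' Construct a phenotype matrix
#'
#' Samples-by-features matrix of molecular quantifications (chromatin peaks,
#' genes or CRD activity) with BED-convention feature coordinates (0-based,
#' half-open). Features are sorted by (chromosome, start).
#'
#' @param values Numeric matrix, samples x features.
#' @param chrom,start,end Per-feature coordinates, `start < end`.
#' @param strand Per-feature strand ("+"/"-"); defaults to "+".
#' @param group_id Per-feature group identifier (QTLtools `gid` column).
#' @param kind One of `"raw_count"`, `"quantified"`, `"normalized"`.
#' @param sample_ids,feature_ids Identifiers; taken from dimnames when omitted.
#' @return An object of class `PhenotypeMatrix`.
#' @export
phenotype_matrix <- function(values, chrom, start, end, strand = NULL,
                             group_id = NULL,
                             kind = c("quantified", "raw_count", "normalized"),
                             sample_ids = rownames(values),
                             feature_ids = colnames(values)) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  nf <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- sprintf("F%05d", seq_len(nf))
  stopifnot(length(chrom) == nf, length(start) == nf, length(end) == nf)
  if (anyDuplicated(sample_ids)) crd_stop("duplicate sample ids")
  if (anyDuplicated(feature_ids)) crd_stop("duplicate feature ids")
  if (any(start >= end)) crd_stop("feature with start >= end")
  if (kind == "raw_count") {
    v <- values[!is.na(values)]
    if (any(v < 0) || any(abs(v - round(v)) > 1e-9))
      crd_stop("raw_count matrix must contain non-negative integers")
  }
  ord <- order(chrom, start)
  values <- values[, ord, drop = FALSE]
  dimnames(values) <- list(sample_ids, feature_ids[ord])
  obj <- list(sample_ids = sample_ids, feature_ids = feature_ids[ord],
              chrom = chrom[ord], start = as.integer(start[ord]),
              end = as.integer(end[ord]),
              strand = (strand %||% rep("+", nf))[ord],
              group_id = (group_id %||% feature_ids)[ord],
              values = values, kind = kind)
  class(obj) <- "PhenotypeMatrix"
  obj
}

#' @export
print.PhenotypeMatrix <- function(x, ...) {
  cat(sprintf("PhenotypeMatrix (%s): %d samples x %d features\n", x$kind,
              length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

#' Subset a phenotype matrix by feature
#' @param pm A `PhenotypeMatrix`.
#' @param idx Logical or integer index over features.
#' @export
subset_features <- function(pm, idx) {
  phenotype_matrix(pm$values[, idx, drop = FALSE], pm$chrom[idx],
                   pm$start[idx], pm$end[idx], pm$strand[idx],
                   pm$group_id[idx], pm$kind, pm$sample_ids,
                   pm$feature_ids[idx])
}

#' Subset a phenotype or genotype matrix by sample
#' @param x A `PhenotypeMatrix` or `GenotypeMatrix`.
#' @param idx Logical or integer index over samples, or sample ids.
#' @export
subset_samples <- function(x, idx) UseMethod("subset_samples")

#' @export
subset_samples.PhenotypeMatrix <- function(x, idx) {
  if (is.character(idx)) idx <- match(idx, x$sample_ids)
  phenotype_matrix(x$values[idx, , drop = FALSE], x$chrom, x$start, x$end,
                   x$strand, x$group_id, x$kind, x$sample_ids[idx],
                   x$feature_ids)
}

#' @export
subset_samples.GenotypeMatrix <- function(x, idx) {
  if (is.character(idx)) idx <- match(idx, x$sample_ids)
  genotype_matrix(x$dosages[idx, , drop = FALSE], x$chrom, x$pos, x$ref,
                  x$alt, x$sample_ids[idx], x$variant_ids)
}

#' Read a QTLtools-style phenotype BED
#'
#' Expected layout: a header line `#chr start end id gid strand sample1 ...`
#' followed by one row per feature. Coordinates stay 0-based half-open.
#'
#' @param path Path to the BED file.
#' @param kind Value kind flag for the resulting matrix.
#' @return A [phenotype_matrix()].
#' @export
read_phenotype_bed <- function(path, kind = "quantified") {
  lines <- readLines(path)
  if (length(lines) < 1L || !startsWith(lines[1L], "#"))
    crd_stop("'%s': missing '#chr start end id gid strand ...' header", path)
  header <- strsplit(sub("^#", "", lines[1L]), "\t")[[1L]]
  ncol_exp <- length(header)
  rows <- strsplit(lines[-1L], "\t")
  bad <- which(vapply(rows, length, 1L) != ncol_exp)
  if (length(bad))
    crd_stop("'%s': row %d has %d fields, expected %d", path, bad[1L] + 1L,
             length(rows[[bad[1L]]]), ncol_exp)
  if (length(rows) == 0L) crd_stop("'%s': no features", path)
  m <- do.call(rbind, rows)
  ids <- m[, 4L]
  if (anyDuplicated(ids)) crd_stop("'%s': duplicate feature id '%s'", path,
                                   ids[duplicated(ids)][1L])
  start <- as.integer(m[, 2L]); end <- as.integer(m[, 3L])
  if (any(start >= end))
    crd_stop("'%s': feature '%s' has start >= end", path, ids[start >= end][1L])
  vals <- matrix(suppressWarnings(as.numeric(m[, -(1:6), drop = FALSE])),
                 nrow = nrow(m))
  phenotype_matrix(t(vals), chrom = m[, 1L], start = start, end = end,
                   strand = m[, 6L], group_id = m[, 5L], kind = kind,
                   sample_ids = header[-(1:6)], feature_ids = ids)
}

#' Write a phenotype matrix as QTLtools-style BED
#' @param pm A `PhenotypeMatrix`.
#' @param path Output path.
#' @export
write_phenotype_bed <- function(pm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#chr", "start", "end", "id", "gid", "strand",
                     pm$sample_ids), collapse = "\t"), con)
  vals <- t(pm$values)
  for (j in seq_along(pm$feature_ids)) {
    v <- if (pm$kind == "raw_count") format(vals[j, ], scientific = FALSE,
                                            trim = TRUE)
         else ifelse(is.na(vals[j, ]), "NA",
                     formatC(vals[j, ], format = "g", digits = 10))
    writeLines(paste(c(pm$chrom[j], pm$start[j], pm$end[j], pm$feature_ids[j],
                       pm$group_id[j], pm$strand[j], v), collapse = "\t"), con)
  }
  invisible(path)
}

## ---- SampleMetadata ---------------------------------------------------------

#' Construct sample metadata
#'
#' @param sample_id Character vector of unique ids.
#' @param disease_status Character/factor with values "case"/"control".
#' @param covariates Optional numeric matrix or data.frame (samples x
#'   covariates) of biological/technical covariates.
#' @return An object of class `SampleMetadata`. `status_code` is the
#'   deterministic binary coding (case = 1, control = 0).
#' @export
sample_metadata <- function(sample_id, disease_status, covariates = NULL) {
  if (anyDuplicated(sample_id)) crd_stop("duplicate sample ids in metadata")
  disease_status <- as.character(disease_status)
  if (!all(disease_status %in% c("case", "control")))
    crd_stop("disease_status must be 'case' or 'control'")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(sample_id))
    rownames(covariates) <- sample_id
  }
  obj <- list(sample_id = sample_id, disease_status = disease_status,
              status_code = as.integer(disease_status == "case"),
              covariates = covariates)
  class(obj) <- "SampleMetadata"
  obj
}

#' Read sample metadata TSV (columns: sample_id, disease_status, covariates...)
#' @param path Path to TSV.
#' @export
read_sample_metadata <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  cov <- if (ncol(df) > 2L) as.matrix(df[, -(1:2), drop = FALSE]) else NULL
  sample_metadata(df$sample_id, df$disease_status, cov)
}

#' Write sample metadata TSV
#' @param meta A `SampleMetadata`.
#' @param path Output path.
#' @export
write_sample_metadata <- function(meta, path) {
  df <- data.frame(sample_id = meta$sample_id,
                   disease_status = meta$disease_status,
                   stringsAsFactors = FALSE)
  if (!is.null(meta$covariates)) df <- cbind(df, as.data.frame(meta$covariates))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- IntervalSet ------------------------------------------------------------

#' Construct an interval set (annotation track, hotspot intervals, ...)
#' @param chrom,start,end Half-open intervals, `start < end`.
#' @param label Optional track label.
#' @export
interval_set <- function(chrom, start, end, label = NULL) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start >= end)) crd_stop("interval with start >= end")
  ord <- order(chrom, start)
  obj <- list(chrom = chrom[ord], start = as.integer(start[ord]),
              end = as.integer(end[ord]), label = label)
  class(obj) <- "IntervalSet"
  obj
}

#' Read a plain BED file (first three columns) into an interval set
#' @param path BED path.
#' @param label Optional label.
#' @export
read_bed_intervals <- function(path, label = NULL) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  interval_set(df[[1L]], df[[2L]], df[[3L]], label = label)
}

#' Test which query intervals overlap an interval set by >= 1 bp
#'
#' @param iv An `IntervalSet`.
#' @param chrom,start,end Query intervals (half-open).
#' @return Logical vector, one per query.
#' @export
overlaps_any <- function(iv, chrom, start, end) {
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    si <- which(iv$chrom == ch)
    if (!length(si)) next
    s_start <- iv$start[si]; s_end <- iv$end[si]
    o <- order(s_start)
    s_start <- s_start[o]; cmax_end <- cummax(s_end[o])
    # overlap iff some subject has start < q.end and (running max) end > q.start
    k <- findInterval(end[qi] - 1L, s_start)   # subjects with start <= end-1
    ok <- k > 0L
    ok[ok] <- cmax_end[k[ok]] > start[qi][ok]
    out[qi] <- ok
  }
  out
}

## ---- Results tables ---------------------------------------------------------

#' Write a typed results table as TSV
#'
#' Records produced by the analysis stages are data.frames carrying a type
#' class (e.g. `qtl_records`, `triplet_records`). Floats are written at 6
#' significant digits; row order is made deterministic by sorting on the id
#' columns.
#'
#' @param records A typed data.frame, or a list of data.frames of one type
#'   (mixed types are an error).
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    types <- unique(vapply(records, function(r) class(r)[1L], ""))
    if (length(types) > 1L)
      crd_stop("mixed record types: %s", paste(types, collapse = ", "))
    records <- do.call(rbind, records)
  }
  stopifnot(is.data.frame(records))
  type <- class(records)[1L]
  df <- as.data.frame(records)
  id_cols <- intersect(c("phenotype_id", "variant_id", "crd_id", "gene_id",
                         "feature_id", "triplet_id", "peak_id"), names(df))
  if (nrow(df) > 1L && length(id_cols))
    df <- df[do.call(order, df[id_cols]), , drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), NA, signif(x, 6)))
  header <- sprintf("#type=%s", type)
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path Input path.
#' @return A data.frame with its type class restored.
#' @export
read_results_table <- function(path) {
  first <- readLines(path, n = 1L)
  type <- sub("^#type=", "", first)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  class(df) <- c(type, "data.frame")
  df
}
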