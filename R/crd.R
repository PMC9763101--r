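# Cis-regulatory domain calling.
#
# The CRD signal is interindividual correlation between nearby peaks: a
# banded Pearson correlation map per chromosome, adjacency-constrained
# hierarchical clustering into a binary tree, and acceptance of maximal tree
# nodes passing three empirical criteria (overall correlation, edge
# correlation, >= 2 non-overlapping members).

#' Build a banded interindividual correlation map per chromosome
#'
#' Pearson correlations on pairwise-complete samples for all peak pairs
#' within `window` peak indices of each other. Pairs with fewer than
#' `min_complete` complete samples get NA (logged). The chromosome-local
#' background is the null correlation scale: the magnitude below which ~99%
#' of uncoordinated pair correlations are expected to fall, estimated
#' robustly as `qnorm(0.995) * median(|r|) / qnorm(0.75)` over banded
#' off-diagonal pairs. The median makes the estimate insensitive to the
#' minority of truly coordinated pairs, and the scaling is exact when null
#' correlations are centred at zero.
#'
#' @param peaks A normalized `PhenotypeMatrix` of peak quantifications.
#' @param window Band half-width in peak-index units (default 250).
#' @param min_complete Minimum pairwise-complete samples per pair.
#' @param background_floor Lower bound applied when the estimate is
#'   non-positive or undefined.
#' @return A named list of `CorrelationMap` objects, one per chromosome.
#' @export
build_correlation_map <- function(peaks, window = 250L, min_complete = 10L,
                                  background_floor = 0.01) {
  stopifnot(inherits(peaks, "PhenotypeMatrix"))
  if (peaks$kind != "normalized")
    crd_stop("build_correlation_map expects a normalized PhenotypeMatrix")
  maps <- list()
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    if (length(idx) < 2L) crd_stop("chromosome '%s' has < 2 peaks", ch)
    v <- peaks$values[, idx, drop = FALSE]
    r <- suppressWarnings(cor(v, use = "pairwise.complete.obs"))
    if (anyNA(v)) {
      cc <- crossprod(!is.na(v))
      low <- cc < min_complete
      if (any(low[upper.tri(low)])) {
        crd_log("correlation map %s: %d pair(s) with < %d complete samples set NA",
                ch, sum(low[upper.tri(low)]), min_complete)
        r[low] <- NA_real_
      }
    }
    n <- length(idx)
    band <- abs(row(r) - col(r)) <= window
    r[!band] <- NA_real_
    offdiag <- band & row(r) != col(r)
    bvals <- r[offdiag]
    sigma <- median(abs(bvals), na.rm = TRUE) / qnorm(0.75)
    background <- qnorm(0.995) * sigma
    if (!is.finite(background) || background <= 0) {
      warning(sprintf("chromosome %s: degenerate background; using floor %g",
                      ch, background_floor))
      background <- background_floor
    }
    background <- max(background, background_floor)
    obj <- list(chrom = ch, peak_ids = peaks$feature_ids[idx],
                start = peaks$start[idx], end = peaks$end[idx],
                r = r, window = as.integer(window), background = background)
    class(obj) <- "CorrelationMap"
    maps[[ch]] <- obj
  }
  maps
}

#' @export
print.CorrelationMap <- function(x, ...) {
  cat(sprintf("CorrelationMap %s: %d peaks, window %d, background %.4f\n",
              x$chrom, length(x$peak_ids), x$window, x$background))
  invisible(x)
}

# Count of mutually non-overlapping intervals among members (greedy by end).
n_nonoverlapping <- function(start, end) {
  o <- order(end)
  cnt <- 0L; cur <- -Inf
  for (i in o) {
    if (start[i] >= cur) { cnt <- cnt + 1L; cur <- end[i] }
  }
  cnt
}

#' Adjacency-constrained hierarchical clustering of a correlation map
#'
#' Agglomerative merging restricted to genomically adjacent clusters: at each
#' step the adjacent cluster pair with the maximal mean pairwise correlation
#' between their members is merged (ties to the leftmost pair). Pairs beyond
#' the band, or with undefined correlation, contribute the background value.
#' Each internal node records its member index range, mean within-node
#' correlation, edge correlation (mean correlation between each of the two
#' boundary peaks and all other members) and the number of non-overlapping
#' member intervals.
#'
#' @param map A `CorrelationMap`.
#' @return A `ClusterTree`: node table plus bookkeeping; leaves are peaks in
#'   genomic order, node `2n - 1` is the root.
#' @export
build_tree <- function(map) {
  stopifnot(inherits(map, "CorrelationMap"))
  n <- length(map$peak_ids)
  bg <- map$background
  M <- map$r
  na_band <- sum(is.na(M[abs(row(M) - col(M)) <= map$window]))
  if (na_band > 0)
    crd_log("build_tree %s: %d banded pair value(s) treated as background",
            map$chrom, na_band)
  M[is.na(M)] <- bg
  diag(M) <- 1
  # 2-D prefix sums: P[i+1, j+1] = sum(M[1:i, 1:j])
  P <- matrix(0, n + 1L, n + 1L)
  cs <- apply(M, 2L, cumsum)
  P[-1L, -1L] <- t(apply(cs, 1L, cumsum))
  blocksum <- function(a1, a2, b1, b2)
    P[a2 + 1L, b2 + 1L] - P[a1, b2 + 1L] - P[a2 + 1L, b1] + P[a1, b1]

  n_nodes <- 2L * n - 1L
  lo <- c(seq_len(n), integer(n - 1L))
  hi <- c(seq_len(n), integer(n - 1L))
  left <- rep(NA_integer_, n_nodes)
  right <- rep(NA_integer_, n_nodes)
  mean_corr <- rep(NA_real_, n_nodes)
  edge_corr <- rep(NA_real_, n_nodes)
  n_nonover <- c(rep(1L, n), integer(n - 1L))

  clo <- seq_len(n); chi <- seq_len(n); cid <- seq_len(n)
  scores <- vapply(seq_len(n - 1L), function(i) M[i, i + 1L], 0)
  nxt <- n
  while (length(cid) > 1L) {
    i <- which.max(scores)            # ties -> leftmost
    nxt <- nxt + 1L
    a1 <- clo[i]; a2 <- chi[i]; b1 <- clo[i + 1L]; b2 <- chi[i + 1L]
    lo[nxt] <- a1; hi[nxt] <- b2
    left[nxt] <- cid[i]; right[nxt] <- cid[i + 1L]
    k <- b2 - a1 + 1L
    mean_corr[nxt] <- (blocksum(a1, b2, a1, b2) - k) / (k * (k - 1L))
    s1 <- blocksum(a1, a1, a1, b2) - 1
    s2 <- blocksum(b2, b2, a1, b2) - 1
    edge_corr[nxt] <- (s1 + s2) / (2 * (k - 1L))
    n_nonover[nxt] <- n_nonoverlapping(map$start[a1:b2], map$end[a1:b2])
    clo <- c(clo[seq_len(i - 1L)], a1, clo[-seq_len(i + 1L)])
    chi <- c(chi[seq_len(i - 1L)], b2, chi[-seq_len(i + 1L)])
    cid <- c(cid[seq_len(i - 1L)], nxt, cid[-seq_len(i + 1L)])
    m <- length(cid)               # clusters after the merge; merged at pos i
    m0 <- m + 1L                   # clusters before the merge
    if (m > 1L) {
      new_scores <- numeric(m - 1L)
      if (i >= 3L) new_scores[seq_len(i - 2L)] <- scores[seq_len(i - 2L)]
      if (i + 1L <= m - 1L)
        new_scores[(i + 1L):(m - 1L)] <- scores[(i + 2L):(m0 - 1L)]
      pair_score <- function(j1, j2)
        blocksum(clo[j1], chi[j1], clo[j2], chi[j2]) /
          ((chi[j1] - clo[j1] + 1) * (chi[j2] - clo[j2] + 1))
      if (i > 1L) new_scores[i - 1L] <- pair_score(i - 1L, i)
      if (i <= m - 1L) new_scores[i] <- pair_score(i, i + 1L)
      scores <- new_scores
    } else scores <- numeric(0)
  }
  obj <- list(chrom = map$chrom, peak_ids = map$peak_ids,
              nodes = data.frame(id = seq_len(n_nodes), lo = lo, hi = hi,
                                 left = left, right = right,
                                 mean_corr = mean_corr, edge_corr = edge_corr,
                                 n_nonoverlapping = n_nonover),
              n_leaves = n, root = n_nodes, background = bg)
  class(obj) <- "ClusterTree"
  obj
}

#' Call CRDs from a cluster tree
#'
#' Depth-first from the root: a node is accepted iff its mean correlation and
#' edge correlation are both at least `factor` times the background and it
#' spans at least two non-overlapping members. Accepted nodes are not
#' descended into, so the result is the set of maximal qualifying domains;
#' rejected subtrees are searched recursively.
#'
#' @param tree A `ClusterTree`.
#' @param map The `CorrelationMap` the tree was built from.
#' @param factor Criteria multiplier on the background (default 2).
#' @return A `CRDSet`: `$table` (one row per CRD: id, chrom, start, end,
#'   n_members, mean_corr, edge_corr, background) and `$members` (named list
#'   of ordered member peak ids).
#' @export
call_crds <- function(tree, map, factor = 2) {
  stopifnot(inherits(tree, "ClusterTree"), inherits(map, "CorrelationMap"))
  nd <- tree$nodes
  bg <- tree$background
  acc <- integer(0)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= tree$n_leaves) next
    ok <- !is.na(nd$mean_corr[v]) && nd$mean_corr[v] >= factor * bg &&
      nd$edge_corr[v] >= factor * bg && nd$n_nonoverlapping[v] >= 2L &&
      (nd$hi[v] - nd$lo[v] + 1L) >= 2L
    if (ok) acc <- c(acc, v)
    else stack <- c(stack, nd$left[v], nd$right[v])
  }
  acc <- acc[order(nd$lo[acc])]
  ids <- sprintf("%s_crd%d", tree$chrom, seq_along(acc))
  members <- lapply(acc, function(v) tree$peak_ids[nd$lo[v]:nd$hi[v]])
  names(members) <- ids
  tab <- data.frame(crd_id = ids, chrom = rep(tree$chrom, length(acc)),
                    start = map$start[nd$lo[acc]], end = map$end[nd$hi[acc]],
                    n_members = nd$hi[acc] - nd$lo[acc] + 1L,
                    mean_corr = nd$mean_corr[acc],
                    edge_corr = nd$edge_corr[acc],
                    background = rep(bg, length(acc)),
                    stringsAsFactors = FALSE)
  obj <- list(table = tab, members = members,
              peak_universe = tree$peak_ids, factor = factor)
  class(obj) <- "CRDSet"
  obj
}

#' @export
print.CRDSet <- function(x, ...) {
  cat(sprintf("CRDSet: %d CRDs over %d peaks\n", nrow(x$table),
              length(x$peak_universe)))
  invisible(x)
}

# Merge per-chromosome CRDSets into one (ids already chromosome-prefixed).
merge_crd_sets <- function(sets) {
  obj <- list(table = do.call(rbind, lapply(sets, `[[`, "table")),
              members = do.call(c, unname(lapply(sets, `[[`, "members"))),
              peak_universe = unlist(lapply(sets, `[[`, "peak_universe"),
                                     use.names = FALSE),
              factor = sets[[1L]]$factor)
  rownames(obj$table) <- NULL
  class(obj) <- "CRDSet"
  obj
}

#' Full CRD call across chromosomes
#'
#' Convenience wrapper: correlation map, clustering tree and CRD call per
#' chromosome, merged into one `CRDSet`.
#'
#' @inheritParams build_correlation_map
#' @inheritParams call_crds
#' @export
crd_call <- function(peaks, window = 250L, factor = 2,
                     background_floor = 0.01) {
  maps <- build_correlation_map(peaks, window = window,
                                background_floor = background_floor)
  sets <- lapply(maps, function(m) call_crds(build_tree(m), m,
                                             factor = factor))
  merge_crd_sets(sets)
}

#' Write a CRD call set as BED
#'
#' Columns: chrom, start, end, crd_id, n_members, mean_corr, edge_corr,
#' member_ids (comma-separated).
#'
#' @param crds A `CRDSet`.
#' @param path Output path.
#' @export
write_crd_bed <- function(crds, path) {
  df <- crds$table
  lines <- paste(df$chrom, df$start, df$end, df$crd_id, df$n_members,
                 format_num(df$mean_corr), format_num(df$edge_corr),
                 vapply(crds$members, paste, collapse = ",", ""),
                 sep = "\t")
  writeLines(c("#chrom\tstart\tend\tcrd_id\tn_members\tmean_corr\tedge_corr\tmember_ids",
               lines), path)
  invisible(path)
}

#' Read a CRD BED written by [write_crd_bed()]
#' @param path Input path.
#' @param peak_universe Optional full peak-id universe to attach.
#' @export
read_crd_bed <- function(path, peak_universe = NULL) {
  df <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "crd_id",
                                 "n_members", "mean_corr", "edge_corr",
                                 "member_ids"))
  members <- setNames(strsplit(df$member_ids, ","), df$crd_id)
  tab <- df[, c("crd_id", "chrom", "start", "end", "n_members", "mean_corr",
                "edge_corr")]
  obj <- list(table = tab, members = members,
              peak_universe = peak_universe %||%
                unique(unlist(members, use.names = FALSE)),
              factor = NA_real_)
  class(obj) <- "CRDSet"
  obj
}

#' Quantify per-sample CRD activity
#'
#' Activity of a CRD in a sample is the mean of its member peaks' normalized
#' quantifications (NA-aware; all-NA yields NA).
#'
#' @param peaks A normalized `PhenotypeMatrix` containing every member peak.
#' @param crds A `CRDSet`.
#' @return A `PhenotypeMatrix` (kind `"quantified"`) of CRD activity with CRD
#'   span coordinates.
#' @export
quantify_crds <- function(peaks, crds) {
  stopifnot(inherits(peaks, "PhenotypeMatrix"), inherits(crds, "CRDSet"))
  miss <- setdiff(unique(unlist(crds$members)), peaks$feature_ids)
  if (length(miss))
    crd_stop("CRD member peak(s) missing from phenotype matrix: %s",
             paste(head(miss, 3L), collapse = ", "))
  act <- vapply(crds$members, function(m) {
    v <- rowMeans(peaks$values[, m, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }, numeric(length(peaks$sample_ids)))
  phenotype_matrix(act, crds$table$chrom, crds$table$start, crds$table$end,
                   kind = "quantified", sample_ids = peaks$sample_ids,
                   feature_ids = crds$table$crd_id)
}

#' Sum raw member-peak counts per CRD
#'
#' @param raw_counts A raw-count `PhenotypeMatrix` of peak counts.
#' @param crds A `CRDSet`.
#' @return A raw-count `PhenotypeMatrix` of integer CRD count sums.
#' @export
sum_crd_counts <- function(raw_counts, crds) {
  stopifnot(inherits(raw_counts, "PhenotypeMatrix"), inherits(crds, "CRDSet"))
  if (raw_counts$kind != "raw_count")
    crd_stop("sum_crd_counts expects kind = 'raw_count'")
  miss <- setdiff(unique(unlist(crds$members)), raw_counts$feature_ids)
  if (length(miss))
    crd_stop("CRD member peak(s) missing from count matrix: %s",
             paste(head(miss, 3L), collapse = ", "))
  cs <- vapply(crds$members, function(m)
    rowSums(raw_counts$values[, m, drop = FALSE]),
    numeric(length(raw_counts$sample_ids)))
  phenotype_matrix(cs, crds$table$chrom, crds$table$start, crds$table$end,
                   kind = "raw_count", sample_ids = raw_counts$sample_ids,
                   feature_ids = crds$table$crd_id)
}
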