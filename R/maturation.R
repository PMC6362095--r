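# Pseudotime as scaled PC1, differential expression between age groups,
# temporal curve fitting, cv2 filtering and k-means temporal classes.

#' Pseudotime as principal component 1 scaled to 0-100
#'
#' Runs PCA on log2(RPKM + 1) over the supplied variable genes and maps
#' the PC1 scores affinely onto \[0, 100\]. The sign of a principal
#' component is arbitrary, so the axis is oriented so that the mean
#' pseudotime of the earliest stage is below that of the latest stage
#' (when stages are supplied).
#'
#' @param expr Genes x cells expression matrix.
#' @param genes Variable genes to use (>= 2).
#' @param stage Optional stage label per cell, used for orientation.
#' @param stage_order Ordered stage labels; defaults to the order of first
#'   appearance in `stage`.
#' @return Object of class `pseudotime`: `values` (named, min 0, max 100),
#'   `flipped`, `var_explained`.
#' @export
compute_pseudotime <- function(expr, genes, stage = NULL,
                               stage_order = NULL) {
  .assert_genes(expr, genes)
  if (length(genes) < 2L || ncol(expr) < 2L)
    stop("need at least 2 genes and 2 cells", call. = FALSE)
  x <- t(.log2p1(expr[genes, , drop = FALSE]))
  if (all(apply(x, 2L, stats::var) < .Machine$double.eps))
    stop("degenerate input: no variance across cells", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 1L)
  s <- pc$x[, 1L]
  rng <- range(s)
  if (diff(rng) < .Machine$double.eps)
    stop("degenerate input: PC1 has zero variance", call. = FALSE)
  pt <- (s - rng[1]) / diff(rng) * 100
  flipped <- FALSE
  if (!is.null(stage)) {
    stopifnot(length(stage) == ncol(expr))
    ord <- stage_order %||% unique(stage)
    early <- stage == ord[1]
    late <- stage == ord[length(ord)]
    if (any(early) && any(late) &&
        mean(pt[early]) > mean(pt[late])) {
      pt <- 100 - pt
      flipped <- TRUE
    }
  }
  structure(list(values = stats::setNames(pt, colnames(expr)),
                 flipped = flipped,
                 var_explained = unname(pc$sdev[1]^2 /
                                          sum(apply(x, 2, stats::var)))),
            class = "pseudotime")
}

#' @export
print.pseudotime <- function(x, ...) {
  cat(sprintf("pseudotime over %d cells (PC1, %.1f%% of variance%s)\n",
              length(x$values), 100 * x$var_explained,
              if (x$flipped) ", orientation flipped" else ""))
  invisible(x)
}

# Wilcoxon rank-sum statistics for every gene with a permutation null.
# The rank matrix is computed once; permuted statistics come from one
# matrix product against random group indicators. The null is pooled
# across genes (all genes share the rank-sum null for fixed group sizes,
# up to tie corrections), giving p-value resolution 1/(n_genes * n_perm)
# — fine enough for stringent FDR thresholds at moderate permutation
# counts, in the spirit of rank-based resampling inference.
.rank_sum_perm <- function(expr, in_group, n_perm = 1000L, seed = 1L) {
  n <- ncol(expr)
  n1 <- sum(in_group)
  r <- .row_ranks(expr)
  w_obs <- as.vector(r %*% as.numeric(in_group))
  mu <- n1 * (n + 1) / 2
  set.seed(seed)
  ind <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) ind[sample(n, n1), b] <- 1
  pooled <- sort(abs(as.vector(r %*% ind) - mu))
  abs_obs <- abs(w_obs - mu)
  n_below <- findInterval(abs_obs - 1e-9, pooled)
  p <- (1 + length(pooled) - n_below) / (1 + length(pooled))
  data.frame(gene = rownames(expr), statistic = w_obs - mu, p = p,
             direction = ifelse(w_obs >= mu, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential expression between age groups
#'
#' Rank-based (Wilcoxon rank-sum) statistics for each pairwise contrast of
#' the age groups, with a permutation-estimated null and
#' Benjamini-Hochberg q-values per contrast. A gene is "changing" if
#' q < `q_threshold` in any contrast.
#'
#' @param expr Genes x cells expression matrix (endogenous genes).
#' @param group Age group per cell (e.g. Embryonic/Perinatal/Adult).
#' @param q_threshold Significance cut-off, default 0.01.
#' @param n_perm Label permutations per contrast.
#' @param seed Permutation seed; results are deterministic given it.
#' @return Object of class `de_result`: `table` (gene, contrast,
#'   statistic, p, q, direction) and `changing` (gene ids).
#' @export
de_between_age_groups <- function(expr, group, q_threshold = 0.01,
                                  n_perm = 1000L, seed = 1L) {
  stopifnot(length(group) == ncol(expr))
  lev <- unique(group)
  if (length(lev) < 2L) stop("need at least two groups", call. = FALSE)
  tabs <- list()
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    sel <- group %in% pr
    if (min(table(group[sel])) < 3L) {
      warning("contrast ", pr[1], " vs ", pr[2],
              " skipped: a group has fewer than 3 cells", call. = FALSE)
      next
    }
    sub <- expr[, sel, drop = FALSE]
    res <- .rank_sum_perm(sub, group[sel] == pr[1], n_perm = n_perm,
                          seed = .child_seed(seed, i))
    res$q <- stats::p.adjust(res$p, method = "BH")
    res$contrast <- paste(pr[1], "vs", pr[2])
    tabs[[length(tabs) + 1L]] <- res
  }
  tab <- do.call(rbind, tabs)
  changing <- unique(tab$gene[tab$q < q_threshold])
  structure(list(table = tab, changing = changing,
                 q_threshold = q_threshold), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("differential expression: %d genes changing (q < %g) across %d contrasts\n",
              length(x$changing), x$q_threshold,
              length(unique(x$table$contrast))))
  invisible(x)
}

#' Fit smooth expression curves along pseudotime
#'
#' Per gene, a natural cubic spline regression of log2(RPKM + 1) on
#' pseudotime with `df` degrees of freedom, evaluated on a uniform grid
#' over \[0, 100\] and clamped at zero. Fits are per-gene independent, so
#' curve fitting commutes with gene subsetting.
#'
#' @param expr Genes x cells matrix.
#' @param pt A [compute_pseudotime()] object or named numeric vector.
#' @param genes Genes to fit (must be in `expr`).
#' @param df Spline degrees of freedom, default 3.
#' @param grid_n Grid resolution, default 100 points.
#' @return Genes x grid matrix with attribute `grid` (pseudotime values).
#' @export
fit_temporal_curves <- function(expr, pt, genes, df = 3L, grid_n = 100L) {
  if (inherits(pt, "pseudotime")) pt <- pt$values
  .assert_genes(expr, genes)
  .assert_cells(expr, names(pt))
  y <- t(.log2p1(expr[genes, names(pt), drop = FALSE]))
  basis <- splines::ns(pt, df = df)
  x <- cbind(1, basis)
  beta <- stats::lm.fit(x, y)$coefficients
  grid <- seq(0, 100, length.out = grid_n)
  xg <- cbind(1, stats::predict(basis, grid))
  curves <- t(xg %*% beta)
  curves[curves < 0] <- 0
  rownames(curves) <- genes
  attr(curves, "grid") <- grid
  curves
}

#' Filter genes by squared coefficient of variation within expression bins
#'
#' Genes are binned into `n_bins` equal-count bins by mean expression; a
#' gene is removed iff its cv2 strictly exceeds the mean cv2 of its bin
#' ("across different expression levels"). `method = "global"` compares
#' against the single global mean cv2 instead.
#'
#' @param expr Genes x cells matrix (raw RPKM-like scale).
#' @param genes Genes to consider; default all rows.
#' @param n_bins Number of equal-count mean-expression bins, default 20.
#' @param method `"binned"` (default) or `"global"`.
#' @return Character vector of retained genes (input order preserved).
#' @export
filter_curves_by_cv2 <- function(expr, genes = rownames(expr),
                                 n_bins = 20L,
                                 method = c("binned", "global")) {
  method <- match.arg(method)
  .assert_genes(expr, genes)
  if (length(genes) == 1L) {
    warning("single gene: returned unchanged", call. = FALSE)
    return(genes)
  }
  st <- .row_stats(expr[genes, , drop = FALSE])
  cv2 <- st$cv2
  cv2[!is.finite(cv2)] <- 0  # constant or all-zero genes carry no variation
  if (method == "global") {
    keep <- cv2 <= mean(cv2)
  } else {
    n_bins <- min(n_bins, length(genes))
    # equal-count bins by mean; ties share a rank so ordering cannot matter
    rk <- rank(st$mean, ties.method = "average")
    bin <- ceiling(rk / length(genes) * n_bins)
    bin_mean <- tapply(cv2, bin, mean)
    keep <- cv2 <= bin_mean[as.character(bin)]
  }
  genes[keep]
}

#' Cluster temporal expression curves with k-means
#'
#' Curves are standardized per gene (zero mean, unit sd over the grid;
#' flat curves map to the zero profile) and clustered with
#' [stats::kmeans()] using `n_init` random restarts under a fixed seed.
#'
#' @param curves Genes x grid matrix from [fit_temporal_curves()].
#' @param k Number of temporal classes, default 3.
#' @param seed Seed for the restarts.
#' @param n_init k-means restarts, default 50.
#' @return Object of class `temporal_clusters`: `cluster` (named ids in
#'   1..k), `centers`, `k`.
#' @export
cluster_temporal_profiles <- function(curves, k = 3L, seed = 1L,
                                      n_init = 50L) {
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (nrow(curves) < k)
    stop("need at least k genes to form k clusters", call. = FALSE)
  mu <- rowMeans(curves)
  sdv <- apply(curves, 1L, stats::sd)
  z <- (curves - mu) / ifelse(sdv > 0, sdv, 1)
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100L)
  structure(list(cluster = stats::setNames(km$cluster, rownames(curves)),
                 centers = km$centers, k = k),
            class = "temporal_clusters")
}

#' @export
print.temporal_clusters <- function(x, ...) {
  cat("temporal clusters:",
      paste(sprintf("%d (n=%d)", seq_len(x$k),
                    tabulate(x$cluster, x$k)), collapse = ", "), "\n")
  invisible(x)
}
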