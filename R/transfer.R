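# Rank-based random-forest consensus label transfer between the
# dissociated (scRNA-seq) and spatial (in situ) modalities, and
# cross-dataset cluster similarity.

#' Within-cell rank transform over a shared gene panel
#'
#' Each cell's values over the shared panel are replaced by their
#' within-cell ranks (average ranks for ties; zeros rank lowest), making
#' the two modalities comparable despite different units. Panel genes
#' absent from the matrix score zero before ranking.
#'
#' @param mat Cells x genes matrix (RPKM or counts).
#' @param genes Shared gene panel (non-empty).
#' @return Cells x panel rank matrix.
#' @export
rank_transform <- function(mat, genes) {
  if (length(genes) == 0L) stop("empty gene panel", call. = FALSE)
  m <- matrix(0, nrow(mat), length(genes),
              dimnames = list(rownames(mat), genes))
  present <- intersect(genes, colnames(mat))
  m[, present] <- as.matrix(mat[, present, drop = FALSE])
  t(apply(m, 1L, rank))
}

#' Train an ensemble of independently seeded random forests
#'
#' Ten forests (by default) are trained on identical data with distinct
#' seeds, each a bagged decision-tree classifier with `ntree` trees and
#' `mtry` candidate features per split (as in the published analysis,
#' mtry = 15, ntree = 1000). Training varies between forests only through
#' the seed, which is what the downstream consensus vote averages over.
#'
#' @param ranks Cells x genes rank matrix ([rank_transform()]).
#' @param labels Class label per cell; >= 2 classes, each with >= 5 cells.
#' @param n_forests Number of forests, default 10.
#' @param seeds Optional explicit seeds (length `n_forests`).
#' @param ntree Trees per forest, default 1000.
#' @param mtry Features tried per split, default 15 (capped at the panel
#'   size with a warning).
#' @param base_seed Used to derive `seeds` when not given.
#' @return Object of class `forest_ensemble`.
#' @export
train_forest_ensemble <- function(ranks, labels, n_forests = 10L,
                                  seeds = NULL, ntree = 1000L, mtry = 15L,
                                  base_seed = 1L) {
  stopifnot(nrow(ranks) == length(labels))
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("need at least two classes", call. = FALSE)
  small <- names(which(table(labels) < 5L))
  if (length(small))
    stop("class(es) with fewer than 5 cells: ",
         paste(small, collapse = ", "),
         "; merge them with a related lineage before training",
         call. = FALSE)
  if (mtry > ncol(ranks)) {
    warning("mtry = ", mtry, " exceeds the panel size ", ncol(ranks),
            "; capped", call. = FALSE)
    mtry <- ncol(ranks)
  }
  if (is.null(seeds))
    seeds <- vapply(seq_len(n_forests), function(i)
      .child_seed(base_seed, i), numeric(1))
  stopifnot(length(seeds) == n_forests)
  forests <- lapply(seeds, function(s) {
    set.seed(s)
    randomForest::randomForest(x = ranks, y = labels, ntree = ntree,
                               mtry = mtry)
  })
  structure(list(forests = forests, panel = colnames(ranks),
                 classes = levels(labels), seeds = seeds,
                 ntree = ntree, mtry = mtry),
            class = "forest_ensemble")
}

#' @export
print.forest_ensemble <- function(x, ...) {
  oob <- vapply(x$forests, function(f)
    f$err.rate[f$ntree, "OOB"], numeric(1))
  cat(sprintf(paste0("forest ensemble: %d forests (ntree = %d, mtry = %d),",
                     " %d classes, mean OOB error %.1f%%\n"),
              length(x$forests), x$ntree, x$mtry, length(x$classes),
              100 * mean(oob)))
  invisible(x)
}

# per-forest label -> consensus label; strictly more than
# forest_majority * n_forests forests must agree on the same class
.consensus_vote <- function(label_mat, forest_majority) {
  n_forests <- ncol(label_mat)
  apply(label_mat, 1L, function(v) {
    v <- v[v != "none"]
    if (!length(v)) return("none")
    tab <- sort(table(v), decreasing = TRUE)
    if (tab[1] > forest_majority * n_forests) names(tab)[1] else "none"
  })
}

#' Consensus prediction from a forest ensemble
#'
#' Per forest, a cell's prediction is its top class when that class's
#' tree-vote fraction strictly exceeds `vote_threshold` (published rule:
#' > 45% of the votes), otherwise "none". The final label is the class
#' predicted by strictly more than `forest_majority` of the forests
#' (> 5 of 10), otherwise "none".
#'
#' @param ens A [train_forest_ensemble()] object.
#' @param query_ranks Cells x genes rank matrix over the training panel.
#' @param vote_threshold Per-forest tree-vote fraction, default 0.45.
#' @param forest_majority Fraction of forests that must agree (strict),
#'   default 0.5.
#' @return Object of class `consensus_prediction`: `label` (named, may be
#'   "none"), `per_forest` (cells x forests label matrix) and
#'   `vote_fraction` (top-class vote fraction per cell per forest).
#' @export
consensus_predict <- function(ens, query_ranks, vote_threshold = 0.45,
                              forest_majority = 0.5) {
  missing <- setdiff(ens$panel, colnames(query_ranks))
  if (length(missing))
    stop("query lacks training panel gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  q <- query_ranks[, ens$panel, drop = FALSE]
  n_cells <- nrow(q)
  n_forests <- length(ens$forests)
  per_forest <- matrix("none", n_cells, n_forests,
                       dimnames = list(rownames(q), NULL))
  vote_frac <- matrix(NA_real_, n_cells, n_forests,
                      dimnames = list(rownames(q), NULL))
  for (i in seq_len(n_forests)) {
    votes <- stats::predict(ens$forests[[i]], q, type = "vote")
    top <- max.col(votes, ties.method = "first")
    frac <- votes[cbind(seq_len(n_cells), top)]
    per_forest[, i] <- ifelse(frac > vote_threshold,
                              colnames(votes)[top], "none")
    vote_frac[, i] <- frac
  }
  label <- .consensus_vote(per_forest, forest_majority)
  structure(list(label = stats::setNames(label, rownames(q)),
                 per_forest = per_forest, vote_fraction = vote_frac,
                 vote_threshold = vote_threshold,
                 forest_majority = forest_majority),
            class = "consensus_prediction")
}

#' @export
print.consensus_prediction <- function(x, ...) {
  cat(sprintf("consensus prediction over %d cells: %.1f%% \"none\"\n",
              length(x$label), 100 * mean(x$label == "none")))
  print(table(x$label))
  invisible(x)
}

#' Mean expression profiles per cluster
#'
#' @param expr Genes x cells matrix.
#' @param labels Cluster/lineage label per cell (matrix column order).
#' @return Clusters x genes matrix of mean expression.
#' @export
cluster_profiles <- function(expr, labels) {
  stopifnot(length(labels) == ncol(expr))
  keep <- !is.na(labels)
  t(vapply(split(seq_len(ncol(expr))[keep], labels[keep]),
           function(idx) rowMeans(expr[, idx, drop = FALSE]),
           numeric(nrow(expr))))
}

#' Spearman similarity between cluster profiles of two datasets
#'
#' All-pairs Spearman correlations between cluster-average expression
#' profiles over a shared gene set. A constant profile has no rank
#' ordering; its correlations are reported as NA.
#'
#' @param profiles_a,profiles_b Clusters x genes mean-expression matrices.
#' @param genes Shared gene set (>= 10 genes).
#' @return Matrix of Spearman correlations, rows = clusters of A,
#'   columns = clusters of B.
#' @export
cross_dataset_similarity <- function(profiles_a, profiles_b, genes) {
  genes <- intersect(intersect(genes, colnames(profiles_a)),
                     colnames(profiles_b))
  if (length(genes) < 10L)
    stop("shared gene set has fewer than 10 genes", call. = FALSE)
  a <- profiles_a[, genes, drop = FALSE]
  b <- profiles_b[, genes, drop = FALSE]
  suppressWarnings(stats::cor(t(a), t(b), method = "spearman"))
}
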