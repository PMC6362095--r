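# Cell-population definition: multiple t-SNE embeddings, a fused 5-NN
# consensus graph, infomap communities, marker-rule lineage annotation,
# age-group assignment and genotype composition.

#' Embed cells in 2D with t-SNE on a gene subset
#'
#' Barnes-Hut t-SNE (via \pkg{Rtsne}) on log2(RPKM + 1) over the given
#' genes. Deterministic given `seed`.
#'
#' @param expr Genes x cells matrix.
#' @param genes Gene subset to embed on.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; must be below (n_cells - 1) / 3.
#' @param ... Passed to [Rtsne::Rtsne()].
#' @return Cells x 2 coordinate matrix with cell rownames.
#' @export
embed_cells <- function(expr, genes, seed = 1L, perplexity = 30, ...) {
  .assert_genes(expr, genes)
  n <- ncol(expr)
  if (n < 3L) stop("need at least 3 cells", call. = FALSE)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity must be below (n_cells - 1) / 3 = ",
         format((n - 1) / 3, digits = 4), call. = FALSE)
  x <- t(.log2p1(expr[genes, , drop = FALSE]))
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2L, perplexity = perplexity,
                      check_duplicates = FALSE, pca = TRUE,
                      partial_pca = FALSE, ...)
  coords <- fit$Y
  rownames(coords) <- colnames(expr)
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}

# k nearest Euclidean neighbours per row of a coordinate matrix
.knn_pairs <- function(coords, k) {
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  n <- nrow(d)
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nn))
  unique(data.frame(a = pmin(i, j), b = pmax(i, j)))
}

#' Fuse nearest-neighbour lists from several embeddings into one graph
#'
#' For each embedding, each cell contributes edges to its `k` nearest
#' Euclidean neighbours; an unordered pair counts at most once per
#' embedding, and the edge weight is the number of embeddings in which the
#' pair appears in either endpoint's neighbour list. Weights therefore lie
#' in 1..length(embeddings) and every node has degree >= k.
#'
#' @param embeddings List of cells x 2 coordinate matrices over the same
#'   cell set (same rownames).
#' @param k Neighbours per cell per embedding, default 5.
#' @return An undirected weighted [igraph][igraph::igraph-package] graph
#'   with vertex names = cell ids and integer edge attribute `weight`.
#' @export
build_consensus_graph <- function(embeddings, k = 5L) {
  stopifnot(length(embeddings) >= 1L)
  cells <- rownames(embeddings[[1]])
  for (e in embeddings) {
    if (!identical(sort(rownames(e)), sort(cells)))
      stop("embeddings cover different cell sets", call. = FALSE)
  }
  if (length(cells) < k + 1L)
    stop("need at least k + 1 cells", call. = FALSE)
  counts <- new.env(parent = emptyenv())
  tallies <- NULL
  for (e in embeddings) {
    e <- e[cells, , drop = FALSE]
    pr <- .knn_pairs(e, k)
    key <- paste(pr$a, pr$b, sep = "_")
    tallies <- c(tallies, key)
  }
  tab <- table(tallies)
  ab <- do.call(rbind, strsplit(names(tab), "_"))
  edges <- data.frame(from = cells[as.integer(ab[, 1])],
                      to = cells[as.integer(ab[, 2])],
                      weight = as.integer(tab))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = cells))
}

#' Infomap community detection on the consensus graph
#'
#' Weighted map-equation community detection
#' ([igraph::cluster_infomap()]) with `trials` attempts; deterministic
#' given `seed`.
#'
#' @param graph Graph from [build_consensus_graph()].
#' @param seed Integer seed.
#' @param trials Infomap trials, default 10.
#' @return Named integer vector: community id per cell, with attribute
#'   `codelength`.
#' @export
detect_communities <- function(graph, seed = 1L, trials = 10L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph", call. = FALSE)
  set.seed(seed)
  cm <- igraph::cluster_infomap(graph,
                                e.weights = igraph::E(graph)$weight,
                                nb.trials = trials)
  out <- stats::setNames(igraph::membership(cm),
                         igraph::V(graph)$name)
  attr(out, "codelength") <- cm$codelength
  out
}

#' Annotate communities with Pitx3 lineage labels by the marker rule
#'
#' A marker is "majority high" in a community when the fraction of member
#' cells with expression strictly above `threshold` (default 150 RPKM)
#' exceeds 0.5. Branch identity takes precedence over within-branch
#' markers: Gad2 assigns the G branch, then Nxph4 the N branch (each split
#' into Th-low/Th-high by the same majority rule on Th), then the Dat
#' branch (Slc6a3/Vip/Aldh1a1) where Vip-high gives VT-Dathigh, else
#' Aldh1a1-high gives AT-Dathigh, else T-Dathigh. Communities matching no
#' marker are labelled ND (non-defined).
#'
#' @param expr Genes x cells matrix.
#' @param clusters Named community id per cell.
#' @param panel Marker genes; defaults to [marker_panel()]. Must contain
#'   Slc6a3, Nxph4, Aldh1a1, Vip, Gad2 and Th.
#' @param threshold High-expression threshold (default 150 RPKM).
#' @return Object of class `lineage_annotation`: `communities`
#'   (data.frame: community, lineage, per-marker high fractions, n) and
#'   `cell_lineage` (named label per cell).
#' @export
annotate_lineages <- function(expr, clusters, panel = marker_panel(),
                              threshold = 150) {
  missing <- setdiff(panel, rownames(expr))
  if (length(missing))
    stop("marker gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cells <- names(clusters)
  .assert_cells(expr, cells)
  coms <- sort(unique(clusters))
  frac <- matrix(NA_real_, length(coms), length(panel),
                 dimnames = list(as.character(coms), panel))
  for (i in seq_along(coms)) {
    members <- cells[clusters == coms[i]]
    frac[i, ] <- rowMeans(expr[panel, members, drop = FALSE] > threshold)
  }
  hi <- frac > 0.5
  lineage <- apply(hi, 1L, function(h) {
    th <- h[["Th"]]
    if (h[["Gad2"]]) {
      if (th) "GT-Datlow" else "G-Datlow"
    } else if (h[["Nxph4"]]) {
      if (th) "NT-Datlow" else "N-Datlow"
    } else if (h[["Slc6a3"]] || h[["Vip"]] || h[["Aldh1a1"]]) {
      if (h[["Vip"]]) "VT-Dathigh"
      else if (h[["Aldh1a1"]]) "AT-Dathigh"
      else "T-Dathigh"
    } else "ND"
  })
  communities <- data.frame(community = coms, lineage = unname(lineage),
                            n = as.integer(table(clusters)[as.character(coms)]),
                            frac, row.names = NULL, check.names = FALSE)
  cell_lineage <- stats::setNames(
    unname(lineage[as.character(clusters)]), cells)
  structure(list(communities = communities, cell_lineage = cell_lineage,
                 threshold = threshold), class = "lineage_annotation")
}

#' @export
print.lineage_annotation <- function(x, ...) {
  tab <- table(x$communities$lineage)
  cat(sprintf("lineage annotation over %d communities (RPKM > %g rule):\n",
              nrow(x$communities), x$threshold))
  print(tab)
  invisible(x)
}

#' Assign each community a general age group by majority vote
#'
#' Stages map to groups as Embryonic (E13.5, E15.5), Perinatal (E18.5,
#' P1, P7) and Adult (P90); ties go to the earlier group.
#'
#' @param clusters Named community id per cell.
#' @param stage Stage label per cell (same order/names as `clusters`).
#' @param groups Named list mapping group label (in temporal order) to its
#'   stages.
#' @return Named character vector: age group per community.
#' @export
assign_age_groups <- function(clusters, stage,
                              groups = list(
                                Embryonic = c("E13.5", "E15.5"),
                                Perinatal = c("E18.5", "P1", "P7"),
                                Adult = "P90")) {
  map <- stats::setNames(rep(names(groups), lengths(groups)),
                         unlist(groups))
  bad <- setdiff(unique(stage), names(map))
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  grp <- factor(map[stage], levels = names(groups))
  vapply(split(grp, clusters), function(g) {
    counts <- table(g)
    names(counts)[which.max(counts)]  # first max = earliest group
  }, character(1))
}

#' Genotype composition per lineage
#'
#' Contingency of lineage x genotype as fractions within each lineage
#' (rows sum to 1).
#'
#' @param cell_lineage Named lineage label per cell (e.g. from
#'   [annotate_lineages()]).
#' @param genotype Genotype label per cell, same order as `cell_lineage`.
#' @return Matrix of per-lineage genotype fractions.
#' @export
genotype_composition <- function(cell_lineage, genotype) {
  stopifnot(length(genotype) == length(cell_lineage))
  tab <- table(lineage = cell_lineage, genotype = genotype)
  prop <- prop.table(tab, margin = 1L)
  unclass(prop)
}

#' Lineage-specific genes by one-vs-rest rank tests
#'
#' For each lineage with at least `min_cells` cells, a one-vs-rest
#' Wilcoxon statistic per gene with a permutation null and BH q-values;
#' genes with q < `q_threshold` and higher expression in the lineage are
#' reported as its markers.
#'
#' @param expr Genes x cells matrix (endogenous genes).
#' @param cell_lineage Named lineage per cell.
#' @param q_threshold Default 0.01.
#' @param n_perm,seed Permutation settings.
#' @param min_cells Minimum lineage size, default 3 (smaller lineages are
#'   skipped with a warning).
#' @return Named list: per lineage, a data.frame of significant genes.
#' @export
lineage_markers <- function(expr, cell_lineage, q_threshold = 0.01,
                            n_perm = 1000L, seed = 1L, min_cells = 3L) {
  cells <- names(cell_lineage)
  .assert_cells(expr, cells)
  expr <- expr[, cells, drop = FALSE]
  lins <- setdiff(unique(cell_lineage), c(NA, "ND"))
  if (length(lins) < 2L)
    stop("need at least two lineages", call. = FALSE)
  out <- list()
  for (i in seq_along(lins)) {
    lin <- lins[i]
    in_lin <- cell_lineage == lin
    if (sum(in_lin) < min_cells) {
      warning("lineage ", lin, " has fewer than ", min_cells,
              " cells; skipped", call. = FALSE)
      next
    }
    res <- .rank_sum_perm(expr, in_lin, n_perm = n_perm,
                          seed = .child_seed(seed, i))
    res$q <- stats::p.adjust(res$p, method = "BH")
    sig <- res[res$q < q_threshold & res$direction == "up", ]
    out[[lin]] <- sig[order(sig$q, -abs(sig$statistic)), ]
  }
  out
}
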