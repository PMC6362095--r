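test_that("t-SNE embedding is seeded, shaped and guarded", {
  sim <- fix_sim()
  genes <- rownames(sim$expr)[!sim$spikein][1:50]
  e1 <- embed_cells(sim$expr, genes, seed = 3, perplexity = 20)
  e2 <- embed_cells(sim$expr, genes, seed = 3, perplexity = 20)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(ncol(sim$expr), 2L))
  expect_identical(rownames(e1), colnames(sim$expr))
  expect_error(embed_cells(sim$expr[, 1:30], genes, perplexity = 10),
               "perplexity")
})

test_that("well-separated planted clusters separate in the embedding", {
  set.seed(4)
  expr <- cbind(matrix(stats::rlnorm(50 * 40, 2, 0.2), 50, 40),
                matrix(stats::rlnorm(50 * 40, 5, 0.2), 50, 40))
  rownames(expr) <- sprintf("g%02d", 1:50)
  colnames(expr) <- sprintf("c%02d", 1:80)
  emb <- embed_cells(expr, rownames(expr), seed = 1, perplexity = 15)
  sil <- cluster::silhouette(rep(1:2, each = 40), stats::dist(emb))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("consensus graph matches the brute-force neighbour oracle", {
  set.seed(5)
  coords <- list(a = matrix(stats::rnorm(100), 50, 2),
                 b = matrix(stats::rnorm(100), 50, 2))
  for (i in 1:2) rownames(coords[[i]]) <- sprintf("c%02d", 1:50)
  g <- build_consensus_graph(coords, k = 5)
  # oracle: accumulate unordered pairs per embedding from all-pairs scans
  expected <- new.env()
  for (emb in coords) {
    nn <- knn_brute_force(emb, 5)
    seen <- character(0)
    for (i in seq_len(50)) for (j in nn[[i]]) {
      key <- paste(min(i, j), max(i, j))
      if (!key %in% seen) seen <- c(seen, key)
    }
    for (key in seen)
      assign(key, (mget(key, expected, ifnotfound = 0)[[1]]) + 1, expected)
  }
  edges <- igraph::as_data_frame(g)
  got <- stats::setNames(edges$weight,
                         paste(pmin(as.integer(sub("c", "", edges$from)),
                                    as.integer(sub("c", "", edges$to))),
                               pmax(as.integer(sub("c", "", edges$from)),
                                    as.integer(sub("c", "", edges$to)))))
  keys <- ls(expected)
  expect_setequal(names(got), keys)
  expect_equal(unname(got[keys]),
               unname(vapply(keys, get, numeric(1), envir = expected)))
})

test_that("graph weights respect the construction bounds", {
  set.seed(6)
  emb <- matrix(stats::rnorm(120), 60, 2,
                dimnames = list(sprintf("c%02d", 1:60), NULL))
  embs <- list(emb, emb, emb, emb)
  g <- build_consensus_graph(embs, k = 5)
  expect_true(all(igraph::E(g)$weight == 4))  # identical embeddings
  expect_true(all(igraph::degree(g) >= 5))
  jit <- lapply(1:4, function(i) emb + stats::rnorm(120, 0, 0.3))
  for (i in 1:4) rownames(jit[[i]]) <- rownames(emb)
  g2 <- build_consensus_graph(jit, k = 5)
  expect_true(all(igraph::E(g2)$weight >= 1 & igraph::E(g2)$weight <= 4))
  bad <- jit
  rownames(bad[[2]]) <- rev(sprintf("x%02d", 1:60))
  expect_error(build_consensus_graph(bad), "different cell sets")
})

test_that("infomap splits planted modules and merges uniform graphs", {
  # two 20-cliques joined by a single weak edge
  edges <- rbind(t(utils::combn(1:20, 2)), t(utils::combn(21:40, 2)))
  df <- data.frame(from = sprintf("c%02d", edges[, 1]),
                   to = sprintf("c%02d", edges[, 2]), weight = 4)
  df <- rbind(df, data.frame(from = "c01", to = "c40", weight = 1))
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  mem <- detect_communities(g, seed = 1)
  expect_identical(length(unique(mem)), 2L)
  expect_identical(length(unique(mem[sprintf("c%02d", 1:20)])), 1L)
  # complete uniform graph is one community
  full <- data.frame(from = sprintf("c%02d", utils::combn(1:15, 2)[1, ]),
                     to = sprintf("c%02d", utils::combn(1:15, 2)[2, ]),
                     weight = 2)
  g1 <- igraph::graph_from_data_frame(full, directed = FALSE)
  expect_identical(length(unique(detect_communities(g1, seed = 1))), 1L)
  expect_error(detect_communities(igraph::make_empty_graph(0)), "empty")
})

test_that("marker-rule annotation follows the printed precedence", {
  cells <- sprintf("c%02d", 1:10)
  base <- matrix(1, 6, 10, dimnames = list(marker_panel(), cells))
  mem <- stats::setNames(rep(1L, 10), cells)
  # 80% Gad2-high, only 10% Th-high -> G-Datlow
  m <- base; m["Gad2", 1:8] <- 400; m["Th", 1] <- 400
  expect_identical(annotate_lineages(m, mem)$communities$lineage, "G-Datlow")
  # Slc6a3 + Aldh1a1 majority-high -> AT-Dathigh
  m <- base; m["Slc6a3", ] <- 400; m["Aldh1a1", 1:6] <- 400; m["Th", ] <- 400
  expect_identical(annotate_lineages(m, mem)$communities$lineage,
                   "AT-Dathigh")
  # Vip outranks Aldh1a1 within the Dat branch
  m["Vip", 1:6] <- 400
  expect_identical(annotate_lineages(m, mem)$communities$lineage,
                   "VT-Dathigh")
  # Gad2 outranks the Dat branch
  m["Gad2", 1:6] <- 400
  expect_identical(annotate_lineages(m, mem)$communities$lineage,
                   "GT-Datlow")
  # no marker majority-high -> ND
  expect_identical(annotate_lineages(base, mem)$communities$lineage, "ND")
  # exactly half high is not a majority
  m <- base; m["Nxph4", 1:5] <- 400
  expect_identical(annotate_lineages(m, mem)$communities$lineage, "ND")
  expect_error(annotate_lineages(base[-1, ], mem), "Slc6a3")
})

test_that("annotation is invariant to cell order and threshold-preserving scaling", {
  sim <- fix_sim()
  mem <- stats::setNames(as.integer(factor(sim$truth$lineage)),
                         sim$cells$cell)
  ann1 <- annotate_lineages(sim$expr, mem)
  perm <- sample(length(mem))
  ann2 <- annotate_lineages(sim$expr[, perm], mem[perm])
  expect_identical(ann1$communities$lineage, ann2$communities$lineage)
  # monotone transform preserving the >150 comparisons: x -> x (no-op) and
  # shifting values away from the threshold on both sides
  shifted <- sim$expr
  shifted[shifted > 150] <- shifted[shifted > 150] * 2
  ann3 <- annotate_lineages(shifted, mem)
  expect_identical(ann1$communities$lineage, ann3$communities$lineage)
  # planted lineages annotate to themselves on ground-truth communities
  lin_of_com <- ann1$communities$lineage[
    match(sort(unique(mem)), ann1$communities$community)]
  expect_setequal(lin_of_com, mda_lineages())
})

test_that("age groups are assigned by majority with the earlier-group tie-break", {
  mem <- stats::setNames(c(rep(1, 10), rep(2, 4), rep(3, 4)), NULL)
  stage <- c(rep("E13.5", 6), rep("P90", 4), rep("P7", 4),
             rep("E13.5", 2), rep("P90", 2))
  got <- assign_age_groups(mem, stage)
  expect_identical(unname(got["1"]), "Embryonic")  # 6 E vs 4 A
  expect_identical(unname(got["2"]), "Perinatal")  # all P7
  expect_identical(unname(got["3"]), "Embryonic")  # 2 vs 2 tie
  expect_error(assign_age_groups(mem, rep("E99", 18)), "unknown stage")
})

test_that("knockout depletion shows up in the genotype composition", {
  cfg <- sim_config(seed = 21L, ko_fraction = 0.25)
  sim <- simulate_scrna(cfg)
  comp <- genotype_composition(sim$truth$lineage[sim$cells$cell],
                               sim$cells$genotype)
  expect_equal(unname(rowSums(comp)), rep(1, nrow(comp)))
  overall_ko <- mean(sim$cells$genotype == "ko")
  expect_lt(comp["AT-Dathigh", "ko"], overall_ko)
  expect_lt(comp["T-Dathigh", "ko"], overall_ko)
  # uniform genotypes (no depletion) sit near the overall prevalence
  cfg0 <- sim_config(seed = 22L, ko_fraction = 0.25,
                     ko_depletion = c("AT-Dathigh" = 1))
  sim0 <- simulate_scrna(cfg0)
  comp0 <- genotype_composition(sim0$truth$lineage[sim0$cells$cell],
                                sim0$cells$genotype)
  expect_true(all(abs(comp0[, "ko"] - mean(sim0$cells$genotype == "ko"))
                  < 0.15))
})

test_that("zero-genotype lineages report fraction zero", {
  comp <- genotype_composition(c("A", "A", "B", "B"),
                               c("het", "het", "het", "ko"))
  expect_identical(unname(comp["A", "ko"]), 0)
})

test_that("one-vs-rest rank tests recover each lineage's planted markers", {
  cfg <- sim_config(n_cells_per_stage = 35L, seed = 31L)
  sim <- simulate_scrna(cfg)
  keep <- !is.na(sim$truth$lineage)
  lm <- lineage_markers(sim$expr[!sim$spikein, sim$cells$cell[keep]],
                        sim$truth$lineage[sim$cells$cell[keep]],
                        n_perm = 400L, seed = 2L)
  hits <- 0L; total <- 0L
  for (lin in mda_lineages()) {
    own <- setdiff(lineage_marker_map()[[lin]], "Th")  # Th spans lineages
    total <- total + length(own)
    hits <- hits + sum(own %in% lm[[lin]]$gene)
  }
  expect_gte(hits / total, 0.9)
  # genes uniform across lineages stay unreported
  uniform <- sprintf("g%04d", 290:310)  # fillers beyond the signatures
  reported <- unlist(lapply(lm, `[[`, "gene"))
  expect_lte(length(intersect(uniform, reported)), 2L)
})
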