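# Shared fixtures (built once per session) and independent oracles.

# default synthetic study reused across files
fix_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_scrna(sim_config(seed = 42L))
    cache
  }
})

fix_variable_genes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- fix_sim()
      cache <<- variable_gene_sets(sim$expr, sim$spikein, sim$cells$stage)
    }
    cache
  }
})

# draw a random QC metrics table straddling the thresholds
random_qc_table <- function(n) {
  data.frame(
    cell = sprintf("c%04d", seq_len(n)),
    unique_pct = stats::runif(n, 0, 100),
    mismatch_pct = stats::runif(n, 0, 100),
    exon_pct = stats::runif(n, 0, 100),
    three_prime_pct = stats::runif(n, 0, 20),
    genes_detected_pct = stats::runif(n, 0, 40),
    reads = round(stats::runif(n, 0, 3e5)),
    stringsAsFactors = FALSE)
}

# per-cell brute-force re-check of the six printed QC comparisons,
# written independently of the vectorized implementation
qc_brute_force <- function(qc, thresholds, stage) {
  groups <- ifelse(stage == "P90", "adult", "embryonic_perinatal")
  out <- logical(nrow(qc))
  for (i in seq_len(nrow(qc))) {
    th <- thresholds[groups[i], ]
    checks <- c(qc$unique_pct[i] > th$min_unique,
                qc$mismatch_pct[i] < th$max_mismatch,
                qc$exon_pct[i] > th$min_exon,
                qc$three_prime_pct[i] < th$max_three_prime,
                qc$genes_detected_pct[i] >= th$min_genes_detected,
                qc$reads[i] > th$min_reads)
    out[i] <- all(checks)
  }
  names(out) <- qc$cell
  out
}

# brute-force k nearest neighbours by all-pairs distances
knn_brute_force <- function(coords, k) {
  n <- nrow(coords)
  lapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    order(d)[seq_len(k)]
  })
}

# expression matrix following the technical model only: gamma noise with
# CV2(m) = a1/m + alpha0, optional extra log-normal biological layer for
# a subset of rows
technical_matrix <- function(n_genes, n_cells, a1 = 3, alpha0 = 0.05,
                             means = NULL, overdispersed = integer(0),
                             extra_sd = 0.8) {
  if (is.null(means)) means <- 2^stats::runif(n_genes, 1, 10)
  m <- matrix(0, n_genes, n_cells,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%04d", seq_len(n_cells))))
  for (g in seq_len(n_genes)) {
    cv2 <- a1 / means[g] + alpha0
    m[g, ] <- means[g] * stats::rgamma(n_cells, 1 / cv2, rate = 1 / cv2)
  }
  if (length(overdispersed))
    m[overdispersed, ] <- m[overdispersed, , drop = FALSE] *
      matrix(stats::rlnorm(length(overdispersed) * n_cells,
                           -extra_sd^2 / 2, extra_sd),
             length(overdispersed), n_cells)
  m
}

# end-to-end lineage recovery for one simulation seed: four embeddings,
# fused graph, infomap, marker annotation; returns fraction of non-ND
# cells whose annotated lineage equals the planted one
lineage_recovery_run <- function(seed) {
  sim <- simulate_scrna(sim_config(seed = seed))
  vg <- variable_gene_sets(sim$expr, sim$spikein, sim$cells$stage)
  sets <- lapply(vg, `[[`, "genes")
  embs <- lapply(seq_along(sets), function(i)
    embed_cells(sim$expr[!sim$spikein, ], sets[[i]], seed = seed * 10 + i))
  g <- build_consensus_graph(embs, k = 5)
  com <- detect_communities(g, seed = seed)
  ann <- annotate_lineages(sim$expr, com)
  truth <- sim$truth$lineage[names(ann$cell_lineage)]
  non_nd <- ann$cell_lineage != "ND" & !is.na(truth)
  c(correct = mean(ann$cell_lineage[non_nd] == truth[non_nd]),
    nd = mean(ann$cell_lineage == "ND"),
    n_communities = length(unique(com)))
}

# paired scRNA reference + in situ query from the same planted lineages;
# returns consensus predictions alongside the planted truth per cell
transfer_run <- function(seed, n_cells = 300L, noise_sd = 8,
                         spots_per_cell = 40L, permute_labels = FALSE,
                         vote_threshold = 0.45) {
  sim <- simulate_scrna(sim_config(seed = seed))
  genes <- c(marker_panel(), "Pitx3", "eGFP",
             sprintf("g%04d", c(1:20, 151:171)))
  cb <- generate_codebook(49, genes = genes, seed = seed)
  keep <- !is.na(sim$truth$lineage)
  labels <- sim$truth$lineage[keep]
  if (permute_labels) {
    set.seed(seed + 1L)
    labels <- sample(labels)
  }
  prof <- cluster_profiles(sim$expr[, keep], sim$truth$lineage[keep])
  freq <- gene_frequencies_from_profiles(prof, names(cb))
  ins <- generate_insitu(
    cb, insitu_layout(n_cells = n_cells, spots_per_cell = spots_per_cell,
                      gene_freq = freq),
    noise_sd = noise_sd, seed = seed + 2L)
  dec <- decode_spots(call_bases(ins$spots), cb)
  asn <- assign_spots_to_cells(dec, ins$nuclei, max_radius = 15)
  filt <- filter_insitu_cells(asn$counts)
  shared <- intersect(colnames(filt), rownames(sim$expr))
  ref_ranks <- rank_transform(t(sim$expr[, keep]), shared)
  ens <- train_forest_ensemble(ref_ranks, labels, ntree = 500L,
                               base_seed = seed)
  pred <- consensus_predict(ens, rank_transform(filt, shared),
                            vote_threshold = vote_threshold)
  truth_cell <- stats::setNames(ins$nuclei$lineage,
                                as.character(ins$nuclei$cell))
  list(pred = pred, truth = truth_cell[names(pred$label)], ens = ens,
       query = rank_transform(filt, shared))
}
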