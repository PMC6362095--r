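# End-to-end orchestration of both arms from a single configuration,
# with fixed seeds and a checksummed output manifest.

#' Default pipeline configuration
#'
#' A nested list controlling both arms. Values standing in for parameters
#' the source protocol leaves unstated (t-SNE perplexity, infomap trials,
#' quality-score threshold, variable-gene FDR) are marked
#' `assumption: true` in the YAML written by [write_pipeline_config()].
#'
#' @param outdir Output directory.
#' @param seed Master seed; every stage derives its own child seed.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("mdaseq_"), seed = 1L) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    scrna = list(
      qc = list(thresholds = "default"),
      variable_genes = list(fdr = 0.1, assumption = TRUE),
      tsne = list(perplexity = 30, assumption = TRUE),
      graph = list(k = 5L),
      infomap = list(trials = 10L, assumption = TRUE),
      annotation = list(threshold = 150),
      de = list(q_threshold = 0.01, n_perm = 500L),
      curves = list(df = 3L, n_bins = 20L, k = 3L)),
    insitu = list(
      qs_threshold = 0.5, assumption = TRUE,
      max_radius = NULL,  # defaults to layout spacing / 2
      vote_threshold = 0.45, forest_majority = 0.5,
      n_forests = 10L, ntree = 1000L, mtry = 15L)),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file to write.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

# run one pipeline stage, prefixing any error with the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.manifest <- function(outdir, files, seed) {
  sums <- tools::md5sum(files)
  manifest <- list(seed = seed,
                   files = lapply(seq_along(files), function(i)
                     list(path = basename(files[i]),
                          md5 = unname(sums[i]))))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  manifest$path <- path
  manifest
}

#' Run the scRNA-seq arm end to end
#'
#' Simulates (or accepts) a study, then composes QC filtering, variable
#' genes per stage subset, pseudotime, age-group differential expression,
#' temporal curves with cv2 filtering and k-means classes, four t-SNE
#' embeddings, the fused 5-NN graph, infomap communities, marker-rule
#' lineage annotation, age groups and genotype composition. All outputs
#' are written as TSV/CSV to `config$outdir` together with a checksummed
#' manifest, so a rerun with the same config is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param sim Optional [simulate_scrna()] result; simulated from
#'   `config$seed` when absent.
#' @return The manifest (invisibly), with the main result objects in
#'   attribute `results`.
#' @export
run_scrna_pipeline <- function(config = pipeline_config(), sim = NULL) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  if (is.null(sim))
    sim <- .stage("synthetic_data",
                  simulate_scrna(sim_config(seed = seed)))
  if (is.null(sim$qc)) .stage("qc_select", stop("missing QC table"))
  expr <- sim$expr; cells <- sim$cells

  pass <- .stage("qc_select",
                 apply_qc_filters(sim$qc, qc_thresholds(), cells$stage))
  keep <- names(pass)[pass]
  expr <- expr[, keep, drop = FALSE]
  cells <- cells[cells$cell %in% keep, , drop = FALSE]

  vg <- .stage("qc_select", variable_gene_sets(
    expr, sim$spikein, cells$stage, fdr = config$scrna$variable_genes$fdr))
  gene_sets <- lapply(vg, `[[`, "genes")

  embeddings <- .stage("ensemble_cluster", lapply(
    seq_along(gene_sets), function(i)
      embed_cells(expr[!sim$spikein, , drop = FALSE], gene_sets[[i]],
                  seed = .child_seed(seed, 10L + i),
                  perplexity = config$scrna$tsne$perplexity)))
  graph <- .stage("ensemble_cluster",
                  build_consensus_graph(embeddings, k = config$scrna$graph$k))
  communities <- .stage("ensemble_cluster",
                        detect_communities(graph,
                                           seed = .child_seed(seed, 20L),
                                           trials = config$scrna$infomap$trials))
  annotation <- .stage("ensemble_cluster",
                       annotate_lineages(expr, communities,
                                         threshold = config$scrna$annotation$threshold))
  age_groups <- .stage("ensemble_cluster",
                       assign_age_groups(communities, cells$stage))
  composition <- .stage("ensemble_cluster",
                        genotype_composition(annotation$cell_lineage,
                                             cells$genotype))

  pt <- .stage("maturation",
               compute_pseudotime(expr, gene_sets$merged, cells$stage))
  group_map <- c("E13.5" = "Embryonic", "E15.5" = "Embryonic",
                 "E18.5" = "Perinatal", "P1" = "Perinatal",
                 "P7" = "Perinatal", "P90" = "Adult")
  de <- .stage("maturation", de_between_age_groups(
    expr[!sim$spikein, , drop = FALSE], group_map[cells$stage],
    q_threshold = config$scrna$de$q_threshold,
    n_perm = config$scrna$de$n_perm, seed = .child_seed(seed, 30L)))
  changing <- de$changing
  retained <- .stage("maturation",
                     if (length(changing) > 1L)
                       filter_curves_by_cv2(expr, changing,
                                            n_bins = config$scrna$curves$n_bins)
                     else changing)
  curves <- .stage("maturation",
                   fit_temporal_curves(expr, pt, retained,
                                       df = config$scrna$curves$df))
  clusters3 <- .stage("maturation", if (nrow(curves) >=
                                        config$scrna$curves$k)
    cluster_temporal_profiles(curves, k = config$scrna$curves$k,
                              seed = .child_seed(seed, 40L))
    else NULL)

  ## --- write artifacts ------------------------------------------------
  out <- config$outdir
  files <- c(
    .write_tsv(data.frame(cell = names(pass), pass = pass),
               file.path(out, "qc_pass.tsv")),
    .write_tsv(data.frame(
      set = rep(names(gene_sets), lengths(gene_sets)),
      gene = unlist(gene_sets, use.names = FALSE)),
      file.path(out, "variable_genes.tsv")),
    .write_tsv(data.frame(cell = names(pt$values), pseudotime = pt$values),
               file.path(out, "pseudotime.tsv")),
    .write_tsv(de$table, file.path(out, "de_age_groups.tsv")),
    .write_tsv(igraph::as_data_frame(graph),
               file.path(out, "graph_edges.tsv")),
    .write_tsv(data.frame(cell = names(communities),
                          community = as.integer(communities),
                          lineage = annotation$cell_lineage),
               file.path(out, "communities.tsv")),
    .write_tsv(annotation$communities, file.path(out, "lineages.tsv")),
    .write_tsv(data.frame(community = names(age_groups),
                          age_group = age_groups),
               file.path(out, "age_groups.tsv")),
    .write_tsv(as.data.frame.matrix(composition) |>
                 (\(d) cbind(lineage = rownames(d), d))(),
               file.path(out, "genotype_composition.tsv")))
  utils::write.csv(curves, file.path(out, "temporal_curves.csv"))
  files <- c(files, file.path(out, "temporal_curves.csv"))
  if (!is.null(clusters3)) {
    files <- c(files, .write_tsv(
      data.frame(gene = names(clusters3$cluster),
                 cluster = clusters3$cluster),
      file.path(out, "temporal_clusters.tsv")))
  }
  manifest <- .manifest(out, files, seed)
  attr(manifest, "results") <- list(
    pass = pass, variable_genes = vg, pseudotime = pt, de = de,
    curves = curves, temporal_clusters = clusters3, graph = graph,
    communities = communities, annotation = annotation,
    age_groups = age_groups, composition = composition, sim = sim)
  invisible(manifest)
}

#' Run the in situ arm end to end
#'
#' Composes base calling, codebook decoding, spot-to-cell assignment, the
#' four cell/gene filters, rank transformation of both modalities,
#' training of the forest ensemble on the annotated scRNA-seq reference,
#' consensus prediction and lineage proportions.
#'
#' @param config A [pipeline_config()].
#' @param reference List with `expr` (genes x cells) and `lineage` (named
#'   label per cell) — typically the annotated scRNA-seq arm.
#' @param insitu Optional [generate_insitu()] result; simulated when
#'   absent from a default 49-gene codebook.
#' @param codebook Codebook used for `insitu` (required when `insitu` is
#'   given).
#' @return The manifest (invisibly), with results in attribute `results`.
#' @export
run_insitu_pipeline <- function(config = pipeline_config(), reference,
                                insitu = NULL, codebook = NULL) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  cfg <- config$insitu
  if (is.null(insitu)) {
    genes <- unique(c(marker_panel(), "Pitx3", "eGFP",
                      rownames(reference$expr)))
    genes <- utils::head(genes, 49L)
    codebook <- .stage("synthetic_data",
                       generate_codebook(length(genes), genes = genes,
                                         seed = .child_seed(seed, 50L)))
    keep <- !is.na(reference$lineage) & reference$lineage != "ND"
    prof <- cluster_profiles(reference$expr[, keep, drop = FALSE],
                             reference$lineage[keep])
    freq <- gene_frequencies_from_profiles(prof, names(codebook))
    insitu <- .stage("synthetic_data",
                     generate_insitu(codebook,
                                     insitu_layout(n_cells = 200L,
                                                   gene_freq = freq),
                                     noise_sd = 5,
                                     seed = .child_seed(seed, 51L)))
  }
  if (is.null(codebook)) stop("codebook required with a spot table",
                              call. = FALSE)
  spacing <- if (nrow(insitu$nuclei) > 1L)
    min(stats::dist(insitu$nuclei[, c("x", "y")])) else 30
  max_radius <- cfg$max_radius %||% (spacing / 2)

  calls <- .stage("insitu_decode", call_bases(insitu$spots))
  decoded <- .stage("insitu_decode",
                    decode_spots(calls, codebook,
                                 qs_threshold = cfg$qs_threshold))
  assigned <- .stage("insitu_decode",
                     assign_spots_to_cells(decoded, insitu$nuclei,
                                           max_radius = max_radius))
  filtered <- .stage("insitu_decode", filter_insitu_cells(assigned$counts))

  shared <- intersect(colnames(filtered), rownames(reference$expr))
  ref_ranks <- .stage("label_transfer",
                      rank_transform(t(reference$expr), shared))
  ref_cells <- names(reference$lineage)[
    !is.na(reference$lineage) & reference$lineage != "ND"]
  ens <- .stage("label_transfer", train_forest_ensemble(
    ref_ranks[ref_cells, , drop = FALSE], reference$lineage[ref_cells],
    n_forests = cfg$n_forests, ntree = cfg$ntree, mtry = cfg$mtry,
    base_seed = .child_seed(seed, 60L)))
  query_ranks <- .stage("label_transfer", rank_transform(filtered, shared))
  pred <- .stage("label_transfer",
                 consensus_predict(ens, query_ranks,
                                   vote_threshold = cfg$vote_threshold,
                                   forest_majority = cfg$forest_majority))
  props <- .stage("insitu_decode",
                  quantify_lineage_proportions(pred$label))

  out <- config$outdir
  decode_rate <- mean(decoded$status == "ok")
  files <- c(
    .write_tsv(decoded[, c("spot", "barcode", "min_qs", "gene", "status")],
               file.path(out, "decoded_spots.tsv")),
    .write_tsv(data.frame(cell = rownames(filtered), filtered,
                          check.names = FALSE),
               file.path(out, "filtered_counts.tsv")),
    .write_tsv(data.frame(cell = names(pred$label), label = pred$label,
                          pred$per_forest, check.names = FALSE),
               file.path(out, "predictions.tsv")),
    .write_tsv(data.frame(lineage = names(props$lineage),
                          fraction = props$lineage),
               file.path(out, "lineage_proportions.tsv")))
  manifest <- .manifest(out, files, seed)
  manifest$decode_rate <- decode_rate
  attr(manifest, "results") <- list(
    decoded = decoded, counts = assigned$counts, filtered = filtered,
    ensemble = ens, prediction = pred, proportions = props,
    codebook = codebook, insitu = insitu)
  invisible(manifest)
}
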