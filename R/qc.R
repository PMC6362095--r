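# Library quality control and spike-in-calibrated variable-gene selection.

.qc_metrics <- c("unique_pct", "mismatch_pct", "exon_pct",
                 "three_prime_pct", "genes_detected_pct", "reads")

#' Stage-specific library QC thresholds
#'
#' The published cut-offs differ between embryonic/perinatal libraries
#' (E13.5-P7) and adult (P90) libraries. Bounds printed with ">"/"<" are
#' strict; the genes-detected bound ("at least") is inclusive.
#'
#' @param min_unique,max_mismatch,min_exon,max_three_prime,min_genes_detected,min_reads
#'   Numeric vectors of length 2 (`embryonic_perinatal`, `adult`), in
#'   percent except `min_reads`.
#' @return A data.frame with one row per stage group.
#' @export
qc_thresholds <- function(min_unique = c(17.1, 21),
                          max_mismatch = c(66, 80),
                          min_exon = c(62, 61),
                          max_three_prime = c(7.8, 8.8),
                          min_genes_detected = c(15, 3.4),
                          min_reads = c(1e5, 1e5)) {
  data.frame(min_unique = min_unique, max_mismatch = max_mismatch,
             min_exon = min_exon, max_three_prime = max_three_prime,
             min_genes_detected = min_genes_detected, min_reads = min_reads,
             row.names = c("embryonic_perinatal", "adult"))
}

#' Map developmental stages to QC threshold groups
#'
#' E13.5-P7 libraries are judged by the embryonic/perinatal thresholds,
#' P90 by the adult ones.
#' @param stage Character vector of stage labels.
#' @return Character vector of `"embryonic_perinatal"` / `"adult"`.
#' @export
qc_stage_group <- function(stage) {
  known <- c("E13.5" = "embryonic_perinatal", "E15.5" = "embryonic_perinatal",
             "E18.5" = "embryonic_perinatal", "P1" = "embryonic_perinatal",
             "P7" = "embryonic_perinatal", "P90" = "adult")
  bad <- setdiff(unique(stage), names(known))
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unname(known[stage])
}

#' Apply the six per-library QC comparisons
#'
#' A cell passes iff all six hold for its stage group: uniquely mapping
#' reads strictly above `min_unique`, mismatch fraction strictly below
#' `max_mismatch`, exon mapping strictly above `min_exon`, 3'-mapping
#' strictly below `max_three_prime`, genes detected at least
#' `min_genes_detected` (inclusive), and normalization reads strictly
#' above `min_reads`. Ties at strict bounds fail.
#'
#' @param qc Data.frame with columns `cell`, `unique_pct`, `mismatch_pct`,
#'   `exon_pct`, `three_prime_pct`, `genes_detected_pct`, `reads`.
#' @param thresholds A [qc_thresholds()] table.
#' @param stage Stage label per cell (recycled against `qc` rows).
#' @return Named logical pass mask.
#' @export
apply_qc_filters <- function(qc, thresholds = qc_thresholds(), stage) {
  miss_col <- setdiff(.qc_metrics, names(qc))
  if (length(miss_col))
    stop("QC table lacks metric(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  for (m in .qc_metrics) {
    if (anyNA(qc[[m]]))
      stop("missing metric ", m, " for cell ",
           qc$cell[which(is.na(qc[[m]]))[1]], call. = FALSE)
  }
  grp <- qc_stage_group(stage)
  th <- thresholds[grp, , drop = FALSE]
  pass <- qc$unique_pct > th$min_unique &
    qc$mismatch_pct < th$max_mismatch &
    qc$exon_pct > th$min_exon &
    qc$three_prime_pct < th$max_three_prime &
    qc$genes_detected_pct >= th$min_genes_detected &
    qc$reads > th$min_reads
  stats::setNames(pass, qc$cell)
}

#' Flag contaminant (oligodendrocyte-like) cells by cluster
#'
#' Cells of any community whose median reporter expression sits below the
#' detection floor while the median contaminant marker exceeds the
#' high-expression threshold are excluded — the rule used to drop
#' eGFP-negative, Olig1-high clusters from the embryonic/perinatal data.
#'
#' @param expr Genes x cells expression matrix (RPKM-like).
#' @param clusters Named community id per cell (e.g. from
#'   [detect_communities()]).
#' @param reporter_gene,contaminant_marker Gene ids (defaults `eGFP`,
#'   `Olig1`).
#' @param detection_floor Reporter median below this counts as absent
#'   (default 1 RPKM).
#' @param high_threshold Contaminant-marker median above this counts as
#'   high (default 150 RPKM, the annotation threshold).
#' @return Character vector of excluded cell ids (possibly empty).
#' @export
flag_contaminant_cells <- function(expr, clusters, reporter_gene = "eGFP",
                                   contaminant_marker = "Olig1",
                                   detection_floor = 1,
                                   high_threshold = 150) {
  .assert_genes(expr, c(reporter_gene, contaminant_marker))
  cells <- names(clusters)
  .assert_cells(expr, cells)
  out <- character(0)
  for (com in unique(clusters)) {
    members <- cells[clusters == com]
    med_rep <- stats::median(expr[reporter_gene, members])
    med_mark <- stats::median(expr[contaminant_marker, members])
    if (med_rep < detection_floor && med_mark > high_threshold)
      out <- c(out, members)
  }
  out
}

#' Select biologically variable genes against the spike-in noise fit
#'
#' Fits the technical noise model CV2(m) = a1/m + alpha0 to the spike-in
#' rows by a gamma GLM with identity link on 1/mean (via
#' [statmod::glmgam.fit()]), then flags endogenous genes whose observed
#' CV2 significantly exceeds the fitted technical expectation at their
#' mean: the one-sided chi-square test
#' (n-1) * CV2_obs / CV2_tech ~ chisq(n-1), Benjamini-Hochberg adjusted.
#' Spike-ins are never selected.
#'
#' @param expr Genes x cells matrix including spike-in rows.
#' @param spikein Logical per row marking spike-ins.
#' @param cells Optional cell subset (character ids or indices).
#' @param fdr Adjusted significance level, default 0.1.
#' @param min_mean Mean-expression floor for both the fit and the test.
#' @return List of class `variable_genes`: `genes`, `stats` (per-gene
#'   mean, cv2, tech expectation, p, q), `fit` = c(a1, alpha0), `fdr`,
#'   `n_cells`, `n_spikeins_used`.
#' @export
select_variable_genes <- function(expr, spikein, cells = NULL, fdr = 0.1,
                                  min_mean = 1) {
  stopifnot(length(spikein) == nrow(expr))
  if (!is.null(cells)) {
    if (is.character(cells)) .assert_cells(expr, cells)
    expr <- expr[, cells, drop = FALSE]
  }
  n <- ncol(expr)
  sp <- .row_stats(expr[spikein, , drop = FALSE])
  sp <- sp[is.finite(sp$cv2) & sp$mean > min_mean, , drop = FALSE]
  if (nrow(sp) < 10L)
    stop("fewer than 10 spike-ins above the mean floor; this cell subset ",
         "cannot be used for variable-gene selection", call. = FALSE)
  fit <- statmod::glmgam.fit(cbind(alpha0 = 1, a1 = 1 / sp$mean), sp$cv2)
  a1 <- unname(fit$coefficients["a1"])
  alpha0 <- unname(fit$coefficients["alpha0"])

  gs <- .row_stats(expr[!spikein, , drop = FALSE])
  gs <- gs[is.finite(gs$cv2) & gs$mean > min_mean, , drop = FALSE]
  cv2_tech <- a1 / gs$mean + alpha0
  stat <- (n - 1) * gs$cv2 / cv2_tech
  p <- stats::pchisq(stat, df = n - 1, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene = rownames(gs), mean = gs$mean, cv2 = gs$cv2,
                    cv2_tech = cv2_tech, p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p, res$gene), ]
  genes <- res$gene[res$q < fdr & res$cv2 > res$cv2_tech]
  structure(list(genes = genes, stats = res,
                 fit = c(a1 = a1, alpha0 = alpha0), fdr = fdr,
                 n_cells = n, n_spikeins_used = nrow(sp)),
            class = "variable_genes")
}

#' @export
print.variable_genes <- function(x, ...) {
  cat(sprintf(paste0("variable genes: %d selected of %d tested ",
                     "(FDR %.2g; fit a1 = %.3g, alpha0 = %.3g)\n"),
              length(x$genes), nrow(x$stats), x$fdr,
              x$fit["a1"], x$fit["alpha0"]))
  invisible(x)
}

#' Variable genes per stage subset plus a merged set
#'
#' Runs [select_variable_genes()] on each listed cell subset and on their
#' union, mirroring the published E18.5 / P1 / P90 / merged design (only
#' those stages carry spike-ins).
#'
#' @param expr,spikein As in [select_variable_genes()].
#' @param stage Stage label per column of `expr`.
#' @param subsets Named list mapping a set label to the stage labels it
#'   covers.
#' @param ... Passed to [select_variable_genes()].
#' @return Named list of `variable_genes` objects including `merged`.
#' @export
variable_gene_sets <- function(expr, spikein, stage,
                               subsets = list(E18.5 = "E18.5", P1 = "P1",
                                              P90 = "P90"), ...) {
  stopifnot(length(stage) == ncol(expr))
  out <- lapply(subsets, function(st)
    select_variable_genes(expr, spikein,
                          cells = colnames(expr)[stage %in% st], ...))
  all_st <- unique(unlist(subsets))
  out$merged <- select_variable_genes(
    expr, spikein, cells = colnames(expr)[stage %in% all_st], ...)
  out
}
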