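# Synthetic data with planted lineage, maturation and barcode structure.
#
# The generators emulate the statistical design of a Smart-seq2 study of
# Pitx3-eGFP midbrain dopamine neurons across six developmental stages
# (E13.5-P90), with seven marker-defined lineages in two Dat branches, ERCC
# spike-in technical noise, dropout, and a 4-round x 4-channel in situ
# sequencing read-out from a Hamming-distance-2 barcode codebook.

.mda_lineages <- c("N-Datlow", "NT-Datlow", "G-Datlow", "GT-Datlow",
                   "T-Dathigh", "AT-Dathigh", "VT-Dathigh")

.mda_marker_map <- list(
  "N-Datlow"   = "Nxph4",
  "NT-Datlow"  = c("Nxph4", "Th"),
  "G-Datlow"   = "Gad2",
  "GT-Datlow"  = c("Gad2", "Th"),
  "T-Dathigh"  = c("Slc6a3", "Th"),
  "AT-Dathigh" = c("Slc6a3", "Aldh1a1", "Th"),
  "VT-Dathigh" = c("Slc6a3", "Vip", "Th"))

.mda_marker_panel <- c("Slc6a3", "Nxph4", "Aldh1a1", "Vip", "Gad2", "Th")

#' Lineage labels and their defining marker genes
#'
#' The seven Pitx3 lineages are defined by majority high expression of a
#' small marker panel: *Nxph4* and *Gad2* define the Dat-low branch (split
#' into Th-low/Th-high sublineages), while *Slc6a3* (Dat), *Aldh1a1* and
#' *Vip* define the Dat-high branch.
#'
#' @return `mda_lineages()` returns the seven lineage labels;
#'   `lineage_marker_map()` a named list mapping each lineage to the marker
#'   genes high in that lineage; `marker_panel()` the six marker genes.
#' @export
mda_lineages <- function() .mda_lineages

#' @rdname mda_lineages
#' @export
lineage_marker_map <- function() .mda_marker_map

#' @rdname mda_lineages
#' @export
marker_panel <- function() .mda_marker_panel

#' Configuration for the single-cell RNA-seq simulator
#'
#' Defines the study conditions emulated by [simulate_scrna()]: six
#' developmental stages, seven planted lineages at given proportions,
#' marker genes expressed above the annotation threshold in their own
#' lineage, a designated set of temporal genes following a per-stage
#' maturation gradient, ERCC-like spike-ins following the technical noise
#' model CV2(m) = a1/m + alpha0, and Bernoulli dropout.
#'
#' Expression values are continuous RPKM-like draws: a log-normal
#' biological layer (geometric sd `bio_sd`) multiplied by a gamma technical
#' layer whose squared coefficient of variation follows the spike-in noise
#' model, so the mean-CV2 relation assumed by the variable-gene selector
#' holds by construction. Spike-in rows carry only the technical layer.
#'
#' @param stages Ordered developmental stage labels.
#' @param n_cells_per_stage Cells simulated per stage (recycled to the
#'   number of stages).
#' @param n_genes Number of endogenous genes, including the marker panel,
#'   `eGFP`, `Olig1` and the temporal genes.
#' @param n_spikeins Number of spike-in rows (default 92, the ERCC mix).
#' @param subgroup_proportions Named lineage proportions; must sum to 1.
#' @param marker_effect Mean RPKM of a lineage's marker genes in that
#'   lineage; the default 300 sits above the 150-RPKM annotation threshold.
#' @param marker_baseline Marker mean outside the expressing lineage.
#' @param baseline_mean Geometric-scale location of filler-gene means.
#' @param bio_sd Log-normal sd of the biological layer.
#' @param dispersion Technical noise parameters `c(a1 = , alpha0 = )`.
#' @param dropout_rate Per-value probability of zeroing an endogenous
#'   measurement.
#' @param n_temporal Number of temporal genes (split equally into early,
#'   intermediate and late classes).
#' @param maturation_gradient Fold change per stage step applied to
#'   temporal genes.
#' @param signature_genes Number of filler genes forming each lineage's
#'   broader expression program (beyond the marker panel), up-regulated
#'   `signature_effect`-fold in that lineage. Real lineages differ across
#'   many genes, and the multi-embedding clustering relies on that breadth
#'   rather than on the six annotation markers alone.
#' @param signature_effect Fold change of signature genes in their
#'   lineage.
#' @param contaminant_cells Number of planted oligodendrocyte-like cells
#'   (eGFP-negative, Olig1-high) appended to the embryonic/perinatal
#'   stages.
#' @param qc_fail_fraction Fraction of cells whose QC metrics table is
#'   deliberately pushed out of bounds on one metric.
#' @param ko_fraction Fraction of Pitx3-knockout (homozygous) cells.
#' @param ko_depletion Named sampling weights (< 1 depletes) applied to
#'   lineage proportions for knockout cells.
#' @param seed Integer seed; runs are bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(stages = c("E13.5", "E15.5", "E18.5", "P1", "P7", "P90"),
                       n_cells_per_stage = 100L,
                       n_genes = 500L,
                       n_spikeins = 92L,
                       subgroup_proportions = NULL,
                       marker_effect = 300,
                       marker_baseline = 5,
                       baseline_mean = 20,
                       bio_sd = 0.35,
                       dispersion = c(a1 = 3, alpha0 = 0.05),
                       dropout_rate = 0.1,
                       n_temporal = 150L,
                       maturation_gradient = 1.6,
                       signature_genes = 20L,
                       signature_effect = 4,
                       contaminant_cells = 0L,
                       qc_fail_fraction = 0.1,
                       ko_fraction = 0,
                       ko_depletion = c("AT-Dathigh" = 0.1, "T-Dathigh" = 0.1),
                       seed = 1L) {
  if (is.null(subgroup_proportions)) {
    subgroup_proportions <- stats::setNames(
      rep(1 / length(.mda_lineages), length(.mda_lineages)), .mda_lineages)
  }
  if (abs(sum(subgroup_proportions) - 1) > 1e-9)
    stop("subgroup_proportions must sum to 1", call. = FALSE)
  if (any(subgroup_proportions < 0))
    stop("subgroup_proportions must be non-negative", call. = FALSE)
  n_cells_per_stage <- rep_len(as.integer(n_cells_per_stage), length(stages))
  if (any(n_cells_per_stage <= 0L) || n_genes <= 0L)
    stop("cell and gene counts must be positive", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must lie in [0, 1]", call. = FALSE)
  n_special <- length(.mda_marker_panel) + 2L  # + eGFP, Olig1
  n_sig_total <- signature_genes * length(.mda_lineages)
  if (n_genes < n_special + n_temporal + n_sig_total)
    stop("n_genes must be at least ", n_special + n_temporal + n_sig_total,
         " to hold markers, reporters, temporal and signature genes",
         call. = FALSE)
  structure(list(
    stages = stages, n_cells_per_stage = n_cells_per_stage,
    n_genes = as.integer(n_genes), n_spikeins = as.integer(n_spikeins),
    subgroup_proportions = subgroup_proportions,
    marker_effect = marker_effect, marker_baseline = marker_baseline,
    baseline_mean = baseline_mean, bio_sd = bio_sd,
    dispersion = dispersion, dropout_rate = dropout_rate,
    n_temporal = as.integer(n_temporal),
    maturation_gradient = maturation_gradient,
    signature_genes = as.integer(signature_genes),
    signature_effect = signature_effect,
    contaminant_cells = as.integer(contaminant_cells),
    qc_fail_fraction = qc_fail_fraction,
    ko_fraction = ko_fraction, ko_depletion = ko_depletion,
    seed = as.integer(seed)), class = "sim_config")
}

# multiplicative technical layer: gamma with mean 1 and CV2 = a1/mu + alpha0
.tech_factor <- function(mu, a1, alpha0) {
  cv2 <- ifelse(mu > 0, a1 / mu + alpha0, 0)
  out <- rep(1, length(mu))
  pos <- cv2 > 0
  out[pos] <- stats::rgamma(sum(pos), shape = 1 / cv2[pos], rate = 1 / cv2[pos])
  out
}

#' Simulate a single-cell RNA-seq study with planted structure
#'
#' Draws an RPKM-like genes x cells matrix with spike-in rows, per-cell
#' stage and genotype metadata, an alignment-QC metrics table, and the
#' ground truth needed to score every downstream stage (true lineage per
#' cell, continuous maturation time, temporal class and marker assignment
#' per gene).
#'
#' @param config A [sim_config()].
#' @return A list of class `mda_sim` with elements `expr` (matrix, genes x
#'   cells; spike-ins last), `spikein` (logical per row), `cells`
#'   (data.frame: cell, stage, genotype, contaminant), `qc` (metrics table
#'   for [apply_qc_filters()]) and `truth` (list: `lineage`, `maturation`,
#'   `genes` data.frame, `qc_fail`).
#' @export
simulate_scrna <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  n_stage <- length(cf$stages)

  ## --- cells ----------------------------------------------------------
  stage <- rep(cf$stages, cf$n_cells_per_stage)
  n_main <- length(stage)
  genotype <- sample(c("het", "ko"), n_main, replace = TRUE,
                     prob = c(1 - cf$ko_fraction, cf$ko_fraction))
  lineage <- character(n_main)
  depl <- stats::setNames(rep(1, length(.mda_lineages)), .mda_lineages)
  depl[names(cf$ko_depletion)] <- cf$ko_depletion
  p_het <- cf$subgroup_proportions[.mda_lineages]
  p_ko <- p_het * depl
  p_ko <- p_ko / sum(p_ko)
  is_ko <- genotype == "ko"
  lineage[!is_ko] <- sample(.mda_lineages, sum(!is_ko), TRUE, prob = p_het)
  if (any(is_ko))
    lineage[is_ko] <- sample(.mda_lineages, sum(is_ko), TRUE, prob = p_ko)

  n_cont <- cf$contaminant_cells
  if (n_cont > 0L) {
    cont_stage <- sample(setdiff(cf$stages, "P90"), n_cont, replace = TRUE)
    stage <- c(stage, cont_stage)
    genotype <- c(genotype, rep("het", n_cont))
    lineage <- c(lineage, rep(NA_character_, n_cont))
  }
  n_cells <- length(stage)
  cell_id <- sprintf("cell%04d", seq_len(n_cells))
  contaminant <- c(rep(FALSE, n_main), rep(TRUE, n_cont))
  stage_idx <- match(stage, cf$stages) - 1L
  maturation <- stage_idx + stats::runif(n_cells)

  ## --- gene catalogue -------------------------------------------------
  panel <- .mda_marker_panel
  n_temp <- cf$n_temporal
  n_fill <- cf$n_genes - length(panel) - 2L - n_temp
  temp_class <- rep(c("early", "intermediate", "late"), length.out = n_temp)
  gene_id <- c(panel, "eGFP", "Olig1",
               sprintf("g%04d", seq_len(n_temp + n_fill)))
  temporal_of <- stats::setNames(rep("none", cf$n_genes), gene_id)
  temp_genes <- gene_id[length(panel) + 2L + seq_len(n_temp)]
  temporal_of[temp_genes] <- temp_class
  marker_of <- stats::setNames(rep("none", cf$n_genes), gene_id)
  for (lin in names(.mda_marker_map))
    for (g in .mda_marker_map[[lin]])
      marker_of[g] <- if (marker_of[g] == "none") lin else
        paste(marker_of[g], lin, sep = ";")
  signature_of <- stats::setNames(rep("none", cf$n_genes), gene_id)
  if (cf$signature_genes > 0L) {
    fill_genes <- gene_id[temporal_of == "none" & marker_of == "none" &
                            !gene_id %in% c("eGFP", "Olig1")]
    sig_genes <- fill_genes[seq_len(cf$signature_genes *
                                      length(.mda_lineages))]
    signature_of[sig_genes] <- rep(.mda_lineages,
                                   each = cf$signature_genes)
  }

  ## --- expected means -------------------------------------------------
  base_mu <- stats::rlnorm(cf$n_genes, log(cf$baseline_mean), 1)
  mu <- matrix(base_mu, cf$n_genes, n_cells,
               dimnames = list(gene_id, cell_id))
  for (g in panel) {
    mu[g, ] <- cf$marker_baseline
    own <- names(.mda_marker_map)[vapply(.mda_marker_map, function(m)
      g %in% m, logical(1))]
    mu[g, lineage %in% own] <- cf$marker_effect
  }
  mu["eGFP", ] <- ifelse(contaminant, 0, 50)
  mu["Olig1", ] <- ifelse(contaminant, 300, 0.1)
  if (cf$signature_genes > 0L) {
    for (lin in .mda_lineages) {
      sg <- names(signature_of)[signature_of == lin]
      mu[sg, lineage %in% lin] <- mu[sg, lineage %in% lin] *
        cf$signature_effect
    }
  }
  if (n_temp > 0L) {
    grad <- cf$maturation_gradient
    mid <- (n_stage - 1) / 2
    mult <- rbind(
      early = grad^(n_stage - 1L - (0:(n_stage - 1L))),
      intermediate = grad^(n_stage - 1 - 2 * abs((0:(n_stage - 1L)) - mid)),
      late = grad^(0:(n_stage - 1L)))
    mu[temp_genes, ] <- 10 * mult[temp_class, stage_idx + 1L, drop = FALSE]
  }

  ## --- noise layers ---------------------------------------------------
  a1 <- cf$dispersion[["a1"]]; alpha0 <- cf$dispersion[["alpha0"]]
  bio <- matrix(stats::rlnorm(length(mu), -cf$bio_sd^2 / 2, cf$bio_sd),
                nrow(mu), ncol(mu))
  tech <- matrix(.tech_factor(as.vector(mu), a1, alpha0), nrow(mu), ncol(mu))
  expr <- mu * bio * tech
  if (cf$dropout_rate > 0) {
    keep <- matrix(stats::rbinom(length(expr), 1L, 1 - cf$dropout_rate),
                   nrow(expr), ncol(expr))
    expr <- expr * keep
  }

  ## --- spike-ins: technical layer only, no dropout --------------------
  if (cf$n_spikeins > 0L) {
    sp_id <- sprintf("ERCC-%03d", seq_len(cf$n_spikeins))
    sp_mu <- 2^seq(0, 12, length.out = cf$n_spikeins)
    sp_mat <- matrix(rep(sp_mu, n_cells), cf$n_spikeins, n_cells,
                     dimnames = list(sp_id, cell_id))
    sp_mat <- sp_mat * matrix(.tech_factor(as.vector(sp_mat), a1, alpha0),
                              cf$n_spikeins, n_cells)
    expr <- rbind(expr, sp_mat)
  }
  spikein <- grepl("^ERCC-", rownames(expr))

  ## --- QC metrics table ----------------------------------------------
  adult <- stage == "P90"
  qc <- data.frame(
    cell = cell_id,
    unique_pct = stats::rnorm(n_cells, ifelse(adult, 55, 50), 8),
    mismatch_pct = stats::rnorm(n_cells, 2, 0.8),
    exon_pct = stats::rnorm(n_cells, 75, 4),
    three_prime_pct = stats::rnorm(n_cells, 3, 1),
    genes_detected_pct = stats::rnorm(n_cells, ifelse(adult, 15, 25), 4),
    reads = round(stats::runif(n_cells, 3e5, 2e6)),
    stringsAsFactors = FALSE)
  qc$mismatch_pct <- pmax(qc$mismatch_pct, 0.1)
  qc$three_prime_pct <- pmax(qc$three_prime_pct, 0.2)
  qc$genes_detected_pct <- pmax(qc$genes_detected_pct, 5)
  qc_fail <- rep(FALSE, n_cells)
  n_fail <- round(cf$qc_fail_fraction * n_cells)
  if (n_fail > 0L) {
    bad <- sample(n_cells, n_fail)
    qc_fail[bad] <- TRUE
    metric <- sample(c("unique_pct", "mismatch_pct", "exon_pct",
                       "three_prime_pct", "genes_detected_pct", "reads"),
                     n_fail, replace = TRUE)
    low <- c(unique_pct = 5, exon_pct = 40, genes_detected_pct = 1,
             reads = 2e4)
    high <- c(mismatch_pct = 90, three_prime_pct = 15)
    for (i in seq_along(bad)) {
      m <- metric[i]
      qc[bad[i], m] <- if (m %in% names(low)) low[[m]] else high[[m]]
    }
  }

  cells <- data.frame(cell = cell_id, stage = stage, genotype = genotype,
                      contaminant = contaminant, stringsAsFactors = FALSE)
  truth <- list(
    lineage = stats::setNames(lineage, cell_id),
    maturation = stats::setNames(maturation, cell_id),
    genes = data.frame(gene = gene_id, temporal_class = temporal_of,
                       marker_of = marker_of, signature_of = signature_of,
                       row.names = NULL, stringsAsFactors = FALSE),
    qc_fail = stats::setNames(qc_fail, cell_id))
  structure(list(expr = expr, spikein = spikein, cells = cells, qc = qc,
                 truth = truth, config = cf), class = "mda_sim")
}

#' @export
print.mda_sim <- function(x, ...) {
  cat("Synthetic dopamine-neuron scRNA-seq study\n")
  cat(sprintf("  %d genes + %d spike-ins x %d cells\n",
              sum(!x$spikein), sum(x$spikein), ncol(x$expr)))
  cat("  stages:", paste(x$config$stages, collapse = ", "), "\n")
  cat("  lineages:", paste(names(table(x$truth$lineage)), collapse = ", "),
      "\n")
  invisible(x)
}

## ---------------------------------------------------------------------
## Barcode codebook
## ---------------------------------------------------------------------

.all_words <- function(len, alphabet) {
  grid <- do.call(expand.grid, rep(list(seq_along(alphabet) - 1L), len))
  apply(grid, 1L, function(r) paste(alphabet[r + 1L], collapse = ""))
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' All-pairs scan; used to verify codebook validity.
#' @param codes Character vector of equal-length barcodes.
#' @return Integer minimum pairwise Hamming distance (Inf for < 2 codes).
#' @export
min_hamming_distance <- function(codes) {
  if (length(codes) < 2L) return(Inf)
  m <- do.call(rbind, strsplit(codes, ""))
  best <- ncol(m)
  for (i in seq_len(nrow(m) - 1L)) {
    d <- rowSums(m[(i + 1L):nrow(m), , drop = FALSE] !=
                   matrix(m[i, ], nrow(m) - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
  }
  best
}

#' Generate a barcode codebook with guaranteed Hamming separation
#'
#' For the default 4-round, 4-letter chemistry with minimum distance 2 the
#' codebook is drawn from the parity code: all words whose last base is the
#' sum of the preceding bases mod 4. Any two parity words differ in at
#' least two positions, and the code attains the maximum possible size
#' (4^3 = 64 words, Singleton bound). Larger requests fail with the bound.
#' Other distance requirements fall back to a greedy search.
#'
#' @param n_genes Number of barcodes requested.
#' @param barcode_len Barcode length (sequencing rounds), default 4.
#' @param alphabet Symbols, default A/C/G/T (read out as the channels
#'   Cy5, Texas Red, Cy3, AF488).
#' @param min_hamming Required minimum pairwise distance, default 2:
#'   enough to detect (not correct) any single-round calling error.
#' @param seed Seed for the random subset / greedy order.
#' @param genes Optional gene names for the barcodes.
#' @return Named character vector of class `codebook` with attributes
#'   `alphabet` and `channel_map`.
#' @export
generate_codebook <- function(n_genes, barcode_len = 4L,
                              alphabet = c("A", "C", "G", "T"),
                              min_hamming = 2L, seed = 1L, genes = NULL) {
  if (n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  q <- length(alphabet)
  set.seed(seed)
  if (min_hamming <= 1L) {
    pool <- .all_words(barcode_len, alphabet)
  } else if (min_hamming == 2L) {
    # parity construction: last symbol = sum of the others mod q
    prefix <- do.call(expand.grid,
                      rep(list(0:(q - 1L)), barcode_len - 1L))
    last <- rowSums(prefix) %% q
    pool <- apply(cbind(prefix, last), 1L, function(r)
      paste(alphabet[unlist(r) + 1L], collapse = ""))
  } else {
    words <- sample(.all_words(barcode_len, alphabet))
    pool <- character(0)
    for (w in words) {
      if (all(vapply(pool, .hamming, integer(1), b = w) >= min_hamming))
        pool <- c(pool, w)
      if (length(pool) >= n_genes) break
    }
  }
  if (n_genes > length(pool))
    stop(sprintf(paste0("requested %d barcodes but at most %d of length %d",
                        " over a %d-letter alphabet satisfy Hamming >= %d"),
                 n_genes, if (min_hamming == 2L) q^(barcode_len - 1L)
                 else length(pool),
                 barcode_len, q, min_hamming), call. = FALSE)
  codes <- sample(pool, n_genes)
  if (is.null(genes)) genes <- sprintf("gene%02d", seq_len(n_genes))
  stopifnot(length(genes) == n_genes)
  structure(stats::setNames(codes, genes),
            alphabet = alphabet,
            channel_map = stats::setNames(seq_along(alphabet), alphabet),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: %d barcodes of length %d, min Hamming %d\n",
              length(x), nchar(x[[1]]), min_hamming_distance(unname(x))))
  invisible(x)
}

## ---------------------------------------------------------------------
## In situ sequencing signals
## ---------------------------------------------------------------------

#' Spatial layout for the in situ simulator
#'
#' Cells sit on a regular grid with centroid spacing `spacing` (pixels);
#' each cell carries a planted lineage and emits exactly `spots_per_cell`
#' amplicon spots scattered within `spacing/3` of its centroid, so the
#' nearest-centroid rule recovers the true cell at radius `spacing/2`.
#'
#' @param n_cells Number of nuclei.
#' @param spacing Centroid grid spacing.
#' @param spots_per_cell Spots emitted per cell (default 40, typical of
#'   padlock-probe panels whose targets include abundant markers).
#' @param lineage_proportions Named lineage mix (default: equal over the
#'   seven lineages).
#' @param gene_freq Optional lineage x gene probability matrix; by default
#'   built from the marker map (markers of the lineage up-weighted 12x,
#'   Pitx3/eGFP 4x everywhere, other genes weight 1).
#' @param signal Fluorescence level of the true channel.
#' @return A list of class `insitu_layout`.
#' @export
insitu_layout <- function(n_cells = 100L, spacing = 30, spots_per_cell = 40L,
                          lineage_proportions = NULL, gene_freq = NULL,
                          signal = 100) {
  if (is.null(lineage_proportions))
    lineage_proportions <- stats::setNames(
      rep(1 / length(.mda_lineages), length(.mda_lineages)), .mda_lineages)
  structure(list(n_cells = as.integer(n_cells), spacing = spacing,
                 spots_per_cell = as.integer(spots_per_cell),
                 lineage_proportions = lineage_proportions,
                 gene_freq = gene_freq, signal = signal),
            class = "insitu_layout")
}

#' Spot frequencies per lineage from reference expression profiles
#'
#' In tissue, the number of amplicon spots a gene produces in a cell
#' scales with its expression, so realistic in situ simulations draw spot
#' genes with probability proportional to the lineage's mean expression
#' profile (e.g. from [cluster_profiles()] of an annotated scRNA-seq
#' reference). Genes missing from the profile (such as Pitx3 probes
#' absent from the reference matrix) get the median profile value.
#'
#' @param profiles Lineages x genes mean-expression matrix.
#' @param genes Codebook genes to cover.
#' @param floor Minimum relative weight, as a fraction of the row mean.
#' @return Lineages x genes probability matrix (rows sum to 1).
#' @export
gene_frequencies_from_profiles <- function(profiles, genes, floor = 0.02) {
  w <- matrix(stats::median(profiles), nrow(profiles), length(genes),
              dimnames = list(rownames(profiles), genes))
  present <- intersect(genes, colnames(profiles))
  w[, present] <- profiles[, present]
  w <- pmax(w, floor * rowMeans(w))
  w / rowSums(w)
}

.default_gene_freq <- function(genes, lineages) {
  w <- matrix(1, length(lineages), length(genes),
              dimnames = list(lineages, genes))
  for (g in intersect(c("Pitx3", "eGFP"), genes)) w[, g] <- 4
  for (lin in lineages) {
    mk <- intersect(.mda_marker_map[[lin]] %||% character(0), genes)
    if (length(mk)) w[lin, mk] <- 12
  }
  w / rowSums(w)
}

#' Simulate an in situ sequencing spot table
#'
#' Each spot's intensity tensor has, in round r, the `signal` level on the
#' channel of barcode position r, `crosstalk * signal` on the other
#' channels, and additive Gaussian noise truncated at zero. With
#' `noise_sd = 0` and `crosstalk < 1` the per-round argmax therefore equals
#' the barcode letter for every spot.
#'
#' @param codebook A [generate_codebook()] result (or named barcode
#'   vector).
#' @param layout An [insitu_layout()].
#' @param noise_sd Additive intensity noise sd.
#' @param crosstalk Fraction of the signal leaking into off-target
#'   channels.
#' @param seed Integer seed.
#' @return List with `spots` (data.frame: spot, x, y, `int_r<i>_c<j>`
#'   intensity columns), `nuclei` (cell, x, y, lineage) and `truth`
#'   (spot, gene, cell).
#' @export
generate_insitu <- function(codebook, layout = insitu_layout(),
                            noise_sd = 0, crosstalk = 0, seed = 1L) {
  if (length(codebook) == 0L) stop("empty codebook", call. = FALSE)
  set.seed(seed)
  alphabet <- attr(codebook, "alphabet") %||% c("A", "C", "G", "T")
  n_rounds <- nchar(unname(codebook)[1])
  n_chan <- length(alphabet)
  lp <- layout$lineage_proportions
  genes <- names(codebook)
  freq <- layout$gene_freq %||% .default_gene_freq(genes, names(lp))

  side <- ceiling(sqrt(layout$n_cells))
  idx <- seq_len(layout$n_cells) - 1L
  nuclei <- data.frame(
    cell = seq_len(layout$n_cells),
    x = (idx %% side) * layout$spacing + layout$spacing / 2,
    y = (idx %/% side) * layout$spacing + layout$spacing / 2,
    lineage = sample(names(lp), layout$n_cells, TRUE, prob = lp),
    stringsAsFactors = FALSE)

  cell_of <- rep(nuclei$cell, each = layout$spots_per_cell)
  n_spots <- length(cell_of)
  gene_of <- character(n_spots)
  for (lin in unique(nuclei$lineage)) {
    sel <- nuclei$lineage[cell_of] == lin
    gene_of[sel] <- sample(genes, sum(sel), TRUE, prob = freq[lin, ])
  }
  theta <- stats::runif(n_spots, 0, 2 * pi)
  rad <- layout$spacing / 3 * sqrt(stats::runif(n_spots))
  sx <- nuclei$x[cell_of] + rad * cos(theta)
  sy <- nuclei$y[cell_of] + rad * sin(theta)

  barcode <- unname(codebook[gene_of])
  letters_mat <- do.call(rbind, strsplit(barcode, ""))
  intens <- matrix(NA_real_, n_spots, n_rounds * n_chan)
  cn <- character(n_rounds * n_chan)
  for (r in seq_len(n_rounds)) {
    true_ch <- match(letters_mat[, r], alphabet)
    for (ch in seq_len(n_chan)) {
      col <- (r - 1L) * n_chan + ch
      cn[col] <- sprintf("int_r%d_c%d", r, ch)
      base <- ifelse(true_ch == ch, layout$signal,
                     crosstalk * layout$signal)
      if (noise_sd > 0) base <- base + stats::rnorm(n_spots, 0, noise_sd)
      intens[, col] <- pmax(base, 0)
    }
  }
  colnames(intens) <- cn
  spots <- cbind(data.frame(spot = seq_len(n_spots), x = sx, y = sy),
                 as.data.frame(intens))
  truth <- data.frame(spot = seq_len(n_spots), gene = gene_of,
                      cell = cell_of, stringsAsFactors = FALSE)
  list(spots = spots, nuclei = nuclei, truth = truth)
}
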