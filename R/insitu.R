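# Decoding in situ sequencing signals: per-round base calling with
# quality scores, codebook matching, spot-to-cell assignment and the
# published cell/gene filters.

# parse the int_r<i>_c<j> intensity columns of a spot table
.intensity_layout <- function(spots) {
  cols <- grep("^int_r[0-9]+_c[0-9]+$", names(spots), value = TRUE)
  if (!length(cols)) stop("no intensity columns (int_r<i>_c<j>) found",
                          call. = FALSE)
  r <- as.integer(sub("^int_r([0-9]+)_c[0-9]+$", "\\1", cols))
  ch <- as.integer(sub("^int_r[0-9]+_c([0-9]+)$", "\\1", cols))
  list(cols = cols, rounds = sort(unique(r)), channels = sort(unique(ch)),
       r = r, ch = ch)
}

#' Call bases from per-round channel intensities
#'
#' For each spot and sequencing round, the called base is the channel-map
#' letter of the highest-intensity channel, and the round's quality score
#' is the maximum signal divided by the sum of all signals (so
#' qs lies in (1/n_channels, 1] whenever the round has signal). Ties are
#' broken toward the lowest channel index and flagged. A round with zero
#' total intensity leaves the quality score undefined (NA); such spots are
#' later rejected as low quality.
#'
#' @param spots Spot table with columns `spot`, `x`, `y` and intensity
#'   columns `int_r<i>_c<j>` (as produced by [generate_insitu()]).
#' @param channels Letters mapped to channels 1..4, default A/C/G/T
#'   (Cy5, Texas Red, Cy3, AF488).
#' @return Data.frame: spot, x, y, barcode, `qs_r<i>` per round, `min_qs`,
#'   `tie` (any tie-broken round).
#' @export
call_bases <- function(spots, channels = c("A", "C", "G", "T")) {
  lay <- .intensity_layout(spots)
  if (length(lay$channels) != length(channels))
    stop("channel map has ", length(channels), " letters but table has ",
         length(lay$channels), " channels", call. = FALSE)
  n <- nrow(spots)
  letters_by_round <- matrix("", n, length(lay$rounds))
  qs <- matrix(NA_real_, n, length(lay$rounds))
  tie <- rep(FALSE, n)
  for (i in seq_along(lay$rounds)) {
    r <- lay$rounds[i]
    m <- as.matrix(spots[, lay$cols[lay$r == r][order(lay$ch[lay$r == r])],
                         drop = FALSE])
    tot <- rowSums(m)
    mx <- do.call(pmax, as.data.frame(m))
    best <- max.col(m, ties.method = "first")
    n_at_max <- rowSums(m == mx)
    tie <- tie | (n_at_max > 1L & tot > 0)
    letters_by_round[, i] <- channels[best]
    qs[, i] <- ifelse(tot > 0, mx / tot, NA_real_)
  }
  out <- data.frame(spot = spots$spot,
                    x = spots$x %||% NA_real_,
                    y = spots$y %||% NA_real_,
                    barcode = apply(letters_by_round, 1L, paste,
                                    collapse = ""),
                    stringsAsFactors = FALSE)
  colnames(qs) <- sprintf("qs_r%d", lay$rounds)
  out <- cbind(out, qs)
  out$min_qs <- suppressWarnings(
    apply(qs, 1L, function(v) if (anyNA(v)) NA_real_ else min(v)))
  out$tie <- tie
  if (any(tie))
    message(sum(tie), " spot(s) had intensity ties broken to the lowest ",
            "channel")
  out
}

#' Decode called barcodes against the codebook
#'
#' A spot is retained iff its minimum per-round quality score is at least
#' `qs_threshold` and its called barcode is an exact codebook member.
#' There is no error correction: a Hamming-distance-2 code detects any
#' single-round error but cannot uniquely correct it, so corrupted
#' barcodes are rejected as `not_in_codebook`, never remapped.
#'
#' @param calls Output of [call_bases()].
#' @param codebook Named barcode vector ([generate_codebook()]).
#' @param qs_threshold Minimum per-round quality score, default 0.5.
#' @return `calls` with columns `gene` (NA when rejected) and `status`
#'   (`ok`, `low_quality`, `not_in_codebook`).
#' @export
decode_spots <- function(calls, codebook, qs_threshold = 0.5) {
  len <- unique(nchar(unname(codebook)))
  if (length(len) != 1L || nchar(calls$barcode[1]) != len)
    stop("barcode length does not match the codebook", call. = FALSE)
  gene_of <- stats::setNames(names(codebook), unname(codebook))
  low <- is.na(calls$min_qs) | calls$min_qs < qs_threshold
  known <- calls$barcode %in% names(gene_of)
  status <- ifelse(low, "low_quality",
                   ifelse(known, "ok", "not_in_codebook"))
  gene <- ifelse(status == "ok", gene_of[calls$barcode], NA_character_)
  out <- calls
  out$gene <- unname(gene)
  out$status <- status
  out
}

#' Assign decoded spots to the nearest nucleus
#'
#' Each accepted spot goes to the nearest nucleus centroid (Euclidean)
#' within `max_radius`; equidistant ties go to the lower cell id. Spots
#' beyond the radius are dropped and counted.
#'
#' @param decoded Output of [decode_spots()] (only `status == "ok"` spots
#'   are assigned).
#' @param nuclei Data.frame with columns `cell`, `x`, `y`.
#' @param max_radius Maximum spot-to-centroid distance.
#' @return List: `counts` (cells x genes matrix over all nuclei and all
#'   codebook genes seen), `assignments` (spot, gene, cell, dist),
#'   `n_unassigned`.
#' @export
assign_spots_to_cells <- function(decoded, nuclei, max_radius) {
  if (nrow(nuclei) == 0L) stop("empty nucleus table", call. = FALSE)
  nuclei <- nuclei[order(nuclei$cell), , drop = FALSE]
  ok <- decoded[decoded$status == "ok", , drop = FALSE]
  if (nrow(ok) > 0L) {
    # block the distance computation to cap memory on large spot tables
    block <- max(1L, floor(2e6 / nrow(nuclei)))
    nearest <- integer(nrow(ok))
    best_d <- numeric(nrow(ok))
    for (start in seq(1L, nrow(ok), by = block)) {
      idx <- start:min(start + block - 1L, nrow(ok))
      d <- sqrt(outer(ok$x[idx], nuclei$x, "-")^2 +
                  outer(ok$y[idx], nuclei$y, "-")^2)
      nearest[idx] <- apply(d, 1L, which.min)  # first min = lowest cell id
      best_d[idx] <- d[cbind(seq_along(idx), nearest[idx])]
    }
    within <- best_d <= max_radius
    assignments <- data.frame(spot = ok$spot[within],
                              gene = ok$gene[within],
                              cell = nuclei$cell[nearest[within]],
                              dist = best_d[within])
  } else {
    assignments <- data.frame(spot = integer(0), gene = character(0),
                              cell = integer(0), dist = numeric(0))
  }
  genes <- sort(unique(ok$gene))
  counts <- matrix(0L, nrow(nuclei), length(genes),
                   dimnames = list(as.character(nuclei$cell), genes))
  if (nrow(assignments) > 0L) {
    tab <- table(factor(as.character(assignments$cell),
                        levels = rownames(counts)),
                 factor(assignments$gene, levels = genes))
    counts[] <- as.integer(tab)
  }
  list(counts = counts, assignments = assignments,
       n_unassigned = nrow(ok) - nrow(assignments))
}

#' Apply the four published in situ cell/gene filters
#'
#' In order: (1) keep only cells expressing any gate gene (Th, Pitx3 or
#' eGFP); (2) remove any gene expressed in fewer than `min_cells_per_gene`
#' cells; (3) remove the `drop_genes` (Pitx3 and eGFP should not drive
#' classification, Nxph4 was over-represented); (4) remove any cell
#' expressing fewer than `min_genes_per_cell` genes.
#'
#' @param counts Cells x genes count matrix.
#' @param gate_genes Rule-1 genes; at least one must be in the panel.
#' @param drop_genes Rule-3 genes.
#' @param min_cells_per_gene Rule-2 floor, default 10 ("less than 10
#'   cells" removed).
#' @param min_genes_per_cell Rule-4 floor, default 3 ("3 or more genes"
#'   kept).
#' @return Filtered count matrix with attribute `removed` (counts removed
#'   per rule).
#' @export
filter_insitu_cells <- function(counts,
                                gate_genes = c("Th", "Pitx3", "eGFP"),
                                drop_genes = c("Pitx3", "eGFP", "Nxph4"),
                                min_cells_per_gene = 10L,
                                min_genes_per_cell = 3L) {
  gate <- intersect(gate_genes, colnames(counts))
  if (!length(gate))
    stop("none of the gate genes (", paste(gate_genes, collapse = ", "),
         ") are in the count matrix", call. = FALSE)
  n0 <- nrow(counts)
  keep_cell <- rowSums(counts[, gate, drop = FALSE] > 0) > 0
  counts <- counts[keep_cell, , drop = FALSE]
  removed_1 <- n0 - nrow(counts)

  cells_per_gene <- colSums(counts > 0)
  keep_gene <- cells_per_gene >= min_cells_per_gene
  removed_2 <- sum(!keep_gene)
  counts <- counts[, keep_gene, drop = FALSE]

  drop <- intersect(drop_genes, colnames(counts))
  removed_3 <- length(drop)
  counts <- counts[, setdiff(colnames(counts), drop), drop = FALSE]

  keep_cell <- rowSums(counts > 0) >= min_genes_per_cell
  removed_4 <- sum(!keep_cell)
  counts <- counts[keep_cell, , drop = FALSE]

  attr(counts, "removed") <- c(cells_no_gate = removed_1,
                               genes_rare = removed_2,
                               genes_dropped = removed_3,
                               cells_few_genes = removed_4)
  counts
}

#' Lineage proportions over consensus predictions
#'
#' Fractions of predicted cells per lineage among non-"none" labels, plus
#' the branch-level roll-up (Dat-high = T/AT/VT, Dat-low = N/NT/G/GT).
#'
#' @param labels Character labels per cell (lineages or "none").
#' @return List: `lineage` (named fractions summing to 1), `branch`
#'   (`dat_high`, `dat_low`), `n` (cells counted).
#' @export
quantify_lineage_proportions <- function(labels) {
  keep <- !is.na(labels) & labels != "none"
  if (!any(keep)) stop("all predictions are \"none\"", call. = FALSE)
  labels <- labels[keep]
  lin <- table(labels) / length(labels)
  high <- c("T-Dathigh", "AT-Dathigh", "VT-Dathigh")
  low <- c("N-Datlow", "NT-Datlow", "G-Datlow", "GT-Datlow")
  branch <- c(dat_high = sum(lin[intersect(names(lin), high)]),
              dat_low = sum(lin[intersect(names(lin), low)]))
  list(lineage = c(unclass(lin)), branch = branch, n = length(labels))
}
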