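# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.log2p1 <- function(x) log2(x + 1)

# derive a reproducible child seed; kept < 2^31
.child_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset) * 9973L) %% 2147483629L
}

.assert_genes <- function(expr, genes) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

.assert_cells <- function(expr, cells) {
  missing <- setdiff(cells, colnames(expr))
  if (length(missing) > 0L)
    stop("cell(s) absent from expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# row-wise mean and squared coefficient of variation on a dense matrix
.row_stats <- function(m) {
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (ncol(m) - 1L)
  data.frame(mean = mu, var = v, cv2 = v / mu^2, row.names = rownames(m))
}

# rank each row across its columns (average ranks for ties)
.row_ranks <- function(m) {
  r <- t(apply(m, 1L, rank))
  dimnames(r) <- dimnames(m)
  r
}
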