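#' Joint principal-component reduction of two datasets
#'
#' Fits one PCA basis on the gene-intersected, row-concatenated, centered
#' expression matrices of both time points and projects each dataset onto the
#' top `d` components. A single shared basis is required for the
#' cross-dataset expression distances to be well defined. Component signs
#' follow a fixed convention (the largest-magnitude loading of each component
#' is positive) so results are reproducible across platforms.
#'
#' @param ds1,ds2 Normalized `spatial_dataset`s.
#' @param d Number of components to retain (default 50).
#' @return A `reduced_pair`: list with `pcs1` (n1 x d), `pcs2` (n2 x d), `d`,
#'   `gene_intersection`, and `sdev` (component standard deviations,
#'   non-increasing).
#' @export
reduce_joint <- function(ds1, ds2, d = 50) {
  if (!ds1$normalized || !ds2$normalized) {
    stop("both datasets must be normalized before reduction", call. = FALSE)
  }
  shared <- intersect(ds1$gene_names, ds2$gene_names)
  if (length(shared) == 0L) {
    stop("datasets share no genes", call. = FALSE)
  }
  n1 <- n_cells(ds1)
  n2 <- n_cells(ds2)
  max_d <- min(length(shared), n1 + n2 - 1L)
  if (d > max_d) {
    stop(sprintf("d = %d exceeds the feasible rank; maximum is %d", d, max_d),
         call. = FALSE)
  }
  joint <- rbind(ds1$counts[, shared, drop = FALSE],
                 ds2$counts[, shared, drop = FALSE])
  pc <- stats::prcomp(joint, center = TRUE, scale. = FALSE, rank. = d)
  scores <- pc$x[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(d)) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) scores[, j] <- -scores[, j]
  }
  rp <- list(pcs1 = scores[seq_len(n1), , drop = FALSE],
             pcs2 = scores[n1 + seq_len(n2), , drop = FALSE],
             d = d,
             gene_intersection = shared,
             sdev = pc$sdev[seq_len(d)])
  class(rp) <- "reduced_pair"
  rp
}

#' @export
print.reduced_pair <- function(x, ...) {
  cat(sprintf("reduced_pair: %d + %d cells, %d components over %d shared genes\n",
              nrow(x$pcs1), nrow(x$pcs2), x$d, length(x$gene_intersection)))
  invisible(x)
}
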