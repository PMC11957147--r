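# Per-gene two-group differential expression on normalized log expression,
# with BH correction and cross-replicate consistency calls.

#' Per-gene Wald test between two cell populations
#'
#' For each gene the Wald statistic is the difference of group means of the
#' normalized log expression divided by its unequal-variance standard error,
#' with a two-sided p-value from the normal reference and
#' Benjamini-Hochberg adjusted q-values over all tested genes. The fold
#' change is the ratio of the expm1-backtransformed group means (group A over
#' group B). Genes constant in both groups with equal means get p = 1 and
#' fold change 1.
#'
#' `fc_min` has no default: the magnitude threshold is a study decision (1.5
#' and 1.25 are both in common use) and must be stated explicitly.
#'
#' @param expr Cells-by-genes matrix of normalized log expression.
#' @param group Per-cell binary label; the first level (or `TRUE`) is group
#'   A.
#' @param fc_min Minimum fold-change magnitude for the `significant` call
#'   (e.g. 1.5); `|log2 fc| >= log2(fc_min)`.
#' @param q_max Maximum BH-adjusted q for the `significant` call.
#' @return data.frame with `gene`, `log2fc`, `statistic`, `p`, `q`,
#'   `significant`.
#' @export
wald_de <- function(expr, group, fc_min, q_max = 0.05) {
  expr <- as.matrix(expr)
  if (missing(fc_min)) {
    stop("fc_min must be given explicitly (e.g. 1.5)", call. = FALSE)
  }
  g <- if (is.logical(group)) !group else {
    f <- factor(group)
    if (nlevels(f) != 2) stop("group must have exactly two levels", call. = FALSE)
    as.integer(f) != 1L
  }
  a <- expr[!g, , drop = FALSE]
  b <- expr[g, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("both groups need at least 2 cells", call. = FALSE)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  se <- sqrt(va / na + vb / nb)
  stat <- (ma - mb) / se
  degenerate <- se == 0
  stat[degenerate & ma == mb] <- 0
  stat[degenerate & ma != mb] <- Inf * sign((ma - mb)[degenerate & ma != mb])
  p <- 2 * stats::pnorm(-abs(stat))
  q <- stats::p.adjust(p, method = "BH")
  pseudo <- 1e-9
  fc <- (expm1(ma) + pseudo) / (expm1(mb) + pseudo)
  fc[degenerate & ma == mb] <- 1
  log2fc <- log2(fc)
  genes <- colnames(expr)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(expr)))
  data.frame(gene = genes, log2fc = log2fc, statistic = stat, p = p, q = q,
             significant = q <= q_max & abs(log2fc) >= log2(fc_min),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genes consistently differentially expressed across two replicates
#'
#' A gene is kept when it is significant in both replicate analyses (under
#' the given thresholds, recomputed here) and its fold change has the same
#' sign in both. Symmetric in its two arguments.
#'
#' @param results_rep1,results_rep2 data.frames from [wald_de()].
#' @param q_max,fc_min Thresholds applied to both replicates.
#' @return Character vector of gene names (possibly empty; disjoint gene
#'   universes give an empty result with a warning).
#' @export
consistent_de <- function(results_rep1, results_rep2, q_max = 0.05,
                          fc_min = 1.5) {
  shared <- intersect(results_rep1$gene, results_rep2$gene)
  if (!length(shared)) {
    warning("replicates share no genes; empty consistency set")
    return(character(0))
  }
  r1 <- results_rep1[match(shared, results_rep1$gene), ]
  r2 <- results_rep2[match(shared, results_rep2$gene), ]
  lfc_min <- log2(fc_min)
  sig1 <- r1$q <= q_max & abs(r1$log2fc) >= lfc_min
  sig2 <- r2$q <= q_max & abs(r2$log2fc) >= lfc_min
  same_dir <- sign(r1$log2fc) == sign(r2$log2fc) & sign(r1$log2fc) != 0
  shared[sig1 & sig2 & same_dir]
}

#' Write a differential-expression table as TSV
#'
#' Columns `gene`, `log2fc`, `statistic`, `p`, `q`, `significant`; the
#' numeric columns double as volcano-plot data.
#'
#' @param results A data.frame from [wald_de()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
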