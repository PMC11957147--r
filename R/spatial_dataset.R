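#' Construct a spatial transcriptomics dataset for one time point
#'
#' Bundles a cells-by-genes count matrix with per-cell spatial coordinates,
#' cell-type labels and structure-membership labels. Cells that belong to no
#' annotated contiguous structure (airway cross-section, follicle, glomerulus,
#' ...) carry the reserved label `"background"`.
#'
#' @param counts Nonnegative numeric matrix, cells in rows, genes in columns.
#'   Column names are used as gene names when `gene_names` is `NULL`.
#' @param x,y Numeric vectors of per-cell spatial coordinates (same length
#'   units, e.g. micrometres).
#' @param cell_type Character vector of per-cell cell-type labels.
#' @param structure Character vector of per-cell structure labels; `NA`
#'   entries are replaced by `"background"`. `NULL` means all background.
#' @param gene_names Character vector of unique gene identifiers.
#' @param normalized Logical flag: has median normalization + log1p already
#'   been applied to `counts`?
#'
#' @return An object of class `spatial_dataset`: a list with fields
#'   `counts`, `x`, `y`, `cell_type`, `structure`, `gene_names`,
#'   `normalized`.
#' @export
#' @examples
#' ds <- spatial_dataset(matrix(1:6, 2, 3), x = c(0, 1), y = c(0, 0),
#'                       cell_type = c("a", "b"), structure = c("s1", NA))
#' n_cells(ds)
spatial_dataset <- function(counts, x, y, cell_type,
                            structure = NULL, gene_names = NULL,
                            normalized = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  if (is.null(gene_names)) {
    gene_names <- colnames(counts)
    if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(counts)))
  }
  if (is.null(structure)) structure <- rep("background", n)
  structure <- as.character(structure)
  structure[is.na(structure)] <- "background"
  ds <- list(
    counts = counts,
    x = as.numeric(x),
    y = as.numeric(y),
    cell_type = as.character(cell_type),
    structure = structure,
    gene_names = as.character(gene_names),
    normalized = isTRUE(normalized)
  )
  class(ds) <- "spatial_dataset"
  colnames(ds$counts) <- ds$gene_names
  validate_spatial_dataset(ds)
  ds
}

#' Validate a spatial_dataset's invariants
#'
#' Checks nonnegative counts (raw data only), consistent per-cell lengths,
#' finite coordinates and unique gene names. Called by the constructor; also
#' useful after manual surgery on the object.
#'
#' @param ds A `spatial_dataset`.
#' @return `ds`, invisibly. Errors on violation.
#' @export
validate_spatial_dataset <- function(ds) {
  stopifnot(inherits(ds, "spatial_dataset"))
  n <- nrow(ds$counts)
  if (n == 0L) stop("dataset is empty: no cells", call. = FALSE)
  lens <- c(length(ds$x), length(ds$y), length(ds$cell_type),
            length(ds$structure))
  if (any(lens != n)) {
    stop(sprintf(
      "per-cell fields out of register with counts (%d cells): x=%d y=%d cell_type=%d structure=%d",
      n, lens[1], lens[2], lens[3], lens[4]), call. = FALSE)
  }
  bad <- which(!is.finite(ds$x) | !is.finite(ds$y))
  if (length(bad)) {
    stop("non-finite coordinates for cell indices: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  if (anyNA(ds$counts) || min(ds$counts) < 0) {
    stop("counts contain NA or negative entries", call. = FALSE)
  }
  if (length(ds$gene_names) != ncol(ds$counts)) {
    stop("gene_names length does not match number of genes", call. = FALSE)
  }
  if (anyDuplicated(ds$gene_names)) {
    stop("gene_names are not unique", call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d cells x %d genes (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw counts"))
  ns <- setdiff(unique(x$structure), "background")
  cat(sprintf("  structures: %d (+ %d background cells)\n",
              length(ns), sum(x$structure == "background")))
  cat(sprintf("  cell types: %s\n",
              paste(utils::head(sort(unique(x$cell_type)), 8L), collapse = ", ")))
  invisible(x)
}

#' Number of cells in a spatial_dataset
#' @param ds A `spatial_dataset`.
#' @return Integer cell count.
#' @export
n_cells <- function(ds) nrow(ds$counts)

#' Subset a spatial_dataset to a set of cells
#'
#' All per-cell annotations are subset consistently.
#'
#' @param ds A `spatial_dataset`.
#' @param idx Integer or logical index over cells.
#' @return A `spatial_dataset` containing only the selected cells.
#' @export
subset_cells <- function(ds, idx) {
  out <- ds
  out$counts <- ds$counts[idx, , drop = FALSE]
  out$x <- ds$x[idx]
  out$y <- ds$y[idx]
  out$cell_type <- ds$cell_type[idx]
  out$structure <- ds$structure[idx]
  validate_spatial_dataset(out)
}

#' Remove cells with too few transcripts
#'
#' Standard pre-processing filter: drops every cell whose total transcript
#' count is below `min_transcripts` (default 10).
#'
#' @param ds A raw (non-normalized) `spatial_dataset`.
#' @param min_transcripts Minimum per-cell total count to keep a cell.
#' @return Filtered `spatial_dataset`.
#' @export
filter_low_count_cells <- function(ds, min_transcripts = 10) {
  if (ds$normalized) {
    stop("filter_low_count_cells expects raw counts (normalized = FALSE)",
         call. = FALSE)
  }
  keep <- rowSums(ds$counts) >= min_transcripts
  if (!any(keep)) {
    stop(sprintf("all %d cells fall below %g transcripts; nothing left",
                 n_cells(ds), min_transcripts), call. = FALSE)
  }
  subset_cells(ds, keep)
}

#' Median-normalize counts and apply log(1 + x)
#'
#' Scales each cell's counts so its total equals the median per-cell total of
#' the input, then applies an elementwise log-plus-one transform and sets the
#' `normalized` flag. For an even number of cells the median is the midpoint
#' of the two central totals (R's default convention).
#'
#' @param ds A raw `spatial_dataset`.
#' @return Normalized `spatial_dataset`.
#' @export
normalize_log1p <- function(ds) {
  if (ds$normalized) {
    stop("dataset is already normalized", call. = FALSE)
  }
  totals <- rowSums(ds$counts)
  if (any(totals == 0)) {
    stop("cells with zero total counts present; filter first", call. = FALSE)
  }
  target <- stats::median(totals)
  out <- ds
  out$counts <- log1p(ds$counts * (target / totals))
  out$normalized <- TRUE
  out
}
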