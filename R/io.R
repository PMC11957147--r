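#' Load a spatial transcriptomics dataset from disk
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{`h5ad`}{AnnData container: counts in `X` (dense array or CSR/CSC
#'     sparse group), coordinates in `obsm/<coord_key>` (two columns, x then
#'     y), labels in `obs` columns named by `cell_type_key` /
#'     `structure_key`.}
#'   \item{`delimited`}{A TSV pair: `path` holds the cells-by-genes count
#'     table with a header row of gene names; `meta_path` (default:
#'     `path` with its extension replaced by `.meta.tsv`) holds columns
#'     `cell_id`, `x`, `y`, `cell_type`, `structure`.}
#' }
#' Cells without a structure annotation (missing column or `NA`) are assigned
#' the reserved `"background"` label.
#'
#' @param path File path (`.h5ad` or counts TSV).
#' @param format One of `"auto"`, `"h5ad"`, `"delimited"`. `"auto"` picks by
#'   file extension.
#' @param meta_path Metadata TSV path (delimited format only).
#' @param cell_type_key,structure_key Names of the label columns.
#' @param coord_key Name of the coordinate slot (h5ad `obsm` entry).
#' @return A validated [spatial_dataset()].
#' @export
load_dataset <- function(path, format = c("auto", "h5ad", "delimited"),
                         meta_path = NULL,
                         cell_type_key = "cell_type",
                         structure_key = "structure",
                         coord_key = "spatial") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.h5ad$", path, ignore.case = TRUE)) "h5ad" else "delimited"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "h5ad") {
    read_h5ad_dataset(path, cell_type_key, structure_key, coord_key)
  } else {
    read_delim_dataset(path, meta_path, cell_type_key, structure_key)
  }
}

#' Save a spatial transcriptomics dataset to disk
#'
#' Writes the formats [load_dataset()] reads; `load(save(ds))` restores all
#' fields.
#'
#' @param ds A `spatial_dataset`.
#' @inheritParams load_dataset
#' @return `path`, invisibly.
#' @export
save_dataset <- function(ds, path, format = c("auto", "h5ad", "delimited"),
                         meta_path = NULL, coord_key = "spatial") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.h5ad$", path, ignore.case = TRUE)) "h5ad" else "delimited"
  }
  validate_spatial_dataset(ds)
  if (format == "h5ad") {
    write_h5ad_dataset(ds, path, coord_key)
  } else {
    write_delim_dataset(ds, path, meta_path)
  }
  invisible(path)
}

default_meta_path <- function(path) {
  sub("\\.[^.]+$", ".meta.tsv", path)
}

read_delim_dataset <- function(path, meta_path, cell_type_key, structure_key) {
  if (is.null(meta_path)) meta_path <- default_meta_path(path)
  if (!file.exists(meta_path)) {
    stop("metadata file not found: ", meta_path, call. = FALSE)
  }
  counts <- utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE)
  counts <- as.matrix(counts)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("x", "y")) {
    if (!col %in% names(meta)) {
      stop("metadata is missing coordinate column '", col, "'", call. = FALSE)
    }
  }
  if (!cell_type_key %in% names(meta)) {
    stop("metadata is missing cell-type column '", cell_type_key, "'",
         call. = FALSE)
  }
  if (nrow(meta) != nrow(counts)) {
    stop(sprintf("counts (%d cells) and metadata (%d rows) do not align",
                 nrow(counts), nrow(meta)), call. = FALSE)
  }
  struct <- if (structure_key %in% names(meta)) meta[[structure_key]] else NULL
  spatial_dataset(counts, meta$x, meta$y, meta[[cell_type_key]],
                  structure = struct, gene_names = colnames(counts))
}

write_delim_dataset <- function(ds, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- default_meta_path(path)
  counts <- as.data.frame(ds$counts, check.names = FALSE)
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- data.frame(cell_id = seq_len(n_cells(ds)), x = ds$x, y = ds$y,
                     cell_type = ds$cell_type, structure = ds$structure,
                     stringsAsFactors = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# --- minimal AnnData (h5ad) reader/writer -----------------------------------
# Only the pieces this package needs: X (dense or CSR/CSC), obs label columns
# (plain or categorical), var index, obsm coordinate slot. Written files carry
# the AnnData v0.2 encoding attributes so python's anndata can read them.

read_h5ad_matrix <- function(path, name, n_obs = NULL) {
  obj <- rhdf5::h5read(path, name, read.attributes = TRUE)
  if (is.list(obj)) {
    enc <- attr(obj, "encoding-type")
    shape <- as.integer(attr(obj, "shape"))
    data <- as.numeric(obj$data)
    indices <- as.integer(obj$indices)
    indptr <- as.integer(obj$indptr)
    if (is.null(enc)) {
      enc <- if (!is.null(n_obs) && length(indptr) == n_obs + 1L)
        "csr_matrix" else "csc_matrix"
    }
    m <- matrix(0, shape[1], shape[2])
    if (identical(enc, "csr_matrix")) {
      for (i in seq_len(shape[1])) {
        rng <- seq.int(indptr[i] + 1L, indptr[i + 1L], length.out = indptr[i + 1L] - indptr[i])
        if (length(rng)) m[i, indices[rng] + 1L] <- data[rng]
      }
    } else {
      for (j in seq_len(shape[2])) {
        rng <- seq.int(indptr[j] + 1L, indptr[j + 1L], length.out = indptr[j + 1L] - indptr[j])
        if (length(rng)) m[indices[rng] + 1L, j] <- data[rng]
      }
    }
    m
  } else {
    # rhdf5 preserves dimension order as stored, which is the transpose of the
    # h5py view; AnnData stores X with h5py shape (n_obs, n_var), so the R
    # array arrives as (n_var, n_obs) and is transposed back here
    m <- t(as.matrix(obj))
    attributes(m) <- list(dim = dim(m))
    m
  }
}

read_h5ad_column <- function(path, name) {
  obj <- rhdf5::h5read(path, name)
  if (is.list(obj) && all(c("categories", "codes") %in% names(obj))) {
    codes <- as.integer(obj$codes)
    out <- as.character(obj$categories)[codes + 1L]
    out[codes < 0L] <- NA_character_
    out
  } else {
    as.vector(obj)
  }
}

read_h5ad_dataset <- function(path, cell_type_key, structure_key, coord_key) {
  contents <- rhdf5::h5ls(path)
  entries <- gsub("//", "/", paste(contents$group, contents$name, sep = "/"))
  has <- function(nm) nm %in% entries
  if (!has("/X")) {
    stop("h5ad file has no X matrix: ", path, call. = FALSE)
  }
  coord_path <- paste0("/obsm/", coord_key)
  if (!has(coord_path)) {
    stop("h5ad file is missing coordinates at obsm/", coord_key, call. = FALSE)
  }
  coords <- rhdf5::h5read(path, coord_path)
  coords <- t(as.matrix(coords))  # h5py shape (n_obs, 2) -> R (2, n_obs)
  if (ncol(coords) != 2L) {
    stop("obsm/", coord_key, " does not have two columns", call. = FALSE)
  }
  n_obs <- nrow(coords)
  counts <- read_h5ad_matrix(path, "/X", n_obs = n_obs)
  ct_path <- paste0("/obs/", cell_type_key)
  if (!has(ct_path)) {
    stop("h5ad file is missing obs column '", cell_type_key, "'",
         call. = FALSE)
  }
  cell_type <- read_h5ad_column(path, ct_path)
  st_path <- paste0("/obs/", structure_key)
  struct <- if (has(st_path)) read_h5ad_column(path, st_path) else NULL
  genes <- tryCatch({
    idx <- rhdf5::h5readAttributes(path, "var")[["_index"]]
    as.character(rhdf5::h5read(path, paste0("/var/", idx)))
  }, error = function(e) NULL)
  if (is.null(genes) && has("/var/_index")) {
    genes <- as.character(rhdf5::h5read(path, "/var/_index"))
  }
  normalized <- if (has("/obs/normalized")) {
    any(as.numeric(read_h5ad_column(path, "/obs/normalized")) > 0)
  } else FALSE
  spatial_dataset(counts, coords[, 1], coords[, 2], cell_type,
                  structure = struct, gene_names = genes,
                  normalized = normalized)
}

h5_write_string_array <- function(fid, name, values) {
  rhdf5::h5write(as.character(values), fid, name,
                 variableLengthString = TRUE, encoding = "UTF-8")
}

h5_set_attrs <- function(path, name, attrs, as_array = character()) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  obj <- rhdf5::H5Oopen(fid, name)
  on.exit(rhdf5::H5Oclose(obj), add = TRUE)
  for (k in names(attrs)) {
    if (length(attrs[[k]]) == 0L) next  # zero-length attributes crash H5Awrite
    rhdf5::h5writeAttribute(attrs[[k]], obj, k,
                            variableLengthString = TRUE,
                            asScalar = length(attrs[[k]]) == 1L &&
                              !k %in% as_array,
                            encoding = "UTF-8")
  }
}

h5ad_dataframe <- function(path, group, index_name, index, columns) {
  rhdf5::h5createGroup(path, group)
  h5_write_string_array(path, paste0(group, "/", index_name), index)
  h5_set_attrs(path, paste0(group, "/", index_name),
               list("encoding-type" = "string-array",
                    "encoding-version" = "0.2.0"))
  for (nm in names(columns)) {
    col <- columns[[nm]]
    target <- paste0(group, "/", nm)
    if (is.character(col)) {
      h5_write_string_array(path, target, col)
      h5_set_attrs(path, target, list("encoding-type" = "string-array",
                                      "encoding-version" = "0.2.0"))
    } else {
      rhdf5::h5write(col, path, target)
      h5_set_attrs(path, target, list("encoding-type" = "array",
                                      "encoding-version" = "0.2.0"))
    }
  }
  h5_set_attrs(path, group,
               list("encoding-type" = "dataframe",
                    "encoding-version" = "0.2.0",
                    "_index" = index_name,
                    "column-order" = names(columns)),
               as_array = "column-order")
}

write_h5ad_dataset <- function(ds, path, coord_key = "spatial") {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  n <- n_cells(ds)
  # store transposed so that h5py sees shape (n_obs, n_var)
  rhdf5::h5write(t(ds$counts), path, "X")
  h5_set_attrs(path, "X", list("encoding-type" = "array",
                               "encoding-version" = "0.2.0"))
  h5ad_dataframe(path, "obs", "cell_id", paste0("cell", seq_len(n)),
                 list(cell_type = ds$cell_type, structure = ds$structure,
                      normalized = rep(as.integer(ds$normalized), n)))
  h5ad_dataframe(path, "var", "_index", ds$gene_names,
                 list(feature_name = ds$gene_names))
  rhdf5::h5createGroup(path, "obsm")
  h5_set_attrs(path, "obsm", list("encoding-type" = "dict",
                                  "encoding-version" = "0.1.0"))
  rhdf5::h5write(t(cbind(ds$x, ds$y)), path, paste0("obsm/", coord_key))
  h5_set_attrs(path, paste0("obsm/", coord_key),
               list("encoding-type" = "array", "encoding-version" = "0.2.0"))
  h5_set_attrs(path, "/", list("encoding-type" = "anndata",
                               "encoding-version" = "0.1.0"))
  invisible(path)
}
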