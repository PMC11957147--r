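#' Squared-Euclidean expression cost between two reduced datasets
#'
#' Entry (i, j) is the squared Euclidean distance between the PC
#' representation of cell i at t1 and cell j at t2; it penalizes mapping
#' cells to descendants with dissimilar expression programs.
#'
#' @param rp A `reduced_pair` from [reduce_joint()], or a list with numeric
#'   matrices `pcs1`, `pcs2` of equal column count.
#' @return An n1 x n2 nonnegative matrix.
#' @export
expression_cost <- function(rp) {
  a <- rp$pcs1
  b <- rp$pcs2
  if (ncol(a) != ncol(b)) stop("pcs1 and pcs2 differ in dimension", call. = FALSE)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Pairwise spatial distance matrix of one dataset
#'
#' Euclidean distances between cell centroids in the native coordinate units.
#'
#' @param ds A `spatial_dataset`.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
spatial_distance_matrix <- function(ds) {
  if (any(!is.finite(ds$x)) || any(!is.finite(ds$y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  as.matrix(stats::dist(cbind(ds$x, ds$y)))
}

#' Structure-disagreement cost matrix
#'
#' Entry (i, j) is 0 when cells i and j belong to the same contiguous
#' structure and `fb` when they do not; it is the building block of the
#' structural-coherence penalty. How cells outside any structure
#' (label `"background"`) enter the matrix is a modelling choice:
#' \describe{
#'   \item{`shared`}{(default) all background cells share one label, so
#'     background-to-structure pairs pay `fb` but background pairs are free.}
#'   \item{`free`}{any pair involving a background cell costs 0; only
#'     splitting of annotated structures is penalized.}
#'   \item{`singleton`}{each background cell is its own unit (pairs of
#'     distinct background cells pay `fb`).}
#' }
#'
#' @param ds A `spatial_dataset`.
#' @param fb Nonnegative penalty magnitude. `fb = 0` disables the structural
#'   term entirely (geometry-only coupling).
#' @param background_policy One of `"shared"`, `"free"`, `"singleton"`.
#' @return Symmetric n x n matrix with entries in \{0, fb\} and zero diagonal.
#' @export
structure_cost_matrix <- function(ds, fb,
                                  background_policy = c("shared", "free",
                                                        "singleton")) {
  if (!is.numeric(fb) || length(fb) != 1L || fb < 0) {
    stop("fb must be a single nonnegative number", call. = FALSE)
  }
  background_policy <- match.arg(background_policy)
  lab <- ds$structure
  n <- length(lab)
  bg <- lab == "background"
  if (background_policy == "singleton" && any(bg)) {
    lab[bg] <- paste0(".bg", seq_len(sum(bg)))
  }
  s <- matrix(fb, n, n)
  same <- outer(lab, lab, "==")
  s[same] <- 0
  if (background_policy == "free" && any(bg)) {
    s[bg, ] <- 0
    s[, bg] <- 0
  }
  diag(s) <- 0
  s
}

#' Assemble all cost matrices for the transport objective
#'
#' Builds the expression cost `Dg`, the two spatial distance matrices `D1`,
#' `D2`, the two structure-disagreement matrices `S1`, `S2`, and the scale
#' factors `f1 = ||D1||_F / ||Dg||_F`, `f2 = ||D2||_F / ||Dg||_F` that put the
#' geometric and structural terms on the scale of the expression term. `S1`,
#' `S2` are stored unscaled (entries 0 or `fb`); the solver divides them by
#' `f1`, `f2` exactly as it does `D1`, `D2`, so the effective structural
#' penalty is `fb / f1` (resp. `fb / f2`). Use [fb_on_expression_scale()] to
#' choose `fb` in units of the expression cost.
#'
#' @param ds1,ds2 The two `spatial_dataset`s.
#' @param rp Their `reduced_pair`.
#' @param fb Structure-penalty magnitude (see [structure_cost_matrix()]).
#' @param background_policy Passed to [structure_cost_matrix()].
#' @return A `cost_set`: list with `Dg`, `D1`, `D2`, `S1`, `S2`, `f1`, `f2`,
#'   `fb`, `background_policy`.
#' @export
build_cost_set <- function(ds1, ds2, rp, fb = 0,
                           background_policy = c("shared", "free",
                                                 "singleton")) {
  background_policy <- match.arg(background_policy)
  n1 <- n_cells(ds1)
  n2 <- n_cells(ds2)
  if (nrow(rp$pcs1) != n1 || nrow(rp$pcs2) != n2) {
    stop("reduced_pair does not match the datasets' cell counts", call. = FALSE)
  }
  dg <- expression_cost(rp)
  ndg <- frobenius(dg)
  if (ndg == 0) {
    stop("expression cost is identically zero; scale factors are undefined",
         call. = FALSE)
  }
  d1 <- spatial_distance_matrix(ds1)
  d2 <- spatial_distance_matrix(ds2)
  cs <- list(
    Dg = dg, D1 = d1, D2 = d2,
    S1 = structure_cost_matrix(ds1, fb, background_policy),
    S2 = structure_cost_matrix(ds2, fb, background_policy),
    f1 = frobenius(d1) / ndg,
    f2 = frobenius(d2) / ndg,
    fb = fb,
    background_policy = background_policy
  )
  if (cs$f1 <= 0 || cs$f2 <= 0) {
    stop("degenerate spatial coordinates: a distance matrix is all zero",
         call. = FALSE)
  }
  class(cs) <- "cost_set"
  cs
}

#' @export
print.cost_set <- function(x, ...) {
  cat(sprintf("cost_set: %d x %d cells; f1 = %.4g, f2 = %.4g, fb = %.4g (%s background)\n",
              nrow(x$Dg), ncol(x$Dg), x$f1, x$f2, x$fb, x$background_policy))
  invisible(x)
}

frobenius <- function(m) sqrt(sum(m^2))

#' Choose the structure penalty on the expression-cost scale
#'
#' Because the structure matrices are divided by the same scale factors as
#' the spatial distances, the raw `fb` is not directly comparable across
#' datasets. This helper returns the `fb` whose effective penalty
#' (`fb / f1`) equals `scale` times the mean expression cost, a unit in which
#' `scale` around 1 firmly discourages structure splitting and `scale`
#' around 0.01 barely biases the plan.
#'
#' @param ds1 The t1 `spatial_dataset` (defines `f1`).
#' @param rp The `reduced_pair`.
#' @param scale Desired effective penalty in units of `mean(Dg)`.
#' @return A single nonnegative number usable as `fb`.
#' @export
fb_on_expression_scale <- function(ds1, rp, scale = 1) {
  dg <- expression_cost(rp)
  f1 <- frobenius(spatial_distance_matrix(ds1)) / frobenius(dg)
  scale * mean(dg) * f1
}

#' Serialize a cost_set to an HDF5 container
#'
#' Datasets `Dg`, `D1`, `D2`, `S1`, `S2` plus scalar attributes `f1`, `f2`,
#' `fb`, `background_policy` on the root group.
#'
#' @param cs A `cost_set`.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_cost_set <- function(cs, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (nm in c("Dg", "D1", "D2", "S1", "S2")) {
    rhdf5::h5write(cs[[nm]], path, nm)
  }
  h5_set_attrs(path, "/", list(f1 = cs$f1, f2 = cs$f2, fb = cs$fb,
                               background_policy = cs$background_policy))
  invisible(path)
}

#' Read a cost_set written by [write_cost_set()]
#' @param path `.h5` path.
#' @return A `cost_set`.
#' @export
read_cost_set <- function(path) {
  at <- rhdf5::h5readAttributes(path, "/")
  cs <- list(Dg = rhdf5::h5read(path, "Dg"),
             D1 = rhdf5::h5read(path, "D1"),
             D2 = rhdf5::h5read(path, "D2"),
             S1 = rhdf5::h5read(path, "S1"),
             S2 = rhdf5::h5read(path, "S2"),
             f1 = as.numeric(at$f1), f2 = as.numeric(at$f2),
             fb = as.numeric(at$fb),
             background_policy = as.character(at$background_policy))
  class(cs) <- "cost_set"
  cs
}
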