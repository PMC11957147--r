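# Evaluation of transport plans: descendant sampling, geometric consistency,
# cell-type / structure mapping profiles, and Hill effective numbers.

# Run an expression with a private RNG state so callers' streams are intact.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Row-normalize a transport plan
#'
#' Divides each row by its sum so rows become per-ancestor descendant
#' distributions. Rows with zero mass are left at zero and reported in the
#' `zero_rows` attribute rather than silently defaulting.
#'
#' @param T Nonnegative matrix.
#' @return Matrix with unit row sums (attribute `zero_rows`: indices of
#'   all-zero rows).
#' @export
normalize_rows <- function(T) {
  if (min(T) < 0) stop("plan has negative entries", call. = FALSE)
  rs <- rowSums(T)
  zero <- which(rs == 0)
  rs[rs == 0] <- 1
  out <- T / rs
  attr(out, "zero_rows") <- zero
  out
}

#' Sample one descendant per ancestor cell from a plan
#'
#' For each row i the descendant index is drawn from the row's normalized
#' distribution by inverse-CDF sampling, mirroring a probabilistic
#' single-descendant assignment. Zero rows yield `NA` and are listed in
#' `missing`.
#'
#' @param T Nonnegative plan matrix.
#' @param seed Integer seed (draws are reproducible given the seed).
#' @param n_draws Number of independent assignments to retain.
#' @return A `descendant_assignment`: list with `descendant_index` (n1 x
#'   n_draws integer matrix), `missing` (zero-row indices), `seed`,
#'   `n_draws`.
#' @export
sample_descendants <- function(T, seed = NULL, n_draws = 1) {
  Tn <- normalize_rows(T)
  zero <- attr(Tn, "zero_rows")
  n1 <- nrow(Tn)
  cdf <- matrix(t(apply(Tn, 1, cumsum)), nrow = n1, ncol = ncol(Tn))
  idx <- with_local_seed(seed, {
    out <- matrix(NA_integer_, n1, n_draws)
    for (d in seq_len(n_draws)) {
      u <- stats::runif(n1)
      for (i in seq_len(n1)) {
        if (!(i %in% zero)) {
          out[i, d] <- findInterval(u[i], cdf[i, ]) + 1L
        }
      }
    }
    out
  })
  out <- list(descendant_index = idx, missing = zero, seed = seed,
              n_draws = n_draws)
  class(out) <- "descendant_assignment"
  out
}

assignment_vector <- function(assignment, draw = 1L) {
  if (inherits(assignment, "descendant_assignment")) {
    assignment$descendant_index[, draw]
  } else {
    as.integer(assignment)
  }
}

#' Geometric consistency of a descendant assignment
#'
#' Pearson correlation between all pairwise ancestor distances at t1 and the
#' pairwise distances between the assigned descendants at t2 (diagonal
#' excluded). A value near 1 means the mapping preserves the sample's global
#' geometry; it is invariant under rigid motions of either dataset.
#'
#' @param ds1,ds2 The two `spatial_dataset`s.
#' @param assignment A `descendant_assignment` (first draw is used) or an
#'   integer vector of descendant indices.
#' @return Pearson correlation coefficient.
#' @export
geometric_consistency <- function(ds1, ds2, assignment) {
  idx <- assignment_vector(assignment)
  if (anyNA(idx)) {
    stop("assignment is incomplete (cells with zero transported mass)",
         call. = FALSE)
  }
  n <- n_cells(ds1)
  if (n < 3) stop("fewer than 3 cells: correlation undefined", call. = FALSE)
  d1 <- spatial_distance_matrix(ds1)
  dd <- as.matrix(stats::dist(cbind(ds2$x[idx], ds2$y[idx])))
  off <- row(d1) != col(d1)
  stats::cor(d1[off], dd[off])
}

#' Hill number (order 1) of a proportion vector
#'
#' `exp(-sum p log p)` with `0 log 0 = 0`: the effective number of categories
#' the vector spreads over. Equals 1 for a one-hot vector and the number of
#' categories for a uniform one.
#'
#' @param p Nonnegative vector summing to 1.
#' @return Scalar in `[1, length(p)]`.
#' @export
hill_number <- function(p) {
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' Mapping profile between source and target categories
#'
#' For each source category k, the proportion of its cells (or mass) mapping
#' into each target category, together with the Hill effective number of the
#' resulting row. With a sampled `assignment`, proportions are averaged over
#' the retained draws; with `plan`, proportions are mass-weighted directly
#' from the transport matrix. To profile the opposite temporal direction
#' (effective ancestors), call this on the transposed plan with the label
#' vectors swapped.
#'
#' @param labels1 Per-cell source categories (length n1).
#' @param labels2 Per-cell target categories (length n2).
#' @param assignment A `descendant_assignment` or index vector (sampled
#'   mode).
#' @param plan An n1 x n2 plan matrix (mass-weighted mode). Provide exactly
#'   one of `assignment`, `plan`.
#' @param drop_background Exclude the reserved `"background"` source
#'   category from the profile rows?
#' @return A `consistency_profile`: list with `labels_from`, `labels_to`,
#'   `proportions` (rows sum to 1), `hill`, `n_source` (cells per source
#'   category), `flagged` (source categories with no cells or no mass).
#' @export
mapping_profile <- function(labels1, labels2, assignment = NULL, plan = NULL,
                            drop_background = FALSE) {
  if (is.null(assignment) == is.null(plan)) {
    stop("provide exactly one of 'assignment' or 'plan'", call. = FALSE)
  }
  labels1 <- as.character(labels1)
  labels2 <- as.character(labels2)
  from <- sort(unique(labels1))
  if (drop_background) from <- setdiff(from, "background")
  to <- sort(unique(labels2))
  prop <- matrix(0, length(from), length(to),
                 dimnames = list(from, to))
  if (!is.null(plan)) {
    stopifnot(nrow(plan) == length(labels1), ncol(plan) == length(labels2))
    for (k in seq_along(from)) {
      rows <- labels1 == from[k]
      mass <- colSums(plan[rows, , drop = FALSE])
      prop[k, ] <- vapply(to, function(t2) sum(mass[labels2 == t2]), 0.0)
    }
  } else {
    idx <- if (inherits(assignment, "descendant_assignment")) {
      assignment$descendant_index
    } else {
      matrix(as.integer(assignment), ncol = 1)
    }
    stopifnot(nrow(idx) == length(labels1))
    for (d in seq_len(ncol(idx))) {
      dest <- labels2[idx[, d]]
      tab <- table(factor(labels1, levels = from),
                   factor(dest, levels = to), useNA = "no")
      prop <- prop + unclass(tab)
    }
  }
  totals <- rowSums(prop)
  flagged <- from[totals == 0]
  ok <- totals > 0
  prop[ok, ] <- prop[ok, , drop = FALSE] / totals[ok]
  hill <- rep(NA_real_, length(from))
  hill[ok] <- apply(prop[ok, , drop = FALSE], 1, hill_number)
  names(hill) <- from
  out <- list(labels_from = from, labels_to = to, proportions = prop,
              hill = hill,
              n_source = vapply(from, function(k) sum(labels1 == k), 0L),
              flagged = flagged)
  class(out) <- "consistency_profile"
  out
}

#' @export
print.consistency_profile <- function(x, ...) {
  cat(sprintf("consistency_profile: %d source x %d target categories\n",
              length(x$labels_from), length(x$labels_to)))
  cat(sprintf("  mean Hill effective number: %.3f\n",
              mean(x$hill, na.rm = TRUE)))
  invisible(x)
}

#' Export a consistency profile as tidy tables
#'
#' Writes `(source_category, target_category, proportion)` and
#' `(source_category, hill)` TSVs.
#'
#' @param profile A `consistency_profile`.
#' @param proportions_path,hill_path Output TSV paths.
#' @return Invisibly, a list of the two data frames.
#' @export
write_profile <- function(profile, proportions_path, hill_path) {
  long <- expand.grid(source_category = profile$labels_from,
                      target_category = profile$labels_to,
                      stringsAsFactors = FALSE)
  long$proportion <- as.vector(profile$proportions)
  utils::write.table(long, proportions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hill <- data.frame(source_category = profile$labels_from,
                     hill = profile$hill)
  utils::write.table(hill, hill_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(proportions = long, hill = hill))
}

#' Classify structures by their dominant descendant category
#'
#' A structure is assigned a descendant category when at least `threshold`
#' (default 80%) of its cells map there; otherwise it is `"ambiguous"`. With
#' descendant categories "maturing" / "not maturing" this reproduces the
#' identification of maturing follicles from a coupling.
#'
#' @param structure Per-cell structure labels at t1 (background excluded
#'   from output).
#' @param descendant_category Per-cell category of each cell's assigned
#'   descendant.
#' @param threshold Minimum fraction (inclusive) for a call.
#' @return data.frame with `structure`, `label`, `proportion` (the winning
#'   fraction).
#' @export
classify_by_descendant <- function(structure, descendant_category,
                                   threshold = 0.8) {
  stopifnot(length(structure) == length(descendant_category))
  ids <- setdiff(sort(unique(structure)), "background")
  out <- data.frame(structure = ids, label = "ambiguous",
                    proportion = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    cats <- descendant_category[structure == ids[i]]
    tab <- table(cats) / length(cats)
    best <- which.max(tab)
    out$proportion[i] <- as.numeric(tab[best])
    if (tab[best] >= threshold) out$label[i] <- names(tab)[best]
  }
  out
}
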