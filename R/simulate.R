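# Synthetic paired time-point generator with contiguous structures,
# per-structure-type expression programs, branching/maturation dynamics,
# count noise, and recorded ground-truth couplings.

#' Parameters for the paired-dataset simulator
#'
#' The generator emulates an organ section containing disk-shaped contiguous
#' structures (airway cross-sections, follicles) embedded in background
#' stroma. Each structure carries one of a small number of expression
#' programs, so several structures share a program -- as airways share an
#' epithelial profile -- and expression alone cannot tell sibling structures
#' apart. Between the time points structures drift, may branch into two
#' daughters (never merge), and may mature: switch expression program, grow
#' by `growth_factor`, and shift toward the tissue center.
#'
#' @param n_structures Number of structures at t1.
#' @param cells_per_structure Length-2 integer range of member-cell counts.
#' @param n_background Background (stroma) cells per time point.
#' @param n_genes Total genes.
#' @param n_program_genes Marker genes per structure-type program.
#' @param n_program_types Number of distinct structure programs (several
#'   structures share each).
#' @param domain_size Side of the square tissue domain (length units).
#' @param structure_radius Disk radius of a structure at t1.
#' @param displacement_sd SD of the between-time-point drift of structure
#'   centers, and of background cell movement.
#' @param growth_factor Radius multiplier applied to maturing structures at
#'   t2.
#' @param branch_prob Probability that a structure splits into two daughters
#'   at t2.
#' @param maturation_prob Probability that a structure switches its
#'   expression program at t2.
#' @param count_depth Mean transcripts per cell.
#' @param noise_model `"negative_binomial"` (default) or `"poisson"`.
#' @param dispersion Negative-binomial dispersion (variance = mu + disp *
#'   mu^2).
#' @param marker_strength Fold elevation of program marker genes over
#'   baseline.
#' @param seed Integer seed; the full pair is reproducible from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_structures = 6, cells_per_structure = c(30, 60),
                       n_background = 100, n_genes = 200,
                       n_program_genes = 15, n_program_types = 3,
                       domain_size = 1000, structure_radius = 60,
                       displacement_sd = 30, growth_factor = 1.5,
                       branch_prob = 0, maturation_prob = 0,
                       count_depth = 500,
                       noise_model = c("negative_binomial", "poisson"),
                       dispersion = 0.3, marker_strength = 10, seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(branch_prob >= 0, branch_prob <= 1,
            maturation_prob >= 0, maturation_prob <= 1,
            n_structures >= 1, n_background >= 0, count_depth > 0,
            (n_program_types + 1) * n_program_genes <= n_genes)
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

# relative expression vector (sums to 1) for each program; programs have
# disjoint marker blocks, "stroma" is the last program
program_profiles <- function(p) {
  n_prog <- p$n_program_types + 1L
  profiles <- matrix(1, n_prog, p$n_genes)
  for (k in seq_len(n_prog)) {
    block <- (k - 1L) * p$n_program_genes + seq_len(p$n_program_genes)
    profiles[k, block] <- p$marker_strength
  }
  profiles / rowSums(profiles)
}

sample_counts <- function(profiles, program_idx, p) {
  mu <- p$count_depth * profiles[program_idx, , drop = FALSE]
  n <- length(program_idx)
  counts <- if (p$noise_model == "poisson") {
    matrix(stats::rpois(n * p$n_genes, lambda = mu), n, p$n_genes)
  } else {
    matrix(stats::rnbinom(n * p$n_genes, mu = mu, size = 1 / p$dispersion),
           n, p$n_genes)
  }
  colnames(counts) <- paste0("gene", seq_len(p$n_genes))
  counts
}

place_centers <- function(p) {
  margin <- p$structure_radius * max(1, p$growth_factor) + 3 * p$displacement_sd
  lo <- margin
  hi <- p$domain_size - margin
  if (hi <= lo) {
    stop("infeasible packing: domain too small for the structure radius; ",
         "increase domain_size", call. = FALSE)
  }
  min_sep <- 3.5 * p$structure_radius
  centers <- matrix(NA_real_, p$n_structures, 2)
  placed <- 0L
  for (tries in seq_len(20000L)) {
    cand <- stats::runif(2, lo, hi)
    if (placed == 0L ||
        min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))) >= min_sep) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == p$n_structures) return(centers)
    }
  }
  stop("infeasible packing: could not place ", p$n_structures,
       " disjoint structures; increase domain_size", call. = FALSE)
}

disk_points <- function(n, center, radius) {
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(a), center[2] + r * sin(a))
}

#' Simulate a paired two-time-point dataset with known ground truth
#'
#' Builds t1 (structures plus background), then derives t2 by drifting,
#' optionally branching and maturing each structure and resampling descendant
#' cells around their ancestors' relative positions. Each t2 cell records its
#' true t1 ancestor; each t2 structure descends from exactly one t1
#' structure (branching happens, merging never). When a structure branches,
#' both daughters receive the same number of cells, so the true
#' descendant-structure profile of the parent is an even split.
#'
#' @param params A [sim_params()].
#' @return A `sim_pair`: list with `ds1`, `ds2` (raw-count
#'   `spatial_dataset`s), `truth_ancestor` (per-t2-cell t1 index),
#'   `truth_structure_map` (data.frame `t2_structure`, `t1_structure`),
#'   `truth_matured` (named logical per t1 structure), `params`.
#' @export
simulate_pair <- function(params = sim_params()) {
  p <- params
  with_local_seed(p$seed, {
    profiles <- program_profiles(p)
    prog_names <- c(paste0("program", seq_len(p$n_program_types)), "stroma")
    centers <- place_centers(p)
    sizes <- p$cells_per_structure[1] +
      sample.int(p$cells_per_structure[2] - p$cells_per_structure[1] + 1L,
                 p$n_structures, replace = TRUE) - 1L
    s_prog <- ((seq_len(p$n_structures) - 1L) %% p$n_program_types) + 1L
    ids1 <- paste0("s", seq_len(p$n_structures))

    # ---- t1 ----
    pos1 <- NULL; struct1 <- character(0); prog1 <- integer(0)
    for (s in seq_len(p$n_structures)) {
      pos1 <- rbind(pos1, disk_points(sizes[s], centers[s, ], p$structure_radius))
      struct1 <- c(struct1, rep(ids1[s], sizes[s]))
      prog1 <- c(prog1, rep(s_prog[s], sizes[s]))
    }
    if (p$n_background > 0) {
      bg1 <- cbind(stats::runif(p$n_background, 0, p$domain_size),
                   stats::runif(p$n_background, 0, p$domain_size))
      pos1 <- rbind(pos1, bg1)
      struct1 <- c(struct1, rep("background", p$n_background))
      prog1 <- c(prog1, rep(p$n_program_types + 1L, p$n_background))
    }
    counts1 <- sample_counts(profiles, prog1, p)
    ds1 <- spatial_dataset(counts1, pos1[, 1], pos1[, 2],
                           cell_type = prog_names[prog1],
                           structure = struct1)

    # ---- dynamics ----
    matured <- stats::runif(p$n_structures) < p$maturation_prob
    branched <- stats::runif(p$n_structures) < p$branch_prob
    names(matured) <- ids1
    dom_center <- rep(p$domain_size / 2, 2)

    pos2 <- NULL; struct2 <- character(0); prog2 <- integer(0)
    anc <- integer(0)
    map_t2 <- character(0); map_t1 <- character(0)
    jitter_sd <- p$structure_radius / 10
    for (s in seq_len(p$n_structures)) {
      members <- which(struct1 == ids1[s])
      c2 <- centers[s, ] + stats::rnorm(2, 0, p$displacement_sd)
      r2 <- p$structure_radius
      prog_s <- s_prog[s]
      if (matured[s]) {
        r2 <- r2 * p$growth_factor
        c2 <- c2 + 0.3 * (dom_center - c2)
        prog_s <- (s_prog[s] %% p$n_program_types) + 1L
      }
      daughters <- if (branched[s]) {
        ang <- stats::runif(1, 0, 2 * pi)
        off <- 1.6 * r2 * c(cos(ang), sin(ang))
        list(list(id = paste0(ids1[s], "a"), center = c2 - off / 2),
             list(id = paste0(ids1[s], "b"), center = c2 + off / 2))
      } else {
        list(list(id = ids1[s], center = c2))
      }
      for (d in daughters) {
        anc_d <- members[sample.int(length(members), sizes[s], replace = TRUE)]
        rel <- (pos1[anc_d, , drop = FALSE] -
                  matrix(centers[s, ], sizes[s], 2, byrow = TRUE)) *
          (r2 / p$structure_radius)
        pts <- rel + matrix(d$center, sizes[s], 2, byrow = TRUE) +
          matrix(stats::rnorm(2 * sizes[s], 0, jitter_sd), sizes[s], 2)
        pos2 <- rbind(pos2, pts)
        struct2 <- c(struct2, rep(d$id, sizes[s]))
        prog2 <- c(prog2, rep(prog_s, sizes[s]))
        anc <- c(anc, anc_d)
        map_t2 <- c(map_t2, d$id)
        map_t1 <- c(map_t1, ids1[s])
      }
    }
    if (p$n_background > 0) {
      bg_idx <- which(struct1 == "background")
      anc_bg <- bg_idx[sample.int(length(bg_idx), p$n_background,
                                  replace = TRUE)]
      pts <- pos1[anc_bg, , drop = FALSE] +
        matrix(stats::rnorm(2 * p$n_background, 0, p$displacement_sd),
               p$n_background, 2)
      pts[, 1] <- pmin(pmax(pts[, 1], 0), p$domain_size)
      pts[, 2] <- pmin(pmax(pts[, 2], 0), p$domain_size)
      pos2 <- rbind(pos2, pts)
      struct2 <- c(struct2, rep("background", p$n_background))
      prog2 <- c(prog2, rep(p$n_program_types + 1L, p$n_background))
      anc <- c(anc, anc_bg)
    }
    counts2 <- sample_counts(profiles, prog2, p)
    ds2 <- spatial_dataset(counts2, pos2[, 1], pos2[, 2],
                           cell_type = prog_names[prog2],
                           structure = struct2)

    sp <- list(ds1 = ds1, ds2 = ds2,
               truth_ancestor = anc,
               truth_structure_map = data.frame(t2_structure = map_t2,
                                                t1_structure = map_t1,
                                                stringsAsFactors = FALSE),
               truth_matured = matured,
               params = p)
    class(sp) <- "sim_pair"
    sp
  })
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf("sim_pair: %d -> %d cells, %d -> %d structures\n",
              n_cells(x$ds1), n_cells(x$ds2),
              length(unique(setdiff(x$ds1$structure, "background"))),
              nrow(x$truth_structure_map)))
  invisible(x)
}

#' Ground-truth transport plan of a simulated pair
#'
#' Puts mass `1/n2` on each (true ancestor, t2 cell) pair. Serves as the
#' oracle when calibrating coupling metrics: its structure-level Hill
#' numbers equal the true branching counts.
#'
#' @param sp A `sim_pair`.
#' @return A `transport_plan` with total mass 1.
#' @export
truth_plan <- function(sp) {
  n1 <- n_cells(sp$ds1)
  n2 <- n_cells(sp$ds2)
  T <- matrix(0, n1, n2)
  T[cbind(sp$truth_ancestor, seq_len(n2))] <- 1 / n2
  plan <- list(T = T, row_mass = rowSums(T), col_mass = colSums(T),
               objective_trace = numeric(0), converged = TRUE,
               iterations = 0L, params = NULL)
  class(plan) <- "transport_plan"
  plan
}

#' Write a simulated pair's ground truth as TSV
#'
#' @param sp A `sim_pair`.
#' @param cells_path TSV of per-cell truth (`t2_cell`, `t1_ancestor`).
#' @param structures_path TSV of the structure ancestry map.
#' @return Invisibly, `cells_path`.
#' @export
write_truth <- function(sp, cells_path, structures_path) {
  utils::write.table(
    data.frame(t2_cell = seq_along(sp$truth_ancestor),
               t1_ancestor = sp$truth_ancestor),
    cells_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sp$truth_structure_map, structures_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(cells_path)
}
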