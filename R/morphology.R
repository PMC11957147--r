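# Structure-level geometric analyses: rotated-chord diameter, distance to the
# tissue boundary, cell density, and Delaunay-graph neighborhoods.

# ---- small computational-geometry primitives --------------------------------

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

# vertices of the convex hull (counter-clockwise), as a 2-column matrix
hull_vertices <- function(coords) {
  coords <- as.matrix(coords)
  h <- grDevices::chull(coords[, 1], coords[, 2])
  coords[rev(h), , drop = FALSE]  # chull returns clockwise; reverse to CCW
}

# distance from points (n x 2) to a segment a-b
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

validate_simple_polygon <- function(boundary) {
  boundary <- as.matrix(boundary)
  m <- nrow(boundary)
  if (m < 3) stop("boundary polygon needs at least 3 vertices", call. = FALSE)
  edges <- cbind(seq_len(m), c(2:m, 1))
  for (e1 in seq_len(m - 1)) {
    for (e2 in (e1 + 1):m) {
      # skip adjacent edges (shared vertex)
      if (abs(e1 - e2) <= 1 || (e1 == 1 && e2 == m)) next
      if (segments_intersect(boundary[edges[e1, 1], ], boundary[edges[e1, 2], ],
                             boundary[edges[e2, 1], ], boundary[edges[e2, 2], ])) {
        stop("boundary polygon is self-intersecting", call. = FALSE)
      }
    }
  }
  boundary
}

# length of the longest chord of convex polygon `v` (CCW) parallel to the
# x-axis after rotating the frame by -theta; the chord-length profile of a
# convex body is concave in the offset, so the maximum sits at a vertex level
chord_max <- function(v, theta) {
  ct <- cos(theta); st <- sin(theta)
  rx <- v[, 1] * ct + v[, 2] * st
  ry <- -v[, 1] * st + v[, 2] * ct
  n <- nrow(v)
  nxt <- c(2:n, 1)
  best <- 0
  for (y0 in unique(ry)) {
    xs <- numeric(0)
    for (e in seq_len(n)) {
      y1 <- ry[e]; y2 <- ry[nxt[e]]
      if ((y1 - y0) * (y2 - y0) <= 0) {
        if (y1 == y2) {
          xs <- c(xs, rx[e], rx[nxt[e]])
        } else {
          t <- (y0 - y1) / (y2 - y1)
          xs <- c(xs, rx[e] + t * (rx[nxt[e]] - rx[e]))
        }
      }
    }
    if (length(xs) >= 2) best <- max(best, max(xs) - min(xs))
  }
  best
}

# ---- exported operations ----------------------------------------------------

#' Rotated-chord diameter of a structure
#'
#' The structure's footprint is its member cells' convex hull. For each of
#' 180 directions (1 to 180 degrees from the x-axis, anchored at the hull
#' centroid) the maximal chord of the hull parallel to that direction is
#' measured; the diameter is the mean of the 180 maxima. For a disc this is
#' the usual diameter; for elongated structures it averages long and short
#' axes.
#'
#' @param coords Two-column matrix of member-cell coordinates (at least 3
#'   non-collinear cells).
#' @param n_angles Number of evenly spaced directions (default 180).
#' @return Mean maximal chord length.
#' @export
follicle_diameter <- function(coords, n_angles = 180) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) {
    stop("degenerate geometry: need at least 3 member cells", call. = FALSE)
  }
  v <- hull_vertices(coords)
  if (nrow(v) < 3 || polygon_area(v) <= 0) {
    stop("degenerate geometry: member cells are collinear", call. = FALSE)
  }
  angles <- seq_len(n_angles) * pi / n_angles
  mean(vapply(angles, function(a) chord_max(v, a), 0.0))
}

#' Mean distance of a structure's cells to the tissue boundary
#'
#' @param coords Two-column matrix of member-cell coordinates.
#' @param boundary Two-column vertex matrix of a simple polygon (implicitly
#'   closed), e.g. a digitized organ border or [tissue_boundary()].
#' @return Mean over cells of the minimal Euclidean distance to the boundary
#'   polyline.
#' @export
distance_to_boundary <- function(coords, boundary) {
  coords <- as.matrix(coords)
  boundary <- validate_simple_polygon(boundary)
  m <- nrow(boundary)
  nxt <- c(2:m, 1)
  d <- matrix(NA_real_, nrow(coords), m)
  for (e in seq_len(m)) {
    d[, e] <- point_segment_distance(coords, boundary[e, ], boundary[nxt[e], ])
  }
  mean(apply(d, 1, min))
}

#' Convex-hull fallback for the tissue boundary
#'
#' When no digitized border is available, the convex hull of all cell
#' positions serves as the tissue outline.
#'
#' @param ds A `spatial_dataset`.
#' @return Two-column vertex matrix (counter-clockwise).
#' @export
tissue_boundary <- function(ds) {
  hull_vertices(cbind(ds$x, ds$y))
}

#' Cell density of a structure
#'
#' Member count divided by area. The area defaults to the convex-hull area
#' of the member cells; a hand-segmented polygon area (e.g. accounting for a
#' follicle antrum) can be supplied instead.
#'
#' @param coords Member-cell coordinates.
#' @param area Optional area override (same squared length units).
#' @return Cells per unit area.
#' @export
structure_density <- function(coords, area = NULL) {
  coords <- as.matrix(coords)
  if (is.null(area)) {
    v <- hull_vertices(coords)
    if (nrow(v) < 3) stop("degenerate geometry for density", call. = FALSE)
    area <- polygon_area(v)
  }
  if (area <= 0) stop("non-positive area", call. = FALSE)
  nrow(coords) / area
}

#' Delaunay neighborhood graph of a dataset
#'
#' Delaunay triangulation of all cell positions, with edges longer than
#' `threshold` removed so that cells across empty space are not called
#' neighbors. The default threshold is 3 times the median Delaunay edge
#' length, which adapts to the dataset's cell density.
#'
#' @param ds A `spatial_dataset`.
#' @param threshold Distance cutoff; retained edges are strictly shorter.
#' @return A `neighborhood_graph`: list with `edges` (two-column index
#'   matrix), `lengths`, `threshold`, `n` (number of cells).
#' @export
neighborhood_graph <- function(ds, threshold = NULL) {
  dd <- deldir::deldir(ds$x, ds$y, suppressMsge = TRUE)
  e <- as.matrix(dd$delsgs[, c("ind1", "ind2")])
  len <- sqrt((ds$x[e[, 1]] - ds$x[e[, 2]])^2 +
                (ds$y[e[, 1]] - ds$y[e[, 2]])^2)
  if (is.null(threshold)) threshold <- 3 * stats::median(len)
  keep <- len < threshold
  g <- list(edges = e[keep, , drop = FALSE], lengths = len[keep],
            threshold = threshold, n = n_cells(ds))
  class(g) <- "neighborhood_graph"
  g
}

#' Cells within a graph distance of a structure
#'
#' Breadth-first search from the structure's member cells: all cells within
#' `degree` hops, excluding the members themselves.
#'
#' @param ds A `spatial_dataset`.
#' @param structure_id A structure label present in `ds$structure`.
#' @param graph A [neighborhood_graph()] built over the same dataset.
#' @param degree Maximum hop count (default 2: first- and second-degree
#'   neighbors).
#' @return Integer vector of neighbor cell indices (possibly empty).
#' @export
neighborhood <- function(ds, structure_id, graph, degree = 2) {
  if (!structure_id %in% ds$structure) {
    stop("unknown structure: ", structure_id, call. = FALSE)
  }
  members <- which(ds$structure == structure_id)
  adj <- vector("list", graph$n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  visited <- logical(graph$n)
  visited[members] <- TRUE
  frontier <- members
  found <- integer(0)
  for (d in seq_len(degree)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!visited[nxt]]
    if (!length(nxt)) break
    visited[nxt] <- TRUE
    found <- c(found, nxt)
    frontier <- nxt
  }
  sort(found)
}

#' Cell density of a structure's neighborhood
#'
#' The neighborhood region is the convex hull of the neighboring cells with
#' the structure's own area removed (an annulus for a compact structure);
#' density is the neighbor count divided by that area.
#'
#' @inheritParams neighborhood
#' @param follicle_area Area of the structure itself; defaults to its member
#'   cells' convex-hull area.
#' @return Cells per unit area over the annular neighborhood.
#' @export
neighborhood_density <- function(ds, structure_id, graph, degree = 2,
                                 follicle_area = NULL) {
  nb <- neighborhood(ds, structure_id, graph, degree)
  if (length(nb) < 3) {
    stop("degenerate neighborhood: fewer than 3 neighbor cells", call. = FALSE)
  }
  members <- which(ds$structure == structure_id)
  if (is.null(follicle_area)) {
    follicle_area <- polygon_area(hull_vertices(cbind(ds$x[members],
                                                      ds$y[members])))
  }
  nb_hull <- hull_vertices(cbind(ds$x[nb], ds$y[nb]))
  ann <- polygon_area(nb_hull) - follicle_area
  if (ann <= 0) {
    stop("degenerate neighborhood: annular area is non-positive", call. = FALSE)
  }
  length(nb) / ann
}

#' Cell-type composition of a structure's neighborhood
#'
#' @inheritParams neighborhood
#' @return Named proportion vector over the cell types of the neighbors.
#' @export
neighborhood_composition <- function(ds, structure_id, graph, degree = 2) {
  nb <- neighborhood(ds, structure_id, graph, degree)
  if (!length(nb)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(ds$cell_type[nb])
  stats::setNames(as.vector(tab / sum(tab)), names(tab))
}

#' Compare a morphological measure between two groups of structures
#'
#' Welch's unequal-variance two-sided t-test by default (a pooled-variance
#' variant is available). When both groups are constant, p is 1 for equal
#' means and 0 otherwise, by convention.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @param pooled Use the pooled-variance (classic two-sample) test instead
#'   of Welch's?
#' @return List with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `p`.
#' @export
compare_groups <- function(values_a, values_b, pooled = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  p <- if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) 1 else 0
  } else {
    stats::t.test(values_a, values_b, var.equal = pooled)$p.value
  }
  list(mean_a = mean(values_a), sd_a = stats::sd(values_a),
       mean_b = mean(values_b), sd_b = stats::sd(values_b), p = p)
}

#' Per-structure morphology table
#'
#' Computes, for every non-background structure: member count, rotated-chord
#' diameter, mean distance to the tissue boundary, area (convex hull or a
#' supplied segmented-polygon area), cell density, and the Delaunay
#' neighborhood density.
#'
#' @param ds A `spatial_dataset`.
#' @param boundary Optional boundary polygon; defaults to
#'   [tissue_boundary()].
#' @param areas Optional named vector of segmented areas per structure.
#' @param graph Optional precomputed [neighborhood_graph()].
#' @param degree Neighborhood degree.
#' @return data.frame with one row per structure.
#' @export
structure_morphology <- function(ds, boundary = NULL, areas = NULL,
                                 graph = NULL, degree = 2) {
  if (is.null(boundary)) boundary <- tissue_boundary(ds)
  if (is.null(graph)) graph <- neighborhood_graph(ds)
  ids <- setdiff(sort(unique(ds$structure)), "background")
  rows <- lapply(ids, function(id) {
    members <- ds$structure == id
    coords <- cbind(ds$x[members], ds$y[members])
    area <- if (!is.null(areas) && id %in% names(areas)) areas[[id]] else
      polygon_area(hull_vertices(coords))
    nb_density <- tryCatch(
      neighborhood_density(ds, id, graph, degree, follicle_area = area),
      error = function(e) NA_real_)
    data.frame(structure_id = id,
               n_cells = sum(members),
               diameter = follicle_diameter(coords),
               edge_distance = distance_to_boundary(coords, boundary),
               area = area,
               density = sum(members) / area,
               neighborhood_density = nb_density,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
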