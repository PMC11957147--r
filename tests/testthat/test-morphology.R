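circle_points <- function(n, r, cx = 0, cy = 0) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(cx + r * cos(a), cy + r * sin(a))
}

test_that("diameter of a circle equals twice the radius", {
  pts <- circle_points(360, 50)
  expect_equal(follicle_diameter(pts), 100, tolerance = 0.01)
})

test_that("diameter of the unit square matches the analytic chord mean", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
               c(0.5, 0), c(1, 0.5), c(0.5, 1), c(0, 0.5))
  # maximal chord of the unit square in direction theta: min(sec, csc)
  angles <- (1:180) * pi / 180
  want <- mean(pmin(1 / abs(cos(angles)), 1 / abs(sin(angles))))
  expect_equal(follicle_diameter(pts), want, tolerance = 1e-9)
})

test_that("diameter scales linearly and rejects degenerate input", {
  set.seed(81)
  pts <- cbind(runif(30), runif(30))
  d1 <- follicle_diameter(pts)
  expect_equal(follicle_diameter(3.7 * pts), 3.7 * d1, tolerance = 1e-9)
  expect_error(follicle_diameter(pts[1:2, ]), "at least 3")
  col <- cbind(1:5, 2 * (1:5))
  expect_error(follicle_diameter(col), "collinear")
})

test_that("geometry is invariant under rigid motion", {
  set.seed(82)
  pts <- cbind(rnorm(25, 10), rnorm(25, -4))
  boundary <- circle_points(60, 30, 10, -4)
  th <- 0.6
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mv <- function(m) sweep(m %*% rot, 2, c(11, -7), "+")
  expect_equal(follicle_diameter(mv(pts)), follicle_diameter(pts),
               tolerance = 1e-3)
  expect_equal(distance_to_boundary(mv(pts), mv(boundary)),
               distance_to_boundary(pts, boundary), tolerance = 1e-9)
  expect_equal(structure_density(mv(pts)), structure_density(pts),
               tolerance = 1e-9)
})

test_that("distance to boundary is zero on the border and R at the center", {
  boundary <- circle_points(200, 25)
  expect_equal(distance_to_boundary(boundary[3, , drop = FALSE], boundary), 0)
  expect_equal(distance_to_boundary(matrix(c(0, 0), 1), boundary), 25,
               tolerance = 0.01)
  shifted_pts <- matrix(c(5, 5), 1)
  expect_equal(distance_to_boundary(shifted_pts + 100, boundary + 100),
               distance_to_boundary(shifted_pts, boundary), tolerance = 1e-9)
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(distance_to_boundary(matrix(c(0, 0), 1), bowtie),
               "self-intersecting")
  expect_error(distance_to_boundary(matrix(c(0, 0), 1), matrix(0, 2, 2)),
               "at least 3")
})

test_that("density is count over area and scales inverse-quadratically", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2),
              c(1, 0), c(2, 1), c(1, 2), c(0, 1), c(1, 1))
  expect_equal(structure_density(sq), 9 / 4)
  expect_equal(structure_density(sq, area = 3), 3)
  expect_equal(structure_density(2 * sq), structure_density(sq) / 4)
  expect_error(structure_density(sq, area = 0), "non-positive")
})

test_that("Delaunay graph edges respect the threshold monotonically", {
  ds <- random_dataset(n = 60, seed = 83)
  g <- neighborhood_graph(ds)
  expect_true(all(g$lengths < g$threshold))
  g_small <- neighborhood_graph(ds, threshold = g$threshold / 2)
  key <- function(g) paste(pmin(g$edges[, 1], g$edges[, 2]),
                           pmax(g$edges[, 1], g$edges[, 2]))
  expect_true(all(key(g_small) %in% key(g)))
})

test_that("Delaunay edges match the empty-circumcircle oracle", {
  set.seed(84)
  n <- 12
  x <- runif(n); y <- runif(n)
  ds <- spatial_dataset(matrix(1, n, 1), x, y, cell_type = rep("a", n))
  g <- neighborhood_graph(ds, threshold = Inf)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  got <- sort(key(g$edges))
  # oracle: (i, j) is a Delaunay edge iff some circle through i and j
  # contains no other point; check circumcircles through each third point
  # and the diametral circle
  inside <- function(cx, cy, r2, k) (x[k] - cx)^2 + (y[k] - cy)^2 < r2 - 1e-12
  is_edge <- function(i, j) {
    others <- setdiff(seq_len(n), c(i, j))
    cx <- (x[i] + x[j]) / 2; cy <- (y[i] + y[j]) / 2
    r2 <- ((x[i] - x[j])^2 + (y[i] - y[j])^2) / 4
    if (!any(vapply(others, function(k) inside(cx, cy, r2, k), TRUE))) {
      return(TRUE)
    }
    for (k in others) {
      ax <- x[i] - x[k]; ay <- y[i] - y[k]
      bx <- x[j] - x[k]; by <- y[j] - y[k]
      d <- 2 * (ax * by - ay * bx)
      if (abs(d) < 1e-14) next
      ux <- (by * (ax^2 + ay^2) - ay * (bx^2 + by^2)) / d
      uy <- (ax * (bx^2 + by^2) - bx * (ax^2 + ay^2)) / d
      cx <- x[k] + ux; cy <- y[k] + uy
      r2 <- ux^2 + uy^2
      rest <- setdiff(others, k)
      if (!any(vapply(rest, function(m) inside(cx, cy, r2, m), TRUE))) {
        return(TRUE)
      }
    }
    FALSE
  }
  want <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (is_edge(i, j)) want <- c(want, paste(i, j))
  }
  expect_equal(got, sort(want))
})

test_that("neighborhoods follow graph distance and exclude members", {
  # chain a - b - c with a in the structure
  ds <- spatial_dataset(matrix(1, 3, 1), x = c(0, 1, 2), y = c(0, 0, 0),
                        cell_type = rep("t", 3),
                        structure = c("f", "background", "background"))
  g <- list(edges = rbind(c(1L, 2L), c(2L, 3L)), lengths = c(1, 1),
            threshold = 2, n = 3L)
  class(g) <- "neighborhood_graph"
  expect_equal(neighborhood(ds, "f", g, degree = 1), 2L)
  expect_equal(neighborhood(ds, "f", g, degree = 2), c(2L, 3L))
  expect_error(neighborhood(ds, "nope", g), "unknown structure")
  # isolated structure
  g0 <- g
  g0$edges <- g$edges[0, , drop = FALSE]
  expect_equal(length(neighborhood(ds, "f", g0, degree = 2)), 0L)
})

test_that("neighborhood search matches a breadth-first oracle", {
  ds <- random_dataset(n = 80, seed = 85)
  g <- neighborhood_graph(ds)
  adj <- lapply(seq_len(g$n), function(i) {
    c(g$edges[g$edges[, 1] == i, 2], g$edges[g$edges[, 2] == i, 1])
  })
  for (id in c("s1", "s2")) {
    for (deg in 1:3) {
      members <- which(ds$structure == id)
      dist <- rep(Inf, g$n)
      dist[members] <- 0
      queue <- members
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if (dist[w] > dist[v] + 1) {
            dist[w] <- dist[v] + 1
            queue <- c(queue, w)
          }
        }
      }
      want <- sort(which(dist >= 1 & dist <= deg))
      expect_equal(neighborhood(ds, id, g, degree = deg), want)
    }
  }
  expect_true(all(neighborhood(ds, "s1", g, 1) %in%
                    neighborhood(ds, "s1", g, 2)))
})

test_that("neighborhood density uses the annular area", {
  # structure at the center, 12 neighbors exactly on a known square hull
  inner <- circle_points(8, 0.5, 5, 5)
  hullpts <- rbind(c(3, 3), c(7, 3), c(7, 7), c(3, 7),
                   c(5, 3), c(7, 5), c(5, 7), c(3, 5))
  all_xy <- rbind(inner, hullpts)
  n <- nrow(all_xy)
  ds <- spatial_dataset(matrix(1, n, 1), all_xy[, 1], all_xy[, 2],
                        cell_type = rep("t", n),
                        structure = c(rep("f", 8), rep("background", 8)))
  # graph connecting every structure cell to every hull cell
  edges <- as.matrix(expand.grid(1:8, 9:n))
  g <- list(edges = edges, lengths = rep(1, nrow(edges)), threshold = Inf,
            n = n)
  class(g) <- "neighborhood_graph"
  # hull of the 8 neighbors is the 4x4 square: area 16
  got <- neighborhood_density(ds, "f", g, degree = 1, follicle_area = 1)
  expect_equal(got, 8 / (16 - 1))
  comp <- neighborhood_composition(ds, "f", g, degree = 1)
  expect_equal(unname(comp["t"]), 1)
  expect_error(neighborhood_density(ds, "f", g, degree = 1,
                                    follicle_area = 16), "non-positive")
})

test_that("neighborhood density recovers a uniform scatter rate", {
  set.seed(86)
  lambda <- 4  # cells per unit area
  side <- 12
  n_bg <- rpois(1, lambda * side^2)
  bg <- cbind(runif(n_bg, 0, side), runif(n_bg, 0, side))
  # the follicle occupies its disk: scatter cells live outside it
  fol_r <- 0.8
  keep <- (bg[, 1] - side / 2)^2 + (bg[, 2] - side / 2)^2 > fol_r^2
  bg <- bg[keep, , drop = FALSE]
  n_bg <- nrow(bg)
  fol <- circle_points(20, fol_r, side / 2, side / 2)
  xy <- rbind(fol, bg)
  ds <- spatial_dataset(matrix(1, nrow(xy), 1), xy[, 1], xy[, 2],
                        cell_type = rep("t", nrow(xy)),
                        structure = c(rep("f", 20), rep("background", n_bg)))
  g <- neighborhood_graph(ds)
  est <- neighborhood_density(ds, "f", g, degree = 2)
  expect_gt(length(neighborhood(ds, "f", g, 2)), 30)
  expect_lt(abs(est - lambda) / lambda, 0.25)
})

test_that("group comparison is a symmetric Welch test with conventions", {
  a <- c(1, 1, 1)
  expect_equal(compare_groups(a, a)$p, 1)
  expect_equal(compare_groups(a, c(2, 2, 2))$p, 0)
  set.seed(87)
  g1 <- rnorm(20)
  g2 <- rnorm(20, mean = 5)
  cg <- compare_groups(g1, g2)
  expect_lt(cg$p, 1e-6)
  expect_equal(cg$p, compare_groups(g2, g1)$p)
  expect_equal(cg$p, t.test(g1, g2)$p.value)
  pooled <- compare_groups(g1, g2, pooled = TRUE)
  expect_equal(pooled$p, t.test(g1, g2, var.equal = TRUE)$p.value)
  expect_error(compare_groups(1, g2), "at least 2")
})

test_that("morphology table covers every structure with sane values", {
  sp <- simulate_pair(sim_params(n_structures = 4, cells_per_structure = c(15, 20),
                                 n_background = 60, seed = 88))
  tab <- structure_morphology(sp$ds1)
  expect_equal(sort(tab$structure_id), paste0("s", 1:4))
  expect_true(all(tab$diameter > 0))
  expect_true(all(tab$density > 0))
  expect_true(all(tab$edge_distance >= 0))
  expect_equal(tab$density, tab$n_cells / tab$area)
})
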