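# Small in-code fixtures shared across test files.

# a tiny raw dataset with known row sums and labels
tiny_dataset <- function() {
  counts <- rbind(c(2, 2, 1),   # total 5
                  c(5, 3, 2),   # total 10
                  c(20, 20, 10) # total 50
  )
  colnames(counts) <- c("g1", "g2", "g3")
  spatial_dataset(counts, x = c(0, 1, 2), y = c(0, 0, 1),
                  cell_type = c("a", "a", "b"),
                  structure = c("s1", "s1", NA))
}

# random raw dataset, reproducible
random_dataset <- function(n = 50, ng = 20, seed = 1, normalized = FALSE) {
  set.seed(seed)
  counts <- matrix(rpois(n * ng, lambda = 5), n, ng)
  colnames(counts) <- paste0("g", seq_len(ng))
  ds <- spatial_dataset(counts, x = runif(n, 0, 100), y = runif(n, 0, 100),
                        cell_type = sample(c("a", "b"), n, replace = TRUE),
                        structure = sample(c("s1", "s2", "background"), n,
                                           replace = TRUE))
  if (normalized) ds <- normalize_log1p(ds)
  ds
}

# a cost_set built from random low-dimensional instances, without going
# through the full dataset pipeline
random_cost_set <- function(n1 = 8, n2 = 8, fb = 0, seed = 99) {
  set.seed(seed)
  rp <- list(pcs1 = matrix(rnorm(n1 * 2), n1),
             pcs2 = matrix(rnorm(n2 * 2), n2))
  Dg <- expression_cost(rp)
  D1 <- as.matrix(dist(matrix(rnorm(n1 * 2), n1)))
  D2 <- as.matrix(dist(matrix(rnorm(n2 * 2), n2)))
  lab1 <- rep(c("u", "v"), length.out = n1)
  lab2 <- rep(c("u", "v"), length.out = n2)
  s_of <- function(lab) {
    s <- matrix(fb, length(lab), length(lab))
    s[outer(lab, lab, "==")] <- 0
    s
  }
  cs <- list(Dg = Dg, D1 = D1, D2 = D2, S1 = s_of(lab1), S2 = s_of(lab2),
             f1 = sqrt(sum(D1^2)) / sqrt(sum(Dg^2)),
             f2 = sqrt(sum(D2^2)) / sqrt(sum(Dg^2)),
             fb = fb, background_policy = "shared")
  class(cs) <- "cost_set"
  cs
}

# preprocess both halves of a simulated pair and build the cost set
prepare_pair <- function(sp, d = 30, fb_scale = 0) {
  ds1 <- normalize_log1p(filter_low_count_cells(sp$ds1))
  ds2 <- normalize_log1p(filter_low_count_cells(sp$ds2))
  rp <- reduce_joint(ds1, ds2, d = d)
  fb <- if (fb_scale > 0) fb_on_expression_scale(ds1, rp, fb_scale) else 0
  list(ds1 = ds1, ds2 = ds2, rp = rp,
       costs = build_cost_set(ds1, ds2, rp, fb = fb))
}

# O(n^4) quadruple-loop oracle for the quadratic coupling energy
quad_energy_bruteforce <- function(A, B, T) {
  n1 <- nrow(T); n2 <- ncol(T)
  acc <- 0
  for (i in seq_len(n1)) for (j in seq_len(n1))
    for (k in seq_len(n2)) for (l in seq_len(n2))
      acc <- acc + (A[i, j] - B[k, l])^2 * T[i, k] * T[j, l]
  acc
}
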