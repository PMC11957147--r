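#' Solver parameters for the structured transport problem
#'
#' The objective minimized over nonnegative coupling matrices T is
#' \deqn{\alpha\,Expr + (1-\alpha)(Geom + Struct) + Reg + \epsilon\,Entr}
#' where `Expr` is the linear expression-distance term, `Geom` and `Struct`
#' are quadratic (Gromov-Wasserstein type) terms comparing within-dataset
#' spatial-distance and structure-disagreement matrices, `Reg` penalizes the
#' row/column marginals' KL departure from the expected mass vectors `p1`,
#' `p2` (weights `rho1`, `rho2`), and `Entr` is the KL of T against the
#' product reference `p1 p2'`. The marginal and entropy penalties use the
#' tensorized KL of the unbalanced Gromov-Wasserstein formulation,
#' `KL(mu x mu | nu x nu)`; with total masses near 1 it behaves like twice
#' the plain KL, a constant absorbed into the effective `rho`, `epsilon`.
#'
#' By default (`relative = TRUE`) `epsilon`, `rho1`, `rho2` are expressed in
#' units of the objective's per-unit-mass cost magnitude at the product-plan
#' start (expression term plus linearized quadratic terms), so the same
#' values are sensible across datasets of different depth, dimension and
#' coordinate units; set `relative = FALSE` to pass absolute values.
#'
#' @param alpha Trade-off in `[0, 1]` between expression (`alpha = 1`) and
#'   geometry + structure (`alpha = 0`).
#' @param rho1,rho2 Nonnegative weights of the descendant-/ancestor-marginal
#'   KL penalties. Larger values hold the marginals closer to `p1`, `p2`.
#' @param epsilon Positive entropic weight; larger values give blurrier
#'   plans.
#' @param max_iter Maximum outer iterations.
#' @param tol Outer convergence tolerance: relative Frobenius change of T.
#' @param inner_tol,inner_max_iter Inner (scaling-iteration) controls.
#' @param p1,p2 Expected-mass vectors; default uniform, each summing to 1.
#' @param relative Interpret `epsilon`, `rho1`, `rho2` in units of
#'   `mean(Dg)`?
#' @param seed Integer seed recorded with the run (the default deterministic
#'   initialization consumes no randomness).
#' @return A `solver_params` list.
#' @export
solver_params <- function(alpha = 0.4, rho1 = 1, rho2 = 1, epsilon = 0.05,
                          max_iter = 200, tol = 1e-6,
                          inner_tol = 1e-7, inner_max_iter = 5000,
                          p1 = NULL, p2 = NULL, relative = TRUE,
                          seed = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (rho1 < 0 || rho2 < 0) stop("rho1, rho2 must be nonnegative", call. = FALSE)
  out <- list(alpha = alpha, rho1 = rho1, rho2 = rho2, epsilon = epsilon,
              max_iter = as.integer(max_iter), tol = tol,
              inner_tol = inner_tol,
              inner_max_iter = as.integer(inner_max_iter),
              p1 = p1, p2 = p2, relative = isTRUE(relative), seed = seed)
  class(out) <- "solver_params"
  out
}

# Magnitude of the objective's per-unit-mass cost at the product-plan start:
# the expression term plus the linearized quadratic terms. Used as the unit
# for relative epsilon/rho, so the marginal and entropy penalties track the
# actual cost scale (the quadratic terms live on the squared-distance scale,
# not the distance scale).
cost_unit <- function(costs, alpha, p1, p2) {
  u <- alpha / 2 * mean(costs$Dg)
  if (alpha < 1) {
    A <- costs$D1 / costs$f1
    B <- costs$D2 / costs$f2
    SA <- costs$S1 / costs$f1
    SB <- costs$S2 / costs$f2
    qmean <- function(A, B) {
      mean(drop((A * A) %*% p1)) + mean(drop((B * B) %*% p2)) -
        2 * mean(drop(A %*% p1)) * mean(drop(B %*% p2))
    }
    u <- u + (1 - alpha) * (qmean(A, B) + qmean(SA, SB))
  }
  max(u, .Machine$double.eps)
}

# Resolve relative scales and default mass vectors against a cost_set.
resolve_params <- function(costs, params) {
  n1 <- nrow(costs$Dg)
  n2 <- ncol(costs$Dg)
  p <- params
  if (is.null(p$p1)) p$p1 <- rep(1 / n1, n1)
  if (is.null(p$p2)) p$p2 <- rep(1 / n2, n2)
  if (length(p$p1) != n1 || length(p$p2) != n2) {
    stop("p1/p2 lengths do not match the cost matrices", call. = FALSE)
  }
  if (any(p$p1 <= 0) || any(p$p2 <= 0)) {
    stop("p1 and p2 must be strictly positive", call. = FALSE)
  }
  if (isTRUE(p$relative)) {
    unit <- cost_unit(costs, p$alpha, p$p1, p$p2)
    p$epsilon <- p$epsilon * unit
    p$rho1 <- p$rho1 * unit
    p$rho2 <- p$rho2 * unit
    p$relative <- FALSE
  }
  p
}

# KL divergence for nonnegative vectors, with mass terms and 0 log 0 = 0.
kl_div <- function(mu, nu) {
  pos <- mu > 0
  sum(mu[pos] * log(mu[pos] / nu[pos])) - sum(mu) + sum(nu)
}

# Tensorized ("quadratic") KL: KL(mu x mu | nu x nu).
kl_quad <- function(mu, nu) {
  m <- sum(mu)
  2 * m * kl_div(mu, nu) + (m - sum(nu))^2
}

# Quadratic GW-type energy sum_{ijkl} (A_ij - B_kl)^2 T_ik T_jl via the
# squared-loss decomposition; A, B symmetric.
quad_energy <- function(A, B, T, r = rowSums(T), cc = colSums(T)) {
  drop(crossprod(r, (A * A) %*% r)) +
    drop(crossprod(cc, (B * B) %*% cc)) -
    2 * sum(T * (A %*% T %*% B))
}

#' Evaluate each term of the transport objective at a given plan
#'
#' Useful for diagnostics and for verifying solver output against
#' independent minimizers. `reg` and `entr` are reported with their weights
#' (`rho`, `epsilon`) included, so
#' `total = alpha * expr + (1 - alpha) * (geom + struct) + reg + entr`.
#'
#' @param costs A `cost_set`.
#' @param params A `solver_params`.
#' @param T An n1 x n2 nonnegative plan matrix.
#' @return List with `expr`, `geom`, `struct`, `reg`, `entr`, `total`.
#' @export
objective_terms <- function(costs, params, T) {
  p <- resolve_params(costs, params)
  A <- costs$D1 / costs$f1
  B <- costs$D2 / costs$f2
  SA <- costs$S1 / costs$f1
  SB <- costs$S2 / costs$f2
  r <- rowSums(T)
  cc <- colSums(T)
  expr <- sum(costs$Dg * T)
  geom <- quad_energy(A, B, T, r, cc)
  struct <- quad_energy(SA, SB, T, r, cc)
  reg <- p$rho1 * kl_quad(r, p$p1) + p$rho2 * kl_quad(cc, p$p2)
  ref <- p$p1 %o% p$p2
  entr <- p$epsilon * kl_quad(as.vector(T), as.vector(ref))
  list(expr = expr, geom = geom, struct = struct, reg = reg, entr = entr,
       total = p$alpha * expr + (1 - p$alpha) * (geom + struct) + reg + entr)
}

#' Solve the structured spatiotemporal transport problem
#'
#' Minimizes the objective described in [solver_params()] by alternating
#' minimization: at each outer iteration the two quadratic terms are
#' linearized around the current plan with the squared-loss decomposition
#' `(a - b)^2 = a^2 + b^2 - 2ab`, the tensorized-KL mass-correction terms are
#' folded into the linear cost, and the resulting entropic unbalanced linear
#' OT subproblem is solved by log-domain scaling iterations (compiled
#' kernel). The fixed point of this scheme is a stationary point of the
#' exact tensorized objective. Initialization is the deterministic product
#' plan `p1 p2'`.
#'
#' @param costs A `cost_set` from [build_cost_set()].
#' @param params A `solver_params`.
#' @return A `transport_plan`: list with the n1 x n2 matrix `T`, `row_mass`,
#'   `col_mass`, `objective_trace` (one total per outer iteration),
#'   `converged`, `iterations`, and the resolved `params`.
#' @export
solve_socs <- function(costs, params = solver_params()) {
  p <- resolve_params(costs, params)
  n1 <- nrow(costs$Dg)
  n2 <- ncol(costs$Dg)
  alpha <- p$alpha
  A <- costs$D1 / costs$f1
  B <- costs$D2 / costs$f2
  SA <- costs$S1 / costs$f1
  SB <- costs$S2 / costs$f2
  A2 <- A * A
  B2 <- B * B
  SA2 <- SA * SA
  SB2 <- SB * SB
  logp1 <- log(p$p1)
  logp2 <- log(p$p2)
  m1 <- sum(p$p1)
  m2 <- sum(p$p2)
  ref <- p$p1 %o% p$p2
  T <- ref
  f <- rep(0, n1)
  g <- rep(0, n2)
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(p$max_iter)) {
    m <- sum(T)
    r <- rowSums(T)
    cc <- colSums(T)
    lin <- alpha / 2 * costs$Dg
    if (alpha < 1) {
      lin <- lin + (1 - alpha) * (
        outer(drop(A2 %*% r), rep(1, n2)) +
          outer(rep(1, n1), drop(B2 %*% cc)) - 2 * (A %*% T %*% B) +
          outer(drop(SA2 %*% r), rep(1, n2)) +
          outer(rep(1, n1), drop(SB2 %*% cc)) - 2 * (SA %*% T %*% SB))
    }
    lam <- p$rho1 * (kl_div(r, p$p1) + (m - m1)) +
      p$rho2 * (kl_div(cc, p$p2) + (m - m2)) +
      p$epsilon * (kl_div(as.vector(T), as.vector(ref)) + (m - m1 * m2))
    C <- lin + lam
    res <- sinkhorn_unbalanced_cpp(C, logp1, logp2,
                                   m * p$epsilon, m * p$rho1, m * p$rho2,
                                   f, g, p$inner_tol, p$inner_max_iter)
    f <- res$f
    g <- res$g
    Tnew <- res$T
    # geometric-mean mass damping (the rescaling step of the iterative
    # unbalanced-GW scheme): kills the period-2 mass oscillation of plain
    # block updates while leaving fixed points untouched
    mn <- sum(Tnew)
    if (is.finite(mn) && mn > 0) {
      s <- sqrt(m / mn)
      Tnew <- Tnew * s
      shift <- m * p$epsilon * log(s) / 2
      f <- f + shift
      g <- g + shift
    }
    if (!all(is.finite(Tnew))) {
      stop(sprintf(paste0(
        "numerical failure at outer iteration %d: non-finite plan entries; ",
        "a larger epsilon usually stabilizes the scaling iterations"), it),
        call. = FALSE)
    }
    iterations <- it
    trace <- c(trace, objective_terms(costs, p, Tnew)$total)
    delta <- frobenius(Tnew - T) / max(frobenius(T), .Machine$double.xmin)
    T <- Tnew
    if (delta < p$tol) {
      converged <- TRUE
      break
    }
  }
  plan <- list(T = T,
               row_mass = rowSums(T),
               col_mass = colSums(T),
               objective_trace = trace,
               converged = converged,
               iterations = iterations,
               params = p)
  class(plan) <- "transport_plan"
  plan
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("transport_plan: %d x %d, total mass %.4g, %s after %d iterations\n",
              nrow(x$T), ncol(x$T), sum(x$T),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (length(x$objective_trace)) {
    cat(sprintf("  objective: %.6g -> %.6g\n",
                x$objective_trace[1], utils::tail(x$objective_trace, 1)))
  }
  invisible(x)
}

#' Serialize a transport plan to an HDF5 container
#'
#' Stores the dense plan, marginals, objective trace and the full parameter
#' record.
#'
#' @param plan A `transport_plan`.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(plan$T, path, "T")
  rhdf5::h5write(plan$row_mass, path, "row_mass")
  rhdf5::h5write(plan$col_mass, path, "col_mass")
  rhdf5::h5write(plan$objective_trace, path, "objective_trace")
  pr <- plan$params
  h5_set_attrs(path, "/", list(
    alpha = pr$alpha, rho1 = pr$rho1, rho2 = pr$rho2, epsilon = pr$epsilon,
    max_iter = pr$max_iter, tol = pr$tol,
    converged = as.integer(plan$converged),
    iterations = plan$iterations,
    seed = if (is.null(pr$seed)) -1L else as.integer(pr$seed)))
  rhdf5::h5write(pr$p1, path, "p1")
  rhdf5::h5write(pr$p2, path, "p2")
  invisible(path)
}

#' Read a transport plan written by [write_plan()]
#' @param path `.h5` path.
#' @return A `transport_plan`.
#' @export
read_plan <- function(path) {
  at <- rhdf5::h5readAttributes(path, "/")
  plan <- list(T = rhdf5::h5read(path, "T"),
               row_mass = as.numeric(rhdf5::h5read(path, "row_mass")),
               col_mass = as.numeric(rhdf5::h5read(path, "col_mass")),
               objective_trace = as.numeric(rhdf5::h5read(path, "objective_trace")),
               converged = as.integer(at$converged) == 1L,
               iterations = as.integer(at$iterations),
               params = list(alpha = as.numeric(at$alpha),
                             rho1 = as.numeric(at$rho1),
                             rho2 = as.numeric(at$rho2),
                             epsilon = as.numeric(at$epsilon),
                             max_iter = as.integer(at$max_iter),
                             tol = as.numeric(at$tol),
                             relative = FALSE,
                             p1 = as.numeric(rhdf5::h5read(path, "p1")),
                             p2 = as.numeric(rhdf5::h5read(path, "p2")),
                             seed = {
                               s <- as.integer(at$seed)
                               if (s < 0) NULL else s
                             }))
  class(plan) <- "transport_plan"
  plan
}

#' Export a plan as sparse triplets
#'
#' Writes a TSV with columns `i`, `j`, `mass` (1-based indices) for entries
#' with mass at or above `threshold`.
#'
#' @param plan A `transport_plan`.
#' @param path Output TSV path.
#' @param threshold Entries below this mass are dropped.
#' @return `path`, invisibly.
#' @export
write_plan_triplets <- function(plan, path, threshold = 1e-12) {
  idx <- which(plan$T >= threshold, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2], mass = plan$T[idx])
  out <- out[order(out$i, out$j), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
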